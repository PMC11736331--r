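---
title: "Quantifying national veterinary antimicrobial consumption from import records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying national veterinary antimicrobial consumption from import records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetamc)
library(dplyr)
```

## The problem

Small island states typically import every veterinary antimicrobial they
use, so border records (a *tier-1* distribution system) are the best
available proxy for national antimicrobial consumption (AMC) in food
animals. `vetamc` implements that surveillance pipeline end to end for
the kind of data a biosecurity authority holds: one row per imported
finished product, with its declared active ingredient, formulation
geometry and pack counts, over a multi-year study window such as Fiji
2017–2021.

The pipeline has four stages:

1. **Quantification** — convert each shipment line to grams of active
   ingredient.
2. **Biomass estimation** — build the national food-animal biomass
   denominator (kg of live weight at risk).
3. **Classification** — partition class totals by WOAH veterinary
   importance (VCIA/VHIA/VIA) and flag WHO critically important
   antimicrobials for human medicine.
4. **Trend analysis** — a Mann–Kendall test on the annual series.

## Quantification model

For a liquid product of strength $s$ (mg/ml) in a container of $v$ ml,
one container holds $sv/1000$ grams of active ingredient; a shipment of
$k$ packs holds $k$ times that. Tablet products contribute
$s_t \cdot n_\text{blisters} \cdot n_\text{tablets}/1000$ grams per
pack, with $s_t$ the strength per tablet in mg. Potency-unit products
(penicillin G for injection is the common case) declare strength in
IU/ml; a compound-specific factor converts to mg/ml first. The bundled
registry carries 0.0006 mg/IU for penicillin G (the international
standard 1 mg ≈ 1667 IU); the factor is data, not code, and can be
overridden per ingredient.

All arithmetic is done in exact double-precision grams. Rounding (half
away from zero, 2 decimals, matching the style of published national
tables) happens only in the report-layer functions `table1_report()`
and `table2_report()`. Combination products are represented as two
records sharing a `record_id` prefix, which keeps the conversion rules
unary. An unknown formulation code is a hard error, never a guessed
default.

Ingredient names are resolved case-insensitively through an explicit
salt-synonym table ("tetracycline hydrochloride" → "tetracycline"),
because import permits declare salts while consumption is reported by
class. A name that fails to resolve is an error that names the
ingredient — records are never silently dropped.

## Biomass denominator

Annual populations are interpolated geometrically between two
agricultural censuses: the compound annual growth rate is
$r = (P_2/P_1)^{1/y} - 1$ over the $y$ years separating them, and
populations for study years are projected from the later census at
constant $r$, kept unrounded (the denominator is continuous).
Per-species conventions:

* **cattle** — interpolated population × live weight, where live
  weight = carcass weight / 0.7 and carcass weight is total slaughter
  weight over head slaughtered (age-structured slaughter proportions
  being unavailable in this setting);
* **sheep and goats** — interpolated population × a 37.5 kg standard
  weight by default. Whether small-ruminant biomass should instead use
  the slaughter-based convention is genuinely open in the source
  method description; both are implemented and `mode = "slaughter"`
  switches basis;
* **pigs and chicken** — annual number slaughtered × live weight
  (carcass weight / 0.78 and / 0.7 respectively). When chicken
  slaughter statistics are missing the generator-documented fallback is
  population × a 2.0 kg standard live weight; that default is our
  assumption, not a value from any national report.

Consumption is standardised as
$\text{mg/kg} = 10^6 \cdot \text{kg imported} / \text{kg biomass}$
per year; the per-study mean and sample standard deviation (always the
$n-1$ convention, which is what published per-year summaries of this
kind use) are attached as attributes.

## Importance classification

Class totals are partitioned by WOAH category. Two percentage
denominators coexist deliberately: within-category shares use the
category total, while the headline "share veterinary-critically
important" uses the *classified* total (VCIA+VHIA+VIA), excluding
classes absent from the WOAH list (nitroimidazoles, reported
separately). This matches the arithmetic of published importance
tables, which exclude unlisted classes from their totals. WHO flags
annotate fluoroquinolones and macrolides as highest-priority CIA and
aminoglycosides and penicillins as high-priority; tetracyclines carry
no CIA flag in human medicine.

## Mann–Kendall trend test

The test is implemented from first principles. The score is
$S = \sum_{i<j}\operatorname{sign}(x_j - x_i)$, $\tau = S / \binom{n}{2}$
(tie-corrected when ties exist), and the null variance is
$[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$. For tie-free series with
$n \le 10$ the default p-value is **exact**: under the null every
ordering is equally likely, and $S$ is a linear function of the
permutation inversion count, whose distribution (the Mahonian numbers)
we compute by dynamic programming; $p = P(|S^*| \ge |S|)$. For longer
or tied series the continuity-corrected normal approximation
$z = (S - \operatorname{sign} S)/\sqrt{\operatorname{var} S}$ is used,
and every result records which method produced it. The two differ
visibly at survey scale: on the bundled five-year Fiji totals the exact
p is $98/120 \approx 0.8167$ while the continuity-corrected normal
value is $\approx 0.806$; published software defaults report the
latter. Constant series return $\tau = 0$, $p = 1$ with a warning
rather than an error.

```{r trend}
annual <- fiji_annual_totals()
mann_kendall(annual$total_kg)
```

## Bundled published totals

The record-level import database behind the Fiji 2017–2021 study is
confidential and not deposited, so the package ships the published
summary layer as fixtures: year-by-class kg cells
(`fiji_annual_class_totals()`), the published annual totals
(`fiji_annual_totals()`), and the study-period class totals
(`fiji_class_totals()`). The printed source table carries typical
rounding artefacts — its margins were computed from unrounded data, so
rounded cells can disagree with printed margins by ~0.01 kg, and one
cell (first-generation cephalosporins, 2018) is entered as 0.01 kg,
the only reading consistent with its printed row total, column total
and percentage. Percentage reproductions from these fixtures are
therefore checked to within 0.01 percentage points rather than by
string equality.

```{r headline}
cells <- fiji_annual_class_totals()
ct <- class_totals(cells)
round_half_up(100 * ct$total_kg / grand_total(cells), 2) |>
  setNames(ct$class)
```

## Synthetic data with provable ground truth

Because the real record-level data cannot be redistributed, correctness
of everything upstream of the summary layer is established on synthetic
data with an exact ledger. `generate_records()` draws per-record target
masses log-normally (defaults `meanlog = 6`, `sdlog = 1.3`, i.e. a
median shipment of ~0.4 kg with heavy right skew), a class mix skewed
to penicillins and tetracyclines as in Pacific import data, a
formulation mix of 70% liquids, 20% blisters, 10% IU-denominated
liquids, and shock multipliers (0.15, 0.2) for 2020–2021 emulating a
pandemic-era import collapse. Each drawn mass is then *back-solved*
into valid geometry — strengths, pack counts and tablet counts chosen
from realistic grids, container volume derived — so that the
quantification equations reproduce the record's grams bit-for-bit, and
the ledger stores the exact (year, class) sums. Aggregating the
quantified records must equal the ledger with zero tolerance; this is
the strongest pipeline test available without real data.
`generate_denominators()` does the analogue for the biomass stage.

The generator emulates the statistical *shape* of import registers
(skew, class dominance, mixed formulations, shocks). It does not
emulate declaration errors, combination products, within-year
seasonality, or illegal imports, so green tests say the arithmetic is
right, not that real-world data entry is clean.

Problem sizes used in the shipped tests — 500-record ledgers, 5000
records for mix recovery, full permutation enumeration up to $n = 7$ —
were chosen as the smallest sizes at which the respective checks are
already conclusive.

```{r synthetic}
cfg <- amc_sim_config(seed = 42, n_per_year = 50)
sim <- generate_records(cfg)
agg <- aggregate_imports(quantify_records(sim$records, load_registry()))
all.equal(agg$kg, sim$ledger$grams / 1000, tolerance = 0)
```

## Known limitations

* The study-period mg/kg series for Fiji (and its 0.86 mg/kg mean)
  depends on supplementary biomass inputs that the main published
  tables do not contain; the package verifies the mg/kg conversion by
  unit properties and construction oracles instead of asserting those
  figures.
* WOAH/WHO list assignments are shipped as edition-stamped data files
  reflecting the study window; they are not kept in live synchrony with
  later list revisions.
* No dose-based metrics (DDDvet/DCDvet): the method is mass-based.
* One national test per run; no multiplicity handling is needed or
  provided.
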