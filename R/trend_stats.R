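#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in a time series. The score
#' is \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)} and Kendall's tau is
#' S over the number of comparable pairs (tie-corrected denominator when
#' ties are present). The null variance is
#' \eqn{[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} summing over tie groups.
#'
#' p-values: for short tie-free series (n <= `exact_limit`) the default
#' is exact enumeration — the null distribution of S follows the Mahonian
#' distribution of permutation inversion counts, computed by dynamic
#' programming, and p = P(|S*| >= |S|). Otherwise (or on request) the
#' normal approximation is used, with continuity correction
#' z = (S - sign(S)) / sqrt(var S) for `"normal-cc"`.
#'
#' @param x numeric series in time order, length >= 3.
#' @param method `"auto"` (exact when n <= `exact_limit` and tie-free,
#'   else normal-cc), `"exact"`, `"normal-cc"`, or `"normal"`.
#' @param exact_limit largest n for which auto uses exact enumeration.
#' @return object of class `mann_kendall`: list with `n`, `S`, `tau`,
#'   `var_S`, `p_value`, `method` (one of EXACT_ENUMERATION, NORMAL_CC,
#'   NORMAL).
#' @export
mann_kendall <- function(x, method = c("auto", "exact", "normal-cc", "normal"),
                         exact_limit = 10) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort_domain("Mann-Kendall needs a series of length >= 3")
  if (any(!is.finite(x))) abort_domain("series values must be finite")

  sgn <- sign(outer(x, x, `-`))
  S <- sum(sgn[lower.tri(sgn)])  # lower.tri: rows j > columns i -> x_j - x_i

  ties <- table(x)
  ties <- ties[ties > 1]
  has_ties <- length(ties) > 0

  n_pairs <- n * (n - 1) / 2
  tie_term <- if (has_ties) sum(ties * (ties - 1)) / 2 else 0
  # tie-corrected tau (tau-b); reduces to S / n_pairs without ties
  denom <- sqrt((n_pairs - tie_term) * n_pairs)
  tau <- if (denom > 0) S / denom else 0

  var_S <- (n * (n - 1) * (2 * n + 5) -
              if (has_ties) sum(ties * (ties - 1) * (2 * ties + 5)) else 0) / 18

  if (stats::sd(x) == 0) {
    rlang::warn("constant series: no trend information (tau = 0, p = 1)")
    out <- list(n = n, S = 0L, tau = 0, var_S = var_S, p_value = 1,
                method = "NORMAL_CC")
    return(structure(out, class = "mann_kendall"))
  }

  if (method == "exact" || (method == "auto" && n <= exact_limit)) {
    if (has_ties) {
      if (method == "exact") {
        rlang::inform("ties present: exact enumeration unavailable, using continuity-corrected normal approximation")
      }
      method_used <- "NORMAL_CC"
      p <- mk_normal_p(S, var_S, continuity = TRUE)
    } else {
      method_used <- "EXACT_ENUMERATION"
      p <- mk_exact_p(S, n)
    }
  } else if (method == "normal") {
    method_used <- "NORMAL"
    p <- mk_normal_p(S, var_S, continuity = FALSE)
  } else {
    method_used <- "NORMAL_CC"
    p <- mk_normal_p(S, var_S, continuity = TRUE)
  }

  structure(list(n = n, S = as.integer(S), tau = tau, var_S = var_S,
                 p_value = p, method = method_used),
            class = "mann_kendall")
}

mk_normal_p <- function(S, var_S, continuity = TRUE) {
  if (var_S <= 0) return(1)
  z <- if (continuity) (S - sign(S)) / sqrt(var_S) else S / sqrt(var_S)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Mahonian counts: permutations of n by inversion number
#'
#' Dynamic-programming convolution of the polynomial
#' \eqn{\prod_{i=1}^{n} (1 + q + \dots + q^{i-1})}; entry k+1 is the
#' number of permutations of n elements with exactly k inversions.
#'
#' @param n number of elements.
#' @return numeric vector of length n(n-1)/2 + 1 summing to n!.
#' @keywords internal
mahonian_counts <- function(n) {
  counts <- 1
  for (i in 2:n) {
    # multiply by (1 + q + ... + q^(i-1)) via cumulative sums
    padded <- c(counts, rep(0, i - 1))
    cs <- cumsum(padded)
    counts <- cs - c(rep(0, i), utils::head(cs, -i))
  }
  counts
}

mk_exact_p <- function(S, n) {
  counts <- mahonian_counts(n)
  max_inv <- n * (n - 1) / 2
  s_values <- max_inv - 2 * (0:max_inv)  # S for a permutation with k inversions
  sum(counts[abs(s_values) >= abs(S)]) / factorial(n)
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall trend test\n  n = %d, S = %d, tau = %.4f\n  var(S) = %.4f, two-sided p = %.4f (%s)\n",
    x$n, x$S, x$tau, x$var_S, x$p_value, x$method))
  invisible(x)
}

#' Mean and sample standard deviation of an annual series
#'
#' @param x numeric vector (n >= 1; sd needs n >= 2 and is `NA` for n = 1).
#' @return named list `mean`, `sd` (sample sd, n - 1 denominator).
#' @export
annual_mean_sd <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) abort_domain("empty series")
  list(mean = mean(x), sd = if (length(x) >= 2) stats::sd(x) else NA_real_)
}

#' Biomass-adjusted consumption (mg of active ingredient per kg biomass)
#'
#' Standardises annual import totals by the national food-animal biomass:
#' mg/kg = (annual kg x 10^6) / biomass kg.
#'
#' @param totals `annual_class_totals`.
#' @param biomass tibble `year`, `biomass_kg` (e.g. from
#'   [national_biomass()]); must cover every year in `totals`.
#' @return tibble `year`, `total_kg`, `biomass_kg`, `mg_per_kg`, with
#'   attributes `mean` and `sd` (sample sd across years).
#' @export
adjust_by_biomass <- function(totals, biomass) {
  yr <- annual_totals(totals)
  missing_years <- setdiff(yr$year, biomass$year)
  if (length(missing_years) > 0) {
    abort_domain("no biomass for year(s): %s",
                 paste(missing_years, collapse = ", "))
  }
  out <- yr |>
    dplyr::left_join(biomass[, c("year", "biomass_kg")], by = "year")
  if (any(!is.finite(out$biomass_kg)) || any(out$biomass_kg <= 0)) {
    abort_domain("biomass must be finite and > 0 for every year")
  }
  out$mg_per_kg <- out$total_kg * 1e6 / out$biomass_kg
  ms <- annual_mean_sd(out$mg_per_kg)
  attr(out, "mean") <- ms$mean
  attr(out, "sd") <- ms$sd
  out
}
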