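# Independent oracles used across tests.

# all permutations of a vector (rows), recursive construction
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# Mann-Kendall score by direct double loop (independent of the package's
# vectorised implementation)
s_stat <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

# exact two-sided p by brute-force enumeration of all orderings
brute_force_mk_p <- function(x) {
  pm <- all_perms(seq_along(x))
  s0 <- s_stat(x)
  svals <- apply(pm, 1, function(p) s_stat(x[p]))
  mean(abs(svals) >= abs(s0))
}

# a small liquid-only record table with hand-computable masses
tiny_records <- function() {
  amc_records(tibble::tibble(
    record_id = c("a", "b", "c"),
    year = c(2017L, 2017L, 2018L),
    ingredient_name = c("penicillin G procaine", "tetracycline hydrochloride",
                        "erythromycin"),
    formulation = c("LIQUID", "LIQUID", "BLISTER"),
    strength = c(200, 100, 500),
    container_volume_ml = c(100, 50, NA),
    tablets_per_blister = c(NA, NA, 10L),
    blisters_per_pack = c(NA, NA, 6L),
    packs = c(12L, 1L, 1L),
    food_animal_indication = TRUE
  ))
}
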