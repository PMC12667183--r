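# Shared fixtures built in code.

# Raw data with exactly the requested group mean and sample SD (n >= 3):
# z-scores are centered/rescaled so the moments match to machine precision.
moment_matched_group <- function(m, s, n) {
  z <- seq_len(n) - (n + 1) / 2
  m + s * z / sd(z)
}

# Long-format records frame for one variable from per-treatment values.
records_from_groups <- function(values_by_trt, variable = "y",
                                depth = "0-20") {
  do.call(rbind, lapply(names(values_by_trt), function(t) {
    v <- values_by_trt[[t]]
    data.frame(treatment = t, replicate = seq_along(v), depth = depth,
               variable = variable, value = v, unit = "",
               stringsAsFactors = FALSE)
  }))
}

# Tiny generator configuration (no community) for fast Monte-Carlo loops.
tiny_config <- function(cv = 0.1, effects = c(1.2, 1.4, 1.6, 1.8),
                        seed = 99) {
  spec <- data.frame(variable = "SOC", unit = "g kg-1",
                     depth = c("0-20", "20-40"), ck_mean = c(20, 15),
                     cv = cv, eff_25 = effects[1], eff_50 = effects[2],
                     eff_75 = effects[3], eff_100 = effects[4],
                     stringsAsFactors = FALSE)
  trial_config(indicator_specs = spec, enzyme_specs = spec[0, ],
               agronomy_specs = default_agronomy_specs()[1:5, ],
               community_spec = NULL, seed = seed)
}

# Random enzyme panel (uniform activities, bounded away from zero).
random_panel <- function() {
  as.list(setNames(runif(6, 5, 200),
                   c("BG", "CB", "XYL", "NAG", "LAP", "ALP")))
}

# Brute-force Mantel: exact one-tailed p over all permutations of d2.
mantel_exact_oracle <- function(d1, d2, method = "pearson") {
  n <- nrow(d1)
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut], method = method)
  perms <- all_permutations(n)
  r_all <- apply(perms, 1, function(p) {
    dp <- d2[p, p]
    cor(d1[ut], dp[ut], method = method)
  })
  # identity permutation is part of the reference set
  sum(r_all >= r_obs) / nrow(perms)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
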