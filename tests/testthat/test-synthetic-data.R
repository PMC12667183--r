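test_that("a fixed seed reproduces the dataset exactly", {
  a <- simulate_trial(trial_config(), seed = 11)
  b <- simulate_trial(trial_config(), seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(a$community$counts, b$community$counts)
  c <- simulate_trial(trial_config(), seed = 12)
  expect_false(identical(a$records$value, c$records$value))
})

test_that("the simulated design is balanced with non-negative values", {
  td <- simulate_trial(trial_config(), seed = 3)
  r <- td$records
  expect_true(all(r$value >= 0))
  # every treatment x depth x variable cell has the same replicate count
  counts <- table(r$treatment, r$depth, r$variable)
  counts <- counts[counts > 0]
  expect_true(all(counts == 3))
  key <- interaction(r$treatment, r$replicate, r$depth, r$variable)
  expect_false(anyDuplicated(key) > 0)
})

test_that("control yield draws recover the configured mean", {
  set.seed(42)
  cfg <- trial_config()
  ck <- unlist(lapply(1:200, function(i) {
    td <- simulate_trial(tiny_config(seed = i), seed = i)
    trial_values(td, "yield", "plot")$value[
      trial_values(td, "yield", "plot")$treatment == "CK"]
  }))
  se <- 0.83 / sqrt(length(ck))
  expect_lt(abs(mean(ck) - 11.3), 3 * se)
})

test_that("degenerate noise with unit effects collapses all means onto the control", {
  cfg <- tiny_config(cv = 1e-9, effects = c(1, 1, 1, 1))
  td <- simulate_trial(cfg, seed = 5)
  v <- trial_values(td, "SOC", "0-20")
  m <- tapply(v$value, v$treatment, mean)
  expect_equal(as.vector(m), rep(20, 5), tolerance = 1e-6)
})

test_that("empirical moments match the configured ones at large n", {
  cfg <- tiny_config(cv = 0.1)
  cfg$replicates <- 20000L
  td <- simulate_trial(cfg, seed = 7, community = FALSE)
  v <- trial_values(td, "SOC", "0-20")
  vals <- v$value[v$treatment == "50%"]
  expect_gt(length(vals), 1000)
  expect_lt(abs(mean(vals) / (20 * 1.4) - 1), 0.02)
  expect_lt(abs(sd(vals) / (0.1 * 20 * 1.4) - 1), 0.02)
})

test_that("invalid configurations are rejected with named offenders", {
  spec <- default_indicator_specs()
  spec$cv[1] <- -0.1
  expect_error(trial_config(indicator_specs = spec), "variation")
  spec <- default_indicator_specs()
  spec$depth[1] <- "40-60"
  expect_error(trial_config(indicator_specs = spec), "40-60")
  cs <- default_community_spec()
  cs$means$mean[1] <- cs$means$mean[1] + 0.5
  expect_error(trial_config(community_spec = cs), "sum to 1")
  expect_error(trial_config(community_spec = default_community_spec(reads = 0)),
               "depth")
})

test_that("large Dirichlet concentration pins compositions to the configured means", {
  # deep sequencing so multinomial read noise does not mask the
  # concentration limit of the Dirichlet proportions themselves
  cfg <- trial_config(community_spec = default_community_spec(
    concentration = 1e6, n_taxa_per_phylum = 1, reads = 1e6))
  comm <- simulate_community(cfg, seed = 8)
  prop <- relative_abundance(comm, level = "phylum")
  ms <- cfg$community_spec$means
  for (j in seq_len(ncol(prop))) {
    md <- comm$metadata[j, ]
    mv <- ms[ms$treatment == md$treatment & ms$depth == md$depth, ]
    expect_lt(max(abs(prop[mv$phylum, j] - mv$mean)), 0.01)
  }
})

test_that("a configured enrichment is recovered over many samples", {
  # 1.25x Actinomycetota in all substitution treatments at both depths
  cs <- default_community_spec(concentration = 500)
  base <- cs$means[cs$means$treatment == "CK", ]
  for (t in c("25%", "50%", "75%", "100%")) for (d in unique(base$depth)) {
    b <- base[base$depth == d, ]
    mv <- b$mean
    mv[b$phylum == "Actinomycetota"] <- 1.25 * mv[b$phylum == "Actinomycetota"]
    mv <- mv / sum(mv)
    sel <- cs$means$treatment == t & cs$means$depth == d
    cs$means$mean[sel] <- mv[match(cs$means$phylum[sel], b$phylum)]
  }
  cfg <- trial_config(replicates = 25, community_spec = cs)
  comm <- simulate_community(cfg, seed = 21)
  prop <- relative_abundance(comm, level = "phylum")
  act <- prop["Actinomycetota", ]
  grp <- comm$metadata$treatment == "CK"
  d020 <- comm$metadata$depth == "0-20"
  ratio_configured <- with(cs, {
    a <- means$mean[means$phylum == "Actinomycetota" & means$depth == "0-20"]
    mean(a[-1]) / a[1]
  })
  ratio_seen <- mean(act[!grp & d020]) / mean(act[grp & d020])
  expect_lt(abs(ratio_seen - ratio_configured), 0.08)
})

test_that("a single phylum with mean one takes every read", {
  cs <- default_community_spec(n_taxa_per_phylum = 1)
  cs$means$mean <- ifelse(cs$means$phylum == "Actinomycetota", 1, 0)
  cfg <- trial_config(community_spec = cs)
  comm <- simulate_community(cfg, seed = 2)
  expect_true(all(colSums(comm$counts) == 10000))
  expect_true(all(comm$counts["Actinomycetota_t1", ] == 10000))
})
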