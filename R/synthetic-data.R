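#' Default indicator specification for the synthetic trial generator
#'
#' One row per physicochemical indicator x depth: the control-plot mean,
#' coefficient of variation, and multiplicative treatment effects for the
#' four substitution rates.  Control means for SOC, AHN, BD and pH come from
#' the trial site's measured topsoil baseline (SOC 21.9 g kg^-1, AHN 99.8
#' mg kg^-1, BD 1.58 g cm^-3); the remaining baselines are typical values
#' for a Mollisol maize field.  Treatment effects are parameterized from the
#' published percent-change ranges per depth, interpolated linearly from the
#' 25% to the 100% substitution rate; indicators with no reported response
#' at a depth get effect 1.
#'
#' @return Data frame with columns `variable`, `unit`, `depth`, `ck_mean`,
#'   `cv`, `eff_25`, `eff_50`, `eff_75`, `eff_100`.
#' @export
default_indicator_specs <- function() {
  # effect endpoints (25% -> 100%) per depth; 1 = no reported change
  spec <- list(
    #         unit        ck020  ck2040  eff020        eff2040
    SOC = list("g kg-1",   21.9, 16.0, c(1.06, 1.10), c(1.00, 1.00)),
    TN  = list("g kg-1",   1.90, 1.30, c(1.00, 1.00), c(0.98, 0.83)),
    AHN = list("mg kg-1",  99.8, 70.0, c(1.00, 1.00), c(1.00, 1.00)),
    AP  = list("mg kg-1",  22.0, 12.0, c(1.22, 1.59), c(0.58, 0.40)),
    AK  = list("mg kg-1", 180.0, 130.0, c(1.00, 1.00), c(0.83, 0.65)),
    DOC = list("mg kg-1", 150.0, 100.0, c(1.00, 1.00), c(1.00, 1.00)),
    DON = list("mg kg-1",  30.0, 20.0, c(0.77, 0.69), c(0.55, 0.48)),
    MBC = list("mg kg-1", 280.0, 140.0, c(1.28, 1.42), c(1.92, 2.12)),
    MBN = list("mg kg-1",  40.0, 18.0, c(1.32, 2.12), c(1.28, 1.59)),
    BD  = list("g cm-3",   1.58, 1.62, c(1.00, 1.00), c(0.92, 0.86)),
    SW  = list("%",        22.0, 19.0, c(1.05, 1.22), c(1.06, 1.22))
  )
  .expand_specs(spec, cv = 0.08)
}

#' Default enzyme-activity specification for the synthetic trial generator
#'
#' Same layout as [default_indicator_specs()] for the six C/N/P-acquiring
#' hydrolases (BG, CB, XYL carbon; NAG, LAP nitrogen; ALP phosphorus).
#' Control activities are typical fluorometric values (nmol g^-1 h^-1) for
#' temperate cropland; treatment effects follow the published per-depth
#' percent-change ranges (strong gains in the 0-20 cm layer; C/N hydrolases
#' suppressed but LAP and ALP raised at 20-40 cm).
#'
#' @return Data frame with the same columns as [default_indicator_specs()].
#' @export
default_enzyme_specs <- function() {
  spec <- list(
    BG  = list("nmol g-1 h-1", 60, 30, c(1.15, 1.67), c(0.54, 0.32)),
    CB  = list("nmol g-1 h-1", 15,  8, c(2.38, 3.39), c(0.88, 0.60)),
    XYL = list("nmol g-1 h-1", 20, 10, c(1.579, 2.17), c(0.72, 0.41)),
    NAG = list("nmol g-1 h-1", 25, 12, c(1.52, 1.74), c(0.60, 0.47)),
    LAP = list("nmol g-1 h-1", 30, 15, c(2.12, 2.85), c(1.67, 2.55)),
    ALP = list("nmol g-1 h-1", 80, 40, c(1.78, 2.25), c(1.27, 2.18))
  )
  .expand_specs(spec, cv = 0.10)
}

# expand the compact per-variable list into the long spec data frame,
# interpolating the (25%, 100%) effect endpoints across the four rates
.expand_specs <- function(spec, cv) {
  rows <- lapply(names(spec), function(v) {
    s <- spec[[v]]
    ck <- c(s[[2]], s[[3]])
    effs <- rbind(s[[4]], s[[5]])
    w <- seq(0, 1, length.out = 4) # 25, 50, 75, 100
    eff <- t(apply(effs, 1, function(e) e[1] + w * (e[2] - e[1])))
    data.frame(variable = v, unit = s[[1]], depth = .depth_levels,
               ck_mean = ck, cv = cv,
               eff_25 = eff[, 1], eff_50 = eff[, 2],
               eff_75 = eff[, 3], eff_100 = eff[, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default agronomic specification (yield and root traits)
#'
#' Per-treatment means and standard deviations for grain yield, root
#' biomass, root length, root surface area and root volume, exactly as
#' reported for the five-treatment trial (n = 3 plots per treatment).
#' These traits are measured per plot, not per depth.
#'
#' @return Data frame with columns `variable`, `unit`, `treatment`, `mean`,
#'   `sd`.
#' @export
default_agronomy_specs <- function() {
  vars <- list(
    yield        = list("Mg ha-1",            c(11.3, 11.7, 10.3, 8.35, 4.03),
                        c(0.83, 1.46, 0.69, 1.22, 0.35)),
    root_biomass = list("g plant-1",          c(19.2, 18.4, 15.5, 16.4, 13.5),
                        c(2.02, 0.97, 1.03, 1.41, 1.39)),
    root_length  = list("1e3 cm plant-1",     c(5.86, 5.12, 4.99, 4.92, 3.32),
                        c(0.86, 0.66, 0.43, 0.42, 0.34)),
    root_surface = list("1e2 cm2 plant-1",    c(13.9, 12.6, 10.2, 11.9, 7.09),
                        c(2.44, 1.69, 1.44, 1.93, 1.23)),
    root_volume  = list("cm3 plant-1",        c(26.2, 24.9, 15.6, 21.5, 12.2),
                        c(5.63, 3.75, 1.88, 3.28, 3.38))
  )
  rows <- lapply(names(vars), function(v) {
    s <- vars[[v]]
    data.frame(variable = v, unit = s[[1]], treatment = .treatment_levels,
               mean = s[[2]], sd = s[[3]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default phylum-level community specification
#'
#' Dirichlet mean composition per treatment x depth over the eleven most
#' abundant soil bacterial phyla (plus an "Other" bin).  The control
#' composition is a typical cropland topsoil profile; treatment effects are
#' multiplicative enrichments/depletions following the reported per-depth
#' directions (topsoil: Actinomycetota, Acidobacteriota, Gemmatimonadota
#' and Methylomirabilota enriched, Bacteroidota, Chloroflexota and
#' Pseudomonadota depleted; subsoil: Pseudomonadota, Acidobacteriota and
#' Bacillota enriched, Actinomycetota depleted), interpolated from the 25%
#' to the 100% rate and renormalized to sum to one.
#'
#' @param concentration Dirichlet concentration parameter controlling
#'   sample-to-sample compositional variability (default 200; larger is
#'   tighter).
#' @param n_taxa_per_phylum Number of synthetic taxa each phylum is split
#'   into (default 5).
#' @param reads Sequencing depth: multinomial total per sample (default
#'   10000).
#' @return List with elements `means` (data frame: `phylum`, `treatment`,
#'   `depth`, `mean`, rows summing to 1 within each treatment x depth),
#'   `concentration`, `n_taxa_per_phylum`, `reads`.
#' @export
default_community_spec <- function(concentration = 200,
                                   n_taxa_per_phylum = 5,
                                   reads = 10000) {
  ck <- list(
    # phylum                base020 base2040  eff020        eff2040
    Pseudomonadota   = list(0.30, 0.28, c(0.87, 0.71), c(1.05, 1.06)),
    Actinomycetota   = list(0.24, 0.26, c(1.14, 1.28), c(0.88, 0.80)),
    Acidobacteriota  = list(0.12, 0.13, c(1.12, 1.35), c(1.11, 1.18)),
    Chloroflexota    = list(0.10, 0.09, c(0.85, 0.76), c(1.00, 1.00)),
    Bacteroidota     = list(0.06, 0.05, c(0.79, 0.43), c(1.00, 1.00)),
    Gemmatimonadota  = list(0.05, 0.05, c(1.64, 1.88), c(1.00, 1.00)),
    Bacillota        = list(0.04, 0.05, c(1.00, 1.00), c(1.12, 1.21)),
    Planctomycetota  = list(0.03, 0.03, c(1.00, 1.00), c(1.00, 1.00)),
    Methylomirabilota = list(0.02, 0.02, c(1.55, 2.01), c(1.00, 1.00)),
    Verrucomicrobiota = list(0.02, 0.02, c(1.00, 1.00), c(1.00, 1.00)),
    Other            = list(0.02, 0.02, c(1.00, 1.00), c(1.00, 1.00))
  )
  w <- seq(0, 1, length.out = 4)
  rows <- list()
  for (d in seq_along(.depth_levels)) {
    base <- vapply(ck, function(s) s[[d]], numeric(1))
    effs <- vapply(ck, function(s) s[[d + 2L]], numeric(2))
    for (t in seq_along(.treatment_levels)) {
      if (t == 1L) {
        mv <- base
      } else {
        e <- effs[1, ] + w[t - 1L] * (effs[2, ] - effs[1, ])
        mv <- base * e
      }
      mv <- mv / sum(mv)
      rows[[length(rows) + 1L]] <- data.frame(
        phylum = names(ck), treatment = .treatment_levels[t],
        depth = .depth_levels[d], mean = unname(mv),
        stringsAsFactors = FALSE)
    }
  }
  means <- do.call(rbind, rows)
  rownames(means) <- NULL
  list(means = means, concentration = concentration,
       n_taxa_per_phylum = n_taxa_per_phylum, reads = reads)
}

#' Configuration object for the synthetic trial generator
#'
#' Bundles the experimental layout (treatments, replicates, depth layers)
#' with the distributional specifications of every variable block.  The
#' defaults emulate a five-rate manure-substitution trial: a randomized
#' complete block design with 3 replicate plots per treatment, sampled at
#' 0-20 and 20-40 cm.
#'
#' @param treatments Ordered treatment labels.
#' @param replicates Plots per treatment (default 3).
#' @param depths Ordered depth-layer labels.
#' @param indicator_specs Physicochemical spec table
#'   (see [default_indicator_specs()]).
#' @param enzyme_specs Enzyme spec table (see [default_enzyme_specs()]).
#' @param agronomy_specs Yield/root spec table
#'   (see [default_agronomy_specs()]).
#' @param community_spec Phylum composition spec
#'   (see [default_community_spec()]), or `NULL` to skip the community.
#' @param block_sd Standard deviation of an optional additive replicate
#'   (block) effect, expressed as a fraction of each variable's mean scale;
#'   0 (default) disables block effects.
#' @param seed Default random seed used by [simulate_trial()] when no seed
#'   is passed explicitly.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(treatments = .treatment_levels,
                         replicates = 3,
                         depths = .depth_levels,
                         indicator_specs = default_indicator_specs(),
                         enzyme_specs = default_enzyme_specs(),
                         agronomy_specs = default_agronomy_specs(),
                         community_spec = default_community_spec(),
                         block_sd = 0,
                         seed = 20240101) {
  cfg <- structure(
    list(treatments = treatments, replicates = as.integer(replicates),
         depths = .normalize_depth(depths),
         indicator_specs = indicator_specs, enzyme_specs = enzyme_specs,
         agronomy_specs = agronomy_specs, community_spec = community_spec,
         block_sd = block_sd, seed = seed),
    class = "trial_config")
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (cfg$replicates < 1L) stop("`replicates` must be >= 1")
  for (nm in c("indicator_specs", "enzyme_specs")) {
    s <- cfg[[nm]]
    need <- c("variable", "depth", "ck_mean", "cv",
              "eff_25", "eff_50", "eff_75", "eff_100")
    miss <- setdiff(need, names(s))
    if (length(miss)) stop(nm, " is missing columns: ",
                           paste(miss, collapse = ", "))
    if (any(s$cv <= 0)) stop(nm, ": coefficients of variation must be > 0")
    bad <- setdiff(.normalize_depth(s$depth), cfg$depths)
    if (length(bad)) stop(nm, ": unknown depth label(s): ",
                          paste(bad, collapse = ", "))
  }
  ag <- cfg$agronomy_specs
  bad <- setdiff(unique(ag$treatment), cfg$treatments)
  if (length(bad)) stop("agronomy_specs names treatment(s) not in the ",
                        "design: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$community_spec)) {
    cs <- cfg$community_spec
    if (cs$concentration <= 0) stop("community concentration must be > 0")
    if (cs$reads < 1) stop("community sequencing depth must be >= 1")
    sums <- tapply(cs$means$mean,
                   interaction(cs$means$treatment, cs$means$depth),
                   sum)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("community mean compositions must sum to 1 within 1e-9")
    }
  }
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat("  treatments: ", paste(x$treatments, collapse = ", "), "\n", sep = "")
  cat("  replicates: ", x$replicates,
      "   depths: ", paste(x$depths, collapse = ", "), "\n", sep = "")
  cat("  indicators: ", length(unique(x$indicator_specs$variable)),
      "   enzymes: ", length(unique(x$enzyme_specs$variable)),
      "   agronomic traits: ", length(unique(x$agronomy_specs$variable)),
      "\n", sep = "")
  cat("  community: ",
      if (is.null(x$community_spec)) "none" else
        paste0(length(unique(x$community_spec$means$phylum)), " phyla, ",
               x$community_spec$reads, " reads/sample"),
      "   seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate one trial dataset
#'
#' Draws a balanced plot-level dataset with the configured design.  Each
#' soil variable is Normal with mean = control mean x treatment effect (per
#' depth) and SD = cv x mean; agronomic traits use their explicit
#' per-treatment means and SDs.  Negative draws are truncated at zero.
#' An optional additive replicate (block) effect with SD `block_sd` x mean
#' can be enabled in the configuration.  Fully reproducible for a fixed
#' seed.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param community Also draw a taxon count table (default `TRUE` when the
#'   configuration carries a community spec)?
#' @return An object of class `trial_data`: a list with `records` (long
#'   data frame: `treatment`, `replicate`, `depth`, `variable`, `value`,
#'   `unit`) and `community` (a `community_table` or `NULL`).
#' @export
#' @examples
#' td <- simulate_trial(trial_config(), seed = 1)
#' head(td$records)
simulate_trial <- function(config = trial_config(), seed = config$seed,
                           community = !is.null(config$community_spec)) {
  .validate_config(config)
  set.seed(seed)
  trt <- config$treatments
  reps <- seq_len(config$replicates)
  depths <- config$depths

  soil <- rbind(config$indicator_specs, config$enzyme_specs)
  soil$depth <- .normalize_depth(soil$depth)
  eff_cols <- paste0("eff_", c(25, 50, 75, 100))

  # block effects: one multiplicative-scale draw per replicate x variable
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(soil))) {
    s <- soil[i, ]
    effects <- c(1, as.numeric(s[eff_cols]))[seq_along(trt)]
    block <- if (config$block_sd > 0)
      rnorm(length(reps), 0, config$block_sd * s$ck_mean) else
      numeric(length(reps))
    for (t in seq_along(trt)) {
      mu <- s$ck_mean * effects[t]
      val <- rnorm(length(reps), mu, s$cv * mu) + block
      val <- pmax(val, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = trt[t], replicate = reps, depth = s$depth,
        variable = s$variable, value = val, unit = s$unit,
        stringsAsFactors = FALSE)
    }
  }

  ag <- config$agronomy_specs
  for (v in unique(ag$variable)) {
    sv <- ag[ag$variable == v, ]
    for (t in seq_along(trt)) {
      st <- sv[sv$treatment == trt[t], ]
      if (nrow(st) != 1L) stop("agronomy spec for '", v,
                               "' missing treatment ", trt[t])
      val <- pmax(rnorm(length(reps), st$mean, st$sd), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = trt[t], replicate = reps, depth = "plot",
        variable = v, value = val, unit = st$unit,
        stringsAsFactors = FALSE)
    }
  }

  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  comm <- NULL
  if (isTRUE(community)) {
    if (is.null(config$community_spec)) {
      stop("community requested but the configuration has no community_spec")
    }
    comm <- .draw_community(config)
  }
  structure(list(records = records, community = comm), class = "trial_data")
}

#' Simulate only the taxon count table
#'
#' @inheritParams simulate_trial
#' @return A `community_table`: list with `counts` (taxon x sample integer
#'   matrix), `metadata` (sample data frame with `treatment`, `replicate`,
#'   `depth`) and `taxonomy` (two-column taxon -> phylum map).
#' @export
simulate_community <- function(config = trial_config(), seed = config$seed) {
  .validate_config(config)
  if (is.null(config$community_spec)) stop("configuration has no community_spec")
  set.seed(seed)
  .draw_community(config)
}

# Dirichlet draw via independent gammas
.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1 # degenerate tiny-alpha guard
  g / sum(g)
}

.draw_community <- function(config) {
  cs <- config$community_spec
  phyla <- unique(cs$means$phylum)
  k <- cs$n_taxa_per_phylum
  taxa <- paste0(rep(phyla, each = k), "_t", seq_len(k))
  taxonomy <- data.frame(taxon = taxa, phylum = rep(phyla, each = k),
                         stringsAsFactors = FALSE)
  # fixed within-phylum split, drawn once per dataset
  split_w <- lapply(phyla, function(p) .rdirichlet(rep(2, k)))
  names(split_w) <- phyla

  meta <- expand.grid(replicate = seq_len(config$replicates),
                      treatment = config$treatments,
                      depth = config$depths,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("treatment", "replicate", "depth")]
  sample_id <- sprintf("%s_r%d_%s", meta$treatment, meta$replicate,
                       gsub("[^0-9A-Za-z]", "", meta$depth))
  counts <- matrix(0L, nrow = length(taxa), ncol = nrow(meta),
                   dimnames = list(taxa, sample_id))
  for (j in seq_len(nrow(meta))) {
    mv <- cs$means[cs$means$treatment == meta$treatment[j] &
                     .normalize_depth(cs$means$depth) == meta$depth[j], ]
    mv <- mv$mean[match(phyla, mv$phylum)]
    prop_phy <- .rdirichlet(cs$concentration * mv)
    prop_tax <- unlist(lapply(seq_along(phyla), function(i)
      prop_phy[i] * split_w[[i]]))
    counts[, j] <- as.integer(rmultinom(1, size = cs$reads, prob = prop_tax))
  }
  structure(list(counts = counts, metadata = cbind(sample = sample_id, meta),
                 taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d taxa x %d samples (%d phyla)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$phylum))))
  invisible(x)
}

#' @export
print.trial_data <- function(x, ...) {
  r <- x$records
  cat(sprintf(paste0("Trial dataset: %d treatments x %d replicates, ",
                     "%d variables, %d rows\n"),
              length(unique(r$treatment)),
              length(unique(r$replicate)),
              length(unique(r$variable)), nrow(r)))
  if (!is.null(x$community)) print(x$community)
  invisible(x)
}

#' Extract one variable of a trial dataset as a wide analysis frame
#'
#' @param data A `trial_data` object or its `records` data frame.
#' @param variable Variable name to extract.
#' @param depth Optional depth-layer filter (use `"plot"` for per-plot
#'   agronomic traits).
#' @return Data frame with `treatment`, `replicate`, `depth`, `value`.
#' @export
trial_values <- function(data, variable, depth = NULL) {
  r <- if (inherits(data, "trial_data")) data$records else data
  out <- r[r$variable == variable, c("treatment", "replicate", "depth",
                                     "value")]
  if (!nrow(out)) stop("variable '", variable, "' not present in the dataset")
  if (!is.null(depth)) {
    out <- out[out$depth == .normalize_depth(depth), ]
    if (!nrow(out)) stop("variable '", variable, "' has no rows at depth '",
                         depth, "'")
  }
  rownames(out) <- NULL
  out
}
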