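#' Read a trial table from CSV
#'
#' Accepts either the long layout (`treatment`, `replicate`, `depth`,
#' `variable`, `value`, optional `unit`) or a wide layout (`treatment`,
#' `replicate`, `depth`, one column per variable), auto-detected from the
#' header.  Depth labels are normalized to ASCII (`"0-20"`, `"20-40"`,
#' `"plot"`).  Duplicate (treatment, replicate, depth, variable) keys and
#' non-numeric values are rejected with informative errors.
#'
#' @param path CSV file path.
#' @return A `trial_data` object (without a community table).
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("treatment", "replicate", "depth")
  miss <- setdiff(base_cols, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$depth <- .normalize_depth(df$depth)

  if (all(c("variable", "value") %in% names(df))) {
    rec <- df
    if (!"unit" %in% names(rec)) rec$unit <- ""
    bad <- which(!is.finite(suppressWarnings(as.numeric(rec$value))))
    if (length(bad)) stop("non-numeric value in row(s): ",
                          paste(utils::head(bad, 5), collapse = ", "))
    rec$value <- as.numeric(rec$value)
    rec <- rec[, c("treatment", "replicate", "depth", "variable", "value",
                   "unit")]
  } else {
    vars <- setdiff(names(df), c(base_cols, "unit"))
    if (!length(vars)) stop("no variable columns found in wide layout")
    rec <- do.call(rbind, lapply(vars, function(v) {
      val <- suppressWarnings(as.numeric(df[[v]]))
      bad <- which(is.na(val) & !is.na(df[[v]]))
      if (length(bad)) stop("non-numeric value for '", v, "' in row(s): ",
                            paste(utils::head(bad, 5), collapse = ", "))
      data.frame(treatment = df$treatment, replicate = df$replicate,
                 depth = df$depth, variable = v, value = val, unit = "",
                 stringsAsFactors = FALSE)
    }))
    rec <- rec[!is.na(rec$value), ]
  }
  key <- interaction(rec$treatment, rec$replicate, rec$depth, rec$variable,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (treatment, replicate, depth, variable) key(s): ",
         paste(utils::head(unique(as.character(key[duplicated(key)])), 3),
               collapse = ", "))
  }
  rownames(rec) <- NULL
  structure(list(records = rec, community = NULL), class = "trial_data")
}

#' Write trial records to a long-format CSV
#'
#' @param data A `trial_data` object or records data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  r <- if (inherits(data, "trial_data")) data$records else data
  write.csv(r, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on one dataset
#'
#' Executes, in order: data simulation (or ingestion), the fertilizer
#' design table, per-trait one-way ANOVA and letter displays, two-way
#' ANOVA for the soil variables, the radar-area SQI, stoichiometry
#' vectors, community summaries (phylum relative abundance, Simpson
#' diversity, Bray-Curtis + PERMANOVA), and the driver analysis.  All
#' stochastic stages run under the single `seed`, so identical inputs give
#' identical outputs.
#'
#' @param data A `trial_data`, or `NULL` (default) to simulate one from
#'   `config`.
#' @param config A [trial_config()] used when simulating.
#' @param seed Integer seed governing simulation, permutations and forests.
#' @param out_dir Optional directory; when given, every stage result is
#'   written as CSV together with a `manifest.csv` recording the seed and
#'   stage row counts.
#' @param n_perm Permutations for Mantel/PERMANOVA (default 199).
#' @param n_null Null refits for importance (default 50).
#' @param n_trees Trees per forest (default 300).
#' @return Named list with elements `data`, `design`, `agronomy_anova`,
#'   `two_way`, `sqi`, `vectors`, `community`, `permanova`, `drivers`.
#' @export
run_all <- function(data = NULL, config = trial_config(), seed = config$seed,
                    out_dir = NULL, n_perm = 199, n_null = 50,
                    n_trees = 300) {
  if (is.null(data)) data <- simulate_trial(config, seed = seed)
  stopifnot(inherits(data, "trial_data"))

  design <- fertilizer_table()

  ag_vars <- intersect(unique(data$records$variable[data$records$depth ==
                                                      "plot"]),
                       unique(data$records$variable))
  agronomy <- lapply(setNames(ag_vars, ag_vars), function(v) {
    vals <- trial_values(data, v, depth = "plot")
    a <- anova_from_raw(data, v, depth = "plot")
    ms <- aggregate(value ~ treatment, vals, mean)
    ss <- aggregate(value ~ treatment, vals, sd)
    let <- tukey_letters(ms$value, ss$value,
                         n = nrow(vals) / nrow(ms), labels = ms$treatment)
    list(anova = a, means = ms, letters = let)
  })

  soil_vars <- unique(data$records$variable[data$records$depth != "plot"])
  two_way <- lapply(setNames(soil_vars, soil_vars),
                    function(v) two_way_anova(data, v))

  sq <- sqi(data)
  vectors <- stoich_vectors(data)

  comm_sum <- NULL; pmv <- NULL
  if (!is.null(data$community)) {
    comm_sum <- community_summary(data$community)
    bc <- bray_curtis(data$community)
    pmv <- lapply(setNames(unique(comm_sum$depth), unique(comm_sum$depth)),
                  function(d) {
                    sel <- comm_sum$depth == d
                    permanova(bc[sel, sel], comm_sum$treatment[sel],
                              n_perm = n_perm, seed = seed)
                  })
  }

  drv <- driver_report(data, n_perm = n_perm, n_null = n_null,
                       n_trees = n_trees, seed = seed)

  out <- list(data = data, design = design, agronomy_anova = agronomy,
              two_way = two_way, sqi = sq, vectors = vectors,
              community = comm_sum, permanova = pmv, drivers = drv)

  if (!is.null(out_dir)) .write_bundle(out, out_dir, seed)
  out
}

.write_bundle <- function(out, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
    nrow(df)
  }
  n <- c(
    records = w(out$data$records, "records.csv"),
    design = w(out$design, "design.csv"),
    sqi = w(out$sqi$samples, "sqi.csv"),
    vectors = w(out$vectors, "vectors.csv"),
    two_way = w(do.call(rbind, lapply(names(out$two_way), function(v)
      cbind(variable = v, out$two_way[[v]]))), "two_way_anova.csv"),
    agronomy = w(do.call(rbind, lapply(names(out$agronomy_anova),
      function(v) {
        a <- out$agronomy_anova[[v]]
        data.frame(variable = v, treatment = a$means$treatment,
                   mean = a$means$value, letters = unname(a$letters),
                   F = a$anova$F, p = a$anova$p)
      })), "agronomy_anova.csv")
  )
  if (!is.null(out$community)) {
    n <- c(n, community = w(out$community, "community_summary.csv"))
  }
  imp <- do.call(rbind, lapply(names(out$drivers$result), function(d) {
    do.call(rbind, lapply(names(out$drivers$result[[d]]), function(rn)
      cbind(depth = d, response = rn,
            as.data.frame(out$drivers$result[[d]][[rn]]$importance))))
  }))
  n <- c(n, drivers = w(imp, "driver_importance.csv"))
  manifest <- data.frame(stage = names(n), rows = as.integer(n),
                         seed = seed)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}
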