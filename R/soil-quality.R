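#' Direction-aware linear (min-max) indicator scoring
#'
#' Rescales one indicator to \[0, 1\] across the samples supplied.  With
#' `direction = "more"` (more of the indicator is better) the score is
#' (x - min) / (max - min); with `"less"` it is (max - x) / (max - min).
#' Scoring is meant to be applied within a single depth layer — the
#' min/max are taken over exactly the values passed in, never pooled
#' across layers.
#'
#' A constant column carries no ranking information; rather than dropping
#' the indicator (which would change the radar geometry between layers) all
#' its scores are set to the neutral value 0.5 and a warning is raised.
#'
#' @param x Numeric vector of indicator values (>= 2 samples).
#' @param direction `"more"` (default) or `"less"`.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
#' @examples
#' linear_score(c(2, 4, 6))            # 0.0 0.5 1.0
#' linear_score(c(2, 4, 6), "less")    # 1.0 0.5 0.0
linear_score <- function(x, direction = c("more", "less")) {
  direction <- match.arg(direction)
  if (length(x) < 2L) stop("linear scoring needs at least 2 samples")
  if (anyNA(x)) stop("indicator values contain NA")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant indicator column: all scores set to the neutral 0.5")
    return(rep(0.5, length(x)))
  }
  s <- (x - rng[1]) / (rng[2] - rng[1])
  if (direction == "less") s <- 1 - s
  s
}

#' Radar-area soil quality index
#'
#' Computes the area-style soil quality index from a vector of linear
#' indicator scores: `SQI = 0.5 * sum(SL_i^2) * sin(2*pi/n)`, where `n` is
#' the number of indicators.  Each spoke contributes its own squared score,
#' so the index is invariant to indicator ordering and bounded by
#' `0.5 * n * sin(2*pi/n)` (all scores 1).
#'
#' A literal radar-polygon area would multiply adjacent spokes
#' (`SL_i * SL_{i+1}`); that variant is order-sensitive and available via
#' `method = "polygon"`, but the squared-spoke form is the default index.
#'
#' @param scores Numeric vector of scores in \[0, 1\], length >= 3.
#' @param method `"squared"` (default) or `"polygon"`.
#' @return Single numeric index value.
#' @export
#' @examples
#' sqi_area(c(1, 0.5, 0.25, 0.75))  # 0.9375
sqi_area <- function(scores, method = c("squared", "polygon")) {
  method <- match.arg(method)
  n <- length(scores)
  if (n < 3L) stop("the radar geometry needs at least 3 indicators, got ", n)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1] with no NA")
  }
  if (method == "squared") {
    0.5 * sum(scores^2) * sin(2 * pi / n)
  } else {
    0.5 * sum(scores * scores[c(2:n, 1)]) * sin(2 * pi / n)
  }
}

#' Per-depth soil quality index pipeline
#'
#' Scores each indicator within each depth layer across all samples of that
#' layer, computes the per-sample radar-area index, and summarizes treatment
#' means together with percent change relative to the reference treatment.
#'
#' @param data A `trial_data` object or a long records data frame
#'   (`treatment`, `replicate`, `depth`, `variable`, `value`).
#' @param indicators Character vector of indicator variables entering the
#'   index; defaults to every soil variable present at all depths (the
#'   physicochemical set plus the six enzymes).
#' @param directions Named character vector mapping indicators to `"more"`
#'   or `"less"`; unnamed default is `"more"` for every indicator.  The
#'   direction of bulk density or dissolved organic N is a substantive
#'   choice — pass e.g. `c(BD = "less")` for a sensitivity run.
#' @param reference Reference treatment for percent change (default "CK").
#' @param method Passed to [sqi_area()].
#' @return Object of class `sqi_result`: list with `samples` (per-sample
#'   data frame: `treatment`, `replicate`, `depth`, `sqi`), `scores`
#'   (per-sample per-indicator score table), `treatment_means` (mean SQI and
#'   percent change vs the reference per treatment x depth), `n_indicators`.
#' @export
sqi <- function(data, indicators = NULL, directions = NULL,
                reference = "CK", method = c("squared", "polygon")) {
  method <- match.arg(method)
  r <- if (inherits(data, "trial_data")) data$records else data
  r <- r[r$depth != "plot", ]
  r$depth <- .normalize_depth(r$depth)
  depths <- unique(r$depth)

  if (is.null(indicators)) {
    # variables observed at every depth layer
    tab <- table(unique(r[, c("variable", "depth")])$variable)
    indicators <- names(tab)[tab == length(depths)]
  }
  missing <- vapply(depths, function(d)
    paste(setdiff(indicators, r$variable[r$depth == d]), collapse = ", "),
    character(1))
  if (any(nzchar(missing))) {
    stop("indicator(s) absent at depth ",
         paste0(depths[nzchar(missing)], " (", missing[nzchar(missing)], ")",
                collapse = "; "))
  }
  n <- length(indicators)
  dir <- setNames(rep("more", n), indicators)
  if (!is.null(directions)) {
    unknown <- setdiff(names(directions), indicators)
    if (length(unknown)) stop("directions given for unknown indicator(s): ",
                              paste(unknown, collapse = ", "))
    dir[names(directions)] <- directions
  }

  samples <- list(); score_rows <- list()
  for (d in depths) {
    rd <- r[r$depth == d & r$variable %in% indicators, ]
    wide <- reshape_wide(rd)
    sc <- wide[, c("treatment", "replicate", "depth")]
    for (v in indicators) {
      sc[[v]] <- linear_score(wide[[v]], dir[[v]])
    }
    sc$sqi_value <- apply(as.matrix(sc[, indicators]), 1, sqi_area,
                          method = method)
    score_rows[[d]] <- sc
    samples[[d]] <- sc[, c("treatment", "replicate", "depth", "sqi_value")]
  }
  samples <- do.call(rbind, samples)
  names(samples)[names(samples) == "sqi_value"] <- "sqi"
  rownames(samples) <- NULL

  tm <- aggregate(sqi ~ treatment + depth, samples, mean)
  ref <- tm[tm$treatment == reference, c("depth", "sqi")]
  tm$pct_change_vs_ref <- mapply(function(trt, dep, v) {
    rv <- ref$sqi[ref$depth == dep]
    if (!length(rv)) return(NA_real_)
    percent_change(rv, v)
  }, tm$treatment, tm$depth, tm$sqi)
  # preserve design order
  trts <- unique(r$treatment)
  tm <- tm[order(match(tm$depth, depths), match(tm$treatment, trts)), ]
  rownames(tm) <- NULL

  structure(list(samples = samples,
                 scores = do.call(rbind, score_rows),
                 treatment_means = tm,
                 indicators = indicators, directions = dir,
                 n_indicators = n, method = method,
                 reference = reference),
            class = "sqi_result")
}

#' @export
print.sqi_result <- function(x, digits = 3, ...) {
  cat(sprintf("Radar-area soil quality index (%d indicators, %s spokes)\n",
              x$n_indicators,
              if (x$method == "squared") "squared" else "polygon"))
  tm <- x$treatment_means
  tm$sqi <- round(tm$sqi, digits)
  tm$pct_change_vs_ref <- round(tm$pct_change_vs_ref, 1)
  print(tm, row.names = FALSE)
  invisible(x)
}

# long (treatment, replicate, depth, variable, value) -> wide, one column
# per variable; errors on duplicate keys
reshape_wide <- function(r) {
  key <- interaction(r$treatment, r$replicate, r$depth, r$variable,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (treatment, replicate, depth, variable) rows: ",
         paste(unique(as.character(key[duplicated(key)]))[1:3],
               collapse = ", "))
  }
  out <- reshape(r[, c("treatment", "replicate", "depth", "variable",
                       "value")],
                 idvar = c("treatment", "replicate", "depth"),
                 timevar = "variable", direction = "wide")
  names(out) <- sub("^value\\.", "", names(out))
  rownames(out) <- NULL
  out
}
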