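#' One-way ANOVA reconstructed from published group summaries
#'
#' Recovers the exact one-way ANOVA from per-group means, standard
#' deviations and a common replicate count — the situation when only a
#' summary table ("means +/- SD, n = 3") is available.  For k equal-sized
#' groups,
#' \deqn{MSB = n \sum_i (m_i - \bar m)^2 / (k - 1), \qquad
#'       MSW = \sum_i SD_i^2 / k,}
#' and `F = MSB/MSW` on (k - 1, k(n - 1)) degrees of freedom.  This equals
#' the ANOVA computed from any raw dataset with those group moments.
#'
#' @param means Per-group means.
#' @param sds Per-group standard deviations (sample SD, denominator n - 1).
#' @param n Replicates per group (equal-n design).
#' @param labels Optional group labels.
#' @return Object of class `anova_recon`: list with `F`, `df`, `p`, `MSB`,
#'   `MSW`, `k`, `n`, `groups`.
#' @export
#' @examples
#' # grain yield of a five-treatment trial, n = 3 plots each
#' anova_from_summary(c(11.3, 11.7, 10.3, 8.35, 4.03),
#'                    c(0.83, 1.46, 0.69, 1.22, 0.35), n = 3)
anova_from_summary <- function(means, sds, n, labels = NULL) {
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  if (length(sds) != k) stop("`means` and `sds` lengths differ")
  if (n < 2L) stop("need at least 2 replicates per group")
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  MSB <- n * sum((means - mean(means))^2) / (k - 1)
  MSW <- sum(sds^2) / k
  df1 <- k - 1
  df2 <- k * (n - 1)
  if (MSW == 0) {
    if (MSB > 0) { F <- Inf; p <- 0 } else { F <- 0; p <- 1 }
  } else {
    F <- MSB / MSW
    p <- pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = F, df = c(df1, df2), p = p, MSB = MSB, MSW = MSW,
                 k = k, n = n,
                 groups = if (is.null(labels)) as.character(seq_len(k))
                          else labels),
            class = "anova_recon")
}

#' One-way ANOVA from raw trial data
#'
#' Standard fixed-effects one-way decomposition of one variable across
#' treatments (delegating to [stats::aov()]), returned in the same
#' `anova_recon` form as the summary-statistics path — the two agree
#' exactly on matched moments.
#'
#' @param data A `trial_data` object or long records data frame.
#' @param variable Variable to analyze.
#' @param depth Depth layer (`"plot"` for agronomic traits, which is the
#'   default when the variable only exists at plot level).
#' @return An `anova_recon` object.
#' @export
anova_from_raw <- function(data, variable, depth = NULL) {
  v <- trial_values(data, variable,
                    depth = depth %||% .default_depth(data, variable))
  n <- table(v$treatment)
  if (length(unique(n)) == 1L) {
    # balanced: identical to the summary-statistics reconstruction applied
    # to the empirical group moments (which also handles zero-variance data)
    m <- tapply(v$value, v$treatment, mean)
    s <- tapply(v$value, v$treatment, sd)
    return(anova_from_summary(as.vector(m), as.vector(s), unname(n[1]),
                              labels = names(m)))
  }
  fit <- aov(value ~ factor(treatment), data = v)
  tab <- anova(fit)
  structure(list(F = tab$`F value`[1], df = tab$Df, p = tab$`Pr(>F)`[1],
                 MSB = tab$`Mean Sq`[1], MSW = tab$`Mean Sq`[2],
                 k = length(n), n = NA_integer_,
                 groups = names(n)),
            class = "anova_recon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_depth <- function(data, variable) {
  r <- if (inherits(data, "trial_data")) data$records else data
  d <- unique(r$depth[r$variable == variable])
  if (length(d) == 1L) d else NULL
}

#' @export
print.anova_recon <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%d groups, df = %d, %d)\n",
              x$k, x$df[1], x$df[2]))
  cat(sprintf("  F = %.3f   p %s\n", x$F, format_p(x$p)))
  invisible(x)
}

#' Format a p-value in the three-decimal reporting style
#'
#' @param p Numeric p-value(s).
#' @return Character: `"<0.001"` below that threshold, otherwise the value
#'   rounded to three decimals (prefixed `"= "`).
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("= %.3f", p))
}

#' Two-way fixed-effects ANOVA: treatment, depth, and their interaction
#'
#' @param data A `trial_data` object or long records data frame.
#' @param variable Soil variable present at both depth layers.
#' @return Data frame with one row per term (`treatment`, `depth`,
#'   `treatment:depth`, `residuals`): `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(data, variable) {
  v <- trial_values(data, variable)
  v <- v[v$depth != "plot", ]
  if (length(unique(v$depth)) < 2L) {
    # degenerate to the one-way decomposition when only one layer exists
    fit <- aov(value ~ factor(treatment), data = v)
    tab <- anova(fit)
    return(data.frame(term = c("treatment", "residuals"),
                      df = tab$Df, sum_sq = tab$`Sum Sq`,
                      mean_sq = tab$`Mean Sq`, F = tab$`F value`,
                      p = tab$`Pr(>F)`, stringsAsFactors = FALSE))
  }
  fit <- aov(value ~ factor(treatment) * factor(depth), data = v)
  tab <- anova(fit)
  out <- data.frame(
    term = c("treatment", "depth", "treatment:depth", "residuals"),
    df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
    F = tab$`F value`, p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compact letter display from group summaries
#'
#' All-pairs comparisons at level `alpha` using the pooled within-group
#' mean square from the summary statistics, followed by the
#' insert-and-absorb construction of a compact letter display: groups are
#' processed in decreasing mean order and letters assigned so that two
#' groups share a letter if and only if their pairwise test is
#' non-significant.
#'
#' Two criteria are available: `"tukey"` (studentized range, HSD) and
#' `"lsd"` (Fisher's least significant difference, pairwise t).
#'
#' @inheritParams anova_from_summary
#' @param alpha Significance level (default 0.05).
#' @param method `"tukey"` (default) or `"lsd"`.
#' @return Named character vector of letter strings, in input order.
#' @export
#' @examples
#' tukey_letters(c(11.3, 11.7, 10.3, 8.35, 4.03),
#'               c(0.83, 1.46, 0.69, 1.22, 0.35), n = 3,
#'               labels = c("CK", "25%", "50%", "75%", "100%"))
tukey_letters <- function(means, sds, n, labels = NULL, alpha = 0.05,
                          method = c("tukey", "lsd")) {
  method <- match.arg(method)
  k <- length(means)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  a <- anova_from_summary(means, sds, n, labels)
  df2 <- a$df[2]
  se_diff <- sqrt(2 * a$MSW / n)
  crit <- switch(method,
    tukey = qtukey(1 - alpha, k, df2) * sqrt(a$MSW / n),
    lsd = qt(1 - alpha / 2, df2) * se_diff)
  diffmat <- abs(outer(means, means, "-")) > crit
  letters_from_sigmat(diffmat, means, labels)
}

# Insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = significantly different).  Guarantees: a significant pair
# never shares a letter; a non-significant pair always shares one.
letters_from_sigmat <- function(sig, means, labels) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  # columns = letter classes, membership over groups in mean order
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    gi <- ord[i]; gj <- ord[j]
    if (!sig[gi, gj]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[gi] && col[gj]) {
        c1 <- col; c1[gj] <- FALSE
        c2 <- col; c2[gi] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb duplicated / subset columns
    keep <- rep(TRUE, length(cols))
    for (aI in seq_along(cols)) for (bI in seq_along(cols)) {
      if (aI != bI && keep[aI] && keep[bI] &&
          all(cols[[aI]] | !cols[[bI]]) && any(cols[[aI]] != cols[[bI]])) {
        keep[bI] <- FALSE
      } else if (aI < bI && keep[aI] && keep[bI] &&
                 all(cols[[aI]] == cols[[bI]])) {
        keep[bI] <- FALSE
      }
    }
    cols <- cols[keep]
  }
  # order letter classes by the best (highest-mean) group they contain
  first <- vapply(cols, function(col) min(match(which(col), ord)),
                  numeric(1))
  cols <- cols[order(first)]
  out <- vapply(seq_len(k), function(g)
    paste0(letters[which(vapply(cols, `[`, logical(1), g))], collapse = ""),
    character(1))
  setNames(out, labels)
}

#' Percent change relative to a reference
#'
#' @param reference Reference (e.g. control) mean; must be nonzero.
#' @param value Treatment mean(s).
#' @return Signed percent change(s), `(value - reference)/reference * 100`.
#' @export
#' @examples
#' percent_change(5.86, 3.32)  # -43.3 (to one decimal)
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference mean must be nonzero")
  (value - reference) / reference * 100
}

#' Range of percent changes across a treatment subset
#'
#' Convenience for statements like "substitution decreased root length by
#' 14.8%-43.3%": returns the min and max absolute percent change of the
#' listed treatments relative to the reference.
#'
#' @param reference Reference mean.
#' @param values Named vector of treatment means.
#' @param treatments Subset of names to include (default all).
#' @return Numeric `c(min, max)` of `abs(percent change)`, one decimal.
#' @export
percent_change_range <- function(reference, values, treatments = NULL) {
  if (!is.null(treatments)) values <- values[treatments]
  pc <- round(abs(percent_change(reference, values)), 1)
  c(min = min(pc), max = max(pc))
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] that flags degenerate
#' (constant) input explicitly instead of erroring opaquely.
#'
#' @param x Numeric sample, 3 <= length <= 5000.
#' @return List with `statistic`, `p`, and `degenerate` flag.
#' @export
normality_check <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L) {
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  s <- shapiro.test(x)
  list(statistic = unname(s$statistic), p = s$p.value, degenerate = FALSE)
}
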