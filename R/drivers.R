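#' Euclidean distance on z-scored variables
#'
#' Standard feature-block-to-distance construction for Mantel analysis:
#' each column is centered and scaled to unit SD, then pairwise Euclidean
#' distances are taken.  Constant columns are dropped with a warning
#' (scaling is undefined for them).
#'
#' @param X Numeric sample x variable matrix or data frame.
#' @return Symmetric sample x sample distance matrix.
#' @export
dist_euclidean_z <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!ncol(X)) stop("no non-constant columns left")
  as.matrix(stats::dist(scale(X)))
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices and
#' assesses the correlation against a null distribution built by applying
#' the same random permutation to the rows and columns of the second
#' matrix.  The one-tailed p uses the add-one rule
#' `p = (1 + #permuted r >= observed) / (1 + n_perm)`, so it can never be
#' zero.
#'
#' @param d1,d2 Square symmetric matrices (or `dist`) of equal dimension
#'   with zero diagonals.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param permutations Optional explicit permutation matrix (rows = sample
#'   index permutations) replacing random sampling — e.g. all `n!`
#'   permutations for an exact test on a small matrix.
#' @return Object of class `mantel_test`: list with `r`, `p`, `n_perm`,
#'   `method`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL, permutations = NULL) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!isTRUE(all.equal(dim(d1), dim(d2)))) stop("dimension mismatch")
  if (nrow(d1) != ncol(d1)) stop("matrices must be square")
  for (m in list(d1, d2)) {
    if (max(abs(m - t(m))) > 1e-8) stop("distance matrices must be symmetric")
  }
  n <- nrow(d1)
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut], method = method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(permutations)) {
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  r_null <- apply(permutations, 1, function(p) {
    dp <- d2[p, p]
    cor(d1[ut], dp[ut], method = method)
  })
  np <- nrow(permutations)
  p <- (1 + sum(r_null >= r_obs)) / (1 + np)
  structure(list(r = r_obs, p = p, n_perm = np, method = method),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.3f, p %s (%d permutations)\n",
              x$method, x$r, format_p(x$p), x$n_perm))
  invisible(x)
}

#' Random-forest permutation importance with response-permutation p-values
#'
#' Fits a random forest regression (via [randomForest::randomForest()])
#' and reports each feature's permutation importance: the mean increase in
#' out-of-bag MSE when that feature's values are shuffled.  Feature-level
#' significance follows the response-permutation scheme: the forest is
#' refitted `n_null` times with the response vector permuted, giving a
#' null importance distribution per feature, and
#' `p = (1 + #null >= observed) / (1 + n_null)`.
#'
#' @param X Sample x feature matrix or data frame (>= 8 samples, no
#'   missing values).
#' @param y Numeric response per sample; must not be constant.
#' @param n_trees Trees per forest (default 500).
#' @param n_null Null refits (default 100).
#' @param seed Optional integer seed covering fit and null refits.
#' @return Object of class `perm_importance`: data frame with `feature`,
#'   `importance` (raw OOB MSE increase), `p`, ordered by decreasing
#'   importance; attributes `n_null`, `rsq`.
#' @export
permutation_importance <- function(X, y, n_trees = 500, n_null = 100,
                                   seed = NULL) {
  X <- as.data.frame(X)
  if (nrow(X) < 8L) stop("need at least 8 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (length(y) != nrow(X)) stop("response length does not match X")
  if (var(y) == 0) stop("constant response: no variance to explain")
  if (!is.null(seed)) set.seed(seed)
  imp_of <- function(resp) {
    fit <- randomForest::randomForest(X, resp, ntree = n_trees,
                                      importance = TRUE)
    list(imp = randomForest::importance(fit, type = 1, scale = FALSE)[, 1],
         rsq = fit$rsq[n_trees])
  }
  obs <- imp_of(y)
  null_imp <- vapply(seq_len(n_null),
                     function(i) imp_of(sample(y))$imp,
                     numeric(ncol(X)))
  if (is.null(dim(null_imp))) null_imp <- matrix(null_imp, nrow = 1)
  p <- (1 + rowSums(null_imp >= obs$imp)) / (1 + n_null)
  out <- data.frame(feature = colnames(X), importance = unname(obs$imp),
                    p = unname(p), stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  structure(out, class = c("perm_importance", "data.frame"),
            n_null = n_null, rsq = obs$rsq)
}

#' @export
print.perm_importance <- function(x, digits = 3, ...) {
  cat(sprintf("Permutation importance (%d null refits, OOB R2 = %.2f)\n",
              attr(x, "n_null"), attr(x, "rsq")))
  df <- as.data.frame(x)
  df$importance <- signif(df$importance, digits)
  df$stars <- p_stars(df$p)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Significance stars at the conventional thresholds
#'
#' @param p Numeric p-value(s).
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   otherwise `""`.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Driver analysis for yield and soil quality
#'
#' Assembles the per-depth feature matrix (physicochemical indicators,
#' enzyme activities, stoichiometry vector length and angle), then for each
#' response runs (i) featurewise Pearson (or Spearman) correlations with
#' significance stars, (ii) a Mantel test between the z-scored feature
#' block distance and the response distance, and (iii) random-forest
#' permutation importance with response-permutation p-values.
#'
#' Per-plot responses such as grain yield are replicated over the depth
#' layers so that each depth's feature block is compared against the same
#' plot-level outcome.
#'
#' @param data A `trial_data` object.
#' @param responses Named list of per-sample response vectors, or the
#'   default `NULL` to use grain yield (from the dataset) and the SQI (from
#'   [sqi()] on the same dataset).
#' @param depths Depth layers to analyze (default: all soil layers
#'   present).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param n_perm Mantel permutations (default 999).
#' @param n_null Importance null refits (default 100).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed for all stochastic stages.
#' @return Object of class `driver_report`: nested list
#'   `result[[depth]][[response]]` with elements `correlations` (data
#'   frame: feature, r, p, stars), `mantel` (a `mantel_test`), and
#'   `importance` (a `perm_importance`).
#' @export
driver_report <- function(data, responses = NULL, depths = NULL,
                          cor_method = c("pearson", "spearman"),
                          n_perm = 999, n_null = 100, n_trees = 500,
                          seed = 1) {
  cor_method <- match.arg(cor_method)
  stopifnot(inherits(data, "trial_data"))
  r <- data$records
  r$depth <- .normalize_depth(r$depth)
  soil_depths <- setdiff(unique(r$depth), "plot")
  depths <- if (is.null(depths)) soil_depths else .normalize_depth(depths)

  vec <- stoich_vectors(data)
  sq <- sqi(data)
  set.seed(seed)

  out <- list()
  for (d in depths) {
    rd <- r[r$depth == d, ]
    wide <- reshape_wide(rd)
    key <- paste(wide$treatment, wide$replicate)
    vd <- vec[vec$depth == d, ]
    feat <- wide[, setdiff(names(wide), c("treatment", "replicate",
                                          "depth")), drop = FALSE]
    feat$vector_length <- vd$length[match(key, paste(vd$treatment,
                                                     vd$replicate))]
    feat$vector_angle <- vd$angle[match(key, paste(vd$treatment,
                                                   vd$replicate))]

    resp <- responses
    if (is.null(resp)) {
      yld <- trial_values(data, "yield", depth = "plot")
      sqd <- sq$samples[sq$samples$depth == d, ]
      resp <- list(
        yield = yld$value[match(key, paste(yld$treatment, yld$replicate))],
        sqi = sqd$sqi[match(key, paste(sqd$treatment, sqd$replicate))])
    }

    per_resp <- list()
    for (rn in names(resp)) {
      y <- resp[[rn]]
      keep <- !vapply(feat, function(col) sd(col) == 0, logical(1))
      Xf <- feat[, keep, drop = FALSE]
      cors <- vapply(Xf, function(col) {
        ct <- stats::cor.test(col, y, method = cor_method, exact = FALSE)
        c(ct$estimate, ct$p.value)
      }, numeric(2))
      correlations <- data.frame(
        feature = colnames(Xf), r = cors[1, ], p = cors[2, ],
        stars = p_stars(cors[2, ]), stringsAsFactors = FALSE)
      correlations <- correlations[order(-abs(correlations$r)), ]
      rownames(correlations) <- NULL
      mant <- mantel_test(dist_euclidean_z(Xf),
                          as.matrix(stats::dist(y)),
                          method = cor_method, n_perm = n_perm)
      imp <- permutation_importance(Xf, y, n_trees = n_trees,
                                    n_null = n_null)
      per_resp[[rn]] <- list(correlations = correlations, mantel = mant,
                             importance = imp)
    }
    out[[d]] <- per_resp
  }
  structure(list(result = out, cor_method = cor_method, seed = seed),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, top = 5, ...) {
  for (d in names(x$result)) {
    for (rn in names(x$result[[d]])) {
      blk <- x$result[[d]][[rn]]
      cat(sprintf("== depth %s, response %s ==\n", d, rn))
      print(blk$mantel)
      cat(sprintf("top %d features by permutation importance:\n", top))
      print(utils::head(as.data.frame(blk$importance), top),
            row.names = FALSE)
    }
  }
  invisible(x)
}
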