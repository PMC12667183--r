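#' Phylum nomenclature aliases
#'
#' Taxonomic sources mix pre- and post-2021 phylum names.  This table maps
#' the older names onto the current nomenclature so aggregated tables line
#' up regardless of the reference database used.
#'
#' @return Named character vector, old name -> current name.
#' @export
phylum_aliases <- function() {
  c(Actinobacteriota = "Actinomycetota",
    Actinobacteria   = "Actinomycetota",
    Proteobacteria   = "Pseudomonadota",
    Acidobacteria    = "Acidobacteriota",
    Chloroflexi      = "Chloroflexota",
    Bacteroidetes    = "Bacteroidota",
    Firmicutes       = "Bacillota",
    Gemmatimonadetes = "Gemmatimonadota",
    Planctomycetes   = "Planctomycetota",
    Verrucomicrobia  = "Verrucomicrobiota",
    Methylomirabiliota = "Methylomirabilota")
}

.normalize_phylum <- function(x) {
  al <- phylum_aliases()
  hit <- x %in% names(al)
  x[hit] <- al[x[hit]]
  x
}

.as_counts <- function(x) {
  if (inherits(x, "community_table")) x$counts else as.matrix(x)
}

#' Relative abundance per sample, optionally aggregated to phylum
#'
#' @param comm A `community_table` (see [simulate_community()]) or a taxon
#'   x sample count matrix.
#' @param level `"taxon"` or `"phylum"` (phylum needs a `community_table`
#'   or an explicit `taxonomy` map).
#' @param taxonomy Optional two-column data frame (`taxon`, `phylum`) when
#'   `comm` is a bare matrix.
#' @return Matrix of proportions with the same sample columns; each column
#'   sums to 1.
#' @export
relative_abundance <- function(comm, level = c("taxon", "phylum"),
                               taxonomy = NULL) {
  level <- match.arg(level)
  counts <- .as_counts(comm)
  if (any(colSums(counts) <= 0)) stop("every sample must have total count > 0")
  if (level == "phylum") {
    if (is.null(taxonomy) && inherits(comm, "community_table")) {
      taxonomy <- comm$taxonomy
    }
    if (is.null(taxonomy)) stop("phylum aggregation needs a taxonomy map")
    phy <- .normalize_phylum(
      taxonomy$phylum[match(rownames(counts), taxonomy$taxon)])
    phy[is.na(phy)] <- "unclassified"
    counts <- rowsum(counts, group = phy)
  }
  sweep(counts, 2, colSums(counts), "/")
}

#' Simpson diversity of a count or proportion vector
#'
#' Gini-Simpson form `1 - sum(p_i^2)`: the probability that two reads
#' drawn at random belong to different taxa.  The inverse-Simpson variant
#' `1 / sum(p_i^2)` is available via `variant`.
#'
#' @param x Non-negative counts or proportions for one sample, or a taxon x
#'   sample matrix (returns one value per sample column).
#' @param variant `"gini-simpson"` (default) or `"inverse"`.
#' @return Numeric diversity value(s).
#' @export
#' @examples
#' simpson_index(c(0.5, 0.3, 0.2))  # 0.62
simpson_index <- function(x, variant = c("gini-simpson", "inverse")) {
  variant <- match.arg(variant)
  if (is.matrix(x) || inherits(x, "community_table")) {
    counts <- .as_counts(x)
    return(apply(counts, 2, simpson_index, variant = variant))
  }
  if (any(x < 0)) stop("counts/proportions must be non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("total count must be > 0")
  D <- sum((x / tot)^2)
  if (variant == "gini-simpson") 1 - D else 1 / D
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' Counts are converted to within-sample relative abundances first (no
#' rarefaction), then `BC(u, v) = sum|u_i - v_i| / sum(u_i + v_i)` is
#' computed for every pair via [vegan::vegdist()].
#'
#' @param comm A `community_table` or taxon x sample count matrix.
#' @return Symmetric sample x sample matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(comm) {
  counts <- .as_counts(comm)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  prop <- relative_abundance(counts)
  as.matrix(vegan::vegdist(t(prop), method = "bray"))
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate ANOVA: partitions the squared
#' dissimilarities among/within groups, forms the pseudo-F, and assesses
#' it against group-label permutations (delegated to [vegan::adonis2()]).
#' The reported p follows the add-one rule
#' `p = (1 + #permuted F >= observed) / (1 + n_perm)`.
#'
#' @param d Square symmetric dissimilarity matrix or `dist`.
#' @param groups Group label per sample.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed for reproducibility.
#' @param permutations Optional explicit permutation matrix (rows =
#'   permutations of sample indices); overrides `n_perm`, e.g. for full
#'   enumeration on small problems.
#' @return Object of class `permanova`: list with `F`, `R2`, `df`, `p`,
#'   `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) {
    stop("`groups` length does not match the dissimilarity matrix")
  }
  if (is.null(permutations) && n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  perm <- permutations %||% n_perm
  df <- data.frame(g = groups)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = perm)
  structure(list(F = fit$F[1], R2 = fit$R2[1],
                 df = c(fit$Df[1], fit$Df[2]),
                 p = fit$`Pr(>F)`[1],
                 n_perm = if (is.matrix(perm)) nrow(perm) else n_perm),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.3f, p %s (%d permutations)\n",
              x$F, x$df[1], x$df[2], x$R2, format_p(x$p), x$n_perm))
  invisible(x)
}

#' Per-sample community summary table
#'
#' Convenience wrapper joining sample metadata with Gini-Simpson diversity
#' and phylum-level relative abundances.
#'
#' @param comm A `community_table`.
#' @return Data frame: metadata columns, `simpson`, then one column per
#'   phylum with its relative abundance.
#' @export
community_summary <- function(comm) {
  stopifnot(inherits(comm, "community_table"))
  prop <- relative_abundance(comm, level = "phylum")
  out <- cbind(comm$metadata,
               simpson = simpson_index(comm$counts),
               as.data.frame(t(prop)))
  rownames(out) <- NULL
  out
}
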