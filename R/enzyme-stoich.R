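#' Ecoenzymatic stoichiometry vector from one enzyme panel
#'
#' Summarizes the relative microbial investment in C- vs N- and
#' P-acquisition from the six hydrolase activities.  With
#' `C = BG + CB + XYL` (carbon), `N = NAG + LAP` (nitrogen) and `P = ALP`
#' (phosphorus), the point
#' \deqn{x = C / (C + P), \qquad y = C / (C + N)}
#' is formed and summarized as
#' \deqn{length = \sqrt{x^2 + y^2}, \qquad
#'       angle = \mathrm{Degrees}(\mathrm{atan2}(y, x)).}
#'
#' The two-argument arctangent follows the spreadsheet convention in which
#' the first listed proportion (C vs P) is the x-coordinate, so larger
#' phosphatase activity (P demand) pushes the angle above 45 degrees and
#' larger N-acquisition pushes it below.  By convention a longer vector
#' indicates stronger relative C demand.  The raw sum of squares
#' `x^2 + y^2` is returned as a diagnostic alongside the rooted length.
#'
#' @param BG,CB,XYL,NAG,LAP,ALP Enzyme activities (nmol g^-1 h^-1), each
#'   a scalar or vectors of common length.  `CB`/`XYL` are also known as
#'   CE/BX; `ALP` as ACP.
#' @return Data frame with columns `x`, `y`, `length`, `length_sq`,
#'   `angle` (degrees).
#' @export
#' @examples
#' enzyme_vector(BG = 50, CB = 25, XYL = 25, NAG = 50, LAP = 50, ALP = 300)
enzyme_vector <- function(BG, CB, XYL, NAG, LAP, ALP) {
  act <- cbind(BG = BG, CB = CB, XYL = XYL, NAG = NAG, LAP = LAP, ALP = ALP)
  if (anyNA(act)) stop("enzyme activities contain NA")
  if (any(act < 0)) stop("enzyme activities must be non-negative")
  C <- act[, "BG"] + act[, "CB"] + act[, "XYL"]
  N <- act[, "NAG"] + act[, "LAP"]
  P <- act[, "ALP"]
  if (any(C <= 0)) {
    stop("C-acquisition sum BG + CB + XYL must be > 0: ",
         "the stoichiometry vector is undefined without C-acquiring activity")
  }
  x <- C / (C + P)
  y <- C / (C + N)
  data.frame(x = x, y = y,
             length = sqrt(x^2 + y^2),
             length_sq = x^2 + y^2,
             angle = atan2(y, x) * 180 / pi)
}

#' Vector length of an enzyme panel
#'
#' @inheritParams enzyme_vector
#' @return Numeric vector of lengths in (0, sqrt(2)].
#' @export
vector_length <- function(BG, CB, XYL, NAG, LAP, ALP) {
  enzyme_vector(BG, CB, XYL, NAG, LAP, ALP)$length
}

#' Vector angle of an enzyme panel, in degrees
#'
#' @inheritParams enzyme_vector
#' @return Numeric vector of angles in (0, 90); 45 when ALP = NAG + LAP.
#' @export
vector_angle <- function(BG, CB, XYL, NAG, LAP, ALP) {
  enzyme_vector(BG, CB, XYL, NAG, LAP, ALP)$angle
}

#' Stoichiometry vectors for every sample of a trial dataset
#'
#' Extracts the six enzyme activities per (treatment, replicate, depth) and
#' computes the per-sample stoichiometry vector.  `ACP` is accepted as an
#' alias for `ALP`, and `CE`/`BX` for `CB`/`XYL`.  Samples missing any of
#' the six activities are skipped with a warning naming them.
#'
#' @param data A `trial_data` object or long records data frame.
#' @return Data frame with `treatment`, `replicate`, `depth`, `x`, `y`,
#'   `length`, `length_sq`, `angle`.
#' @export
stoich_vectors <- function(data) {
  r <- if (inherits(data, "trial_data")) data$records else data
  alias <- c(ACP = "ALP", CE = "CB", BX = "XYL")
  hit <- r$variable %in% names(alias)
  r$variable[hit] <- alias[r$variable[hit]]
  r <- r[r$variable %in% .enzyme_names, ]
  if (!nrow(r)) stop("no enzyme activity variables found in the dataset")
  r$depth <- .normalize_depth(r$depth)
  wide <- reshape_wide(r)
  have <- intersect(.enzyme_names, names(wide))
  if (length(have) < 6L) {
    stop("enzyme variable(s) absent from the dataset: ",
         paste(setdiff(.enzyme_names, have), collapse = ", "))
  }
  complete <- stats::complete.cases(wide[, .enzyme_names])
  if (any(!complete)) {
    bad <- wide[!complete, ]
    warning(sum(!complete), " sample(s) skipped for missing enzymes: ",
            paste(sprintf("%s/r%s/%s", bad$treatment, bad$replicate,
                          bad$depth), collapse = ", "))
    wide <- wide[complete, ]
  }
  v <- enzyme_vector(wide$BG, wide$CB, wide$XYL, wide$NAG, wide$LAP,
                     wide$ALP)
  out <- cbind(wide[, c("treatment", "replicate", "depth")], v)
  rownames(out) <- NULL
  out
}
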