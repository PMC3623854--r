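#' Orthogonalize area deprivation and neighbour deprivation
#'
#' An area's deprivation index and the mean deprivation of its neighbours
#' are strongly collinear, which makes their separate effects on a health
#' outcome hard to identify. A principal-components rotation of the pair
#' (IMD, ALD) yields two exactly uncorrelated predictors: the first
#' component ("target area deprivation") captures the shared level of
#' deprivation of the area and its surroundings; the second ("deprivation
#' differential") is positive when the area is more deprived than its
#' neighbours and negative when it sits among more deprived surroundings.
#'
#' By default the rotation is the eigendecomposition of the 2x2 covariance
#' matrix of the mean-centred, unstandardized pair; `mode = "correlation"`
#' standardizes both variables first (for two variables this always gives
#' loadings of magnitude 1/sqrt(2), so it is offered only for sensitivity
#' analysis). Scores are raw projections of the centred data onto the
#' sign-fixed eigenvectors; no rescaling to unit variance is applied, since
#' downstream standardized regression is invariant to it.
#'
#' Sign convention: both loadings of the first component are positive, and
#' the second component loads positively on the area's own index and
#' negatively on the neighbour mean. Exactly tied eigenvalues are broken by
#' assigning the first component to the eigenvector with the larger loading
#' on the area's own index.
#'
#' @param imd numeric vector of area deprivation scores (named by area
#'   identifier or bare).
#' @param ald numeric vector of neighbour-mean deprivation, aligned with
#'   `imd` (same names or same length; islands must already be excluded).
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return An object of class `deprivation_components`: list with
#'   `target_deprivation` and `deprivation_differential` (named numeric
#'   scores), `loadings` (2x2; rows PC1/PC2, columns imd/ald),
#'   `variance_explained` (the two eigenvalues), `means` (centring
#'   constants), `scales` (1s, or SDs in correlation mode), `mode`, `ids`.
#' @examples
#' set.seed(1)
#' imd <- runif(25, 5, 60)
#' ald <- 0.8 * imd + rnorm(25, sd = 4)
#' dc <- decompose_deprivation(imd, ald)
#' cor(dc$target_deprivation, dc$deprivation_differential)  # ~0
#' @export
decompose_deprivation <- function(imd, ald, mode = c("covariance",
                                                     "correlation")) {
  mode <- match.arg(mode)
  if (!is.null(names(imd)) && !is.null(names(ald))) {
    if (!setequal(names(imd), names(ald))) {
      stop("'imd' and 'ald' must cover the same area set", call. = FALSE)
    }
    ald <- ald[names(imd)]
  } else if (length(imd) != length(ald)) {
    stop("'imd' and 'ald' must be aligned on the same areas", call. = FALSE)
  }
  if (length(imd) < 3) stop("need at least 3 areas", call. = FALSE)
  if (anyNA(imd) || anyNA(ald)) stop("inputs contain NA", call. = FALSE)
  if (stats::sd(imd) == 0) stop("degenerate input: 'imd' is constant",
                                call. = FALSE)
  if (stats::sd(ald) == 0) stop("degenerate input: 'ald' is constant",
                                call. = FALSE)
  ids <- names(imd)
  if (is.null(ids)) ids <- as.character(seq_along(imd))

  mu <- c(imd = mean(imd), ald = mean(ald))
  sc <- c(imd = 1, ald = 1)
  if (mode == "correlation") sc <- c(imd = stats::sd(imd),
                                     ald = stats::sd(ald))
  X <- cbind(imd = (imd - mu[1]) / sc[1], ald = (ald - mu[2]) / sc[2])
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors  # columns are eigenvectors, by decreasing eigenvalue
  if (abs(vals[1] - vals[2]) < .Machine$double.eps * max(abs(vals), 1)) {
    # tied eigenvalues: PC1 gets the vector loading harder on imd
    if (abs(vecs[1, 2]) > abs(vecs[1, 1])) {
      vecs <- vecs[, 2:1]; vals <- vals[2:1]
    }
  }
  v1 <- vecs[, 1]; v2 <- vecs[, 2]
  # sign fixing: PC1 loadings positive; PC2 positive on imd, negative on ald
  if (sum(v1) < 0) v1 <- -v1
  if (v2[1] < 0) v2 <- -v2
  loadings <- rbind(PC1 = v1, PC2 = v2)
  colnames(loadings) <- c("imd", "ald")
  scores <- X %*% t(loadings)
  structure(list(
    target_deprivation = stats::setNames(scores[, 1], ids),
    deprivation_differential = stats::setNames(scores[, 2], ids),
    loadings = loadings,
    variance_explained = stats::setNames(vals, c("PC1", "PC2")),
    means = mu,
    scales = sc,
    mode = mode,
    ids = ids
  ), class = "deprivation_components")
}

#' @export
print.deprivation_components <- function(x, ...) {
  cat("Deprivation components (", x$mode, " PCA, n = ",
      length(x$ids), " areas)\n", sep = "")
  cat(" ", format_loadings(x), "\n")
  ve <- x$variance_explained / sum(x$variance_explained)
  cat("  variance shares: PC1", sprintf("%.1f%%", 100 * ve[1]),
      " PC2", sprintf("%.1f%%", 100 * ve[2]), "\n")
  invisible(x)
}

# "PC1 = 0.76 IMD + 0.64 ALD; PC2 = 0.64 IMD - 0.76 ALD" style echo
format_loadings <- function(components) {
  L <- components$loadings
  term <- function(a, b) {
    sprintf("%.2f IMD %s %.2f ALD", a, if (b >= 0) "+" else "-", abs(b))
  }
  paste0("PC1 = ", term(L[1, 1], L[1, 2]),
         "; PC2 = ", term(L[2, 1], L[2, 2]))
}

#' Orientation report for the deprivation differential
#'
#' Confirms that the sign convention points the way the analysis expects:
#' an area whose own deprivation sits above its neighbours' mean (relative
#' to the sample means) receives a positive deprivation-differential score.
#' Also reports the descriptive score ranges.
#'
#' @param components a `deprivation_components` object.
#' @return List with `sign_ok`, `range_target`, `range_differential`,
#'   `loadings_text`.
#' @export
interpret_differential <- function(components) {
  stopifnot(inherits(components, "deprivation_components"))
  L <- components$loadings
  sign_ok <- all(L[1, ] > 0) && L[2, "imd"] > 0 && L[2, "ald"] < 0
  # direct check: a probe area above-average on imd, below-average on ald
  probe <- L[2, "imd"] * 1 + L[2, "ald"] * (-1)
  list(
    sign_ok = sign_ok && probe > 0,
    range_target = range(components$target_deprivation),
    range_differential = range(components$deprivation_differential),
    loadings_text = format_loadings(components)
  )
}
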