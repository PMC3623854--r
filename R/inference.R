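#' Standardized ordinary least squares
#'
#' Z-scores the outcome and every predictor (sample SD, n-1) and fits OLS;
#' the slopes are then standardized betas, so for a single predictor the
#' slope equals the Pearson correlation. Two-sided t-test p-values use
#' n - p - 1 degrees of freedom; adjusted R-squared is
#' 1 - (1 - R^2)(n - 1)/(n - p - 1). Significance stars follow the usual
#' convention: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise.
#'
#' @param y numeric outcome vector.
#' @param X numeric matrix or data frame of predictors (columns named).
#' @param weights optional per-area weights (hook; default NULL =
#'   unweighted).
#' @return Object of class `regression_fit`: `predictors`, `std_slopes`,
#'   `p_values`, `stars`, `r2`, `adj_r2`, `n`.
#' @examples
#' x <- rnorm(50); y <- 2 * x
#' standardized_ols(y, cbind(x = x))$std_slopes  # 1
#' @export
standardized_ols <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("'y' and 'X' must be aligned", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values in regression input",
                                 call. = FALSE)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (stats::sd(y) == 0) stop("outcome is constant", call. = FALSE)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  zy <- (y - mean(y)) / stats::sd(y)
  zX <- scale(X)
  if (p > 1 && kappa(crossprod(zX), exact = TRUE) > 1e8) {
    stop("predictors are (near-)collinear: condition number > 1e8",
         call. = FALSE)
  }
  dat <- data.frame(.y = zy, zX, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                               collapse = " + ")))
  fit <- stats::lm(fml, data = dat, weights = weights)
  sm <- summary(fit)
  co <- sm$coefficients[colnames(X), , drop = FALSE]
  pvals <- co[, 4]
  structure(list(
    predictors = colnames(X),
    std_slopes = stats::setNames(co[, 1], colnames(X)),
    p_values = stats::setNames(pvals, colnames(X)),
    stars = stats::setNames(significance_stars(pvals), colnames(X)),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    n = n
  ), class = "regression_fit")
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("Standardized OLS (n =", x$n, ")\n")
  for (k in seq_along(x$predictors)) {
    cat(sprintf("  %-28s beta = %6.3f %s\n", x$predictors[k],
                x$std_slopes[k], x$stars[k]))
  }
  cat(sprintf("  R2 = %.3f  adjusted R2 = %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' Bivariate and multivariate deprivation models per outcome
#'
#' For each outcome, fits three standardized regressions of the log10
#' morbidity percentage: on the target-area deprivation alone, on the
#' deprivation differential alone, and on both jointly. Because the two
#' components are uncorrelated by construction, the multivariate
#' standardized slopes equal the bivariate ones, and the unadjusted
#' multivariate R-squared equals the sum of the two bivariate R-squareds —
#' both identities are computed and reported as diagnostics.
#'
#' @param outcome_table an `outcome_table` from [compute_outcomes()].
#' @param components a `deprivation_components` object.
#' @return Object of class `decomposition_table`: per outcome, a list with
#'   `bivariate_target`, `bivariate_differential`, `multivariate`
#'   (`regression_fit`s) and `additivity` (sum vs multivariate R2, raw and
#'   adjusted).
#' @export
fit_decomposition_table <- function(outcome_table, components) {
  stopifnot(inherits(components, "deprivation_components"))
  ids <- components$ids
  per_outcome <- split(outcome_table, outcome_table$outcome)
  res <- lapply(per_outcome, function(d) {
    d <- d[match(ids, d$area_id), ]
    if (anyNA(d$area_id)) {
      stop("outcome table does not cover all component areas", call. = FALSE)
    }
    y <- d$log10_pct
    X <- cbind(target_deprivation = unname(components$target_deprivation),
               deprivation_differential =
                 unname(components$deprivation_differential))
    b1 <- standardized_ols(y, X[, 1, drop = FALSE])
    b2 <- standardized_ols(y, X[, 2, drop = FALSE])
    mv <- standardized_ols(y, X)
    list(
      bivariate_target = b1,
      bivariate_differential = b2,
      multivariate = mv,
      additivity = list(
        r2_sum = b1$r2 + b2$r2,
        r2_multivariate = mv$r2,
        adj_r2_sum = b1$adj_r2 + b2$adj_r2,
        adj_r2_multivariate = mv$adj_r2
      )
    )
  })
  structure(res, class = "decomposition_table")
}

#' @export
print.decomposition_table <- function(x, ...) {
  for (oname in names(x)) {
    f <- x[[oname]]
    cat(oname, " (n = ", f$multivariate$n, ")\n", sep = "")
    cat(sprintf("  beta1 (target area deprivation)   %6.3f %s\n",
                f$multivariate$std_slopes[1], f$multivariate$stars[1]))
    cat(sprintf("  beta2 (deprivation differential)  %6.3f %s\n",
                f$multivariate$std_slopes[2], f$multivariate$stars[2]))
    cat(sprintf("  adjusted R2: bivariate %0.3f + %0.3f ; multivariate %0.3f\n",
                f$bivariate_target$adj_r2, f$bivariate_differential$adj_r2,
                f$multivariate$adj_r2))
  }
  invisible(x)
}

#' Tidy one-row-per-model view of a decomposition table
#'
#' @param dt a `decomposition_table`.
#' @return Data frame with outcome, model, beta1, beta2, stars and
#'   R-squared columns (NA where a predictor is absent from a model).
#' @export
decomposition_table_df <- function(dt) {
  rows <- list()
  for (oname in names(dt)) {
    f <- dt[[oname]]
    rows[[length(rows) + 1]] <- data.frame(
      outcome = oname,
      model = c("bivariate_target", "bivariate_differential", "multivariate"),
      beta1 = c(f$bivariate_target$std_slopes[1], NA,
                f$multivariate$std_slopes[1]),
      stars1 = c(f$bivariate_target$stars[1], NA, f$multivariate$stars[1]),
      beta2 = c(NA, f$bivariate_differential$std_slopes[1],
                f$multivariate$std_slopes[2]),
      stars2 = c(NA, f$bivariate_differential$stars[1],
                 f$multivariate$stars[2]),
      r2 = c(f$bivariate_target$r2, f$bivariate_differential$r2,
             f$multivariate$r2),
      adj_r2 = c(f$bivariate_target$adj_r2, f$bivariate_differential$adj_r2,
                 f$multivariate$adj_r2),
      n = f$multivariate$n,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
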