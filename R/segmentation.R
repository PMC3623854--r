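#' Deprivation tertiles
#'
#' Rank-based split of areas into three equal-as-possible groups by
#' deprivation score: the most deprived third, the middle third and the
#' least deprived third. Group sizes differ by at most one (remainders go
#' to the most deprived groups first); ties in the score are broken by area
#' identifier, so the assignment is deterministic.
#'
#' @param imd numeric deprivation scores, named by area identifier (bare
#'   vectors are given identifiers "1", "2", ...).
#' @return Named character vector of labels: `"Upper third (most
#'   deprived)"`, `"Medium third (middle deprived)"`, `"Lower third (least
#'   deprived)"`.
#' @export
assign_tertiles <- function(imd) {
  n <- length(imd)
  if (n < 3) stop("need at least 3 areas for tertiles", call. = FALSE)
  ids <- names(imd)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(-imd, ids)  # most deprived first, ties by identifier
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- c("Upper third (most deprived)",
              "Medium third (middle deprived)",
              "Lower third (least deprived)")
  lab <- rep(labels, times = sizes)
  out <- character(n)
  out[ord] <- lab
  stats::setNames(out, ids)
}

#' Ranks of the canonical tertile labels (1 = most deprived)
#' @keywords internal
tertile_ranks <- function() {
  c("Upper third (most deprived)" = 1L,
    "Medium third (middle deprived)" = 2L,
    "Lower third (least deprived)" = 3L)
}

#' Ratio of the two standardized slopes
#'
#' The headline comparison statistic of the segmented analysis: how many
#' times stronger the effect of an area's own deprivation is than the
#' effect of its deprivation differential.
#'
#' @param beta1 standardized slope of the target-area deprivation.
#' @param beta2 standardized slope of the deprivation differential.
#' @return `beta1 / beta2`.
#' @examples
#' beta_ratio(0.638, 0.688)  # 0.927 at 3 decimals
#' @export
beta_ratio <- function(beta1, beta2) {
  if (length(beta1) != 1 || length(beta2) != 1) {
    stop("'beta1' and 'beta2' must be scalars", call. = FALSE)
  }
  if (abs(beta2) <= 1e-9) {
    stop("degenerate ratio: |beta2| <= 1e-9", call. = FALSE)
  }
  beta1 / beta2
}

#' Replicate the multivariate model within population segments
#'
#' Refits the two-predictor standardized regression of log10 morbidity
#' percentage on (target-area deprivation, deprivation differential)
#' separately inside each segment. Outcome and predictors are re-z-scored
#' within each segment, so the betas are comparable within-segment effect
#' sizes; the components themselves are computed once globally and only
#' subset here. Segments smaller than `min_size` are dropped with a
#' warning. Rows are ordered by descending beta1/beta2 ratio (ties broken
#' by segment name; an undefined ratio sorts last and is reported `NA`).
#'
#' @param outcome_table an `outcome_table` (one outcome at a time or
#'   several; a report is produced per outcome).
#' @param components a `deprivation_components` object.
#' @param labels named character vector: segment label per area identifier.
#' @param ranks optional named integer vector mapping segment label to a
#'   deprivation rank (1 = most deprived). If omitted, segments are ranked
#'   by descending mean deprivation component of their areas.
#' @param min_size minimum areas per retained segment (default 30).
#' @param scheme label recorded in the report: `"imd_tertiles"` or
#'   `"categorical"`.
#' @return A named list of `segment_report` objects, one per outcome; each
#'   is a data frame with columns `segment`, `deprivation_rank`, `beta1`,
#'   `stars1`, `beta2`, `stars2`, `ratio`, `n_areas`.
#' @export
segment_regressions <- function(outcome_table, components, labels,
                                ranks = NULL, min_size = 30,
                                scheme = c("categorical", "imd_tertiles")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(components, "deprivation_components"))
  ids <- components$ids
  if (is.null(names(labels))) {
    stop("'labels' must be named by area identifier", call. = FALSE)
  }
  miss <- setdiff(ids, names(labels))
  if (length(miss) > 0) {
    stop("segment label missing for area(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  labels <- labels[ids]
  if (is.null(ranks)) {
    segmeans <- tapply(components$target_deprivation, labels, mean)
    ranks <- stats::setNames(rank(-segmeans, ties.method = "first"),
                             names(segmeans))
  }
  pc1 <- components$target_deprivation
  pc2 <- components$deprivation_differential
  per_outcome <- split(as.data.frame(outcome_table), outcome_table$outcome)
  reports <- lapply(per_outcome, function(d) {
    d <- d[d$area_id %in% ids, ]
    rows <- list()
    for (seg in unique(labels)) {
      seg_ids <- ids[labels == seg]
      dd <- d[d$area_id %in% seg_ids, ]
      if (nrow(dd) < min_size) {
        warning("segment '", seg, "' dropped: ", nrow(dd), " < ", min_size,
                " areas [", d$outcome[1], "]", call. = FALSE)
        next
      }
      X <- cbind(target_deprivation = unname(pc1[dd$area_id]),
                 deprivation_differential = unname(pc2[dd$area_id]))
      fit <- standardized_ols(dd$log10_pct, X)
      b1 <- unname(fit$std_slopes[1]); b2 <- unname(fit$std_slopes[2])
      r <- tryCatch(beta_ratio(b1, b2), error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        segment = seg,
        deprivation_rank = unname(ranks[seg]),
        beta1 = b1, stars1 = unname(fit$stars[1]),
        beta2 = b2, stars2 = unname(fit$stars[2]),
        ratio = r, n_areas = fit$n,
        stringsAsFactors = FALSE
      )
    }
    if (length(rows) == 0) {
      stop("no segment reached the minimum size for outcome '",
           d$outcome[1], "'", call. = FALSE)
    }
    rep <- do.call(rbind, rows)
    ord <- order(-rep$ratio, rep$segment, na.last = TRUE)
    rep <- rep[ord, ]
    rownames(rep) <- NULL
    structure(rep, outcome = d$outcome[1], scheme = scheme,
              class = c("segment_report", "data.frame"))
  })
  reports
}

#' @export
print.segment_report <- function(x, ...) {
  cat("Segmented regression (", attr(x, "scheme"), "), outcome: ",
      attr(x, "outcome"), "\n", sep = "")
  disp <- x
  for (col in c("beta1", "beta2", "ratio")) {
    disp[[col]] <- sprintf("%.3f", x[[col]])
  }
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}
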