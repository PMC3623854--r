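#' Build morbidity outcome variables from counts
#'
#' Converts per-area numerator counts and denominators into percentages and
#' log10 percentages for each self-reported morbidity outcome. The two
#' canonical outcomes are the share of the adult population reporting
#' 'not good' general health and the share reporting a limiting long-term
#' illness (LLTI); the denominator is the adult (15-65) population of the
#' area. Percentages (not proportions) are the canonical pre-log scale;
#' standardized regression downstream is invariant to that affine choice.
#'
#' Zero numerators leave log10 undefined. The default policy is a hard
#' error naming the offending areas; `zero_policy = "continuity"` instead
#' adds 0.5 to zero numerators, with a warning.
#'
#' @param area_table data frame with columns `area_id`, `denominator` and
#'   one count column per outcome.
#' @param outcome_cols named character vector mapping outcome name to count
#'   column, default `c(not_good_health = "notgood_count", llti =
#'   "llti_count")`.
#' @param zero_policy `"error"` (default) or `"continuity"`.
#' @return Data frame of class `outcome_table`, one row per area x outcome:
#'   `area_id`, `outcome`, `count`, `denominator`, `percentage`,
#'   `log10_pct`.
#' @examples
#' tab <- data.frame(area_id = "a1", notgood_count = 150,
#'                   llti_count = 300, denominator = 1500)
#' compute_outcomes(tab)  # 10% -> log10_pct 1; 20% -> 1.301
#' @export
compute_outcomes <- function(area_table,
                             outcome_cols = c(not_good_health = "notgood_count",
                                              llti = "llti_count"),
                             zero_policy = c("error", "continuity")) {
  zero_policy <- match.arg(zero_policy)
  need <- c("area_id", "denominator", unname(outcome_cols))
  miss <- setdiff(need, names(area_table))
  if (length(miss) > 0) {
    stop("area table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(area_table$area_id)) {
    stop("duplicate area_id in area table", call. = FALSE)
  }
  den <- area_table$denominator
  if (any(!is.finite(den)) || any(den <= 0)) {
    stop("nonpositive denominator for area(s): ",
         paste(utils::head(area_table$area_id[!is.finite(den) | den <= 0], 5),
               collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (k in seq_along(outcome_cols)) {
    oname <- names(outcome_cols)[k]
    cnt <- area_table[[outcome_cols[k]]]
    if (any(!is.finite(cnt)) || any(cnt < 0)) {
      stop("invalid count in '", outcome_cols[k], "'", call. = FALSE)
    }
    if (any(cnt > den)) {
      stop("numerator exceeds denominator for area(s): ",
           paste(utils::head(area_table$area_id[cnt > den], 5),
                 collapse = ", "), " [", oname, "]", call. = FALSE)
    }
    zero <- cnt == 0
    if (any(zero)) {
      if (zero_policy == "error") {
        stop("zero numerator (log10 undefined) for area(s): ",
             paste(utils::head(area_table$area_id[zero], 5), collapse = ", "),
             " [", oname, "]; use zero_policy = 'continuity' to correct",
             call. = FALSE)
      }
      warning(sum(zero), " zero numerator(s) in '", oname,
              "' corrected by +0.5", call. = FALSE)
      cnt <- cnt + 0.5 * zero
    }
    pct <- 100 * cnt / den
    out[[k]] <- data.frame(
      area_id = as.character(area_table$area_id),
      outcome = oname,
      count = cnt,
      denominator = den,
      percentage = pct,
      log10_pct = log10(pct),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("outcome_table", "data.frame")
  res
}

#' Mean and SD of log10 morbidity percentages
#'
#' Descriptive summary per outcome: sample mean and sample standard
#' deviation (n-1 denominator) of `log10_pct`. With a single area the SD is
#' undefined and reported as `NA` with a warning.
#'
#' @param outcome_table an `outcome_table` from [compute_outcomes()].
#' @return Data frame with columns `outcome`, `n`, `mean_log10_pct`,
#'   `sd_log10_pct`.
#' @export
summarize_outcomes <- function(outcome_table) {
  if (nrow(outcome_table) == 0) stop("empty outcome table", call. = FALSE)
  sp <- split(outcome_table, outcome_table$outcome)
  rows <- lapply(sp, function(d) {
    s <- if (nrow(d) > 1) stats::sd(d$log10_pct) else {
      warning("single area for outcome '", d$outcome[1],
              "': SD undefined", call. = FALSE)
      NA_real_
    }
    data.frame(outcome = d$outcome[1], n = nrow(d),
               mean_log10_pct = mean(d$log10_pct),
               sd_log10_pct = s, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
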