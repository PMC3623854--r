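#' Configuration for a synthetic study region
#'
#' Bundles and validates the parameters of the lattice generator. The
#' generator emulates the statistical structure the analysis assumes: a
#' spatially autocorrelated deprivation field on a queen-contiguity grid,
#' log10 morbidity percentages that depend linearly on the two orthogonal
#' deprivation components with Gaussian noise, binomial count sampling
#' given area denominators, and categorical segments correlated with
#' deprivation rank.
#'
#' @param grid_rows,grid_cols lattice dimensions (product >= 9).
#' @param autocorr_mix neighbour-mixing weight rho in `[0, 1)`; each
#'   smoothing round replaces the field d by `(1 - rho) d + rho *`
#'   (neighbour mean of d).
#' @param smoothing_rounds nonnegative integer number of mixing passes.
#' @param effect_target true effect b1 of the standardized target-area
#'   deprivation on the log10 morbidity percentage.
#' @param effect_differential true effect b2 of the standardized
#'   deprivation differential.
#' @param noise_sd residual SD sigma on the log10-percentage scale (> 0).
#' @param baseline_log10_pct intercept mu of the latent model, for the
#'   'not good health' outcome (default 0.95, i.e. about 9%).
#' @param llti_offset added to `baseline_log10_pct` for the LLTI outcome
#'   (default 0.31, putting LLTI near 18%).
#' @param denominator_range integer pair, min/max adults per area; default
#'   900-2100 around a typical small-area adult population of ~1500.
#' @param n_segments number of geodemographic-style segments (>= 2).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(grid_rows = 50, grid_cols = 50,
                              autocorr_mix = 0.8, smoothing_rounds = 5,
                              effect_target = 0.6,
                              effect_differential = 0.3,
                              noise_sd = 0.74, baseline_log10_pct = 0.95,
                              llti_offset = 0.31,
                              denominator_range = c(900L, 2100L),
                              n_segments = 13, seed = 1) {
  cfg <- list(grid_rows = grid_rows, grid_cols = grid_cols,
              autocorr_mix = autocorr_mix,
              smoothing_rounds = smoothing_rounds,
              effect_target = effect_target,
              effect_differential = effect_differential,
              noise_sd = noise_sd, baseline_log10_pct = baseline_log10_pct,
              llti_offset = llti_offset,
              denominator_range = denominator_range,
              n_segments = n_segments, seed = seed)
  bad <- function(field, msg) {
    stop("invalid simulation config field '", field, "': ", msg,
         call. = FALSE)
  }
  is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x)
  if (!is_count(grid_rows) || grid_rows < 1) bad("grid_rows",
                                                 "positive integer required")
  if (!is_count(grid_cols) || grid_cols < 1) bad("grid_cols",
                                                 "positive integer required")
  if (grid_rows * grid_cols < 9) bad("grid_rows",
                                     "grid must have at least 9 areas")
  if (!is.finite(autocorr_mix) || autocorr_mix < 0 || autocorr_mix >= 1) {
    bad("autocorr_mix", "must lie in [0, 1)")
  }
  if (!is_count(smoothing_rounds) || smoothing_rounds < 0) {
    bad("smoothing_rounds", "nonnegative integer required")
  }
  if (!is.finite(effect_target)) bad("effect_target", "must be finite")
  if (!is.finite(effect_differential)) bad("effect_differential",
                                           "must be finite")
  if (!is.finite(noise_sd) || noise_sd <= 0) bad("noise_sd",
                                                 "must be positive")
  if (!is.finite(baseline_log10_pct)) bad("baseline_log10_pct",
                                          "must be finite")
  if (length(denominator_range) != 2 ||
      any(denominator_range != round(denominator_range)) ||
      denominator_range[1] < 1 ||
      denominator_range[2] < denominator_range[1]) {
    bad("denominator_range", "integer pair with 1 <= min <= max required")
  }
  if (!is_count(n_segments) || n_segments < 1) bad("n_segments",
                                                   "positive integer required")
  if (!is_count(seed)) bad("seed", "integer required")
  structure(cfg, class = "simulation_config")
}

# One neighbour-mean mixing pass of the field over the graph.
smooth_field <- function(d, graph, rho) {
  nbmean <- vapply(seq_along(d), function(i) {
    ni <- graph$nb[[i]]
    if (length(ni) == 0) d[i] else mean(d[ni])
  }, numeric(1))
  (1 - rho) * d + rho * nbmean
}

#' Generate a synthetic study region
#'
#' Builds the queen-contiguity lattice, draws iid standard-normal
#' innovations, applies `smoothing_rounds` neighbour-mixing passes
#' (inducing the spatial autocorrelation — and hence the IMD/ALD
#' collinearity — the analysis is designed for), and affine-maps the field
#' to a nonnegative deprivation score. Outcome counts are then simulated
#' through the real pipeline: the spatial lag and principal-component
#' decomposition of the generated field define the predictors on which the
#' generative effects act (see [simulate_outcomes()]). Segment labels
#' correlated with deprivation are attached.
#'
#' @param config a `simulation_config`.
#' @return List with `area_table` (data frame: `area_id`, `imd`,
#'   `notgood_count`, `llti_count`, `denominator`, `segment`), `graph`
#'   (the `contiguity_graph`), and `truth` (the generating parameters plus
#'   the latent components used).
#' @examples
#' reg <- simulate_region(simulation_config(grid_rows = 10, grid_cols = 10))
#' head(reg$area_table)
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$grid_rows * config$grid_cols
  ids <- sprintf("A%05d", seq_len(n))
  graph <- queen_from_grid(config$grid_rows, config$grid_cols, ids = ids)
  set.seed(config$seed)
  d <- stats::rnorm(n)
  if (config$smoothing_rounds > 0 && config$autocorr_mix > 0) {
    for (r in seq_len(config$smoothing_rounds)) {
      d <- smooth_field(d, graph, config$autocorr_mix)
    }
  }
  imd <- d - min(d) + 0.5  # nonnegative, IMD-like: higher = more deprived
  names(imd) <- ids
  den_pool <- seq(config$denominator_range[1], config$denominator_range[2])
  den <- den_pool[sample.int(length(den_pool), n, replace = TRUE)]
  lag <- spatial_lag(imd, graph)
  keep <- setdiff(ids, lag$islands)
  comps <- decompose_deprivation(imd[keep], lag$ald[keep])
  notgood <- simulate_outcomes(comps, config, stats::setNames(den, ids)[keep])
  llti <- simulate_outcomes(comps, config, stats::setNames(den, ids)[keep],
                            baseline = config$baseline_log10_pct +
                              config$llti_offset)
  seg <- simulate_segments(imd[keep], config$n_segments)
  area_table <- data.frame(
    area_id = keep,
    imd = unname(imd[keep]),
    notgood_count = unname(notgood),
    llti_count = unname(llti),
    denominator = unname(stats::setNames(den, ids)[keep]),
    segment = unname(seg[keep]),
    stringsAsFactors = FALSE
  )
  list(area_table = area_table, graph = graph,
       truth = list(config = config, components = comps,
                    ald = lag$ald[keep]))
}

#' Simulate binomial morbidity counts from the latent linear model
#'
#' Inverts the analysis model: the latent log10 morbidity percentage is
#' `y_i = mu + b1 z(PC1_i) + b2 z(PC2_i) + sigma e_i` with `z()` the
#' z-score across areas and `e_i` iid standard normal; the implied
#' proportion `10^y / 100` is clipped to
#' `[1/(den_i + 2), 1 - 1/(den_i + 2)]` so it is always a valid binomial
#' probability and the log10 transform of the realized percentage is
#' defined; counts are drawn `Binomial(den_i, p_i)`.
#'
#' Draws from the current RNG stream; pass `seed` to make a standalone
#' call reproducible (inside [simulate_region()] the stream is already
#' seeded).
#'
#' @param components a `deprivation_components` computed from the simulated
#'   field by the real decomposition — the generative effects act on
#'   exactly the predictors the analysis uses.
#' @param config a `simulation_config` (supplies b1, b2, sigma, mu).
#' @param denominators named positive integer vector over the component
#'   areas.
#' @param baseline override of `config$baseline_log10_pct` (used for the
#'   second outcome).
#' @param seed optional integer seed.
#' @return Named integer vector of counts.
#' @export
simulate_outcomes <- function(components, config, denominators,
                              baseline = config$baseline_log10_pct,
                              seed = NULL) {
  stopifnot(inherits(components, "deprivation_components"),
            inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  ids <- components$ids
  if (!is.null(names(denominators))) denominators <- denominators[ids]
  if (length(denominators) != length(ids) || anyNA(denominators) ||
      any(denominators < 1)) {
    stop("denominators must be positive and cover all component areas",
         call. = FALSE)
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  y <- baseline +
    config$effect_target * z(components$target_deprivation) +
    config$effect_differential * z(components$deprivation_differential) +
    config$noise_sd * stats::rnorm(length(ids))
  if (any(!is.finite(y))) {
    stop("invalid simulation config: latent log10 percentages are not ",
         "finite (effects or noise too large)", call. = FALSE)
  }
  p <- 10^y / 100
  lo <- 1 / (denominators + 2)
  p <- pmin(pmax(p, lo), 1 - lo)
  stats::setNames(stats::rbinom(length(ids), denominators, p), ids)
}

#' Simulate geodemographic-style segment labels
#'
#' Assigns areas to `n_segments` quantile bins of the deprivation score
#' (bin 1 = least deprived), then reassigns a random `reassign_frac` of
#' areas to an adjacent bin, so the segments correlate with — but are not
#' determined by — deprivation, mimicking geodemographic classes that carry
#' a deprivation rank.
#'
#' @param deprivation named numeric vector of deprivation scores.
#' @param n_segments number of segments (2 <= n_segments <= number of
#'   areas).
#' @param seed optional integer seed (draws from the current stream when
#'   `NULL`).
#' @param reassign_frac fraction of areas moved to an adjacent bin
#'   (default 0.1).
#' @return Named character vector of labels `"S01"`, `"S02"`, ... with the
#'   bin index increasing with deprivation.
#' @export
simulate_segments <- function(deprivation, n_segments, seed = NULL,
                              reassign_frac = 0.1) {
  n <- length(deprivation)
  if (n_segments < 2) stop("'n_segments' must be at least 2", call. = FALSE)
  if (n_segments > n) {
    stop("'n_segments' (", n_segments, ") exceeds the number of areas (",
         n, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- names(deprivation)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rk <- rank(deprivation, ties.method = "first")
  bin <- floor((rk - 1) * n_segments / n) + 1L
  n_move <- floor(reassign_frac * n)
  if (n_move > 0) {
    movers <- sample(n, n_move)
    step <- sample(c(-1L, 1L), n_move, replace = TRUE)
    nb <- bin[movers] + step
    nb[nb < 1L] <- 2L
    nb[nb > n_segments] <- n_segments - 1L
    bin[movers] <- nb
  }
  stats::setNames(sprintf("S%02d", bin), ids)
}

#' Closed-form standardized slopes implied by the generator
#'
#' With standardized orthogonal predictors and latent variance
#' `b1^2 + b2^2 + sigma^2`, the population standardized slope of predictor
#' k is `b_k / sqrt(b1^2 + b2^2 + sigma^2)`. Used as the recovery target
#' when fitting the pipeline to simulated data.
#'
#' @param config a `simulation_config`.
#' @return Named numeric: expected standardized slopes for the target
#'   deprivation and the differential.
#' @export
expected_std_slopes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tot <- sqrt(config$effect_target^2 + config$effect_differential^2 +
                config$noise_sd^2)
  c(target_deprivation = config$effect_target / tot,
    deprivation_differential = config$effect_differential / tot)
}
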