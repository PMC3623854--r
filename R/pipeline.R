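#' Read an area attribute table
#'
#' Canonical CSV schema: `area_id, imd, notgood_count, llti_count,
#' denominator[, segment]`, one row per small area, identifiers opaque
#' strings. All joins downstream are by identifier, never by row order.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_area_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(area_id = "character"))
  need <- c("area_id", "imd", "denominator")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("area table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$area_id)) {
    stop("duplicate area_id in ", path, call. = FALSE)
  }
  tab
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' End-to-end deprivation-differential analysis
#'
#' Runs the full pipeline on an area table and a contiguity source:
#' neighbour structure, spatial lag of the deprivation index, principal
#' component orthogonalization, outcome construction (log10 percentage),
#' the bivariate/multivariate standardized regressions, and the segmented
#' beta-ratio replication. Islands are excluded from all model stages with
#' a warning and reconciled in the report; nothing is silently dropped.
#'
#' @param area_table data frame (schema of [read_area_table()]) or a CSV
#'   path.
#' @param graph a `contiguity_graph`, or a path to an edge-list CSV
#'   (`area_id_a, area_id_b`), or a GeoJSON polygon path (detected by
#'   `.geojson`/`.json` extension).
#' @param outcome_cols named map outcome name -> count column; default the
#'   canonical two morbidity outcomes.
#' @param zero_policy passed to [compute_outcomes()].
#' @param pca_mode passed to [decompose_deprivation()].
#' @param segmentation `"imd_tertiles"` (default) or `"categorical"` (uses
#'   the area table's `segment` column).
#' @param segment_ranks optional named integer vector (segment -> rank,
#'   1 = most deprived) for categorical segmentation.
#' @param min_segment_size minimum areas per retained segment.
#' @param output_dir optional directory; when given, all tables are written
#'   as CSV and the report as JSON.
#' @return Object of class `run_report`: areas in/retained, islands,
#'   loadings echo, outcome summaries, the decomposition (Table-1 analog),
#'   segment reports per outcome, orthogonality/additivity diagnostics,
#'   warnings, and a config echo.
#' @export
run_analysis <- function(area_table, graph,
                         outcome_cols = c(not_good_health = "notgood_count",
                                          llti = "llti_count"),
                         zero_policy = "error",
                         pca_mode = "covariance",
                         segmentation = c("imd_tertiles", "categorical"),
                         segment_ranks = NULL,
                         min_segment_size = 30,
                         output_dir = NULL) {
  segmentation <- match.arg(segmentation)
  if (is.character(area_table)) area_table <- read_area_table(area_table)
  need <- c("area_id", "imd", unname(outcome_cols), "denominator")
  miss <- setdiff(need, names(area_table))
  if (length(miss) > 0) {
    stop("area table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (segmentation == "categorical" && !("segment" %in% names(area_table))) {
    stop("categorical segmentation requires a 'segment' column",
         call. = FALSE)
  }
  if (is.character(graph)) {
    graph <- if (grepl("\\.(geo)?json$", graph, ignore.case = TRUE)) {
      queen_from_polygons(graph)
    } else {
      queen_from_edgelist(graph, nodes = area_table$area_id)
    }
  }
  stopifnot(inherits(graph, "contiguity_graph"))
  if (!setequal(graph$ids, area_table$area_id)) {
    stop("graph nodes and area table identifiers do not match",
         call. = FALSE)
  }
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  imd <- stats::setNames(area_table$imd, area_table$area_id)
  lag <- withCallingHandlers(
    spatial_lag(imd, graph),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  if (length(lag$islands) > 0) {
    msg <- paste0(length(lag$islands),
                  " island area(s) excluded from analysis: ",
                  paste(utils::head(lag$islands, 5), collapse = ", "))
    note(msg); warning(msg, call. = FALSE)
  }
  keep <- setdiff(area_table$area_id, lag$islands)
  tab <- area_table[match(keep, area_table$area_id), ]

  comps <- decompose_deprivation(imd[keep], lag$ald[keep], mode = pca_mode)
  orient <- interpret_differential(comps)
  outcomes <- withCallingHandlers(
    compute_outcomes(tab, outcome_cols = outcome_cols,
                     zero_policy = zero_policy),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  osum <- summarize_outcomes(outcomes)
  table1 <- fit_decomposition_table(outcomes, comps)

  if (segmentation == "imd_tertiles") {
    labels <- assign_tertiles(imd[keep])
    ranks <- tertile_ranks()
  } else {
    labels <- stats::setNames(as.character(tab$segment), tab$area_id)
    ranks <- segment_ranks
  }
  segments <- withCallingHandlers(
    segment_regressions(outcomes, comps, labels, ranks = ranks,
                        min_size = min_segment_size,
                        scheme = if (segmentation == "imd_tertiles")
                          "imd_tertiles" else "categorical"),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })

  ortho <- stats::cor(comps$target_deprivation,
                      comps$deprivation_differential)
  report <- structure(list(
    n_in = nrow(area_table),
    n_retained = length(keep),
    islands = lag$islands,
    loadings_text = orient$loadings_text,
    components = comps,
    orientation = orient,
    outcome_summary = osum,
    table1 = table1,
    segments = segments,
    diagnostics = list(
      score_correlation = ortho,
      additivity = lapply(table1, `[[`, "additivity")
    ),
    warnings = warnings_log,
    config = list(outcome_cols = outcome_cols, zero_policy = zero_policy,
                  pca_mode = pca_mode, segmentation = segmentation,
                  min_segment_size = min_segment_size),
    version = as.character(utils::packageVersion("depdiff"))
  ), class = "run_report")

  if (!is.null(output_dir)) write_run_outputs(report, outcomes, output_dir)
  report
}

write_run_outputs <- function(report, outcomes, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  comps <- report$components
  write_csv_plain(data.frame(
    area_id = comps$ids,
    target_deprivation = unname(comps$target_deprivation),
    deprivation_differential = unname(comps$deprivation_differential),
    stringsAsFactors = FALSE
  ), file.path(output_dir, "components.csv"))
  write_csv_plain(as.data.frame(outcomes),
                  file.path(output_dir, "outcomes.csv"))
  write_csv_plain(decomposition_table_df(report$table1),
                  file.path(output_dir, "table1.csv"))
  for (oname in names(report$segments)) {
    write_csv_plain(as.data.frame(report$segments[[oname]]),
                    file.path(output_dir,
                              paste0("segments_", oname, ".csv")))
  }
  jsonlite::write_json(list(
    n_in = report$n_in, n_retained = report$n_retained,
    islands = report$islands, loadings = report$loadings_text,
    score_correlation = report$diagnostics$score_correlation,
    warnings = report$warnings, config = report$config,
    version = report$version
  ), file.path(output_dir, "run_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Deprivation-differential analysis run\n")
  cat("  areas:", x$n_in, "in,", x$n_retained, "retained,",
      length(x$islands), "island(s)\n")
  cat("  ", x$loadings_text, "\n", sep = "")
  cat(sprintf("  PC score correlation: %.2e\n",
              x$diagnostics$score_correlation))
  print(x$table1)
  for (oname in names(x$segments)) print(x$segments[[oname]])
  if (length(x$warnings) > 0) {
    cat("warnings:\n"); for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Simulate a region and analyse it end-to-end
#'
#' Generates a synthetic study region, optionally persists the generated
#' inputs, runs [run_analysis()] on them, and appends a recovery section
#' comparing the fitted standardized slopes with the closed-form targets
#' implied by the generator ([expected_std_slopes()]).
#'
#' @param sim_config a `simulation_config`.
#' @param tolerance recovery tolerance on each standardized slope
#'   (default 0.05).
#' @param zero_policy passed to [run_analysis()]; defaults to
#'   `"continuity"` here (unlike the analysis default) because with a
#'   large residual SD the latent model legitimately produces areas whose
#'   expected count is below one, and a simulation run should not abort on
#'   a sampled zero.
#' @param output_dir optional directory for the generated inputs
#'   (`area_table.csv`, `edges.csv`) and all analysis outputs.
#' @param ... passed to [run_analysis()].
#' @return List: `report` (a `run_report`), `area_table`, `graph`, and
#'   `recovery` (data frame per outcome/predictor: fitted, expected,
#'   absolute error, within tolerance; plus the recovered effect
#'   directions).
#' @export
run_simulation <- function(sim_config, tolerance = 0.05,
                           output_dir = NULL, zero_policy = "continuity",
                           ...) {
  stopifnot(inherits(sim_config, "simulation_config"))
  reg <- simulate_region(sim_config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_plain(reg$area_table,
                    file.path(output_dir, "area_table.csv"))
    write_csv_plain(graph_edges(reg$graph), file.path(output_dir,
                                                      "edges.csv"))
  }
  report <- run_analysis(reg$area_table, reg$graph,
                         output_dir = output_dir,
                         zero_policy = zero_policy, ...)
  target <- expected_std_slopes(sim_config)
  rows <- list()
  for (oname in names(report$table1)) {
    fit <- report$table1[[oname]]$multivariate
    for (k in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oname,
        predictor = names(target)[k],
        fitted = unname(fit$std_slopes[k]),
        expected = unname(target[k]),
        abs_error = abs(unname(fit$std_slopes[k]) - unname(target[k])),
        within_tolerance =
          abs(unname(fit$std_slopes[k]) - unname(target[k])) <= tolerance,
        sign_recovered =
          sign(unname(fit$std_slopes[k])) == sign(unname(target[k])) ||
          unname(target[k]) == 0,
        stringsAsFactors = FALSE
      )
    }
  }
  recovery <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    write_csv_plain(recovery, file.path(output_dir, "recovery.csv"))
  }
  list(report = report, area_table = reg$area_table, graph = reg$graph,
       recovery = recovery)
}

#' Export a contiguity graph as an edge list
#'
#' @param graph a `contiguity_graph`.
#' @return Data frame `area_id_a, area_id_b`, each undirected edge once.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "contiguity_graph"))
  rows <- list()
  for (i in seq_along(graph$ids)) {
    for (j in graph$nb[[i]]) {
      if (j > i) rows[[length(rows) + 1]] <- c(graph$ids[i], graph$ids[j])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(area_id_a = character(0), area_id_b = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  data.frame(area_id_a = m[, 1], area_id_b = m[, 2],
             stringsAsFactors = FALSE)
}
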