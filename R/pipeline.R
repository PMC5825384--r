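# End-to-end reproducible workflow: simulate or read layers, preprocess,
# build networks, compute indicators for every dispersal distance,
# classify priorities at the reference distance, aggregate, and write the
# report tables. All defaults are the reference parameterisation of the
# method (d_med ladder 1/10/30/100 km with 10 km as reference, 500 km
# transboundary buffer, 1 km^2 minimum PA area, 100 m simplification,
# 17% target).

#' Build a run configuration
#'
#' @param d_med dispersal distances (km).
#' @param reference_dmed distance used for classification (km).
#' @param buffer_km transboundary buffer (km).
#' @param min_area_km2 minimum retained PA polygon area (km^2).
#' @param simplify_m vertex simplification tolerance (m).
#' @param contig_tol_m contiguity tolerance (m).
#' @param target coverage/connectivity target (percent).
#' @param seed integer seed for synthetic scenarios.
#' @param preset optional preset scenario name (see [preset_scenario()]).
#' @param pa_path,land_path GeoJSON inputs when no preset is used.
#' @param grouping_path optional CSV with `iso3,group` columns.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(d_med = c(1, 10, 30, 100), reference_dmed = 10,
                       buffer_km = 500, min_area_km2 = 1, simplify_m = 100,
                       contig_tol_m = 0, target = 17, seed = 1L,
                       preset = NULL, pa_path = NULL, land_path = NULL,
                       grouping_path = NULL, out_dir = NULL) {
  stopifnot(all(d_med > 0), reference_dmed %in% d_med)
  structure(list(d_med = d_med, reference_dmed = reference_dmed,
                 buffer_km = buffer_km, min_area_km2 = min_area_km2,
                 simplify_m = simplify_m, contig_tol_m = contig_tol_m,
                 target = target, seed = as.integer(seed), preset = preset,
                 pa_path = pa_path, land_path = land_path,
                 grouping_path = grouping_path, out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

write_table <- function(df, path) {
  # fixed formatting so identical runs give byte-identical files
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full indicator pipeline
#'
#' @param config a [run_config()].
#' @return list with `indicators`, `classification`, `aggregates` (or NULL),
#'   `logs`; tables are also written as CSV under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$preset)) {
    sc <- generate_scenario(preset_scenario(config$preset, seed = config$seed))
    pa_layer <- sc$pa_layer
    land_layer <- sc$land_layer
  } else {
    if (is.null(config$pa_path) || is.null(config$land_path))
      stop("stage input: either a preset or pa_path + land_path is required")
    pa_layer <- read_geojson(config$pa_path)
    land_layer <- read_geojson(config$land_path)
  }
  not_disp <- !isTRUE_vec(land_layer$disputed)
  countries <- sort(unique(land_layer$iso3[not_disp]))
  rows <- list(); logs <- list()
  contexts <- list()
  for (iso in countries) {
    prep <- tryCatch(
      preprocess_country(pa_layer, land_layer, iso,
                         min_area_km2 = config$min_area_km2,
                         buffer_km = config$buffer_km,
                         simplify_km = config$simplify_m / 1000,
                         contig_tol = config$contig_tol_m / 1000),
      error = function(e) stop("stage preprocess failed for ", iso, ": ",
                               conditionMessage(e)))
    logs[[iso]] <- prep$log
    contexts[[iso]] <- prep$context
    for (dm in config$d_med) {
      rows[[length(rows) + 1L]] <- tryCatch(
        country_indicators(prep$nodes, prep$dist, prep$context, dm,
                           contig_tol = config$contig_tol_m / 1000),
        error = function(e) stop("stage indicators failed for ", iso,
                                 " d_med=", dm, ": ", conditionMessage(e)))
    }
  }
  indicators <- do.call(rbind, rows)
  rownames(indicators) <- NULL
  validate_indicator_set(indicators)
  classification <- classify_priorities(indicators, target = config$target,
                                        reference_dmed = config$reference_dmed)
  aggregates <- NULL
  areas <- data.frame(iso3 = countries,
                      A_L = vapply(contexts, function(cx) cx$A_L, numeric(1)),
                      stringsAsFactors = FALSE)
  grouping <- data.frame(iso3 = countries, group = "Global",
                         stringsAsFactors = FALSE)
  if (!is.null(config$grouping_path))
    grouping <- rbind(grouping,
                      utils::read.csv(config$grouping_path,
                                      stringsAsFactors = FALSE)[, c("iso3", "group")])
  aggregates <- aggregate_indicators(indicators, areas, grouping)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(indicators, file.path(config$out_dir, "indicators.csv"))
    write_table(classification, file.path(config$out_dir, "classification.csv"))
    write_table(aggregates, file.path(config$out_dir, "aggregates.csv"))
    write_table(component_breakdown(indicators, config$reference_dmed),
                file.path(config$out_dir, "components.csv"))
  }
  list(indicators = indicators, classification = classification,
       aggregates = aggregates, areas = areas, logs = logs)
}

#' Pie-chart style component breakdown of country land
#'
#' One row per country at the reference distance: the shares of country
#' land that are protected-connected, protected-unconnected by each cause,
#' and unprotected; they sum to 100.
#'
#' @param indicators indicator data.frame.
#' @param reference_dmed distance to report (default 10 km).
#' @export
component_breakdown <- function(indicators, reference_dmed = 10) {
  ind <- indicators
  if (!is.null(ind$d_med))
    ind <- ind[ind$d_med == reference_dmed, , drop = FALSE]
  data.frame(iso3 = ind$iso3, d_med = ind$d_med,
             protconn = ind$protconn,
             protunconn_sea = ind$protunconn_sea,
             protunconn_outland = ind$protunconn_outland,
             protunconn_design = ind$protunconn_design,
             unprotected = 100 - ind$prot,
             protconn_bound = ind$protconn_bound,
             stringsAsFactors = FALSE)
}
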