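#' Write one level of a hierarchy as a GeoJSON FeatureCollection
#'
#' Each feature carries a `Polygon` geometry, the properties `area_id` and
#' `level`, and any additional per-area attributes supplied in `values`
#' (e.g. observed and fitted SIRs for map export).
#'
#' @param hierarchy an [area_hierarchy()] with geometry.
#' @param level level name.
#' @param values optional data frame with a column `area_id` plus numeric
#'   attribute columns.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_geojson <- function(hierarchy, level, values = NULL, path) {
  geom <- hierarchy$geometry[[level]]
  if (is.null(geom)) stop("no geometry stored for level ", level)
  ids <- hierarchy$ids[[level]]
  features <- lapply(seq_along(ids), function(i) {
    props <- list(area_id = ids[i], level = level)
    if (!is.null(values)) {
      row <- values[match(ids[i], values$area_id), setdiff(names(values), "area_id"),
                    drop = FALSE]
      props <- c(props, as.list(row))
    }
    ring <- lapply(seq_len(nrow(geom[[i]])), function(k) unname(geom[[i]][k, ]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Expects features with `Polygon` geometry and an `area_id` property
#' (a `level` property is returned when present).
#'
#' @param path GeoJSON file path.
#' @return List with `ids`, `level`, `polygons` (list of coordinate
#'   matrices — outer rings only) and `properties` (data frame).
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  feats <- fc$features
  ids <- vapply(feats, function(f) as.character(f$properties$area_id), "")
  level <- unique(vapply(feats, function(f) {
    lv <- f$properties$level
    if (is.null(lv)) NA_character_ else as.character(lv)
  }, ""))
  polygons <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon")) stop("only Polygon supported")
    ring <- f$geometry$coordinates[[1L]]
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  })
  props <- do.call(rbind, lapply(feats, function(f) {
    as.data.frame(lapply(f$properties, function(x) if (is.null(x)) NA else x),
                  stringsAsFactors = FALSE)
  }))
  list(ids = ids, level = level[!is.na(level)], polygons = polygons,
       properties = props)
}

#' Read an experiment/model configuration file (JSON or YAML)
#'
#' Recognised top-level keys: `scenario` (fields of [scenario_config()])
#' and `model` (fields of [bym_config()]).  A `seed` inside each section is
#' honoured; pipeline runs require one.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return List with `scenario` and `model` config objects.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml")
  scenario <- do.call(scenario_config, as.list(raw$scenario %||% list()))
  model <- do.call(bym_config, as.list(raw$model %||% list()))
  list(scenario = scenario, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
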