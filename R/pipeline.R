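.write_manifest <- function(dir, step, inputs, outputs, config, seed = NULL) {
  manifest <- list(
    step = step,
    package_version = as.character(utils::packageVersion("boulderreef")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    inputs = inputs,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  path <- file.path(dir, paste0("manifest_", step, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a survey to disk
#'
#' Runs the synthetic generator and writes the three files the real pipeline
#' consumes — `mesh.ply` (binary little-endian), `annotations.csv` and
#' `presence.csv` (S8 schema) — plus a JSON manifest recording the seed,
#' configuration and output checksums, so identical configuration reproduces
#' byte-identical outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [terrain_config()].
#' @param model a [presence_model()].
#' @return named character vector of written paths, invisibly.
#' @export
simulate_survey <- function(out_dir, config = terrain_config(),
                            model = presence_model()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- generate_terrain(config)
  pres <- generate_presence(tr$annotations, model, seed = config$seed)
  paths <- c(mesh = file.path(out_dir, "mesh.ply"),
             annotations = file.path(out_dir, "annotations.csv"),
             presence = file.path(out_dir, "presence.csv"))
  write_mesh(tr$mesh, paths[["mesh"]], binary = TRUE)
  write_annotations(tr$annotations, paths[["annotations"]])
  write_s8_table(pres, paths[["presence"]])
  .write_manifest(out_dir, "simulate", inputs = list(),
                  outputs = as.list(paths), config = unclass(config),
                  seed = config$seed)
  invisible(paths)
}

#' Compute per-boulder indicators from files or objects
#'
#' Thin orchestration over [boulder_indicators()]: accepts a mesh (object or
#' PLY/OBJ path) and annotations (object or CSV path), and optionally writes
#' the indicator CSV plus a manifest.
#'
#' @param mesh a [seafloor_mesh()] or a mesh file path.
#' @param annotations a [boulder_annotations()] table or a CSV path.
#' @param config an [indicator_config()].
#' @param out optional output CSV path.
#' @return the indicator data.frame (see [boulder_indicators()]).
#' @export
compute_indicators <- function(mesh, annotations,
                               config = indicator_config(), out = NULL) {
  mesh_path <- NULL
  if (is.character(mesh)) { mesh_path <- mesh; mesh <- read_mesh(mesh) }
  ann_path <- NULL
  if (is.character(annotations)) {
    ann_path <- annotations
    annotations <- read_annotations(annotations)
  }
  ind <- boulder_indicators(mesh, annotations, config)
  if (!is.null(out)) {
    write_indicators(ind, out)
    .write_manifest(dirname(out), "indicators",
                    inputs = list(mesh = mesh_path, annotations = ann_path),
                    outputs = list(out), config = unclass(config))
  }
  ind
}

#' Analyse a survey from files or objects
#'
#' Joins presence records to per-boulder indicators on `boulder_id`,
#' classifies the vegetation, runs [run_full_analysis()], and (when
#' `out_dir` is given) writes `report.json`, `report.txt` and the merged,
#' classified `records.csv` in the S8 schema.
#'
#' @param presence records table or S8-schema CSV path.
#' @param indicators optional indicator table or CSV path
#'   (from [compute_indicators()]).
#' @param out_dir optional output directory.
#' @return the [run_full_analysis()] `reef_analysis` object.
#' @export
analyze_survey <- function(presence, indicators = NULL, out_dir = NULL) {
  pres_path <- NULL
  if (is.character(presence)) {
    pres_path <- presence
    presence <- read_s8_table(presence)
  }
  ind_path <- NULL
  if (!is.null(indicators)) {
    if (is.character(indicators)) {
      ind_path <- indicators
      indicators <- read_indicators(indicators)
    }
    keep <- c("boulder_id", "relative_height_m", "surface_complexity", "valid")
    keep <- intersect(keep, names(indicators))
    ind <- indicators[, keep, drop = FALSE]
    names(ind)[names(ind) == "relative_height_m"] <- "relative_height"
    presence$relative_height <- NULL
    presence$surface_complexity <- NULL
    presence <- merge(presence, ind, by = "boulder_id", all.x = TRUE,
                      sort = FALSE)
  }
  records <- classify_records(presence)
  analysis <- run_full_analysis(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(json = file.path(out_dir, "report.json"),
               text = file.path(out_dir, "report.txt"),
               records = file.path(out_dir, "records.csv"))
    report_json(analysis, paths[["json"]])
    report_text(analysis, paths[["text"]])
    write_s8_table(records, paths[["records"]])
    .write_manifest(out_dir, "analyze",
                    inputs = list(presence = pres_path, indicators = ind_path),
                    outputs = as.list(paths), config = list())
  }
  analysis
}

.circle_coords <- function(cx, cy, r, segments = 24L) {
  th <- seq(0, 2 * pi, length.out = segments + 1L)
  lapply(seq_along(th), function(i) c(cx + r * cos(th[i]), cy + r * sin(th[i])))
}

#' Render a vegetation map as GeoJSON
#'
#' One feature per boulder, in annotation order: a circular polygon over the
#' footprint with the community, score and bottom type as properties —
#' the vector equivalent of a colour-coded vegetation map.
#'
#' @param records classified records table (must contain every annotated
#'   `boulder_id`).
#' @param annotations a [boulder_annotations()] table.
#' @param path optional output path for the GeoJSON file.
#' @param segments vertices per circle polygon.
#' @return the GeoJSON structure as a list (class `geo_list`-like),
#'   invisibly written to `path` when given.
#' @export
render_vegetation_map <- function(records, annotations, path = NULL,
                                  segments = 24L) {
  if (!"community" %in% names(records) && nrow(records) > 0L) {
    records <- classify_records(records)
  }
  if (nrow(records) > 0L) {
    missing_ids <- setdiff(annotations$boulder_id, records$boulder_id)
    if (length(missing_ids)) {
      stop("annotations without matching records: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  features <- list()
  if (nrow(records) > 0L) {
    ri <- match(annotations$boulder_id, records$boulder_id)
    features <- lapply(seq_len(nrow(annotations)), function(i) {
      r <- records[ri[i], ]
      list(type = "Feature",
           properties = list(boulder_id = annotations$boulder_id[i],
                             community = as.character(r$community),
                             score = as.integer(r$score),
                             bottom_type = as.character(annotations$bottom_type[i])),
           geometry = list(type = "Polygon",
                           coordinates = list(.circle_coords(
                             annotations$x_m[i], annotations$y_m[i],
                             annotations$radius_m[i], segments))))
    })
  }
  gj <- list(type = "FeatureCollection", features = features)
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(gj)
}
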