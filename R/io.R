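# File formats and the pipeline driver.
#
# Regions travel as GeoJSON FeatureCollections (QuPath-style: planar
# micrometre coordinates, one Polygon feature per ring, a "role" property
# naming the region kind); cells and cohorts as CSV; configuration as YAML;
# machine-readable summaries as JSON.

.REGION_ROLES <- c("tumor", "para", "exclusion", "lobule", "stroma")

#' Read a region annotation from GeoJSON
#'
#' Expects a FeatureCollection whose features are Polygons with a
#' `properties$role` among `tumor`, `para`, `exclusion`, `lobule`,
#' `stroma`. Multiple tumor features become rings of one tumor polygon.
#' Optional top-level (or per-tumor-feature) properties
#' `stromal_fraction_tumor` / `stromal_fraction_para` carry the manual
#' stromal fractions.
#'
#' @param path GeoJSON file path.
#' @return a [region_annotation()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("schema error: expected a GeoJSON FeatureCollection")
  rings <- list(tumor = list(), para = list(), exclusion = list(),
                lobule = list(), stroma = list())
  f_tum <- NULL
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    role <- f$properties$role
    if (is.null(role) || !role %in% .REGION_ROLES)
      stop("schema error: feature ", i, " has unknown role '",
           if (is.null(role)) "<missing>" else role, "'")
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon")
      stop("schema error: feature ", i, " is not a Polygon")
    for (ring in geom$coordinates) {
      xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      # GeoJSON rings are closed; drop the duplicated last vertex
      if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), ]
      rings[[role]] <- c(rings[[role]], list(list(x = xy[, 1], y = xy[, 2])))
    }
    if (role == "tumor" && is.null(f_tum)) f_tum <- f$properties
  }
  if (length(rings$tumor) == 0L) stop("schema error: no tumor feature present")
  get_frac <- function(key) {
    v <- gj$properties[[key]]
    if (is.null(v)) v <- f_tum[[key]]
    if (is.null(v)) NULL else as.numeric(v)
  }
  region_annotation(
    tumor = rings$tumor,
    para = if (length(rings$para)) rings$para else NULL,
    exclusions = rings$exclusion, lobules = rings$lobule,
    stroma = rings$stroma,
    stromal_fraction_tumor = get_frac("stromal_fraction_tumor"),
    stromal_fraction_para = get_frac("stromal_fraction_para"))
}

.ring_to_geojson <- function(ring) {
  closed <- Map(function(x, y) list(x, y), c(ring$x, ring$x[1]), c(ring$y, ring$y[1]))
  list(closed)
}

#' Write a region annotation to GeoJSON
#'
#' @param annotation a [region_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(annotation, path) {
  stopifnot(inherits(annotation, "region_annotation"))
  feats <- list()
  add <- function(paths, role) {
    for (ring in paths)
      feats[[length(feats) + 1L]] <<- list(
        type = "Feature",
        properties = list(role = role),
        geometry = list(type = "Polygon", coordinates = .ring_to_geojson(ring)))
  }
  add(annotation$tumor, "tumor"); add(annotation$para, "para")
  add(annotation$exclusions, "exclusion"); add(annotation$lobules, "lobule")
  add(annotation$stroma, "stroma")
  props <- list()
  if (!is.null(annotation$stromal_fraction_tumor))
    props$stromal_fraction_tumor <- annotation$stromal_fraction_tumor
  if (!is.null(annotation$stromal_fraction_para))
    props$stromal_fraction_para <- annotation$stromal_fraction_para
  obj <- list(type = "FeatureCollection", properties = props, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Mandatory columns: `id`, `x_um`, `y_um`, `cell_class`,
#' `nucleus_area_um2`, `in_stroma`; optional: `marker` (blank means none),
#' `pdl1_positive`. Malformed rows (non-finite coordinates, non-positive
#' nucleus area, unknown class) are rejected with a report of their line
#' numbers attached as attribute `"rejected"` and a warning.
#'
#' @param path CSV path.
#' @return data.frame of cell records with columns `id`, `x`, `y`,
#'   `cell_class`, `nucleus_area_um2`, `in_stroma`, `marker`,
#'   `pdl1_positive`.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_um", "y_um", "cell_class", "nucleus_area_um2", "in_stroma")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (!"marker" %in% names(raw)) raw$marker <- "none"
  if (!"pdl1_positive" %in% names(raw)) raw$pdl1_positive <- NA
  raw$marker[is.na(raw$marker) | raw$marker == ""] <- "none"

  x <- suppressWarnings(as.numeric(raw$x_um))
  y <- suppressWarnings(as.numeric(raw$y_um))
  area <- suppressWarnings(as.numeric(raw$nucleus_area_um2))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(area) | area <= 0 |
    !raw$cell_class %in% c("lymphocyte", "tumor", "other") |
    !raw$marker %in% c("CD4", "CD8", "CD20", "none") |
    (raw$marker != "none" & raw$cell_class != "lymphocyte")
  cells <- data.frame(id = as.character(raw$id), x = x, y = y,
                      cell_class = raw$cell_class, nucleus_area_um2 = area,
                      in_stroma = as.logical(raw$in_stroma),
                      marker = raw$marker,
                      pdl1_positive = as.logical(raw$pdl1_positive),
                      stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(cells) <- NULL
  if (any(bad)) {
    rejected <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                           id = as.character(raw$id)[bad])
    warning(sum(bad), " malformed cell row(s) rejected (lines ",
            paste(utils::head(rejected$line, 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "", ")")
    attr(cells, "rejected") <- rejected
  }
  cells
}

#' Write a cell table to CSV
#'
#' @param cells cell data.frame (columns `id`, `x`, `y`, `cell_class`,
#'   `nucleus_area_um2`, `in_stroma`, optionally `marker`,
#'   `pdl1_positive`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  out <- data.frame(id = cells$id, x_um = cells$x, y_um = cells$y,
                    cell_class = cells$cell_class,
                    nucleus_area_um2 = cells$nucleus_area_um2,
                    in_stroma = cells$in_stroma,
                    marker = if ("marker" %in% names(cells)) cells$marker else "none",
                    pdl1_positive = if ("pdl1_positive" %in% names(cells))
                      cells$pdl1_positive else NA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param im_width_um invasive-margin band width (micrometres, > 0).
#' @param cut_tc,cut_im,cut_para classification cut-offs in (0, 1).
#' @param stromal_fraction_tumor,stromal_fraction_para fallback manual
#'   stromal fractions applied when an annotation carries none.
#' @param holm_adjust apply Holm correction to families of p-values.
#' @param reverse_km use the reverse-KM follow-up summary.
#' @param seed RNG seed used by stochastic steps.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(im_width_um = 500, cut_tc = 0.20, cut_im = 0.10,
                            cut_para = 0.20, stromal_fraction_tumor = NULL,
                            stromal_fraction_para = NULL, holm_adjust = FALSE,
                            reverse_km = FALSE, seed = 1L) {
  ip_cutoffs(cut_tc, cut_im, cut_para)  # validates
  if (im_width_um <= 0) stop("im_width_um must be > 0")
  structure(list(im_width_um = im_width_um, cut_tc = cut_tc, cut_im = cut_im,
                 cut_para = cut_para,
                 stromal_fraction_tumor = stromal_fraction_tumor,
                 stromal_fraction_para = stromal_fraction_para,
                 holm_adjust = isTRUE(holm_adjust),
                 reverse_km = isTRUE(reverse_km), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the assessment pipeline over one or more slides
#'
#' Executes geometry, quantification and classification per slide, in that
#' order, and returns per-case metrics plus the cohort pattern summary.
#' When `out_dir` is given, writes `case_metrics.csv` and `summary.json`
#' (byte-stable for fixed inputs).
#'
#' @param slides named list; each element is a list with `regions` (path or
#'   [region_annotation()]) and `cells` (path or cell data.frame).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `metrics` (per-case data.frame: ratios, sTIL%,
#'   pattern, flags), `summary` (pattern distribution), `config`.
#' @export
run_pipeline <- function(slides, config = pipeline_config(), out_dir = NULL) {
  if (length(slides) == 0L) stop("no input slides")
  ids <- names(slides)
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_along(slides))
  rows <- vector("list", length(slides))
  for (i in seq_along(slides)) {
    res <- tryCatch({
      ann <- slides[[i]]$regions
      if (is.character(ann)) ann <- read_regions(ann)
      if (is.null(ann$stromal_fraction_tumor) &&
          !is.null(config$stromal_fraction_tumor))
        ann$stromal_fraction_tumor <- config$stromal_fraction_tumor
      if (is.null(ann$stromal_fraction_para) &&
          !is.null(config$stromal_fraction_para))
        ann$stromal_fraction_para <- config$stromal_fraction_para
      cells <- slides[[i]]$cells
      if (is.character(cells)) cells <- read_cells(cells)
      geom <- build_compartments(ann, im_width = config$im_width_um)
      m <- compartment_metrics(cells, geom)
      lab <- classify_ip(m$r_tc, m$r_im, m$r_para,
                         ip_cutoffs(config$cut_tc, config$cut_im, config$cut_para))
      data.frame(case_id = ids[i], r_tc = m$r_tc, r_im = m$r_im,
                 r_para = m$r_para, stromal_til_pct = m$stromal_til_pct,
                 ip = as.character(lab$ip), merged = as.character(lab$merged),
                 n_lymphocytes = sum(m$n_cells),
                 flags = paste(c(m$flags,
                                 if (lab$tc_im_discordant) "TC_IM_DISCORDANT"),
                               collapse = ";"),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      stop("pipeline failed at case '", ids[i], "': ", conditionMessage(e),
           call. = FALSE))
    rows[[i]] <- res
  }
  metrics <- do.call(rbind, rows)
  summ <- classify_cohort(metrics[, c("r_tc", "r_im", "r_para")],
                          ip_cutoffs(config$cut_tc, config$cut_im,
                                     config$cut_para))$summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "case_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(n_cases = nrow(metrics), ip_distribution = summ),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(metrics = metrics, summary = summ, config = config)
}
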