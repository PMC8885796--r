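# Quantification of lymphocyte infiltration per compartment.
#
# The scoring unit is the lymphatic-nucleus-area-to-stromal-area ratio: the
# summed nucleus area of stromal lymphocytes (TILs in TC/IM, PILs in Para;
# plasma cells count as lymphocytes) divided by the stromal area of the
# compartment, both in consistent units. A global linear calibration maps
# this nucleus-area ratio to the conventional stromal-TIL percentage: a 20%
# nucleus-area ratio corresponds to 50% stromal TILs (the
# lymphocyte-predominant threshold), i.e. percentage = 250 * ratio.

.MARKERS <- c("CD4", "CD8", "CD20")
.COMPARTMENTS <- c("TC", "IM", "PARA")

.check_cells <- function(cells, need = c("cell_class", "nucleus_area_um2")) {
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(cells)
}

#' Lymphatic-nucleus-area to stromal-area ratio
#'
#' Sums the nucleus areas of stromal lymphocytes assigned to one compartment
#' and divides by the compartment's stromal area.
#'
#' @param cells data.frame of cell records carrying at least `cell_class`,
#'   `nucleus_area_um2`, `in_stroma` and a `compartment` label column (as
#'   produced by [assign_compartment()]).
#' @param compartment one of `"TC"`, `"IM"`, `"PARA"`.
#' @param stromal_area_mm2 stromal area of the compartment (> 0).
#' @return dimensionless ratio >= 0; 0 when no qualifying cells.
#' @export
nucleus_area_ratio <- function(cells, compartment, stromal_area_mm2) {
  compartment <- match.arg(compartment, .COMPARTMENTS)
  if (!is.numeric(stromal_area_mm2) || stromal_area_mm2 <= 0)
    stop("stromal_area_mm2 must be > 0")
  if (nrow(cells) == 0L) return(0)
  .check_cells(cells, c("cell_class", "nucleus_area_um2", "in_stroma", "compartment"))
  sel <- cells$cell_class == "lymphocyte" & as.logical(cells$in_stroma) &
    cells$compartment == compartment
  if (any(cells$nucleus_area_um2[sel] <= 0))
    stop("nucleus_area_um2 must be > 0 for all cells")
  sum(cells$nucleus_area_um2[sel]) / (stromal_area_mm2 * 1e6)
}

#' Convert a nucleus-area ratio to a stromal-TIL percentage
#'
#' Applies the linear nucleus-to-whole-cell calibration under which a 0.20
#' nucleus-area ratio equals 50% stromal TILs: `percent = 250 * ratio`.
#' Values above 100 are capped at 100 and flagged via the `"capped"`
#' attribute.
#'
#' @param r_nuc nucleus-area ratio(s), >= 0.
#' @return percentage(s) in `[0, 100]`.
#' @export
stromal_til_percent <- function(r_nuc) {
  if (any(!is.finite(r_nuc)) || any(r_nuc < 0))
    stop("nucleus-area ratio must be finite and >= 0")
  pct <- 250 * r_nuc
  capped <- pct > 100
  pct[capped] <- 100
  attr(pct, "capped") <- capped
  pct
}

#' Marker-positive lymphocyte density
#'
#' Count of lymphocytes carrying an IHC marker in a compartment divided by
#' the compartment's total area (cells per mm^2, matching the per-mm^2
#' reporting convention; the denominator is total, not stromal, area).
#'
#' @param cells labeled cell table (see [nucleus_area_ratio()]) with a
#'   `marker` column.
#' @param compartment one of `"TC"`, `"IM"`, `"PARA"`.
#' @param marker one of `"CD4"`, `"CD8"`, `"CD20"`.
#' @param area_mm2 total compartment area (> 0).
#' @return density in positive lymphocytes per mm^2.
#' @export
marker_density <- function(cells, compartment, marker, area_mm2) {
  compartment <- match.arg(compartment, .COMPARTMENTS)
  if (!marker %in% .MARKERS) stop("unknown marker: ", marker)
  if (!is.numeric(area_mm2) || area_mm2 <= 0) stop("area_mm2 must be > 0")
  if (nrow(cells) == 0L) return(0)
  .check_cells(cells, c("cell_class", "marker", "compartment"))
  n <- sum(cells$cell_class == "lymphocyte" & cells$marker == marker &
             cells$compartment == compartment, na.rm = TRUE)
  n / area_mm2
}

#' Lymphocyte subpopulation ratios
#'
#' T-to-B, B-to-T and cytotoxic-T fractions from CD4/CD8/CD20 densities.
#' A zero denominator yields `NA` plus an entry in the `undefined` flag set
#' rather than an infinity.
#'
#' @param cd4,cd8,cd20 non-negative densities (cells per mm^2).
#' @return list with `t_to_b` = (CD4+CD8)/CD20, `b_to_t` = CD20/(CD4+CD8),
#'   `cd8_to_t` = CD8/(CD4+CD8), and `undefined` (character vector naming
#'   ratios with zero denominators).
#' @export
subpopulation_ratios <- function(cd4, cd8, cd20) {
  v <- c(cd4 = cd4, cd8 = cd8, cd20 = cd20)
  if (any(!is.finite(v)) || any(v < 0)) stop("densities must be finite and >= 0")
  t_total <- cd4 + cd8
  undefined <- character(0)
  t_to_b <- if (cd20 > 0) t_total / cd20 else { undefined <- c(undefined, "t_to_b"); NA_real_ }
  b_to_t <- if (t_total > 0) cd20 / t_total else { undefined <- c(undefined, "b_to_t"); NA_real_ }
  cd8_to_t <- if (t_total > 0) cd8 / t_total else { undefined <- c(undefined, "cd8_to_t"); NA_real_ }
  list(t_to_b = t_to_b, b_to_t = b_to_t, cd8_to_t = cd8_to_t, undefined = undefined)
}

#' Per-slide compartment metrics
#'
#' Convenience wrapper running assignment (when needed) and computing the
#' ratio triple, the calibrated stromal-TIL percentage, marker densities and
#' lymphocyte counts per compartment for one slide.
#'
#' @param cells cell table; a `compartment` column is added via
#'   [assign_compartment()] when absent (requires `x`, `y`).
#' @param geom a [build_compartments()] result.
#' @return list of class `compartment_metrics` with `r_tc`, `r_im`,
#'   `r_para`, `stromal_til_pct`, `density` (compartment x marker matrix),
#'   `n_cells` (lymphocytes per compartment) and `flags`.
#' @export
compartment_metrics <- function(cells, geom) {
  stopifnot(inherits(geom, "compartment_geometry"))
  if (!"compartment" %in% names(cells))
    cells$compartment <- assign_compartment(cells, geom)
  a <- geom$areas
  ratio1 <- function(comp) {
    s <- a$stromal_area_mm2[a$compartment == comp]
    if (s <= 0) return(NA_real_)
    nucleus_area_ratio(cells, comp, s)
  }
  r <- vapply(.COMPARTMENTS, ratio1, numeric(1))
  dens <- matrix(0, 3, 3, dimnames = list(.COMPARTMENTS, .MARKERS))
  for (comp in .COMPARTMENTS) {
    ar <- a$area_mm2[a$compartment == comp]
    if (ar > 0)
      for (m in .MARKERS) dens[comp, m] <- marker_density(cells, comp, m, ar)
  }
  n_cells <- vapply(.COMPARTMENTS, function(comp)
    sum(cells$cell_class == "lymphocyte" & cells$compartment == comp), numeric(1))
  flags <- character(0)
  if (any(r > 1, na.rm = TRUE)) flags <- c(flags, "RATIO_GT_1")
  if (geom$tc_empty) flags <- c(flags, "TC_EMPTY")
  structure(list(
    r_tc = r[["TC"]], r_im = r[["IM"]], r_para = r[["PARA"]],
    stromal_til_pct = if (is.na(r[["TC"]])) NA_real_
                      else as.numeric(stromal_til_percent(r[["TC"]])),
    density = dens, n_cells = n_cells, flags = flags
  ), class = "compartment_metrics")
}

#' @export
print.compartment_metrics <- function(x, ...) {
  cat(sprintf("r_TC = %.4f, r_IM = %.4f, r_Para = %.4f (sTIL %% = %.1f)\n",
              x$r_tc, x$r_im, x$r_para, x$stromal_til_pct))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Pool marker densities into "hot tumor" and "hot Para" groups
#'
#' For immune-subpopulation comparisons: the hot-tumor sample is the
#' per-case average of TC and IM marker densities over IP1 and IP2 cases
#' (the lymphocyte-predominant patterns); the hot-Para sample is the Para
#' marker density over IP1 and IP4 cases (the patterns with heavy para
#' infiltration). Per-case subpopulation ratios are returned for downstream
#' rank tests.
#'
#' @param densities data.frame with one row per case and columns `ip` plus
#'   `<comp>_<marker>` densities, e.g. `tc_cd4`, `im_cd8`, `para_cd20`.
#' @return list with data.frames `hot_tumor` and `hot_para`, each holding
#'   per-case pooled `cd4`, `cd8`, `cd20` densities and the derived
#'   `t_to_b`, `b_to_t`, `cd8_to_t` ratio columns.
#' @export
hot_group_metrics <- function(densities) {
  need <- c("ip", paste0(rep(c("tc_", "im_", "para_"), each = 3),
                         rep(c("cd4", "cd8", "cd20"), 3)))
  miss <- setdiff(need, names(densities))
  if (length(miss)) stop("densities table lacks column(s): ", paste(miss, collapse = ", "))
  with_ratios <- function(d) {
    tt <- d$cd4 + d$cd8
    d$t_to_b <- ifelse(d$cd20 > 0, tt / d$cd20, NA_real_)
    d$b_to_t <- ifelse(tt > 0, d$cd20 / tt, NA_real_)
    d$cd8_to_t <- ifelse(tt > 0, d$cd8 / tt, NA_real_)
    d
  }
  tum <- densities[densities$ip %in% c("IP1", "IP2"), , drop = FALSE]
  if (nrow(tum) == 0L) stop("empty-sample: no IP1/IP2 cases for the hot-tumor group")
  hot_tumor <- data.frame(
    case = rownames(tum),
    cd4 = (tum$tc_cd4 + tum$im_cd4) / 2,
    cd8 = (tum$tc_cd8 + tum$im_cd8) / 2,
    cd20 = (tum$tc_cd20 + tum$im_cd20) / 2
  )
  par <- densities[densities$ip %in% c("IP1", "IP4"), , drop = FALSE]
  if (nrow(par) == 0L) stop("empty-sample: no IP1/IP4 cases for the hot-Para group")
  hot_para <- data.frame(case = rownames(par), cd4 = par$para_cd4,
                         cd8 = par$para_cd8, cd20 = par$para_cd20)
  list(hot_tumor = with_ratios(hot_tumor), hot_para = with_ratios(hot_para))
}
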