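# ---- polygon primitives -----------------------------------------------------
# Polygons are "path lists" in the polyclip convention: a list of rings, each
# ring a list(x = , y = ) in micrometre coordinates (image convention: origin
# top-left, y increasing downward). Boolean results from polyclip carry holes
# as opposite-orientation rings, so signed areas sum to the enclosed area.

.as_paths <- function(p, name = "polygon") {
  if (is.null(p) || (is.list(p) && length(p) == 0L)) return(list())
  if (is.matrix(p) || is.data.frame(p)) {
    p <- as.data.frame(p)
    if (!all(c("x", "y") %in% names(p))) names(p)[1:2] <- c("x", "y")
    return(list(list(x = as.numeric(p$x), y = as.numeric(p$y))))
  }
  if (is.list(p) && !is.null(p$x) && !is.null(p$y)) {
    return(list(list(x = as.numeric(p$x), y = as.numeric(p$y))))
  }
  if (is.list(p)) {
    return(unlist(lapply(p, .as_paths, name = name), recursive = FALSE))
  }
  stop("cannot interpret ", name, " as a polygon (need x/y list, matrix or list of rings)")
}

.ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Area of a polygon path list in square millimetres
#'
#' Holes (opposite-orientation rings, as produced by the clipping backend)
#' subtract from the total.
#'
#' @param paths polygon path list (list of rings with `x`, `y` in micrometres).
#' @return area in mm^2 (scalar, >= 0).
#' @export
poly_area_mm2 <- function(paths) {
  paths <- .as_paths(paths)
  if (length(paths) == 0L) return(0)
  abs(sum(vapply(paths, .ring_signed_area, numeric(1)))) / 1e6
}

# self-intersection test for a single ring (O(n^2) segment check; annotation
# rings are small). Shared endpoints of adjacent segments are not crossings.
.ring_self_intersects <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 4L) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  seg_int <- function(i, j) {
    d1x <- x2[i] - x[i]; d1y <- y2[i] - y[i]
    d2x <- x2[j] - x[j]; d2y <- y2[j] - y[j]
    denom <- d1x * d2y - d1y * d2x
    if (abs(denom) < 1e-12) return(FALSE)
    t <- ((x[j] - x[i]) * d2y - (y[j] - y[i]) * d2x) / denom
    u <- ((x[j] - x[i]) * d1y - (y[j] - y[i]) * d1x) / denom
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) if (seg_int(i, j)) return(TRUE)
  }
  FALSE
}

.poly_op <- function(a, b, op) {
  if (length(a) == 0L) {
    if (op == "union") return(b)
    return(list())
  }
  if (length(b) == 0L) {
    if (op == "intersection") return(list())
    return(a)
  }
  polyclip::polyclip(a, b, op = op, fillA = "nonzero", fillB = "nonzero")
}

# membership of points in a path list: even-odd over rings, boundary counts
# as inside (ties between regions are resolved by assignment priority).
# A bounding-box prefilter keeps the cost of small rings (exclusion discs,
# lobules) proportional to the points near them.
.points_in_paths <- function(x, y, paths) {
  n <- length(x)
  if (length(paths) == 0L || n == 0L) return(rep(FALSE, n))
  inside <- integer(n)
  on_bd <- rep(FALSE, n)
  for (ring in paths) {
    cand <- which(x >= min(ring$x) & x <= max(ring$x) &
                    y >= min(ring$y) & y <= max(ring$y))
    if (length(cand) == 0L) next
    hit <- polyclip::pointinpolygon(list(x = x[cand], y = y[cand]), ring)
    inside[cand] <- inside[cand] + (hit == 1L)
    on_bd[cand] <- on_bd[cand] | (hit == -1L)
  }
  (inside %% 2L == 1L) | on_bd
}

# ---- region annotation ------------------------------------------------------

#' Construct a slide region annotation
#'
#' Bundles the manually delineated regions of one whole-slide image: the
#' tumor boundary, the para-tumor (lobular) boundary, confounder exclusions
#' (necrosis, tertiary lymphoid structures, intermixed normal tissue),
#' lobule outlines, and either manual stromal fractions or explicit stroma
#' polygons. Coordinates are micrometres.
#'
#' @param tumor tumor boundary: ring(s) as `list(x =, y =)`, a two-column
#'   matrix/data.frame, or a list of such rings (holes allowed).
#' @param para para-tumor boundary, or `NULL` when no para region was
#'   annotated.
#' @param exclusions list of exclusion polygons to subtract from every
#'   compartment.
#' @param lobules list of lobule outlines (must lie inside `para`).
#' @param stroma optional explicit stroma polygons; when supplied, stromal
#'   areas are computed by intersection instead of from the fractions.
#' @param stromal_fraction_tumor,stromal_fraction_para manual
#'   stromal-to-total area fractions in (0, 1]; default to 1 with a warning
#'   when neither a fraction nor stroma polygons are available.
#' @param overlap_tol maximal tolerated fraction of the para area that may
#'   overlap the tumor interior (overlap is clipped away).
#' @return an object of class `region_annotation`.
#' @export
region_annotation <- function(tumor, para = NULL, exclusions = list(),
                              lobules = list(), stroma = list(),
                              stromal_fraction_tumor = NULL,
                              stromal_fraction_para = NULL,
                              overlap_tol = 0.01) {
  tumor <- .as_paths(tumor, "tumor")
  if (length(tumor) == 0L) stop("tumor boundary is required")
  for (ring in tumor) {
    if (length(ring$x) < 3L) stop("tumor ring has fewer than 3 vertices")
    if (!all(is.finite(ring$x)) || !all(is.finite(ring$y)))
      stop("invalid-geometry: non-finite tumor coordinates")
    if (.ring_self_intersects(ring))
      stop("invalid-geometry: self-intersecting tumor polygon")
  }
  if (poly_area_mm2(tumor) <= 0) stop("tumor boundary encloses zero area")
  para <- .as_paths(para, "para")
  exclusions <- .as_paths(exclusions, "exclusions")
  lobules <- if (length(lobules)) lapply(lobules, function(l) .as_paths(l, "lobule")[[1L]]) else list()
  stroma <- .as_paths(stroma, "stroma")

  if (length(para)) {
    ov <- poly_area_mm2(.poly_op(para, tumor, "intersection"))
    if (ov > overlap_tol * poly_area_mm2(para))
      stop("para boundary overlaps the tumor interior beyond tolerance (",
           signif(ov, 4), " mm^2)")
    for (l in lobules) {
      out <- poly_area_mm2(.poly_op(list(l), para, "minus"))
      if (out > 1e-9 * max(poly_area_mm2(list(l)), 1e-12))
        stop("lobule lies outside the para boundary")
    }
  } else if (length(lobules)) {
    stop("lobules supplied without a para boundary")
  }

  chk_frac <- function(f, nm) {
    if (!is.null(f) && (!is.numeric(f) || f <= 0 || f > 1))
      stop(nm, " must lie in (0, 1]")
    f
  }
  structure(list(
    tumor = tumor, para = para, exclusions = exclusions,
    lobules = lobules, stroma = stroma,
    stromal_fraction_tumor = chk_frac(stromal_fraction_tumor, "stromal_fraction_tumor"),
    stromal_fraction_para = chk_frac(stromal_fraction_para, "stromal_fraction_para")
  ), class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("Slide region annotation\n")
  cat(sprintf("  tumor area: %.3f mm^2 (%d ring%s)\n", poly_area_mm2(x$tumor),
              length(x$tumor), if (length(x$tumor) > 1) "s" else ""))
  if (length(x$para)) cat(sprintf("  para area:  %.3f mm^2\n", poly_area_mm2(x$para)))
  cat(sprintf("  exclusions: %d, lobules: %d, stroma polygons: %d\n",
              length(x$exclusions), length(x$lobules), length(x$stroma)))
  invisible(x)
}

# ---- compartment construction -----------------------------------------------

.stromal_fraction <- function(frac, what) {
  if (is.null(frac)) {
    warning("stromal_fraction_", what,
            " not provided; defaulting to 1.0 (ratios use total area)")
    1.0
  } else frac
}

#' Build tumor-center, invasive-margin and para compartments
#'
#' The invasive margin (IM) is the band of the annotated tumor area lying
#' within `im_width` of the tumor boundary; the tumor center (TC) is the
#' rest of the tumor area; the para compartment is the annotated para region
#' clipped to exclude the tumor. Exclusion polygons are subtracted from all
#' three compartments before any area is measured. TC may be empty when the
#' band swallows the whole tumor (flagged, not an error).
#'
#' @param annotation a [region_annotation()].
#' @param im_width band width in micrometres (> 0); default 500.
#' @return object of class `compartment_geometry` with elements `tc`, `im`,
#'   `para` (path lists), `areas` (data.frame of total and stromal area in
#'   mm^2 per compartment), `im_width`, and flag `tc_empty`.
#' @export
build_compartments <- function(annotation, im_width = 500) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (!is.numeric(im_width) || length(im_width) != 1L || im_width <= 0)
    stop("im_width must be a positive length in micrometres")

  tumor <- annotation$tumor
  excl <- annotation$exclusions
  tumor_net <- .poly_op(tumor, excl, "minus")
  if (poly_area_mm2(tumor_net) <= 0)
    stop("empty-compartment: exclusions cover the entire tumor (TC and IM empty)")

  core <- polyclip::polyoffset(tumor, -im_width, jointype = "round")
  im <- .poly_op(.poly_op(tumor, core, "minus"), excl, "minus")
  tc <- .poly_op(core, excl, "minus")
  para <- .poly_op(.poly_op(annotation$para, tumor, "minus"), excl, "minus")

  tc_empty <- poly_area_mm2(tc) <= 0
  if (tc_empty)
    warning("tumor center is empty: im_width >= maximal inscribed radius; ",
            "the IM band covers the whole tumor")

  a_tc <- poly_area_mm2(tc); a_im <- poly_area_mm2(im); a_para <- poly_area_mm2(para)
  if (length(annotation$stroma)) {
    s_tc <- poly_area_mm2(.poly_op(tc, annotation$stroma, "intersection"))
    s_im <- poly_area_mm2(.poly_op(im, annotation$stroma, "intersection"))
    s_para <- poly_area_mm2(.poly_op(para, annotation$stroma, "intersection"))
  } else {
    f_t <- .stromal_fraction(annotation$stromal_fraction_tumor, "tumor")
    f_p <- if (length(para)) .stromal_fraction(annotation$stromal_fraction_para, "para") else 1
    s_tc <- a_tc * f_t; s_im <- a_im * f_t; s_para <- a_para * f_p
  }

  areas <- data.frame(
    compartment = c("TC", "IM", "PARA"),
    area_mm2 = c(a_tc, a_im, a_para),
    stromal_area_mm2 = c(s_tc, s_im, s_para),
    stringsAsFactors = FALSE
  )
  structure(list(tc = tc, im = im, para = para,
                 exclusions = excl, tumor = tumor, tumor_net = tumor_net,
                 im_width = im_width, areas = areas, tc_empty = tc_empty),
            class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("Compartment geometry (IM width %g um)%s\n", x$im_width,
              if (x$tc_empty) " [TC EMPTY]" else ""))
  print(x$areas, row.names = FALSE)
  invisible(x)
}

#' Assign cells to spatial compartments
#'
#' Labels each cell centroid with exactly one of `EXCLUDED`, `IM`, `TC`,
#' `PARA`, `OUTSIDE` by point-in-polygon membership, resolved in that
#' priority order (boundary points belong to the highest-priority region
#' whose boundary they touch, which makes assignment deterministic).
#'
#' @param cells data.frame with numeric columns `x`, `y` in micrometres
#'   (additional columns are ignored).
#' @param geom a [build_compartments()] result.
#' @return factor of compartment labels, one per row of `cells`, with levels
#'   `TC`, `IM`, `PARA`, `EXCLUDED`, `OUTSIDE`.
#' @export
assign_compartment <- function(cells, geom) {
  stopifnot(inherits(geom, "compartment_geometry"))
  x <- as.numeric(cells$x); y <- as.numeric(cells$y)
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("invalid-cell: non-finite cell coordinates")
  lab <- rep("OUTSIDE", length(x))
  todo <- rep(TRUE, length(x))
  for (region in list(c("EXCLUDED", "exclusions"), c("IM", "im"),
                      c("TC", "tc"), c("PARA", "para"))) {
    if (!any(todo)) break
    hit <- .points_in_paths(x[todo], y[todo], geom[[region[2L]]])
    lab[todo][hit] <- region[1L]
    todo[todo] <- !hit
  }
  factor(lab, levels = c("TC", "IM", "PARA", "EXCLUDED", "OUTSIDE"))
}

#' Check the TC + IM area partition
#'
#' Reports how closely area(TC) + area(IM) matches the area of the tumor
#' with exclusions removed. Used as a self-diagnostic; never raises.
#'
#' @param geom a [build_compartments()] result (or `NULL` for a degenerate
#'   empty report).
#' @param annotation the matching [region_annotation()] (optional; the
#'   reference area is recomputed from it when given, otherwise taken from
#'   `geom`).
#' @return list with `absolute_mm2` and `relative` residuals and the areas.
#' @export
partition_check <- function(geom, annotation = NULL) {
  if (is.null(geom)) {
    return(list(absolute_mm2 = 0, relative = 0, tc_im_mm2 = 0, tumor_net_mm2 = 0))
  }
  stopifnot(inherits(geom, "compartment_geometry"))
  ref <- if (!is.null(annotation)) {
    poly_area_mm2(.poly_op(annotation$tumor, annotation$exclusions, "minus"))
  } else {
    poly_area_mm2(geom$tumor_net)
  }
  got <- sum(geom$areas$area_mm2[geom$areas$compartment %in% c("TC", "IM")])
  abs_res <- abs(got - ref)
  list(absolute_mm2 = abs_res,
       relative = if (ref > 0) abs_res / ref else 0,
       tc_im_mm2 = got, tumor_net_mm2 = ref)
}
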