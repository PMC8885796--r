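# shared fixtures built in code

square_ring <- function(side_um = 4000, x0 = 0, y0 = 0) {
  list(x = x0 + c(0, side_um, side_um, 0), y = y0 + c(0, 0, side_um, side_um))
}

circle_ring <- function(r_um, n = 360, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + r_um * cos(th), y = cy + r_um * sin(th))
}

square_annotation <- function(side_um = 4000, stromal = 0.5, ...) {
  region_annotation(square_ring(side_um), stromal_fraction_tumor = stromal, ...)
}

# cells at given coordinates, all stromal lymphocytes of fixed nucleus area
lymph_cells <- function(x, y, area = 30, in_stroma = TRUE, marker = "none") {
  data.frame(x = x, y = y, cell_class = "lymphocyte",
             nucleus_area_um2 = area, in_stroma = in_stroma, marker = marker,
             stringsAsFactors = FALSE)
}

# small fast simulation config for round-trip style tests
fast_config <- function(...) {
  simulation_config(tumor_diameter_um = c(2000, 3500), ...)
}
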