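test_that("square tumor partitions exactly into TC and IM", {
  ann <- square_annotation(4000, stromal = 0.5)
  g <- build_compartments(ann, im_width = 500)
  a <- g$areas
  expect_equal(a$area_mm2[a$compartment == "TC"], 9)
  expect_equal(a$area_mm2[a$compartment == "IM"], 7)
  expect_equal(a$stromal_area_mm2[a$compartment == "TC"], 4.5)
  pc <- partition_check(g, ann)
  expect_lt(pc$relative, 1e-9)
})

test_that("circular tumor IM area matches the closed-form annulus", {
  ann <- region_annotation(circle_ring(2000), stromal_fraction_tumor = 1)
  g <- build_compartments(ann, im_width = 500)
  exact <- pi * (2^2 - 1.5^2)
  got <- g$areas$area_mm2[g$areas$compartment == "IM"]
  expect_lt(abs(got - exact) / exact, 0.01)
})

test_that("band wider than the inradius empties TC with a warning", {
  ann <- region_annotation(circle_ring(400), stromal_fraction_tumor = 1)
  expect_warning(g <- build_compartments(ann, im_width = 500), "empty")
  expect_true(g$tc_empty)
  expect_equal(g$areas$area_mm2[g$areas$compartment == "TC"], 0)
  # whole tumor became IM
  expect_lt(abs(g$areas$area_mm2[g$areas$compartment == "IM"] -
                  poly_area_mm2(list(circle_ring(400)))), 1e-6)
})

test_that("interior exclusion holes are subtracted before area computation", {
  # 1 mm^2 square hole centred in the tumor
  hole <- square_ring(1000, x0 = 1500, y0 = 1500)
  ann <- region_annotation(square_ring(4000), exclusions = list(hole),
                           stromal_fraction_tumor = 1)
  g <- build_compartments(ann, im_width = 500)
  pc <- partition_check(g, ann)
  expect_lt(pc$relative, 1e-3)
  expect_equal(pc$tumor_net_mm2, 15, tolerance = 1e-9)
  # hole is interior to TC, so only TC shrinks
  expect_equal(g$areas$area_mm2[g$areas$compartment == "TC"], 8, tolerance = 1e-9)
})

test_that("partition residual stays below 0.1% on random blob tumors", {
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    ring <- circle_ring(runif(1, 1000, 4000), n = 90)
    k <- sample(2:5, 1)
    mod <- 1 + runif(1, 0, 0.2) * cos(k * atan2(ring$y, ring$x) + runif(1, 0, 2 * pi))
    ring <- list(x = ring$x * mod, y = ring$y * mod)
    ann <- region_annotation(ring, stromal_fraction_tumor = 1)
    g <- suppressWarnings(build_compartments(ann, im_width = 500))
    worst <- max(worst, partition_check(g, ann)$relative)
  }
  expect_lt(worst, 1e-3)
})

test_that("IM area is monotone in band width and vanishes as width -> 0", {
  ann <- square_annotation(4000, stromal = 1)
  widths <- c(1, 50, 200, 500, 1000, 1500)
  ims <- tcs <- numeric(length(widths))
  for (i in seq_along(widths)) {
    g <- suppressWarnings(build_compartments(ann, im_width = widths[i]))
    ims[i] <- g$areas$area_mm2[g$areas$compartment == "IM"]
    tcs[i] <- g$areas$area_mm2[g$areas$compartment == "TC"]
  }
  expect_true(all(diff(ims) >= 0))
  expect_true(all(diff(tcs) <= 0))
  expect_lt(ims[1], 0.02)  # 1 um band of a 16 mm^2 square
})

test_that("compartment assignment respects the priority rules", {
  hole <- square_ring(400, x0 = 2800, y0 = 2800)
  ann <- region_annotation(square_ring(4000), exclusions = list(hole),
                           stromal_fraction_tumor = 1)
  g <- build_compartments(ann, im_width = 500)
  cells <- data.frame(
    x = c(2000, 100, 3000, -50, 2000),
    y = c(2000, 2000, 3000, 2000, 3900))
  lab <- assign_compartment(cells, g)
  expect_equal(as.character(lab),
               c("TC", "IM", "EXCLUDED", "OUTSIDE", "IM"))
  # totality/exclusivity: one label each; permutation permutes labels
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(as.character(assign_compartment(cells[perm, ], g)),
               as.character(lab)[perm])
})

test_that("para compartment is the para band minus tumor and exclusions", {
  tumor <- circle_ring(1500)
  para <- circle_ring(2500)  # encloses tumor: overlapping para is rejected
  expect_error(region_annotation(tumor, para = para, stromal_fraction_tumor = 1,
                                 stromal_fraction_para = 1),
               "overlaps")
  band <- polyclip::polyclip(list(para), list(tumor), op = "minus")
  ann <- region_annotation(tumor, para = band, stromal_fraction_tumor = 1,
                           stromal_fraction_para = 1)
  g <- build_compartments(ann, im_width = 300)
  expect_equal(g$areas$area_mm2[g$areas$compartment == "PARA"],
               pi * (2.5^2 - 1.5^2), tolerance = 0.01)
  pt <- data.frame(x = 2000, y = 0)
  expect_equal(as.character(assign_compartment(pt, g)), "PARA")
})

test_that("band membership agrees with distance-to-boundary on a convex tumor", {
  ann <- square_annotation(4000, stromal = 1)
  g <- build_compartments(ann, im_width = 500)
  set.seed(21)
  x <- runif(1000, 1, 3999); y <- runif(1000, 1, 3999)
  # distance to the boundary of the axis-aligned square
  d <- pmin(x, y, 4000 - x, 4000 - y)
  lab <- assign_compartment(data.frame(x = x, y = y), g)
  on_edge <- abs(d - 500) < 1e-6
  expect_equal(as.character(lab)[!on_edge],
               ifelse(d[!on_edge] <= 500, "IM", "TC"))
})

test_that("invalid geometry is rejected", {
  bowtie <- list(x = c(0, 1000, 0, 1000), y = c(0, 1000, 1000, 0))
  expect_error(region_annotation(bowtie), "self-intersecting")
  expect_error(region_annotation(square_ring(0)), "vertices|zero area")
  ann <- square_annotation(4000)
  expect_error(build_compartments(ann, im_width = -5), "positive")
  # exclusions covering the whole tumor
  ann2 <- region_annotation(square_ring(1000),
                            exclusions = list(square_ring(2000, -500, -500)),
                            stromal_fraction_tumor = 1)
  expect_error(build_compartments(ann2, 100), "empty-compartment")
  g <- build_compartments(ann, 500)
  expect_error(assign_compartment(data.frame(x = NA_real_, y = 1), g),
               "invalid-cell")
})

test_that("degenerate partition report is all zeros", {
  pc <- partition_check(NULL)
  expect_equal(pc$absolute_mm2, 0)
  expect_equal(pc$relative, 0)
})

test_that("missing stromal fraction defaults to 1 with a warning", {
  ann <- region_annotation(square_ring(2000))
  expect_warning(g <- build_compartments(ann, 200), "stromal_fraction")
  a <- g$areas
  expect_equal(a$stromal_area_mm2[1:2], a$area_mm2[1:2])
})

test_that("explicit stroma polygons override the fraction", {
  # stroma = left half of the tumor
  stroma <- list(x = c(0, 2000, 2000, 0), y = c(0, 0, 4000, 4000))
  ann <- region_annotation(square_ring(4000), stroma = list(stroma))
  g <- build_compartments(ann, 500)
  a <- g$areas
  # TC: inner 3x3 mm sits in x [500,3500]; its left part up to x=2000 is stromal
  expect_equal(a$stromal_area_mm2[a$compartment == "TC"], 1.5 * 3,
               tolerance = 1e-9)
  # left half of the square is 8 mm^2; 4.5 of it is TC, the rest IM
  expect_equal(a$stromal_area_mm2[a$compartment == "IM"], 8 - 4.5,
               tolerance = 1e-9)
})
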