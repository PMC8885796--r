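test_that("nucleus-area ratio is the stromal lymphocyte area over stromal area", {
  cells <- lymph_cells(runif(100, 600, 3400), runif(100, 600, 3400), area = 30)
  cells$compartment <- "TC"
  # 100 cells x 30 um^2 = 3000 um^2 over 0.015 mm^2 of stroma
  expect_equal(nucleus_area_ratio(cells, "TC", 0.015), 0.20)
  # non-stromal cells contribute nothing
  cells$in_stroma <- FALSE
  expect_equal(nucleus_area_ratio(cells, "TC", 0.015), 0)
  # no cells at all is 0, not an error
  expect_equal(nucleus_area_ratio(cells[0, ], "TC", 1), 0)
  expect_error(nucleus_area_ratio(cells, "TC", 0), "> 0")
})

test_that("ratio matches a brute-force filter-and-sum over labeled cells", {
  set.seed(5)
  n <- 100
  cells <- lymph_cells(runif(n), runif(n), area = runif(n, 10, 60))
  cells$in_stroma <- runif(n) < 0.7
  cells$compartment <- sample(c("TC", "IM", "PARA"), n, replace = TRUE)
  cells$cell_class[sample(n, 10)] <- "tumor"
  manual <- sum(cells$nucleus_area_um2[
    cells$compartment == "TC" & cells$in_stroma & cells$cell_class == "lymphocyte"])
  expect_equal(nucleus_area_ratio(cells, "TC", 0.5), manual / 0.5e6)
})

test_that("ratios are invariant under a common scaling of areas", {
  cells <- lymph_cells(1:50, 1:50, area = 25)
  cells$compartment <- "IM"
  r1 <- nucleus_area_ratio(cells, "IM", 0.01)
  cells$nucleus_area_um2 <- cells$nucleus_area_um2 * 3.7
  r2 <- nucleus_area_ratio(cells, "IM", 0.037)
  expect_equal(r1, r2)
})

test_that("stromal-TIL calibration maps 0.20 to 50% and is linear", {
  expect_identical(as.numeric(stromal_til_percent(0.20)), 50)
  expect_identical(as.numeric(stromal_til_percent(0)), 0)
  expect_identical(as.numeric(stromal_til_percent(0.10)), 25)
  capped <- stromal_til_percent(0.5)
  expect_equal(as.numeric(capped), 100)
  expect_true(attr(capped, "capped"))
  expect_error(stromal_til_percent(-0.1), ">= 0")
})

test_that("marker density counts positive lymphocytes per total mm^2", {
  cells <- lymph_cells(1:50, 1:50, marker = "CD8")
  cells$compartment <- "IM"
  expect_equal(marker_density(cells, "IM", "CD8", 2), 25)
  expect_equal(marker_density(cells, "IM", "CD20", 2), 0)
  expect_error(marker_density(cells, "IM", "FOXP3", 2), "unknown marker")
  # brute-force counting oracle on random labels
  set.seed(9)
  cells$marker <- sample(c("CD4", "CD8", "CD20", "none"), 50, replace = TRUE)
  cells$compartment <- sample(c("TC", "IM"), 50, replace = TRUE)
  for (m in c("CD4", "CD8", "CD20")) {
    manual <- sum(cells$marker == m & cells$compartment == "TC")
    expect_equal(marker_density(cells, "TC", m, 1.25), manual / 1.25)
  }
})

test_that("subpopulation ratios handle degenerate denominators", {
  r <- subpopulation_ratios(30, 20, 25)
  expect_equal(r$t_to_b, 2.0)
  expect_equal(r$cd8_to_t, 0.4)
  r0 <- subpopulation_ratios(10, 5, 0)
  expect_true(is.na(r0$t_to_b))
  expect_equal(r0$undefined, "t_to_b")
  expect_equal(r0$b_to_t, 0)
  req <- subpopulation_ratios(10, 10, 10)
  expect_equal(req$t_to_b, 2.0)
  expect_equal(req$b_to_t, 0.5)
  expect_equal(req$cd8_to_t, 0.5)
  expect_error(subpopulation_ratios(-1, 2, 3), ">= 0")
})

test_that("pooled ratio over TC+IM equals the stromal-area-weighted mean", {
  set.seed(13)
  cells <- lymph_cells(runif(200), runif(200), area = runif(200, 20, 40))
  cells$compartment <- sample(c("TC", "IM"), 200, replace = TRUE)
  s_tc <- 0.4; s_im <- 0.25
  r_tc <- nucleus_area_ratio(cells, "TC", s_tc)
  r_im <- nucleus_area_ratio(cells, "IM", s_im)
  pooled_cells <- cells; pooled_cells$compartment <- "TC"
  r_pool <- nucleus_area_ratio(pooled_cells, "TC", s_tc + s_im)
  expect_equal(r_pool, (r_tc * s_tc + r_im * s_im) / (s_tc + s_im))
})

test_that("per-slide metrics agree with the individual operations", {
  ann <- square_annotation(4000, stromal = 0.5)
  g <- build_compartments(ann, 500)
  set.seed(3)
  cells <- lymph_cells(runif(400, 0, 4000), runif(400, 0, 4000), area = 30)
  cells$marker <- sample(c("CD4", "CD8", "CD20", "none"), 400, replace = TRUE)
  m <- compartment_metrics(cells, g)
  lab <- assign_compartment(cells, g)
  cells$compartment <- lab
  expect_equal(m$r_tc, nucleus_area_ratio(cells, "TC", 4.5))
  expect_equal(m$r_im, nucleus_area_ratio(cells, "IM", 3.5))
  expect_equal(m$density["IM", "CD8"], marker_density(cells, "IM", "CD8", 7))
  expect_equal(unname(m$n_cells["TC"]), sum(lab == "TC"))
  expect_equal(m$stromal_til_pct, 250 * m$r_tc)
  # marker counts never exceed the lymphocyte count per compartment
  for (comp in c("TC", "IM")) {
    area <- g$areas$area_mm2[g$areas$compartment == comp]
    expect_lte(sum(m$density[comp, ]) * area, m$n_cells[[comp]])
  }
})

test_that("hot-tumor pools TC/IM of IP1-2 and hot-Para pools Para of IP1+IP4", {
  d <- data.frame(ip = c("IP1", "IP2", "IP3", "IP4"),
                  tc_cd4 = c(10, 4, 1, 1), tc_cd8 = c(10, 6, 1, 1),
                  tc_cd20 = c(5, 2, 1, 1),
                  im_cd4 = c(30, 8, 9, 2), im_cd8 = c(30, 10, 8, 2),
                  im_cd20 = c(15, 4, 6, 2),
                  para_cd4 = c(8, 1, 1, 12), para_cd8 = c(6, 1, 1, 9),
                  para_cd20 = c(20, 2, 2, 30))
  hg <- hot_group_metrics(d)
  expect_equal(nrow(hg$hot_tumor), 2)           # IP1, IP2
  expect_equal(hg$hot_tumor$cd8[1], (10 + 30) / 2)
  expect_equal(nrow(hg$hot_para), 2)            # IP1, IP4
  expect_equal(hg$hot_para$cd20, c(20, 30))
  expect_equal(hg$hot_tumor$t_to_b[1], (20 + 20) / 10)
  expect_error(hot_group_metrics(d[d$ip == "IP3", , drop = FALSE]),
               "empty-sample")
})
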