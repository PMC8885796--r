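# Synthetic virtual slides and clinicopathological cohorts.
#
# The generator emulates the measured structure of the assessment pipeline:
# a smooth tumor blob with a surrounding para-tumor band and lobules,
# homogeneous Poisson lymphocyte point patterns per compartment whose
# intensity is chosen so the expected nucleus-area ratio lands in a
# per-pattern target interval, log-normal nucleus areas, compartment-
# dependent marker mixes (T-skewed in the tumor, B-skewed in the para),
# pattern-conditional clinicopathological covariates matching the published
# proportions, and Weibull disease-free survival with pattern-by-subtype
# hazards reproducing the published qualitative orderings.

.SUBTYPES <- c("luminalA", "luminalB", "luminalHER2", "HER2", "TNBC")

#' Default configuration for the synthetic cohort generator
#'
#' All probabilities conditional on pattern default to the published
#' proportions; geometry and nuisance parameters default to values typical
#' of breast whole-slide annotations (documented in the methods vignette).
#'
#' @param n_cases number of cases for [simulate_cohort()].
#' @param ip_probs pattern mixture (defaults to 69/19/110/130/251
#'   normalized).
#' @param target_ratio_ranges per-pattern list of 3x2 matrices (rows TC,
#'   IM, PARA) giving the interval the expected nucleus-area ratio is drawn
#'   from; defaults keep every interval at least 0.02 from every cut-off.
#' @param im_width_um invasive-margin band width.
#' @param tumor_diameter_um range of tumor blob diameters.
#' @param para_width_um width of the para-tumor band around the tumor.
#' @param nucleus_area_mean_um2,nucleus_area_cv log-normal nucleus-area
#'   moments (mean 30 um^2, CV 0.3).
#' @param stromal_fraction_tumor,stromal_fraction_para manual stromal
#'   fractions written into every virtual annotation.
#' @param marker_mix_tumor,marker_mix_para probabilities over CD4, CD8,
#'   CD20, none for lymphocytes in tumor compartments vs the para.
#' @param lobular_p,embolus_p,late_stage_p per-pattern covariate
#'   probabilities (published values).
#' @param subtype_probs,grade_probs per-pattern 5-level subtype and 3-level
#'   grade probabilities (published where available).
#' @param pdl1_ic_pos_p per-pattern probability of PD-L1 immune-cell
#'   positivity at the 1% cut-off (published rates).
#' @param pdl1_tc_pos_p tumor-cell PD-L1 positivity probability.
#' @param weibull_shape DFS Weibull shape (mild aging).
#' @param base_scale_months per-subtype Weibull scale for the reference
#'   (best-prognosis) pattern group.
#' @param hr_merged per-subtype hazard-ratio vector over merged groups
#'   IP1/2, IP3/4, IP5 encoding the published survival orderings.
#' @param censor_range_months administrative censoring window.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cases = 579L,
    ip_probs = c(69, 19, 110, 130, 251) / 579,
    target_ratio_ranges = list(
      IP1 = rbind(tc = c(0.25, 0.35), im = c(0.15, 0.30), para = c(0.25, 0.35)),
      IP2 = rbind(tc = c(0.25, 0.35), im = c(0.15, 0.30), para = c(0.03, 0.08)),
      IP3 = rbind(tc = c(0.03, 0.10), im = c(0.13, 0.25), para = c(0.03, 0.08)),
      IP4 = rbind(tc = c(0.02, 0.08), im = c(0.02, 0.07), para = c(0.25, 0.35)),
      IP5 = rbind(tc = c(0.005, 0.05), im = c(0.005, 0.07), para = c(0.005, 0.05))),
    im_width_um = 500,
    tumor_diameter_um = c(2000, 8000),
    para_width_um = 1000,
    nucleus_area_mean_um2 = 30,
    nucleus_area_cv = 0.3,
    stromal_fraction_tumor = 0.5,
    stromal_fraction_para = 0.6,
    marker_mix_tumor = c(CD4 = 0.35, CD8 = 0.30, CD20 = 0.20, none = 0.15),
    marker_mix_para = c(CD4 = 0.25, CD8 = 0.18, CD20 = 0.42, none = 0.15),
    lobular_p = c(IP1 = 0.6812, IP2 = 0.2632, IP3 = 0.4182, IP4 = 0.9308, IP5 = 0.3904),
    embolus_p = c(IP1 = 0.1159, IP2 = 0.1579, IP3 = 0.2091, IP4 = 0.3231, IP5 = 0.1873),
    late_stage_p = c(IP1 = 0.0290, IP2 = 0.0526, IP3 = 0.1909, IP4 = 0.1240, IP5 = 0.1640),
    subtype_probs = NULL,
    grade_probs = NULL,
    pdl1_ic_pos_p = c(IP1 = 0.8406, IP2 = 0.8947, IP3 = 0.3171, IP4 = 0.3182, IP5 = 0.0286),
    pdl1_tc_pos_p = 0.0625,
    weibull_shape = 1.2,
    base_scale_months = c(luminalA = 400, luminalB = 260, luminalHER2 = 260,
                          HER2 = 220, TNBC = 180),
    hr_merged = list(
      luminalA = c("IP1/2" = 1.0, "IP3/4" = 1.0, "IP5" = 1.0),
      luminalB = c("IP1/2" = 1.5, "IP3/4" = 2.5, "IP5" = 1.0),
      luminalHER2 = c("IP1/2" = 0.8, "IP3/4" = 1.2, "IP5" = 1.0),
      HER2 = c("IP1/2" = 0.8, "IP3/4" = 1.2, "IP5" = 1.0),
      TNBC = c("IP1/2" = 0.4, "IP3/4" = 1.0, "IP5" = 1.0)),
    censor_range_months = c(36, 120)) {
  cfg <- mget(names(formals()))
  if (n_cases <= 0) stop("n_cases must be positive")
  if (abs(sum(ip_probs) - 1) > 1e-9) stop("ip_probs must sum to 1")
  if (any(ip_probs < 0)) stop("ip_probs must be non-negative")
  if (is.null(subtype_probs)) {
    counts <- rbind(IP1 = c(1, 29, 6, 14, 19), IP2 = c(1, 10, 2, 3, 3),
                    IP3 = c(19, 51, 11, 10, 19), IP4 = c(27, 61, 13, 10, 19),
                    IP5 = c(88, 121, 26, 10, 6))
    colnames(counts) <- .SUBTYPES
    subtype_probs <- counts / rowSums(counts)
  }
  if (is.null(grade_probs)) {
    counts <- rbind(IP1 = c(0, 26, 43), IP2 = c(0, 9, 10), IP3 = c(6, 60, 44),
                    IP4 = c(7, 71, 52), IP5 = c(36, 185, 30))
    colnames(counts) <- c("1", "2", "3")
    grade_probs <- counts / rowSums(counts)
  }
  cuts <- ip_cutoffs()
  for (ip in names(target_ratio_ranges)) {
    m <- target_ratio_ranges[[ip]]
    if (any(m < 0)) stop("infeasible target interval for ", ip)
    want <- classify_ip(mean(m["tc", ]), mean(m["im", ]), mean(m["para", ]), cuts)$ip
    if (as.character(want) != ip)
      stop("target interval for ", ip, " is inconsistent with the cut-offs")
  }
  cfg$subtype_probs <- subtype_probs
  cfg$grade_probs <- grade_probs
  structure(cfg, class = "simulation_config")
}

# ---- virtual slide ----------------------------------------------------------

# smooth star-shaped blob: radius modulated by low-order harmonics
.random_blob <- function(cx, cy, r0, n_vertices = 90L, roughness = 0.15) {
  k <- 2:5
  amp <- stats::runif(length(k), 0, roughness / seq_along(k))
  phi <- stats::runif(length(k), 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- r0 * (1 + rowSums(sapply(seq_along(k), function(i)
    amp[i] * cos(k[i] * th + phi[i]))))
  r <- pmax(r, 0.3 * r0)
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

.circle_path <- function(cx, cy, r, n = 36L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# uniform points inside a path list, by rejection from the bounding box
.runif_in_paths <- function(n, paths) {
  if (n == 0L || length(paths) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  xr <- range(unlist(lapply(paths, `[[`, "x")))
  yr <- range(unlist(lapply(paths, `[[`, "y")))
  out_x <- numeric(0); out_y <- numeric(0)
  area_frac <- max(poly_area_mm2(paths) * 1e6 / (diff(xr) * diff(yr)), 0.02)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / area_frac * 1.1) + 16L
    cx <- stats::runif(m, xr[1], xr[2]); cy <- stats::runif(m, yr[1], yr[2])
    keep <- .points_in_paths(cx, cy, paths)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
  }
  data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

.lognormal_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one annotated virtual slide
#'
#' Draws a random smooth tumor blob with a para-tumor band, lobules and
#' exclusion regions, then fills each compartment with a homogeneous
#' Poisson lymphocyte pattern whose intensity is set so that the expected
#' nucleus-area ratio equals a target drawn from the pattern's configured
#' interval. Cells are flagged stromal with probability equal to the
#' compartment's stromal fraction, making the expected stromal ratio equal
#' to intensity times mean nucleus area regardless of the fraction.
#'
#' @param ip_target target pattern, `"IP1"`..`"IP5"`.
#' @param config a [simulation_config()].
#' @param seed integer seed (local to this call).
#' @return list of class `virtual_slide`: `annotation`, `geom`, `cells`
#'   (cell table with `id`, `x`, `y`, `cell_class`, `nucleus_area_um2`,
#'   `in_stroma`, `marker`), `ip_target`, `target_ratios`, `seed`.
#' @export
simulate_slide <- function(ip_target, config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  ip_target <- match.arg(ip_target, names(config$target_ratio_ranges))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)

  r0 <- stats::runif(1, config$tumor_diameter_um[1], config$tumor_diameter_um[2]) / 2
  centre <- r0 + config$para_width_um + 200
  tumor <- .random_blob(centre, centre, r0)
  para_outer <- polyclip::polyoffset(list(tumor), config$para_width_um,
                                     jointype = "round")
  para_band <- .poly_op(para_outer, list(tumor), "minus")

  # exclusions: 0-3 discs inside the tumor
  n_excl <- sample(0:3, 1L)
  exclusions <- list()
  if (n_excl > 0L) {
    for (i in seq_len(n_excl)) {
      th <- stats::runif(1, 0, 2 * pi); d <- stats::runif(1, 0, 0.5 * r0)
      exclusions[[i]] <- .circle_path(centre + d * cos(th), centre + d * sin(th),
                                      stats::runif(1, 100, min(400, 0.3 * r0)))
    }
  }
  # lobules: 3-10 discs inside the para band
  n_lob <- sample(3:10, 1L)
  lobules <- list()
  band_mid <- r0 + config$para_width_um / 2
  for (i in seq_len(n_lob)) {
    th <- stats::runif(1, 0, 2 * pi)
    lob <- .circle_path(centre + band_mid * cos(th), centre + band_mid * sin(th),
                        stats::runif(1, 100, 250))
    inside <- poly_area_mm2(.poly_op(list(lob), para_band, "minus")) < 1e-9
    if (inside) lobules[[length(lobules) + 1L]] <- lob
  }

  ann <- region_annotation(
    tumor = tumor, para = para_band, exclusions = exclusions,
    lobules = lobules,
    stromal_fraction_tumor = config$stromal_fraction_tumor,
    stromal_fraction_para = config$stromal_fraction_para)
  geom <- build_compartments(ann, im_width = config$im_width_um)

  rng <- config$target_ratio_ranges[[ip_target]]
  targets <- c(tc = stats::runif(1, rng["tc", 1], rng["tc", 2]),
               im = stats::runif(1, rng["im", 1], rng["im", 2]),
               para = stats::runif(1, rng["para", 1], rng["para", 2]))

  lp <- .lognormal_pars(config$nucleus_area_mean_um2, config$nucleus_area_cv)
  frac <- c(TC = config$stromal_fraction_tumor, IM = config$stromal_fraction_tumor,
            PARA = config$stromal_fraction_para)
  mix <- list(TC = config$marker_mix_tumor, IM = config$marker_mix_tumor,
              PARA = config$marker_mix_para)
  cells <- list()
  for (comp in c("TC", "IM", "PARA")) {
    paths <- geom[[tolower(comp)]]
    area_um2 <- poly_area_mm2(paths) * 1e6
    if (area_um2 <= 0) next
    lambda <- targets[[tolower(comp)]] / config$nucleus_area_mean_um2  # per um^2
    n_cell <- stats::rpois(1, lambda * area_um2)
    if (n_cell == 0L) next
    pts <- .runif_in_paths(n_cell, paths)
    cells[[comp]] <- data.frame(
      x = pts$x, y = pts$y, cell_class = "lymphocyte",
      nucleus_area_um2 = stats::rlnorm(n_cell, lp$meanlog, lp$sdlog),
      in_stroma = stats::runif(n_cell) < frac[[comp]],
      marker = sample(names(mix[[comp]]), n_cell, replace = TRUE,
                      prob = mix[[comp]]),
      stringsAsFactors = FALSE)
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(x = numeric(0), y = numeric(0), cell_class = character(0),
               nucleus_area_um2 = numeric(0), in_stroma = logical(0),
               marker = character(0))
  rownames(cells) <- NULL
  cells <- cbind(id = sprintf("cell_%06d", seq_len(nrow(cells))), cells)
  structure(list(annotation = ann, geom = geom, cells = cells,
                 ip_target = ip_target, target_ratios = targets, seed = seed),
            class = "virtual_slide")
}

#' @export
print.virtual_slide <- function(x, ...) {
  cat(sprintf("Virtual slide (target %s, seed %d): %d cells, tumor %.2f mm^2\n",
              x$ip_target, x$seed, nrow(x$cells), poly_area_mm2(x$annotation$tumor)))
  invisible(x)
}

# ---- cohort -----------------------------------------------------------------

.sample_cat <- function(n, levels, prob) {
  if (n == 0L) return(character(0))
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

#' Simulate a clinicopathological cohort
#'
#' Samples a pattern per case from the configured mixture, covariates from
#' the per-pattern conditional tables, PD-L1 immune-cell percentages from a
#' mixture calibrated to the configured positivity rates at the 1% cut-off,
#' and disease-free survival from Weibull distributions whose pattern-by-
#' subtype hazards encode the published qualitative orderings. Ratio
#' triples are drawn from the per-pattern target intervals (attach realized
#' slide metrics via [simulate_slide()]/[recover_parameters()] when full
#' virtual slides are wanted).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (local to this call).
#' @return data.frame with one row per case: `case_id`, `ip_true`, `r_tc`,
#'   `r_im`, `r_para`, `subtype`, `grade`, `stage_group`,
#'   `lobular_involvement`, `cancerous_embolus`, `pdl1_ic_pct`,
#'   `pdl1_tc_pct`, `dfs_months`, `event`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- as.integer(config$n_cases)
  if (n <= 0L) stop("n_cases must be positive")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)

  ips <- names(config$target_ratio_ranges)
  ip <- .sample_cat(n, ips, config$ip_probs)
  rng <- config$target_ratio_ranges
  r <- t(vapply(ip, function(p) {
    m <- rng[[p]]
    c(stats::runif(1, m["tc", 1], m["tc", 2]),
      stats::runif(1, m["im", 1], m["im", 2]),
      stats::runif(1, m["para", 1], m["para", 2]))
  }, numeric(3)))

  subtype <- character(n); grade <- integer(n)
  for (p in ips) {
    idx <- which(ip == p)
    subtype[idx] <- .sample_cat(length(idx), .SUBTYPES, config$subtype_probs[p, ])
    grade[idx] <- as.integer(.sample_cat(length(idx), c("1", "2", "3"),
                                         config$grade_probs[p, ]))
  }
  lob <- stats::runif(n) < config$lobular_p[ip]
  emb <- stats::runif(n) < config$embolus_p[ip]
  late <- stats::runif(n) < config$late_stage_p[ip]

  ic_pos <- stats::runif(n) < config$pdl1_ic_pos_p[ip]
  pdl1_ic <- ifelse(ic_pos, 1 + stats::rgamma(n, shape = 1.2, scale = 15),
                    stats::runif(n, 0, 0.99))
  pdl1_ic <- pmin(pdl1_ic, 100)
  tc_pos <- stats::runif(n) < config$pdl1_tc_pos_p
  pdl1_tc <- ifelse(tc_pos, 1 + stats::rgamma(n, shape = 1, scale = 5),
                    stats::runif(n, 0, 0.99))
  pdl1_tc <- pmin(pdl1_tc, 100)

  merged <- as.character(merge_ip(ip))
  shape <- config$weibull_shape
  hr <- vapply(seq_len(n), function(i)
    config$hr_merged[[subtype[i]]][[merged[i]]], numeric(1))
  scale <- config$base_scale_months[subtype] * hr^(-1 / shape)
  t_event <- stats::rweibull(n, shape = shape, scale = scale)
  censor <- stats::runif(n, config$censor_range_months[1],
                         config$censor_range_months[2])
  dfs <- pmax(pmin(t_event, censor), 0.01)
  event <- as.integer(t_event <= censor)

  data.frame(
    case_id = sprintf("case_%05d", seq_len(n)),
    ip_true = ip, r_tc = r[, 1], r_im = r[, 2], r_para = r[, 3],
    subtype = subtype, grade = grade,
    stage_group = ifelse(late, "late", "early"),
    lobular_involvement = as.integer(lob), cancerous_embolus = as.integer(emb),
    pdl1_ic_pct = pdl1_ic, pdl1_tc_pct = pdl1_tc,
    dfs_months = dfs, event = event,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Round-trip parameter recovery report
#'
#' Runs the full pipeline (geometry, assignment, quantification,
#' classification) over a set of virtual slides and summarizes how well the
#' generating parameters are recovered; optionally tests the luminal-B
#' IP3-vs-IP5 survival difference on an accompanying cohort.
#'
#' @param slides list of [simulate_slide()] results.
#' @param cohort optional [simulate_cohort()] table for the survival check.
#' @return list with `confusion` (target vs recovered pattern table),
#'   `accuracy`, `ratio_bias` (mean realized-minus-target per compartment),
#'   `realized` (per-slide data.frame), and `lumB_logrank` (a `til_test`
#'   or `NULL`).
#' @export
recover_parameters <- function(slides, cohort = NULL) {
  realized <- do.call(rbind, lapply(seq_along(slides), function(i) {
    s <- slides[[i]]
    geom <- build_compartments(s$annotation, im_width = s$geom$im_width)
    m <- compartment_metrics(s$cells, geom)
    data.frame(slide = i, ip_target = s$ip_target,
               r_tc = m$r_tc, r_im = m$r_im, r_para = m$r_para,
               t_tc = s$target_ratios[["tc"]], t_im = s$target_ratios[["im"]],
               t_para = s$target_ratios[["para"]], stringsAsFactors = FALSE)
  }))
  labels <- classify_ip(realized$r_tc, realized$r_im, realized$r_para)
  confusion <- table(target = factor(realized$ip_target, levels = .IP_LEVELS),
                     recovered = labels$ip)
  accuracy <- mean(as.character(labels$ip) == realized$ip_target)
  ratio_bias <- c(tc = mean(realized$r_tc - realized$t_tc),
                  im = mean(realized$r_im - realized$t_im),
                  para = mean(realized$r_para - realized$t_para))
  lumb <- NULL
  if (!is.null(cohort)) {
    sub <- cohort[cohort$subtype == "luminalB" & cohort$ip_true %in% c("IP3", "IP5"), ]
    if (nrow(sub) > 0L && length(unique(sub$ip_true)) == 2L && sum(sub$event) > 0L)
      lumb <- weighted_logrank(sub$dfs_months, sub$event, sub$ip_true, "logrank")
  }
  list(confusion = confusion, accuracy = accuracy, ratio_bias = ratio_bias,
       realized = realized, lumB_logrank = lumb)
}
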