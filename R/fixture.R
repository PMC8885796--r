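# The bundled 579-case cohort fixture.
#
# One row per patient, reconstructed from the published cohort summary: the
# immunoarchitectural-pattern counts (69/19/110/130/251), every marginal of
# the clinicopathological table, and the per-pattern cross-tabulations that
# are published (clinical stage, lobular involvement, cancerous embolus,
# histological grade where stated, molecular subtype where stated). Joint
# structure beyond those published tables is synthetic: characteristics are
# interleaved deterministically within each pattern, so any cross-tab the
# publication does not pin down should not be read as data. Synthetic fills
# are listed in `table1_fixture_notes()`.

.IP_N <- c(IP1 = 69L, IP2 = 19L, IP3 = 110L, IP4 = 130L, IP5 = 251L)

# deterministic within-block interleaving: stride coprime with most block
# sizes, so repeated category blocks decorrelate across characteristics
.stride_order <- function(n, stride) {
  if (n <= 1L) return(seq_len(n))
  s <- stride %% n
  if (s == 0L) s <- 1L
  while (.gcd(n, s) != 1L) s <- s + 1L
  ((seq_len(n) - 1L) * s) %% n + 1L
}
.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

.fill <- function(values, counts, n, stride) {
  stopifnot(sum(counts) == n)
  rep(values, counts)[.stride_order(n, stride)]
}

#' Reconstructed per-patient cohort behind the published summary table
#'
#' Builds the 579-row clinicopathological cohort consistent with every
#' published marginal count and per-pattern cross-tabulation. Fully
#' deterministic; no RNG.
#'
#' @return data.frame with one row per patient: `case_id`, `ip`,
#'   `age_group`, `sex`, `menopausal`, `family_history`, `tumor_size_cat`,
#'   `n_stage`, `m_stage`, `tnm_stage`, `er`, `pr`, `her2_status`, `ki67`,
#'   `subtype`, `lobular_involvement`, `cancerous_embolus`, `grade`.
#' @seealso [load_table1_cohort()] for the CSV copy shipped with the
#'   package, [table1_fixture_notes()] for which entries are synthetic.
#' @export
table1_fixture <- function() {
  ips <- names(.IP_N)
  per_ip <- function(make) {
    out <- vector("list", 5L)
    for (i in seq_along(ips)) out[[i]] <- make(ips[i], .IP_N[[i]])
    unlist(out, use.names = FALSE)
  }

  stage_counts <- list(  # I, II, III, IV, unknown; late = III + IV
    IP1 = c(36L, 31L, 2L, 0L, 0L), IP2 = c(10L, 8L, 1L, 0L, 0L),
    IP3 = c(48L, 41L, 19L, 2L, 0L), IP4 = c(61L, 52L, 14L, 2L, 1L),
    IP5 = c(114L, 95L, 38L, 3L, 1L))
  grade_counts <- list(  # grades 1, 2, 3; IP3/IP4 splits are synthetic fills
    IP1 = c(0L, 26L, 43L), IP2 = c(0L, 9L, 10L), IP3 = c(6L, 60L, 44L),
    IP4 = c(7L, 71L, 52L), IP5 = c(36L, 185L, 30L))
  subtype_counts <- list(  # luminalA, luminalB, luminalHER2, HER2, TNBC
    IP1 = c(1L, 29L, 6L, 14L, 19L), IP2 = c(1L, 10L, 2L, 3L, 3L),
    IP3 = c(19L, 51L, 11L, 10L, 19L), IP4 = c(27L, 61L, 13L, 10L, 19L),
    IP5 = c(88L, 121L, 26L, 10L, 6L))
  lobular_counts <- c(IP1 = 47L, IP2 = 5L, IP3 = 46L, IP4 = 121L, IP5 = 98L)
  embolus_counts <- c(IP1 = 8L, IP2 = 3L, IP3 = 23L, IP4 = 42L, IP5 = 47L)

  d <- data.frame(
    case_id = sprintf("case_%03d", seq_len(579L)),
    ip = rep(ips, .IP_N),
    tnm_stage = per_ip(function(ip, n)
      .fill(c("I", "II", "III", "IV", "unknown"), stage_counts[[ip]], n, 7L)),
    grade = per_ip(function(ip, n)
      .fill(c(1L, 2L, 3L), grade_counts[[ip]], n, 11L)),
    subtype = per_ip(function(ip, n)
      .fill(c("luminalA", "luminalB", "luminalHER2", "HER2", "TNBC"),
            subtype_counts[[ip]], n, 13L)),
    lobular_involvement = per_ip(function(ip, n)
      .fill(c(1L, 0L), c(lobular_counts[[ip]], n - lobular_counts[[ip]]), n, 17L)),
    cancerous_embolus = per_ip(function(ip, n)
      .fill(c(1L, 0L), c(embolus_counts[[ip]], n - embolus_counts[[ip]]), n, 19L)),
    stringsAsFactors = FALSE
  )

  # columns pinned only at the cohort margin, interleaved across the cohort
  n <- nrow(d)
  d$age_group <- .fill(c("<=35", "35-50", ">=50"), c(32L, 218L, 329L), n, 23L)
  d$family_history <- .fill(c("no", "yes", "unknown"), c(560L, 15L, 4L), n, 29L)
  d$n_stage <- .fill(c("N0", "N1", "N2", "N3"), c(377L, 143L, 38L, 21L), n, 31L)

  # deterministic couplings
  d$m_stage <- ifelse(d$tnm_stage == "IV", "M1", "M0")
  d$her2_status <- ifelse(d$subtype %in% c("luminalHER2", "HER2"),
                          "positive", "negative")
  # tumor size: the two stage-unknown cases are the size-missing cases
  d$tumor_size_cat <- NA_character_
  known <- d$tnm_stage != "unknown"
  d$tumor_size_cat[!known] <- "unknown"
  d$tumor_size_cat[known] <- .fill(c("T1", "T2", "T3", "T4"),
                                   c(379L, 155L, 10L, 33L), sum(known), 37L)
  # hormone receptors: ER+ = luminal minus 5 discordant luminal B cases
  luminal <- d$subtype %in% c("luminalA", "luminalB", "luminalHER2")
  d$er <- ifelse(luminal, "positive", "negative")
  d$er[which(d$subtype == "luminalB")[1:5]] <- "negative"
  d$pr <- ifelse(luminal, "positive", "negative")
  d$pr[which(luminal)[seq_len(57L)]] <- "negative"   # 466 - 57 = 409 PR+
  # Ki-67: low = all luminal A plus 15 luminal-HER2 cases
  d$ki67 <- "high"
  d$ki67[d$subtype == "luminalA"] <- "low"
  d$ki67[which(d$subtype == "luminalHER2")[seq_len(15L)]] <- "low"
  # sex / menopause: a single male case (postmenopausal field not applicable)
  d$sex <- "F"; d$sex[n] <- "M"
  d$menopausal <- NA_character_
  d$menopausal[n] <- "null_male"
  d$menopausal[-n] <- .fill(c("premenopausal", "postmenopausal", "unknown"),
                            c(312L, 260L, 6L), n - 1L, 41L)
  d[, c("case_id", "ip", "age_group", "sex", "menopausal", "family_history",
        "tumor_size_cat", "n_stage", "m_stage", "tnm_stage", "er", "pr",
        "her2_status", "ki67", "subtype", "lobular_involvement",
        "cancerous_embolus", "grade")]
}

#' Which fixture entries are synthetic fills
#'
#' @return character vector describing the fixture quantities that are not
#'   pinned by published counts and were filled with neutral values.
#' @export
table1_fixture_notes <- function() {
  c("IP2 cancerous-embolus count (3/19) is synthetic: not published.",
    "IP3/IP4 histological-grade splits are synthetic, chosen to show more grade 3 and less grade 1 than IP5 as described.",
    "Luminal B vs luminal-HER2 split within each IP is synthetic (totals 272/58 are exact).",
    "Stage I vs II split within each IP is synthetic (early-stage totals per IP and cohort-wide 269/227 are exact).",
    "Stage III vs IV split within late-stage IPs is synthetic (74/7 cohort-wide is exact).",
    "Age, sex, menopause, family history, tumor size, N stage, ER/PR/Ki-67 are assigned to match the published marginals only; their joint distribution with IP is synthetic.",
    "All cross-characteristic couplings beyond HER2-status-from-subtype, M1-iff-stage-IV and hormone-receptor-from-subtype are not modeled.")
}

#' Load the shipped per-patient cohort fixture CSV
#'
#' @return the fixture as a data.frame (identical to [table1_fixture()]).
#' @export
load_table1_cohort <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "tilpatterns",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published summary counts used for proportion checks
#'
#' Small table of published numerator/denominator pairs (per-pattern
#' lobular involvement, cancerous embolus, late stage, PD-L1 positivity,
#' oncodriver-gene summary) for recomputing the published percentages.
#'
#' @return data.frame with `quantity`, `numerator`, `denominator`.
#' @export
printed_counts <- function() {
  data.frame(
    quantity = c("lobular_IP1", "lobular_IP2", "lobular_IP3", "lobular_IP4",
                 "lobular_IP5", "embolus_IP1", "embolus_IP3", "embolus_IP4",
                 "embolus_IP5", "late_stage_IP1", "late_stage_IP2",
                 "late_stage_IP3", "late_stage_IP4", "late_stage_IP5",
                 "pdl1_ic_positive", "pdl1_tc_positive", "oncodriver_lower_in_IP5"),
    numerator = c(47L, 5L, 46L, 121L, 98L, 8L, 23L, 42L, 47L,
                  2L, 1L, 21L, 16L, 41L, 103L, 13L, 141L),
    denominator = c(69L, 19L, 110L, 130L, 251L, 69L, 110L, 130L, 251L,
                    69L, 19L, 110L, 129L, 250L, 208L, 208L, 320L),
    stringsAsFactors = FALSE
  )
}

#' Cohort summary in the published table's style
#'
#' Counts and percentages (two decimals, half-up) per category of each
#' clinicopathological characteristic, computed on the non-missing
#' denominator, plus the derived early/late clinical-stage summary.
#'
#' @param cohort per-patient data.frame in the fixture schema (only the
#'   columns present are summarized).
#' @return list of data.frames, one per characteristic (`ip`, `age_group`,
#'   ..., `stage_group`), each with `category`, `n`, `pct`.
#' @export
table1_summarize <- function(cohort) {
  if (nrow(cohort) == 0L) return(list())
  level_order <- list(
    ip = c("IP1", "IP2", "IP3", "IP4", "IP5"),
    age_group = c("<=35", "35-50", ">=50"),
    tnm_stage = c("I", "II", "III", "IV", "unknown"),
    tumor_size_cat = c("T1", "T2", "T3", "T4", "unknown"),
    n_stage = c("N0", "N1", "N2", "N3"), m_stage = c("M0", "M1"),
    subtype = c("luminalA", "luminalB", "luminalHER2", "HER2", "TNBC"),
    grade = c("1", "2", "3")
  )
  cols <- intersect(c("ip", "age_group", "sex", "menopausal",
                      "family_history", "tumor_size_cat", "n_stage",
                      "m_stage", "tnm_stage", "er", "pr", "her2_status",
                      "ki67", "subtype", "lobular_involvement",
                      "cancerous_embolus", "grade"), names(cohort))
  out <- list()
  for (col in cols) {
    v <- as.character(cohort[[col]])
    v <- v[!is.na(v)]
    tab <- table(v)
    lev <- level_order[[col]]
    if (!is.null(lev)) {
      present <- intersect(lev, names(tab))
      tab <- tab[c(present, setdiff(names(tab), lev))]
    }
    out[[col]] <- data.frame(category = names(tab), n = as.integer(tab),
                             pct = round_half_up(100 * as.integer(tab) / sum(tab), 2),
                             stringsAsFactors = FALSE)
  }
  if ("tnm_stage" %in% names(cohort)) {
    st <- cohort$tnm_stage
    n_early <- sum(st %in% c("I", "II")); n_late <- sum(st %in% c("III", "IV"))
    denom <- n_early + n_late
    out$stage_group <- data.frame(
      category = c("early (I-II)", "late (III-IV)"),
      n = c(n_early, n_late),
      pct = round_half_up(100 * c(n_early, n_late) / denom, 2),
      stringsAsFactors = FALSE)
  }
  out
}
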