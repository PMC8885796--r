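# Five-way immunoarchitectural pattern (IP) classification.
#
# Decision tree over the compartment ratio triple (r_TC, r_IM, r_Para) with
# inclusive cut-offs (default 0.20 / 0.10 / 0.20):
#   r_TC >= cut_tc          -> lymphocyte-predominant: IP1 if r_Para >= cut_para
#                              else IP2
#   else r_IM >= cut_im     -> IP3 (margin-restricted infiltration; r_Para
#                              is not consulted on this branch)
#   else r_Para >= cut_para -> IP4 (cold tumor, hot para)
#   else                    -> IP5 (cold everywhere)
# Merged prognostic groups: IP1,IP2 -> IP1/2; IP3,IP4 -> IP3/4; IP5 -> IP5.

.IP_LEVELS <- c("IP1", "IP2", "IP3", "IP4", "IP5")
.MERGED_LEVELS <- c("IP1/2", "IP3/4", "IP5")

#' Ratio cut-offs for IP classification
#'
#' @param cut_tc,cut_im,cut_para inclusive thresholds in (0, 1) on the
#'   nucleus-area ratios in the tumor center, invasive margin and para
#'   compartments. Defaults 0.20, 0.10, 0.20.
#' @return named list of validated cut-offs.
#' @export
ip_cutoffs <- function(cut_tc = 0.20, cut_im = 0.10, cut_para = 0.20) {
  for (v in c(cut_tc, cut_im, cut_para))
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop("cut-offs must be single numbers in (0, 1)")
  list(cut_tc = cut_tc, cut_im = cut_im, cut_para = cut_para)
}

#' Classify ratio triples into immunoarchitectural patterns
#'
#' Vectorized over cases. Boundary values are inclusive: a case exactly at a
#' cut-off satisfies it. `r_para` may be `NA` only when it is not consulted,
#' i.e. on the IP3 branch; it is required both to split IP1 from IP2 and
#' IP4 from IP5.
#'
#' @param r_tc,r_im,r_para nucleus-area ratios (>= 0), recycled to a common
#'   length.
#' @param cutoffs an [ip_cutoffs()] list.
#' @return data.frame with columns `ip` (factor IP1..IP5), `merged` (factor
#'   IP1/2, IP3/4, IP5), `tc_im_discordant` (high TC but low IM, a
#'   combination not observed in practice) and `ratio_gt_1`.
#' @export
classify_ip <- function(r_tc, r_im, r_para = NA_real_, cutoffs = ip_cutoffs()) {
  n <- max(length(r_tc), length(r_im), length(r_para))
  r_tc <- rep_len(as.numeric(r_tc), n)
  r_im <- rep_len(as.numeric(r_im), n)
  r_para <- rep_len(as.numeric(r_para), n)
  if (anyNA(r_tc) || anyNA(r_im)) stop("r_tc and r_im must be non-missing")
  if (any(r_tc < 0) || any(r_im < 0) || any(r_para < 0, na.rm = TRUE))
    stop("ratios must be >= 0")

  lpbc <- r_tc >= cutoffs$cut_tc
  im_hi <- r_im >= cutoffs$cut_im
  para_needed <- lpbc | !im_hi
  if (any(para_needed & is.na(r_para)))
    stop("missing-input: r_para is required to split IP1/IP2 and IP4/IP5")

  ip <- character(n)
  ip[lpbc] <- ifelse(r_para[lpbc] >= cutoffs$cut_para, "IP1", "IP2")
  ip[!lpbc & im_hi] <- "IP3"
  low <- !lpbc & !im_hi
  ip[low] <- ifelse(r_para[low] >= cutoffs$cut_para, "IP4", "IP5")

  data.frame(
    ip = factor(ip, levels = .IP_LEVELS),
    merged = merge_ip(ip),
    tc_im_discordant = lpbc & !im_hi,
    ratio_gt_1 = (r_tc > 1) | (r_im > 1) | (!is.na(r_para) & r_para > 1)
  )
}

#' Map IP labels to merged prognostic groups
#'
#' @param ip character or factor of labels among IP1..IP5.
#' @return factor with levels `IP1/2`, `IP3/4`, `IP5`.
#' @export
merge_ip <- function(ip) {
  ip <- as.character(ip)
  bad <- !ip %in% .IP_LEVELS & !is.na(ip)
  if (any(bad)) stop("unknown IP label(s): ", paste(unique(ip[bad]), collapse = ", "))
  merged <- c(IP1 = "IP1/2", IP2 = "IP1/2", IP3 = "IP3/4",
              IP4 = "IP3/4", IP5 = "IP5")[ip]
  factor(unname(merged), levels = .MERGED_LEVELS)
}

#' Half-up rounding
#'
#' Rounds halves away from zero, the convention used for printed
#' percentages in clinical summary tables (base `round()` rounds halves to
#' even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify a cohort and summarize the pattern distribution
#'
#' @param metrics data.frame with columns `r_tc`, `r_im`, `r_para` (one row
#'   per case), or a list of [compartment_metrics()] objects.
#' @param cutoffs an [ip_cutoffs()] list.
#' @return list with `labels` (the [classify_ip()] data.frame) and
#'   `summary` (data.frame of `ip`, `n`, `pct` with percentages rounded
#'   half-up to two decimals).
#' @export
classify_cohort <- function(metrics, cutoffs = ip_cutoffs()) {
  if (is.list(metrics) && !is.data.frame(metrics) &&
      all(vapply(metrics, inherits, logical(1), "compartment_metrics"))) {
    metrics <- data.frame(
      r_tc = vapply(metrics, `[[`, numeric(1), "r_tc"),
      r_im = vapply(metrics, `[[`, numeric(1), "r_im"),
      r_para = vapply(metrics, `[[`, numeric(1), "r_para")
    )
  }
  if (nrow(metrics) == 0L) stop("empty-input: no cases to classify")
  labels <- classify_ip(metrics$r_tc, metrics$r_im, metrics$r_para, cutoffs)
  n <- as.integer(table(labels$ip))
  list(labels = labels,
       summary = data.frame(ip = .IP_LEVELS, n = n,
                            pct = round_half_up(100 * n / sum(n), 2)))
}
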