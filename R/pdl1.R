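# PD-L1 immune-cell scoring at the 1% cut-off (SP142-style convention:
# positive when at least 1% of tumor-area-associated immune cells stain at
# any intensity).

#' Score PD-L1 immune-cell positivity
#'
#' @param ic_pct PD-L1-positive immune-cell percentage(s) in `[0, 100]`.
#' @param cutoff positivity cut-off in percent (inclusive); default 1.
#' @return logical vector of positivity calls.
#' @export
score_pdl1 <- function(ic_pct, cutoff = 1.0) {
  if (any(!is.finite(ic_pct)) || any(ic_pct < 0) || any(ic_pct > 100))
    stop("ic_pct must lie in [0, 100]")
  if (cutoff < 0 || cutoff > 100) stop("cutoff must lie in [0, 100]")
  ic_pct >= cutoff
}

#' PD-L1 positivity by immunoarchitectural pattern
#'
#' Per-pattern positive fractions plus an association test: Pearson
#' chi-square when all expected counts reach 5, otherwise Fisher's exact
#' test. A constant outcome (all positive or all negative) cannot be
#' tested and is flagged instead.
#'
#' @param ic_pct immune-cell percentages.
#' @param ip pattern labels (IP1..IP5 or any grouping).
#' @param cutoff positivity cut-off.
#' @return list with `rates` (data.frame `ip`, `n`, `n_positive`, `rate`),
#'   `test` (a `til_test` or `NULL`), and `degenerate` flag.
#' @export
pdl1_by_ip <- function(ic_pct, ip, cutoff = 1.0) {
  if (length(ic_pct) == 0L) stop("empty-input: no PD-L1 records")
  if (length(ic_pct) != length(ip)) stop("ic_pct and ip lengths differ")
  pos <- score_pdl1(ic_pct, cutoff)
  ip <- factor(ip)
  n <- as.integer(table(ip))
  np <- as.integer(tapply(pos, ip, sum, default = 0L))
  rates <- data.frame(ip = levels(ip), n = n, n_positive = np, rate = np / n)
  degenerate <- all(pos) || !any(pos) || nlevels(ip) < 2L
  test <- NULL
  if (!degenerate) {
    tab <- rbind(negative = n - np, positive = np)
    test <- if (all(pearson_chi_square(tab)$expected >= 5)) pearson_chi_square(tab)
            else fisher_exact(tab, seed = 1L)
  }
  list(rates = rates, test = test, degenerate = degenerate)
}

#' Survival by PD-L1 status
#'
#' Kaplan-Meier estimates per positivity stratum and the weighted log-rank
#' family comparing them.
#'
#' @param ic_pct immune-cell percentages.
#' @param time,event disease-free survival data.
#' @param cutoff positivity cut-off.
#' @return list with `km` (list of [km_estimator()] per stratum) and
#'   `tests` (named list of `til_test` for logrank / breslow /
#'   tarone_ware).
#' @export
pdl1_survival <- function(ic_pct, time, event, cutoff = 1.0) {
  pos <- score_pdl1(ic_pct, cutoff)
  if (length(unique(pos)) < 2L)
    stop("need both PD-L1-positive and -negative strata")
  if (sum(event) == 0L) stop("need at least one event")
  grp <- ifelse(pos, "PD-L1+", "PD-L1-")
  km <- lapply(split(seq_along(time), grp), function(i)
    km_estimator(time[i], event[i]))
  tests <- lapply(c(logrank = "logrank", breslow = "breslow",
                    tarone_ware = "tarone_ware"), function(s)
    weighted_logrank(time, event, grp, s))
  list(km = km, tests = tests)
}
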