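# Outcome analytics for molecularly guided therapy: Kaplan-Meier curves,
# log-rank tests, RECIST response rates, and the kernel-based Kaplan-Meier
# estimate of the PFS2/PFS1 ratio benefit rate at the efficacy threshold
# delta (default 1.3).

#' Kaplan-Meier estimate
#'
#' Product-limit estimator (deaths processed before censorings at tied
#' times) with Greenwood standard errors; the median is the smallest time at
#' which the survival estimate drops to 0.5 or below, reported as not
#' reached (`NA`) when the curve never does.
#'
#' @param data Data frame of one observation per subject.
#' @param time,event Columns (tidy-selected) holding the follow-up time and
#'   the event indicator (logical or 0/1).
#' @param conf_level Confidence level for the median CI (default 0.95).
#' @return An object of class `km_curve` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3, 4), e = TRUE)
#' glance(km_estimate(d, t, e))
km_estimate <- function(data, time, event, conf_level = 0.95) {
  t <- rlang::eval_tidy(rlang::enquo(time), data)
  e <- as.integer(rlang::eval_tidy(rlang::enquo(event), data))
  if (length(t) < 1) abort("at least one observation is required")
  if (any(t < 0, na.rm = TRUE)) abort("times must be non-negative")
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  steps <- tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv,
    std_error = s$std.err,           # Greenwood SE of S(t)
    conf_low = s$lower, conf_high = s$upper
  )
  # median: smallest time at which the survival estimate reaches 0.5 or less
  ev <- steps[steps$n_event > 0, ]
  med <- if (any(ev$estimate <= 0.5)) min(ev$time[ev$estimate <= 0.5]) else NA_real_
  tab <- summary(fit)$table
  ci_names <- grep("LCL|UCL", names(tab), value = TRUE)
  med_ci <- if (length(ci_names) == 2) unname(tab[ci_names]) else c(NA_real_, NA_real_)
  structure(list(fit = fit, steps = steps, n = length(t),
                 n_events = sum(e), median = med,
                 median_ci = med_ci, conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median = x$median,
         median_ci_lower = x$median_ci[1], median_ci_upper = x$median_ci[2])
}

#' Survival at a given time from a `km_curve`
#' @param curve A `km_curve`.
#' @param at Time at which to evaluate (right-continuous step function).
#' @return Survival probability.
#' @export
km_survival_at <- function(curve, at) {
  st <- curve$steps |> filter(.data$n_event > 0)
  if (nrow(st) == 0 || at < min(st$time)) return(1)
  st$estimate[max(which(st$time <= at))]
}

#' Log-rank test
#'
#' Standard Mantel-Haenszel log-rank comparison of two or more groups.
#'
#' @param data Data frame.
#' @param time,event,group Columns (tidy-selected).
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- rlang::eval_tidy(rlang::enquo(time), data)
  e <- as.integer(rlang::eval_tidy(rlang::enquo(event), data))
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  if (length(unique(g)) < 2) abort("log-rank needs at least two groups")
  if (any(table(g) == 0)) abort("empty group")
  if (sum(e) < 1) abort("log-rank needs at least one event")
  fit <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- length(fit$n) - 1
  tibble(statistic = fit$chisq, df = df,
         p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Objective response and disease control rates
#'
#' `ORR = (CR + PR) / n`; `DCR = (CR + PR + SD) / n`. By default `NE`
#' (not evaluable) responses remain in the denominator as non-responses
#' (intention-to-treat style); set `include_ne = FALSE` to drop them.
#'
#' @param records Data frame with a `best_response` column
#'   (`CR`/`PR`/`SD`/`PD`/`NE`).
#' @param include_ne Keep NE in the denominator (default `TRUE`).
#' @return One-row tibble: `n`, `n_response`, `orr`, `n_control`, `dcr`.
#' @export
#' @examples
#' response_rates(tibble::tibble(best_response = c("PR", "SD", "PD")))
response_rates <- function(records, include_ne = TRUE) {
  assert_columns(records, "best_response", "records")
  r <- records$best_response
  if (!include_ne) r <- r[r != "NE"]
  if (length(r) == 0) abort("no evaluable records")
  n <- length(r)
  tibble(
    n = n,
    n_response = sum(r %in% c("CR", "PR")),
    orr = sum(r %in% c("CR", "PR")) / n,
    n_control = sum(r %in% c("CR", "PR", "SD")),
    dcr = sum(r %in% c("CR", "PR", "SD")) / n
  )
}

# Kaplan-Meier jumps of the ratio distribution: event ratios, jump masses,
# and the residual mass beyond the last event. Lean product-limit
# computation (deaths processed before censorings at tied times) so the
# bootstrap loop stays fast; verified against survival::survfit in the
# test suite.
km_jumps <- function(ratio, event) {
  if (!any(event)) return(list(t = numeric(), d = numeric(), resid = 1))
  o <- order(ratio)
  rs <- ratio[o]; es <- event[o]
  grp <- rle(rs)
  n <- length(rs)
  last <- cumsum(grp$lengths)
  n_risk <- n - last + grp$lengths        # at risk just before each tied time
  d_t <- as.numeric(rowsum(as.numeric(es), group = match(rs, grp$values),
                           reorder = TRUE))
  keep <- d_t > 0
  surv <- cumprod(1 - d_t[keep] / n_risk[keep])
  jump <- -diff(c(1, surv))
  list(t = grp$values[keep], d = jump, resid = surv[length(surv)])
}

# Smoothed survival of the ratio at delta: Gaussian kernel on the log-ratio
# scale applied to the KM jump masses; bandwidth 0 degrades to the KM step.
smooth_survival_at <- function(jumps, delta, bandwidth) {
  if (delta <= 0) return(1)
  if (length(jumps$t) == 0) return(1)
  if (bandwidth <= 0) {
    return(sum(jumps$d[jumps$t > delta]) + jumps$resid)
  }
  z <- (log(jumps$t) - log(delta)) / bandwidth
  sum(jumps$d * pnorm(z)) + jumps$resid
}

silverman_bandwidth <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  spread <- min(sd(x), IQR(x) / 1.349)
  if (!is.finite(spread) || spread <= 0) spread <- sd(x)
  if (!is.finite(spread) || spread <= 0) return(0)
  0.9 * spread * n^(-1 / 5)
}

#' PFS2/PFS1 ratio analysis (kernel-based Kaplan-Meier)
#'
#' Computes per-patient ratios `r = pfs2 / pfs1`, with censoring inherited
#' from PFS2 (PFS1 is treated as fully observed: progression on the prior
#' line motivated the therapy switch; records with explicitly censored PFS1
#' are excluded and counted). The survival function of the ratio is
#' estimated by Kaplan-Meier and kernel-smoothed with a Gaussian kernel on
#' the log-ratio scale (Silverman plug-in bandwidth by default); the benefit
#' rate is the smoothed survival at the efficacy threshold `delta`. The CI
#' is a percentile bootstrap over patients.
#'
#' @param records Data frame with `pfs1_months`, `pfs2_months` and optional
#'   `pfs1_event`, `pfs2_event` (events default to observed when absent).
#' @param delta Efficacy threshold (default 1.3).
#' @param bandwidth Kernel bandwidth on the log-ratio scale; `NULL` (default)
#'   uses the Silverman plug-in; `0` disables smoothing (pure KM step).
#' @param B Bootstrap replicates for the benefit-rate CI (default 2000;
#'   `0` skips the bootstrap).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @param grid Ratio grid on which the smoothed curve is evaluated
#'   (default 0 to 5 by 0.01).
#' @return An object of class `pfs_ratio_result` with `tidy()`, `glance()`
#'   and `autoplot()` methods. `glance()` reports the benefit rate, its CI,
#'   the KM median ratio and exclusion counts.
#' @export
#' @examples
#' d <- tibble::tibble(pfs1_months = 1, pfs2_months = c(2.0, 1.0, 0.5, 2.6, 1.4))
#' glance(pfs_ratio_analysis(d, bandwidth = 0, B = 0))
pfs_ratio_analysis <- function(records, delta = 1.3, bandwidth = NULL,
                               B = 2000, level = 0.95, seed = 1L,
                               grid = seq(0, 5, by = 0.01)) {
  assert_columns(records, c("pfs1_months", "pfs2_months"), "records")
  n_input <- nrow(records)
  p1e <- if ("pfs1_event" %in% names(records))
    dplyr::coalesce(records$pfs1_event, TRUE) else rep(TRUE, n_input)
  miss1 <- is.na(records$pfs1_months)
  miss2 <- is.na(records$pfs2_months) & !miss1
  cens1 <- !miss1 & !miss2 & !p1e
  zero1 <- !miss1 & !miss2 & !cens1 & records$pfs1_months == 0
  drop <- miss1 | miss2 | cens1 | zero1
  if (any(miss1)) {
    log_msg("INFO", sprintf("PFS1 missing for %d case(s); excluded", sum(miss1)))
  }
  if (any(cens1)) {
    log_msg("INFO", sprintf("PFS1 censored for %d case(s); excluded", sum(cens1)))
  }
  if (any(zero1)) {
    log_msg("WARN", sprintf("PFS1 is zero for %d case(s); excluded", sum(zero1)))
  }
  kept <- records[!drop, , drop = FALSE]
  ratio <- kept$pfs2_months / kept$pfs1_months
  event <- if ("pfs2_event" %in% names(kept))
    dplyr::coalesce(kept$pfs2_event, TRUE) else rep(TRUE, nrow(kept))
  if (length(ratio) == 0) abort("no evaluable PFS-ratio records")

  h <- bandwidth %||% silverman_bandwidth(log(ratio[event]))
  jumps <- km_jumps(ratio, event)
  undefined <- all(!event) && all(ratio < delta)
  benefit <- if (undefined) NA_real_ else smooth_survival_at(jumps, delta, h)
  curve <- tibble(
    delta = grid,
    survival = vapply(grid, function(d) smooth_survival_at(jumps, d, h),
                      numeric(1))
  )
  km <- km_estimate(tibble(t = ratio, e = event), t, e)

  ci <- c(NA_real_, NA_real_)
  if (B > 0 && !undefined) {
    boot <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(length(ratio), replace = TRUE)
        rb <- ratio[idx]; eb <- event[idx]
        hb <- bandwidth %||% silverman_bandwidth(log(rb[eb]))
        smooth_survival_at(km_jumps(rb, eb), delta, hb)
      }, numeric(1))
    })
    alpha <- (1 - level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(list(
    data = tibble(ratio = ratio, event = event),
    delta = delta, bandwidth = h,
    benefit_rate = benefit, ci_lower = ci[1], ci_upper = ci[2],
    benefit_undefined = undefined,
    curve = curve, km = km,
    n_input = n_input, n_used = length(ratio),
    n_missing_pfs1 = sum(miss1), n_censored_pfs1 = sum(cens1),
    n_zero_pfs1 = sum(zero1), n_missing_pfs2 = sum(miss2),
    B = B, level = level
  ), class = "pfs_ratio_result")
}

#' @export
print.pfs_ratio_result <- function(x, ...) {
  cat(sprintf("<pfs_ratio_result> n = %d/%d used; S(delta = %.2f) = %s",
              x$n_used, x$n_input, x$delta,
              if (is.na(x$benefit_rate)) "undefined"
              else sprintf("%.3f", x$benefit_rate)))
  if (!is.na(x$ci_lower)) {
    cat(sprintf(" (%.0f%% CI %.3f-%.3f)", 100 * x$level, x$ci_lower, x$ci_upper))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.pfs_ratio_result <- function(x, ...) x$curve

#' @export
glance.pfs_ratio_result <- function(x, ...) {
  km <- glance(x$km)
  tibble(
    n_input = x$n_input, n_used = x$n_used,
    n_missing_pfs1 = x$n_missing_pfs1,
    delta = x$delta, bandwidth = x$bandwidth,
    benefit_rate = x$benefit_rate,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    median_ratio = km$median,
    median_ratio_ci_lower = km$median_ci_lower,
    median_ratio_ci_upper = km$median_ci_upper
  )
}

#' Summary of molecularly guided therapy outcomes
#'
#' For records flagged `received_guided_therapy`, reports per-stratum sample
#' size, Kaplan-Meier median PFS2 with CI, ORR, DCR, and the PFS-ratio
#' benefit rate at `delta`; strata are the whole guided group plus each
#' basket and evidence level.
#'
#' @param records Clinical tibble ([read_clinical_table()] columns).
#' @param delta Efficacy threshold (default 1.3).
#' @param bandwidth,seed Passed to [pfs_ratio_analysis()] (point estimate
#'   only; no bootstrap in the per-stratum summary).
#' @return Tibble with one row per stratum.
#' @export
guided_therapy_summary <- function(records, delta = 1.3, bandwidth = NULL,
                                   seed = 1L) {
  assert_columns(records, c("received_guided_therapy"), "records")
  g <- filter(records, dplyr::coalesce(.data$received_guided_therapy, FALSE))
  if (nrow(g) == 0) {
    log_msg("INFO", "no patients received molecularly guided therapy")
    return(tibble(stratum = character(), level = character(), n = integer(),
                  median_pfs2 = numeric(), median_ci_lower = numeric(),
                  median_ci_upper = numeric(), orr = numeric(),
                  dcr = numeric(), benefit_rate = numeric()))
  }
  one_stratum <- function(rows, stratum, level) {
    rows <- mutate(rows, .ev = if ("pfs2_event" %in% names(rows))
      dplyr::coalesce(.data$pfs2_event, TRUE) else TRUE)
    km <- glance(km_estimate(rows, .data$pfs2_months, .data$.ev))
    rr <- response_rates(rows)
    pr <- tryCatch(
      glance(pfs_ratio_analysis(rows, delta = delta, bandwidth = bandwidth,
                                B = 0, seed = seed))$benefit_rate,
      error = function(e) NA_real_)
    tibble(stratum = stratum, level = level, n = nrow(rows),
           median_pfs2 = km$median, median_ci_lower = km$median_ci_lower,
           median_ci_upper = km$median_ci_upper,
           orr = rr$orr, dcr = rr$dcr, benefit_rate = pr)
  }
  out <- one_stratum(g, "overall", "all")
  for (col in intersect(c("basket", "evidence_level"), names(g))) {
    for (lev in sort(unique(g[[col]]))) {
      out <- dplyr::bind_rows(
        out, one_stratum(g[g[[col]] %in% lev, , drop = FALSE], col, lev))
    }
  }
  out
}
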