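## Discard survival: immediate survival at onboard arrival with
## beta-binomial credibility intervals, captive vitality tracking, and
## short-term Kaplan-Meier survival with right-censoring.

#' Immediate survival at onboard arrival
#'
#' Point estimate `alive/total` with a central Bayesian credibility
#' interval from the Beta(alive + 1, total - alive + 1) posterior (uniform
#' prior on the survival probability).
#'
#' @param alive number of animals alive at arrival, or a data frame with
#'   columns `alive` and `total` (and optionally `species`).
#' @param total number of animals examined (when `alive` is numeric).
#' @param ci_level credibility level (default 0.95).
#' @return data frame with columns `alive`, `total`, `point`, `cri_low`,
#'   `cri_high` (plus `species` when supplied).
#' @examples
#' immediate_survival(82, 127)  # spiny lobster row of the survival table
#' @export
immediate_survival <- function(alive, total = NULL, ci_level = 0.95) {
  if (is.data.frame(alive)) {
    df <- alive
    check_columns(df, c("alive", "total"), "survival counts")
    alive <- df$alive
    total <- df$total
  } else {
    df <- NULL
  }
  if (any(total < 1)) stopf("total must be at least 1")
  if (any(alive < 0) || any(alive > total))
    stopf("alive must lie in [0, total]")
  a <- (1 - ci_level) / 2
  out <- data.frame(alive = alive, total = total, point = alive / total,
                    cri_low = stats::qbeta(a, alive + 1, total - alive + 1),
                    cri_high = stats::qbeta(1 - a, alive + 1,
                                            total - alive + 1))
  if (!is.null(df) && "species" %in% names(df))
    out <- cbind(species = df$species, out)
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with the standard deaths-before-censoring tie
#' convention, Greenwood standard errors and confidence intervals on the
#' log-survival scale clipped to [0, 1] (via [survival::survfit()]).  The
#' Greenwood SE is set to 0 where the curve reaches 0.
#'
#' @param time follow-up time in days (>= 0), or a data frame with columns
#'   `time` and `event`.
#' @param event event indicator (`TRUE`/1 = death, `FALSE`/0 = censored).
#' @param conf_level confidence level (default 0.95).
#' @return data frame of class `km_curve` with one row per event time:
#'   `time`, `n_risk`, `n_event`, `survival`, `greenwood_se`, `ci_low`,
#'   `ci_high`.  The underlying `survfit` object is kept in attribute
#'   `"survfit"`.
#' @export
km_fit <- function(time, event = NULL, conf_level = 0.95) {
  if (is.data.frame(time)) {
    check_columns(time, c("time", "event"), "km input")
    event <- time$event
    time <- time$time
  }
  if (length(time) == 0L) stopf("at least one individual is required")
  if (any(!is.finite(time)) || any(time < 0))
    stopf("times must be finite and nonnegative")
  event <- as.integer(as.logical(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log", conf.int = conf_level)
  keep <- sf$n.event > 0
  out <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                    n_event = sf$n.event[keep], survival = sf$surv[keep],
                    greenwood_se = sf$std.err[keep] * sf$surv[keep],
                    ci_low = sf$lower[keep], ci_high = sf$upper[keep])
  zero <- out$survival <= 0
  out$greenwood_se[zero] <- 0
  out$ci_low[zero] <- 0
  out$ci_high[zero] <- 0
  out$ci_low <- pmax(out$ci_low, 0)
  out$ci_high <- pmin(out$ci_high, 1)
  attr(out, "survfit") <- sf
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve
#'
#' Step-function lookup of the survival probability at given times.
#'
#' @param curve a [km_fit()] result.
#' @param times evaluation times.
#' @return survival probabilities (1 before the first event).
#' @export
km_survival <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Combine immediate and short-term survival into one cohort
#'
#' Builds the right-censored input for the combined Kaplan-Meier analysis:
#' animals dead at arrival are events at day 0; survivors not kept in
#' captivity are censored at day 0; captive animals contribute an event at
#' their first day with DEAD status, or are censored at the last
#' observation day.
#'
#' @param alive,total immediate-survival counts for the species.
#' @param captive vitality records of the captive subsample (data frame
#'   with `individual_id`, `day`, `status`), or `NULL`.
#' @return data frame with columns `time` and `event`.
#' @export
combine_survival_cohort <- function(alive, total, captive = NULL) {
  if (alive > total) stopf("alive must not exceed total")
  n_cap <- 0L
  cap_time <- numeric(0)
  cap_event <- integer(0)
  if (!is.null(captive) && nrow(captive) > 0L) {
    check_columns(captive, c("individual_id", "day", "status"), "captive")
    ids <- unique(captive$individual_id)
    n_cap <- length(ids)
    if (n_cap > alive)
      stopf("captive subsample larger than the number of survivors")
    last_day <- max(captive$day)
    for (id in ids) {
      sub <- captive[captive$individual_id == id, , drop = FALSE]
      sub <- sub[order(sub$day), , drop = FALSE]
      dead <- sub$day[sub$status == "DEAD"]
      if (length(dead) > 0L) {
        cap_time <- c(cap_time, min(dead))
        cap_event <- c(cap_event, 1L)
      } else {
        cap_time <- c(cap_time, last_day)
        cap_event <- c(cap_event, 0L)
      }
    }
  }
  data.frame(
    time = c(rep(0, total - alive), rep(0, alive - n_cap), cap_time),
    event = c(rep(1L, total - alive), rep(0L, alive - n_cap), cap_event))
}

#' Vitality contingency table
#'
#' Counts of each vitality status per observation day for captive animals,
#' after checking the monotone-death invariant (an animal recorded DEAD
#' stays DEAD at later days).
#'
#' @param records data frame with columns `individual_id`, `day`, `status`
#'   (status in `DEAD < POOR < GOOD < EXCELLENT`).
#' @return integer matrix, days (rows, sorted) by the four statuses.
#' @export
vitality_table <- function(records) {
  if (nrow(records) == 0L)
    return(matrix(integer(0), nrow = 0, ncol = 4,
                  dimnames = list(NULL, VITALITY_LEVELS)))
  check_columns(records, c("individual_id", "day", "status"), "vitality")
  bad <- which(!records$status %in% VITALITY_LEVELS)
  if (length(bad) > 0L)
    stopf("row %d: unknown vitality status '%s'", bad[1],
          records$status[bad[1]])
  for (id in unique(records$individual_id)) {
    sub <- records[records$individual_id == id, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    dead_at <- which(sub$status == "DEAD")
    if (length(dead_at) > 0L &&
          any(sub$status[seq(min(dead_at), nrow(sub))] != "DEAD"))
      stopf("individual '%s' regresses from DEAD", id)
  }
  tab <- table(factor(records$day, levels = sort(unique(records$day))),
               factor(records$status, levels = VITALITY_LEVELS))
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), VITALITY_LEVELS))
  out
}
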