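# Sleep parameters on the 2-min epoch grid.  All durations are in minutes
# (epochs x 2); the identity SL + WASO + TST = TIB holds exactly by
# construction for both PSG- and activity-derived parameters.

#' Run-length rule parameters
#'
#' The two run-length thresholds of the activity-based sleep-parameter
#' definitions: sleep onset is the start of the first run of at least
#' \code{n_sl} consecutive sleep-scored epochs, and only wake runs of at
#' least \code{n_waso} epochs after onset count toward wake after sleep
#' onset.  The defaults (4 and 5 epochs, i.e. 8 and 10 min) are the optima
#' of the published run-length search.
#'
#' @param n_sl Consecutive sleep epochs defining onset, integer in 1--10.
#' @param n_waso Minimum counted wake-run length, integer in 1--10.
#' @return A list of class \code{"run_rule_params"}.
#' @export
run_rule_params <- function(n_sl = 4L, n_waso = 5L) {
  n_sl <- as.integer(n_sl); n_waso <- as.integer(n_waso)
  for (n in c(n_sl, n_waso))
    if (is.na(n) || n < 1L || n > 10L)
      stop("run-length parameters must be integers in 1..10", call. = FALSE)
  structure(list(n_sl = n_sl, n_waso = n_waso), class = "run_rule_params")
}

sw_labels <- function(x) {
  if (inherits(x, "sw_series")) return(x$label)
  if (inherits(x, "collapsed_hypnogram")) return(x$sw)
  x <- as.character(x)
  if (any(!(x %in% c("S", "W"))))
    stop("sleep/wake labels must be 'S' or 'W'", call. = FALSE)
  x
}

new_sleep_parameters <- function(sl, waso, tst, tib, no_onset = FALSE) {
  se <- if (no_onset) 0 else 100 * tst / tib
  structure(list(sl_min = sl, waso_min = waso, tst_min = tst, tib_min = tib,
                 se_pct = se, no_onset = no_onset),
            class = "sleep_parameters")
}

#' @export
print.sleep_parameters <- function(x, ...) {
  if (x$no_onset) {
    cat(sprintf("sleep parameters: no sleep onset in %g min in bed (SE = 0%%)\n",
                x$tib_min))
  } else {
    cat(sprintf("sleep parameters: SL %g min, WASO %g min, TST %g min, TIB %g min, SE %.2f%%\n",
                x$sl_min, x$waso_min, x$tst_min, x$tib_min, x$se_pct))
  }
  invisible(x)
}

#' @export
as.data.frame.sleep_parameters <- function(x, ...) {
  data.frame(sl_min = x$sl_min, waso_min = x$waso_min, tst_min = x$tst_min,
             tib_min = x$tib_min, se_pct = x$se_pct, no_onset = x$no_onset)
}

#' Sleep parameters from collapsed polysomnography
#'
#' Computes the four standard parameters from the 2-min sleep/wake sequence:
#' sleep latency (lights-off to the first sleep epoch), total sleep time
#' (sleep epochs from onset to lights-on), wake after sleep onset
#' (TIB - SL - TST) and sleep efficiency (100 TST / TIB).
#'
#' @param ch A [collapse_hypnogram()] result, or a character vector of
#'   \code{"S"}/\code{"W"} 2-min labels.
#' @return A \code{"sleep_parameters"} object.  A night with no sleep epoch
#'   is flagged \code{no_onset}; its SL/TST/WASO are \code{NA} and SE is 0.
#' @export
psg_parameters <- function(ch) {
  sw <- sw_labels(ch)
  if (length(sw) < 1L) stop("empty epoch sequence", call. = FALSE)
  tib <- 2 * length(sw)
  onset <- match("S", sw)
  if (is.na(onset))
    return(new_sleep_parameters(NA_real_, NA_real_, NA_real_, tib,
                                no_onset = TRUE))
  sl <- 2 * (onset - 1L)
  tst <- 2 * sum(sw[onset:length(sw)] == "S")
  new_sleep_parameters(sl, tib - sl - tst, tst, tib)
}

qualifying_run <- function(len, n, strict_gt) if (strict_gt) len > n else len >= n

#' Activity-scored sleep onset
#'
#' Finds the first epoch of the first run of consecutive sleep-scored
#' epochs long enough to qualify as sleep onset.  By default a run of
#' \code{n_sl} or more epochs qualifies; \code{strict_gt = TRUE} requires
#' strictly more than \code{n_sl}.
#'
#' @param s An [score_series()] result or character \code{"S"}/\code{"W"}
#'   vector.
#' @param n_sl Run-length threshold, integer in 1--10.
#' @param strict_gt Use the strict reading of "more than n epochs".
#' @return 0-based epoch index of sleep onset, or \code{NA} when no run
#'   qualifies.
#' @export
act_sleep_onset <- function(s, n_sl = 4L, strict_gt = FALSE) {
  labels <- sw_labels(s)
  n_sl <- as.integer(n_sl)
  if (is.na(n_sl) || n_sl < 1L || n_sl > 10L)
    stop("n_sl must be an integer in 1..10", call. = FALSE)
  r <- rle(labels)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  hit <- which(r$values == "S" & qualifying_run(r$lengths, n_sl, strict_gt))
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]] - 1L
}

#' Wake after activity-scored sleep onset
#'
#' Sums, over the epochs strictly after the onset epoch, the lengths of
#' maximal wake-scored runs of at least \code{n_waso} epochs (2 min each).
#' Shorter wake runs contribute nothing to WASO -- they are treated as sleep
#' for parameter purposes only; epoch labels themselves are never rewritten,
#' so validation metrics are unaffected.
#'
#' @param s Labels as in [act_sleep_onset()].
#' @param onset 0-based onset epoch index (from [act_sleep_onset()]).
#' @param n_waso Minimum counted run length, integer in 1--10.
#' @param strict_gt Use the strict reading of "more than n epochs".
#' @return WASO in minutes.
#' @export
act_waso <- function(s, onset, n_waso = 5L, strict_gt = FALSE) {
  labels <- sw_labels(s)
  if (is.na(onset)) stop("sleep onset is undefined; WASO unavailable",
                         call. = FALSE)
  n_waso <- as.integer(n_waso)
  if (is.na(n_waso) || n_waso < 1L || n_waso > 10L)
    stop("n_waso must be an integer in 1..10", call. = FALSE)
  after <- labels[seq_along(labels) > onset + 1L]
  if (!length(after)) return(0)
  r <- rle(after)
  keep <- r$values == "W" & qualifying_run(r$lengths, n_waso, strict_gt)
  2 * sum(r$lengths[keep])
}

#' Sleep parameters from activity-scored epochs
#'
#' Applies the run-length rules to an activity-scored sleep/wake sequence:
#' SL from the first qualifying sleep run, WASO from qualifying wake runs
#' after onset, TST = TIB - SL - WASO, SE = 100 TST / TIB.
#'
#' @param s An [score_series()] result or \code{"S"}/\code{"W"} vector.
#' @param rules A [run_rule_params()] object (defaults n_sl = 4, n_waso = 5).
#' @param strict_gt Use the strict reading of "more than n epochs".
#' @return A \code{"sleep_parameters"} object; flagged \code{no_onset} when
#'   no sleep run qualifies (SE = 0).
#' @export
act_parameters <- function(s, rules = run_rule_params(), strict_gt = FALSE) {
  labels <- sw_labels(s)
  stopifnot(inherits(rules, "run_rule_params"))
  tib <- 2 * length(labels)
  onset <- act_sleep_onset(labels, rules$n_sl, strict_gt)
  if (is.na(onset))
    return(new_sleep_parameters(NA_real_, NA_real_, NA_real_, tib,
                                no_onset = TRUE))
  sl <- 2 * onset
  waso <- act_waso(labels, onset, rules$n_waso, strict_gt)
  new_sleep_parameters(sl, waso, tib - sl - waso, tib)
}

paired_t_safe <- function(a, b) {
  d <- a - b
  if (length(d) < 2L) return(c(t = NA_real_, p = NA_real_))
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(c(t = 0, p = 1))
    return(c(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Run-length optimization search
#'
#' For each candidate run length \code{n}, compares the cohort's
#' activity-derived parameter values against the matched PSG values: the
#' mean difference (delta = mean act - mean psg), a two-sided paired t-test,
#' and the intraclass correlation ICC(2,1).  An \code{n} is feasible when
#' the difference is not significant (p >= alpha) and agreement is
#' sufficient (ICC >= icc_min); among feasible \code{n} the one minimizing
#' |delta| is chosen, smallest \code{n} on ties.
#'
#' @param psg Numeric vector of per-subject PSG parameter values (minutes).
#' @param act_by_n Numeric matrix, one row per subject, one column per
#'   candidate \code{n}, of activity-derived values.
#' @param n_values Candidate run lengths, one per column (default 1..ncol).
#' @param alpha Significance level for the paired t-test (default 0.05).
#' @param icc_min Minimum acceptable ICC (default 0.6).
#' @return A list of class \code{"run_rule_optimization"} with the per-n
#'   \code{table} (mean_act, mean_psg, delta, t, p, icc, icc_p, feasible)
#'   and \code{chosen_n} (\code{NA} when no n is feasible).
#' @export
optimize_run_rule <- function(psg, act_by_n, n_values = NULL,
                              alpha = 0.05, icc_min = 0.6) {
  act_by_n <- as.matrix(act_by_n)
  psg <- as.numeric(psg)
  if (length(psg) < 3L) stop("optimization needs at least 3 subjects",
                             call. = FALSE)
  if (nrow(act_by_n) != length(psg))
    stop("act_by_n must have one row per subject", call. = FALSE)
  if (is.null(n_values)) n_values <- seq_len(ncol(act_by_n))
  if (length(n_values) != ncol(act_by_n))
    stop("n_values must match the columns of act_by_n", call. = FALSE)
  rows <- lapply(seq_along(n_values), function(j) {
    act <- act_by_n[, j]
    ok <- is.finite(act) & is.finite(psg)
    if (sum(ok) < 3L)
      return(data.frame(n = n_values[j], n_subjects = sum(ok),
                        mean_act = NA_real_, mean_psg = NA_real_,
                        delta = NA_real_, t = NA_real_, p = NA_real_,
                        icc = NA_real_, icc_p = NA_real_, feasible = FALSE))
    tt <- paired_t_safe(act[ok], psg[ok])
    ic <- icc_agreement(psg[ok], act[ok])
    feasible <- is.finite(tt["p"]) && tt["p"] >= alpha &&
      is.finite(ic$icc) && ic$icc >= icc_min
    data.frame(n = n_values[j], n_subjects = sum(ok),
               mean_act = mean(act[ok]), mean_psg = mean(psg[ok]),
               delta = mean(act[ok]) - mean(psg[ok]),
               t = unname(tt["t"]), p = unname(tt["p"]),
               icc = ic$icc, icc_p = ic$p, feasible = feasible)
  })
  tab <- do.call(rbind, rows)
  chosen <- NA_integer_
  if (any(tab$feasible)) {
    feas <- tab[tab$feasible, ]
    # order() is stable, so equal |delta| resolves to the smallest n
    feas <- feas[order(abs(feas$delta), feas$n), ]
    chosen <- as.integer(feas$n[1])
  }
  structure(list(table = tab, chosen_n = chosen,
                 alpha = alpha, icc_min = icc_min),
            class = "run_rule_optimization")
}

#' @export
print.run_rule_optimization <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat(if (is.na(x$chosen_n)) "no feasible n\n" else
    sprintf("chosen n = %d (p >= %g, ICC >= %g, |delta| minimal)\n",
            x$chosen_n, x$alpha, x$icc_min))
  invisible(x)
}

#' Optimize both run-length rules on a cohort
#'
#' Runs the exhaustive search over \code{n = 1..10} for the sleep-latency
#' rule first, then -- holding each subject's onset at the chosen
#' \code{n_sl} -- for the WASO rule, mirroring the two-stage design of the
#' original optimization ("wake after (optimized) sleep onset").
#'
#' @param cohort List of per-subject lists, each with elements \code{psg}
#'   (a [collapse_hypnogram()] result or \code{"S"}/\code{"W"} vector) and
#'   \code{act} (an [score_series()] result or label vector).
#' @param n_values Candidate run lengths (default 1..10).
#' @param alpha,icc_min Feasibility rules as in [optimize_run_rule()].
#' @param strict_gt Use the strict reading of "more than n epochs".
#' @return A list with elements \code{sl} and \code{waso} (each a
#'   \code{"run_rule_optimization"}) and \code{rules}, the chosen
#'   [run_rule_params()] (falling back to the published defaults 4/5 for a
#'   rule with no feasible n).
#' @export
optimize_sleep_rules <- function(cohort, n_values = 1:10, alpha = 0.05,
                                 icc_min = 0.6, strict_gt = FALSE) {
  if (length(cohort) < 3L) stop("optimization needs at least 3 subjects",
                                call. = FALSE)
  psg_sl <- vapply(cohort, function(s) psg_parameters(s$psg)$sl_min, numeric(1))
  act_sl <- t(vapply(cohort, function(s) {
    labels <- sw_labels(s$act)
    vapply(n_values, function(n) {
      onset <- act_sleep_onset(labels, n, strict_gt)
      if (is.na(onset)) NA_real_ else 2 * onset
    }, numeric(1))
  }, numeric(length(n_values))))
  sl_opt <- optimize_run_rule(psg_sl, act_sl, n_values, alpha, icc_min)
  n_sl <- if (is.na(sl_opt$chosen_n)) 4L else sl_opt$chosen_n

  psg_waso <- vapply(cohort, function(s) psg_parameters(s$psg)$waso_min,
                     numeric(1))
  act_waso_tab <- t(vapply(cohort, function(s) {
    labels <- sw_labels(s$act)
    onset <- act_sleep_onset(labels, n_sl, strict_gt)
    vapply(n_values, function(n) {
      if (is.na(onset)) NA_real_ else act_waso(labels, onset, n, strict_gt)
    }, numeric(1))
  }, numeric(length(n_values))))
  waso_opt <- optimize_run_rule(psg_waso, act_waso_tab, n_values, alpha,
                                icc_min)
  n_waso <- if (is.na(waso_opt$chosen_n)) 5L else waso_opt$chosen_n

  list(sl = sl_opt, waso = waso_opt,
       rules = run_rule_params(n_sl, n_waso))
}
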