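# Epoch-by-epoch validation of activity scoring against collapsed PSG.
# Convention throughout: sleep is the "positive" class, so sensitivity is
# the true-sleep detection rate and specificity the true-wake detection
# rate.  Percentages with an empty denominator class are reported as NA and
# excluded from cross-subject means.

pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den

#' Epoch-by-epoch confusion metrics
#'
#' Tallies the 2x2 sleep/wake confusion table between PSG and activity
#' scoring over aligned epochs and derives the overall agreement rate,
#' sensitivity (fraction of PSG sleep epochs scored sleep) and specificity
#' (fraction of PSG wake epochs scored wake).
#'
#' @param psg PSG labels: a [collapse_hypnogram()] result or
#'   \code{"S"}/\code{"W"} vector.
#' @param act Activity labels: an [score_series()] result or
#'   \code{"S"}/\code{"W"} vector of the same length.
#' @return A list of class \code{"validation_report"} with
#'   \code{agreement_pct}, \code{sensitivity_pct}, \code{specificity_pct}
#'   (\code{NA} when the denominator class is absent), the confusion
#'   \code{cells} (ss, sw, ws, ww; PSG class first) and \code{n_epochs}.
#' @export
confusion_metrics <- function(psg, act) {
  p <- sw_labels(psg)
  a <- sw_labels(act)
  if (length(p) != length(a))
    stop(sprintf("PSG (%d) and activity (%d) label lengths differ",
                 length(p), length(a)), call. = FALSE)
  if (!length(p)) stop("empty label sequences", call. = FALSE)
  cells <- c(ss = sum(p == "S" & a == "S"),
             sw = sum(p == "S" & a == "W"),
             ws = sum(p == "W" & a == "S"),
             ww = sum(p == "W" & a == "W"))
  structure(list(
    agreement_pct = unname(pct(cells[["ss"]] + cells[["ww"]], length(p))),
    sensitivity_pct = unname(pct(cells[["ss"]], cells[["ss"]] + cells[["sw"]])),
    specificity_pct = unname(pct(cells[["ww"]], cells[["ws"]] + cells[["ww"]])),
    cells = cells, n_epochs = length(p)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("epoch-by-epoch validation over %d 2-min epochs\n", x$n_epochs))
  cat(sprintf("  agreement %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$agreement_pct, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Per-stage agreement with PSG
#'
#' For each PSG-determined category of the collapsed hypnogram, the
#' percentage of its epochs whose activity score matches: sleep stages
#' (N1, N2, N3, R) count epochs scored sleep, the wake category counts
#' epochs scored wake.  A category absent from the night is \code{NA}.
#'
#' @param ch A [collapse_hypnogram()] result (substages required).
#' @param act Activity labels as in [confusion_metrics()], same length.
#' @return Named numeric vector of percentages for N1, N2, N3, R, W.
#' @export
stagewise_agreement <- function(ch, act) {
  stopifnot(inherits(ch, "collapsed_hypnogram"))
  a <- sw_labels(act)
  if (length(ch$sw) != length(a))
    stop("collapsed hypnogram and activity label lengths differ",
         call. = FALSE)
  out <- c(N1 = NA_real_, N2 = NA_real_, N3 = NA_real_, R = NA_real_,
           W = NA_real_)
  for (st in c("N1", "N2", "N3", "R")) {
    sel <- ch$sw == "S" & !is.na(ch$substage) & ch$substage == st
    out[st] <- pct(sum(sel & a == "S"), sum(sel))
  }
  out["W"] <- pct(sum(ch$sw == "W" & a == "W"), sum(ch$sw == "W"))
  out
}

#' Intraclass correlation between two measurement methods
#'
#' Single-measures intraclass correlation across subjects measured by two
#' methods (e.g. PSG and actigraphy).  The default \code{"ICC2"} is the
#' two-way random-effects absolute-agreement form ICC(2,1), the standard
#' choice for method-agreement studies; \code{"ICC3"} is the two-way mixed
#' consistency form ICC(3,1), which does not penalize a constant offset.
#' Significance is the F test of the between-subject mean square against
#' the residual, with (n-1) and (n-1)(k-1) degrees of freedom.
#'
#' @param x,y Paired per-subject values from the two methods (length >= 3).
#' @param type \code{"ICC2"} (default) or \code{"ICC3"}.
#' @return List with \code{icc}, \code{p}, \code{type} and the mean squares
#'   \code{msr}, \code{msc}, \code{mse}.  \code{icc} is \code{NA} when
#'   there is no variance at all to apportion.
#' @export
icc_agreement <- function(x, y, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("ICC needs at least 3 subject pairs", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("ICC inputs must be finite", call. = FALSE)
  n <- length(x); k <- 2L
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - grand)^2) - k * sum((row_m - grand)^2) -
    n * sum((col_m - grand)^2)
  mse <- max(sse, 0) / ((n - 1) * (k - 1))
  den <- if (type == "ICC2")
    msr + (k - 1) * mse + k * (msc - mse) / n
  else
    msr + (k - 1) * mse
  icc <- if (den <= 0) NA_real_ else (msr - mse) / den
  p <- if (mse == 0) {
    if (msr == 0) NA_real_ else 0
  } else {
    stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = icc, p = p, type = type, msr = msr, msc = msc, mse = mse)
}

unpaired_t_safe <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Two-sided t-tests between two groups of validation metrics
#'
#' Compares each shared metric column of two per-subject metric tables with
#' a two-sided Student's t-test: unpaired (pooled variance, df =
#' nA + nB - 2) for independent groups, or paired (df = n - 1) for matched
#' designs.  Missing values (flagged undefined denominators) are dropped
#' pairwise.
#'
#' @param a,b Data frames of per-subject metrics with common numeric
#'   columns (at least 2 subjects each; equal rows when paired).
#' @param paired Paired test?
#' @return Data frame with one row per metric: means, \code{t}, \code{df},
#'   \code{p}.
#' @export
group_ttests <- function(a, b, paired = FALSE) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  metrics <- intersect(names(a)[vapply(a, is.numeric, logical(1))],
                       names(b)[vapply(b, is.numeric, logical(1))])
  if (!length(metrics)) stop("no shared numeric metric columns", call. = FALSE)
  if (paired && nrow(a) != nrow(b))
    stop("paired comparison needs equal group sizes", call. = FALSE)
  rows <- lapply(metrics, function(mname) {
    va <- a[[mname]]; vb <- b[[mname]]
    if (paired) {
      ok <- is.finite(va) & is.finite(vb)
      va <- va[ok]; vb <- vb[ok]
      if (length(va) < 2L) stop(sprintf("metric '%s': fewer than 2 complete pairs",
                                        mname), call. = FALSE)
      tt <- paired_t_safe(va, vb)
      df <- length(va) - 1L
    } else {
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) < 2L || length(vb) < 2L)
        stop(sprintf("metric '%s': fewer than 2 observations per group", mname),
             call. = FALSE)
      tt <- unpaired_t_safe(va, vb)
      df <- length(va) + length(vb) - 2L
    }
    data.frame(metric = mname, mean_a = mean(va), mean_b = mean(vb),
               t = unname(tt["t"]), df = df, p = unname(tt["p"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

collapse_of <- function(subject, tib_cap_min) {
  if (!is.null(subject$psg)) {
    if (inherits(subject$psg, "collapsed_hypnogram")) return(subject$psg)
  }
  if (!is.null(subject$hypnogram))
    return(collapse_hypnogram(subject$hypnogram, tib_cap_min = tib_cap_min))
  stop("subject must carry a 'hypnogram' or collapsed 'psg' element",
       call. = FALSE)
}

scored_of <- function(subject, model, edge) {
  if (!is.null(subject$act) && inherits(subject$act, "sw_series"))
    return(subject$act)
  if (!is.null(subject$activity))
    return(score_series(subject$activity, model, edge))
  stop("subject must carry an 'activity' series or scored 'act' labels",
       call. = FALSE)
}

#' Validate a cohort of paired recordings
#'
#' Scores each subject's activity series with the model, aligns it with the
#' collapsed hypnogram, and computes the epoch-by-epoch metrics and
#' per-stage agreement.  Metrics are computed per subject and then averaged
#' (mean and SD) across subjects, with flagged undefined values excluded;
#' \code{pooled = TRUE} instead tallies all epochs of the cohort into one
#' confusion table.
#'
#' @param cohort List of subjects; each either a simulated subject (with
#'   \code{hypnogram} and \code{activity}) or a list with a collapsed
#'   \code{psg} and scored \code{act}.
#' @param model A [discriminant_model()]; default [child_fs760()].
#' @param edge Edge policy for [score_series()].
#' @param tib_cap_min Time-in-bed cap forwarded to [collapse_hypnogram()].
#' @param pooled Also report metrics pooled over all epochs?
#' @return A list of class \code{"cohort_validation"} with
#'   \code{per_subject} (one row of metrics per subject), \code{summary}
#'   (mean and SD per metric) and, when requested, \code{pooled}.
#' @export
validate_cohort <- function(cohort, model = child_fs760(),
                            edge = c("zero", "extend"), tib_cap_min = 420,
                            pooled = FALSE) {
  edge <- match.arg(edge)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    ch <- collapse_of(s, tib_cap_min)
    sc <- scored_of(s, model, edge)
    n <- min(length(ch$sw), nrow(sc))
    cm <- confusion_metrics(ch$sw[seq_len(n)], sc$label[seq_len(n)])
    ch_n <- ch
    ch_n$sw <- ch$sw[seq_len(n)]; ch_n$substage <- ch$substage[seq_len(n)]
    st <- stagewise_agreement(ch_n, sc$label[seq_len(n)])
    data.frame(subject = if (!is.null(s$id)) s$id else i,
               overall_pct = cm$agreement_pct,
               n1_pct = st[["N1"]], n2_pct = st[["N2"]],
               n3_pct = st[["N3"]], r_pct = st[["R"]], w_pct = st[["W"]],
               sensitivity_pct = cm$sensitivity_pct,
               specificity_pct = cm$specificity_pct,
               n_epochs = cm$n_epochs,
               stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_subject), c("subject", "n_epochs"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mname)
      mean(per_subject[[mname]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(mname)
      stats::sd(per_subject[[mname]], na.rm = TRUE), numeric(1)),
    n = vapply(metric_cols, function(mname)
      sum(is.finite(per_subject[[mname]])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(per_subject = per_subject, summary = summary,
              model_label = model$label, edge_policy = edge)
  if (pooled) {
    all_psg <- unlist(lapply(cohort, function(s) {
      ch <- collapse_of(s, tib_cap_min)
      sc <- scored_of(s, model, edge)
      ch$sw[seq_len(min(length(ch$sw), nrow(sc)))]
    }))
    all_act <- unlist(lapply(cohort, function(s) {
      ch <- collapse_of(s, tib_cap_min)
      sc <- scored_of(s, model, edge)
      sc$label[seq_len(min(length(ch$sw), nrow(sc)))]
    }))
    out$pooled <- confusion_metrics(all_psg, all_act)
  }
  structure(out, class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("cohort validation: %d subjects, model '%s', edge policy '%s'\n",
              nrow(x$per_subject), x$model_label, x$edge_policy))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-subject feature table
#'
#' Summarizes each subject for downstream modelling outside the package
#' (e.g. regressing algorithm agreement on subject characteristics): age
#' when known, PSG sleep efficiency, and the mean activity count within
#' PSG-determined wake, NREM and REM epochs.
#'
#' @param cohort As in [validate_cohort()].
#' @param ages Optional numeric vector of ages, one per subject.
#' @param model,edge,tib_cap_min As in [validate_cohort()].
#' @return Data frame with one row per subject.
#' @export
subject_features <- function(cohort, ages = NULL, model = child_fs760(),
                             edge = c("zero", "extend"), tib_cap_min = 420) {
  edge <- match.arg(edge)
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    ch <- collapse_of(s, tib_cap_min)
    sc <- scored_of(s, model, edge)
    n <- min(length(ch$sw), nrow(sc))
    counts <- sc$count[seq_len(n)]
    sw <- ch$sw[seq_len(n)]
    sub <- ch$substage[seq_len(n)]
    nrem <- sw == "S" & sub %in% c("N1", "N2", "N3")
    rem <- sw == "S" & !is.na(sub) & sub == "R"
    data.frame(subject = if (!is.null(s$id)) s$id else i,
               age = if (is.null(ages)) NA_real_ else ages[i],
               se_psg_pct = psg_parameters(sw)$se_pct,
               mean_count_wake = if (any(sw == "W")) mean(counts[sw == "W"]) else NA_real_,
               mean_count_nrem = if (any(nrem)) mean(counts[nrem]) else NA_real_,
               mean_count_rem = if (any(rem)) mean(counts[rem]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
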