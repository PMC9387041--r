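# Deriving a five-epoch discriminant from paired activity and PSG data.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assemble an epoch-pooled training set
#'
#' Builds the design for discriminant derivation: one row per scored 2-min
#' epoch pooled across all subjects, with the five-epoch activity window
#' (x_-2 .. x_+2) as features and the collapsed PSG class as the label
#' (sleep = 0, wake = 1).  Edge epochs get their missing neighbours from
#' the chosen edge policy.
#'
#' @param cohort List of subjects as in [validate_cohort()] (each with a
#'   \code{hypnogram} and \code{activity}, or a collapsed \code{psg} plus
#'   \code{activity}).
#' @param edge Edge policy, \code{"zero"} or \code{"extend"}.
#' @param tib_cap_min Time-in-bed cap forwarded to [collapse_hypnogram()].
#' @return A list of class \code{"training_set"}: \code{features}
#'   (n x 5 matrix), \code{labels} (0/1 integer), \code{subject}.
#' @export
assemble_training_set <- function(cohort, edge = c("zero", "extend"),
                                  tib_cap_min = 420) {
  edge <- match.arg(edge)
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  feats <- list(); labs <- list(); subj <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    ch <- collapse_of(s, tib_cap_min)
    counts <- if (inherits(s$activity, "activity_series")) s$activity$counts
      else as.numeric(s$activity)
    n <- min(length(ch$sw), length(counts))
    f <- t(vapply(seq_len(n), function(j) edge_window(counts[seq_len(n)], j, edge),
                  numeric(5)))
    feats[[i]] <- f
    labs[[i]] <- as.integer(ch$sw[seq_len(n)] == "W")
    subj[[i]] <- rep(if (!is.null(s$id)) s$id else i, n)
  }
  features <- do.call(rbind, feats)
  colnames(features) <- c("x_m2", "x_m1", "x_0", "x_p1", "x_p2")
  labels <- unlist(labs)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("degenerate training set: both sleep and wake epochs are required",
         call. = FALSE)
  structure(list(features = features, labels = labels,
                 subject = unlist(subj), edge_policy = edge),
            class = "training_set")
}

#' Fit a five-epoch sleep/wake discriminant
#'
#' Fisher's two-class linear discriminant on the pooled training set: the
#' direction is w = S_pooled^{-1} (mu_W - mu_S), cut at the equal-cost class
#' midpoint c0 = w . (mu_S + mu_W) / 2 (optionally shifted by the log prior
#' odds).  The returned model divides w by the cut so that the decision
#' boundary sits exactly at score 1, matching the convention that z >= 1
#' means wake.
#'
#' A singular pooled covariance (integer counts can collapse onto few
#' values) triggers a ridge-regularized refit with
#' lambda = 1e-6 trace(S)/5 and a warning.  A non-positive cut cannot be
#' rescaled to a unit boundary and is an error.
#'
#' @param ts A [assemble_training_set()] result, or any list with a numeric
#'   \code{features} matrix (5 columns) and 0/1 \code{labels}.
#' @param prior_weighted Shift the cut by log(prior_S / prior_W) estimated
#'   from class frequencies (equal-cost midpoint when \code{FALSE}).
#' @param label Label for the returned model.
#' @return A [discriminant_model()] with threshold 1.
#' @export
fit_discriminant <- function(ts, prior_weighted = FALSE,
                             label = "fitted_lda") {
  X <- as.matrix(ts$features)
  y <- as.integer(ts$labels)
  if (ncol(X) != 5L) stop("training features must have 5 columns",
                          call. = FALSE)
  if (nrow(X) != length(y)) stop("features and labels misaligned",
                                 call. = FALSE)
  if (!any(y == 1L) || !any(y == 0L))
    stop("degenerate training set: both classes are required", call. = FALSE)
  Xs <- X[y == 0L, , drop = FALSE]
  Xw <- X[y == 1L, , drop = FALSE]
  if (nrow(Xs) < 2L || nrow(Xw) < 2L)
    stop("each class needs at least 2 epochs to estimate covariance",
         call. = FALSE)
  mu_s <- colMeans(Xs)
  mu_w <- colMeans(Xw)
  sp <- ((nrow(Xs) - 1) * stats::cov(Xs) + (nrow(Xw) - 1) * stats::cov(Xw)) /
    (nrow(Xs) + nrow(Xw) - 2)
  w <- tryCatch(solve(sp, mu_w - mu_s), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w)) || rcond(sp) < 1e-12) {
    lambda <- 1e-6 * sum(diag(sp)) / 5
    if (lambda <= 0) lambda <- 1e-8
    warning(sprintf(
      "pooled covariance singular; refitting with ridge lambda = %.3g",
      lambda), call. = FALSE)
    w <- solve(sp + diag(lambda, 5), mu_w - mu_s)
  }
  if (sqrt(sum((mu_w - mu_s)^2)) < 1e-12)
    stop("identical class means: discriminant direction undefined",
         call. = FALSE)
  cut <- sum(w * (mu_s + mu_w)) / 2
  if (prior_weighted)
    cut <- cut + log(mean(y == 0L) / mean(y == 1L))
  if (!is.finite(cut) || cut <= 0)
    stop(sprintf(
      "decision cut %.4g is not positive; the rule cannot be rescaled to a unit boundary",
      cut), call. = FALSE)
  discriminant_model(w / cut, threshold = 1, label = label)
}

#' Split a cohort into two near-equal random groups
#'
#' Seeded subject-level partition for split-sample derivation and
#' validation: group sizes differ by at most one, and the same seed always
#' reproduces the same split.  The caller's RNG state is left untouched.
#'
#' @param subjects Either a vector of subject identifiers or a single
#'   integer n (interpreted as identifiers 1..n; at least 2 subjects).
#' @param seed Integer seed.
#' @return List with elements \code{A} and \code{B} holding the two groups
#'   of identifiers (\code{A} gets the extra subject when n is odd).
#' @export
split_cohort <- function(subjects, seed) {
  ids <- if (length(subjects) == 1L && is.numeric(subjects))
    seq_len(as.integer(subjects)) else subjects
  n <- length(ids)
  if (n < 2L) stop("a split needs at least 2 subjects", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  n_a <- ceiling(n / 2)
  list(A = ids[sort(perm[seq_len(n_a)])],
       B = ids[sort(perm[(n_a + 1L):n])])
}
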