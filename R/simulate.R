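# Seeded simulator of paired 30-s hypnograms and 2-min activity-count
# series.  The hypnogram is a first-order Markov chain over the five AASM
# stages at 30-s steps; activity is an overdispersed (negative-binomial)
# count per 2-min epoch whose mean depends on the stage dominating that
# window, rounded into the device's 32-level range.

default_transition_matrix <- function() {
  m <- matrix(c(
    # to:  W      N1     N2     N3     R        from:
    0.940, 0.060, 0.000, 0.000, 0.000,  # W
    0.020, 0.550, 0.350, 0.030, 0.050,  # N1
    0.004, 0.030, 0.886, 0.050, 0.030,  # N2
    0.002, 0.003, 0.065, 0.930, 0.000,  # N3
    0.010, 0.040, 0.050, 0.000, 0.900   # R
  ), nrow = 5, byrow = TRUE, dimnames = list(STAGE_LEVELS, STAGE_LEVELS))
  m
}

# Mean 2-min activity count by stage.  Children move more than adults in
# every stage; within a night means are ordered W > R > N1 > N2 > N3
# (REM motor inhibition is weaker in children, deep NREM is the stillest).
# In-bed wakefulness is strongly overdispersed (small size): much of it is
# quiet lying still, the known hard case for actigraphy.
activity_profiles <- list(
  child = list(mu = c(W = 5.0, N1 = 0.8, N2 = 0.4, N3 = 0.15, R = 1.0),
               size = c(W = 0.5, N1 = 1.0, N2 = 1.0, N3 = 1.0, R = 1.0)),
  adult = list(mu = c(W = 4.0, N1 = 0.5, N2 = 0.25, N3 = 0.1, R = 0.6),
               size = c(W = 0.5, N1 = 1.0, N2 = 1.0, N3 = 1.0, R = 1.0))
)

#' Simulation configuration
#'
#' Parameters of the paired hypnogram/activity simulator.  The defaults
#' describe a 7-h (420-min) time in bed of a healthy sleeper with sleep
#' efficiency near 90%: lights-off wakefulness with a mean latency around
#' 8--10 min, consolidated NREM/REM cycling, and brief nocturnal
#' awakenings.  The \code{"child"} activity profile has a higher mean count
#' than \code{"adult"} in every stage.
#'
#' @param profile \code{"child"} or \code{"adult"} activity scale.
#' @param tib_min Time in bed in minutes, divisible by 2 (default 420).
#' @param transition_matrix 5x5 row-stochastic matrix over the stages
#'   (rows/columns in the order W, N1, N2, N3, R) at 30-s steps.
#' @param initial Initial stage distribution (default: asleep-in-bed nights
#'   start awake, i.e. all mass on W).
#' @param activity_mu,activity_size Named per-stage mean and dispersion of
#'   the negative-binomial 2-min count law (overrides the profile).
#' @param lights_off Lights-off anchor timestamp (ISO-8601 string).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(profile = c("child", "adult"), tib_min = 420,
                       transition_matrix = NULL, initial = NULL,
                       activity_mu = NULL, activity_size = NULL,
                       lights_off = "2000-01-01T22:00:00") {
  profile <- match.arg(profile)
  tm <- if (is.null(transition_matrix)) default_transition_matrix() else
    as.matrix(transition_matrix)
  if (!all(dim(tm) == c(5L, 5L)))
    stop("transition matrix must be 5x5 over the stages W, N1, N2, N3, R",
         call. = FALSE)
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-8))
    stop("transition matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  dimnames(tm) <- list(STAGE_LEVELS, STAGE_LEVELS)
  init <- if (is.null(initial)) c(W = 1, N1 = 0, N2 = 0, N3 = 0, R = 0) else
    initial
  if (length(init) != 5L || any(init < 0) || abs(sum(init) - 1) > 1e-8)
    stop("initial distribution must be 5 non-negative values summing to 1",
         call. = FALSE)
  names(init) <- STAGE_LEVELS
  if (tib_min < 2 || tib_min %% 2 != 0)
    stop("tib_min must be a positive multiple of 2 minutes", call. = FALSE)
  prof <- activity_profiles[[profile]]
  mu <- if (is.null(activity_mu)) prof$mu else activity_mu[STAGE_LEVELS]
  size <- if (is.null(activity_size)) prof$size else
    activity_size[STAGE_LEVELS]
  if (any(!is.finite(mu)) || any(mu < 0) || any(!is.finite(size)) ||
      any(size <= 0))
    stop("activity means must be non-negative and dispersions positive",
         call. = FALSE)
  structure(list(profile = profile, tib_min = tib_min,
                 transition_matrix = tm, initial = init,
                 activity_mu = mu, activity_size = size,
                 lights_off = lights_off),
            class = "sim_config")
}

# Stage dominating a 4-stage window, ties broken W, R, N1, N2, N3.
dominant_stage <- function(stages) {
  ord <- c("W", "R", "N1", "N2", "N3")
  counts <- vapply(ord, function(s) sum(stages == s), integer(1))
  ord[which.max(counts)]
}

#' Simulate one night of paired recordings
#'
#' Draws a 30-s stage chain of length \code{tib_min * 2} from the Markov
#' kernel, then, for each 2-min window, one activity count from the
#' negative-binomial law of the window's dominant stage, rounded and
#' clipped into the device range 0--31.  Two independent RNG streams
#' (derived from \code{seed}) drive the hypnogram and the activity, so
#' changing one model leaves the other trace unchanged.  The caller's RNG
#' state is restored on exit.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the night exactly.
#' @return A list of class \code{"simulated_subject"} with
#'   \code{hypnogram} ([hypnogram()]), \code{activity}
#'   ([activity_series()]), \code{truth} (dominant generating stage per
#'   2-min epoch) and \code{profile}.
#' @export
simulate_subject <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  streams <- with_seed(seed, sample.int(2147483646L, 2L))
  n30 <- as.integer(cfg$tib_min * 2)
  stages <- with_seed(streams[1], {
    out <- character(n30)
    out[1] <- sample(STAGE_LEVELS, 1L, prob = cfg$initial)
    for (i in seq_len(n30 - 1L))
      out[i + 1L] <- sample(STAGE_LEVELS, 1L,
                            prob = cfg$transition_matrix[out[i], ])
    out
  })
  n2 <- n30 %/% 4L
  truth <- vapply(seq_len(n2), function(i)
    dominant_stage(stages[(4L * (i - 1L) + 1L):(4L * i)]), character(1))
  counts <- with_seed(streams[2], {
    raw <- vapply(truth, function(st)
      stats::rnbinom(1L, size = cfg$activity_size[[st]],
                     mu = cfg$activity_mu[[st]]), numeric(1))
    pmin(pmax(as.integer(round(raw)), 0L), 31L)
  })
  structure(list(
    hypnogram = hypnogram(stages, cfg$lights_off),
    activity = activity_series(counts, cfg$lights_off),
    truth = truth, profile = cfg$profile, seed = seed),
    class = "simulated_subject")
}

#' @export
print.simulated_subject <- function(x, ...) {
  cat(sprintf("simulated %s night: %d 30-s stages, %d activity epochs (seed %d)\n",
              x$profile, length(x$hypnogram$stages), length(x$activity$counts),
              x$seed))
  invisible(x)
}

#' Simulate a cohort of independent nights
#'
#' Each subject is generated by [simulate_subject()] under its own seed
#' derived from the master seed, so cohorts are reproducible and a prefix
#' of a larger cohort equals the smaller one.
#'
#' @param cfg A [sim_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master integer seed.
#' @return List of \code{"simulated_subject"} objects with ids
#'   \code{"S001"}, \code{"S002"}, ...
#' @export
simulate_cohort <- function(cfg, n_subjects, seed) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects must be at least 1", call. = FALSE)
  seeds <- with_seed(seed, sample.int(2147483646L, n_subjects))
  lapply(seq_len(n_subjects), function(i) {
    s <- simulate_subject(cfg, seeds[i])
    s$id <- sprintf("S%03d", i)
    s
  })
}
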