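# Independent brute-force oracles.  These are literal transcriptions of the
# scoring and run-length rules, written as plain loops so they share no code
# with the package implementation.

# Collapse rule, transcribed literally: two or more W in the four 30-s
# stages -> wake; otherwise sleep, sub-classified as the most frequent
# non-W stage, ties resolved in the order R, N1, N2, N3.
oracle_collapse <- function(window) {
  n_w <- 0L
  for (s in window) if (s == "W") n_w <- n_w + 1L
  if (n_w >= 2L) return(list(sw = "W", substage = NA_character_))
  best <- NULL
  best_count <- -1L
  for (cand in c("R", "N1", "N2", "N3")) {
    cnt <- 0L
    for (s in window) if (s == cand) cnt <- cnt + 1L
    if (cnt > best_count) {  # strict: earlier candidate wins ties
      best <- cand
      best_count <- cnt
    }
  }
  list(sw = "S", substage = best)
}

# Naive per-epoch scoring loop.
oracle_score <- function(counts, coefs, threshold, edge) {
  n <- length(counts)
  z <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in -2:2) {
      idx <- i + j
      xv <- if (idx >= 1 && idx <= n) counts[idx]
        else if (edge == "zero") 0
        else counts[if (idx < 1) 1 else n]
      acc <- acc + coefs[j + 3] * xv
    }
    z[i] <- acc
  }
  list(z = z, label = ifelse(z >= threshold, "W", "S"))
}

# Maximal runs of `value` in labels: data.frame(start 1-based, length).
oracle_runs <- function(labels, value) {
  starts <- integer(0); lens <- integer(0)
  i <- 1L
  while (i <= length(labels)) {
    if (labels[i] == value) {
      j <- i
      while (j < length(labels) && labels[j + 1L] == value) j <- j + 1L
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, length = lens)
}

oracle_onset <- function(labels, n, strict = FALSE) {
  runs <- oracle_runs(labels, "S")
  for (r in seq_len(nrow(runs))) {
    ok <- if (strict) runs$length[r] > n else runs$length[r] >= n
    if (ok) return(runs$start[r] - 1L)  # 0-based
  }
  NA_integer_
}

oracle_waso <- function(labels, onset0, n, strict = FALSE) {
  after <- labels[seq_along(labels) > onset0 + 1L]
  runs <- oracle_runs(after, "W")
  total <- 0L
  for (r in seq_len(nrow(runs))) {
    ok <- if (strict) runs$length[r] > n else runs$length[r] >= n
    if (ok) total <- total + runs$length[r]
  }
  2 * total
}

# ICC(2,1) via an aov() two-way decomposition (k = 2 raters).
oracle_icc2 <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(v ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

random_sw <- function(n, p_s = 0.8) {
  ifelse(stats::runif(n) < p_s, "S", "W")
}

random_stages <- function(n) {
  sample(c("W", "N1", "N2", "N3", "R"), n, replace = TRUE)
}

# All 625 4-stage windows.
all_windows <- function() {
  g <- expand.grid(s1 = stage_levels(), s2 = stage_levels(),
                   s3 = stage_levels(), s4 = stage_levels(),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
}
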