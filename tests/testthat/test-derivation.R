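# Fixtures for discriminant recovery: two homoscedastic 5-D Gaussian
# classes whose Bayes boundary, after midpoint rescaling, is exactly the
# target coefficient vector with a unit threshold.
gaussian_classes <- function(n_per_class, w_true, sep = 6, seed = 1) {
  stopifnot(length(w_true) == 5)
  nrm2 <- sum(w_true^2)
  mu_s <- w_true * (1 - sep * nrm2 / 2) / nrm2
  mu_w <- mu_s + sep * w_true
  set.seed(seed)
  xs <- matrix(rnorm(5 * n_per_class), ncol = 5, byrow = TRUE) +
    matrix(mu_s, n_per_class, 5, byrow = TRUE)
  xw <- matrix(rnorm(5 * n_per_class), ncol = 5, byrow = TRUE) +
    matrix(mu_w, n_per_class, 5, byrow = TRUE)
  list(features = rbind(xs, xw),
       labels = rep(c(0L, 1L), each = n_per_class),
       mu_s = mu_s, mu_w = mu_w)
}

test_that("training-set assembly pools epochs across subjects", {
  off <- "2000-01-01T22:00:00"
  subj <- list(hypnogram = hypnogram(c(rep("N2", 20), rep("W", 20)), off),
               activity = activity_series(c(rep(0L, 5), rep(9L, 5)), off))
  ts <- assemble_training_set(list(subj, subj))
  expect_equal(nrow(ts$features), 20)
  expect_equal(ncol(ts$features), 5)
  expect_equal(sum(ts$labels), 10)
  # first epoch of each subject: zero-padded left context
  expect_equal(unname(ts$features[1, ]), c(0, 0, 0, 0, 0))

  asleep <- list(hypnogram = hypnogram(rep("N2", 40), off),
                 activity = activity_series(rep(0L, 10), off))
  expect_error(assemble_training_set(list(asleep)), "degenerate")
})

test_that("fitted discriminant scores the class midpoint at exactly 1", {
  g <- gaussian_classes(500, c(0.11, 0.15, 0.23, 0.10, 0.06), seed = 11)
  m <- fit_discriminant(g)
  mid <- colMeans(g$features[g$labels == 0L, ]) / 2 +
    colMeans(g$features[g$labels == 1L, ]) / 2
  expect_equal(discriminant_score(mid, m), 1, tolerance = 1e-9)
  expect_equal(m$threshold, 1)
})

test_that("fit recovers a known generating rule and matches the Fisher direction", {
  w_true <- c(0.11, 0.15, 0.23, 0.10, 0.06)
  g <- gaussian_classes(4000, w_true, seed = 12)
  m <- fit_discriminant(g)
  rel_err <- sqrt(sum((m$coefficients - w_true)^2)) / sqrt(sum(w_true^2))
  expect_lt(rel_err, 0.15)

  skip_if_not_installed("MASS")
  fit <- MASS::lda(g$features, grouping = g$labels)
  dir_mass <- as.numeric(fit$scaling)
  cosang <- abs(sum(dir_mass * m$coefficients)) /
    sqrt(sum(dir_mass^2) * sum(m$coefficients^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("rescaling leaves the classification rule unchanged", {
  g <- gaussian_classes(800, c(0.11, 0.15, 0.23, 0.10, 0.06), seed = 13)
  m <- fit_discriminant(g)
  # reconstruct the unscaled Fisher rule and compare decisions
  xs <- g$features[g$labels == 0L, ]; xw <- g$features[g$labels == 1L, ]
  sp <- ((nrow(xs) - 1) * cov(xs) + (nrow(xw) - 1) * cov(xw)) /
    (nrow(xs) + nrow(xw) - 2)
  w_raw <- solve(sp, colMeans(xw) - colMeans(xs))
  cut_raw <- sum(w_raw * (colMeans(xs) + colMeans(xw))) / 2
  set.seed(14)
  fresh <- matrix(rnorm(5 * 500, sd = 3), ncol = 5)
  dec_raw <- (fresh %*% w_raw)[, 1] >= cut_raw
  dec_scaled <- (fresh %*% m$coefficients)[, 1] >= 1
  expect_identical(dec_raw, dec_scaled)
})

test_that("fit is invariant to row order and rejects degenerate inputs", {
  g <- gaussian_classes(300, c(0.11, 0.15, 0.23, 0.10, 0.06), seed = 15)
  m1 <- fit_discriminant(g)
  set.seed(16)
  perm <- sample(nrow(g$features))
  m2 <- fit_discriminant(list(features = g$features[perm, ],
                              labels = g$labels[perm]))
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)

  shared <- matrix(rnorm(250), ncol = 5)
  same_means <- list(features = rbind(shared, shared),
                     labels = rep(c(0L, 1L), each = 50))
  expect_error(suppressWarnings(fit_discriminant(same_means)),
               "identical class means|not positive")
})

test_that("split_cohort is seeded, balanced and reproducible", {
  sp <- split_cohort(65, seed = 7)
  expect_equal(length(sp$A), 33)
  expect_equal(length(sp$B), 32)
  expect_setequal(c(sp$A, sp$B), 1:65)
  expect_identical(sp, split_cohort(65, seed = 7))
  expect_false(identical(sp, split_cohort(65, seed = 8)))

  sp2 <- split_cohort(2, seed = 1)
  expect_equal(lengths(sp2), c(A = 1L, B = 1L))
  expect_error(split_cohort(1, seed = 1), "at least 2")
})
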