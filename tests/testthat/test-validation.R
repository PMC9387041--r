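test_that("confusion metrics match direct counts", {
  r <- confusion_metrics(c("S", "S", "S", "W", "W"),
                         c("S", "S", "W", "W", "S"))
  expect_equal(r$agreement_pct, 60)
  expect_equal(r$sensitivity_pct, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(r$specificity_pct, 50)
  expect_equal(unname(r$cells), c(2L, 1L, 1L, 1L))

  psg <- random_sw(50)
  ident <- confusion_metrics(psg, psg)
  expect_equal(ident$agreement_pct, 100)
  expect_equal(ident$sensitivity_pct, 100)
  expect_equal(ident$specificity_pct, 100)

  no_w <- confusion_metrics(rep("S", 10), random_sw(10))
  expect_true(is.na(no_w$specificity_pct))
  expect_error(confusion_metrics(rep("S", 3), rep("S", 4)), "differ")
})

test_that("confusion metrics equal a brute-force tally on random inputs", {
  set.seed(601)
  for (rep in 1:50) {
    n <- sample(5:100, 1)
    psg <- random_sw(n, 0.7); act <- random_sw(n, 0.7)
    r <- confusion_metrics(psg, act)
    ss <- 0L; sw <- 0L; ws <- 0L; ww <- 0L
    for (i in seq_len(n)) {
      if (psg[i] == "S" && act[i] == "S") ss <- ss + 1L
      if (psg[i] == "S" && act[i] == "W") sw <- sw + 1L
      if (psg[i] == "W" && act[i] == "S") ws <- ws + 1L
      if (psg[i] == "W" && act[i] == "W") ww <- ww + 1L
    }
    expect_equal(unname(r$cells), c(ss, sw, ws, ww))
    expect_equal(r$agreement_pct, 100 * (ss + ww) / n)
  }
})

test_that("label swap S<->W complements sensitivity and specificity", {
  set.seed(602)
  psg <- random_sw(200, 0.7)
  act <- random_sw(200, 0.7)
  r <- confusion_metrics(psg, act)
  swapped <- ifelse(act == "S", "W", "S")
  r2 <- confusion_metrics(psg, swapped)
  expect_equal(r2$sensitivity_pct, 100 - r$sensitivity_pct)
  expect_equal(r2$specificity_pct, 100 - r$specificity_pct)
})

test_that("per-stage agreement scores sleep stages against S and wake against W", {
  h <- hypnogram(c(rep("N3", 8), rep("R", 16), rep("W", 4)),
                 "2000-01-01T22:00:00")
  ch <- collapse_hypnogram(h)  # N3, N3, R, R, R, R, W
  act <- c("S", "S", "S", "S", "S", "W", "W")
  st <- stagewise_agreement(ch, act)
  expect_equal(st[["N3"]], 100)
  expect_equal(st[["R"]], 75)
  expect_equal(st[["W"]], 100)
  expect_true(is.na(st[["N1"]]))  # stage absent from the night

  # overall agreement is the epoch-count-weighted combination of stages
  cm <- confusion_metrics(ch$sw, act)
  counts <- c(N1 = 0, N2 = 0,
              N3 = sum(ch$substage %in% "N3"), R = sum(ch$substage %in% "R"),
              W = sum(ch$sw == "W"))
  weighted <- sum(st[names(counts)] * counts, na.rm = TRUE) / sum(counts)
  expect_equal(cm$agreement_pct, weighted)
})

test_that("ICC(2,1) matches the ANOVA decomposition oracle", {
  x <- c(10, 14, 18, 24, 30, 8)
  y <- c(12, 13, 20, 26, 28, 10)
  r <- icc_agreement(x, y)
  expect_equal(r$icc, oracle_icc2(x, y), tolerance = 1e-10)

  # identical raters with between-subject variance
  ident <- icc_agreement(x, x)
  expect_equal(ident$icc, 1)
  expect_lt(ident$p, 1e-6)

  # a constant offset is penalized by absolute agreement but not consistency
  off <- icc_agreement(x, x + 5)
  expect_lt(off$icc, 1)
  expect_equal(off$icc, oracle_icc2(x, x + 5), tolerance = 1e-10)
  expect_equal(icc_agreement(x, x + 5, type = "ICC3")$icc, 1, tolerance = 1e-9)

  expect_true(is.na(icc_agreement(rep(3, 5), rep(3, 5))$icc))
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("group t-tests match the closed-form pooled-variance formula", {
  a <- data.frame(m = c(1, 2, 3, 4))
  b <- data.frame(m = c(3, 4, 5, 6))
  r <- group_ttests(a, b)
  sp2 <- (3 * var(a$m) + 3 * var(b$m)) / 6
  t_hand <- (mean(a$m) - mean(b$m)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$t, t_hand, tolerance = 1e-10)
  expect_equal(r$df, 6)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 6), tolerance = 1e-10)

  same <- group_ttests(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  paired0 <- group_ttests(a, a, paired = TRUE)
  expect_equal(paired0$t, 0)
  expect_equal(paired0$df, 3)
})

test_that("cohort validation averages per-subject metrics and can pool epochs", {
  set.seed(603)
  cfg <- sim_config("child", tib_min = 120)
  cohort <- simulate_cohort(cfg, 5, seed = 99)
  v <- validate_cohort(cohort, pooled = TRUE)
  expect_equal(nrow(v$per_subject), 5)
  expect_true(all(c("overall_pct", "sensitivity_pct", "specificity_pct")
                  %in% v$summary$metric))
  expect_true(all(v$per_subject$n_epochs == 60))
  ag <- v$summary$mean[v$summary$metric == "overall_pct"]
  expect_gte(ag, 0); expect_lte(ag, 100)
  expect_s3_class(v$pooled, "validation_report")
  expect_equal(v$pooled$n_epochs, 300)

  feats <- subject_features(cohort, ages = c(7, 9, 11, 13, 15))
  expect_equal(nrow(feats), 5)
  expect_equal(feats$age, c(7, 9, 11, 13, 15))
  expect_true(all(is.finite(feats$se_psg_pct)))
})
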