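test_that("psg_parameters implements the four definitions", {
  # 210 epochs: two wake epochs then 208 sleep
  sw <- c("W", "W", rep("S", 208))
  p <- psg_parameters(sw)
  expect_equal(p$sl_min, 4)
  expect_equal(p$tst_min, 416)
  expect_equal(p$waso_min, 0)
  expect_equal(p$tib_min, 420)
  expect_equal(p$se_pct, 100 * 416 / 420, tolerance = 1e-9)

  all_s <- psg_parameters(rep("S", 100))
  expect_equal(all_s$sl_min, 0)
  expect_equal(all_s$waso_min, 0)
  expect_equal(all_s$se_pct, 100)

  none <- psg_parameters(rep("W", 100))
  expect_true(none$no_onset)
  expect_true(is.na(none$sl_min))
  expect_equal(none$se_pct, 0)
})

test_that("act_sleep_onset finds the first qualifying sleep run", {
  labels <- c("W", "W", "S", "S", "S", "W", "S", "S", "S", "S")
  expect_equal(act_sleep_onset(labels, 4), 6L)
  expect_equal(act_sleep_onset(labels, 1), 2L)
  expect_equal(act_sleep_onset(rep("S", 12), 10), 0L)
  expect_true(is.na(act_sleep_onset(labels, 5)))
  # strict "more than n" reading shifts the n = 3 case
  expect_equal(act_sleep_onset(labels, 3), 2L)
  expect_equal(act_sleep_onset(labels, 3, strict_gt = TRUE), 6L)
  expect_error(act_sleep_onset(labels, 11), "1..10")
})

test_that("act_waso counts only qualifying wake runs after onset", {
  # after onset: W-runs of lengths 3, 5, 7
  labels <- c("S", "S", "S", "S",
              rep("W", 3), rep("S", 2), rep("W", 5), rep("S", 2), rep("W", 7),
              "S")
  expect_equal(act_waso(labels, 0L, 5), 2 * (5 + 7))
  expect_equal(act_waso(labels, 0L, 1), 2 * (3 + 5 + 7))
  expect_equal(act_waso(rep("S", 20), 0L, 5), 0)
  expect_error(act_waso(labels, NA, 5), "undefined")
})

test_that("act_parameters satisfies the conservation identity on random series", {
  p <- act_parameters(c("W", "W", rep("S", 6), rep("W", 5), rep("S", 197)),
                      run_rule_params(4, 5))
  expect_equal(p$sl_min + p$waso_min + p$tst_min, p$tib_min)
  expect_equal(p$sl_min, 4)
  expect_equal(p$waso_min, 10)

  set.seed(501)
  for (rep in 1:100) {
    labels <- random_sw(sample(5:120, 1), p_s = runif(1, 0.3, 0.95))
    rules <- run_rule_params(sample(1:10, 1), sample(1:10, 1))
    p <- act_parameters(labels, rules)
    if (p$no_onset) {
      expect_equal(p$se_pct, 0)
    } else {
      expect_equal(p$sl_min + p$waso_min + p$tst_min, p$tib_min)
      expect_gte(p$se_pct, 0); expect_lte(p$se_pct, 100)
    }
  }
})

test_that("run detection equals brute-force enumeration for every n", {
  set.seed(502)
  for (rep in 1:60) {
    labels <- random_sw(sample(5:80, 1), p_s = runif(1, 0.4, 0.9))
    for (n in 1:10) {
      o <- oracle_onset(labels, n)
      expect_identical(act_sleep_onset(labels, n), o)
      if (!is.na(o))
        expect_identical(act_waso(labels, o, n), oracle_waso(labels, o, n))
    }
  }
})

test_that("onset is earliest at n = 1 and WASO is non-increasing in n", {
  set.seed(503)
  for (rep in 1:40) {
    labels <- random_sw(sample(10:100, 1))
    on1 <- act_sleep_onset(labels, 1)
    wprev <- Inf
    for (n in 1:10) {
      on <- act_sleep_onset(labels, n)
      if (!is.na(on) && !is.na(on1)) expect_lte(on1, on)
      if (!is.na(on1)) {
        w <- act_waso(labels, on1, n)
        expect_lte(w, wprev)
        wprev <- w
      }
    }
  }
})

test_that("the published run-rule defaults are 4 and 5 epochs", {
  rules <- run_rule_params()
  expect_equal(rules$n_sl, 4L)
  expect_equal(rules$n_waso, 5L)
  expect_error(run_rule_params(0, 5), "1..10")
  expect_error(run_rule_params(4, 11), "1..10")
})

test_that("optimization picks n = 1 under perfect concordance", {
  set.seed(504)
  # PSG latencies with real between-subject variance; ACT identical
  psg <- 2 * sample(0:30, 12, replace = TRUE)
  act_by_n <- matrix(rep(psg, 10), ncol = 10)
  res <- optimize_run_rule(psg, act_by_n)
  expect_equal(res$chosen_n, 1L)
  expect_equal(res$table$delta[1], 0)
  expect_equal(res$table$icc[1], 1)
})

test_that("optimization agrees with an exhaustive-search oracle on an injected-wake cohort", {
  set.seed(505)
  n_subj <- 16
  cohort <- lapply(seq_len(n_subj), function(i) {
    # one true wake bout of 5-9 epochs after onset, visible to both methods
    true_len <- sample(5:9, 1)
    sw <- c(rep("W", sample(1:8, 1)), rep("S", 25),
            rep("W", true_len), rep("S", 60))
    # ACT additionally carries one brief false-wake run of exactly 4 epochs
    act <- sw
    pos <- length(sw) - 20L
    act[pos:(pos + 3L)] <- "W"
    list(psg = sw, act = act)
  })
  psg_w <- vapply(cohort, function(s) psg_parameters(s$psg)$waso_min,
                  numeric(1))
  act_w <- t(vapply(cohort, function(s) {
    on <- act_sleep_onset(s$act, 4)
    vapply(1:10, function(n) act_waso(s$act, on, n), numeric(1))
  }, numeric(10)))
  res <- optimize_run_rule(psg_w, act_w)

  # oracle: recompute the per-n statistics independently and search
  feas <- c(); deltas <- c()
  for (n in 1:10) {
    delta <- mean(act_w[, n]) - mean(psg_w)
    d <- act_w[, n] - psg_w
    p <- if (sd(d) == 0) 1 else t.test(act_w[, n], psg_w, paired = TRUE)$p.value
    icc <- oracle_icc2(psg_w, act_w[, n])
    feas <- c(feas, p >= 0.05 && !is.na(icc) && icc >= 0.6)
    deltas <- c(deltas, delta)
  }
  oracle_n <- if (any(feas)) which(feas)[which.min(abs(deltas[feas]))] else NA
  expect_equal(res$chosen_n, as.integer(oracle_n))
  # false-wake runs of length 4 only drop out at n >= 5
  expect_gte(res$chosen_n, 5L)
})

test_that("two-stage cohort optimization returns run_rule_params", {
  set.seed(506)
  cohort <- lapply(1:10, function(i) {
    sw <- c(rep("W", sample(2:10, 1)), random_sw(150, 0.92))
    list(psg = sw, act = sw)
  })
  res <- optimize_sleep_rules(cohort)
  expect_s3_class(res$rules, "run_rule_params")
  expect_equal(res$sl$chosen_n, 1L)  # perfect concordance
  expect_equal(res$waso$chosen_n, 1L)
})
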