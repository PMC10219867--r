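test_that("rank-based AUC matches enumeration and handles ties and single classes", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(rep(5, 10), rep(c(0, 1), 5)), 0.5)  # all ties
  expect_equal(auc_score(c(3, 1, 2, 0), c(1, 0, 0, 1)), 0.5) # 2 wins of 4
  expect_true(is.na(auc_score(1:5, rep(1, 5))))              # undefined

  # property: equals all-pairs enumeration on random tied instances
  set.seed(30)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    scores <- sample(0:9, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels))
  }

  # invariance under strictly increasing transforms
  set.seed(31)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5)
  expect_equal(auc_score(exp(s), l), auc_score(s, l))
  expect_equal(auc_score(qlogis(plogis(s)), l), auc_score(s, l))
})

test_that("downsampling balances classes deterministically and preserves AUC in expectation", {
  set.seed(77)
  pairs <- binormal_pairs(10, 90, 1)
  bal <- downsample_balance(pairs, seed = 4)
  expect_equal(sum(bal$label == 1), 10)
  expect_equal(sum(bal$label == 0), 10)
  expect_identical(bal, downsample_balance(pairs, seed = 4))
  expect_false(identical(bal, downsample_balance(pairs, seed = 5)))
  # degenerate direction downsamples positives
  expect_warning(b2 <- downsample_balance(binormal_pairs(30, 10, 1), 1),
                 "positives")
  expect_equal(sum(b2$label == 1), 10)

  # averaging over seeded draws recovers the full-sample AUC
  set.seed(78)
  big <- binormal_pairs(50, 500, 1.2)
  full <- auc_score(big$score, big$label)
  draws <- vapply(1:200, function(s) {
    b <- downsample_balance(big, s)
    auc_score(b$score, b$label)
  }, numeric(1))
  expect_lt(abs(mean(draws) - full), 0.03)
})

test_that("bootstrap interval is degenerate under perfect separation and covers the true AUC", {
  pairs <- tibble::tibble(score = c(5, 6, 7, 1, 2, 3),
                          label = c(1, 1, 1, 0, 0, 0))
  ci <- auc_ci(pairs, B = 250, seed = 2)
  expect_equal(ci$auc, 1.0)
  expect_equal(ci$ci_lo, 1.0)
  expect_equal(ci$ci_hi, 1.0)
  expect_equal(ci$B, 250)
})

test_that("binary metrics reproduce the confusion-matrix arithmetic", {
  # TP=8, FN=2, FP=4, TN=16
  scores <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 16))
  labels <- c(rep(1, 10), rep(0, 20))
  m <- binary_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$fp, 4); expect_equal(m$tn, 16)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$f1, 8 / 11)

  perfect <- binary_metrics(c(9, 9, 1, 1), c(1, 1, 0, 0), 5)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "precision",
                                "f1")]),
               c(sensitivity = 1, specificity = 1, precision = 1, f1 = 1))

  none <- binary_metrics(c(1, 1, 1), c(1, 0, 1), 5)
  expect_true(is.na(none$precision))
  expect_equal(none$sensitivity, 0)
})

test_that("continuous metrics follow their definitions with RMSE >= MAE", {
  rows <- tibble::tibble(model_id = "A", target = "occupancy",
                         yhat = c(1, 0, 5), y_actual = c(0, 2, 2),
                         horizon = 1:3, origin_hour = 0,
                         origin = Sys.time(), hour_label = 0L)
  cm <- continuous_metrics(rows)
  expect_equal(cm$mae, 2)
  expect_equal(cm$mse, 14 / 3)
  expect_equal(cm$rmse, sqrt(14 / 3))

  # identical predictions give zero error; RMSE >= MAE on random rows
  rows$yhat <- rows$y_actual
  expect_equal(unlist(continuous_metrics(rows)[, c("mae", "mse", "rmse")]),
               c(mae = 0, mse = 0, rmse = 0))
  set.seed(11)
  rnd <- tibble::tibble(model_id = "A", target = "occupancy",
                        yhat = rnorm(200, 50, 10),
                        y_actual = rnorm(200, 50, 10))
  cm <- continuous_metrics(rnd)
  expect_gte(cm$rmse, cm$mae)
})

oracle_rows <- function(n_days = 30, seed = 21) {
  # aligned rows in which the forecast equals the realised occupancy
  ed <- simulate_ed(n_days = n_days, seed = seed)
  scheme <- derive_crowding_scheme(ed$occupancy)
  occ <- label_hours(ed$occupancy, scheme)
  origins <- occ$timestamp[occ$timestamp <= occ$timestamp[nrow(occ)] - 24 * 3600]
  rows <- tidyr::expand_grid(origin = origins, horizon = 1:24)
  idx <- match(as.numeric(rows$origin) + 3600 * rows$horizon,
               as.numeric(occ$timestamp))
  tibble::tibble(origin = rows$origin, model_id = "oracle",
                 target = "occupancy", horizon = rows$horizon,
                 yhat = occ$value[idx], y_actual = occ$value[idx],
                 hour_label = occ$crowded[idx],
                 origin_hour = lubridate::hour(rows$origin))
}

test_that("the oracle forecaster scores AUC 1 everywhere; a label-independent one scores 0.5", {
  rows <- oracle_rows()
  p <- pph(rows, B = 30, seed = 3)
  expect_true(all(p$auc == 1))
  o <- ppo(rows, B = 30, seed = 3)
  expect_true(all(o$auc[!is.na(o$auc)] == 1))
  m <- auc_matrix(rows)
  expect_true(all(m$auc[!is.na(m$auc)] == 1))

  # noise scores carry no skill: ~100 events per horizon over 120 days
  big <- oracle_rows(n_days = 120, seed = 45)
  set.seed(44)
  big$yhat <- rnorm(nrow(big))
  p <- pph(big, B = 30, seed = 3, draws = 20)
  expect_true(all(abs(p$auc - 0.5) < 0.1))
  expect_lt(abs(mean(p$auc) - 0.5), 0.04)
})

test_that("AUC matrix cells equal the AUC of their filtered subsets, with missing single-class cells", {
  rows <- oracle_rows(n_days = 20, seed = 33)
  set.seed(1); rows$yhat <- rows$y_actual + rnorm(nrow(rows), 0, 20)
  m <- auc_matrix(rows)
  # brute-force filter-then-score check on a sample of cells
  cells <- m[sample(nrow(m), 40), ]
  for (i in seq_len(nrow(cells))) {
    sub <- rows[rows$origin_hour == cells$origin_hour[i] &
                  rows$horizon == cells$horizon[i] &
                  !is.na(rows$hour_label), ]
    expect_equal(cells$auc[i], auc_brute(sub$yhat, sub$hour_label))
  }
  # a cell with no crowding events is undefined
  expect_true(all(is.na(m$auc[m$n_pos == 0])))
  expect_true(any(m$n_pos == 0))
})
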