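# BP regression (AdaBoost.R2 over rpart trees), metrics, BHS grading and the
# three evaluation protocols.

make_toy_dataset <- function(n_per_trial = 60, n_trials = 6, seed = 1,
                             locations = "POS1") {
  set.seed(seed)
  parts <- lapply(seq_along(locations), function(li) {
    n <- n_per_trial * n_trials
    x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
    sbp <- 110 + 40 * x1 + 10 * x2 + rnorm(n, 0, 1)
    dbp <- 70 + 20 * x2 + 5 * x3 + rnorm(n, 0, 1)
    feats <- data.frame(beat = seq_len(n), valid = TRUE,
                        dicrotic_absent = FALSE,
                        f1 = x1, f2 = x2, f3 = x3)
    structure(list(features = feats, sbp = sbp, dbp = dbp,
                   trial_id = rep(seq_len(n_trials), each = n_per_trial),
                   location_id = rep(locations[li], n)),
              class = "bp_dataset")
  })
  do.call(bind_bp_datasets, parts)
}

test_that("reference smoothing behaves at its edge cases", {
  x <- rnorm(50)
  expect_equal(smooth_reference_bp(x, 1), x)
  expect_equal(smooth_reference_bp(rep(7, 30), 20), rep(7, 30))
  # a unit step becomes a monotone ramp of width ~20 beats
  step <- c(rep(0, 40), rep(1, 40))
  sm <- smooth_reference_bp(step, 20)
  expect_true(all(diff(sm) >= 0))
  expect_equal(sm[1:20], rep(0, 20))
  expect_equal(sm[61:80], rep(1, 20))
  expect_gt(sum(sm > 0.01 & sm < 0.99), 15)
})

test_that("evaluation metrics match hand computation and the BHS table", {
  ref <- c(100, 110, 120, 130, 140)
  ev <- evaluate_bp(ref + 2, ref)
  expect_equal(ev$me, 2)
  expect_equal(ev$std, 0)
  expect_equal(ev$rmse, 2)
  ev0 <- evaluate_bp(ref, ref)
  expect_equal(ev0$me, 0)
  expect_equal(ev0$rmse, 0)
  # constant error series: correlation of pred vs ref still defined,
  # but constant predictions flag r as NA
  expect_true(is.na(evaluate_bp(rep(120, 5), ref)$r))
  # brute-force formulas on random pairs
  set.seed(2)
  pred <- rnorm(200, 120, 8); refr <- rnorm(200, 120, 8)
  ev2 <- evaluate_bp(pred, refr)
  e <- pred - refr
  expect_equal(ev2$me, sum(e) / 200)
  expect_equal(ev2$std, sqrt(sum((e - mean(e))^2) / 199))
  expect_equal(ev2$rmse, sqrt(sum(e^2) / 200))
  expect_equal(ev2$r, stats::cor(pred, refr))
  # rmse^2 = me^2 + std^2 (n-1)/n
  expect_equal(ev2$rmse^2, ev2$me^2 + ev2$std^2 * 199 / 200, tolerance = 1e-12)
  # BHS cumulative percentages are non-decreasing and grade the right rows
  expect_true(with(ev2$bhs, p5 <= p10 && p10 <= p15))
  errs_a <- c(rep(3, 70), rep(8, 20), rep(12, 8), rep(20, 2))
  expect_equal(evaluate_bp(120 + errs_a, rep(120, 100))$bhs$grade, "A")
  errs_c <- c(rep(4, 45), rep(9, 25), rep(14, 16), rep(25, 14))
  expect_equal(evaluate_bp(120 + errs_c, rep(120, 100))$bhs$grade, "C")
})

test_that("the boosted ensemble memorizes a clean monotone map", {
  ds <- make_toy_dataset(seed = 3)
  m <- train_bp_model(ds$features, ds$sbp, seed = 1)
  pred <- predict_bp(m, ds$features, average_window = 1)
  expect_gte(stats::cor(pred, ds$sbp), 0.99)
  # deterministic under a fixed seed
  m2 <- train_bp_model(ds$features, ds$sbp, seed = 1)
  expect_identical(pred, predict_bp(m2, ds$features, average_window = 1))
  # degenerate target and insufficient data are rejected
  expect_error(train_bp_model(ds$features, rep(100, nrow(ds$features))),
               "variance")
  expect_error(train_bp_model(ds$features[1:50, ], ds$sbp[1:50]), "at least")
})

test_that("prediction averaging reduces variance without changing the mean much", {
  ds <- make_toy_dataset(seed = 4)
  m <- train_bp_model(ds$features, ds$sbp, seed = 1)
  raw <- predict_bp(m, ds$features, average_window = 1)
  sm <- predict_bp(m, ds$features, average_window = 20)
  expect_lt(stats::sd(diff(sm)), stats::sd(diff(raw)))
  expect_lt(abs(mean(sm) - mean(raw)), 0.5)
  # constant features give constant output
  cf <- ds$features[rep(1, 120), ]
  expect_equal(diff(range(predict_bp(m, cf, average_window = 1))), 0)
})

test_that("protocol splits partition the data without leakage", {
  ds <- make_toy_dataset(n_per_trial = 61, seed = 5)  # 366 beats, not divisible
  sp <- protocol_splits(ds, "kfold20")
  expect_length(sp, 20)
  tests <- lapply(sp, `[[`, "test")
  # exact partition of POS1 beats
  expect_setequal(unlist(tests), seq_along(ds$sbp))
  expect_equal(sum(lengths(tests)), length(ds$sbp))
  # contiguous blocks, sizes differ by at most one
  expect_lte(diff(range(lengths(tests))), 1)
  for (s in sp) {
    expect_true(all(diff(sort(s$test)) == 1))
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(ds$sbp))
  }
  # leave-one-trial: one split per trial
  sp_t <- protocol_splits(ds, "leave_one_trial")
  expect_length(sp_t, 6)
  expect_setequal(unlist(lapply(sp_t, `[[`, "test")), seq_along(ds$sbp))
})

test_that("protocols emit the expected report sets", {
  ds <- make_toy_dataset(n_per_trial = 40, n_trials = 6,
                         locations = c("POS1", "POS2", "POS3", "ReAttach"),
                         seed = 6)
  rep_t <- run_protocol(ds, "leave_one_trial", n_estimators = 4, seed = 1)
  expect_length(rep_t$reports, 6)
  expect_true(all(vapply(rep_t$reports, function(r)
    inherits(r$sbp, "bp_eval") && inherits(r$dbp, "bp_eval"), logical(1))))
  rep_l <- run_protocol(ds, "cross_location", n_estimators = 4, seed = 1,
                        min_train = 50)
  expect_setequal(names(rep_l$reports), c("POS1", "POS2", "POS3", "ReAttach"))
  # the held-out POS1 beats are trials 5-6 only
  sp <- protocol_splits(ds, "cross_location")
  pos1 <- which(ds$location_id == "POS1")
  expect_setequal(sp$POS1$test, pos1[ds$trial_id[pos1] %in% 5:6])
  expect_error(run_protocol(ds, "cross_location", n_train_trials = 6),
               "trials")
})

test_that("per-location models are labelled AE1 through AE4", {
  expect_equal(ae_model_label("POS1"), "AE1")
  expect_equal(ae_model_label("POS2"), "AE2")
  expect_equal(ae_model_label("POS3"), "AE3")
  expect_equal(ae_model_label("ReAttach"), "AE4")
  expect_error(ae_model_label("POS9"), "unknown")
})
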