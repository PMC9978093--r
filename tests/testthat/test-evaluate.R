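test_that("confusion metrics evaluate the exact rational formulas", {
  m <- confusion_metrics(list(TP = 11, FN = 4, TN = 11, FP = 5))
  expect_equal(m$accuracy, 22 / 31)
  expect_equal(m$sensitivity, 11 / 15)
  expect_equal(m$specificity, 11 / 16)
  all_right <- confusion_metrics(list(TP = 10, FN = 0, TN = 12, FP = 0))
  expect_equal(c(all_right$accuracy, all_right$sensitivity, all_right$specificity),
               c(1, 1, 1))
  m2 <- confusion_metrics(list(TP = 4, FN = 11, TN = 9, FP = 7))
  expect_equal(m2$accuracy, 13 / 31)
  # zero denominators flagged as NA
  expect_true(is.na(confusion_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1))$sensitivity))
})

test_that("confusion counts treat failed folds as guaranteed errors", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, NA, 0, NA))
  expect_equal(cc, list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(with(cc, TP + TN + FP + FN), 4L)
})

test_that("exact binomial test doubles the smaller tail and matches pmf summation", {
  expect_equal(binomial_vs_chance(10, 20, 0.5), 1)
  expect_equal(binomial_vs_chance(5, 5, 0.5), 2 * (1 / 32))
  expect_lt(binomial_vs_chance(22, 31, 0.5), 0.05)
  # against direct probability-mass summation for n <= 50
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(3:50, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.2, 0.8)
    lower <- sum(dbinom(0:k, n, p0))
    upper <- sum(dbinom(k:n, n, p0))
    expect_equal(binomial_vs_chance(k, n, p0), min(1, 2 * min(lower, upper)),
                 tolerance = 1e-12)
    expect_equal(binomial_vs_chance(k, n, p0, "greater"), upper,
                 tolerance = 1e-12)
  }
  expect_error(binomial_vs_chance(5, 4, 0.5), "invalid")
  expect_error(binomial_vs_chance(2, 4, 0), "invalid")
})

test_that("nested LOPO predicts every participant without leaking the held-out one", {
  co <- small_cohort(n_per_group = 4, groups = c("control", "Sz"), seed = 31)
  res <- nested_lopo(co, "baseline", cfg = fast_cfg(seed = 2))
  expect_equal(nrow(res$predictions), 8)
  expect_setequal(res$predictions$participant_id,
                  unique(co$manifest$participant_id))
  # audit trail: no fold's training set contains its held-out participant,
  # and every fold trains on the same balanced pool size (3 + 3 here)
  grp_of <- co$manifest$group[match(unique(co$manifest$participant_id),
                                    co$manifest$participant_id)]
  names(grp_of) <- unique(co$manifest$participant_id)
  for (p in names(res$fold_train_participants)) {
    pool <- res$fold_train_participants[[p]]
    expect_false(p %in% pool)
    expect_equal(as.integer(table(grp_of[pool])), c(3L, 3L))
  }
  # control vs Sz under default profiles is strongly separable
  rep_f <- metrics_report(res, "forest")
  rep_h <- metrics_report(res, "hard")
  expect_gte(rep_h$accuracy, 0.75)
  expect_gte(rep_f$accuracy, 0.75)
  expect_equal(rep_f$counts$TP + rep_f$counts$TN + rep_f$counts$FP +
                 rep_f$counts$FN, 8)
  # metrics agree with a brute-force recount of the prediction table
  pr <- res$predictions
  expect_equal(rep_h$accuracy, mean(pr$pred_hard == pr$y_true))
})

test_that("a fold whose training pool loses a class is recorded as failed", {
  co <- small_cohort(n_per_group = 1, groups = c("control", "Sz"), seed = 32)
  co2 <- small_cohort(n_per_group = 2, groups = c("control", "Sz"), seed = 32)
  # 2 controls + 1 Sz: holding out the lone Sz leaves a single-class pool
  sz_rows <- co$manifest[co$manifest$group == "Sz", ]
  sz_trials <- co$trials[sz_rows$trial_id]
  sz_rows$participant_id <- "P999"
  sz_rows$trial_id <- sub("^P[0-9]+", "P999", sz_rows$trial_id)
  names(sz_trials) <- sz_rows$trial_id
  manifest <- rbind(co2$manifest[co2$manifest$group == "control", ], sz_rows)
  trials <- c(co2$trials[co2$manifest$trial_id[co2$manifest$group == "control"]],
              sz_trials)
  mixed <- structure(list(manifest = manifest, trials = trials,
                          population = "adult", config = co$config),
                     class = "gaze_cohort")
  res <- nested_lopo(mixed, "baseline", cfg = fast_cfg(seed = 3))
  sz_row <- res$predictions[res$predictions$group == "Sz", ]
  expect_true(sz_row$fold_failed)
  expect_true(is.na(sz_row$pred_hard))
  # failed folds count as errors, so totals still reconcile
  cc <- confusion_counts(res$predictions$y_true, res$predictions$pred_hard)
  expect_equal(with(cc, TP + TN + FP + FN), 3)
})

test_that("pairwise-only evaluation is enforced", {
  co <- simulate_cohort(cohort_config(
    lapply(default_profiles("adult"), function(p) list(profile = p, n = 1)),
    "adult", seed = 33))
  expect_error(nested_lopo(co, "baseline"), "pairwise")
  expect_error(nested_lopo(subset_cohort(co, "control"), "baseline"))
})
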