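test_that("brain-age gap follows the true-minus-predicted sign convention", {
  expect_equal(compute_bag(10, 8), 2)     # underestimated: positive
  expect_equal(compute_bag(12, 15), -3)   # overestimated: negative
  expect_equal(compute_bag(9, 9), 0)
  expect_error(compute_bag(NA, 1), "finite")
  # bag + predicted = true, exactly, per row.
  set.seed(1)
  truth <- runif(50, 6, 21)
  pred <- truth + rnorm(50)
  expect_identical(compute_bag(truth, pred) + pred, truth)
})

test_that("age bins are left-closed right-open with an inclusive top", {
  expect_identical(assign_age_bin(c(6, 6.5, 8, 9.5, 11, 13, 15, 21)),
                   c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 6L))
  expect_error(assign_age_bin(5.9), "\\[6, 21\\]")
  expect_error(assign_age_bin(21.1), "\\[6, 21\\]")
})

test_that("BAG tables join predictions to covariates with exact arithmetic", {
  cfg <- sim_config(n_participants = 45, n_roi = 10,
                    frac_developmental_edges = 0.3,
                    age_slope_z_per_year = 0.05, edge_noise_sd = 0.05,
                    seed = 30)
  parc <- generate_parcellation(10, 7, seed = 30)
  coh <- simulate_cohort(cfg)
  fc <- simulate_fc(coh, parc, cfg)
  ens <- run_ensemble(coh, fc, n_permutations = 30, base_seed = 31)
  bt <- bag_table(list(whole = ens, reduced = ens), coh)
  expect_identical(bt$bag + bt$pred_age, bt$age)
  expect_identical(bt$age_bin, assign_age_bin(bt$age))
  expect_setequal(levels(bt$model), c("whole", "reduced"))
})

test_that("identical bags across models give a null Model effect", {
  bt <- simulate_bag_table(n_per_group = 30, seed = 40)
  # Force the three models identical per subject.
  wide <- bt[bt$model == "m1", ]
  bt_id <- dplyr::bind_rows(lapply(c("m1", "m2", "m3"), function(m) {
    out <- wide
    out$model <- m
    out
  }))
  bt_id$model <- factor(bt_id$model, levels = c("m1", "m2", "m3"))
  res <- rm_ancova(bt_id)
  eff <- tidy(res)
  expect_equal(eff$F[eff$effect == "Model"], 0)
  expect_equal(eff$p_value[eff$effect == "Model"], 1)
})

test_that("the RM-ANCOVA detects planted group offsets and reports sane effect structure", {
  hits <- 0L
  for (s in 1:20) {
    bt <- simulate_bag_table(n_per_group = 100,
                             offsets = c(PR = 0.8, TR = 0, ER = -0.8),
                             noise_sd = 1, seed = 500 + s)
    res <- rm_ancova(bt)
    eff <- tidy(res)
    if (eff$p_value[eff$effect == "Group"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
  # Structure: all headline effects present, valid ranges.
  bt <- simulate_bag_table(n_per_group = 50, seed = 41)
  eff <- tidy(rm_ancova(bt, covariates = c("gender", "ses", "piq", "handedness")))
  expect_true(all(c("Group", "Model", "Group:Model", "Group:Age") %in%
                    gsub("Model:Group", "Group:Model", eff$effect) |
                    c("Group", "Model", "Model:Group", "Group:Age") %in% eff$effect))
  expect_true(all(eff$F >= 0))
  expect_true(all(eff$p_value > 0 & eff$p_value <= 1))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
})

test_that("listwise deletion drops incomplete rows and errors on emptied groups", {
  bt <- simulate_bag_table(n_per_group = 30, seed = 42)
  bt$ses[bt$id %in% sprintf("sub-%04d", 1:5)] <- NA
  res <- rm_ancova(bt, covariates = "ses")
  expect_identical(glance(res)$n_dropped, 5L)
  expect_identical(glance(res)$n, 85L)
  bt$ses[bt$group == "PR"] <- NA
  expect_error(rm_ancova(bt, covariates = "ses"), "PR")
})

test_that("pairwise post-hocs apply Bonferroni arithmetic and detect planted differences", {
  bt <- simulate_bag_table(n_per_group = 30, seed = 43)
  d1 <- bt[bt$model == "m1", ]
  ph <- posthoc_pairwise(d1)
  expect_identical(nrow(ph), 3L)
  # Bonferroni: reported p is 3x the raw Welch p, capped at 1.
  raw <- stats::t.test(d1$bag[d1$group == "PR"], d1$bag[d1$group == "TR"])$p.value
  expect_equal(ph$p_value[ph$level_a == "PR" & ph$level_b == "TR"],
               min(1, 3 * raw))
  # Identical groups: degenerate d = 0, p = 1.
  same <- tibble::tibble(group = rep(c("a", "b"), each = 5), bag = rep(1, 10))
  ph0 <- posthoc_pairwise(same)
  expect_equal(ph0$cohens_d, 0)
  expect_equal(ph0$p_value, 1)
  # Planted ER/TR gap of d ~ 1 at n = 40/group is usually detected.
  found <- 0L
  for (s in 1:10) {
    bt2 <- simulate_bag_table(n_per_group = 40,
                              offsets = c(PR = 0, TR = 0, ER = -1.1),
                              noise_sd = 1, n_models = 1, seed = 600 + s)
    ph2 <- posthoc_pairwise(bt2)
    if (ph2$p_value[ph2$level_a == "TR" & ph2$level_b == "ER"] < 0.05) {
      found <- found + 1L
    }
  }
  expect_gte(found, 7L)
})

test_that("reading-skill regression recovers planted TOWRE effects with scale-free betas", {
  set.seed(44)
  bt <- simulate_bag_table(n_per_group = 100, n_models = 1, seed = 44)
  bt$bag <- 0.05 * bt$towre_index + rnorm(nrow(bt), 0, 0.8)
  res <- towre_regression(bt)
  tw <- res[res$term == "towre_index" & res$scope == "overall", ]
  expect_gt(tw$beta, 0)
  expect_lt(tw$p_value, 0.001)
  inter <- res[res$term == "age:towre_index", ]
  expect_gt(inter$p_value, 0.01)
  # Standardized beta invariant under linear rescaling of the predictor.
  bt2 <- bt
  bt2$towre_index <- bt2$towre_index * 10 + 3
  res2 <- towre_regression(bt2)
  expect_equal(res2$beta[res2$term == "towre_index"], tw$beta,
               tolerance = 1e-10)
  # Calibration: independent TOWRE stays non-significant at the nominal rate.
  sig <- 0L
  for (s in 1:10) {
    btn <- simulate_bag_table(n_per_group = 60, n_models = 1, seed = 700 + s)
    rn <- towre_regression(btn)
    if (rn$p_value[rn$term == "towre_index" & rn$scope == "overall"] < 0.05) {
      sig <- sig + 1L
    }
  }
  expect_lte(sig, 3L)
})

test_that("per-bin follow-ups run when the TOWRE-by-age interaction is present", {
  set.seed(45)
  bt <- simulate_bag_table(n_per_group = 150, n_models = 1, seed = 45)
  tw_z <- scale(bt$towre_index)[, 1]
  age_z <- scale(bt$age)[, 1]
  bt$bag <- 0.5 * tw_z - 0.6 * tw_z * age_z + rnorm(nrow(bt), 0, 0.5)
  res <- towre_regression(bt)
  expect_true(any(grepl("^bin ", res$scope)))
  bins <- res[grepl("^bin ", res$scope) & res$term == "towre_index", ]
  # The planted moderation: TOWRE effect declines across bins.
  expect_gt(bins$beta[1], bins$beta[nrow(bins)])
})

test_that("BAG correlates positively with true age when predictions compress the age range", {
  set.seed(46)
  age <- runif(300, 6, 21)
  pred <- mean(age) + 0.5 * (age - mean(age)) + rnorm(300, 0, 1)
  bag <- compute_bag(age, pred)
  expect_gt(cor(bag, age), 0.3)
})
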