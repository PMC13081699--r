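# Minimal hand-built model object for closed-form back-projection checks.
fake_model <- function(rotation, weights, mean = rep(0, nrow(rotation)),
                       intercept = 0) {
  structure(
    list(pca_mean = mean, rotation = rotation,
         explained_variance_ratio = rep(1 / ncol(rotation), ncol(rotation)),
         n_components = ncol(rotation), svr_weights = weights,
         svr_intercept = intercept, variance_retained = 0.95,
         epsilon = 0.1, cost = 1),
    class = "fcage_perm_model"
  )
}

test_that("back-projection reduces to closed forms for simple component matrices", {
  expect_equal(backproject(fake_model(diag(3), c(1, -2, 0.5))),
               c(1, -2, 0.5))
  w <- 0.8
  expect_equal(backproject(fake_model(matrix(1 / sqrt(2), 2, 1), w)),
               c(w / sqrt(2), w / sqrt(2)))
})

test_that("back-projected weights reproduce direct predictions exactly", {
  set.seed(20)
  for (i in 1:5) {
    x_train <- matrix(rnorm(40 * 12), 40)
    age <- rnorm(40, 11, 3)
    model <- fit_permutation(x_train, age)
    x_new <- matrix(rnorm(10 * 12), 10)
    direct <- predict_raw(model, x_new)
    w_edge <- backproject(model)
    via_edges <- drop(sweep(x_new, 2, model$pca_mean) %*% w_edge) +
      model$svr_intercept
    expect_equal(via_edges, direct, tolerance = 1e-8)
  }
})

test_that("coefficient averaging is an element-wise permutation-invariant mean", {
  edges <- fcage:::edge_pairs(0:3)
  fake_ens <- function(W) {
    structure(list(edges = edges,
                   backprojection = list(w_edge = W)),
              class = "fcage_ensemble")
  }
  v <- c(1, -2, 3, 0.5, 0, -1)
  one <- average_coefficients(fake_ens(matrix(v, 1)))
  expect_equal(one$coefficient, v)
  cancel <- average_coefficients(fake_ens(rbind(v, -v)))
  expect_equal(cancel$coefficient, rep(0, 6))
  perm_order <- average_coefficients(fake_ens(rbind(v, 2 * v)))
  swapped <- average_coefficients(fake_ens(rbind(2 * v, v)))
  expect_equal(perm_order$coefficient, swapped$coefficient)
})

test_that("edge permutation nulls behave at the extremes and near nominal alpha", {
  edges <- fcage:::edge_pairs(0:49)
  # All magnitudes equal: nothing can be significant.
  flat <- tibble::tibble(edge = 1:nrow(edges), roi_i = edges$roi_i,
                         roi_j = edges$roi_j,
                         coefficient = rep(c(0.3, -0.3), length.out = nrow(edges)))
  res <- edge_significance(flat, n_perm = 200, seed = 1)
  expect_false(any(res$significant))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # One coefficient dwarfing the rest is flagged near the permutation floor.
  set.seed(2)
  m <- 1000
  spike <- tibble::tibble(coefficient = c(100, rnorm(m - 1)))
  res2 <- edge_significance(spike, n_perm = 2500, seed = 3)
  expect_identical(res2$rank[1], 1L)
  expect_lt(res2$p_value[1], 0.005)
  expect_true(res2$significant[1])
  # Calibration on exchangeable Gaussian coefficients.
  set.seed(4)
  gauss <- tibble::tibble(coefficient = rnorm(2000))
  res3 <- edge_significance(gauss, n_perm = 500, alpha = 0.05, seed = 5)
  expect_lt(abs(mean(res3$significant) - 0.05), 0.03)
  # Flagged sets shrink as alpha decreases.
  strict <- edge_significance(gauss, n_perm = 500, alpha = 0.01, seed = 5)
  expect_true(all(which(strict$significant) %in% which(res3$significant)))
})

test_that("ROI pooling tallies both endpoints and conserves 2k slots", {
  parc <- generate_parcellation(10, 7, seed = 6)
  sig <- tibble::tibble(roi_i = c(0, 0), roi_j = c(1, 2))
  fr <- pool_roi_frequencies(sig, parc)
  expect_identical(fr$frequency[fr$roi_id == 0], 2L)
  expect_identical(fr$frequency[fr$roi_id == 1], 1L)
  expect_identical(fr$frequency[fr$roi_id == 2], 1L)
  expect_identical(sum(fr$frequency), 2L * nrow(sig))
  # Share arithmetic: frequency over number of significant edges.
  expect_equal(fr$share[fr$roi_id == 0], 1)
  expect_error(pool_roi_frequencies(sig[0, ], parc), "No significant")
})

test_that("ROI overrepresentation nulls flag only genuine excess", {
  parc <- generate_parcellation(40, 7, seed = 7)
  # An ROI present in every significant edge: permutation-floor p.
  k <- 200
  sig <- tibble::tibble(roi_i = rep(0, k),
                        roi_j = rep(1:39, length.out = k))
  fr <- pool_roi_frequencies(sig, parc)
  rt <- roi_overrepresentation(fr, parc, n_perm = 500, seed = 8)
  expect_equal(rt$table$p_value[rt$table$roi_id == 0], 1 / 501)
  # Null draws conserve the slot total.
  expect_true(all(rowSums(rt$null_counts) == sum(fr$frequency)))
  # Frequencies at the uniform expectation: nothing flagged at 1e-4.
  fr_unif <- fr
  fr_unif$frequency <- rep(sum(fr$frequency) / nrow(fr), nrow(fr))
  rt2 <- roi_overrepresentation(fr_unif, parc, n_perm = 500, seed = 9)
  expect_false(any(rt2$table$significant))
})

test_that("network representation compares shares against extent-matched nulls", {
  # Single-network parcellation: observed share 1 equals every null draw.
  parc1 <- tibble::tibble(roi_id = 0:9, name = paste0("r", 0:9),
                          network = factor("Default"),
                          hemisphere = factor(rep(c("L", "R"), 5)),
                          x = 1, y = 1, z = 1)
  sig <- tibble::tibble(roi_i = c(0, 2), roi_j = c(1, 3))
  fr1 <- pool_roi_frequencies(sig, parc1)
  nr1 <- network_representation(fr1, parc1, n_perm = 200, seed = 10)
  expect_equal(nr1$observed_share, 1)
  expect_equal(nr1$p_value, 1)
  # Planted enrichment of one network is flagged as over-represented.
  parc <- generate_parcellation(60, 7, seed = 11)
  def_ids <- parc$roi_id[parc$network == "Default"]
  sig2 <- tibble::tibble(
    roi_i = rep(def_ids[1], 100),
    roi_j = rep(def_ids[-1], length.out = 100)
  )
  fr2 <- pool_roi_frequencies(sig2, parc)
  nr2 <- network_representation(fr2, parc, n_perm = 500, seed = 12)
  def_row <- nr2[nr2$network == "Default", ]
  expect_identical(unname(def_row$direction), "over")
  expect_lt(def_row$p_value, 0.01)
  # Shares sum to one, observed and null.
  expect_equal(sum(nr2$observed_share), 1)
  expect_equal(sum(nr2$null_mean_share), 1)
})

test_that("edge-class census matches brute-force counts on a toy parcellation", {
  parc <- tibble::tibble(
    roi_id = 0:3, name = paste0("r", 0:3),
    network = factor(c("Default", "Default", "Cont", "Cont")),
    hemisphere = factor(c("L", "R", "L", "R"), levels = c("L", "R")),
    x = c(-1, 1, -1, 1), y = 0, z = 0
  )
  all_edges <- fcage:::edge_pairs(0:3)       # 6 edges
  sig <- all_edges[c(1, 6), ]                # (0,1) within/inter, (2,3) within/inter
  cen <- summarize_edge_classes(sig, all_edges, parc)
  net <- cen[cen$dimension == "network", ]
  expect_identical(net$n_significant[net$class == "within"], 2L)
  expect_identical(net$n_all[net$class == "within"], 2L)
  expect_identical(net$n_all[net$class == "between"], 4L)
  expect_equal(net$share_ratio[net$class == "within"], (2 / 2) / (2 / 6))
  # Significant set = all edges: all ratios exactly one.
  full <- summarize_edge_classes(all_edges, all_edges, parc)
  expect_true(all(abs(full$share_ratio - 1) < 1e-12))
})

test_that("the high-magnitude report filter applies the mean + k*SD rule", {
  coefs <- tibble::tibble(coefficient = c(rep(0.1, 50), 5))
  top <- top_coefficient_edges(coefs, sd_threshold = 2.5)
  expect_identical(nrow(top), 1L)
  expect_equal(top$coefficient, 5)
})
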