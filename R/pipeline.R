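#' Stratified 2:1 train-test split
#'
#' Splits the cohort into training and held-out test sets separately
#' within each reading group, so groups are represented proportionally in
#' both: per group, ids are shuffled and the first `floor(n_g / 3)` go to
#' test, the rest to train. With group sizes 211/338/193 this yields the
#' 496-train / 246-test split.
#'
#' @param cohort Cohort tibble with `id` and `group` columns.
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `test` (character id vectors), `seed`.
#' @export
stratified_split <- function(cohort, seed) {
  stopifnot(all(c("id", "group") %in% names(cohort)))
  set.seed(as.integer(seed))
  train <- character(0)
  test <- character(0)
  for (g in levels(factor(cohort$group))) {
    ids <- cohort$id[cohort$group == g]
    if (length(ids) == 0L) next
    if (length(ids) < 3L) {
      warn(sprintf("Group %s has fewer than 3 members; none held out.", g))
    }
    ids <- ids[sample.int(length(ids))]
    n_test <- length(ids) %/% 3L
    test <- c(test, ids[seq_len(n_test)])
    train <- c(train, ids[setdiff(seq_along(ids), seq_len(n_test))])
  }
  list(train = train, test = test, seed = as.integer(seed))
}

#' Fit one ensemble member: PCA then linear epsilon-SVR
#'
#' Fits PCA on the training features only, keeps the minimal number of
#' leading components whose cumulative explained variance reaches
#' `variance_retained`, and fits a linear epsilon-insensitive
#' support-vector regression of age on the retained component scores.
#' Reading ability never enters fitting.
#'
#' @param x Training feature matrix (participants x edges), Fisher-z.
#' @param age Training ages in years.
#' @param variance_retained Cumulative explained-variance threshold
#'   (default 0.95).
#' @param epsilon SVR insensitivity tube in years (default 0.1).
#' @param cost SVR regularization constant C (default 1).
#' @return An object of class `fcage_perm_model`: `pca_mean`, `rotation`
#'   (edges x components), `explained_variance_ratio`, `n_components`,
#'   `svr_weights`, `svr_intercept`.
#' @export
fit_permutation <- function(x, age, variance_retained = 0.95,
                            epsilon = 0.1, cost = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("Need at least 2 training participants.")
  if (any(!is.finite(x))) abort("Features must be finite.")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  total <- sum(ev)
  if (total <= 1e-12) abort("Degenerate features: no variance in training data.")
  evr <- ev / total
  k <- which(cumsum(evr) >= variance_retained - 1e-12)[1]
  rotation <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  fit <- e1071::svm(x = scores, y = age, type = "eps-regression",
                    kernel = "linear", epsilon = epsilon, cost = cost,
                    scale = FALSE)
  structure(
    list(
      pca_mean = pr$center,
      rotation = rotation,
      explained_variance_ratio = evr,
      n_components = k,
      svr_weights = drop(t(fit$coefs) %*% fit$SV),
      svr_intercept = -fit$rho,
      variance_retained = variance_retained,
      epsilon = epsilon,
      cost = cost
    ),
    class = "fcage_perm_model"
  )
}

#' Raw age predictions from a fitted ensemble member
#'
#' `raw = svr_weights . (rotation' (x - pca_mean)) + svr_intercept`.
#'
#' @param model An `fcage_perm_model`.
#' @param x Feature matrix with the training edge order.
#' @return Numeric vector of raw (unrescaled) predicted ages.
#' @export
predict_raw <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$pca_mean)) {
    abort(sprintf("Feature dimension %d does not match the model's %d.",
                  ncol(x), length(model$pca_mean)))
  }
  scores <- sweep(x, 2, model$pca_mean) %*% model$rotation
  drop(scores %*% model$svr_weights) + model$svr_intercept
}

#' Rescale raw predictions to the sample's age scale
#'
#' Converts raw predictions to z-scores (their own mean and SD),
#' multiplies by the sample's age SD and adds the sample's mean age, so
#' error metrics are not inflated by the regression-to-the-mean shrinkage
#' of raw SVR output while relative predictions are preserved. If the raw
#' predictions are constant, all outputs equal the mean age.
#'
#' @param raw Numeric vector of raw predictions (length >= 2).
#' @param age_mean,age_sd Sample age mean and SD (years).
#' @return Rescaled predictions in years.
#' @examples
#' rescale_predictions(c(0, 1, 2), age_mean = 10, age_sd = 3)
#' @export
rescale_predictions <- function(raw, age_mean, age_sd) {
  stopifnot(length(raw) >= 2)
  s <- sd(raw)
  if (s == 0) return(rep(age_mean, length(raw)))
  (raw - mean(raw)) / s * age_sd + age_mean
}

# Stratified k-fold assignment within the training set: per reading
# group, shuffled then dealt cyclically across folds.
make_folds <- function(groups, k) {
  folds <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

cv_mae_one <- function(scores, age, groups, k_folds, epsilon, cost) {
  k <- min(k_folds, nrow(scores))
  folds <- make_folds(groups, k)
  fold_maes <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- e1071::svm(x = scores[tr, , drop = FALSE], y = age[tr],
                      type = "eps-regression", kernel = "linear",
                      epsilon = epsilon, cost = cost, scale = FALSE)
    mae(age[!tr], predict(fit, scores[!tr, , drop = FALSE]))
  }, numeric(1))
  fold_maes
}

#' Run the permutation ensemble
#'
#' The full brain-age procedure: for each of `n_permutations`
#' permutations, a fresh stratified 2:1 split is drawn, PCA (95% variance)
#' is fit on the training set only, 5-fold cross-validation (stratified by
#' reading group) is run on the PCA-transformed training features, a final
#' linear epsilon-SVR is fit on the whole training set, and raw
#' predictions are rescaled to the sample age scale. Predictions are then
#' averaged within participant over the permutations in which that
#' participant was held out, giving subject-level predicted age and MAE;
#' ensemble stability is the coefficient of variation (CoV, %) of the
#' per-permutation test MAEs.
#'
#' @param cohort Cohort tibble (`id`, `age`, `group`).
#' @param fc An [fc_set()] covering every cohort id.
#' @param roi_set Optional ROI ids defining a reduced model; `NULL` uses
#'   every ROI (whole-brain model).
#' @param n_permutations Number of split permutations (study scale: 1000).
#' @param k_folds CV folds within the training set (default 5).
#' @param variance_retained,epsilon,cost Passed to [fit_permutation()].
#' @param base_seed Integer; spawns one child seed per permutation so any
#'   single permutation is independently reproducible.
#' @param rescale_scope `"split"` standardizes each permutation's
#'   predictions over the full train+test prediction set; `"test"` over
#'   the held-out set only.
#' @param keep_backprojections Store per-permutation edge-space weights
#'   (needed by the feature-importance stage).
#' @param label Model label carried through results (e.g. `"400-ROI"`).
#' @return An object of class `fcage_ensemble`; see [tidy()] and
#'   [glance()] methods.
#' @export
run_ensemble <- function(cohort, fc, roi_set = NULL,
                         n_permutations = 1000, k_folds = 5,
                         variance_retained = 0.95, epsilon = 0.1, cost = 1,
                         base_seed = 1,
                         rescale_scope = c("split", "test"),
                         keep_backprojections = TRUE,
                         label = NULL) {
  rescale_scope <- match.arg(rescale_scope)
  stopifnot(inherits(fc, "fcage_fc"))
  if (!setequal(cohort$id, fc$participant_id)) {
    abort("`cohort$id` and FC participant ids must match.")
  }
  if (!is.null(roi_set)) fc <- subset_edges(fc, roi_set)
  x_all <- fc$z[match(cohort$id, fc$participant_id), , drop = FALSE]
  m <- ncol(x_all)
  n <- nrow(cohort)
  if (is.null(label)) label <- sprintf("%d-ROI", length(fc$roi_ids))

  age_mean <- mean(cohort$age)
  age_sd <- sd(cohort$age)
  seeds <- spawn_seeds(base_seed, n_permutations)

  perm_rows <- vector("list", n_permutations)
  bp_w <- if (keep_backprojections) matrix(NA_real_, n_permutations, m) else NULL
  bp_mean <- if (keep_backprojections) matrix(NA_real_, n_permutations, m) else NULL
  bp_b <- if (keep_backprojections) numeric(n_permutations) else NULL
  sum_pred <- numeric(n)
  sum_abs_err <- numeric(n)
  n_test <- integer(n)

  for (p in seq_len(n_permutations)) {
    res <- tryCatch({
      split <- stratified_split(cohort, seeds[p])
      tr_idx <- match(split$train, cohort$id)
      te_idx <- match(split$test, cohort$id)
      model <- fit_permutation(x_all[tr_idx, , drop = FALSE],
                               cohort$age[tr_idx],
                               variance_retained, epsilon, cost)
      scores_tr <- sweep(x_all[tr_idx, , drop = FALSE], 2, model$pca_mean) %*%
        model$rotation
      fold_maes <- cv_mae_one(scores_tr, cohort$age[tr_idx],
                              as.character(cohort$group[tr_idx]),
                              k_folds, epsilon, cost)
      if (rescale_scope == "split") {
        raw <- predict_raw(model, x_all)
        resc <- rescale_predictions(raw, age_mean, age_sd)
        resc_test <- resc[te_idx]
      } else {
        raw <- predict_raw(model, x_all[te_idx, , drop = FALSE])
        resc_test <- rescale_predictions(raw, age_mean, age_sd)
      }
      list(model = model, te_idx = te_idx, fold_maes = fold_maes,
           resc_test = resc_test)
    }, error = function(e) {
      abort(sprintf("Permutation %d failed: %s", p, conditionMessage(e)))
    })

    te_idx <- res$te_idx
    abs_err <- abs(cohort$age[te_idx] - res$resc_test)
    sum_pred[te_idx] <- sum_pred[te_idx] + res$resc_test
    sum_abs_err[te_idx] <- sum_abs_err[te_idx] + abs_err
    n_test[te_idx] <- n_test[te_idx] + 1L

    if (keep_backprojections) {
      bp_w[p, ] <- backproject(res$model)
      bp_mean[p, ] <- res$model$pca_mean
      bp_b[p] <- res$model$svr_intercept
    }
    perm_rows[[p]] <- tibble::tibble(
      permutation = p, seed = seeds[p],
      n_components = res$model$n_components,
      cv_mae = mean(res$fold_maes),
      test_mae = mean(abs_err)
    )
  }

  perms <- dplyr::bind_rows(perm_rows)
  subjects <- tibble::tibble(
    id = cohort$id, age = cohort$age, group = cohort$group,
    n_test = n_test,
    pred_age = ifelse(n_test > 0, sum_pred / n_test, NA_real_),
    subject_mae = ifelse(n_test > 0, sum_abs_err / n_test, NA_real_)
  )
  test_maes <- perms$test_mae
  structure(
    list(
      label = label,
      perms = perms,
      subjects = subjects,
      summary = list(
        label = label,
        n_permutations = n_permutations,
        n_edges = m,
        n_roi = length(fc$roi_ids),
        cv_mae = mean(perms$cv_mae),
        test_mae = mean(test_maes),
        cov_pct = 100 * sd(test_maes) / mean(test_maes),
        n_components_mean = mean(perms$n_components)
      ),
      backprojection = if (keep_backprojections) {
        list(w_edge = bp_w, pca_mean = bp_mean, intercept = bp_b)
      },
      edges = fc$edges,
      roi_ids = fc$roi_ids,
      age_mean = age_mean,
      age_sd = age_sd,
      base_seed = base_seed,
      params = list(variance_retained = variance_retained, epsilon = epsilon,
                    cost = cost, k_folds = k_folds,
                    rescale_scope = rescale_scope)
    ),
    class = "fcage_ensemble"
  )
}

#' @export
print.fcage_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fcage_ensemble> %s: %d permutations over %d edges (%d ROIs)\n  CV MAE %.2f yr | test MAE %.2f yr | CoV %.2f%% | mean components %.0f\n",
    s$label, s$n_permutations, s$n_edges, s$n_roi,
    s$cv_mae, s$test_mae, s$cov_pct, s$n_components_mean))
  invisible(x)
}

#' Permutation-null significance of cross-validated accuracy
#'
#' Tests whether the ensemble's cross-validated MAE beats chance: each
#' null iteration draws a fresh stratified split, shuffles the training
#' age labels (preserving their multiset), repeats the PCA + 5-fold-CV
#' procedure, and records the null CV MAE. The p-value uses the add-one
#' estimator `p = (1 + #{null <= observed}) / (1 + n_null)`.
#'
#' @param observed Observed CV MAE, or an `fcage_ensemble` (its summary
#'   CV MAE is used).
#' @param cohort,fc,roi_set As in [run_ensemble()].
#' @param n_null Number of null iterations (study scale: 1000).
#' @param k_folds,variance_retained,epsilon,cost As in [run_ensemble()].
#' @param base_seed Seed spawning one child seed per null iteration.
#' @return List with `p`, `observed_cv_mae`, `null_cv_mae` (vector).
#' @export
cv_significance <- function(observed, cohort, fc, roi_set = NULL,
                            n_null = 1000, k_folds = 5,
                            variance_retained = 0.95, epsilon = 0.1,
                            cost = 1, base_seed = 1) {
  if (inherits(observed, "fcage_ensemble")) observed <- observed$summary$cv_mae
  stopifnot(is.numeric(observed), length(observed) == 1L)
  stopifnot(inherits(fc, "fcage_fc"))
  if (!is.null(roi_set)) fc <- subset_edges(fc, roi_set)
  x_all <- fc$z[match(cohort$id, fc$participant_id), , drop = FALSE]
  seeds <- spawn_seeds(base_seed, n_null)

  null_mae <- vapply(seq_len(n_null), function(j) {
    split <- stratified_split(cohort, seeds[j])
    tr_idx <- match(split$train, cohort$id)
    x_tr <- x_all[tr_idx, , drop = FALSE]
    age_tr <- sample(cohort$age[tr_idx])   # label shuffle
    model <- fit_permutation(x_tr, age_tr, variance_retained, epsilon, cost)
    scores <- sweep(x_tr, 2, model$pca_mean) %*% model$rotation
    mean(cv_mae_one(scores, age_tr, as.character(cohort$group[tr_idx]),
                    k_folds, epsilon, cost))
  }, numeric(1))

  list(
    p = (1 + sum(null_mae <= observed)) / (1 + n_null),
    observed_cv_mae = observed,
    null_cv_mae = null_mae
  )
}

#' Pairwise model comparison of subject-level MAE
#'
#' Two-sided Wilcoxon signed-rank test on paired subject-level MAEs from
#' two models (chosen over a paired t-test because subject-level error
#' distributions are typically non-normal), with Cohen's d of the paired
#' differences as effect size. If every difference is zero the comparison
#' is degenerate and `p = 1`, `d = 0` are reported.
#'
#' @param mae_a,mae_b Paired numeric vectors (same participants, same
#'   order).
#' @return One-row tibble: `n`, `statistic` (W), `p_value`, `cohens_d`.
#' @export
compare_models <- function(mae_a, mae_b) {
  if (length(mae_a) != length(mae_b)) abort("Inputs must be paired (equal length).")
  d <- mae_a - mae_b
  if (all(d == 0)) {
    return(tibble::tibble(n = length(d), statistic = NA_real_,
                          p_value = 1, cohens_d = 0))
  }
  wt <- suppressWarnings(wilcox.test(mae_a, mae_b, paired = TRUE,
                                     exact = FALSE))
  tibble::tibble(
    n = length(d),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    cohens_d = mean(d) / sd(d)
  )
}
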