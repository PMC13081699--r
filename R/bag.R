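#' Brain-age gap
#'
#' `BAG = true age - predicted age`, in years. Positive values mean the
#' model reads the brain as younger than it is (underestimation), the
#' signature the maturational-lag hypothesis predicts for poor readers;
#' negative values mean overestimation.
#'
#' @param true_age,predicted_age Numeric vectors in years.
#' @return Numeric vector of gaps.
#' @examples
#' compute_bag(10, 8)   # +2: underestimated
#' compute_bag(12, 15)  # -3: overestimated
#' @export
compute_bag <- function(true_age, predicted_age) {
  if (any(!is.finite(true_age)) || any(!is.finite(predicted_age))) {
    abort("Ages must be finite.")
  }
  true_age - predicted_age
}

#' Assign developmental age bins
#'
#' Six bins over 6-21 years: [6,8), [8,9.5), [9.5,11), [11,13), [13,15),
#' [15,21]. Intervals are left-closed/right-open with an inclusive top,
#' so shared printed boundaries go to the higher bin.
#'
#' @param age Numeric ages in `[6, 21]`.
#' @return Integer bins 1-6.
#' @examples
#' assign_age_bin(c(6.5, 9.5, 21))
#' @export
assign_age_bin <- function(age) {
  if (any(!is.finite(age)) || any(age < 6 | age > 21)) {
    abort("Ages must lie in [6, 21].")
  }
  findInterval(age, c(6, 8, 9.5, 11, 13, 15))
}

#' Build a BAG table from ensemble results
#'
#' Joins subject-level averaged predictions from one or more ensembles to
#' the cohort covariates, in long format (participant x model) with
#' `bag = age - pred_age` and the developmental age bin.
#'
#' @param ensembles Named list of `fcage_ensemble` objects (names become
#'   model labels) or a single ensemble.
#' @param cohort Cohort tibble with covariates.
#' @return Tibble: `id`, `model`, `age`, `pred_age`, `bag`, `age_bin`,
#'   `group`, `towre_index`, `gender`, `ses`, `piq`, `handedness`.
#' @export
bag_table <- function(ensembles, cohort) {
  if (inherits(ensembles, "fcage_ensemble")) ensembles <- list(ensembles)
  if (is.null(names(ensembles)) || any(names(ensembles) == "")) {
    names(ensembles) <- vapply(ensembles, function(e) e$label, character(1))
  }
  rows <- purrr::imap(ensembles, function(e, nm) {
    dplyr::transmute(e$subjects, id = .data$id, model = nm,
                     pred_age = .data$pred_age)
  })
  out <- dplyr::bind_rows(rows)
  n_na <- length(unique(out$id[is.na(out$pred_age)]))
  if (n_na > 0L) {
    inform(sprintf(
      "%d participant(s) never held out in some ensemble; dropped from the BAG table.",
      n_na))
    out <- out[!out$id %in% out$id[is.na(out$pred_age)], ]
  }
  out <- out |>
    dplyr::inner_join(cohort, by = "id") |>
    dplyr::mutate(
      model = factor(.data$model, levels = names(ensembles)),
      bag = compute_bag(.data$age, .data$pred_age),
      age_bin = assign_age_bin(.data$age)
    )
  keep <- intersect(c("id", "model", "age", "pred_age", "bag", "age_bin",
                      "group", "towre_index", "gender", "ses", "piq",
                      "handedness"), names(out))
  dplyr::select(out, dplyr::all_of(keep))
}

# Within-subject response matrix (subjects x models) plus the
# between-subject frame, after listwise deletion on covariates.
bag_wide <- function(bag_tbl, covariates) {
  wide <- tidyr::pivot_wider(
    dplyr::select(bag_tbl, "id", "model", "bag"),
    names_from = "model", values_from = "bag"
  )
  model_levels <- levels(bag_tbl$model)
  between <- dplyr::distinct(
    dplyr::select(bag_tbl, dplyr::all_of(c("id", "age", "group", covariates)))
  )
  dat <- dplyr::inner_join(wide, between, by = "id")
  complete <- complete.cases(dat)
  n_dropped <- sum(!complete)
  dat <- dat[complete, ]
  if (nrow(dat) == 0L) abort("No complete cases after listwise deletion.")
  empty <- setdiff(levels(factor(bag_tbl$group)), unique(as.character(dat$group)))
  if (length(empty) > 0L) {
    abort(paste0("Group cell(s) empty after listwise deletion: ",
                 paste(empty, collapse = ", ")))
  }
  list(Y = as.matrix(dat[, model_levels, drop = FALSE]),
       between = dat, model_levels = model_levels, n_dropped = n_dropped)
}

#' Repeated-measures ANCOVA on brain-age gaps
#'
#' Tests reading-group bias in BAG across models: Model (within-subject),
#' Group (between-subject), true age as a covariate (BAG correlates
#' strongly with true age whenever predictions compress the age range),
#' the Group x Age interaction, and optional nuisance covariates. Type
#' III sums of squares; Mauchly's test assesses sphericity and the
#' Greenhouse-Geisser correction is applied to within-subject terms when
#' it is violated (p < .05). Rows with missing covariates are dropped
#' listwise (count reported via `glance()`).
#'
#' @param bag_tbl Long BAG table from [bag_table()] (>= 2 models).
#' @param covariates Character vector of nuisance covariate columns
#'   (default none; use e.g. `c("gender", "ses", "piq", "handedness")`).
#' @param sphericity_alpha Mauchly p-value below which the GG correction
#'   is applied (default 0.05).
#' @return Object of class `fcage_ancova`: `$effects` tibble with
#'   `effect`, `df1`, `df2`, `F`, `p_value`, `partial_eta_sq`,
#'   `correction`; plus `$mauchly`, `$gg_epsilon`, `$n`, `$n_dropped`.
#' @export
rm_ancova <- function(bag_tbl, covariates = character(0),
                      sphericity_alpha = 0.05) {
  dat <- bag_wide(bag_tbl, covariates)
  Y <- dat$Y
  n <- nrow(Y)
  # Degenerate within-subject structure: identical bags across models.
  within_dev <- sweep(Y, 1, rowMeans(Y))
  degenerate <- max(abs(within_dev)) < 1e-10

  rhs <- paste(c("group * age", covariates), collapse = " + ")
  between <- dat$between
  between$group <- factor(between$group)

  if (degenerate || length(dat$model_levels) < 2L) {
    fit <- lm(as.formula(paste("rowMeans(Y) ~", rhs)), data = between)
    a <- car::Anova(fit, type = 3)
    terms <- rownames(a)[!rownames(a) %in% c("(Intercept)", "Residuals")]
    err_ss <- a["Residuals", "Sum Sq"]
    err_df <- a["Residuals", "Df"]
    eff <- tibble::tibble(
      effect = sub("group", "Group", sub("age", "Age", terms)),
      df1 = a[terms, "Df"], df2 = err_df,
      F = a[terms, "F value"], p_value = a[terms, "Pr(>F)"],
      partial_eta_sq = a[terms, "Sum Sq"] / (a[terms, "Sum Sq"] + err_ss),
      correction = "none"
    )
    within_eff <- tibble::tibble(
      effect = c("Model", paste0("Model:", c("Group", "Age", covariates))),
      df1 = NA_real_, df2 = NA_real_, F = 0, p_value = 1,
      partial_eta_sq = 0, correction = "degenerate"
    )
    return(structure(list(effects = dplyr::bind_rows(eff, within_eff),
                          mauchly = NULL, gg_epsilon = NA_real_,
                          n = n, n_dropped = dat$n_dropped),
                     class = "fcage_ancova"))
  }

  mlm <- lm(as.formula(paste("Y ~", rhs)), data = between)
  idata <- data.frame(model = factor(dat$model_levels,
                                     levels = dat$model_levels))
  a <- car::Anova(mlm, idata = idata, idesign = ~model, type = 3)
  s <- suppressWarnings(summary(a, multivariate = FALSE))
  uni <- s$univariate.tests
  terms <- rownames(uni)[rownames(uni) != "(Intercept)"]
  within <- grepl("(^|:)model($|:)", terms)

  mauchly <- s$sphericity.tests
  gg <- s$pval.adjustments
  sphericity_violated <- !is.null(mauchly) && nrow(mauchly) > 0 &&
    mauchly[1, "p-value"] < sphericity_alpha
  gg_eps <- if (!is.null(gg) && nrow(gg) > 0) unname(gg[1, "GG eps"]) else NA_real_

  eff <- purrr::map_dfr(terms, function(tm) {
    is_within <- grepl("(^|:)model($|:)", tm)
    F_val <- uni[tm, "F value"]
    df1 <- uni[tm, "num Df"]
    df2 <- uni[tm, "den Df"]
    p <- uni[tm, "Pr(>F)"]
    corr <- "none"
    if (is_within && sphericity_violated && !is.null(gg) &&
        tm %in% rownames(gg)) {
      p <- gg[tm, "Pr(>F[GG])"]
      df1 <- df1 * gg_eps
      df2 <- df2 * gg_eps
      corr <- "greenhouse-geisser"
    }
    ss <- uni[tm, "Sum Sq"]
    err <- uni[tm, "Error SS"]
    tibble::tibble(
      effect = pretty_effect(tm),
      df1 = unname(df1), df2 = unname(df2), F = unname(F_val),
      p_value = unname(p),
      partial_eta_sq = unname(ss / (ss + err)),
      correction = corr
    )
  })
  structure(
    list(effects = eff,
         mauchly = if (!is.null(mauchly)) {
           tibble::tibble(term = rownames(mauchly),
                          W = mauchly[, "Test statistic"],
                          p_value = mauchly[, "p-value"])
         },
         gg_epsilon = gg_eps, n = n, n_dropped = dat$n_dropped),
    class = "fcage_ancova"
  )
}

pretty_effect <- function(tm) {
  parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
  parts <- vapply(parts, function(p) switch(p, group = "Group", age = "Age",
                                            model = "Model", p),
                  character(1))
  paste(parts, collapse = ":")
}

#' @export
print.fcage_ancova <- function(x, ...) {
  cat(sprintf("<fcage_ancova> n = %d (%d dropped listwise)\n",
              x$n, x$n_dropped))
  print(x$effects, n = Inf)
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All level pairs of `factor_col` compared on `value_col` with Welch
#' t-tests; p-values multiplied by the number of comparisons (capped at
#' 1) and Cohen's d computed with the pooled SD. Identical groups give
#' the degenerate `d = 0, p = 1`.
#'
#' @param data A data frame (e.g. one model's rows of a BAG table).
#' @param factor_col Grouping column name (default `"group"`).
#' @param value_col Value column name (default `"bag"`).
#' @return Tibble: `level_a`, `level_b`, `mean_diff`, `cohens_d`,
#'   `p_value` (corrected), `n_a`, `n_b`.
#' @export
posthoc_pairwise <- function(data, factor_col = "group", value_col = "bag") {
  f <- factor(data[[factor_col]])
  lv <- levels(f)
  if (length(lv) < 2L) abort("Need at least 2 factor levels.")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    a <- data[[value_col]][f == pr[1]]
    b <- data[[value_col]][f == pr[2]]
    pooled <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                     (length(a) + length(b) - 2))
    if (!is.finite(pooled) || pooled == 0) {
      d <- 0
      p <- 1
    } else {
      d <- (mean(a) - mean(b)) / pooled
      p <- min(1, stats::t.test(a, b)$p.value * m)
    }
    tibble::tibble(level_a = pr[1], level_b = pr[2],
                   mean_diff = mean(a) - mean(b), cohens_d = d,
                   p_value = p, n_a = length(a), n_b = length(b))
  })
}

#' Continuous reading-skill regression on BAG
#'
#' For each model, regresses BAG on age, the TOWRE index, their
#' interaction, and any covariates, over complete cases, reporting
#' standardized coefficients (numeric predictors and the response
#' z-scored, so betas are scale-free). When the TOWRE x Age interaction
#' is significant at `follow_up_alpha`, simple-effects regressions of BAG
#' on TOWRE (re-standardized within bin, controlling covariates) are run
#' in each age bin.
#'
#' @param bag_tbl Long BAG table from [bag_table()].
#' @param covariates Nuisance covariate columns (default none).
#' @param follow_up_alpha Interaction p triggering per-bin follow-ups
#'   (default 0.05).
#' @return Tibble with `model`, `scope` (`"overall"` or `"bin <b>"`),
#'   `term`, `beta`, `t`, `p_value`, `n`.
#' @export
towre_regression <- function(bag_tbl, covariates = character(0),
                             follow_up_alpha = 0.05) {
  zscore <- function(x) {
    if (is.numeric(x)) {
      s <- sd(x)
      if (s == 0) abort("Constant predictor: rank-deficient design.")
      (x - mean(x)) / s
    } else x
  }
  run_lm <- function(df, formula_str, scope, model_lab) {
    num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    df[num_cols] <- lapply(df[num_cols], zscore)
    fit <- lm(as.formula(formula_str), data = df)
    if (any(is.na(stats::coef(fit)))) {
      abort(sprintf("Rank-deficient design in %s (%s).", model_lab, scope))
    }
    cf <- summary(fit)$coefficients
    terms <- rownames(cf)[rownames(cf) != "(Intercept)"]
    tibble::tibble(model = model_lab, scope = scope, term = terms,
                   beta = cf[terms, "Estimate"], t = cf[terms, "t value"],
                   p_value = cf[terms, "Pr(>|t|)"], n = nrow(df))
  }
  cov_rhs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  purrr::map_dfr(levels(bag_tbl$model), function(ml) {
    df <- bag_tbl[bag_tbl$model == ml,
                  c("bag", "age", "towre_index", "age_bin", covariates)]
    df <- df[complete.cases(df), ]
    overall <- run_lm(df[, setdiff(names(df), "age_bin")],
                      paste("bag ~ age * towre_index", cov_rhs),
                      "overall", ml)
    inter_p <- overall$p_value[overall$term == "age:towre_index"]
    bins <- NULL
    if (length(inter_p) == 1 && inter_p < follow_up_alpha) {
      bins <- purrr::map_dfr(sort(unique(df$age_bin)), function(b) {
        sub <- df[df$age_bin == b, setdiff(names(df), c("age_bin", "age"))]
        if (nrow(sub) < length(covariates) + 3) return(NULL)
        run_lm(sub, paste("bag ~ towre_index", cov_rhs),
               sprintf("bin %d", b), ml)
      })
    }
    dplyr::bind_rows(overall, bins)
  })
}
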