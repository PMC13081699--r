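#' Tidy an ensemble's per-permutation metrics
#'
#' @param x An `fcage_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per permutation: `permutation`, `seed`,
#'   `n_components`, `cv_mae`, `test_mae`.
#' @method tidy fcage_ensemble
#' @export
tidy.fcage_ensemble <- function(x, ...) x$perms

#' One-row ensemble summary
#'
#' @param x An `fcage_ensemble`.
#' @param ... Unused.
#' @return Tibble: `label`, `n_permutations`, `n_roi`, `n_edges`,
#'   `cv_mae`, `test_mae`, `cov_pct`, `n_components_mean`.
#' @method glance fcage_ensemble
#' @export
glance.fcage_ensemble <- function(x, ...) {
  tibble::as_tibble(x$summary[c("label", "n_permutations", "n_roi",
                                "n_edges", "cv_mae", "test_mae", "cov_pct",
                                "n_components_mean")])
}

#' Subject-level predictions from an ensemble
#'
#' @param x An `fcage_ensemble`.
#' @param ... Unused.
#' @return Tibble with per-subject averaged rescaled prediction and MAE.
#' @method augment fcage_ensemble
#' @export
augment.fcage_ensemble <- function(x, ...) x$subjects

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy RM-ANCOVA effects
#'
#' @param x An `fcage_ancova`.
#' @param ... Unused.
#' @return The effects tibble (`effect`, `df1`, `df2`, `F`, `p_value`,
#'   `partial_eta_sq`, `correction`).
#' @method tidy fcage_ancova
#' @export
tidy.fcage_ancova <- function(x, ...) x$effects

#' One-row RM-ANCOVA summary
#'
#' @param x An `fcage_ancova`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_dropped`, `gg_epsilon`, `mauchly_p`.
#' @method glance fcage_ancova
#' @export
glance.fcage_ancova <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_dropped = x$n_dropped, gg_epsilon = x$gg_epsilon,
    mauchly_p = if (!is.null(x$mauchly)) x$mauchly$p_value[1] else NA_real_
  )
}
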