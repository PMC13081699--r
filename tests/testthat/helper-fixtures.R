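# Small builders shared across test files. Everything is generated in
# code; no stored fixtures.

tiny_parcellation <- function(n_roi = 14, seed = 11) {
  generate_parcellation(n_roi, n_networks = 7, seed = seed)
}

# A hand-specified cohort for closed-form FC checks: ages and groups are
# exact, no sampling involved.
manual_cohort <- function(ages, groups) {
  n <- length(ages)
  tibble::tibble(
    id = sprintf("sub-%04d", seq_len(n)),
    age = ages,
    towre_pde = 100, towre_swe = 100, towre_index = 100,
    group = factor(groups, levels = c("PR", "TR", "ER")),
    gender = factor("female", levels = c("female", "male")),
    ses = 8L, piq = 10L,
    handedness = factor("right", levels = c("right", "left"))
  )
}

# Directly simulated BAG table (no ensemble): subject random intercepts
# plus iid noise per model, optional additive group offsets in years.
simulate_bag_table <- function(n_per_group = 100, offsets = c(PR = 0, TR = 0, ER = 0),
                               noise_sd = 1, n_models = 3, seed = 1) {
  set.seed(seed)
  groups <- rep(c("PR", "TR", "ER"), each = n_per_group)
  n <- length(groups)
  subjects <- tibble::tibble(
    id = sprintf("sub-%04d", seq_len(n)),
    age = runif(n, 6, 21),
    group = factor(groups, levels = c("PR", "TR", "ER")),
    towre_index = rnorm(n, 100, 15),
    gender = factor(sample(c("female", "male"), n, replace = TRUE)),
    ses = round(runif(n, 3, 12)),
    piq = round(runif(n, 5, 15)),
    handedness = factor(sample(c("right", "left"), n, replace = TRUE,
                               prob = c(0.9, 0.1)))
  )
  subj_int <- rnorm(n, 0, 0.5)
  purrr::map_dfr(seq_len(n_models), function(mdl) {
    dplyr::mutate(subjects,
                  model = sprintf("m%d", mdl),
                  bag = offsets[groups] + subj_int + rnorm(n, 0, noise_sd),
                  age_bin = assign_age_bin(age))
  }) |>
    dplyr::mutate(model = factor(model, levels = sprintf("m%d", seq_len(n_models))))
}
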