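#' Reading-group reference profiles used by the cohort simulator
#'
#' Per-group targets the simulator draws from: TOWRE Phonemic Decoding
#' Efficiency (PDE) and Sight Word Efficiency (SWE) standard-score means
#' and SDs, covariate summaries (% female, SES mean/SD and missingness,
#' PIQ scaled-score mean/SD and missingness, % right-handed). Defaults
#' emulate a large developmental cohort (ages 6-21) with 211 poor (PR),
#' 338 typical (TR), and 193 exceptional (ER) readers.
#'
#' @return A tibble with one row per reading group.
#' @export
default_group_profiles <- function() {
  tibble::tibble(
    group        = factor(c("PR", "TR", "ER"), levels = c("PR", "TR", "ER")),
    pde_mean     = c(76.1, 98.4, 118.0),
    pde_sd       = c(9.3, 7.6, 8.4),
    swe_mean     = c(77.5, 100.7, 123.8),
    swe_sd       = c(10.0, 7.8, 8.6),
    female_prop  = c(0.346, 0.367, 0.295),
    ses_mean     = c(6.8, 8.5, 9.0),
    ses_sd       = c(3.7, 3.1, 3.0),
    ses_na_rate  = c(0.25, 0.17, 0.14),
    piq_mean     = c(8.9, 10.3, 11.6),
    piq_sd       = c(2.9, 3.2, 3.1),
    piq_na_rate  = c(0.16, 0.0, 0.0),
    right_prop   = c(0.910, 0.867, 0.917)
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort / connectivity generator.
#' The defaults are the emulated study conditions: N = 742 split
#' 211/338/193 across poor/typical/exceptional readers, ages 6-21 skewed
#' toward childhood, a 400-ROI seven-network parcellation, and
#' age-related connectivity change concentrated in default-mode and
#' control network connections.
#'
#' @param n_participants Cohort size.
#' @param group_proportions Named proportions for PR, TR, ER (sum to 1).
#' @param age_range Two numbers in years, within `[6, 21]` by default.
#' @param age_shape Skew-normal shape for the age distribution:
#'   `list(xi, omega, alpha)` (location, scale, slant). The default slants
#'   mass toward 8-12 years.
#' @param maturational_lag_years Developmental shift delta in years applied
#'   to each group's effective age on lag-scope edges: PR get `-delta`
#'   (connectivity of a younger brain), TR 0, ER `+delta`.
#' @param lag_scope Either `"reading_network_edges"` (delta applies only to
#'   edges with both endpoints in `reading_rois`) or `"all_edges"`.
#' @param reading_rois Optional integer ROI ids defining the reading
#'   network for `lag_scope = "reading_network_edges"`. `NULL` picks a
#'   deterministic default: lowest-id left-hemisphere Default, Cont and
#'   SalVentAttn ROIs, about 7% of the parcellation.
#' @param n_roi Number of ROIs (even; split across hemispheres).
#' @param n_networks Number of functional networks (default 7).
#' @param frac_developmental_edges Fraction of edges with a nonzero age
#'   slope.
#' @param age_slope_z_per_year Slope magnitude, z-units per year, on the
#'   structured developmental edges.
#' @param edge_noise_sd Independent edge noise SD, z-units.
#' @param seed Integer seed; all generator output is a pure function of
#'   the config including this seed.
#' @param group_profiles Per-group score/covariate targets
#'   (see [default_group_profiles()]).
#' @return A list of class `fcage_sim_config`.
#' @export
sim_config <- function(n_participants = 742,
                       group_proportions = c(PR = 211, TR = 338, ER = 193) / 742,
                       age_range = c(6, 21),
                       age_shape = list(xi = 7.5, omega = 4.2, alpha = 3),
                       maturational_lag_years = 0,
                       lag_scope = c("reading_network_edges", "all_edges"),
                       reading_rois = NULL,
                       n_roi = 400,
                       n_networks = 7,
                       frac_developmental_edges = 0.05,
                       age_slope_z_per_year = 0.02,
                       edge_noise_sd = 0.10,
                       seed = 1,
                       group_profiles = default_group_profiles()) {
  lag_scope <- match.arg(lag_scope)
  stopifnot(
    n_participants >= 1,
    length(group_proportions) == 3,
    abs(sum(group_proportions) - 1) <= 1e-9,
    all(group_proportions >= 0),
    length(age_range) == 2, age_range[1] < age_range[2],
    n_roi >= 2, n_networks >= 1, n_roi >= n_networks,
    frac_developmental_edges >= 0, frac_developmental_edges <= 1,
    edge_noise_sd >= 0
  )
  if (is.null(names(group_proportions))) {
    names(group_proportions) <- c("PR", "TR", "ER")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      group_proportions = group_proportions[c("PR", "TR", "ER")],
      age_range = age_range,
      age_shape = age_shape,
      maturational_lag_years = maturational_lag_years,
      lag_scope = lag_scope,
      reading_rois = reading_rois,
      n_roi = as.integer(n_roi),
      n_networks = as.integer(n_networks),
      frac_developmental_edges = frac_developmental_edges,
      age_slope_z_per_year = age_slope_z_per_year,
      edge_noise_sd = edge_noise_sd,
      seed = as.integer(seed),
      group_profiles = group_profiles
    ),
    class = "fcage_sim_config"
  )
}

#' Assign a reading group from a TOWRE composite index
#'
#' Poor reader (PR) below 91, typical reader (TR) from 91 to 109
#' inclusive, exceptional reader (ER) above 109.
#'
#' @param towre_index Numeric composite standard scores.
#' @return Factor with levels PR, TR, ER.
#' @examples
#' assign_reading_group(c(90, 91, 109, 110))
#' @export
assign_reading_group <- function(towre_index) {
  if (any(!is.finite(towre_index))) abort("`towre_index` must be finite.")
  factor(
    dplyr::case_when(
      towre_index < 91 ~ "PR",
      towre_index <= 109 ~ "TR",
      TRUE ~ "ER"
    ),
    levels = c("PR", "TR", "ER")
  )
}

# Group cutoff check used by rejection sampling.
group_cutoff_ok <- function(group, towre_index) {
  (group == "PR" & towre_index < 91) |
    (group == "TR" & towre_index >= 91 & towre_index <= 109) |
    (group == "ER" & towre_index > 109)
}

#' Simulate a reading cohort
#'
#' Draws a cohort table with ages, TOWRE subscores consistent with each
#' group's cutoff (by rejection sampling against the group's score
#' distribution), and demographic covariates. Group sizes follow
#' largest-remainder apportionment of `n_participants`, so the default
#' proportions reproduce 211/338/193 exactly at N = 742.
#'
#' @param config A [sim_config()].
#' @return A tibble (class `CohortTable`-like): `id`, `age`, `towre_pde`,
#'   `towre_swe`, `towre_index`, `group`, `gender`, `ses`, `piq`,
#'   `handedness`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fcage_sim_config"))
  seeds <- spawn_seeds(config$seed, 3L)
  set.seed(seeds[1])

  sizes <- apportion(config$n_participants, config$group_proportions)
  prof <- config$group_profiles
  max_resample <- 1000L

  rows <- purrr::map(c("PR", "TR", "ER"), function(g) {
    n_g <- sizes[[g]]
    if (n_g == 0L) return(NULL)
    pr <- prof[prof$group == g, ]
    pde <- rnorm_trunc(n_g, pr$pde_mean, pr$pde_sd, 55, 145)
    swe <- rnorm_trunc(n_g, pr$swe_mean, pr$swe_sd, 55, 145)
    idx <- (pde + swe) / 2
    tries <- 0L
    bad <- which(!group_cutoff_ok(g, idx))
    while (length(bad) > 0L) {
      tries <- tries + 1L
      if (tries > max_resample) {
        abort(sprintf(
          "Could not draw TOWRE scores satisfying the %s cutoff after %d resamples; check the group profile means.",
          g, max_resample))
      }
      pde[bad] <- rnorm_trunc(length(bad), pr$pde_mean, pr$pde_sd, 55, 145)
      swe[bad] <- rnorm_trunc(length(bad), pr$swe_mean, pr$swe_sd, 55, 145)
      idx <- (pde + swe) / 2
      bad <- which(!group_cutoff_ok(g, idx))
    }
    ses <- round(rnorm_trunc(n_g, pr$ses_mean, pr$ses_sd, 0, 15))
    ses[runif(n_g) < pr$ses_na_rate] <- NA
    piq <- round(rnorm_trunc(n_g, pr$piq_mean, pr$piq_sd, 1, 19))
    piq[runif(n_g) < pr$piq_na_rate] <- NA
    tibble::tibble(
      group = factor(g, levels = c("PR", "TR", "ER")),
      towre_pde = pde, towre_swe = swe, towre_index = idx,
      gender = factor(ifelse(runif(n_g) < pr$female_prop, "female", "male"),
                      levels = c("female", "male")),
      ses = ses, piq = piq,
      handedness = factor(ifelse(runif(n_g) < pr$right_prop, "right", "left"),
                          levels = c("right", "left"))
    )
  })
  cohort <- dplyr::bind_rows(rows)

  sh <- config$age_shape
  cohort$age <- rskewnorm_trunc(nrow(cohort), sh$xi, sh$omega, sh$alpha,
                                config$age_range[1], config$age_range[2])
  cohort$id <- sprintf("sub-%04d", seq_len(nrow(cohort)))
  dplyr::select(cohort, "id", "age", "towre_pde", "towre_swe",
                "towre_index", "group", "gender", "ses", "piq", "handedness")
}

#' Generate a synthetic parcellation
#'
#' Builds an ROI table shaped like a seven-network cortical atlas: ROIs
#' split evenly across hemispheres, networks assigned in unequal fixed
#' proportions (Default and Cont largest, mimicking their real spatial
#' extent), and centroids sampled in a brain-sized MNI box with the x
#' coordinate signed by hemisphere (left negative).
#'
#' @param n_roi Even number of ROIs.
#' @param n_networks Number of networks (the first seven use canonical
#'   labels Vis, SomMot, DorsAttn, SalVentAttn, Limbic, Cont, Default).
#' @param seed Integer seed for centroid placement.
#' @return Tibble with `roi_id` (0-based), `name`, `network`,
#'   `hemisphere`, `x`, `y`, `z`.
#' @export
generate_parcellation <- function(n_roi, n_networks = 7, seed = 1) {
  if (n_roi %% 2 != 0) abort("`n_roi` must be even (split across hemispheres).")
  stopifnot(n_roi >= n_networks, n_networks >= 1)
  labels7 <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
               "Cont", "Default")
  labels <- if (n_networks <= 7) labels7[seq_len(n_networks)] else
    c(labels7, paste0("Net", seq.int(8, n_networks)))
  # Unequal fixed weights: Default and Cont largest.
  w7 <- c(Vis = 0.15, SomMot = 0.15, DorsAttn = 0.12, SalVentAttn = 0.12,
          Limbic = 0.08, Cont = 0.17, Default = 0.21)
  w <- if (n_networks <= 7) w7[labels] else
    c(w7, stats::setNames(rep(0.05, n_networks - 7), labels[-(1:7)]))
  # Every network gets at least one ROI, remainder by largest remainder.
  counts <- rep(1L, n_networks) + apportion(n_roi - n_networks, w)
  # Split each network's count across hemispheres, balancing to n_roi/2 each.
  l_counts <- counts %/% 2L
  odd <- which(counts %% 2L == 1L)
  need_l <- n_roi %/% 2L - sum(l_counts)
  if (need_l > 0) l_counts[odd[seq_len(need_l)]] <- l_counts[odd[seq_len(need_l)]] + 1L
  r_counts <- counts - l_counts

  network <- c(rep(labels, l_counts), rep(labels, r_counts))
  hemisphere <- rep(c("L", "R"), c(sum(l_counts), sum(r_counts)))

  set.seed(as.integer(seed))
  n <- n_roi
  x_mag <- runif(n, 8, 68)
  out <- tibble::tibble(
    roi_id = 0:(n - 1L),
    network = factor(network, levels = labels),
    hemisphere = factor(hemisphere, levels = c("L", "R")),
    x = ifelse(hemisphere == "L", -x_mag, x_mag),
    y = runif(n, -100, 68),
    z = runif(n, -45, 75)
  )
  out$name <- sprintf("%s_%s_%03d", out$hemisphere, out$network, out$roi_id)
  dplyr::select(out, "roi_id", "name", "network", "hemisphere", "x", "y", "z")
}

# Deterministic default reading-network ROI set: lowest-id left-hemisphere
# ROIs from higher-order association networks, ~7% of the parcellation
# (27/400 in the emulated atlas).
default_reading_rois <- function(parcellation, frac = 27 / 400) {
  n_target <- max(2L, round(frac * nrow(parcellation)))
  pref <- parcellation[parcellation$hemisphere == "L" &
                         parcellation$network %in% c("Default", "Cont", "SalVentAttn"), ]
  ids <- sort(pref$roi_id)
  if (length(ids) < n_target) {
    rest <- sort(setdiff(parcellation$roi_id[parcellation$hemisphere == "L"], ids))
    ids <- c(ids, rest)
  }
  sort(head(ids, n_target))
}

#' Simulate Fisher-z connectivity for a cohort
#'
#' Generates a participants-by-edges matrix in z-space with the
#' developmental structure the downstream analysis assumes: higher
#' within-network than between-network baselines; a configurable fraction
#' of edges with age-dependent change, concentrated as within-network
#' strengthening of Default and Cont edges and deepening Default-Cont
#' anticorrelation; and a per-group maturational shift of effective age
#' (`delta`) on lag-scope edges, so poor readers' connectivity looks like
#' that of a younger brain.
#'
#' For edge e and participant p:
#' `z = baseline(e) + slope(e) * (effective_age(p, e) - age_ref) + N(0, sd)`
#' with `age_ref` the midpoint of the configured age range.
#'
#' @param cohort A cohort table from [simulate_cohort()].
#' @param parcellation A parcellation from [generate_parcellation()].
#' @param config The same [sim_config()] used for the cohort.
#' @return An [fc_set()] with attributes `baseline_z`, `age_slope_z`,
#'   `developmental_edges` (logical), `lag_edges` (logical), and
#'   `reading_rois`.
#' @export
simulate_fc <- function(cohort, parcellation, config) {
  stopifnot(inherits(config, "fcage_sim_config"))
  if (nrow(parcellation) != config$n_roi) {
    abort("`parcellation` size does not match `config$n_roi`.")
  }
  seeds <- spawn_seeds(config$seed, 3L)
  set.seed(seeds[3])

  edges <- classify_edges(edge_pairs(parcellation$roi_id), parcellation)
  m <- nrow(edges)
  n <- nrow(cohort)

  baseline <- ifelse(edges$network_relation == "within", 0.35, 0.10) +
    rnorm(m, 0, 0.05)

  # Structured developmental edges: within-network Default/Cont gain with
  # age; Default<->Cont between-network edges anticorrelate more with age.
  s <- config$age_slope_z_per_year
  within_dc <- edges$network_relation == "within" &
    edges$network_i %in% c("Default", "Cont")
  between_dc <- edges$network_relation == "between" &
    ((edges$network_i == "Default" & edges$network_j == "Cont") |
       (edges$network_i == "Cont" & edges$network_j == "Default"))
  slope <- rep(0, m)
  n_dev <- round(config$frac_developmental_edges * m)
  structured <- which(within_dc | between_dc)
  if (length(structured) > n_dev) {
    structured <- sort(sample(structured, n_dev))
  }
  slope[structured] <- ifelse(within_dc[structured], s, -s)
  remainder <- n_dev - length(structured)
  if (remainder > 0) {
    pool <- setdiff(seq_len(m), structured)
    extra <- sort(sample(pool, min(remainder, length(pool))))
    slope[extra] <- sample(c(-s / 2, s / 2), length(extra), replace = TRUE)
  }
  dev_edges <- slope != 0

  # Lag scope: which edges carry the group maturational shift.
  reading_rois <- config$reading_rois
  if (config$lag_scope == "reading_network_edges") {
    if (is.null(reading_rois)) reading_rois <- default_reading_rois(parcellation)
    lag_edges <- edges$roi_i %in% reading_rois & edges$roi_j %in% reading_rois
  } else {
    lag_edges <- rep(TRUE, m)
  }

  delta <- config$maturational_lag_years
  shift <- c(PR = -delta, TR = 0, ER = delta)[as.character(cohort$group)]
  age_ref <- mean(config$age_range)
  a0 <- cohort$age - age_ref
  a_lag <- a0 + shift

  z <- outer(a0, slope)
  if (delta != 0 && any(lag_edges)) {
    z[, lag_edges] <- outer(a_lag, slope[lag_edges])
  }
  z <- sweep(z, 2, baseline, "+")
  if (config$edge_noise_sd > 0) {
    z <- z + matrix(rnorm(n * m, 0, config$edge_noise_sd), n, m)
  }

  out <- fc_set(z, cohort$id, parcellation$roi_id)
  attr(out, "baseline_z") <- baseline
  attr(out, "age_slope_z") <- slope
  attr(out, "developmental_edges") <- dev_edges
  attr(out, "lag_edges") <- lag_edges
  attr(out, "reading_rois") <- reading_rois
  out
}

#' Simulate a meta-analysis coordinate list
#'
#' Builds a list of MNI-mm points shaped like pooled coordinates from
#' reading/language neuroimaging meta-analyses: `n_in_range` points
#' jittered around centroids of target (reading-network) ROIs, plus
#' `n_out_of_range` points placed outside the parcellation's reach so
#' they map to no ROI. The default totals (367 in-range + 49 out of 416)
#' mirror the emulated study's coordinate pool.
#'
#' @param parcellation Parcellation table.
#' @param n_in_range,n_out_of_range Point counts.
#' @param radius Mapping radius (mm) the in-range points must respect.
#' @param target_rois ROI ids to centre in-range points on; default the
#'   deterministic reading set of [simulate_fc()].
#' @param seed Integer seed.
#' @return Tibble with `x`, `y`, `z` (mm).
#' @export
simulate_coordinates <- function(parcellation, n_in_range = 367,
                                 n_out_of_range = 49, radius = 12,
                                 target_rois = NULL, seed = 1) {
  set.seed(as.integer(seed))
  if (is.null(target_rois)) target_rois <- default_reading_rois(parcellation)
  cent <- parcellation[match(target_rois, parcellation$roi_id),
                       c("x", "y", "z")]
  pick <- sample(seq_len(nrow(cent)), n_in_range, replace = TRUE)
  jit <- matrix(runif(3 * n_in_range, -1, 1), ncol = 3)
  jit <- jit / pmax(sqrt(rowSums(jit^2)), 1e-12) *
    runif(n_in_range, 0, radius * 0.45)
  inr <- as.matrix(cent)[pick, , drop = FALSE] + jit
  # Out-of-range: far below the inferior-most centroid.
  z_floor <- min(parcellation$z) - 3 * radius
  outr <- cbind(runif(n_out_of_range, -60, 60),
                runif(n_out_of_range, -90, 60),
                runif(n_out_of_range, z_floor - 40, z_floor))
  out <- rbind(inr, outr)
  tibble::tibble(x = out[, 1], y = out[, 2], z = out[, 3])
}
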