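#' Map point coordinates to parent ROIs
#'
#' Assigns each MNI-mm coordinate to the parcellation ROI whose centroid
#' is nearest, provided it lies within `radius` mm; otherwise the point is
#' out-of-range (`NA`). Distance ties are broken by lowest ROI id and
#' flagged. (With a real labelled template, containment would replace the
#' centroid rule; the interface is the same.)
#'
#' @param coords Data frame with `x`, `y`, `z` columns (mm).
#' @param parcellation Parcellation table with centroids.
#' @param radius Maximum centroid distance in mm (default 12).
#' @return Tibble: `x`, `y`, `z`, `roi_id` (`NA` if out-of-range),
#'   `distance`, `tie`.
#' @export
map_coordinates <- function(coords, parcellation, radius = 12) {
  if (nrow(parcellation) == 0L) abort("Empty parcellation.")
  pts <- as.matrix(coords[, c("x", "y", "z")])
  if (any(!is.finite(pts))) abort("Coordinates must be finite.")
  cent <- as.matrix(parcellation[, c("x", "y", "z")])
  # Squared distances, points x ROIs.
  d2 <- outer(rowSums(pts^2), rowSums(cent^2), "+") - 2 * pts %*% t(cent)
  d2[d2 < 0] <- 0
  # Order centroids by ROI id so which.min's first-match rule is the
  # lowest-id tie-break.
  ord <- order(parcellation$roi_id)
  d2 <- d2[, ord, drop = FALSE]
  ids <- parcellation$roi_id[ord]
  best <- apply(d2, 1, which.min)
  dmin <- sqrt(d2[cbind(seq_len(nrow(pts)), best)])
  tie <- vapply(seq_len(nrow(pts)), function(i) {
    sum(abs(sqrt(d2[i, ]) - dmin[i]) < 1e-9) > 1L
  }, logical(1))
  roi <- ifelse(dmin <= radius, ids[best], NA_integer_)
  tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    roi_id = as.integer(roi), distance = dmin, tie = tie
  )
}

#' Tally coordinate hits per ROI
#'
#' Counts how many coordinates map to each parcellation ROI (several
#' unique coordinates may share a parent ROI), and how many fall
#' out-of-range. `sum(hit_count) + n_out_of_range == n_coords` always.
#'
#' @inheritParams map_coordinates
#' @return Tibble with one row per ROI (`roi_id`, `hit_count`) and
#'   attributes `n_coords`, `n_out_of_range`, `n_in_range`.
#' @export
count_hits <- function(coords, parcellation, radius = 12) {
  if (nrow(coords) == 0L) abort("`coords` must be nonempty.")
  mapped <- map_coordinates(coords, parcellation, radius)
  tab <- table(factor(mapped$roi_id, levels = sort(parcellation$roi_id)))
  out <- tibble::tibble(
    roi_id = as.integer(names(tab)),
    hit_count = as.integer(tab)
  )
  attr(out, "n_coords") <- nrow(coords)
  attr(out, "n_out_of_range") <- sum(is.na(mapped$roi_id))
  attr(out, "n_in_range") <- sum(!is.na(mapped$roi_id))
  out
}

#' Threshold a hit table into an ROI cutoff set
#'
#' Returns the ids of ROIs hit by at least `k` coordinates. `k = 0` keeps
#' every ROI (the whole-brain model); increasing `k` yields the nested
#' ladder of reduced reading-network models (in the emulated study,
#' k = 1, 2, 4 gave 152-, 78- and 27-ROI sets from the 400-ROI atlas).
#'
#' @param hits Output of [count_hits()].
#' @param k Minimum hit count (>= 0).
#' @return Sorted integer vector of ROI ids.
#' @export
apply_cutoff <- function(hits, k) {
  stopifnot(k >= 0)
  sort(hits$roi_id[hits$hit_count >= k])
}
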