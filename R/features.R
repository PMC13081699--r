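#' Fisher z-transform of correlation coefficients
#'
#' Variance-stabilises Pearson correlations with `atanh`, after clipping
#' magnitudes to `1 - 1e-7` so that degenerate (perfectly correlated)
#' inputs map to a large finite value instead of infinity.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of z-values.
#' @examples
#' fisher_z(c(0, 0.5, 0.9))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    abort("`r` must be finite correlations with |r| <= 1.")
  }
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

# Canonical edge order shared by every module: pairs (i, j) with i < j by
# ROI id, row-major -- (1,2), (1,3), ..., (1,n), (2,3), ...
edge_pairs <- function(roi_ids) {
  ids <- sort(unique(roi_ids))
  n <- length(ids)
  if (n < 2L) {
    return(tibble::tibble(roi_i = ids[integer(0)], roi_j = ids[integer(0)]))
  }
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq.int(2L, n))
  tibble::tibble(roi_i = ids[i], roi_j = ids[j])
}

#' Connectivity matrix from ROI time series
#'
#' Computes the Pearson correlation between every pair of ROI time series
#' and Fisher z-transforms it. The diagonal is set to 0 and is never part
#' of the feature set (self-connections are not features).
#'
#' @param ts Numeric matrix, timepoints x ROIs (T >= 3). Column names, if
#'   present, carry through to the result.
#' @return Symmetric square z-matrix with zero diagonal.
#' @export
fc_from_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) abort("Need at least 3 timepoints.")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labs <- colnames(ts)[bad] %||% as.character(bad)
    abort(paste0("Constant time series for ROI(s): ",
                 paste(labs, collapse = ", ")))
  }
  r <- cor(ts)
  z <- matrix(fisher_z(c(r)), nrow(r), ncol(r), dimnames = dimnames(r))
  diag(z) <- 0
  z
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Flattens a symmetric square z-matrix into the canonical edge order:
#' pairs `(i, j)` with `i < j` by ROI id, row-major. A matrix over `n`
#' ROIs yields `choose(n, 2)` features (79,800 for 400 ROIs).
#'
#' @param mat Symmetric square matrix (asymmetry beyond 1e-8 is an error).
#' @param roi_ids ROI ids labelling rows/columns, in matrix order.
#' @return Named numeric vector of length `choose(n, 2)`; the edge table
#'   is attached as attribute `"edges"`.
#' @export
vectorize_upper <- function(mat, roi_ids) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n) abort("`mat` must be square.")
  if (length(roi_ids) != n) abort("`roi_ids` must match matrix dimension.")
  if (max(abs(mat - t(mat))) > 1e-8) abort("`mat` is not symmetric (tolerance 1e-8).")
  ord <- order(roi_ids)
  mat <- mat[ord, ord, drop = FALSE]
  ids <- roi_ids[ord]
  edges <- edge_pairs(ids)
  pos_i <- match(edges$roi_i, ids)
  pos_j <- match(edges$roi_j, ids)
  out <- mat[cbind(pos_i, pos_j)]
  attr(out, "edges") <- edges
  out
}

# Inverse of vectorize_upper, mainly for round-trip checks and plotting.
matrix_from_edges <- function(values, roi_ids) {
  ids <- sort(unique(roi_ids))
  n <- length(ids)
  edges <- edge_pairs(ids)
  stopifnot(length(values) == nrow(edges))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  pos_i <- match(edges$roi_i, ids)
  pos_j <- match(edges$roi_j, ids)
  m[cbind(pos_i, pos_j)] <- values
  m[cbind(pos_j, pos_i)] <- values
  m
}

#' Construct an FC feature set
#'
#' Bundles a participants-by-edges matrix of Fisher-z connectivity values
#' with its canonical edge order. Rows are participants; columns follow
#' [edge_pairs()] over the supplied ROI ids.
#'
#' @param z Numeric matrix, participants x edges.
#' @param participant_id Character vector of row ids.
#' @param roi_ids Integer ROI ids the edges are built over.
#' @return An object of class `fcage_fc`.
#' @export
fc_set <- function(z, participant_id, roi_ids) {
  z <- as.matrix(z)
  edges <- edge_pairs(roi_ids)
  if (ncol(z) != nrow(edges)) {
    abort(sprintf("Expected %d edge columns for %d ROIs, got %d.",
                  nrow(edges), length(unique(roi_ids)), ncol(z)))
  }
  if (nrow(z) != length(participant_id)) abort("One row per participant required.")
  if (any(!is.finite(z))) abort("All connectivity values must be finite.")
  structure(
    list(z = z, participant_id = as.character(participant_id),
         roi_ids = sort(unique(as.integer(roi_ids))), edges = edges),
    class = "fcage_fc"
  )
}

#' @export
print.fcage_fc <- function(x, ...) {
  cat(sprintf("<fcage_fc> %d participants x %d edges (%d ROIs)\n",
              nrow(x$z), ncol(x$z), length(x$roi_ids)))
  invisible(x)
}

#' @export
dim.fcage_fc <- function(x) dim(x$z)

#' Restrict an FC feature set to a subset of ROIs
#'
#' Keeps exactly the edges whose both endpoints lie in `roi_subset`,
#' preserving the canonical order (the relative order of surviving edges
#' is unchanged, and equals the canonical order over the subset).
#'
#' @param fc An [fc_set()].
#' @param roi_subset Integer ids; must all exist in `fc`.
#' @return A new `fcage_fc` over the subset (possibly with 0 edges).
#' @export
subset_edges <- function(fc, roi_subset) {
  stopifnot(inherits(fc, "fcage_fc"))
  roi_subset <- sort(unique(as.integer(roi_subset)))
  unknown <- setdiff(roi_subset, fc$roi_ids)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown ROI id(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- fc$edges$roi_i %in% roi_subset & fc$edges$roi_j %in% roi_subset
  out <- fc
  out$z <- fc$z[, keep, drop = FALSE]
  out$roi_ids <- roi_subset
  out$edges <- fc$edges[keep, ]
  out
}

#' Classify edges by network and hemisphere relation
#'
#' For each ROI pair, reports whether the connection is within one of the
#' seven canonical networks or between networks, and whether it is
#' left-intrahemispheric (`LL`), right-intrahemispheric (`RR`), or
#' interhemispheric (`inter`). Symmetric in argument order.
#'
#' @param edges Data frame with `roi_i`, `roi_j` columns (ids).
#' @param parcellation A parcellation table (see [generate_parcellation()]).
#' @return The input with `network_relation` and `hemisphere_relation`
#'   columns added (plus `network_i`, `network_j`).
#' @export
classify_edges <- function(edges, parcellation) {
  if (any(edges$roi_i == edges$roi_j)) abort("Self-edges cannot be classified.")
  idx_i <- match(edges$roi_i, parcellation$roi_id)
  idx_j <- match(edges$roi_j, parcellation$roi_id)
  if (anyNA(idx_i) || anyNA(idx_j)) abort("Edge references an ROI id missing from the parcellation.")
  net_i <- parcellation$network[idx_i]
  net_j <- parcellation$network[idx_j]
  hem_i <- parcellation$hemisphere[idx_i]
  hem_j <- parcellation$hemisphere[idx_j]
  dplyr::mutate(
    tibble::as_tibble(edges),
    network_i = net_i,
    network_j = net_j,
    network_relation = ifelse(net_i == net_j, "within", "between"),
    hemisphere_relation = dplyr::case_when(
      hem_i == "L" & hem_j == "L" ~ "LL",
      hem_i == "R" & hem_j == "R" ~ "RR",
      TRUE ~ "inter"
    )
  )
}
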