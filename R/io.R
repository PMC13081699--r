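#' Read and write pipeline tables
#'
#' Cohort, parcellation, coordinate and hit tables travel as
#' tab-separated text with fixed headers; FC matrices as one
#' whitespace-delimited square matrix file per participant plus a
#' manifest TSV mapping participant id to file path, with an edge-order
#' sidecar (`roi_i`, `roi_j` per line) written alongside.
#'
#' @param x Object to write.
#' @param path File (tables) or directory (FC sets).
#' @name fcage-io
NULL

#' @rdname fcage-io
#' @export
write_cohort <- function(x, path) readr::write_tsv(x, path)

#' @rdname fcage-io
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(
      group = factor(.data$group, levels = c("PR", "TR", "ER")),
      gender = factor(.data$gender, levels = c("female", "male")),
      handedness = factor(.data$handedness, levels = c("right", "left"))
    )
}

#' @rdname fcage-io
#' @export
write_parcellation <- function(x, path) readr::write_tsv(x, path)

#' @rdname fcage-io
#' @export
read_parcellation <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out$network <- factor(out$network, levels = unique(out$network))
  out$hemisphere <- factor(out$hemisphere, levels = c("L", "R"))
  out
}

#' @rdname fcage-io
#' @export
write_coordinates <- function(x, path) readr::write_tsv(x, path)

#' @rdname fcage-io
#' @export
read_coordinates <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' @rdname fcage-io
#' @export
write_fc_set <- function(x, path) {
  stopifnot(inherits(x, "fcage_fc"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$edges, file.path(path, "edge_order.tsv"))
  files <- file.path(path, paste0(x$participant_id, ".txt"))
  for (i in seq_along(files)) {
    m <- matrix_from_edges(x$z[i, ], x$roi_ids)
    utils::write.table(m, files[i], row.names = FALSE, col.names = FALSE)
  }
  manifest <- tibble::tibble(id = x$participant_id, path = basename(files))
  readr::write_tsv(manifest, file.path(path, "manifest.tsv"))
  invisible(path)
}

#' @rdname fcage-io
#' @export
read_fc_set <- function(path) {
  manifest <- readr::read_tsv(file.path(path, "manifest.tsv"),
                              show_col_types = FALSE)
  edges <- readr::read_tsv(file.path(path, "edge_order.tsv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             roi_i = readr::col_integer(),
                             roi_j = readr::col_integer()))
  roi_ids <- sort(unique(c(edges$roi_i, edges$roi_j)))
  z <- t(vapply(manifest$path, function(f) {
    m <- as.matrix(utils::read.table(file.path(path, f)))
    vectorize_upper(unname(m), roi_ids)
  }, numeric(nrow(edges))))
  fc_set(z, manifest$id, roi_ids)
}
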