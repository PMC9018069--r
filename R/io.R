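#' Write and read ROI time series as tab-delimited text
#'
#' Layout: first row ROI labels, second row network labels, then one row
#' per volume of numeric BOLD values. Values round-trip at full precision.
#'
#' @param x volumes x ROIs numeric matrix with ROI column names.
#' @param path output file.
#' @param networks character vector of per-ROI network labels.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(x, path, networks) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) abort("ROI column names required.")
  if (length(networks) != ncol(x)) {
    abort("One network label per ROI required.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  writeLines(paste(networks, collapse = "\t"), con)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @param known_networks optional vector of allowed network labels; others
#'   raise an error.
#' @return for the reader: volumes x ROIs matrix with attribute `networks`.
#' @export
read_roi_timeseries <- function(path, known_networks = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) abort("File too short for the ROI layout.")
  rois <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  networks <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(rois)) {
    abort(paste0("Duplicate ROI label(s): ",
                 paste(unique(rois[duplicated(rois)]), collapse = ", ")))
  }
  if (length(networks) != length(rois)) abort("Header rows differ in length.")
  if (!is.null(known_networks) && !all(networks %in% known_networks)) {
    abort(paste0("Unknown network label(s): ",
                 paste(setdiff(networks, known_networks), collapse = ", ")))
  }
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(rois))) {
    abort(sprintf("Ragged row(s) at volume %s.",
                  paste(which(widths != length(rois))[1], collapse = ", ")))
  }
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(length(rois))))
  if (anyNA(vals)) {
    bad_row <- which(apply(matrix(is.na(vals), nrow = length(rois)), 2, any))[1]
    abort(sprintf("Non-numeric cell at volume row %d.", bad_row))
  }
  m <- t(matrix(vals, nrow = length(rois)))
  colnames(m) <- rois
  attr(m, "networks") <- networks
  m
}

#' Write and read a square labelled matrix (covariance or tangent vector)
#'
#' Tab-delimited with an ROI-label header row; full double precision.
#'
#' @param m square numeric matrix.
#' @param path file path.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  labels <- colnames(m)
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(body) != length(labels))) abort("Ragged matrix rows.")
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(length(labels))))
  if (anyNA(vals)) abort("Non-numeric cell in matrix file.")
  m <- t(matrix(vals, nrow = length(labels)))
  dimnames(m) <- list(labels, labels)
  m
}

#' Write a per-trial behavioral table as tab-delimited text
#' @param trials trial tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}
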