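#' Read and write structural networks and region tables
#'
#' Network matrices are stored as plain delimited numeric text (no header,
#' no row names); the delimiter is auto-detected from the first line
#' (tab, comma, or whitespace). Region metadata is strict tab-separated
#' text with a header line containing the columns `label`, `x_mm`, `y_mm`,
#' `z_mm`, `volume`, `system`. Asymmetric matrices are rejected (within
#' `symmetry_tol`) rather than silently symmetrized, and NaN entries are
#' rejected.
#'
#' @param path file path.
#' @param regions optional region table (or path to one) to attach when
#'   reading a matrix; when omitted, a minimal placeholder table is built so
#'   that the object is still a valid `structural_network`.
#' @param symmetry_tol tolerance for the symmetry check.
#' @return `read_network` returns a [structural_network()];
#'   `read_regions` returns a data.frame.
#' @name network_io
NULL

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

read_matrix_file <- function(path) {
  sep <- sniff_delim(path)
  m <- as.matrix(read.table(path, header = FALSE, sep = sep,
                            colClasses = "numeric", comment.char = ""))
  dimnames(m) <- NULL
  m
}

placeholder_regions <- function(n) {
  data.frame(
    label = sprintf("region_%03d", seq_len(n)),
    x_mm = 0, y_mm = 0, z_mm = 0, volume = 1,
    system = "unassigned", stringsAsFactors = FALSE
  )
}

#' @rdname network_io
#' @export
read_network <- function(path, regions = NULL, symmetry_tol = 1e-8) {
  m <- read_matrix_file(path)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in '%s' must be square, got %d rows x %d columns",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  if (anyNA(m) || !all(is.finite(m))) {
    stop("matrix in '", path, "' contains NaN/NA/Inf entries", call. = FALSE)
  }
  if (is.character(regions)) regions <- read_regions(regions)
  if (is.null(regions)) regions <- placeholder_regions(nrow(m))
  structural_network(m, regions, symmetry_tol = symmetry_tol)
}

#' @rdname network_io
#' @param net a [structural_network()] or numeric matrix.
#' @param digits significant digits written (defaults to full precision).
#' @export
write_network <- function(net, path, digits = 17L) {
  m <- as_weights(net)
  lines <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname network_io
#' @export
read_regions <- function(path) {
  rs <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "", quote = "")
  validate_regions(rs)
  rs
}

#' @rdname network_io
#' @param rs region data.frame.
#' @export
write_regions <- function(rs, path) {
  validate_regions(rs)
  write.table(rs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
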