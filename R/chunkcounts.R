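# Chunkcount (coancestry) matrix container and ChromoPainter-dialect I/O.
#
# The chunkcount matrix is the square recipient x donor matrix produced by
# chromosome painting: entry (i, j) counts the genome "chunks" recipient i
# copied from donor j. The diagonal is zero (no self-copying).

#' Construct and validate a chunkcount matrix
#'
#' @param counts A square numeric matrix of nonnegative copy counts with a
#'   zero diagonal; entry (i, j) is the number of chunks recipient i copied
#'   from donor j.
#' @param ids Individual identifiers for the rows/columns; defaults to the
#'   matrix dimnames.
#' @return A numeric matrix of class `chunkcounts` with ids as dimnames.
#' @export
chunkcounts <- function(counts, ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(ids)) abort("chunkcount matrix needs individual ids.")
  ids <- as.character(ids)
  if (nrow(counts) != ncol(counts)) {
    abort(sprintf("chunkcount matrix must be square (got %d x %d).",
                  nrow(counts), ncol(counts)))
  }
  if (length(ids) != nrow(counts)) abort("`ids` length must match the matrix.")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!is.null(colnames(counts)) &&
      !identical(as.character(colnames(counts)), ids)) {
    if (!setequal(colnames(counts), ids)) {
      abort("row and column ids differ in content, not only order.")
    }
    counts <- counts[, ids, drop = FALSE]
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    abort("chunkcount matrix contains missing or non-finite entries.")
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    abort(sprintf("negative count for recipient '%s'.", ids[neg[1, 1]]))
  }
  bad_diag <- which(abs(diag(counts)) > 1e-6)
  if (length(bad_diag) > 0L) {
    abort(sprintf("nonzero diagonal for recipient '%s'.", ids[bad_diag[1]]))
  }
  diag(counts) <- 0
  dimnames(counts) <- list(ids, ids)
  structure(counts, class = c("chunkcounts", class(matrix())))
}

#' @export
print.chunkcounts <- function(x, ...) {
  cat(sprintf("<chunkcounts: %d individuals, total %s chunks>\n",
              nrow(x), format(sum(x))))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' Read a chunkcount matrix in the ChromoPainter dialect
#'
#' The format is whitespace-delimited: an optional leading comment line
#' starting with `#` (e.g. `#Cfactor ...`), a header row (`Recipient`
#' followed by the donor ids), then one row per recipient: id and integer
#' counts. Donor column order is reconciled to recipient row order by id.
#'
#' @param path Path to the chunkcounts file.
#' @return A [chunkcounts] matrix.
#' @export
read_chunkcounts <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && startsWith(lines[[1]], "#")) lines <- lines[-1]
  if (length(lines) < 2L) abort("chunkcounts file has no data rows.")
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  donors <- header[-1]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  ids <- vapply(rows, `[[`, character(1), 1L)
  counts <- matrix(NA_real_, length(rows), length(donors),
                   dimnames = list(ids, donors))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (length(vals) != length(donors) || anyNA(vals)) {
      abort(sprintf("malformed counts row for recipient '%s'.", ids[i]))
    }
    counts[i, ] <- vals
  }
  if (!setequal(ids, donors)) {
    abort("recipient ids and donor header do not name the same individuals.")
  }
  chunkcounts(counts[, ids, drop = FALSE], ids)
}

#' Write a chunkcount matrix in the ChromoPainter dialect
#'
#' @param x A [chunkcounts] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chunkcounts <- function(x, path) {
  ids <- rownames(x)
  header <- paste(c("Recipient", ids), collapse = " ")
  body <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], format(unclass(x)[i, ], trim = TRUE, scientific = FALSE)),
          collapse = " ")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
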