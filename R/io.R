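# Delimited-text matrix I/O and JSON result records.  Matrices round-trip
# losslessly: values are written with 17 significant digits, which is enough
# to reproduce any double bit-for-bit.

#' Read a matrix from comma-separated text
#'
#' Rows are lines, values comma-separated, row-major; an optional single
#' header row (non-numeric fields) is skipped.  Ragged rows are an error.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  parse_row <- function(ln) {
    fields <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[1])
  if (anyNA(first)) lines <- lines[-1]          # header row
  rows <- lapply(lines, parse_row)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    stop("malformed matrix (ragged rows) in ", path)
  }
  if (anyNA(unlist(rows))) stop("non-numeric value in matrix body of ", path)
  do.call(rbind, rows)
}

#' Write a matrix as comma-separated text
#'
#' @param x numeric matrix or vector (vectors become one column).
#' @param path file path.
#' @param digits significant digits (default 17: lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, digits = 17) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  fmt <- paste0("%.", digits, "g")
  lines <- apply(x, 1, function(r) paste(sprintf(fmt, r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

# 32-bit FNV-1a hash of a character scalar, with multiplication done in
# 16-bit halves to stay exact in double precision.  Used to stamp result
# records with a digest of their inputs.
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor_u32(h, b)
    h <- mul_u32(h, 16777619)
  }
  sprintf("%04x%04x", h %/% 2^16, h %% 2^16)
}

# unsigned 32-bit helpers on doubles
xor_u32 <- function(a, b) {
  ah <- a %/% 2^16; al <- a %% 2^16
  bh <- b %/% 2^16; bl <- b %% 2^16
  bitwXor(as.integer(ah), as.integer(bh)) * 2^16 +
    bitwXor(as.integer(al), as.integer(bl))
}
mul_u32 <- function(a, b) {
  al <- a %% 2^16; ah <- a %/% 2^16
  (al * b + ((ah * b) %% 2^16) * 2^16) %% 2^32
}

#' Hash of a set of numeric inputs
#'
#' Deterministic 32-bit digest of the 17-digit text serialization of the
#' inputs; stamped into JSON result records so outputs can be traced to the
#' exact matrices that produced them.
#'
#' @param ... numeric vectors/matrices (NULLs ignored).
#' @return 8-character hex string.
#' @export
inputs_hash <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  txt <- vapply(parts, function(p) {
    paste(sprintf("%.17g", as.numeric(p)), collapse = ",")
  }, character(1))
  .fnv1a(paste(txt, collapse = ";"))
}

#' Write a structured JSON result record
#'
#' Adds the package version and a timestamp, then writes the record with
#' unboxed scalars and full precision.
#'
#' @param record named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(record, path) {
  record$package_version <- as.character(utils::packageVersion("noisecorr"))
  record$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
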