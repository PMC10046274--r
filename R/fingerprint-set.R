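#' Construct a fingerprint set
#'
#' A fingerprint set holds the binary substructure fingerprints of a molecule
#' library: an `n x L` 0/1 matrix (one row per molecule) together with the
#' molecule identifiers and the fingerprint parameters. It is the common input
#' of the similarity, outlier-filtering and clustering functions.
#'
#' @param bits Integer or numeric matrix of 0s and 1s, one row per molecule.
#' @param ids Character vector of unique molecule identifiers, one per row.
#'   Defaults to row names of `bits`, or `m1, m2, ...` when absent.
#' @param radius Morgan radius used to compute the fingerprints, or `NA` when
#'   unknown (e.g. fingerprints read from an external file).
#' @param labels_true Optional vector of planted ("ground-truth") cluster
#'   labels, used by the synthetic-data generator and by validation tests.
#'   The value `"outlier"` marks planted outlier molecules.
#' @return An object of class `fingerprint_set`.
#' @examples
#' fps <- fingerprint_set(matrix(c(1, 0, 1, 1, 0, 0), nrow = 2, byrow = TRUE))
#' fps
#' @export
fingerprint_set <- function(bits, ids = NULL, radius = NA_integer_,
                            labels_true = NULL) {
  if (!is.matrix(bits)) abort_validation("`bits` must be a matrix.")
  storage.mode(bits) <- "integer"
  if (nrow(bits) > 0 && !all(bits == 0L | bits == 1L)) {
    abort_validation("`bits` must contain only 0s and 1s.")
  }
  if (ncol(bits) < 1) abort_validation("fingerprint length must be positive.")
  if (is.null(ids)) {
    ids <- rownames(bits) %||% sprintf("m%d", seq_len(nrow(bits)))
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(bits)) {
    abort_validation("`ids` must have one entry per fingerprint row.")
  }
  if (anyDuplicated(ids)) abort_validation("molecule ids must be unique.")
  if (!is.null(labels_true) && length(labels_true) != nrow(bits)) {
    abort_validation("`labels_true` must have one entry per molecule.")
  }
  dimnames(bits) <- NULL
  structure(
    list(ids = ids, bits = bits, n_bits = ncol(bits),
         radius = as.integer(radius), labels_true = labels_true),
    class = "fingerprint_set"
  )
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("<fingerprint_set> %d molecules x %d bits", nrow(x$bits), x$n_bits))
  if (!is.na(x$radius)) cat(sprintf(" (Morgan radius %d)", x$radius))
  if (!is.null(x$labels_true)) cat(", planted labels present")
  cat("\n")
  dens <- if (nrow(x$bits) > 0) mean(x$bits) else NA_real_
  cat(sprintf("  mean bit density: %s\n",
              ifelse(is.na(dens), "-", format(dens, digits = 3))))
  invisible(x)
}

#' @export
length.fingerprint_set <- function(x) nrow(x$bits)

#' Subset a fingerprint set by molecule
#'
#' @param x A [fingerprint_set()].
#' @param i Row index, logical mask or character vector of molecule ids.
#' @param ... Unused.
#' @return A `fingerprint_set` with the selected molecules, in the order given.
#' @export
`[.fingerprint_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) abort_validation("unknown molecule id in subset.")
  fingerprint_set(x$bits[i, , drop = FALSE], ids = x$ids[i],
                  radius = x$radius,
                  labels_true = if (is.null(x$labels_true)) NULL else x$labels_true[i])
}

#' @rdname fingerprint_set
#' @param x Object to test.
#' @export
is_fingerprint_set <- function(x) inherits(x, "fingerprint_set")

#' Tidy a fingerprint set into a per-molecule tibble
#'
#' @param x A [fingerprint_set()].
#' @param ... Unused.
#' @return A tibble with columns `id`, `n_on` (number of set bits) and, when
#'   planted labels are present, `label_true`.
#' @export
tidy.fingerprint_set <- function(x, ...) {
  out <- tibble::tibble(id = x$ids, n_on = as.integer(rowSums(x$bits)))
  if (!is.null(x$labels_true)) out$label_true <- x$labels_true
  out
}

# --- hex (de)serialisation -------------------------------------------------
# Bit i of a row maps to bit (i - 1) %% 8 of byte ceiling(i / 8), i.e. the
# first molecule bit is the least significant bit of the first byte. Rows are
# padded with zero bits to a whole number of bytes.

bits_to_hex <- function(row) {
  pad <- (-length(row)) %% 8
  raw <- packBits(as.logical(c(row, integer(pad))), type = "raw")
  paste(sprintf("%02x", as.integer(raw)), collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex) - 1, 2),
                            seq(2, nchar(hex), 2)), base = 16L)
  if (anyNA(bytes)) abort_format("invalid hex fingerprint string.")
  bits <- as.integer(rawToBits(as.raw(bytes)))
  if (length(bits) < n_bits) abort_format("hex string shorter than header n_bits.")
  if (any(bits[-seq_len(n_bits)] != 0L)) {
    abort_format("set bits beyond the declared fingerprint length.")
  }
  bits[seq_len(n_bits)]
}

#' Write / read fingerprint sets as plain-text TSV
#'
#' Fingerprints are stored in a diff-able, toolkit-independent TSV format: a
#' header comment line carrying the fingerprint length and Morgan radius,
#' followed by one row per molecule with the id and the hex-encoded bit
#' string (and the planted label, when present). `read_fingerprints()` is the
#' exact inverse of `write_fingerprints()`.
#'
#' @param fps A [fingerprint_set()].
#' @param path File path.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns a `fingerprint_set`.
#' @examples
#' fps <- fingerprint_set(matrix(rbinom(40, 1, 0.3), nrow = 5))
#' f <- tempfile(fileext = ".tsv")
#' write_fingerprints(fps, f)
#' identical(read_fingerprints(f)$bits, fps$bits)
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(is_fingerprint_set(fps))
  header <- sprintf("#molclust-fingerprints\tn_bits=%d\tradius=%s",
                    fps$n_bits,
                    ifelse(is.na(fps$radius), "NA", fps$radius))
  rows <- vapply(seq_len(nrow(fps$bits)),
                 function(i) bits_to_hex(fps$bits[i, ]), character(1))
  body <- paste(fps$ids, rows, sep = "\t")
  if (!is.null(fps$labels_true)) {
    body <- paste(body, fps$labels_true, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 1 || !startsWith(lines[[1]], "#molclust-fingerprints")) {
    abort_format("not a molclust fingerprint file (missing header).")
  }
  fields <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit) != 1) abort_format(sprintf("header field `%s` missing.", key))
    sub(paste0("^", key, "="), "", hit)
  }
  n_bits <- as.integer(get_field("n_bits"))
  radius <- suppressWarnings(as.integer(get_field("radius")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(fingerprint_set(matrix(integer(0), nrow = 0, ncol = n_bits),
                           ids = character(0), radius = radius))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2)) abort_format("fingerprint rows must have id and bits.")
  ids <- vapply(parts, `[[`, character(1), 1)
  hex <- vapply(parts, `[[`, character(1), 2)
  if (any(nchar(hex) != 2 * ceiling(n_bits / 8))) {
    abort_format("bit-width of a row does not match the header n_bits.")
  }
  bits <- t(vapply(hex, hex_to_bits, integer(n_bits), n_bits = n_bits))
  dimnames(bits) <- NULL
  labels_true <- if (all(ncols >= 3)) vapply(parts, `[[`, character(1), 3) else NULL
  fingerprint_set(bits, ids = ids, radius = radius, labels_true = labels_true)
}
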