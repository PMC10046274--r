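#' Read a molecule table
#'
#' Reads molecules (identifier + SMILES) from either a CSV file with columns
#' `id` and `smiles`, or a `.smi` file with whitespace-delimited
#' `SMILES [id]` lines (molecules without an id are numbered `mol<row>`).
#'
#' @param path File path.
#' @param format `"csv"` or `"smi"`. Guessed from the file extension when
#'   omitted.
#' @return A tibble with character columns `id` and `smiles`, in file order.
#' @export
read_molecule_table <- function(path, format = c("auto", "csv", "smi")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.smi$", path, ignore.case = TRUE)) "smi" else "csv"
  }
  if (format == "csv") {
    tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (!all(c("id", "smiles") %in% names(tab))) {
      abort_format("CSV molecule tables need columns `id` and `smiles`.")
    }
    tab <- tibble::tibble(id = tab$id, smiles = tab$smiles)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[[:space:]]+")
    tab <- tibble::tibble(
      id = vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) >= 2) parts[[i]][[2]] else paste0("mol", i)
      }, character(1)),
      smiles = vapply(parts, `[[`, character(1), 1)
    )
  }
  if (nrow(tab) == 0) abort_validation("molecule table is empty.")
  if (any(is.na(tab$smiles) | !nzchar(tab$smiles))) {
    abort_validation("every molecule needs a non-empty SMILES.")
  }
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate molecule ids: %s",
                             paste(utils::head(dup, 5), collapse = ", ")))
  }
  tab
}

# Locate the python interpreter used for the chemistry toolkit and the
# manifold embedding. Overridable via options(molclust.python = ...).
molclust_python <- function() {
  py <- getOption("molclust.python", Sys.which("python"))
  if (!nzchar(py)) {
    abort_environment("no `python` interpreter found; set options(molclust.python=).")
  }
  py
}

run_python <- function(code, args = character(0)) {
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script))
  writeLines(code, script)
  out <- suppressWarnings(
    system2(molclust_python(), c(script, args), stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    abort_environment(paste0("python helper failed:\n",
                             paste(utils::tail(out, 10), collapse = "\n")))
  }
  out
}

#' Compute Morgan fingerprints from SMILES
#'
#' Hashes circular substructures of each molecule into a fixed-length binary
#' fingerprint (Morgan / ECFP-style). Substructure enumeration and hashing are
#' delegated to the RDKit chemistry toolkit, driven through the system
#' `python`; this package only post-processes the resulting bit matrix.
#' Unparseable SMILES are skipped with a warning rather than aborting, since
#' real library exports routinely contain a few entries no toolkit accepts.
#'
#' @param molecules A data frame with character columns `id` and `smiles`
#'   (e.g. from [read_molecule_table()]).
#' @param radius Morgan radius (default 2, the ECFP4-equivalent setting).
#' @param n_bits Fingerprint length in bits (default 1024).
#' @return A [fingerprint_set()] with one row per parseable molecule, in input
#'   order, and an attribute `skipped` holding the ids that failed to parse.
#' @export
compute_fingerprints <- function(molecules, radius = 2L, n_bits = 1024L) {
  stopifnot(is.data.frame(molecules),
            all(c("id", "smiles") %in% names(molecules)))
  if (radius < 0) abort_validation("`radius` must be >= 0.")
  if (n_bits < 1) abort_validation("`n_bits` must be positive.")
  if (anyDuplicated(molecules$id)) abort_validation("molecule ids must be unique.")

  smi_file <- tempfile(fileext = ".tsv")
  out_file <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(smi_file, out_file)))
  readr::write_tsv(tibble::tibble(id = as.character(molecules$id),
                                  smiles = molecules$smiles),
                   smi_file, col_names = FALSE)

  code <- c(
    "import sys",
    "try:",
    "    from rdkit import Chem, RDLogger",
    "    from rdkit.Chem import AllChem",
    "except ImportError:",
    "    sys.exit(3)",
    "RDLogger.DisableLog('rdApp.*')",
    "inp, outp, radius, n_bits = sys.argv[1:5]",
    "radius, n_bits = int(radius), int(n_bits)",
    "with open(inp) as fh, open(outp, 'w') as oh:",
    "    for line in fh:",
    "        mid, smi = line.rstrip('\\n').split('\\t')",
    "        mol = Chem.MolFromSmiles(smi)",
    "        if mol is None:",
    "            oh.write(mid + '\\tNA\\n')",
    "            continue",
    "        fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=n_bits)",
    "        oh.write(mid + '\\t' + fp.ToBitString() + '\\n')"
  )
  run_python(code, c(smi_file, out_file, radius, n_bits))

  parsed <- readr::read_tsv(out_file, col_names = c("id", "bitstring"),
                            col_types = "cc", progress = FALSE)
  ok <- parsed$bitstring != "NA" & !is.na(parsed$bitstring)
  skipped <- parsed$id[!ok]
  if (!any(ok)) abort_validation("no SMILES could be parsed by the toolkit.")
  if (length(skipped) > 0) {
    rlang::warn(sprintf("skipped %d unparseable SMILES (%s%s)",
                        length(skipped),
                        paste(utils::head(skipped, 3), collapse = ", "),
                        if (length(skipped) > 3) ", ..." else ""))
  }
  bits <- t(vapply(strsplit(parsed$bitstring[ok], ""),
                   function(ch) as.integer(ch), integer(n_bits)))
  fps <- fingerprint_set(bits, ids = parsed$id[ok], radius = radius)
  attr(fps, "skipped") <- skipped
  fps
}
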