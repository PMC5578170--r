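#' Amino-acid physicochemical property table
#'
#' The six per-residue scales used to turn a protein sequence into a numeric
#' signal: hydrophobicity (`H`), side-chain volume (`VSC`, cubic Angstrom),
#' polarity (`P1`), polarizability (`P2`), solvent-accessible surface area
#' (`SASA`) and the net charge index of the side chain (`NCISC`). The raw
#' values ship with the package as a CSV
#' (`system.file("extdata", "aa_properties.csv", package = "dtiwave")`) and
#' may be overridden with a file of the same layout.
#'
#' @param path optional path to an alternative property CSV. The file must
#'   have an `amino_acid` column with the 20 standard one-letter codes and
#'   six numeric property columns.
#' @return a `physchem_table` object: a list with `raw` (20 x 6 numeric
#'   matrix, rownames = one-letter codes), `normalized` (same shape, each
#'   column centred and scaled; see [normalize_property_table()]),
#'   `properties` (column labels) and `sd_method`.
#' @seealso [normalize_property_table()], [encode_sequence()]
#' @export
aa_property_table <- function(path = NULL) {
  cache_key <- if (is.null(path)) ".default_property_table" else NULL
  if (!is.null(cache_key) && !is.null(.dtiwave_cache[[cache_key]])) {
    return(.dtiwave_cache[[cache_key]])
  }
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.csv", package = "dtiwave")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!"amino_acid" %in% names(raw)) {
    stop("property table must have an 'amino_acid' column", call. = FALSE)
  }
  aa <- toupper(raw$amino_acid)
  mat <- as.matrix(raw[, setdiff(names(raw), "amino_acid"), drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric entry in property table", call. = FALSE)
  rownames(mat) <- aa
  tab <- normalize_property_table(mat)
  if (!is.null(cache_key)) .dtiwave_cache[[cache_key]] <- tab
  tab
}

#' Column-normalize a raw property matrix
#'
#' Each property column j is centred by its mean over the 20 amino-acid
#' types and divided by its standard deviation:
#' \deqn{P'_{ij} = (P_{ij} - \bar{P}_j) / S_j.}
#' Because the normalization runs over the complete, fixed 20-letter
#' alphabet (not a sample from a larger population), the default standard
#' deviation is the population SD (divisor 20); `sd_method = "sample"`
#' switches to divisor 19.
#'
#' @param raw 20 x 6 numeric matrix, rownames = the standard one-letter
#'   amino-acid codes, one column per property.
#' @param sd_method `"population"` (default) or `"sample"`.
#' @return a `physchem_table` (see [aa_property_table()]).
#' @export
normalize_property_table <- function(raw, sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("raw property table must be a numeric matrix", call. = FALSE)
  }
  if (nrow(raw) != 20L || ncol(raw) != 6L) {
    stop(sprintf("property table must be 20 x 6, got %d x %d",
                 nrow(raw), ncol(raw)), call. = FALSE)
  }
  if (anyNA(raw)) stop("property table contains missing values", call. = FALSE)
  if (is.null(rownames(raw)) ||
      !setequal(rownames(raw), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("rownames must be the 20 standard one-letter amino-acid codes",
         call. = FALSE)
  }
  mu <- colMeans(raw)
  centred <- sweep(raw, 2L, mu, "-")
  n <- nrow(raw)
  ss <- colSums(centred^2)
  s <- if (sd_method == "population") sqrt(ss / n) else sqrt(ss / (n - 1L))
  if (any(s == 0)) {
    stop(sprintf("degenerate property scale: column(s) %s have zero variance",
                 paste(colnames(raw)[s == 0], collapse = ", ")), call. = FALSE)
  }
  normalized <- sweep(centred, 2L, s, "/")
  structure(
    list(raw = raw, normalized = normalized,
         properties = colnames(raw), sd_method = sd_method,
         column_means = mu, column_sds = s),
    class = "physchem_table")
}

#' @export
print.physchem_table <- function(x, ...) {
  cat("physicochemical property table: 20 amino acids x",
      length(x$properties), "properties\n")
  cat("properties:", paste(x$properties, collapse = ", "), "\n")
  cat("normalization: mean 0 /", x$sd_method, "SD per column\n")
  invisible(x)
}

# substitutions used by the "map" policy for ambiguity codes and the two
# rare genetically encoded residues; X and gaps have no sensible stand-in
# and are always dropped under "map"
.aa_substitutions <- c(B = "N", Z = "Q", J = "L", U = "C", O = "K")

#' Sanitize an amino-acid sequence string
#'
#' Upper-cases and strips whitespace, digits and common separator characters
#' (`*`, `-`, `.`). Non-standard residues are handled per `nonstandard`:
#' `"drop"` removes them with a warning, `"map"` substitutes the conventional
#' stand-in (B->N, Z->Q, J->L, U->C, O->K; X is dropped), `"error"` aborts.
#'
#' @param sequence character scalar.
#' @param nonstandard policy, one of `"drop"`, `"map"`, `"error"`.
#' @return character vector of single one-letter codes, all standard.
#' @export
sanitize_sequence <- function(sequence, nonstandard = c("drop", "map", "error")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- gsub("[[:space:][:digit:]*.-]", "", toupper(sequence))
  res <- strsplit(s, "")[[1]]
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- !(res %in% standard)
  if (any(bad)) {
    if (nonstandard == "error") {
      stop(sprintf("non-standard residue(s): %s",
                   paste(unique(res[bad]), collapse = ", ")), call. = FALSE)
    }
    if (nonstandard == "map") {
      mappable <- bad & res %in% names(.aa_substitutions)
      res[mappable] <- .aa_substitutions[res[mappable]]
      bad <- !(res %in% standard)
    }
    if (any(bad)) {
      warning(sprintf("dropping %d non-standard residue(s): %s",
                      sum(bad), paste(unique(res[bad]), collapse = ", ")),
              call. = FALSE)
      res <- res[!bad]
    }
  }
  res
}

#' Encode a protein sequence as a six-channel physicochemical signal
#'
#' Each retained residue becomes one row of an L x 6 matrix whose columns are
#' the normalized property values, in the fixed channel order of the property
#' table (H, VSC, P1, P2, SASA, NCISC). This matrix is the signal that the
#' wavelet feature extractor compresses.
#'
#' @param sequence amino-acid string (case-insensitive; whitespace/digits
#'   ignored).
#' @param table a `physchem_table`; defaults to the packaged one.
#' @param sequence_id optional identifier stored as an attribute.
#' @param nonstandard non-standard residue policy, see [sanitize_sequence()].
#' @return L x 6 numeric matrix of class `seq_signal`, with attributes
#'   `sequence_id` and `residues`.
#' @export
encode_sequence <- function(sequence, table = aa_property_table(),
                            sequence_id = NULL,
                            nonstandard = c("drop", "map", "error")) {
  stopifnot(inherits(table, "physchem_table"))
  res <- sanitize_sequence(sequence, nonstandard)
  if (length(res) == 0L) {
    stop("sequence is empty after sanitization", call. = FALSE)
  }
  m <- table$normalized[res, , drop = FALSE]
  rownames(m) <- NULL
  structure(m, class = c("seq_signal", class(m)),
            sequence_id = sequence_id, residues = res)
}

#' Read a multi-record protein FASTA file
#'
#' @param path FASTA file (wrapped lines allowed).
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path, width = 70L) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
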