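#' MACCS substructure fingerprint of a molecule
#'
#' Computes the 166-key MACCS fingerprint (presence/absence of the MDL
#' substructure dictionary) from a SMILES string via the OpenBabel bindings
#' in \pkg{ChemmineOB}. OpenBabel stores MACCS in a 256-bit container with
#' the key number as bit position; only keys 1-166 are returned, so bit `k`
#' of the result is MACCS key `k`. Bit-level parity across cheminformatics
#' toolkits (OpenBabel, RDKit, MDL) is close but not guaranteed; the backing
#' toolkit is recorded in the `source` attribute.
#'
#' @param smiles SMILES string of one molecule.
#' @param drug_id identifier stored on the result.
#' @param reject_empty reject molecules with zero atoms (default `TRUE`);
#'   when `FALSE` an empty molecule yields the all-zero vector.
#' @return integer vector of length 166 (0/1) with attributes `drug_id` and
#'   `source`.
#' @export
fingerprint_molecule <- function(smiles, drug_id = NULL, reject_empty = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB (OpenBabel bindings) is required to compute MACCS keys; ",
         "use load_fingerprint_table() for precomputed fingerprints",
         call. = FALSE)
  }
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) {
    if (reject_empty) stop("empty molecule rejected", call. = FALSE)
    return(.as_fingerprint(integer(166L), drug_id))
  }
  bits <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "MACCS"),
    error = function(e) stop(sprintf("cannot parse molecule%s: %s",
                                     if (is.null(drug_id)) "" else paste0(" ", drug_id),
                                     conditionMessage(e)), call. = FALSE))
  bits <- as.integer(bits[seq_len(166L)])
  if (reject_empty && sum(bits) == 0L && !grepl("[A-Za-z]", smiles)) {
    stop("empty molecule rejected", call. = FALSE)
  }
  .as_fingerprint(bits, drug_id)
}

.as_fingerprint <- function(bits, drug_id, source = "computed") {
  structure(bits, drug_id = drug_id, source = source,
            class = "drug_fingerprint")
}

#' @export
print.drug_fingerprint <- function(x, ...) {
  cat(sprintf("MACCS fingerprint%s: %d of 166 keys set (%s)\n",
              if (is.null(attr(x, "drug_id"))) "" else
                paste0(" of ", attr(x, "drug_id")),
              sum(unclass(x)), attr(x, "source")))
  invisible(x)
}

#' Fingerprint a SMILES file
#'
#' Reads a two-column file (`id<TAB>smiles`, no header) and fingerprints each
#' molecule. Unparsable records are skipped with a warning and listed in the
#' `failures` attribute so a long run is not aborted by one bad structure.
#'
#' @param path tab-separated file, one molecule per line.
#' @return integer matrix (n_drugs x 166, rownames = drug ids, colnames
#'   `maccs_1` ... `maccs_166`) with attribute `failures`.
#' @export
fingerprint_smiles_file <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("id", "smiles"))
  rows <- vector("list", nrow(df))
  failed <- character(0)
  for (i in seq_len(nrow(df))) {
    fp <- tryCatch(fingerprint_molecule(df$smiles[i], df$id[i]),
                   error = function(e) {
                     warning(sprintf("skipping %s: %s", df$id[i],
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    rows[[i]] <- fp
    if (is.null(fp)) failed <- c(failed, df$id[i])
  }
  keep <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, lapply(rows[keep], unclass))
  rownames(m) <- df$id[keep]
  colnames(m) <- paste0("maccs_", seq_len(166L))
  attr(m, "failures") <- failed
  m
}

#' Load / write a precomputed fingerprint table
#'
#' A fingerprint TSV has a `drug_id` column followed by exactly 166 binary
#' columns. Loading validates shape and binarity; the writer emits the same
#' layout, so write-then-load is the identity on the bit matrix.
#'
#' @param path TSV file.
#' @return integer matrix (n x 166, rownames = drug ids).
#' @export
load_fingerprint_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty fingerprint table: ", path, call. = FALSE)
    m <- matrix(integer(0), 0L, 166L,
                dimnames = list(NULL, paste0("maccs_", 1:166)))
    return(m)
  }
  if (ncol(df) != 167L) {
    stop(sprintf("fingerprint table must have 1 id + 166 bit columns, got %d",
                 ncol(df)), call. = FALSE)
  }
  m <- as.matrix(df[, -1L])
  bad <- which(!(m == 0L | m == 1L), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("non-binary fingerprint entry at row %d (drug %s)",
                 bad[1L, "row"], df[[1L]][bad[1L, "row"]]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  colnames(m) <- paste0("maccs_", seq_len(166L))
  m
}

#' @rdname load_fingerprint_table
#' @param x integer matrix (n x 166) with drug ids as rownames.
#' @export
write_fingerprint_table <- function(x, path) {
  stopifnot(is.matrix(x), ncol(x) == 166L, !is.null(rownames(x)))
  df <- data.frame(drug_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1L] <- paste0("maccs_", seq_len(166L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
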