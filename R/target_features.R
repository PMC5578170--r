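#' Feature layout of the wavelet target descriptor
#'
#' Enumerates, in a fixed order, every entry of the target feature vector:
#' for each physicochemical channel and each decomposition level, four band
#' statistics (max, min, mean, SD) of the approximation and of the detail
#' band, followed by the leading DCT coefficients of the approximation
#' band(s). Under the defaults (6 channels, 4 levels, both bands, 4
#' statistics, 5 DCT coefficients per level) the length is
#' 6*4*2*4 + 6*4*5 = 312.
#'
#' @param channels channel labels (default the six property names).
#' @param levels decomposition depth.
#' @param n_dct leading DCT coefficients kept per approximation band.
#' @param dct_scope `"all"` (DCT of the approximation band at every level) or
#'   `"last"` (deepest level only).
#' @return data.frame with columns `index`, `kind` (`"stat"`/`"dct"`),
#'   `channel`, `level`, `band`, `stat` (or DCT coefficient number) and a
#'   unique `name` per entry.
#' @export
target_feature_layout <- function(channels = c("H", "VSC", "P1", "P2", "SASA", "NCISC"),
                                  levels = 4L, n_dct = 5L,
                                  dct_scope = c("all", "last")) {
  dct_scope <- match.arg(dct_scope)
  stats <- c("max", "min", "mean", "sd")
  bands <- c("approx", "detail")
  rows <- list()
  for (ch in channels) for (l in seq_len(levels)) for (b in bands) for (s in stats) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "stat", channel = ch, level = l, band = b, stat = s,
      stringsAsFactors = FALSE)
  }
  dct_levels <- if (dct_scope == "all") seq_len(levels) else levels
  for (ch in channels) for (l in dct_levels) for (k in seq_len(n_dct)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "dct", channel = ch, level = l, band = "approx",
      stat = paste0("c", k), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$index <- seq_len(nrow(out))
  out$name <- sprintf("t_%s_l%d_%s_%s", out$channel, out$level, out$band, out$stat)
  out[, c("index", "kind", "channel", "level", "band", "stat", "name")]
}

#' Band statistics of a wavelet decomposition
#'
#' For every (level, band) pair of a single-channel decomposition, the four
#' summary statistics max, min, mean and SD, in that order. The SD follows
#' the sample convention (divisor n - 1) by default; a band with a single
#' coefficient gets SD 0.
#'
#' @param decomp a `dwt_decomposition` (see [dwt_decompose()]).
#' @param sd_method `"sample"` (default) or `"population"`.
#' @return numeric matrix with `2 * levels` rows (level-major, approximation
#'   band first) and columns `max`, `min`, `mean`, `sd`.
#' @export
band_statistics <- function(decomp, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  stopifnot(inherits(decomp, "dwt_decomposition"))
  out <- matrix(NA_real_, nrow = 2L * decomp$levels, ncol = 4L,
                dimnames = list(NULL, c("max", "min", "mean", "sd")))
  rn <- character(2L * decomp$levels)
  r <- 0L
  for (l in seq_len(decomp$levels)) {
    for (b in c("approx", "detail")) {
      cf <- decomp[[b]][[l]]
      if (length(cf) == 0L) stop("empty coefficient band", call. = FALSE)
      r <- r + 1L
      out[r, ] <- c(max(cf), min(cf), mean(cf), .band_sd(cf, sd_method))
      rn[r] <- sprintf("l%d_%s", l, b)
    }
  }
  rownames(out) <- rn
  out
}

.band_sd <- function(cf, sd_method) {
  n <- length(cf)
  if (n == 1L) return(0)
  if (sd_method == "sample") sd(cf) else sqrt(sum((cf - mean(cf))^2) / n)
}

#' Wavelet + DCT feature vector of one protein target
#'
#' Runs the multi-level DWT independently on each of the six physicochemical
#' channels of an encoded sequence, then assembles band statistics and the
#' leading DCT coefficients of the approximation bands into a fixed-length
#' vector ordered by [target_feature_layout()]. A sequence too short for the
#' requested depth is decomposed to the maximum feasible depth and the
#' missing bands' features are zero-filled (with a warning), so feature
#' matrices stay rectangular.
#'
#' @param signal an L x 6 `seq_signal` matrix from [encode_sequence()] (any
#'   numeric L x C matrix is accepted).
#' @param wavelet,levels,mode passed to [dwt_decompose()].
#' @param n_dct,dct_scope passed to the DCT block, see
#'   [target_feature_layout()].
#' @param sd_method band-SD convention, see [band_statistics()].
#' @return named numeric vector (length 312 under defaults) with the layout
#'   data.frame attached as attribute `layout`.
#' @export
target_features <- function(signal, wavelet = "db4", levels = 4L,
                            mode = "symmetric", n_dct = 5L,
                            dct_scope = c("all", "last"),
                            sd_method = c("sample", "population")) {
  dct_scope <- match.arg(dct_scope)
  sd_method <- match.arg(sd_method)
  stopifnot(is.matrix(signal), is.numeric(signal))
  channels <- colnames(signal)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(signal)))
  layout <- target_feature_layout(channels, levels, n_dct, dct_scope)
  feasible <- min(levels, dwt_max_levels(nrow(signal), wavelet, mode))
  if (feasible < 1L) {
    stop(sprintf("sequence of length %d too short for wavelet '%s'",
                 nrow(signal), wavelet), call. = FALSE)
  }
  if (feasible < levels) {
    warning(sprintf(
      "sequence of length %d supports %d of %d levels; deeper bands zero-filled",
      nrow(signal), feasible, levels), call. = FALSE)
  }
  vec <- numeric(nrow(layout))
  dct_levels <- if (dct_scope == "all") seq_len(levels) else levels
  for (ci in seq_along(channels)) {
    dec <- dwt_decompose(signal[, ci], wavelet, feasible, mode)
    st <- band_statistics(dec, sd_method)
    for (l in seq_len(feasible)) {
      for (b in c("approx", "detail")) {
        sel <- layout$kind == "stat" & layout$channel == channels[ci] &
          layout$level == l & layout$band == b
        vec[layout$index[sel]] <- st[sprintf("l%d_%s", l, b), ]
      }
      if (l %in% dct_levels) {
        sel <- layout$kind == "dct" & layout$channel == channels[ci] &
          layout$level == l
        vec[layout$index[sel]] <- suppressWarnings(dct_head(dec$approx[[l]], n_dct))
      }
    }
  }
  names(vec) <- layout$name
  attr(vec, "layout") <- layout
  vec
}

#' Featurize a set of protein sequences
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param table property table, see [aa_property_table()].
#' @param nonstandard non-standard residue policy, see [sanitize_sequence()].
#' @param ... passed to [target_features()].
#' @return numeric matrix, one row per sequence (rownames = sequence ids),
#'   one column per layout entry.
#' @export
featurize_targets <- function(sequences, table = aa_property_table(),
                              nonstandard = "drop", ...) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  rows <- lapply(seq_along(sequences), function(i) {
    sig <- encode_sequence(sequences[[i]], table, names(sequences)[i],
                           nonstandard)
    target_features(sig, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(sequences)
  out
}

#' Write / read a feature matrix as TSV
#'
#' The header row carries the layout names so a written matrix can be
#' re-loaded without recomputation.
#'
#' @param x numeric matrix with rownames (ids) and colnames (feature names).
#' @param path file path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
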