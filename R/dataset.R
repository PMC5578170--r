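#' Balanced pair datasets by negative sub-sampling
#'
#' Each subset contains every known interaction as a positive plus an
#' equal-sized uniform sample (without replacement, independent across
#' subsets) of unknown pairs as negatives. This mirrors the balanced
#' evaluation regime in which ten such subsets are drawn per network.
#'
#' @param network a `dti_network`.
#' @param n_subsets number of balanced subsets (default 10).
#' @param seed RNG seed (local to this call).
#' @return list of data.frames (`drug_id`, `target_id`, `label` in
#'   \{-1, +1\}), positives first.
#' @export
build_balanced <- function(network, n_subsets = 10L, seed = 1L) {
  stopifnot(inherits(network, "dti_network"))
  pos_idx <- which(network$adjacency == 1L, arr.ind = TRUE)
  if (nrow(pos_idx) == 0L) stop("network has no interactions", call. = FALSE)
  positives <- data.frame(drug_id = network$drug_ids[pos_idx[, 1L]],
                          target_id = network$target_ids[pos_idx[, 2L]],
                          label = 1L, stringsAsFactors = FALSE)
  unk <- unknown_pairs(network)
  if (nrow(unk) < nrow(positives)) {
    stop(sprintf("only %d unknown pairs but %d positives; cannot balance",
                 nrow(unk), nrow(positives)), call. = FALSE)
  }
  withr_seed <- .local_seed(seed)
  on.exit(withr_seed())
  lapply(seq_len(n_subsets), function(s) {
    neg <- unk[sample.int(nrow(unk), nrow(positives)), ]
    neg$label <- -1L
    out <- rbind(positives, neg)
    rownames(out) <- NULL
    out
  })
}

#' Imbalanced pair dataset: every pair, labeled by adjacency
#'
#' @param network a `dti_network`.
#' @return data.frame (`drug_id`, `target_id`, `label`) with exactly
#'   `n_drugs * n_targets` rows; known interactions +1, all others -1.
#' @export
build_imbalanced <- function(network) {
  stopifnot(inherits(network, "dti_network"))
  grid <- expand.grid(target_id = network$target_ids,
                      drug_id = network$drug_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("drug_id", "target_id")]
  lab <- network$adjacency[cbind(match(grid$drug_id, network$drug_ids),
                                 match(grid$target_id, network$target_ids))]
  grid$label <- ifelse(lab == 1L, 1L, -1L)
  if (all(grid$label == 1L)) {
    warning("fully connected network: no negative pairs", call. = FALSE)
  }
  rownames(grid) <- NULL
  grid
}

#' Assemble the feature matrix for a set of pairs
#'
#' Concatenates, per pair and in this fixed block order: the target's
#' wavelet feature vector, the pair's interaction-profile feature from
#' `network`, and the drug's MACCS fingerprint. The resulting width is
#' `ncol(target_feats) + (n_t - 1) + (n_d - 1) + 166`.
#'
#' @param pairs data.frame with `drug_id`, `target_id` (and optionally
#'   `label`).
#' @param target_feats matrix from [featurize_targets()], rownames = target
#'   ids.
#' @param fingerprints matrix (n_drugs x 166), rownames = drug ids.
#' @param network the `dti_network` used for net features (mask test edges
#'   first during cross-validation).
#' @return numeric matrix, one row per pair; attribute `blocks` records the
#'   column span of each feature block.
#' @export
pair_feature_matrix <- function(pairs, target_feats, fingerprints, network) {
  ti <- match(as.character(pairs$target_id), rownames(target_feats))
  di <- match(as.character(pairs$drug_id), rownames(fingerprints))
  if (anyNA(ti)) stop("pair references target without features: ",
                      pairs$target_id[which(is.na(ti))[1L]], call. = FALSE)
  if (anyNA(di)) stop("pair references drug without fingerprint: ",
                      pairs$drug_id[which(is.na(di))[1L]], call. = FALSE)
  tf <- target_feats[ti, , drop = FALSE]
  nf <- net_feature_matrix(network, pairs)
  fp <- fingerprints[di, , drop = FALSE]
  out <- cbind(tf, nf, fp)
  rownames(out) <- paste(pairs$drug_id, pairs$target_id, sep = "|")
  attr(out, "blocks") <- c(target = ncol(tf), net = ncol(nf),
                           maccs = ncol(fp))
  out
}

#' Stratified cross-validation folds
#'
#' @param labels vector of +1/-1 labels.
#' @param k number of folds.
#' @param seed RNG seed (local).
#' @return list of integer vectors (test indices per fold); folds partition
#'   the samples and preserve the class ratio to within one sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, length(labels) >= k)
  restore <- .local_seed(seed)
  on.exit(restore())
  fold_of <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

# run code under a fixed seed, then restore the caller's RNG state
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
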