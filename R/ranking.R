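#' Rank unknown drug-target pairs as candidate novel interactions
#'
#' Trains on a balanced dataset built from all known interactions (positives
#' plus an equal uniform sample of unknown pairs), then scores the remaining
#' unknown pairs and returns them sorted by score. Ties are broken
#' deterministically by (drug_id, target_id) lexicographic order. Scores are
#' Platt-scaled interaction probabilities by default (`calibrate = TRUE`)
#' or raw decision values.
#'
#' @param network a `dti_network`.
#' @param target_feats wavelet feature matrix, rownames = target ids.
#' @param fingerprints MACCS bit matrix, rownames = drug ids.
#' @param top_n how many top-ranked pairs to return (default 5; capped at
#'   the number of scored pairs).
#' @param seed RNG seed for the negative draw.
#' @param selection,k,step_fraction,corr_threshold feature-selection
#'   controls, see [evaluate_cv()].
#' @param cost,gamma SVM hyperparameters, see [dti_train()].
#' @param calibrate score by Platt-scaled probability (default) instead of
#'   decision value.
#' @param exclude_training_negatives drop the sampled training negatives
#'   from the ranked list (default `TRUE`: only pairs the model never saw
#'   are ranked).
#' @param score_table_path optional path: the full ranked table is written
#'   there as TSV.
#' @return data.frame `rank`, `drug_id`, `target_id`, `score` of the top
#'   `top_n` pairs, with the full table as attribute `full_table` and the
#'   fitted `dti_model` as attribute `model`.
#' @export
rank_novel_pairs <- function(network, target_feats, fingerprints, top_n = 5L,
                             seed = 1L, selection = TRUE, k = 200L,
                             step_fraction = 0.1, corr_threshold = 0.9,
                             cost = 8, gamma = NULL, calibrate = TRUE,
                             exclude_training_negatives = TRUE,
                             score_table_path = NULL) {
  stopifnot(inherits(network, "dti_network"))
  train_pairs <- build_balanced(network, n_subsets = 1L, seed = seed)[[1L]]
  X_train <- pair_feature_matrix(train_pairs, target_feats, fingerprints,
                                 network)
  y <- train_pairs$label
  usable <- which(apply(X_train, 2L, sd) > 0)
  sel_global <- usable
  if (selection) {
    rk <- svm_rfe_cbr(X_train[, usable, drop = FALSE], y,
                      step_fraction = step_fraction,
                      corr_threshold = corr_threshold)
    sel_local <- select_top_k(rk, k, X_train[, usable, drop = FALSE], y,
                              seed = seed)
    sel_global <- usable[sel_local]
  }
  model <- dti_train(X_train, y, selected = sel_global, cost = cost,
                     gamma = gamma, probability = calibrate, seed = seed)

  candidates <- unknown_pairs(network)
  if (exclude_training_negatives) {
    neg <- train_pairs[train_pairs$label == -1L, ]
    used <- paste(neg$drug_id, neg$target_id)
    candidates <- candidates[!(paste(candidates$drug_id,
                                     candidates$target_id) %in% used), ]
  }
  if (nrow(candidates) == 0L) {
    warning("no unknown pairs left to rank", call. = FALSE)
    return(data.frame(rank = integer(0), drug_id = character(0),
                      target_id = character(0), score = numeric(0)))
  }
  X_cand <- pair_feature_matrix(candidates, target_feats, fingerprints,
                                network)
  score <- predict(model, X_cand,
                   type = if (calibrate) "probability" else "decision")
  tab <- data.frame(drug_id = candidates$drug_id,
                    target_id = candidates$target_id, score = score,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$drug_id, tab$target_id), ]
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c("rank", "drug_id", "target_id", "score")]
  rownames(tab) <- NULL
  if (!is.null(score_table_path)) {
    write.table(tab, score_table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out <- head(tab, min(top_n, nrow(tab)))
  attr(out, "full_table") <- tab
  attr(out, "model") <- model
  out
}
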