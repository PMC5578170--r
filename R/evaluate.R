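#' Cross-validated evaluation of the DTI predictor
#'
#' Runs the full leakage-safe protocol. Per fold: the positive test pairs
#' are masked out of the interaction network (so interaction-profile
#' features never see held-out labels), features are assembled from the
#' masked network, constant columns are dropped and, optionally, SVM-RFE+CBR
#' feature selection is fit on the training rows only; an RBF-SVM is trained
#' and the test fold is scored by decision values. ACC/sensitivity/
#' specificity are computed at decision threshold 0, AUC and AUPR from the
#' continuous scores.
#'
#' Regimes: `"balanced-5fold"` draws `n_subsets` balanced datasets
#' (all positives + equal sampled negatives) and cross-validates each with 5
#' folds; `"imbalanced-10fold"` uses every drug-target pair once with 10
#' folds.
#'
#' @param network a `dti_network` with the known interactions.
#' @param target_feats wavelet feature matrix from [featurize_targets()].
#' @param fingerprints MACCS bit matrix (rownames = drug ids).
#' @param regime `"balanced-5fold"` or `"imbalanced-10fold"`.
#' @param n_subsets balanced subsets to draw (balanced regime only).
#' @param seed master seed; subset draws, folds and inner searches derive
#'   from it.
#' @param selection run SVM-RFE+CBR inside each training fold?
#' @param k feature-subset size passed to [select_top_k()] (integer or
#'   `"auto"`).
#' @param step_fraction,corr_threshold RFE parameters, see [svm_rfe_cbr()].
#' @param cost,gamma SVM hyperparameters (or `"grid"`), see [dti_train()].
#' @param mask_test_net mask test-fold edges before computing net features
#'   (default `TRUE`; `FALSE` reproduces the permissive protocol in which
#'   profiles see the full network).
#' @param permute_labels permute labels before cross-validation — a null
#'   control that should score near AUC 0.5.
#' @return a `dti_evaluation`: list with `folds` (per-fold metric rows),
#'   `summary` (mean and SD per metric), `pooled` (scores and labels across
#'   folds), `roc`, `pr` (pooled curve points) and `params`.
#' @export
evaluate_cv <- function(network, target_feats, fingerprints,
                        regime = c("balanced-5fold", "imbalanced-10fold"),
                        n_subsets = 10L, seed = 1L, selection = TRUE,
                        k = 200L, step_fraction = 0.1, corr_threshold = 0.9,
                        cost = 8, gamma = NULL, mask_test_net = TRUE,
                        permute_labels = FALSE) {
  regime <- match.arg(regime)
  stopifnot(inherits(network, "dti_network"))
  n_folds <- if (regime == "balanced-5fold") 5L else 10L
  datasets <- if (regime == "balanced-5fold") {
    build_balanced(network, n_subsets, seed = seed)
  } else {
    list(build_imbalanced(network))
  }

  fold_rows <- list()
  pooled_scores <- numeric(0)
  pooled_labels <- integer(0)
  skipped <- 0L
  for (si in seq_along(datasets)) {
    pairs <- datasets[[si]]
    labels <- pairs$label
    if (permute_labels) {
      restore <- .local_seed(seed + 7919L * si)
      labels <- sample(labels)
      restore()
    }
    folds <- stratified_folds(labels, n_folds, seed = seed + si)
    for (fi in seq_along(folds)) {
      te <- folds[[fi]]
      if (length(unique(labels[te])) < 2L) {
        warning(sprintf("subset %d fold %d has one class in test; skipped",
                        si, fi), call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      net_for_features <- if (mask_test_net) {
        mask_test_edges(network, pairs[te, ][labels[te] == 1L, ])
      } else {
        network
      }
      X <- pair_feature_matrix(pairs, target_feats, fingerprints,
                               net_for_features)
      y_tr <- labels[-te]
      usable <- which(apply(X[-te, , drop = FALSE], 2L, sd) > 0)
      sel_global <- usable
      if (selection) {
        rk <- svm_rfe_cbr(X[-te, usable, drop = FALSE], y_tr,
                          step_fraction = step_fraction,
                          corr_threshold = corr_threshold)
        sel_local <- select_top_k(rk, k, X[-te, usable, drop = FALSE], y_tr,
                                  seed = seed + fi)
        sel_global <- usable[sel_local]
      }
      model <- dti_train(X[-te, , drop = FALSE], y_tr, selected = sel_global,
                         cost = cost, gamma = gamma, probability = FALSE,
                         seed = seed + fi)
      dv <- predict(model, X[te, , drop = FALSE])
      row <- score_fold(dv, labels[te])
      row$subset <- si
      row$fold <- fi
      row$k <- length(sel_global)
      fold_rows[[length(fold_rows) + 1L]] <- row
      pooled_scores <- c(pooled_scores, dv)
      pooled_labels <- c(pooled_labels, labels[te])
    }
  }
  if (length(fold_rows) == 0L) stop("all folds skipped", call. = FALSE)
  folds_df <- do.call(rbind, fold_rows)
  metrics <- c("acc", "sn", "spec", "auc", "aupr")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_df[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) sd(folds_df[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(
    list(folds = folds_df, summary = summary,
         pooled = list(scores = pooled_scores, labels = pooled_labels),
         roc = roc_points(pooled_scores, pooled_labels),
         pr = pr_points(pooled_scores, pooled_labels),
         skipped_folds = skipped,
         params = list(regime = regime, n_subsets = n_subsets, seed = seed,
                       selection = selection, k = k,
                       step_fraction = step_fraction,
                       corr_threshold = corr_threshold, cost = cost,
                       gamma = gamma, mask_test_net = mask_test_net,
                       permute_labels = permute_labels)),
    class = "dti_evaluation")
}

#' @export
print.dti_evaluation <- function(x, ...) {
  p <- x$params
  cat(sprintf("DTI cross-validation (%s%s, seed %d, %d fold rows)\n",
              p$regime,
              if (p$regime == "balanced-5fold")
                sprintf(", %d subsets", p$n_subsets) else "",
              p$seed, nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.3f +/- %.3f\n", toupper(s$metric[i]),
                s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `summary.json` (per-metric mean/SD plus parameters), `folds.tsv`
#' (per-fold rows) and `roc.tsv` / `pr.tsv` curve points for plotting.
#'
#' @param evaluation a `dti_evaluation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(evaluation, dir) {
  stopifnot(inherits(evaluation, "dti_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_json(list(summary = evaluation$summary,
                  skipped_folds = evaluation$skipped_folds,
                  params = evaluation$params),
             file.path(dir, "summary.json"), auto_unbox = TRUE,
             pretty = TRUE, digits = NA)
  write.table(evaluation$folds, file.path(dir, "folds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(evaluation$roc, file.path(dir, "roc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(evaluation$pr, file.path(dir, "pr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
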