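#' SVM recursive feature elimination with correlation bias reduction
#'
#' Ranks features by iterating: fit a linear SVM on the surviving features,
#' score feature j by its squared weight \eqn{w_j^2}, correct correlation
#' bias, and eliminate the lowest-scoring fraction. The correlation bias
#' reduction (CBR) step groups surviving features whose absolute pairwise
#' Pearson correlation exceeds `corr_threshold` (transitively, i.e.
#' connected components of the correlation graph) and assigns every group
#' member the group's best score, so that sets of mutually redundant but
#' informative features are not eliminated prematurely just because the SVM
#' spreads weight across them. Ranks are assigned in reverse elimination
#' order: the last survivors rank best. The ranking SVM is linear — the
#' explicit weight vector is what the \eqn{w^2} criterion needs — even when
#' the downstream classifier is kernelized.
#'
#' @param X numeric sample x feature matrix (standardized internally;
#'   constant columns are rejected).
#' @param y labels in \{-1, +1\} (anything coercible to two classes).
#' @param step_fraction fraction of survivors eliminated per iteration
#'   (default 0.1; at least one feature is always eliminated).
#' @param corr_threshold absolute-correlation threshold for CBR grouping
#'   (default 0.9); set `cbr = FALSE` to disable the correction.
#' @param cost linear-SVM cost parameter.
#' @param cbr apply the correlation correction? (default `TRUE`)
#' @return an `rfe_ranking`: list with `ranks` (integer vector, `ranks[j]` =
#'   rank of feature j, 1 = best), `ordering` (feature indices best-first),
#'   `history` (data.frame of iteration, n_surviving, removed indices,
#'   criterion at removal) and the call parameters.
#' @export
svm_rfe_cbr <- function(X, y, step_fraction = 0.1, corr_threshold = 0.9,
                        cost = 1, cbr = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (min(table(y)) < 2L) stop("need >= 2 samples per class", call. = FALSE)
  p <- ncol(X)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant feature(s) must be filtered first: %s",
                 paste(head(which(sds == 0), 5L), collapse = ", ")),
         call. = FALSE)
  }
  Xs <- scale(X)

  surviving <- seq_len(p)
  elim_order <- integer(0)          # first eliminated .. last eliminated
  hist_rows <- list()
  iter <- 0L
  while (length(surviving) > 1L) {
    iter <- iter + 1L
    fit <- svm(Xs[, surviving, drop = FALSE], y, kernel = "linear",
               cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    score <- w^2
    adj <- score
    if (cbr && length(surviving) > 2L) {
      grp <- .correlation_groups(Xs[, surviving, drop = FALSE], corr_threshold)
      adj <- vapply(seq_along(score),
                    function(j) max(score[grp == grp[j]]), numeric(1))
    }
    n_remove <- max(1L, floor(step_fraction * length(surviving)))
    n_remove <- min(n_remove, length(surviving) - 1L)
    # lowest adjusted score out first; ties broken by raw score then index
    ord <- order(adj, score, seq_along(adj))
    drop_local <- ord[seq_len(n_remove)]
    removed <- surviving[drop_local]
    hist_rows[[iter]] <- data.frame(
      iteration = iter, n_surviving = length(surviving),
      removed = I(list(removed)), criterion = I(list(score[drop_local])))
    # record least important first within the batch
    elim_order <- c(elim_order, removed[order(adj[drop_local], score[drop_local])])
    surviving <- surviving[-drop_local]
  }
  # final survivor is the best-ranked feature
  full_order <- c(elim_order, surviving)       # worst .. best
  ranks <- integer(p)
  ranks[full_order] <- p:1L
  structure(list(ranks = ranks, ordering = rev(full_order),
                 history = do.call(rbind, hist_rows),
                 step_fraction = step_fraction,
                 corr_threshold = if (cbr) corr_threshold else NA_real_,
                 cbr = cbr, cost = cost),
            class = "rfe_ranking")
}

# connected components of the |cor| > threshold graph, via union-find
.correlation_groups <- function(X, threshold) {
  p <- ncol(X)
  cm <- suppressWarnings(abs(cor(X)))
  cm[is.na(cm)] <- 0
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  hits <- which(cm > threshold & upper.tri(cm), arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    a <- find(hits[k, 1L])
    b <- find(hits[k, 2L])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(p), find, integer(1))
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat(sprintf("SVM-RFE%s ranking of %d features (%d iterations, step %.0f%%)\n",
              if (x$cbr) "+CBR" else "", length(x$ranks),
              nrow(x$history), 100 * x$step_fraction))
  cat("top 10:", paste(head(x$ordering, 10L), collapse = ", "), "\n")
  invisible(x)
}

#' Select the top-k ranked features
#'
#' With numeric `k`, simply the `k` best-ranked feature indices. With
#' `k = "auto"`, candidate sizes on a log2 grid are compared by inner
#' cross-validated AUC of a linear SVM on the supplied (training) data and
#' the smallest size within one SD of the best mean AUC is chosen.
#'
#' @param ranking an `rfe_ranking`.
#' @param k integer, or `"auto"`.
#' @param X,y training data (required for `"auto"`).
#' @param inner_folds folds for the inner CV (default 3).
#' @param cost linear-SVM cost for the inner CV.
#' @param seed RNG seed for the inner folds.
#' @return integer vector of selected feature indices (best rank first) with
#'   attributes `k` and, in auto mode, `k_grid` and `k_auc`.
#' @export
select_top_k <- function(ranking, k = "auto", X = NULL, y = NULL,
                         inner_folds = 3L, cost = 1, seed = 1L) {
  stopifnot(inherits(ranking, "rfe_ranking"))
  p <- length(ranking$ranks)
  if (identical(k, "auto")) {
    if (is.null(X) || is.null(y)) {
      stop("k = 'auto' needs training data X and y", call. = FALSE)
    }
    grid <- unique(pmin(p, c(2^seq(3L, ceiling(log2(p))), p)))
    aucs <- matrix(NA_real_, length(grid), inner_folds)
    y <- factor(y)
    folds <- stratified_folds(as.integer(as.character(y)), inner_folds, seed)
    for (gi in seq_along(grid)) {
      sel <- ranking$ordering[seq_len(grid[gi])]
      for (f in seq_along(folds)) {
        te <- folds[[f]]
        fit <- svm(X[-te, sel, drop = FALSE], y[-te], kernel = "linear",
                   cost = cost, scale = TRUE)
        dv <- .decision_values(fit, X[te, sel, drop = FALSE])
        aucs[gi, f] <- auc_roc(dv, as.integer(as.character(y[te])))
      }
    }
    mean_auc <- rowMeans(aucs)
    best <- which.max(mean_auc)
    sd_best <- sd(aucs[best, ])
    eligible <- which(mean_auc >= mean_auc[best] - sd_best)
    k <- grid[min(eligible)]
    sel <- ranking$ordering[seq_len(k)]
    attr(sel, "k") <- k
    attr(sel, "k_grid") <- grid
    attr(sel, "k_auc") <- mean_auc
    return(sel)
  }
  k <- as.integer(k)
  if (k < 1L || k > p) stop("k out of range", call. = FALSE)
  sel <- ranking$ordering[seq_len(k)]
  attr(sel, "k") <- k
  sel
}
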