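# orient libsvm decision values so larger = class "+1"
.decision_values <- function(fit, newdata) {
  dv <- attr(predict(fit, newdata, decision.values = TRUE), "decision.values")
  out <- dv[, 1L]
  lab <- colnames(dv)[1L]
  # column name "A/B": positive value votes for class A
  if (!is.null(lab) && strsplit(lab, "/")[[1L]][1L] %in% c("-1", "FALSE", "0")) {
    out <- -out
  }
  unname(out)
}

#' Train the RBF-kernel SVM classifier
#'
#' Z-scores each feature with statistics learned from the training rows
#' (zero-variance features get scale 1, so binary fingerprint and profile
#' columns pass through safely), optionally restricts to a selected feature
#' subset, and fits a C-SVM with an RBF kernel
#' \eqn{K(x, x') = \exp(-\gamma \|x - x'\|^2)}. With `cost = "grid"` or
#' `gamma = "grid"` an inner cross-validated grid search (powers of 4 over
#' \eqn{C \in 2^{-5}..2^{15}}, \eqn{\gamma \in 2^{-15}..2^{3}}) maximizes
#' AUC on the training data.
#'
#' @param X numeric sample x feature matrix (training rows only).
#' @param y labels in \{-1, +1\}.
#' @param selected integer vector of feature column indices (default all).
#' @param cost SVM cost C, or `"grid"`.
#' @param gamma RBF width, `NULL` for 1/n_features, or `"grid"`.
#' @param probability fit Platt-scaled probability estimates on the training
#'   data (needed for probability-ranked novel pairs).
#' @param inner_folds folds for the grid search.
#' @param seed RNG seed for the grid-search folds.
#' @return a `dti_model`: list with the fitted `svm`, `center`/`scale`
#'   vectors, `selected`, `cost`, `gamma`, and `grid` diagnostics when a
#'   search ran.
#' @export
dti_train <- function(X, y, selected = seq_len(ncol(X)), cost = 8,
                      gamma = NULL, probability = TRUE, inner_folds = 3L,
                      seed = 1L) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(-1L, 1L))
  if (any(is.na(yf))) stop("labels must be -1/+1", call. = FALSE)
  if (nlevels(droplevels(yf)) < 2L) {
    stop("training fold has a single class", call. = FALSE)
  }
  Xs <- X[, selected, drop = FALSE]
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xs, 2L, ctr, "-"), 2L, scl, "/")

  grid_info <- NULL
  if (identical(cost, "grid") || identical(gamma, "grid")) {
    cost_grid <- if (identical(cost, "grid")) 2^seq(-5, 15, by = 2) else cost
    gamma_grid <- if (identical(gamma, "grid")) 2^seq(-15, 3, by = 2) else
      if (is.null(gamma)) 1 / ncol(Xs) else gamma
    folds <- stratified_folds(as.integer(as.character(yf)), inner_folds, seed)
    best <- c(auc = -Inf, cost = NA, gamma = NA)
    rows <- list()
    for (C in cost_grid) for (g in gamma_grid) {
      aucs <- vapply(folds, function(te) {
        fit <- svm(Xs[-te, , drop = FALSE], yf[-te], kernel = "radial",
                   cost = C, gamma = g, scale = FALSE)
        auc_roc(.decision_values(fit, Xs[te, , drop = FALSE]),
                as.integer(as.character(yf[te])))
      }, numeric(1))
      m <- mean(aucs)
      rows[[length(rows) + 1L]] <- data.frame(cost = C, gamma = g, auc = m)
      if (m > best["auc"]) best <- c(auc = m, cost = C, gamma = g)
    }
    cost <- best[["cost"]]
    gamma <- best[["gamma"]]
    grid_info <- do.call(rbind, rows)
  }
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)

  fit <- svm(Xs, yf, kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE, probability = probability)
  structure(list(svm = fit, center = ctr, scale = scl, selected = selected,
                 cost = cost, gamma = gamma, probability = probability,
                 grid = grid_info, n_features = length(selected)),
            class = "dti_model")
}

#' Predict with a trained DTI model
#'
#' @param object a `dti_model`.
#' @param newdata matrix with the same columns as the training `X` (the
#'   model applies its stored selection and normalization).
#' @param type `"decision"` (default; signed decision values, larger = more
#'   likely interacting), `"probability"` (Platt-scaled P(interaction)) or
#'   `"label"` (+1/-1 at threshold 0).
#' @param ... unused.
#' @return numeric (or integer for `"label"`) vector, one value per row.
#' @export
predict.dti_model <- function(object, newdata, type = c("decision", "probability", "label"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$selected, drop = FALSE]
  newdata <- sweep(sweep(newdata, 2L, object$center, "-"), 2L,
                   object$scale, "/")
  if (type == "probability") {
    if (!object$probability) {
      stop("model was trained without probability estimates", call. = FALSE)
    }
    pr <- attr(predict(object$svm, newdata, probability = TRUE),
               "probabilities")
    return(unname(pr[, "1"]))
  }
  dv <- .decision_values(object$svm, newdata)
  if (type == "label") ifelse(dv > 0, 1L, -1L) else dv
}

#' @export
print.dti_model <- function(x, ...) {
  cat(sprintf("RBF-SVM DTI model: %d features, C = %g, gamma = %g, %d SVs%s\n",
              x$n_features, x$cost, x$gamma, nrow(x$svm$SV),
              if (!is.null(x$grid)) " (grid-searched)" else ""))
  invisible(x)
}
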