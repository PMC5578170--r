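#' Bipartite drug-target interaction network
#'
#' A binary adjacency matrix over ordered drug and target registries. The
#' registry order of the input (file or vectors) is preserved so that
#' interaction-profile feature indices are stable across runs.
#'
#' @param drug_ids,target_ids unique identifier vectors.
#' @param edges two-column data.frame (`drug_id`, `target_id`) of known
#'   interactions; every id must be in the registries.
#' @param adjacency alternatively, a binary n_drugs x n_targets matrix (used
#'   instead of `edges` when supplied).
#' @return a `dti_network`: list with `drug_ids`, `target_ids`, `adjacency`.
#' @export
interaction_network <- function(drug_ids, target_ids, edges = NULL,
                                adjacency = NULL) {
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids", call. = FALSE)
  if (anyDuplicated(target_ids)) stop("duplicate target ids", call. = FALSE)
  if (is.null(adjacency)) {
    adjacency <- matrix(0L, length(drug_ids), length(target_ids),
                        dimnames = list(drug_ids, target_ids))
    if (!is.null(edges) && nrow(edges) > 0L) {
      d <- match(as.character(edges[[1L]]), drug_ids)
      t <- match(as.character(edges[[2L]]), target_ids)
      if (anyNA(d)) stop("edge references unknown drug id: ",
                         edges[[1L]][which(is.na(d))[1L]], call. = FALSE)
      if (anyNA(t)) stop("edge references unknown target id: ",
                         edges[[2L]][which(is.na(t))[1L]], call. = FALSE)
      adjacency[cbind(d, t)] <- 1L
    }
  } else {
    stopifnot(nrow(adjacency) == length(drug_ids),
              ncol(adjacency) == length(target_ids))
    if (!all(adjacency %in% c(0L, 1L))) {
      stop("adjacency entries must be 0/1", call. = FALSE)
    }
    storage.mode(adjacency) <- "integer"
    dimnames(adjacency) <- list(drug_ids, target_ids)
  }
  structure(list(drug_ids = drug_ids, target_ids = target_ids,
                 adjacency = adjacency),
            class = "dti_network")
}

#' @export
print.dti_network <- function(x, ...) {
  cat(sprintf("DTI network: %d drugs x %d targets, %d interactions (ratio n/m = %.2f)\n",
              length(x$drug_ids), length(x$target_ids), sum(x$adjacency),
              length(x$drug_ids) / length(x$target_ids)))
  invisible(x)
}

#' Read a drug-target edge list
#'
#' Two tab-separated columns, `drug_id<TAB>target_id`, one interaction per
#' line (the distribution format of the gold-standard benchmark sets, with
#' KEGG-style ids such as `D00545` / `hsa1571`). Registries default to the
#' ids in order of first appearance; pass explicit registries to include
#' isolated drugs/targets.
#'
#' @param path edge-list file.
#' @param drug_ids,target_ids optional explicit registries.
#' @param header does the file have a header line?
#' @return a `dti_network`.
#' @export
read_edge_list <- function(path, drug_ids = NULL, target_ids = NULL,
                           header = FALSE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs two columns", call. = FALSE)
  names(df)[1:2] <- c("drug_id", "target_id")
  if (is.null(drug_ids)) drug_ids <- unique(df$drug_id)
  if (is.null(target_ids)) target_ids <- unique(df$target_id)
  interaction_network(drug_ids, target_ids, df[, 1:2])
}

#' @rdname read_edge_list
#' @param network a `dti_network` to write.
#' @export
write_edge_list <- function(network, path) {
  idx <- which(network$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(drug_id = network$drug_ids[idx[, 1L]],
                   target_id = network$target_ids[idx[, 2L]])
  df <- df[order(df$drug_id, df$target_id), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a full adjacency matrix
#'
#' The gold-standard distribution ships adjacency as a labeled TSV with
#' targets in rows and drugs in columns; set `drugs_in = "rows"` if the
#' orientation is transposed.
#'
#' @param path TSV with row and column labels.
#' @param drugs_in `"columns"` (distribution convention) or `"rows"`.
#' @return a `dti_network`.
#' @export
read_adjacency_matrix <- function(path, drugs_in = c("columns", "rows")) {
  drugs_in <- match.arg(drugs_in)
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
  if (drugs_in == "columns") m <- t(m)
  interaction_network(rownames(m), colnames(m), adjacency = m)
}

#' Interaction-profile ("net") feature of a drug-target pair
#'
#' The drug's binary interaction profile over all targets other than the
#' query target, concatenated with the target's profile over all drugs other
#' than the query drug: a `(n_t - 1) + (n_d - 1)` binary vector in which
#' known interactions are 1 and unknown pairs 0. Excluding the query row and
#' column means a pair's own label never enters its own feature.
#'
#' @param network a `dti_network`.
#' @param drug,target registry ids.
#' @return list of class `net_feature` with `drug_profile` (length n_t - 1),
#'   `target_profile` (length n_d - 1) and `combined`.
#' @export
net_feature <- function(network, drug, target) {
  stopifnot(inherits(network, "dti_network"))
  di <- match(drug, network$drug_ids)
  ti <- match(target, network$target_ids)
  if (is.na(di)) stop("unknown drug id: ", drug, call. = FALSE)
  if (is.na(ti)) stop("unknown target id: ", target, call. = FALSE)
  dp <- network$adjacency[di, -ti]
  tp <- network$adjacency[-di, ti]
  structure(list(drug_profile = dp, target_profile = tp,
                 combined = c(dp, tp), drug = drug, target = target),
            class = "net_feature")
}

#' Net features for many pairs at once
#'
#' @param network a `dti_network`.
#' @param pairs data.frame with `drug_id` and `target_id` columns.
#' @return numeric matrix, one row per pair, `(n_t - 1) + (n_d - 1)` columns
#'   (`net_d_*` block then `net_t_*` block).
#' @export
net_feature_matrix <- function(network, pairs) {
  stopifnot(inherits(network, "dti_network"))
  nd <- length(network$drug_ids)
  nt <- length(network$target_ids)
  di <- match(as.character(pairs$drug_id), network$drug_ids)
  ti <- match(as.character(pairs$target_id), network$target_ids)
  if (anyNA(di) || anyNA(ti)) stop("pair references unknown id", call. = FALSE)
  out <- matrix(0L, nrow(pairs), (nt - 1L) + (nd - 1L))
  colnames(out) <- c(paste0("net_d_", seq_len(nt - 1L)),
                     paste0("net_t_", seq_len(nd - 1L)))
  for (i in seq_len(nrow(pairs))) {
    out[i, ] <- c(network$adjacency[di[i], -ti[i]],
                  network$adjacency[-di[i], ti[i]])
  }
  out
}

#' Zero out test-fold edges before computing net features
#'
#' During cross-validation the positive pairs of the test fold are masked
#' (set to 0) in the adjacency so that training-fold interaction profiles
#' carry no information about held-out labels.
#'
#' @param network a `dti_network`.
#' @param test_pairs data.frame with `drug_id`, `target_id` (labels ignored;
#'   masking a pair that is already 0 is a no-op).
#' @return a `dti_network` copy with the masked adjacency.
#' @export
mask_test_edges <- function(network, test_pairs) {
  stopifnot(inherits(network, "dti_network"))
  if (is.null(test_pairs) || nrow(test_pairs) == 0L) return(network)
  di <- match(as.character(test_pairs$drug_id), network$drug_ids)
  ti <- match(as.character(test_pairs$target_id), network$target_ids)
  if (anyNA(di) || anyNA(ti)) stop("test pair outside registries", call. = FALSE)
  adj <- network$adjacency
  adj[cbind(di, ti)] <- 0L
  interaction_network(network$drug_ids, network$target_ids, adjacency = adj)
}

#' All unknown (non-interacting) pairs of a network
#'
#' @param network a `dti_network`.
#' @return data.frame `drug_id`, `target_id`, in drug-major registry order.
#' @export
unknown_pairs <- function(network) {
  idx <- which(t(network$adjacency) == 0L, arr.ind = TRUE)
  data.frame(drug_id = network$drug_ids[idx[, 2L]],
             target_id = network$target_ids[idx[, 1L]],
             stringsAsFactors = FALSE)
}
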