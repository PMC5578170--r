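test_that("balanced subsets contain all positives plus equal negatives", {
  net <- random_network(8L, 6L, 12L, seed = 2)
  subsets <- build_balanced(net, n_subsets = 4L, seed = 9)
  expect_length(subsets, 4L)
  pos_keys <- with(as.data.frame(which(net$adjacency == 1L, arr.ind = TRUE)),
                   paste(net$drug_ids[row], net$target_ids[col]))
  for (s in subsets) {
    expect_equal(sum(s$label == 1L), 12L)
    expect_equal(sum(s$label == -1L), 12L)
    expect_setequal(paste(s$drug_id, s$target_id)[s$label == 1L], pos_keys)
    # negatives really are unknown pairs
    neg <- s[s$label == -1L, ]
    expect_true(all(net$adjacency[cbind(match(neg$drug_id, net$drug_ids),
                                        match(neg$target_id, net$target_ids))] == 0L))
    expect_false(anyDuplicated(paste(s$drug_id, s$target_id)) > 0L)
  }
  # seeded determinism
  again <- build_balanced(net, n_subsets = 4L, seed = 9)
  expect_identical(subsets, again)
})

test_that("negative overlap across subsets matches the hypergeometric rate", {
  # 6 x 5 toy network, 6 positives -> 24 unknown pairs, 6 drawn per subset;
  # uniform draws overlap in expectation 6 * 6/24 = 1.5 pairs
  net <- random_network(6L, 5L, 6L, seed = 4)
  subsets <- build_balanced(net, n_subsets = 30L, seed = 21)
  neg_keys <- lapply(subsets, function(s)
    paste(s$drug_id, s$target_id)[s$label == -1L])
  overlaps <- c()
  for (i in seq_along(neg_keys)) {
    for (j in seq_len(i - 1L)) {
      overlaps <- c(overlaps, length(intersect(neg_keys[[i]], neg_keys[[j]])))
    }
  }
  expect_gt(mean(overlaps), 1.5 - 0.35)
  expect_lt(mean(overlaps), 1.5 + 0.35)
})

test_that("balanced sampling fails when negatives cannot match positives", {
  dense <- interaction_network(c("d1", "d2"), c("t1", "t2"),
                               adjacency = matrix(c(1L, 1L, 1L, 0L), 2L))
  expect_error(build_balanced(dense, 1L), "cannot balance")
})

test_that("imbalanced dataset enumerates every pair with adjacency labels", {
  net <- interaction_network(paste0("d", 1:3), paste0("t", 1:2),
                             edges = data.frame(d = c("d1", "d3"),
                                                t = c("t1", "t2")))
  ds <- build_imbalanced(net)
  expect_equal(nrow(ds), 6L)
  expect_equal(sum(ds$label == 1L), 2L)
  expect_equal(sum(ds$label == -1L), 4L)

  full <- interaction_network("d1", c("t1", "t2"),
                              adjacency = matrix(1L, 1L, 2L))
  expect_warning(build_imbalanced(full), "no negative")

  # gold-standard-shaped synthetic network keeps the books straight
  big <- synthesize_benchmark(n_drugs = 445L, n_targets = 664L,
                              n_edges = 2926L, signal_strength = 0,
                              seed = 1)$network
  dsb <- build_imbalanced(big)
  expect_equal(nrow(dsb), 445L * 664L)
  expect_equal(sum(dsb$label == 1L), 2926L)
  expect_equal(sum(dsb$label == -1L), 445L * 664L - 2926L)
})

test_that("pair feature matrix concatenates target, net, maccs blocks", {
  b <- synthesize_benchmark(n_drugs = 10L, n_targets = 8L, n_edges = 15L,
                            seed = 5)
  tf <- featurize_targets(b$sequences)
  pairs <- build_balanced(b$network, 1L, seed = 2)[[1L]]
  X <- pair_feature_matrix(pairs, tf, b$fingerprints, b$network)
  expect_equal(ncol(X), 312L + (8L - 1L) + (10L - 1L) + 166L)
  expect_equal(unname(attr(X, "blocks")), c(312L, 16L, 166L))
  i <- 7L
  expect_equal(unname(X[i, 1:312]), unname(tf[pairs$target_id[i], ]))
  expect_equal(unname(X[i, 329:494]),
               unname(b$fingerprints[pairs$drug_id[i], ]))
  expect_equal(unname(X[i, 313:328]),
               unname(net_feature_matrix(b$network, pairs[i, , drop = FALSE])[1L, ]))
  expect_error(pair_feature_matrix(data.frame(drug_id = "nope",
                                              target_id = pairs$target_id[1L]),
                                   tf, b$fingerprints, b$network),
               "without fingerprint")
})

test_that("stratified folds partition samples and preserve class balance", {
  labels <- rep(c(1L, -1L), c(40L, 60L))
  folds <- stratified_folds(labels, 5L, seed = 3)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  for (f in folds) {
    expect_equal(sum(labels[f] == 1L), 8L)
    expect_equal(sum(labels[f] == -1L), 12L)
  }
})

test_that("synthetic benchmark is reproducible and writes identical files", {
  b1 <- synthesize_benchmark(n_drugs = 15L, n_targets = 10L, n_edges = 30L,
                             seed = 77)
  b2 <- synthesize_benchmark(n_drugs = 15L, n_targets = 10L, n_edges = 30L,
                             seed = 77)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$fingerprints, b2$fingerprints)
  expect_identical(b1$network$adjacency, b2$network$adjacency)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  synthesize_benchmark(n_drugs = 15L, n_targets = 10L, n_edges = 30L,
                       seed = 77, dir = d1)
  synthesize_benchmark(n_drugs = 15L, n_targets = 10L, n_edges = 30L,
                       seed = 77, dir = d2)
  for (f in c("sequences.fasta", "fingerprints.tsv", "edges.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # generator does not disturb the caller's RNG stream
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(synthesize_benchmark(n_drugs = 5L, n_targets = 4L, n_edges = 5L,
                                 seed = 123))
  expect_identical(rnorm(1), before)
})

test_that("benchmark edges concentrate on high-propensity groups", {
  b <- synthesize_benchmark(seed = 2)
  pos <- which(b$network$adjacency == 1L, arr.ind = TRUE)
  top_d <- b$drug_groups[pos[, 1L]] == 4L
  top_t <- b$target_groups[pos[, 2L]] == 4L
  # at full signal the top of four groups hosts far more than its 25% share
  expect_gt(mean(top_d), 0.5)
  expect_gt(mean(top_t), 0.5)
  null <- synthesize_benchmark(signal_strength = 0, seed = 2)
  nullpos <- which(null$network$adjacency == 1L, arr.ind = TRUE)
  expect_lt(mean(null$drug_groups[nullpos[, 1L]] == 4L), 0.4)
})
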