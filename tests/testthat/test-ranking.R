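# a hand-built network in which "active" drugs (signature fingerprint block)
# hit "active" targets (biased composition); one active-active edge is held
# out and should be recovered at rank 1
make_holdout_case <- function(seed = 1L) {
  withr::with_seed(seed, {
    n_d <- 10L
    n_t <- 8L
    drug_ids <- sprintf("D%03d", 1:n_d)
    target_ids <- sprintf("hsa%03d", 1:n_t)
    active_d <- 1:5
    active_t <- 1:4
    fps <- matrix(rbinom(n_d * 166L, 1L, 0.1), n_d, 166L,
                  dimnames = list(drug_ids, paste0("maccs_", 1:166)))
    fps[active_d, 1:20] <- 1L
    seqs <- setNames(character(n_t), target_ids)
    for (t in 1:n_t) {
      pool <- if (t %in% active_t) c("A", "K", "E") else c("F", "I", "V")
      seqs[t] <- paste(sample(pool, 180L, TRUE), collapse = "")
    }
    edges <- expand.grid(drug_id = drug_ids[active_d],
                         target_id = target_ids[active_t],
                         stringsAsFactors = FALSE)
    holdout <- edges[7L, ]
    edges <- edges[-7L, ]
    net <- interaction_network(drug_ids, target_ids, edges)
    list(network = net, tf = featurize_targets(seqs), fps = fps,
         holdout = holdout)
  })
}

test_that("a held-out true interaction ranks first among unknown pairs", {
  case <- make_holdout_case()
  # the negative draw at this seed leaves the held-out pair unseen, so the
  # model meets it only at ranking time
  tr <- build_balanced(case$network, 1L, seed = 1L)[[1L]]
  neg <- tr[tr$label == -1L, ]
  expect_false(any(neg$drug_id == case$holdout$drug_id &
                     neg$target_id == case$holdout$target_id))
  top <- rank_novel_pairs(case$network, case$tf, case$fps, top_n = 5L,
                          seed = 1L, selection = FALSE,
                          exclude_training_negatives = FALSE)
  expect_equal(top$drug_id[1L], case$holdout$drug_id)
  expect_equal(top$target_id[1L], case$holdout$target_id)
  expect_true(all(diff(top$score) <= 0))
})

test_that("ranking is exhaustive, deterministic and writes its table", {
  case <- make_holdout_case(seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  top <- rank_novel_pairs(case$network, case$tf, case$fps, top_n = 10000L,
                          seed = 3L, selection = FALSE, calibrate = FALSE,
                          exclude_training_negatives = FALSE,
                          score_table_path = path)
  n_unknown <- sum(case$network$adjacency == 0L)
  expect_equal(nrow(top), n_unknown)
  expect_equal(top$rank, seq_len(n_unknown))
  tab <- read.delim(path)
  expect_equal(nrow(tab), n_unknown)
  top2 <- rank_novel_pairs(case$network, case$tf, case$fps, top_n = 10000L,
                           seed = 3L, selection = FALSE, calibrate = FALSE,
                           exclude_training_negatives = FALSE)
  expect_equal(top$score, top2$score)
})

test_that("tied scores break by lexicographic pair order", {
  case <- make_holdout_case(seed = 4L)
  # clone a drug: identical fingerprint and interactions as D001
  net <- case$network
  adj <- rbind(net$adjacency, net$adjacency["D001", , drop = FALSE])
  ids <- c(net$drug_ids, "D000")
  net2 <- interaction_network(ids, net$target_ids, adjacency = adj)
  fps2 <- rbind(case$fps, D000 = case$fps["D001", ])
  top <- rank_novel_pairs(net2, case$tf, fps2, top_n = 1000L, seed = 5L,
                          selection = FALSE, calibrate = FALSE,
                          exclude_training_negatives = FALSE)
  # for targets with all-zero interaction columns the clone pair rows are
  # bit-identical, so scores tie exactly and D000 must precede D001
  zero_targets <- net$target_ids[colSums(net$adjacency) == 0L]
  expect_gte(length(zero_targets), 2L)
  checked <- 0L
  for (t in zero_targets) {
    r0 <- top$rank[top$drug_id == "D000" & top$target_id == t]
    r1 <- top$rank[top$drug_id == "D001" & top$target_id == t]
    if (length(r0) == 1L && length(r1) == 1L) {
      expect_equal(r1, r0 + 1L)
      expect_equal(top$score[r0], top$score[r1])
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 2L)
})

test_that("training negatives can be excluded from the candidate list", {
  case <- make_holdout_case(seed = 6L)
  top_all <- rank_novel_pairs(case$network, case$tf, case$fps, top_n = 1e4L,
                              seed = 7L, selection = FALSE,
                              exclude_training_negatives = FALSE)
  top_ex <- rank_novel_pairs(case$network, case$tf, case$fps, top_n = 1e4L,
                             seed = 7L, selection = FALSE,
                             exclude_training_negatives = TRUE)
  n_pos <- sum(case$network$adjacency)
  expect_equal(nrow(top_all) - nrow(top_ex), n_pos)  # balanced draw size
})
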