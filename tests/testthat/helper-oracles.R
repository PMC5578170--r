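# Independent reference implementations used as oracles. These are written
# as literal loops / closed forms so they share no code path with the
# package internals they check.

# brute-force one-level filter-bank step: explicit boundary extension,
# explicit correlation sums, keep every second output
oracle_dwt_step <- function(x, lo, hi, mode = "symmetric") {
  fl <- length(lo)
  n <- length(x)
  ext <- switch(mode,
    symmetric = {
      stopifnot(n >= fl - 1L)
      c(x[(fl - 1L):1L], x, x[n:(n - fl + 2L)])
    },
    zero = c(rep(0, fl - 1L), x, rep(0, fl - 1L)),
    periodization = {
      idx <- function(i) ((i - 1L) %% n) + 1L
      c(x[idx((n - fl / 2 + 1L):n)], x, x[idx(1L:fl)])
    })
  n_out <- length(ext) - fl + 1L
  a_full <- numeric(n_out)
  d_full <- numeric(n_out)
  for (i in seq_len(n_out)) {
    s_a <- 0
    s_d <- 0
    for (k in seq_len(fl)) {
      s_a <- s_a + ext[i + k - 1L] * lo[fl - k + 1L]
      s_d <- s_d + ext[i + k - 1L] * hi[fl - k + 1L]
    }
    a_full[i] <- s_a
    d_full[i] <- s_d
  }
  keep <- seq(2L, n_out, by = 2L)
  a <- a_full[keep]
  d <- d_full[keep]
  if (mode == "periodization") {
    a <- a[seq_len(n %/% 2L)]
    d <- d[seq_len(n %/% 2L)]
  }
  list(approx = a, detail = d)
}

# recursive multi-level wrapper around the brute-force step
oracle_dwt_multilevel <- function(x, lo, hi, levels, mode = "symmetric") {
  approx <- list()
  detail <- list()
  cur <- x
  for (l in seq_len(levels)) {
    st <- oracle_dwt_step(cur, lo, hi, mode)
    approx[[l]] <- st$approx
    detail[[l]] <- st$detail
    cur <- st$approx
  }
  list(approx = approx, detail = detail)
}

# DCT-II by literal basis-matrix multiplication
oracle_dct <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (k in 0:(n - 1L)) {
    acc <- 0
    for (t in 0:(n - 1L)) {
      acc <- acc + x[t + 1L] * cos(pi * k * (2 * t + 1) / (2 * n))
    }
    out[k + 1L] <- acc * if (k == 0L) sqrt(1 / n) else sqrt(2 / n)
  }
  out
}

# AUC as the Mann-Whitney rank statistic (tie-free scores assumed where the
# 1e-10 comparison is made; ties get the usual half credit via rank())
oracle_auc_rank <- function(scores, labels) {
  pos <- labels > 0
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_sequences <- function(n, len_range = c(100L, 300L), seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    stats::setNames(
      vapply(lens, function(L) paste(sample(AA20, L, TRUE), collapse = ""), ""),
      paste0("t", seq_len(n)))
  })
}

# small random bipartite network
random_network <- function(n_d, n_t, n_e, seed = 1L) {
  withr::with_seed(seed, {
    sel <- sample(n_d * n_t, n_e)
    adj <- matrix(0L, n_d, n_t)
    adj[sel] <- 1L
    interaction_network(sprintf("D%03d", 1:n_d), sprintf("hsa%03d", 1:n_t),
                        adjacency = adj)
  })
}
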