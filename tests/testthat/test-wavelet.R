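test_that("Haar DWT of a constant signal is as the filter bank dictates", {
  d <- dwt_decompose(rep(2.5, 64), "haar", levels = 4L)
  for (l in 1:4) {
    expect_true(all(abs(d$detail[[l]]) < 1e-12))
    expect_true(all(abs(d$approx[[l]] - 2.5 * 2^(l / 2)) < 1e-12))
  }
})

test_that("decomposition matches the brute-force convolution oracle", {
  for (wname in c("haar", "db2", "db4")) {
    filt <- wavelet_filters(wname)
    for (n in c(16L, 50L, 127L)) {
      x <- withr::with_seed(n, rnorm(n))
      lv <- min(4L, dwt_max_levels(n, wname))
      got <- dwt_decompose(x, wname, lv)
      want <- oracle_dwt_multilevel(x, filt$lo, filt$hi, lv)
      for (l in seq_len(lv)) {
        expect_equal(got$approx[[l]], want$approx[[l]], tolerance = 1e-10)
        expect_equal(got$detail[[l]], want$detail[[l]], tolerance = 1e-10)
      }
    }
  }
})

test_that("level l+1 is computed from the level-l approximation band", {
  x <- withr::with_seed(9, rnorm(96))
  d <- dwt_decompose(x, "db4", 3L)
  sub <- dwt_decompose(d$approx[[1L]], "db4", 1L)
  expect_equal(d$approx[[2L]], sub$approx[[1L]], tolerance = 1e-12)
  expect_equal(d$detail[[2L]], sub$detail[[1L]], tolerance = 1e-12)
})

test_that("too-short signals fail with an informative minimum length", {
  expect_error(dwt_decompose(c(1, 2, 3), "db4", 4L), "supports only 0 level")
  expect_error(dwt_decompose(rnorm(10), "db4", 4L), "need length >=")
  # feasibility rule: one step needs at least one filter length of signal
  expect_equal(dwt_max_levels(7L, "db4"), 0L)
  expect_equal(dwt_max_levels(8L, "db4"), 1L)
})

test_that("inverse transform reconstructs the input", {
  for (wname in c("haar", "db2", "db4")) {
    for (n in c(33L, 64L)) {
      x <- withr::with_seed(n + 1L, rnorm(n))
      lv <- min(4L, dwt_max_levels(n, wname))
      expect_equal(idwt_reconstruct(dwt_decompose(x, wname, lv)), x,
                   tolerance = 1e-8)
      if (n %% 16L == 0L) {
        expect_equal(idwt_reconstruct(dwt_decompose(x, wname, 4L,
                                                    "periodization")), x,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("periodized transform conserves energy (Parseval)", {
  for (wname in c("haar", "db2", "db4")) {
    x <- withr::with_seed(3, rnorm(160))
    d <- dwt_decompose(x, wname, 4L, "periodization")
    coef_energy <- sum(unlist(d$detail)^2) + sum(d$approx[[4L]]^2)
    expect_equal(coef_energy, sum(x^2), tolerance = 1e-8)
  }
})

test_that("band statistics match a direct reference computation", {
  d <- dwt_decompose(withr::with_seed(5, rnorm(80)), "db2", 3L)
  st <- band_statistics(d)
  for (l in 1:3) {
    for (b in c("approx", "detail")) {
      cf <- d[[b]][[l]]
      expect_equal(unname(st[sprintf("l%d_%s", l, b), ]),
                   c(max(cf), min(cf), mean(cf),
                     sqrt(sum((cf - mean(cf))^2) / (length(cf) - 1))),
                   tolerance = 1e-12)
    }
  }
  # closed-form cases
  one <- dwt_decompose(rep(1, 8), "haar", 1L)
  one$approx[[1L]] <- c(1, 1, 1)
  one$detail[[1L]] <- c(-2, 0, 2)
  st2 <- band_statistics(one)
  expect_equal(unname(st2["l1_approx", ]), c(1, 1, 1, 0))
  expect_equal(unname(st2["l1_detail", ]), c(2, -2, 0, 2))
})

test_that("DCT head matches the basis-matrix oracle and pads short bands", {
  # constant input: only the DC coefficient is nonzero
  dc <- dct_head(rep(3, 16), 5L)
  expect_equal(dc[1L], 3 * sqrt(16), tolerance = 1e-12)
  expect_true(all(abs(dc[2:5]) < 1e-10))
  # unit impulse: first column of the DCT basis
  expect_equal(dct_ii(c(1, 0, 0, 0)), oracle_dct(c(1, 0, 0, 0)),
               tolerance = 1e-12)
  x <- withr::with_seed(6, rnorm(40))
  expect_equal(dct_ii(x), oracle_dct(x), tolerance = 1e-10)
  expect_warning(padded <- dct_head(c(1, 2), 5L), "zero-filled")
  expect_length(padded, 5L)
  expect_equal(padded[3:5], c(0, 0, 0))
})

test_that("target feature vector has the configured fixed length", {
  seqs <- random_sequences(2, c(64L, 64L), seed = 8)
  v <- target_features(encode_sequence(seqs[[1L]]))
  expect_length(v, 312L)  # 6*4*2*4 stats + 6*4*5 dct
  layout <- attr(v, "layout")
  expect_equal(nrow(layout), 312L)
  expect_false(anyDuplicated(layout$name) > 0L)
  expect_identical(layout$index, seq_len(312L))
  # last-level-only DCT scope
  v_last <- target_features(encode_sequence(seqs[[1L]]), dct_scope = "last")
  expect_length(v_last, 6L * 4L * 2L * 4L + 6L * 5L)
  # feature length invariant to sequence length
  long <- target_features(encode_sequence(random_sequences(1, c(590L, 600L),
                                                           seed = 9)[[1L]]))
  expect_length(long, 312L)
})

test_that("identical sequences give bit-identical feature vectors", {
  s <- random_sequences(1, c(120L, 120L), seed = 10)[[1L]]
  expect_identical(target_features(encode_sequence(s)),
                   target_features(encode_sequence(s)))
})

test_that("homopolymer channels have all-zero Haar detail statistics", {
  v <- target_features(encode_sequence(strrep("A", 64L)), wavelet = "haar")
  layout <- attr(v, "layout")
  det <- layout$kind == "stat" & layout$band == "detail"
  expect_true(all(abs(v[layout$index[det]]) < 1e-12))
})

test_that("full target pipeline matches an all-oracle recomputation", {
  filt <- wavelet_filters("db4")
  seqs <- random_sequences(25, c(60L, 300L), seed = 12)
  got <- featurize_targets(seqs)
  for (i in seq_along(seqs)) {
    sig <- encode_sequence(seqs[[i]])
    lv <- min(4L, dwt_max_levels(nrow(sig), "db4"))
    want <- numeric(0)
    dct_part <- numeric(0)
    for (ch in seq_len(6L)) {
      dec <- oracle_dwt_multilevel(sig[, ch], filt$lo, filt$hi, lv)
      for (l in seq_len(4L)) {
        for (b in c("approx", "detail")) {
          cf <- if (l <= lv) dec[[b]][[l]] else NULL
          want <- c(want, if (is.null(cf)) rep(0, 4) else
            c(max(cf), min(cf), mean(cf), sd(cf)))
        }
      }
      for (l in seq_len(4L)) {
        dct_part <- c(dct_part, if (l <= lv)
          oracle_dct(dec$approx[[l]])[1:5] else rep(0, 5))
      }
    }
    expect_equal(unname(got[i, ]), c(want, dct_part), tolerance = 1e-8)
  }
})

test_that("short sequences fall back to feasible depth with zero-fill", {
  s <- "ACDEFGHIKLMN"  # length 12: only 3 feasible db4 levels
  expect_warning(v <- target_features(encode_sequence(s)), "zero-filled|supports")
  expect_length(v, 312L)
  layout <- attr(v, "layout")
  l4 <- layout$kind == "stat" & layout$level == 4L
  expect_true(all(v[layout$index[l4]] == 0))
})

test_that("feature tables round-trip through TSV", {
  m <- featurize_targets(random_sequences(3, c(64L, 80L), seed = 13))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(m, path)
  back <- read_feature_table(path)
  expect_equal(back, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(m))
})
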