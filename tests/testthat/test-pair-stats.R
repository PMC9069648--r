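test_that("binomial upper tail matches closed forms and the summation oracle", {
  expect_identical(binom_upper_tail(0, 10, 0.3), 1)
  expect_equal(binom_upper_tail(10, 10, 0.5), 2^-10, tolerance = 1e-15)
  expect_equal(binom_upper_tail(7, 20, 0.2), oracle_binom_tail(7, 20, 0.2),
               tolerance = 1e-12)
  expect_error(binom_upper_tail(1, 2, 1.5), "p must be")
})

mk_homog_profiles <- function(N, n_both, x_enh, y_prom, motif = "M") {
  # n_both pairs carry the motif in both regions; the remaining enh/prom
  # carriers are disjoint singles
  enh <- rep(list(character(0)), N)
  prom <- rep(list(character(0)), N)
  enh[seq_len(x_enh)] <- list(motif)
  prom[c(seq_len(n_both), seq.int(x_enh + 1, length.out = y_prom - n_both))] <-
    list(motif)
  tibble::tibble(ep_id = paste0("p", 1:N), enh_motifs = enh,
                 prom_motifs = prom)
}

test_that("length-aware homogeneous test reproduces the oracle p-value", {
  # N=100 pairs, mean promoter length 1100, enhancer 300, 280 instances
  N <- 100; n <- 9; x <- 280
  pr <- mk_homog_profiles(N, n_both = n, x_enh = 40, y_prom = 30)
  occ <- tibble::tibble(
    motif = "M",
    seq_id = rep(paste0("s", 1:70), length.out = x),
    start = 0L, strand = "+", score = 5, pvalue = 1e-8
  )
  out <- homogeneous_tests(pr, occ, variant = "length_aware", K = 10,
                           l1 = 1100, l2 = 300)
  expect_equal(out$p_success, x / (N * 1400), tolerance = 1e-12)
  expect_equal(out$pvalue, oracle_binom_tail(n, N, x / (N * 1400)),
               tolerance = 1e-12)
  expect_equal(out$n, n)
  expect_true(out$significant == (out$pvalue < 0.01 / 10))
})

test_that("presence-based homogeneous test uses p = x*y/N^2", {
  N <- 100; x <- 50; y <- 40; n <- 30
  pr <- mk_homog_profiles(N, n_both = n, x_enh = x, y_prom = y)
  out <- homogeneous_tests(pr, variant = "presence_based", K = 5)
  expect_equal(out$x, x)
  expect_equal(out$y, y)
  expect_equal(out$p_success, x * y / N^2)
  expect_equal(out$pvalue, oracle_binom_tail(n, N, 0.2), tolerance = 1e-12)

  # n = x*y/N exactly -> p-value near 0.5 up to binomial discreteness
  pr2 <- mk_homog_profiles(N, n_both = 20, x_enh = x, y_prom = y)
  out2 <- homogeneous_tests(pr2, variant = "presence_based", K = 5)
  expect_gt(out2$pvalue, 0.35)
  expect_lt(out2$pvalue, 0.65)

  # motif everywhere -> degenerate success probability is an error
  pr3 <- mk_homog_profiles(N, n_both = N, x_enh = N, y_prom = N)
  expect_error(homogeneous_tests(pr3, variant = "presence_based", K = 5),
               "degenerate")
})

test_that("homogeneous significance threshold scales as 0.01/K", {
  N <- 80
  pr <- mk_homog_profiles(N, n_both = 12, x_enh = 30, y_prom = 25)
  a <- homogeneous_tests(pr, variant = "presence_based", K = 1)
  b <- homogeneous_tests(pr, variant = "presence_based", K = 2)
  expect_equal(a$pvalue, b$pvalue)  # K never changes the p-value
  expect_true(a$significant >= b$significant)  # only the threshold moves

  # a motif never co-occurring in both regions is never significant
  pr0 <- mk_homog_profiles(N, n_both = 0, x_enh = 10, y_prom = 10)
  out0 <- homogeneous_tests(pr0, variant = "presence_based", K = 1)
  expect_identical(out0$pvalue, 1)
  expect_false(out0$significant)
})

test_that("preference tests are symmetric and length-calibrated", {
  pr <- mk_homog_profiles(60, n_both = 10, x_enh = 20, y_prom = 20)
  out <- preference_tests(pr, variant = "count_only")
  expect_gte(out$pvalue_enh, 0.25)
  expect_gte(out$pvalue_prom, 0.25)

  # promoters three times longer, carriers proportional 3:1 -> not significant
  pr2 <- mk_homog_profiles(100, n_both = 5, x_enh = 15, y_prom = 45)
  out2 <- preference_tests(pr2, variant = "length_aware", l1 = 900, l2 = 300)
  expect_gt(out2$pvalue_enh, 0.05)
  expect_gt(out2$pvalue_prom, 0.05)

  # all carriers in promoters, count-only: closed form 2^-(e+p) tail
  pr3 <- mk_homog_profiles(30, n_both = 0, x_enh = 0, y_prom = 12)
  out3 <- preference_tests(pr3, variant = "count_only")
  expect_equal(out3$pvalue_prom, 2^-12, tolerance = 1e-12)
  expect_identical(out3$pvalue_enh, 1)
})

test_that("hypergeometric enrichment matches the enumeration oracle", {
  db <- tibble::tibble(
    tf_a = c("T1", "T1", "T2", "T3", "T5"),
    tf_b = c("T2", "T3", "T3", "T4", "T6"),
    type = "direct"
  )
  db_tfs <- paste0("T", 1:10)      # universe: 10 TFs, 45 possible pairs
  pred <- tibble::tibble(tf_a = c("T1", "T1", "T2"),
                         tf_b = c("T2", "T3", "T3"))
  # n = 3 predicted TFs -> 3 candidate pairs, m = 3 in the database
  out <- hypergeom_enrichment(pred, db, db_tfs = db_tfs)
  expect_equal(out$m_pairs, 3L)
  expect_equal(out$n_tfs, 3L)
  expect_equal(out$M_pairs, 5L)
  expect_equal(out$pvalue, oracle_hyper_tail(3, 3, 5, 45), tolerance = 1e-12)

  # 5 distinct predicted TFs -> 10 candidate pairs, 3 database hits
  pred2 <- tibble::tibble(tf_a = c("T1", "T1", "T2", "T5"),
                          tf_b = c("T2", "T3", "T3", "T7"))
  out2 <- hypergeom_enrichment(pred2, db, db_tfs = db_tfs)
  expect_equal(out2$n_tfs, 5L)
  expect_equal(out2$pvalue,
               oracle_hyper_tail(3, 10, 5, 45), tolerance = 1e-12)

  # m = 0 -> p-value exactly 1
  pred0 <- tibble::tibble(tf_a = "T9", tf_b = "T10")
  expect_identical(hypergeom_enrichment(pred0, db, db_tfs = db_tfs)$pvalue, 1)

  # predicted TFs outside the namespace are dropped with a message
  predx <- tibble::tibble(tf_a = c("T1", "ZZZ"), tf_b = c("T2", "T3"))
  expect_message(outx <- hypergeom_enrichment(predx, db, db_tfs = db_tfs),
                 "dropped")
  expect_equal(outx$m_pairs, 1L)
})

test_that("tail functions agree with oracles across all small instances", {
  for (N in c(5, 13, 30)) {
    for (p in c(0.07, 0.5, 0.83)) {
      for (n in 0:N) {
        expect_equal(binom_upper_tail(n, N, p), oracle_binom_tail(n, N, p),
                     tolerance = 1e-12)
      }
    }
  }
  withr::with_seed(8, {
    for (i in 1:40) {
      universe <- sample(10:30, 1L)
      M <- sample.int(universe - 1L, 1L)
      draws <- sample.int(universe - 1L, 1L)
      m <- sample(0:min(M, draws), 1L)
      got <- if (m == 0) 1 else
        phyper(m - 1, M, universe - M, draws, lower.tail = FALSE)
      expect_equal(got, oracle_hyper_tail(m, draws, M, universe),
                   tolerance = 1e-12)
    }
  })
})

test_that("TF interaction lists deduplicate symmetric pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CTCF\tYY1\tdirect", "YY1\tCTCF\tdirect",
               "yy1\tZNF143\tindirect", "CTCF\tCTCF\tdirect"), f)
  db <- read_tf_interactions(f)
  expect_equal(nrow(db), 2L)
  expect_true(all(db$tf_a < db$tf_b))
  expect_setequal(db$type, c("direct", "indirect"))
})

test_that("motif-to-TF mapping honours the all/best modes", {
  ctcf <- pwm_from_consensus("CTCF", "GCGCCCTCTAGT")
  ctcfl <- pwm_from_consensus("CTCFL", "GCGCCCTCTAGT")  # same matrix
  other <- pwm_from_consensus("OTHER", "ATTATGCAATGG")
  lib <- list(CTCF = ctcf, CTCFL = ctcfl, OTHER = other)
  pred <- list(Q = pwm_from_consensus("Q", "GCGCCCTCTAGT"))
  all_map <- map_motifs_to_tfs(pred, lib, mode = "all", seed = 2)
  expect_setequal(all_map$Q, c("CTCF", "CTCFL"))
  best_map <- map_motifs_to_tfs(pred, lib, mode = "best", seed = 2)
  expect_equal(best_map$Q, "CTCF")   # tie broken lexicographically
  none <- map_motifs_to_tfs(list(Z = other), list(CTCF = ctcf),
                            mode = "all", seed = 2)
  expect_equal(none$Z, character(0))
})
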