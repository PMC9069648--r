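test_that("JASPAR and MEME parsers agree and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(
    ">M1",
    "A [ 10  0  0 10  5  0  0 10 ]",
    "C [  0 10  0  0  5  0  0  0 ]",
    "G [  0  0 10  0  0 10  0  0 ]",
    "T [  0  0  0  0  0  0 10  0 ]"
  ), f)
  pj <- read_motifs(f, "jaspar")
  expect_equal(length(pj), 1L)
  expect_equal(pj$M1$width, 8L)
  expect_true(all(abs(colSums(pj$M1$probs) - 1) < 1e-9))
  expect_true(all(pj$M1$probs > 0))

  m <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "MOTIF M1",
    "letter-probability matrix: alength= 4 w= 8",
    "1.0 0.0 0.0 0.0", "0.0 1.0 0.0 0.0", "0.0 0.0 1.0 0.0",
    "1.0 0.0 0.0 0.0", "0.5 0.5 0.0 0.0", "0.0 0.0 1.0 0.0",
    "0.0 0.0 0.0 1.0", "1.0 0.0 0.0 0.0"
  ), m)
  pm <- read_motifs(m, "meme")
  expect_equal(unname(pm$M1$probs), unname(pj$M1$probs), tolerance = 1e-9)

  writeLines(c(">M1", "A [ 1 2 3 4 ]", "C [ 1 2 3 ]",
               "G [ 1 2 3 4 ]", "T [ 1 2 3 4 ]"), f)
  expect_error(read_motifs(f, "jaspar"), "mismatch")

  writeLines(c(">M1", "A [ 1 2 3 4 ]", "C [ 1 2 3 4 ]",
               "G [ 1 2 3 4 ]", "T [ 1 2 3 4 ]",
               ">M1", "A [ 1 2 3 4 ]", "C [ 1 2 3 4 ]",
               "G [ 1 2 3 4 ]", "T [ 1 2 3 4 ]"), f)
  expect_error(read_motifs(f, "jaspar"), "duplicate")
})

test_that("write_motifs round-trips names, widths and consensus", {
  lib <- list(A = pwm_from_consensus("A", "ACGTACGT"),
              B = pwm_from_consensus("B", "TTTTGGGG"))
  f <- withr::local_tempfile(fileext = ".pfm")
  write_motifs(lib, f)
  back <- read_motifs(f, "jaspar")
  expect_equal(names(back), c("A", "B"))
  expect_equal(purrr::map_chr(back, consensus),
               purrr::map_chr(lib, consensus))
})

test_that("uniform PWM yields zero scores and no hits", {
  m <- pwm("U", matrix(0.25, 4, 5), pseudocount = 0)
  seqs <- tibble::tibble(id = "s", seq = random_seq(100, seed = 1))
  expect_equal(nrow(scan_motifs(m, seqs)), 0L)
})

test_that("consensus PWM hit has the closed-form score and enumeration p-value", {
  m <- pwm("C4", matrix(c(0.97, 0.01, 0.01, 0.01,
                          0.01, 0.97, 0.01, 0.01,
                          0.01, 0.01, 0.97, 0.01,
                          0.01, 0.01, 0.01, 0.97), 4), pseudocount = 0)
  seqs <- tibble::tibble(id = "s", seq = "ACGT")
  # p of the consensus word is 1/256 under a uniform background, so scan
  # with a threshold above that
  hits <- scan_motifs(m, seqs, p_threshold = 0.005)
  plus <- dplyr::filter(hits, strand == "+")
  expect_equal(plus$start, 0L)
  expect_equal(plus$score, 4 * log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(plus$pvalue, 1 / 256, tolerance = 1e-12)
  # ACGT is its own reverse complement: a minus-strand hit is reported too
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("scanner equals the brute-force all-windows oracle", {
  withr::with_seed(5, {
    for (trial in 1:6) {
      w <- sample(4:8, 1L)
      probs <- matrix(stats::rgamma(4 * w, 0.6), 4, w)
      m <- pwm(sprintf("R%d", trial), sweep(probs, 2, colSums(probs), "/"))
      s <- random_seq(sample(50:200, 1L))
      if (trial %% 2 == 0) {  # inject Ns
        pos <- sample.int(nchar(s) - 5L, 3L)
        for (p in pos) substr(s, p, p) <- "N"
      }
      got <- scan_motifs(m, tibble::tibble(id = "s", seq = s),
                         p_threshold = 0.01)
      want <- oracle_scan(m, s, p_threshold = 0.01)
      got <- dplyr::arrange(got, start, strand)[, c("start", "strand",
                                                    "score", "pvalue")]
      if (nrow(want) == 0L) {
        expect_equal(nrow(got), 0L)
      } else {
        want <- dplyr::arrange(want, start, strand)[, c("start", "strand",
                                                        "score", "pvalue")]
        expect_equal(as.data.frame(got), as.data.frame(want),
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  })
})

test_that("top-word p-value equals exact word counting for width <= 6", {
  withr::with_seed(9, {
    for (w in 4:6) {
      probs <- matrix(stats::rgamma(4 * w, 0.5), 4, w)
      m <- pwm("T", sweep(probs, 2, colSums(probs), "/"))
      s <- random_seq(150)
      hits <- scan_motifs(m, tibble::tibble(id = "s", seq = s),
                          p_threshold = 0.5)
      top <- hits[which.max(hits$score), ]
      # count words scoring at least as high, over all 4^w words
      lod <- log2(m$probs / 0.25)
      if (top$strand == "-") lod <- log2(revcomp_pwm(m)$probs / 0.25)
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      scores <- apply(words, 1L, function(v) sum(lod[cbind(v, seq_len(w))]))
      expect_equal(top$pvalue,
                   sum(scores >= top$score - 1e-9) / 4^w,
                   tolerance = 1e-12)
    }
  })
})

test_that("lattice distribution path (wide motifs) gives the exact consensus p", {
  m <- pwm_from_consensus("W", "ACGTACGTACGT")  # width 12 -> DP path
  s <- paste0(random_seq(30, seed = 2), "ACGTACGTACGT", random_seq(30, seed = 3))
  hits <- scan_motifs(m, tibble::tibble(id = "s", seq = s),
                      p_threshold = 1e-4)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$start, 30L)
  # unique maximal word: the tail at the top score is exactly 4^-12
  expect_equal(top$pvalue, 4^-12, tolerance = 1e-9)
})

test_that("sequences shorter than the motif give an empty result, not an error", {
  m <- pwm_from_consensus("M", "ACGTAC")
  out <- scan_motifs(m, tibble::tibble(id = "s", seq = "ACG"))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "scanned_ids"), "s")
})

test_that("self-similarity is perfect in both orientations", {
  m <- pwm_from_consensus("M", "ACGGTCAT")
  same <- motif_similarity(m, m, seed = 1)
  expect_equal(same$score, 1)
  expect_equal(same$best_offset, 0L)
  expect_equal(same$best_orientation, "same")
  expect_lt(same$evalue, 1e-5)
  rc <- motif_similarity(m, revcomp_pwm(m), seed = 1)
  expect_equal(rc$score, 1)
  expect_equal(rc$best_orientation, "revcomp")
})

test_that("similarity is symmetric in score", {
  withr::with_seed(3, {
    a <- pwm("A", prop.table(matrix(stats::rgamma(40, 1), 4, 10), 2))
    b <- pwm("B", prop.table(matrix(stats::rgamma(48, 1), 4, 12), 2))
    sab <- motif_similarity(a, b, seed = 1)
    sba <- motif_similarity(b, a, seed = 1)
    expect_equal(sab$score, sba$score, tolerance = 1e-12)
  })
})

test_that("random independent motif pairs are almost never similar at 1e-5", {
  withr::with_seed(21, {
    n_big <- 0L
    for (i in 1:100) {
      a <- pwm("A", prop.table(matrix(stats::rgamma(40, 0.7), 4, 10), 2))
      b <- pwm("B", prop.table(matrix(stats::rgamma(40, 0.7), 4, 10), 2))
      sim <- motif_similarity(a, b, n_shuffles = 200, seed = i)
      if (sim$evalue > 1e-5) n_big <- n_big + 1L
    }
    expect_gte(n_big, 95L)
  })
})

test_that("deduplication keeps one representative per similar group", {
  a <- pwm_from_consensus("A", "ACGGTCATACGT")
  a2 <- pwm_from_consensus("A2", "ACGGTCATACGT")
  b <- pwm_from_consensus("B", "TTGACCGGTTAA")
  out <- deduplicate_motifs(list(A = a, A2 = a2, B = b),
                            n_shuffles = 500, seed = 4)
  expect_equal(names(out), c("A", "B"))
  cl <- attr(out, "clusters")
  expect_equal(unname(cl$representative[cl$motif == "A2"]), "A")

  # all-distinct set unchanged, and dedup is idempotent
  out2 <- deduplicate_motifs(out, n_shuffles = 500, seed = 4)
  expect_equal(names(out2), names(out))
})

test_that("similarity errors when no >= 4 column overlap is possible", {
  # width < 4 is rejected at construction, which enforces the overlap
  expect_error(pwm("tiny", matrix(0.25, 4, 3)), "width")
})
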