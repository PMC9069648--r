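# build small profile tibbles directly
mk_profiles <- function(enh, prom) {
  tibble::tibble(
    ep_id = paste0("ep", seq_along(enh)),
    enh_motifs = enh, prom_motifs = prom
  )
}

# presence profiles with i.i.d. planting per region
random_profiles <- function(n, motifs, p_enh, p_prom = p_enh) {
  mk_profiles(
    purrr::map(seq_len(n), ~ motifs[stats::runif(length(motifs)) < p_enh]),
    purrr::map(seq_len(n), ~ motifs[stats::runif(length(motifs)) < p_prom])
  )
}

test_that("poisson_tail matches closed forms and direct summation", {
  expect_identical(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_tail(12, 3), oracle_poisson_tail(12, 3),
               tolerance = 1e-12)
  expect_error(poisson_tail(1, 0), "lam")
})

test_that("profiles reflect scanner hits per region and flag unscanned pairs", {
  ep <- tibble::tibble(ep_id = c("p1", "p2", "p3"),
                       enh_id = c("e1", "e2", "e3"),
                       prom_id = c("r1", "r2", "r3"))
  occ <- tibble::tibble(
    motif = c("M1", "M1", "M2", "M2"),
    seq_id = c("e1", "e2", "r1", "r2"),
    start = 0L, strand = "+", score = 10, pvalue = 1e-8
  )
  pr <- build_profiles(ep, occ, scanned_ids = c("e1", "e2", "e3",
                                                "r1", "r2", "r3"))
  expect_equal(pr$enh_motifs[[1]], "M1")
  expect_equal(pr$prom_motifs[[1]], "M2")
  expect_equal(pr$enh_motifs[[3]], character(0))
  expect_equal(pr$prom_motifs[[3]], character(0))
  # exactly two profiles carry the oriented pattern M1(enh) + M2(prom)
  has <- purrr::map2_lgl(pr$enh_motifs, pr$prom_motifs,
                         ~ "M1" %in% .x && "M2" %in% .y)
  expect_equal(sum(has), 2L)
  # hits above the presence threshold do not count
  occ_weak <- dplyr::mutate(occ, pvalue = 1e-4)
  pr2 <- build_profiles(ep, occ_weak, p_threshold = 1e-5,
                        scanned_ids = c("e1", "e2", "e3", "r1", "r2", "r3"))
  expect_true(all(lengths(pr2$enh_motifs) == 0L))

  expect_error(build_profiles(ep, occ, scanned_ids = c("e1", "r1")), "p2")
})

test_that("planted module is found; empty when support is unreachable", {
  withr::with_seed(31, {
    motifs <- sprintf("M%02d", 1:8)
    pr <- random_profiles(500, motifs, 0.05)
    # plant {M01 enh, M02 prom} jointly in 200 profiles
    idx <- sample.int(500, 200)
    pr$enh_motifs[idx] <- purrr::map(pr$enh_motifs[idx], ~ union(.x, "M01"))
    pr$prom_motifs[idx] <- purrr::map(pr$prom_motifs[idx], ~ union(.x, "M02"))
    mods <- find_modules(pr, min_support = 30)
    expect_true(any(purrr::map_lgl(mods$motifs,
                                   ~ setequal(.x, c("M01", "M02")))))
    expect_equal(nrow(find_modules(pr, min_support = 501)), 0L)
  })
})

test_that("Apriori enumeration equals the brute-force subset oracle", {
  withr::with_seed(13, {
    motifs <- sprintf("M%02d", 1:12)
    pr <- random_profiles(200, motifs, 0.35)
    min_support <- 8
    got <- find_modules(pr, min_support = min_support, max_size = 5,
                        alpha = 1.01)  # keep everything: compare enumeration
    want <- oracle_modules(pr, min_support, 5)
    key <- function(s) paste(sort(s), collapse = ",")
    got_keys <- sort(purrr::map_chr(got$motifs, key))
    want_keys <- sort(purrr::map_chr(want, ~ key(.x$motifs)))
    expect_equal(got_keys, want_keys)
    want_support <- setNames(purrr::map_int(want, "support"),
                             purrr::map_chr(want, ~ key(.x$motifs)))
    expect_equal(unname(want_support[purrr::map_chr(got$motifs, key)]),
                 got$support)
  })
})

test_that("independence null yields no corrected-significant modules", {
  withr::with_seed(77, {
    motifs <- sprintf("M%02d", 1:10)
    clean <- 0L
    for (i in 1:20) {
      pr <- random_profiles(500, motifs, 0.05)
      mods <- find_modules(pr, min_support = 30)
      if (nrow(mods) == 0L) clean <- clean + 1L
    }
    expect_gte(clean, 19L)
  })
})

test_that("oriented pairs honour region classes and hand counts", {
  # M1 only in enhancers, M2 only in promoters -> single forced orientation
  pr <- mk_profiles(
    c(rep(list("M1"), 40), rep(list(character(0)), 10)),
    c(rep(list("M2"), 40), rep(list(character(0)), 10))
  )
  mods <- tibble::tibble(motifs = list(c("M1", "M2")), size = 2L,
                         support = 40L, lambda = 1, pvalue = 1e-10,
                         pvalue_corrected = 1e-10)
  pairs <- extract_pairs(mods, pr, min_support = 30)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$motif_E, "M1")
  expect_equal(pairs$motif_P, "M2")
  expect_equal(pairs$support_k, 40L)
  expect_equal(pairs$a_count, 40, ignore_attr = TRUE)
  expect_equal(pairs$N, 40 + 10)
  expect_equal(pairs$lambda, 40 * 40 / 50, ignore_attr = TRUE)

  # both motifs only in enhancers -> no pair
  pr2 <- mk_profiles(
    rep(list(c("M1", "M2")), 50),
    rep(list(character(0)), 50)
  )
  expect_equal(nrow(extract_pairs(mods, pr2, min_support = 30)), 0L)

  # both orientations present and supported -> both reported
  pr3 <- mk_profiles(
    rep(list(c("M1", "M2")), 50),
    rep(list(c("M1", "M2")), 50)
  )
  pairs3 <- extract_pairs(mods, pr3, min_support = 30)
  expect_equal(nrow(pairs3), 2L)
})

test_that("multiple-testing correction follows Bonferroni and BH", {
  pairs <- tibble::tibble(
    motif_E = sprintf("E%02d", 1:10), motif_P = sprintf("P%02d", 1:10),
    support_k = 30L, a_count = 50, b_count = 50, N = 100,
    lambda = 25, pvalue = rep(1e-4, 10)
  )
  out <- correct_pvalues(pairs, alpha = 0.01)
  expect_equal(out$pvalue_corrected, rep(1e-3, 10))
  expect_true(all(out$significant))
  one <- correct_pvalues(pairs[1, ])
  expect_equal(one$pvalue_corrected, one$pvalue)

  # BH against a direct step-up implementation
  withr::with_seed(2, {
    for (i in 1:20) {
      p <- stats::runif(sample(3:25, 1L))
      df <- tibble::tibble(motif_E = as.character(seq_along(p)),
                           motif_P = "x", support_k = 1L, a_count = 1,
                           b_count = 1, N = 1, lambda = 1, pvalue = p)
      got <- correct_pvalues(df, method = "BH")$pvalue_corrected
      m <- length(p)
      o <- order(p)
      stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
      want <- numeric(m); want[o] <- pmin(1, stepup)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("null raw p-values of oriented pairs are not anti-conservative", {
  withr::with_seed(55, {
    motifs <- sprintf("M%02d", 1:8)
    fracs <- c()
    for (rep in 1:5) {
      pr <- random_profiles(400, motifs, 0.35)
      mods <- tibble::tibble(motifs = utils::combn(motifs, 2, simplify = FALSE))
      mods$size <- 2L; mods$support <- 999L; mods$lambda <- 1
      mods$pvalue <- 0; mods$pvalue_corrected <- 0
      pairs <- extract_pairs(mods, pr, min_support = 1)
      for (alpha in c(0.01, 0.05)) {
        fracs <- c(fracs, mean(pairs$pvalue < alpha) / alpha)
      }
    }
    # Poisson-approximation conservativeness band
    expect_true(all(fracs <= 2))
  })
})
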