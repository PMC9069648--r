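# Shared builders and independent oracles for the test suite.

pwm_from_consensus <- function(name, cons, major = 0.97) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(cons, "")[[1L]], bases)
  stopifnot(!anyNA(idx))
  probs <- matrix((1 - major) / 3, 4L, length(idx))
  probs[cbind(idx, seq_along(idx))] <- major
  pwm(name, probs)
}

random_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

with_seed_sample <- function(seed, x) withr::with_seed(seed, sample(x))

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# --- independent tail oracles (direct term-by-term summation) -------------

oracle_binom_tail <- function(n, N, p) {
  if (n == 0) return(1)
  sum(vapply(n:N, function(i) choose(N, i) * p^i * (1 - p)^(N - i),
             numeric(1L)))
}

oracle_poisson_tail <- function(k, lam) {
  if (k == 0) return(1)
  1 - sum(vapply(0:(k - 1), function(i) exp(-lam) * lam^i / factorial(i),
                 numeric(1L)))
}

# P(X >= m) for hypergeometric: draws from universe with M successes
oracle_hyper_tail <- function(m, draws, M, universe) {
  if (m == 0) return(1)
  ks <- m:min(draws, M)
  sum(vapply(ks, function(k) {
    choose(M, k) * choose(universe - M, draws - k) / choose(universe, draws)
  }, numeric(1L)))
}

# --- brute-force scanner oracle -------------------------------------------

# scores every window on both strands; p-values by full word enumeration
oracle_scan <- function(m, seq, bg = rep(0.25, 4), p_threshold = 1e-4) {
  bases <- c("A", "C", "G", "T")
  w <- m$width
  all_words <- function() {
    g <- expand.grid(rep(list(1:4), w))[, w:1, drop = FALSE]
    as.matrix(g)
  }
  word_stats <- function(probs) {
    lod <- log2(sweep(probs, 1L, bg, "/"))
    words <- all_words()
    scores <- numeric(nrow(words))
    wts <- numeric(nrow(words))
    for (r in seq_len(nrow(words))) {
      scores[r] <- sum(lod[cbind(words[r, ], seq_len(w))])
      wts[r] <- prod(bg[words[r, ]])
    }
    list(scores = scores, wts = wts, lod = lod)
  }
  pval_of <- function(stats, s) sum(stats$wts[stats$scores >= s - 1e-9])
  out <- list()
  ch <- strsplit(seq, "")[[1L]]
  enc <- match(ch, bases)
  for (strand in c("+", "-")) {
    probs <- if (strand == "+") m$probs else revcomp_pwm(m)$probs
    st <- word_stats(probs)
    nw <- length(enc) - w + 1L
    if (nw < 1L) next
    for (o in seq_len(nw)) {
      win <- enc[o:(o + w - 1L)]
      if (anyNA(win)) next
      s <- sum(st$lod[cbind(win, seq_len(w))])
      p <- pval_of(st, s)
      if (p < p_threshold) {
        out[[length(out) + 1L]] <- tibble::tibble(
          motif = m$name, start = o - 1L, strand = strand,
          score = s, pvalue = p
        )
      }
    }
  }
  dplyr::bind_rows(out) |>
    (\(d) if (nrow(d) > 0) dplyr::arrange(d, start, strand) else d)()
}

# --- brute-force frequent-itemset oracle ----------------------------------

oracle_modules <- function(profiles, min_support, max_size) {
  motifs <- sort(unique(c(unlist(profiles$enh_motifs),
                          unlist(profiles$prom_motifs))))
  any_sets <- purrr::map2(profiles$enh_motifs, profiles$prom_motifs, union)
  out <- list()
  for (k in 2:max_size) {
    if (length(motifs) < k) break
    sets <- utils::combn(motifs, k, simplify = FALSE)
    for (s in sets) {
      sup <- sum(vapply(any_sets, function(a) all(s %in% a), logical(1L)))
      if (sup >= min_support) {
        out[[length(out) + 1L]] <- list(motifs = s, support = sup)
      }
    }
  }
  out
}

# --- toy EP fixture --------------------------------------------------------

# hand-built contact matrix + annotations used in several tests:
# chr1, resolution 50 kb
#   bins (0, 100000)      value 42   -> interacting
#   bins (0, 150000)      value 30   -> neither (not > 30, not < 5)
#   bins (50000, 200000)  value  4   -> non-interacting
#   bins (0, 250000)      value 160  -> interacting (also at cutoff 150)
toy_contacts <- function() {
  as_contacts(tibble::tibble(
    chrom = "chr1",
    bin_a = c(0, 0, 50000, 0),
    bin_b = c(100000, 150000, 200000, 250000),
    value = c(42, 30, 4, 160)
  ), resolution = 50000)
}

toy_enhancers <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(10000L, 60000L, 90000L),
    end   = c(10500L, 60300L, 90400L),
    name = c("E1", "E2", "E3"), score = 0, strand = "."
  )
}

toy_tss <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    chrom = "chr1",
    tss = c(120000L, 220000L, 260000L),
    strand = c("+", "+", "-")
  )
}
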