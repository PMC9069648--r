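#' Homogeneous motif-pair tests
#'
#' Tests, per motif, whether the same motif co-occurs in both the enhancer
#' and the promoter of interacting EP pairs more often than chance. With
#' `N` EP pairs of which `n` carry the motif in both regions, the p-value is
#' the binomial upper tail `P(X >= n)` with `X ~ Binomial(N, p)`:
#'
#' * `variant = "length_aware"`: `p = x / (N * (l1 + l2))`, where `x` is the
#'   total number of motif instances across the N pairs and `l1`, `l2` are
#'   the mean promoter and enhancer lengths in bp (a per-base occurrence
#'   rate).
#' * `variant = "presence_based"`: `p = x * y / N^2`, where `x` enhancers and
#'   `y` promoters contain the motif.
#'
#' A motif is significant when the p-value is below `alpha / K`, with `K`
#' the number of motifs tested.
#'
#' @param profiles Tibble from [build_profiles()].
#' @param occurrences Scanner hits (needed for `length_aware`; instance
#'   counts use every hit passing `p_threshold`).
#' @param ep_pairs EP-pair tibble with sequences attached (used to compute
#'   mean region lengths for `length_aware`); alternatively pass `l1`/`l2`.
#' @param variant Which null model (see above); default both.
#' @param K Number of motifs tested (defaults to the number of motifs in the
#'   profiles).
#' @param alpha Family significance level (default 0.01).
#' @param p_threshold Instance p-value cutoff for counting occurrences.
#' @param l1,l2 Mean promoter / enhancer length in bp (computed from
#'   `ep_pairs` when omitted).
#' @return Tibble with one row per motif and variant: `motif`, `variant`,
#'   `N`, `n`, `x`, `y`, `l1`, `l2`, `K`, `p_success`, `pvalue`,
#'   `significant`.
#' @export
homogeneous_tests <- function(profiles, occurrences = NULL, ep_pairs = NULL,
                              variant = c("length_aware", "presence_based"),
                              K = NULL, alpha = 0.01, p_threshold = 1e-5,
                              l1 = NULL, l2 = NULL) {
  variant <- match.arg(variant, several.ok = TRUE)
  pm <- profile_matrices(profiles)
  N <- nrow(profiles)
  motifs <- pm$motifs
  K <- K %||% length(motifs)
  if (K < 1L) return(tibble::tibble())
  if ("length_aware" %in% variant) {
    if (is.null(l1) || is.null(l2)) {
      if (is.null(ep_pairs)) {
        stop("length_aware variant needs ep_pairs (or l1 and l2)")
      }
      l1 <- mean(ep_pairs$prom_end - ep_pairs$prom_start)
      l2 <- mean(ep_pairs$enh_end - ep_pairs$enh_start)
    }
    if (is.null(occurrences)) {
      stop("length_aware variant needs scanner occurrences")
    }
  }
  n_both <- unname(colSums(pm$enh & pm$prom))
  x_enh <- unname(colSums(pm$enh))
  y_prom <- unname(colSums(pm$prom))

  res <- list()
  if ("length_aware" %in% variant) {
    occ <- dplyr::filter(occurrences, .data$pvalue < p_threshold)
    if (!is.null(ep_pairs)) {
      # restrict instance counts to the sequences of these EP pairs
      occ <- dplyr::filter(occ, .data$seq_id %in%
                             c(ep_pairs$enh_id, ep_pairs$prom_id))
    }
    counts <- table(factor(occ$motif, levels = motifs))
    x_tot <- as.integer(counts[motifs])
    p1 <- x_tot / (N * (l1 + l2))
    bad <- which(p1 >= 1)
    if (length(bad) > 0L) {
      stop("degenerate per-base rate (p >= 1) for motif ",
           motifs[bad[1L]])
    }
    keep <- x_tot >= 1L
    res$length_aware <- tibble::tibble(
      motif = motifs[keep], variant = "length_aware",
      N = N, n = as.integer(n_both[keep]), x = x_tot[keep], y = NA_integer_,
      l1 = l1, l2 = l2, K = K,
      p_success = p1[keep],
      pvalue = binom_upper_tail(n_both[keep], N, p1[keep])
    )
  }
  if ("presence_based" %in% variant) {
    p2 <- x_enh * y_prom / (N * N)
    incons <- which((x_enh == 0 | y_prom == 0) & n_both > 0)
    if (length(incons) > 0L) {
      stop("inconsistent counts for motif ", motifs[incons[1L]],
           ": n > 0 with x = 0 or y = 0")
    }
    if (any(p2 >= 1)) {
      stop("degenerate presence rate (p >= 1) for motif ",
           motifs[which(p2 >= 1)[1L]])
    }
    keep <- p2 > 0
    res$presence_based <- tibble::tibble(
      motif = motifs[keep], variant = "presence_based",
      N = N, n = as.integer(n_both[keep]), x = as.integer(x_enh[keep]),
      y = as.integer(y_prom[keep]),
      l1 = NA_real_, l2 = NA_real_, K = K,
      p_success = p2[keep],
      pvalue = binom_upper_tail(n_both[keep], N, p2[keep])
    )
  }
  out <- dplyr::bind_rows(res)
  out$significant <- out$pvalue < alpha / K
  dplyr::arrange(out, .data$variant, .data$pvalue, .data$motif)
}

#' Enhancer/promoter preference tests
#'
#' Tests, per motif, whether it occurs preferentially in enhancers or in
#' promoters, by a binomial tail on the split of carrier sequences. With
#' `e` enhancers and `p` promoters containing the motif:
#'
#' * `count_only`: success probability 0.5 (regions exchangeable);
#' * `length_aware`: success probability `l2 / (l1 + l2)` for an enhancer
#'   carrier, accounting for mean promoter length `l1` and mean enhancer
#'   length `l2`.
#'
#' `pvalue_enh` is `P(X >= e)` (enhancer preference), `pvalue_prom` is
#' `P(X >= p)` under the complementary probability.
#'
#' @inheritParams homogeneous_tests
#' @return Tibble: `motif`, `variant`, `e_hits`, `p_hits`, `p_success`,
#'   `pvalue_enh`, `pvalue_prom`.
#' @export
preference_tests <- function(profiles, ep_pairs = NULL,
                             variant = c("count_only", "length_aware"),
                             l1 = NULL, l2 = NULL) {
  variant <- match.arg(variant, several.ok = TRUE)
  pm <- profile_matrices(profiles)
  e_hits <- unname(colSums(pm$enh))
  p_hits <- unname(colSums(pm$prom))
  keep <- e_hits + p_hits >= 1L
  motifs <- pm$motifs[keep]
  e_hits <- e_hits[keep]; p_hits <- p_hits[keep]
  if ("length_aware" %in% variant && (is.null(l1) || is.null(l2))) {
    if (is.null(ep_pairs)) {
      stop("length_aware variant needs ep_pairs (or l1 and l2)")
    }
    l1 <- mean(ep_pairs$prom_end - ep_pairs$prom_start)
    l2 <- mean(ep_pairs$enh_end - ep_pairs$enh_start)
  }
  one <- function(v, p_e) {
    tibble::tibble(
      motif = motifs, variant = v,
      e_hits = as.integer(e_hits), p_hits = as.integer(p_hits),
      p_success = p_e,
      pvalue_enh = binom_upper_tail(e_hits, e_hits + p_hits, p_e),
      pvalue_prom = binom_upper_tail(p_hits, e_hits + p_hits, 1 - p_e)
    )
  }
  out <- list()
  if ("count_only" %in% variant) out$count_only <- one("count_only", 0.5)
  if ("length_aware" %in% variant) {
    out$length_aware <- one("length_aware", l2 / (l1 + l2))
  }
  dplyr::bind_rows(out)
}

#' Read a TF-TF interaction list
#'
#' Two-column TSV (`tf_a`, `tf_b`, optional `type` in direct/indirect).
#' Symmetric duplicates and self-pairs are removed; names are matched
#' case-insensitively (stored uppercase).
#'
#' @param path Path to the TSV (optional `#` header).
#' @return Tibble with `tf_a`, `tf_b` (alphabetical within pair), `type`.
#' @export
read_tf_interactions <- function(path) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2L) stop("interaction list needs at least two columns")
  out <- tibble::tibble(
    tf_a = toupper(df[[1L]]),
    tf_b = toupper(df[[2L]]),
    type = if (ncol(df) >= 3L) tolower(df[[3L]]) else "direct"
  )
  a <- pmin(out$tf_a, out$tf_b)
  b <- pmax(out$tf_a, out$tf_b)
  out$tf_a <- a
  out$tf_b <- b
  out |>
    dplyr::filter(.data$tf_a != .data$tf_b) |>
    dplyr::distinct(.data$tf_a, .data$tf_b, .keep_all = TRUE)
}

#' Map predicted motifs to database TFs by motif similarity
#'
#' @param predicted Named list of predicted `pwm`s.
#' @param library Named list of library `pwm`s whose names are TF symbols.
#' @param mode `"all"`: every TF whose motif is similar below
#'   `evalue_cutoff`; `"best"`: only the TF with the smallest E-value (ties
#'   broken lexicographically).
#' @param evalue_cutoff Similarity E-value cutoff (default 1e-5).
#' @param n_shuffles,seed Passed to [motif_similarity()].
#' @return Named list mapping each predicted motif name to a character vector
#'   of TF symbols (possibly empty).
#' @export
map_motifs_to_tfs <- function(predicted, library, mode = c("all", "best"),
                              evalue_cutoff = 1e-5, n_shuffles = 1000,
                              seed = 1) {
  mode <- match.arg(mode)
  n_comp <- length(predicted) * length(library)
  out <- purrr::imap(predicted, function(m, nm) {
    sims <- purrr::map_dfr(library, function(lib) {
      motif_similarity(m, lib, n_shuffles = n_shuffles,
                       n_comparisons = n_comp, seed = seed)
    })
    hit <- dplyr::filter(sims, .data$evalue < evalue_cutoff)
    if (nrow(hit) == 0L) return(character(0))
    if (mode == "best") {
      hit <- dplyr::arrange(hit, .data$evalue, .data$motif_b)
      toupper(hit$motif_b[1L])
    } else {
      sort(unique(toupper(hit$motif_b)))
    }
  })
  out
}

#' Hypergeometric enrichment of predicted TF pairs in an interaction database
#'
#' With `N_tfs` TFs and `M_pairs` interacting pairs in the database, and
#' `n_tfs` distinct database-mappable TFs among the predictions forming
#' `n_tfs*(n_tfs-1)/2` candidate pairs of which `m_pairs` are in the
#' database, the p-value is the upper tail of the hypergeometric
#' distribution: the probability of at least `m_pairs` database pairs when
#' drawing `n_tfs*(n_tfs-1)/2` pairs from the universe of
#' `N_tfs*(N_tfs-1)/2`.
#'
#' @param predicted_tf_pairs Tibble with `tf_a`, `tf_b` (predicted pairs).
#' @param db Interaction tibble from [read_tf_interactions()].
#' @param db_tfs TF namespace of the database (default: every TF appearing
#'   in `db`); predicted TFs outside it are dropped with a message.
#' @param mode `"direct"` or `"direct_plus_indirect"`: which database pairs
#'   count.
#' @return One-row tibble: `N_tfs`, `M_pairs`, `n_tfs`, `m_pairs`, `pvalue`,
#'   `mode`.
#' @export
hypergeom_enrichment <- function(predicted_tf_pairs, db, db_tfs = NULL,
                                 mode = c("direct", "direct_plus_indirect")) {
  mode <- match.arg(mode)
  dbp <- if (mode == "direct") {
    dplyr::filter(db, .data$type == "direct")
  } else {
    db
  }
  db_tfs <- toupper(db_tfs %||% unique(c(dbp$tf_a, dbp$tf_b)))
  pred <- tibble::tibble(
    tf_a = pmin(toupper(predicted_tf_pairs$tf_a),
                toupper(predicted_tf_pairs$tf_b)),
    tf_b = pmax(toupper(predicted_tf_pairs$tf_a),
                toupper(predicted_tf_pairs$tf_b))
  ) |>
    dplyr::filter(.data$tf_a != .data$tf_b) |>
    dplyr::distinct()
  n_dropped <- sum(!(pred$tf_a %in% db_tfs) | !(pred$tf_b %in% db_tfs))
  if (n_dropped > 0L) {
    message(n_dropped, " predicted pair(s) with TF(s) outside the database ",
            "namespace dropped")
  }
  pred <- dplyr::filter(pred, .data$tf_a %in% db_tfs, .data$tf_b %in% db_tfs)
  N_tfs <- length(db_tfs)
  M_pairs <- nrow(dplyr::distinct(dbp, .data$tf_a, .data$tf_b))
  n_tfs <- length(unique(c(pred$tf_a, pred$tf_b)))
  m_pairs <- nrow(dplyr::semi_join(pred, dbp, by = c("tf_a", "tf_b")))
  draws <- n_tfs * (n_tfs - 1) / 2
  universe <- N_tfs * (N_tfs - 1) / 2
  if (m_pairs > M_pairs || m_pairs > draws) {
    stop("inconsistent counts: m_pairs exceeds M_pairs or candidate pairs")
  }
  pvalue <- if (m_pairs == 0) {
    1
  } else {
    phyper(m_pairs - 1, M_pairs, universe - M_pairs, draws,
           lower.tail = FALSE)
  }
  tibble::tibble(N_tfs = N_tfs, M_pairs = M_pairs, n_tfs = n_tfs,
                 m_pairs = m_pairs, pvalue = pvalue, mode = mode)
}
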