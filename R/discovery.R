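#' Upper tail of the Poisson distribution
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, evaluated in log space; exactly 1 at
#' `k = 0`. This is the clumping-heuristic tail used to score motif module
#' and motif pair co-occurrence against its independence expectation.
#'
#' @param k Non-negative integer count (vectorized).
#' @param lam Positive Poisson mean.
#' @return `P(X >= k)`.
#' @export
poisson_tail <- function(k, lam) {
  stopifnot(all(k >= 0), all(k == floor(k)))
  if (any(lam <= 0)) stop("lam must be > 0")
  ifelse(k == 0, 1, ppois(k - 1, lam, lower.tail = FALSE))
}

#' Upper tail of the binomial distribution
#'
#' `P(X >= n)` for `X ~ Binomial(N, p)` (the tail includes `i = n`),
#' evaluated in log space; exactly 1 at `n = 0`.
#'
#' @param n Observed count (vectorized).
#' @param N Number of trials.
#' @param p Success probability in (0, 1).
#' @return `P(X >= n)`.
#' @export
binom_upper_tail <- function(n, N, p) {
  stopifnot(all(n >= 0), all(n <= N))
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  ifelse(n == 0, 1, pbinom(n - 1, N, p, lower.tail = FALSE))
}

#' Build per-EP-pair motif occurrence profiles
#'
#' Converts scanner hits into presence/absence profiles: which motifs have at
#' least one instance in the enhancer and which in the promoter of each EP
#' pair. Presence is assessed at `p_threshold`, which defaults to a stricter
#' value (1e-5) than the scan-reporting threshold because presence/absence
#' co-occurrence statistics are sensitive to the per-kilobase false-instance
#' rate of a permissive scan.
#'
#' @param ep_pairs Tibble from [build_ep_pairs()] (needs `ep_id`, `enh_id`,
#'   `prom_id`).
#' @param occurrences Hit tibble from [scan_motifs()] with attribute
#'   `scanned_ids` (or pass `scanned_ids`).
#' @param p_threshold Instances with `pvalue < p_threshold` count toward
#'   presence.
#' @param scanned_ids Optional character vector of all sequence IDs that were
#'   scanned; defaults to `attr(occurrences, "scanned_ids")`.
#' @return Tibble with columns `ep_id`, `enh_motifs` (list), `prom_motifs`
#'   (list).
#' @export
build_profiles <- function(ep_pairs, occurrences, p_threshold = 1e-5,
                           scanned_ids = NULL) {
  scanned_ids <- scanned_ids %||% attr(occurrences, "scanned_ids")
  if (is.null(scanned_ids)) {
    stop("scanned_ids not available; pass the scan_motifs() result or ",
         "scanned_ids explicitly")
  }
  unscanned <- ep_pairs$ep_id[!(ep_pairs$enh_id %in% scanned_ids) |
                                !(ep_pairs$prom_id %in% scanned_ids)]
  if (length(unscanned) > 0L) {
    stop("EP pair(s) whose sequences were never scanned: ",
         paste(head(unscanned, 3L), collapse = ", "))
  }
  occ <- dplyr::filter(occurrences, .data$pvalue < p_threshold)
  by_seq <- split(occ$motif, occ$seq_id)
  motif_set <- function(ids) {
    out <- by_seq[ids]
    out <- purrr::map(out, unique)
    out[purrr::map_lgl(out, is.null)] <- list(character(0))
    unname(out)
  }
  tibble::tibble(
    ep_id = ep_pairs$ep_id,
    enh_motifs = motif_set(ep_pairs$enh_id),
    prom_motifs = motif_set(ep_pairs$prom_id)
  )
}

profile_matrices <- function(profiles) {
  motifs <- sort(unique(c(unlist(profiles$enh_motifs),
                          unlist(profiles$prom_motifs))))
  n <- nrow(profiles)
  mk <- function(col) {
    M <- matrix(FALSE, n, length(motifs), dimnames = list(NULL, motifs))
    idx <- tibble::tibble(
      row = rep(seq_len(n), lengths(col)),
      motif = unlist(col)
    )
    if (nrow(idx) > 0L) M[cbind(idx$row, match(idx$motif, motifs))] <- TRUE
    M
  }
  enh <- mk(profiles$enh_motifs)
  prom <- mk(profiles$prom_motifs)
  list(motifs = motifs, enh = enh, prom = prom, any = enh | prom)
}

#' Find significantly co-occurring motif modules
#'
#' Apriori-style level-wise enumeration of motif sets (sizes 2 to
#' `max_size`) over the per-EP-pair union profiles (motif present in either
#' region), with anti-monotone pruning at `min_support`. Each candidate
#' module's support is compared with its independence expectation
#' `lambda = N * prod(member marginal frequencies)` by a Poisson upper tail;
#' modules significant after Bonferroni correction (over the number of
#' support-passing candidates) at `alpha` are returned.
#'
#' @param profiles Tibble from [build_profiles()].
#' @param min_support Minimum number of EP profiles containing all members
#'   (default 30).
#' @param max_size Maximum module size (default 5).
#' @param alpha Significance level on the corrected p-value (default 0.01).
#' @return Tibble with `motifs` (list column), `size`, `support`, `lambda`,
#'   `pvalue`, `pvalue_corrected`; attribute `n_tested` is the Bonferroni
#'   denominator.
#' @export
find_modules <- function(profiles, min_support = 30, max_size = 5,
                         alpha = 0.01) {
  stopifnot(min_support >= 1)
  pm <- profile_matrices(profiles)
  N <- nrow(profiles)
  counts <- colSums(pm$any)
  freq <- counts / N
  frequent1 <- names(counts)[counts >= min_support]
  out <- list()
  level <- purrr::map(frequent1, identity)   # itemsets as sorted char vectors
  level_cols <- purrr::map(frequent1, function(m) pm$any[, m])
  k <- 1L
  while (k < max_size && length(level) > 0L) {
    k <- k + 1L
    # candidate generation: join sets sharing the first k-2 items
    keys <- purrr::map_chr(level, function(s) {
      paste(s[-length(s)], collapse = "\r")
    })
    cand <- list(); cand_cols <- list()
    for (grp in split(seq_along(level), keys)) {
      if (length(grp) < 2L) next
      for (a in seq_len(length(grp) - 1L)) {
        for (b in (a + 1L):length(grp)) {
          i <- grp[a]; j <- grp[b]
          set <- sort(union(level[[i]], level[[j]]))
          if (length(set) != k) next
          col <- level_cols[[i]] & level_cols[[j]]
          sup <- sum(col)
          if (sup < min_support) next
          cand[[length(cand) + 1L]] <- set
          cand_cols[[length(cand_cols) + 1L]] <- col
        }
      }
    }
    if (length(cand) == 0L) break
    sup <- purrr::map_int(cand_cols, sum)
    lam <- N * purrr::map_dbl(cand, function(s) prod(freq[s]))
    out[[length(out) + 1L]] <- tibble::tibble(
      motifs = cand, size = k, support = as.integer(sup), lambda = lam
    )
    level <- cand
    level_cols <- cand_cols
  }
  res <- dplyr::bind_rows(out)
  n_tested <- nrow(res)
  if (n_tested == 0L) {
    res <- tibble::tibble(motifs = list(), size = integer(),
                          support = integer(), lambda = numeric(),
                          pvalue = numeric(), pvalue_corrected = numeric())
    attr(res, "n_tested") <- 0L
    return(res)
  }
  res$pvalue <- poisson_tail(res$support, res$lambda)
  res$pvalue_corrected <- pmin(1, res$pvalue * n_tested)
  res <- dplyr::filter(res, .data$pvalue_corrected < alpha)
  attr(res, "n_tested") <- n_tested
  res
}

#' Extract oriented enhancer/promoter motif pairs from modules
#'
#' For every unordered motif pair inside a significant module, both oriented
#' hypotheses are evaluated: X in the enhancer with Y in the promoter, and
#' the flip. An orientation is kept only when its region-resolved support
#' reaches `min_support`, which drops pairs whose co-occurrence is confined
#' to a single region class. Support `k`, the region marginals `a_count`
#' (enhancers containing the E-side motif) and `b_count` (promoters
#' containing the P-side motif), the independence expectation
#' `lambda = a_count * b_count / N`, and the Poisson upper-tail p-value are
#' computed from the profiles.
#'
#' @param modules Tibble from [find_modules()].
#' @param profiles Tibble from [build_profiles()].
#' @param min_support Minimum oriented support (default 30).
#' @return Tibble with `motif_E`, `motif_P`, `support_k`, `a_count`,
#'   `b_count`, `N`, `lambda`, `pvalue` (uncorrected; see
#'   [correct_pvalues()]).
#' @export
extract_pairs <- function(modules, profiles, min_support = 30) {
  pm <- profile_matrices(profiles)
  N <- nrow(profiles)
  empty <- tibble::tibble(
    motif_E = character(), motif_P = character(), support_k = integer(),
    a_count = integer(), b_count = integer(), N = integer(),
    lambda = numeric(), pvalue = numeric()
  )
  if (nrow(modules) == 0L) return(empty)
  oriented <- modules$motifs |>
    purrr::map(function(s) {
      if (length(s) < 2L) return(NULL)
      un <- combn(sort(s), 2L)
      tibble::tibble(motif_E = c(un[1L, ], un[2L, ]),
                     motif_P = c(un[2L, ], un[1L, ]))
    }) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
  if (nrow(oriented) == 0L) return(empty)
  oriented |>
    dplyr::mutate(
      support_k = purrr::map2_int(.data$motif_E, .data$motif_P, function(x, y) {
        sum(pm$enh[, x] & pm$prom[, y])
      }),
      a_count = colSums(pm$enh)[.data$motif_E],
      b_count = colSums(pm$prom)[.data$motif_P],
      N = N
    ) |>
    dplyr::filter(.data$support_k >= min_support,
                  .data$a_count > 0, .data$b_count > 0) |>
    dplyr::mutate(
      lambda = .data$a_count * .data$b_count / .data$N,
      pvalue = poisson_tail(.data$support_k, .data$lambda)
    ) |>
    dplyr::arrange(.data$pvalue, .data$motif_E, .data$motif_P)
}

#' Correct motif-pair p-values for multiple testing
#'
#' Bonferroni by default (`pvalue * number of oriented pairs tested`, capped
#' at 1); Benjamini-Hochberg available as `method = "BH"`. Flags the
#' significant subset at `alpha`.
#'
#' @param pairs Tibble from [extract_pairs()].
#' @param method `"bonferroni"` or `"BH"`.
#' @param alpha Significance level on the corrected value (default 0.01).
#' @return `pairs` with `pvalue_corrected` and `significant` columns.
#' @export
correct_pvalues <- function(pairs, method = c("bonferroni", "BH"),
                            alpha = 0.01) {
  method <- match.arg(method)
  if (nrow(pairs) == 0L) {
    pairs$pvalue_corrected <- numeric(0)
    pairs$significant <- logical(0)
    return(pairs)
  }
  pairs$pvalue_corrected <- stats::p.adjust(
    pairs$pvalue, method = if (method == "bonferroni") "bonferroni" else "BH")
  pairs$significant <- pairs$pvalue_corrected < alpha
  pairs
}

#' Discover motif pairs from EP pairs and scanner occurrences
#'
#' Convenience wrapper: profiles -> modules -> oriented pairs -> correction.
#'
#' @inheritParams build_profiles
#' @inheritParams find_modules
#' @inheritParams correct_pvalues
#' @return Corrected motif-pair tibble (see [correct_pvalues()]); attributes
#'   `modules` and `profiles` carry the intermediates.
#' @export
discover_motif_pairs <- function(ep_pairs, occurrences, p_threshold = 1e-5,
                                 min_support = 30, max_size = 5,
                                 alpha = 0.01,
                                 method = c("bonferroni", "BH")) {
  profiles <- build_profiles(ep_pairs, occurrences, p_threshold = p_threshold)
  modules <- find_modules(profiles, min_support = min_support,
                          max_size = max_size, alpha = alpha)
  pairs <- extract_pairs(modules, profiles, min_support = min_support)
  pairs <- correct_pvalues(pairs, method = method, alpha = alpha)
  attr(pairs, "modules") <- modules
  attr(pairs, "profiles") <- profiles
  pairs
}
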