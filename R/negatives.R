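#' Type-1 negatives: per-sequence nucleotide permutation
#'
#' Each positive EP pair yields one negative pair whose enhancer and
#' promoter sequences are independent random permutations of the positive
#' pair's sequences (mononucleotide shuffle; exact composition preserved).
#' `dinucleotide = TRUE` uses a dinucleotide-preserving Eulerian shuffle
#' instead.
#'
#' @param positives EP-pair tibble with `enh_seq`/`prom_seq` columns (see
#'   [add_ep_sequences()]).
#' @param seed Integer seed; output is a pure function of (input, seed).
#' @param dinucleotide Preserve dinucleotide composition.
#' @return EP-pair tibble with shuffled sequences, `label = "negative1"`,
#'   new `ep_id`/`enh_id`/`prom_id` suffixed `_perm`; attribute `provenance`
#'   records seed and parameters.
#' @export
make_type1 <- function(positives, seed = 1, dinucleotide = FALSE) {
  if (is.null(positives$enh_seq) || is.null(positives$prom_seq)) {
    stop("positives must carry enh_seq and prom_seq")
  }
  shuf <- if (dinucleotide) shuffle_dinuc else shuffle_strings
  out <- positives
  with_local_seed(seed, {
    out$enh_seq <- shuf(positives$enh_seq)
    out$prom_seq <- shuf(positives$prom_seq)
  })
  out$label <- "negative1"
  out$enh_id <- paste0(out$enh_id, "_perm")
  out$prom_id <- paste0(out$prom_id, "_perm")
  out$ep_id <- paste0(out$ep_id, "_perm")
  attr(out, "provenance") <- list(kind = "type1_permuted", seed = seed,
                                  dinucleotide = dinucleotide)
  out
}

#' Type-2 negatives: random genomic regions in place of enhancers
#'
#' Keeps each positive pair's promoter and replaces the enhancer with a
#' random genomic region of exactly the same length, at a TSS distance drawn
#' from the empirical positive distance distribution (with replacement,
#' random side, clipped into `[min_distance, max_distance]` and chromosome
#' bounds). Sampled regions must not overlap `excluded_regions`; after
#' `max_attempts` failed draws the pair is skipped with a warning.
#'
#' @param positives EP-pair tibble (midpoint-to-TSS distances assumed).
#' @param genome Genome tibble (`id`, `seq`) for chromosome bounds and
#'   sequence extraction.
#' @param excluded_regions Tibble of intervals the sampled regions must not
#'   overlap (default: the positive enhancers and promoters).
#' @param seed Integer seed.
#' @param min_distance,max_distance Distance clip bounds in bp.
#' @param max_attempts Resampling attempts per pair.
#' @return EP-pair tibble with `label = "negative2"` and resampled enhancer
#'   coordinates/sequences; attribute `provenance` records the seed.
#' @export
make_type2 <- function(positives, genome, excluded_regions = NULL, seed = 1,
                       min_distance = 2500, max_distance = 2e6,
                       max_attempts = 100) {
  if (is.null(excluded_regions)) {
    excluded_regions <- dplyr::bind_rows(
      tibble::tibble(chrom = positives$chrom, start = positives$enh_start,
                     end = positives$enh_end),
      tibble::tibble(chrom = positives$chrom, start = positives$prom_start,
                     end = positives$prom_end)
    )
  }
  chrom_len <- setNames(nchar(genome$seq), genome$id)
  excl <- split(excluded_regions[, c("start", "end")], excluded_regions$chrom)
  overlaps_excl <- function(chrom, s, e) {
    ex <- excl[[chrom]]
    if (is.null(ex)) return(FALSE)
    any(ex$start < e & s < ex$end)
  }
  n <- nrow(positives)
  out <- positives
  keep <- logical(n)
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      len <- positives$enh_end[i] - positives$enh_start[i]
      tss <- positives$tss[i]
      chrom <- positives$chrom[i]
      L <- chrom_len[[chrom]]
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        d <- sample(positives$distance, 1L)
        d <- min(max(d, min_distance), max_distance)
        side <- if (sample.int(2L, 1L) == 1L) 1L else -1L
        mid <- tss + side * d
        s <- as.integer(round(mid - len / 2))
        e <- s + len
        if (s < 0L || e > L) next
        if (overlaps_excl(chrom, s, e)) next
        out$enh_start[i] <- s
        out$enh_end[i] <- e
        out$distance[i] <- abs((s + e) %/% 2L - tss)
        ok <- TRUE
        break
      }
      keep[i] <- ok
    }
  })
  if (sum(!keep) > n * 0.1) {
    stop("could not place random regions for >10% of pairs; ",
         "chromosomes too short or exclusions too dense")
  }
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) skipped after ", max_attempts, " attempts")
  }
  out <- out[keep, , drop = FALSE]
  out$label <- "negative2"
  out$enh_id <- interval_id(out$chrom, out$enh_start, out$enh_end)
  out$ep_id <- paste0(out$enh_id, "|", out$gene_id, "_rand")
  enh <- extract_sequences(genome, tibble::tibble(
    chrom = out$chrom, start = out$enh_start, end = out$enh_end, strand = "."
  ))
  out$enh_seq <- enh$seq
  attr(out, "provenance") <- list(kind = "type2_random_region", seed = seed,
                                  max_attempts = max_attempts)
  out
}

#' Type-3 negatives: annotated EP pairs with low contact
#'
#' Delegates to [call_noninteracting_bins()] (strict `value < cutoff`,
#' absent bin pairs count as 0) and [build_ep_pairs()] with label
#' `"negative3"`. Candidate bin pairs default to every annotated
#' enhancer-bin x promoter-bin combination on the same chromosome.
#'
#' @param contacts Contact tibble.
#' @param enhancers,promoters Annotation tibbles as for [build_ep_pairs()].
#' @param resolution Bin size in bp.
#' @param cutoff Strict upper contact threshold (default 5).
#' @param all_bins Optional explicit candidate bin pairs.
#' @param exclude_pairs Optional EP-pair tibble (typically the positives);
#'   any (enhancer, gene) combination present there is dropped, so a pair
#'   also supported by an interacting bin pair never enters the negative set.
#' @param ... Passed to [build_ep_pairs()] (distance bounds etc.).
#' @return EP-pair tibble with `label = "negative3"`.
#' @export
make_type3 <- function(contacts, enhancers, promoters, resolution,
                       cutoff = 5, all_bins = NULL, exclude_pairs = NULL,
                       ...) {
  if (is.null(all_bins)) {
    eb <- enhancers |>
      dplyr::mutate(bin = bins_of_interval(.data$start, .data$end, resolution)) |>
      tidyr::unnest("bin") |>
      dplyr::distinct(.data$chrom, .data$bin)
    pb <- promoters |>
      dplyr::mutate(bin = bins_of_interval(.data$start, .data$end, resolution)) |>
      tidyr::unnest("bin") |>
      dplyr::distinct(.data$chrom, .data$bin)
    all_bins <- dplyr::inner_join(
      dplyr::rename(eb, bin_a = "bin"),
      dplyr::rename(pb, bin_b = "bin"),
      by = "chrom", relationship = "many-to-many"
    )
  }
  low <- call_noninteracting_bins(contacts, all_bins, cutoff = cutoff)
  out <- build_ep_pairs(low, enhancers, promoters, resolution,
                        label = "negative3", ...)
  if (!is.null(exclude_pairs) && nrow(out) > 0L) {
    out <- dplyr::anti_join(out, exclude_pairs,
                            by = c("enh_id", "gene_id"))
  }
  out
}
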