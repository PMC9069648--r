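#' Read a sparse normalized contact matrix
#'
#' Expects a TSV with columns `chrom`, `bin_a`, `bin_b`, `value` holding
#' intra-chromosomal, pre-normalized contact values at a fixed bin
#' resolution (Rao-style normalized dumps). Records are canonicalized to
#' `bin_a <= bin_b`; duplicate bin pairs are summed with a warning.
#'
#' @param path Path to the contact TSV (optional `#` header line).
#' @param resolution Bin size in bp; every bin start must be a multiple.
#' @return Tibble with columns `chrom`, `bin_a`, `bin_b`, `value` and
#'   attribute `resolution`.
#' @export
read_contacts <- function(path, resolution) {
  if (!file.exists(path)) stop("contact file not found: ", path)
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("chrom", "bin_a", "bin_b", "value"),
                        col_types = "ciid", progress = FALSE)
  as_contacts(df, resolution)
}

#' Validate and canonicalize an in-memory contact table
#'
#' @param df Tibble with columns `chrom`, `bin_a`, `bin_b`, `value`.
#' @inheritParams read_contacts
#' @return Canonicalized contact tibble.
#' @export
as_contacts <- function(df, resolution) {
  stopifnot(resolution > 0)
  off <- which(df$bin_a %% resolution != 0 | df$bin_b %% resolution != 0)
  if (length(off) > 0L) {
    stop("bin start not a multiple of resolution ", resolution,
         " at record ", off[1L])
  }
  if (any(df$value < 0)) stop("negative contact value")
  swap <- df$bin_a > df$bin_b
  if (any(swap)) {
    tmp <- df$bin_a[swap]
    df$bin_a[swap] <- df$bin_b[swap]
    df$bin_b[swap] <- tmp
  }
  ndup <- nrow(df) - nrow(dplyr::distinct(df, .data$chrom, .data$bin_a, .data$bin_b))
  if (ndup > 0L) {
    warning(ndup, " duplicate bin pair(s) summed")
    df <- df |>
      dplyr::summarise(value = sum(.data$value),
                       .by = c("chrom", "bin_a", "bin_b"))
  }
  out <- dplyr::arrange(tibble::as_tibble(df), .data$chrom, .data$bin_a, .data$bin_b)
  attr(out, "resolution") <- resolution
  out
}

#' Call interacting bin pairs from a contact table
#'
#' A pair of genomic bins is called interacting when its normalized contact
#' value is strictly larger than `cutoff` (default 30; use 150 for
#' high-sequencing-depth libraries to control false positives).
#'
#' @param contacts Contact tibble from [read_contacts()].
#' @param cutoff Strict lower threshold on the normalized value.
#' @return Tibble of bin pairs (`chrom`, `bin_a`, `bin_b`, `value`).
#' @export
call_interacting_bins <- function(contacts, cutoff = 30) {
  stopifnot(cutoff > 0)
  dplyr::filter(contacts, .data$value > cutoff)
}

#' Call non-interacting bin pairs
#'
#' A candidate bin pair is non-interacting when its normalized contact value
#' is strictly smaller than `cutoff` (default 5); candidate pairs absent from
#' the contact table count as value 0.
#'
#' @param contacts Contact tibble.
#' @param all_bins Tibble enumerating candidate bin pairs (`chrom`, `bin_a`,
#'   `bin_b`), e.g. annotated bin pairs within the distance window.
#' @param cutoff Strict upper threshold.
#' @return Tibble of bin pairs with their (possibly zero) values.
#' @export
call_noninteracting_bins <- function(contacts, all_bins, cutoff = 5) {
  swap <- all_bins$bin_a > all_bins$bin_b
  if (any(swap)) {
    tmp <- all_bins$bin_a[swap]
    all_bins$bin_a[swap] <- all_bins$bin_b[swap]
    all_bins$bin_b[swap] <- tmp
  }
  all_bins |>
    dplyr::distinct(.data$chrom, .data$bin_a, .data$bin_b) |>
    dplyr::left_join(contacts, by = c("chrom", "bin_a", "bin_b")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0)) |>
    dplyr::filter(.data$value < cutoff)
}

bins_of_interval <- function(start, end, resolution) {
  purrr::map2(start, end, function(s, e) {
    seq.int((s %/% resolution) * resolution,
            ((e - 1L) %/% resolution) * resolution,
            by = resolution)
  })
}

#' Build enhancer-promoter pairs from selected bin pairs
#'
#' Overlaps active enhancers and active promoters with a set of selected
#' (interacting or non-interacting) bin pairs: an EP pair is emitted when its
#' enhancer overlaps (>= 1 bp) one bin and its promoter overlaps the other
#' bin of some selected bin pair, and the enhancer-promoter distance is
#' within `[min_distance, max_distance]` (defaults 2.5 kb and 2 Mb). Distance
#' is `|enhancer midpoint - TSS|` by default (`distance_mode = "midpoint"`)
#' or the edge-to-edge gap (`"edge"`). Pairs are deduplicated on
#' (enhancer, promoter, gene); the contact value is the maximum over
#' supporting bin pairs.
#'
#' @param bin_pairs Tibble of selected bin pairs (`chrom`, `bin_a`, `bin_b`,
#'   `value`).
#' @param enhancers Tibble of active enhancer intervals (`chrom`, `start`,
#'   `end`).
#' @param promoters Tibble of active promoter intervals from
#'   [make_promoters()] (`chrom`, `start`, `end`, `gene_id`, `tss`, `strand`).
#' @param resolution Bin size in bp.
#' @param label Label attached to every pair (e.g. `"positive"`,
#'   `"negative3"`).
#' @param min_distance,max_distance Distance filter bounds in bp (inclusive).
#' @param distance_mode `"midpoint"` or `"edge"`.
#' @return Tibble of EP pairs with columns `ep_id`, `chrom`, `enh_start`,
#'   `enh_end`, `prom_start`, `prom_end`, `gene_id`, `tss`, `strand`,
#'   `distance`, `contact`, `label`, `enh_id`, `prom_id`.
#' @export
build_ep_pairs <- function(bin_pairs, enhancers, promoters, resolution,
                           label = "positive",
                           min_distance = 2500, max_distance = 2e6,
                           distance_mode = c("midpoint", "edge")) {
  distance_mode <- match.arg(distance_mode)
  if (nrow(bin_pairs) == 0L || nrow(enhancers) == 0L || nrow(promoters) == 0L) {
    return(empty_ep_pairs())
  }
  enh <- enhancers |>
    dplyr::mutate(.enh = dplyr::row_number(),
                  bin = bins_of_interval(.data$start, .data$end, resolution)) |>
    tidyr::unnest("bin") |>
    dplyr::select(chrom = "chrom", enh_bin = "bin", ".enh")
  prom <- promoters |>
    dplyr::mutate(.prom = dplyr::row_number(),
                  bin = bins_of_interval(.data$start, .data$end, resolution)) |>
    tidyr::unnest("bin") |>
    dplyr::select(chrom = "chrom", prom_bin = "bin", ".prom")

  # both orders: enhancer in bin_a & promoter in bin_b, and the reverse
  hits1 <- bin_pairs |>
    dplyr::inner_join(enh, by = c(chrom = "chrom", bin_a = "enh_bin"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(prom, by = c(chrom = "chrom", bin_b = "prom_bin"),
                      relationship = "many-to-many")
  hits2 <- bin_pairs |>
    dplyr::inner_join(enh, by = c(chrom = "chrom", bin_b = "enh_bin"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(prom, by = c(chrom = "chrom", bin_a = "prom_bin"),
                      relationship = "many-to-many")
  hits <- dplyr::bind_rows(hits1, hits2)
  if (nrow(hits) == 0L) return(empty_ep_pairs())

  pairs <- hits |>
    dplyr::summarise(contact = max(.data$value), .by = c(".enh", ".prom")) |>
    dplyr::mutate(
      chrom = enhancers$chrom[.data$.enh],
      enh_start = enhancers$start[.data$.enh],
      enh_end = enhancers$end[.data$.enh],
      prom_start = promoters$start[.data$.prom],
      prom_end = promoters$end[.data$.prom],
      gene_id = promoters$gene_id[.data$.prom],
      tss = promoters$tss[.data$.prom],
      strand = promoters$strand[.data$.prom]
    )
  mid <- (pairs$enh_start + pairs$enh_end) %/% 2L
  pairs$distance <- if (distance_mode == "midpoint") {
    abs(mid - pairs$tss)
  } else {
    pmax(0L, pmax(pairs$prom_start - pairs$enh_end,
                  pairs$enh_start - pairs$prom_end))
  }
  pairs |>
    dplyr::filter(.data$distance >= min_distance,
                  .data$distance <= max_distance) |>
    dplyr::mutate(
      label = label,
      enh_id = interval_id(.data$chrom, .data$enh_start, .data$enh_end),
      prom_id = interval_id(.data$chrom, .data$prom_start, .data$prom_end,
                            .data$strand),
      ep_id = paste0(.data$enh_id, "|", .data$gene_id)
    ) |>
    dplyr::arrange(.data$chrom, .data$enh_start, .data$prom_start,
                   .data$gene_id) |>
    dplyr::select("ep_id", "chrom", "enh_start", "enh_end", "prom_start",
                  "prom_end", "gene_id", "tss", "strand", "distance",
                  "contact", "label", "enh_id", "prom_id")
}

empty_ep_pairs <- function() {
  tibble::tibble(
    ep_id = character(), chrom = character(),
    enh_start = integer(), enh_end = integer(),
    prom_start = integer(), prom_end = integer(),
    gene_id = character(), tss = integer(), strand = character(),
    distance = numeric(), contact = numeric(), label = character(),
    enh_id = character(), prom_id = character()
  )
}

#' Attach enhancer and promoter sequences to EP pairs
#'
#' @param ep_pairs Tibble from [build_ep_pairs()].
#' @param genome Genome tibble (`id`, `seq`).
#' @return `ep_pairs` with added `enh_seq` and `prom_seq` columns (promoter
#'   sequence is strand-oriented).
#' @export
add_ep_sequences <- function(ep_pairs, genome) {
  enh <- extract_sequences(genome, tibble::tibble(
    chrom = ep_pairs$chrom, start = ep_pairs$enh_start,
    end = ep_pairs$enh_end, strand = "."
  ))
  prom <- extract_sequences(genome, tibble::tibble(
    chrom = ep_pairs$chrom, start = ep_pairs$prom_start,
    end = ep_pairs$prom_end, strand = ep_pairs$strand
  ))
  ep_pairs$enh_seq <- enh$seq
  ep_pairs$prom_seq <- prom$seq
  ep_pairs
}
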