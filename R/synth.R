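#' Configuration for the synthetic input generator
#'
#' Defines the study conditions the generator emulates: EP pairs laid out in
#' disjoint genomic blocks, a contact matrix whose interacting bin pairs take
#' values well above the calling cutoff and whose non-interacting annotated
#' pairs sit below the non-interaction cutoff, an information-rich motif
#' library, and a planted oriented motif pair carried jointly (enhancer side
#' + promoter side) by a fraction `q_joint` of the interacting EP pairs over
#' a per-region background presence rate.
#'
#' @param n_ep_pairs Number of interacting (positive) EP pairs (default 500).
#' @param n_neg3 Number of low-contact annotated blocks (default
#'   `n_ep_pairs`).
#' @param n_chroms Number of chromosomes the blocks are spread over.
#' @param resolution Contact bin size in bp (default 5000).
#' @param block_size Genomic block reserved per EP pair (default 30000 bp).
#' @param enhancer_length Enhancer length in bp (default 300, so promoters
#'   are roughly three times longer than enhancers).
#' @param distance_range Enhancer-midpoint-to-TSS distance range sampled per
#'   pair (default 2500-25000 bp, inside the 2.5 kb-2 Mb filter).
#' @param base_freq Background base frequencies (A, C, G, T).
#' @param motif_library_size Number of motifs in the library (default 10).
#' @param motif_width Width of generated motifs (default 12).
#' @param planted_pairs Tibble with `motif_E`, `motif_P`, `q_joint`; default
#'   one pair (first two motifs) at `q_joint`.
#' @param q_joint Joint planting probability for the default planted pair.
#' @param background_presence Probability that any region receives one site
#'   of a random motif (default 0.05).
#' @param contact_high,contact_low Value ranges for interacting and
#'   non-interacting bin pairs (defaults (60, 200) and (0, 4.5), so the
#'   cutoffs 30 and 5 separate the classes by construction).
#' @param noisy_sites Mutate one position of every planted site.
#' @param seed Integer seed; the bundle is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ep_pairs = 500, n_neg3 = n_ep_pairs, n_chroms = 2,
                       resolution = 5000, block_size = 30000,
                       enhancer_length = 300,
                       distance_range = c(2500, 25000),
                       base_freq = rep(0.25, 4),
                       motif_library_size = 10, motif_width = 12,
                       planted_pairs = NULL, q_joint = 0.4,
                       background_presence = 0.05,
                       contact_high = c(60, 200), contact_low = c(0, 4.5),
                       noisy_sites = FALSE, seed = 1) {
  stopifnot(contact_high[1] > 30, contact_low[2] < 5,
            q_joint >= 0, q_joint <= 1,
            distance_range[1] >= 2500)
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(
      motif_E = "TF01", motif_P = "TF02", q_joint = q_joint
    )
  }
  structure(
    list(n_ep_pairs = n_ep_pairs, n_neg3 = n_neg3, n_chroms = n_chroms,
         resolution = resolution, block_size = block_size,
         enhancer_length = enhancer_length, distance_range = distance_range,
         base_freq = base_freq, motif_library_size = motif_library_size,
         motif_width = motif_width, planted_pairs = planted_pairs,
         background_presence = background_presence,
         contact_high = contact_high, contact_low = contact_low,
         noisy_sites = noisy_sites, seed = seed),
    class = "sim_config"
  )
}

random_motif_library <- function(n, width, major = 0.97) {
  cons <- character(0)
  while (length(cons) < n) {
    cand <- paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
    ok <- all(vapply(cons, function(x) {
      sum(strsplit(x, "")[[1L]] != strsplit(cand, "")[[1L]]) >= width %/% 2
    }, logical(1L)))
    if (ok) cons <- c(cons, cand)
  }
  names <- sprintf("TF%02d", seq_len(n))
  purrr::map2(names, cons, function(nm, cs) {
    idx <- match(strsplit(cs, "")[[1L]], DNA_BASES)
    probs <- matrix((1 - major) / 3, 4L, width)
    probs[cbind(idx, seq_len(width))] <- major
    pwm(nm, probs)
  }) |> setNames(names)
}

plant_site <- function(block, start, len, site) {
  if (sample.int(2L, 1L) == 2L) site <- revcomp(site)
  w <- nchar(site)
  off <- start + sample.int(len - w + 1L, 1L) - 1L
  substr(block, off + 1L, off + w) <- site
  block
}

mutate_site <- function(site) {
  i <- sample.int(nchar(site), 1L)
  old <- substr(site, i, i)
  substr(site, i, i) <- sample(setdiff(DNA_BASES, old), 1L)
  site
}

#' Generate a complete synthetic input bundle
#'
#' Produces, deterministically from the config seed, every input the
#' pipeline consumes: genome FASTA, active-enhancer BED, TSS table, sparse
#' normalized contact TSV, motif library, TF-interaction list, and a
#' ground-truth manifest. Each EP pair occupies its own genomic block with a
#' promoter (1000 bp upstream to 100 bp downstream of a strand-random TSS)
#' and an enhancer at a sampled distance; interacting bin pairs receive
#' contact values in `contact_high`, low-contact blocks values in
#' `contact_low` (every other one left absent). Planted consensus sites of
#' the planted pair are inserted (after background sites, so they are never
#' overwritten) into the enhancer/promoter of carrier pairs.
#'
#' @param config A [sim_config()] list.
#' @param dir Optional directory; when given, all files are written there
#'   and their paths recorded in the returned bundle.
#' @return A `sim_bundle` list: `genome`, `enhancers`, `tss`, `contacts`,
#'   `motifs`, `tf_interactions`, `manifest` (ground truth: `ep_truth`,
#'   `carriers`, `interacting_bins`, `planted_pairs`, `seed`), and `paths`
#'   when written.
#' @export
simulate_bundle <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    motifs <- random_motif_library(cfg$motif_library_size, cfg$motif_width)
    miss <- setdiff(c(cfg$planted_pairs$motif_E, cfg$planted_pairs$motif_P),
                    names(motifs))
    if (length(miss) > 0L) stop("planted motif(s) not in library: ",
                                paste(miss, collapse = ", "))

    n_pos <- cfg$n_ep_pairs
    n_tot <- n_pos + cfg$n_neg3
    chrom_of <- rep(sprintf("chr%d", seq_len(cfg$n_chroms)),
                    length.out = n_tot)
    # interleave positive and low-contact blocks across chromosomes
    block_idx <- stats::ave(seq_len(n_tot), chrom_of,
                            FUN = seq_along)
    is_pos <- seq_len(n_tot) <= n_pos

    bs <- cfg$block_size
    tss_off <- 2000L
    prom_up <- 1000L; prom_down <- 100L
    elen <- cfg$enhancer_length
    blocks <- vector("list", n_tot)
    pair <- tibble::tibble(
      idx = seq_len(n_tot), chrom = chrom_of, block = block_idx,
      block_start = (block_idx - 1L) * bs,
      strand = sample(c("+", "-"), n_tot, replace = TRUE),
      d = sample(seq.int(cfg$distance_range[1L], cfg$distance_range[2L]),
                 n_tot, replace = TRUE),
      label = ifelse(is_pos, "positive", "negative3")
    )
    pair$tss <- pair$block_start + tss_off
    pair$enh_mid <- pair$tss + pair$d
    pair$enh_start <- pair$enh_mid - elen %/% 2L
    pair$enh_end <- pair$enh_start + elen
    pair$gene_id <- sprintf("G%04d", pair$idx)

    carriers <- rep(FALSE, n_tot)
    planted <- cfg$planted_pairs
    for (i in seq_len(n_tot)) {
      block <- paste(sample(DNA_BASES, bs, replace = TRUE,
                            prob = cfg$base_freq), collapse = "")
      # local (block-relative) coordinates
      p_start <- if (pair$strand[i] == "+") tss_off - prom_up else
        tss_off - prom_down
      e_start <- pair$enh_start[i] - pair$block_start[i]
      # background sites: any region may receive a site of any motif
      for (reg in list(c(p_start, prom_up + prom_down), c(e_start, elen))) {
        if (stats::runif(1) < cfg$background_presence) {
          m <- motifs[[sample.int(length(motifs), 1L)]]
          block <- plant_site(block, reg[1L], reg[2L], consensus(m))
        }
      }
      if (is_pos[i] && nrow(planted) > 0L) {
        for (pp in seq_len(nrow(planted))) {
          if (stats::runif(1) < planted$q_joint[pp]) {
            se <- consensus(motifs[[planted$motif_E[pp]]])
            sp <- consensus(motifs[[planted$motif_P[pp]]])
            if (cfg$noisy_sites) {
              se <- mutate_site(se); sp <- mutate_site(sp)
            }
            block <- plant_site(block, e_start, elen, se)
            block <- plant_site(block, p_start, prom_up + prom_down, sp)
            carriers[i] <- TRUE
          }
        }
      }
      blocks[[i]] <- block
    }
    genome <- tibble::tibble(
      id = sprintf("chr%d", seq_len(cfg$n_chroms)),
      seq = vapply(seq_len(cfg$n_chroms), function(c) {
        paste(blocks[chrom_of == sprintf("chr%d", c)], collapse = "")
      }, character(1L))
    )

    res <- cfg$resolution
    bin_a <- (pmin(pair$enh_start, pair$tss) %/% res) * res
    bin_b <- (pmax(pair$enh_start, pair$tss) %/% res) * res
    value <- ifelse(is_pos,
                    stats::runif(n_tot, cfg$contact_high[1L],
                                 cfg$contact_high[2L]),
                    stats::runif(n_tot, cfg$contact_low[1L],
                                 cfg$contact_low[2L]))
    contacts_all <- tibble::tibble(chrom = pair$chrom, bin_a = bin_a,
                                   bin_b = bin_b, value = value)
    # every other low-contact record is left absent (counts as value 0)
    drop <- !is_pos & (seq_len(n_tot) %% 2L == 0L)
    contacts <- as_contacts(contacts_all[!drop, , drop = FALSE], res)

    enhancers <- tibble::tibble(
      chrom = pair$chrom, start = pair$enh_start, end = pair$enh_end,
      name = sprintf("E%04d", pair$idx), score = 0, strand = "."
    )
    tss <- tibble::tibble(
      gene_id = pair$gene_id, chrom = pair$chrom, tss = pair$tss,
      strand = pair$strand
    )

    tfs <- names(motifs)
    planted_tf <- tibble::tibble(
      tf_a = pmin(planted$motif_E, planted$motif_P),
      tf_b = pmax(planted$motif_E, planted$motif_P),
      type = "direct"
    )
    others <- t(combn(tfs, 2L))
    extra <- tibble::tibble(tf_a = others[, 1L], tf_b = others[, 2L]) |>
      dplyr::anti_join(planted_tf, by = c("tf_a", "tf_b")) |>
      dplyr::slice_sample(n = min(6L, nrow(others) - nrow(planted_tf))) |>
      dplyr::mutate(type = rep_len(c("direct", "indirect"), dplyr::n()))
    tf_interactions <- dplyr::bind_rows(planted_tf, extra)

    manifest <- list(
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "planted_pairs")],
      planted_pairs = planted,
      carriers = pair$gene_id[carriers],
      interacting_bins = contacts_all[is_pos, , drop = FALSE],
      ep_truth = pair[, c("chrom", "enh_start", "enh_end", "gene_id",
                          "tss", "strand", "d", "label")]
    )
    bundle <- structure(
      list(genome = genome, enhancers = enhancers, tss = tss,
           contacts = contacts, motifs = motifs,
           tf_interactions = tf_interactions, manifest = manifest,
           config = cfg),
      class = "sim_bundle"
    )
  })
  if (!is.null(dir)) bundle <- write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to disk in standard formats
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return The bundle with a `paths` element added.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    enhancers = file.path(dir, "enhancers.bed"),
    tss = file.path(dir, "tss.bed"),
    contacts = file.path(dir, "contacts.tsv"),
    motifs = file.path(dir, "motifs.jaspar"),
    tf_interactions = file.path(dir, "tf_interactions.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fasta(bundle$genome, paths$genome)
  write_bed(bundle$enhancers, paths$enhancers)
  write_bed(tibble::tibble(
    chrom = bundle$tss$chrom, start = bundle$tss$tss,
    end = bundle$tss$tss + 1L, name = bundle$tss$gene_id, score = 0,
    strand = bundle$tss$strand
  ), paths$tss)
  readr::write_tsv(bundle$contacts, paths$contacts, col_names = FALSE)
  write_motifs(bundle$motifs, paths$motifs)
  readr::write_tsv(bundle$tf_interactions, paths$tf_interactions,
                   col_names = FALSE)
  manifest <- bundle$manifest
  manifest$config$base_freq <- as.numeric(manifest$config$base_freq)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$paths <- paths
  bundle
}

#' Read a previously written bundle through the package's standard readers
#'
#' @param dir Directory written by [write_bundle()].
#' @param resolution Contact resolution (defaults to the manifest's value).
#' @return A `sim_bundle`-like list (manifest included).
#' @export
read_bundle <- function(dir, resolution = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  resolution <- resolution %||% manifest$config$resolution
  structure(
    list(
      genome = read_fasta(file.path(dir, "genome.fa")),
      enhancers = read_bed(file.path(dir, "enhancers.bed")),
      tss = read_tss(file.path(dir, "tss.bed")),
      contacts = read_contacts(file.path(dir, "contacts.tsv"), resolution),
      motifs = read_motifs(file.path(dir, "motifs.jaspar"), "jaspar"),
      tf_interactions = read_tf_interactions(
        file.path(dir, "tf_interactions.tsv")),
      manifest = manifest,
      config = manifest$config
    ),
    class = "sim_bundle"
  )
}

#' Compare discovered motif pairs with the planted ground truth
#'
#' @param discovered Corrected motif-pair tibble (from
#'   [discover_motif_pairs()] or [correct_pvalues()]).
#' @param manifest Bundle manifest (with `planted_pairs`).
#' @return List with `per_pair` (tibble: planted pair, recovered flag),
#'   `n_recovered`, `n_planted`, `false_discoveries` (significant pairs not
#'   planted, orientation-sensitive).
#' @export
evaluate_recovery <- function(discovered, manifest) {
  planted <- tibble::as_tibble(manifest$planted_pairs)
  sig <- discovered[discovered$significant %||% logical(nrow(discovered)), ,
                    drop = FALSE]
  per_pair <- planted |>
    dplyr::mutate(recovered = purrr::map2_lgl(
      .data$motif_E, .data$motif_P,
      function(e, p) any(sig$motif_E == e & sig$motif_P == p)
    ))
  fd <- sig |>
    dplyr::anti_join(planted, by = c("motif_E", "motif_P"))
  list(
    per_pair = per_pair,
    n_recovered = sum(per_pair$recovered),
    n_planted = nrow(per_pair),
    false_discoveries = fd
  )
}
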