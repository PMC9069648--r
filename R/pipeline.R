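#' Pipeline run configuration
#'
#' Collects every threshold of the pipeline with its standard default:
#' interaction cutoff 30 (150 for very deep libraries), non-interaction
#' cutoff 5, distance window 2.5 kb-2 Mb, FIMO-style scan p-value 1e-4,
#' presence p-value 1e-5, motif-similarity E-value cutoffs 1e-5 (annotation/
#' redundancy) and 1e-8 (cross-condition sharing), module support >= 30 and
#' sizes 2-5, Bonferroni correction at alpha 0.01.
#'
#' @param interaction_cutoff,noninteraction_cutoff Contact-value cutoffs.
#' @param min_distance,max_distance EP distance filter in bp.
#' @param scan_p Scan reporting p-value threshold.
#' @param presence_p Instance p-value for presence/absence profiles.
#' @param similarity_evalue,sharing_evalue Motif-similarity E-value cutoffs.
#' @param alpha Significance level for corrected p-values.
#' @param min_support Minimum module / oriented-pair support.
#' @param max_module_size Largest motif-module size.
#' @param correction `"bonferroni"` or `"BH"`.
#' @param negative_types Integer subset of 1:3 to generate.
#' @param balance Subsample negatives to the positive count before
#'   classification.
#' @param enrichment_mode `"direct"` or `"direct_plus_indirect"`.
#' @param n_folds Cross-validation folds.
#' @param seed Master seed; stage seeds are derived from it.
#' @param resolution Contact bin size (required when reading files).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(interaction_cutoff = 30,
                            noninteraction_cutoff = 5,
                            min_distance = 2500, max_distance = 2e6,
                            scan_p = 1e-4, presence_p = 1e-5,
                            similarity_evalue = 1e-5, sharing_evalue = 1e-8,
                            alpha = 0.01, min_support = 30,
                            max_module_size = 5,
                            correction = "bonferroni",
                            negative_types = c(1, 2, 3), balance = FALSE,
                            enrichment_mode = "direct", n_folds = 10,
                            seed = 1, resolution = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

write_tsv_hash <- function(df, path) {
  readr::write_lines(paste0("#", paste(names(df), collapse = "\t")), path)
  readr::write_tsv(df, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Run the full discovery pipeline on an input bundle
#'
#' Executes, in dependency order: EP-pair construction (positives at the
#' interaction cutoff, type-3 negatives at the non-interaction cutoff),
#' sequence extraction, negative-set generation, motif scanning, motif-pair
#' discovery, homogeneous/preference/enrichment statistics, and
#' cross-validated classification per negative type. Counts at every filter
#' are logged via `message()`, and all tables are written under `out_dir`
#' as TSV (header lines starting `#`) plus JSON summaries when `out_dir`
#' is given.
#'
#' @param input A `sim_bundle` (from [simulate_bundle()] / [read_bundle()])
#'   or a directory path containing a written bundle.
#' @param config A [pipeline_config()] list.
#' @param out_dir Optional output directory.
#' @return An `ep_run` list with elements `positives`, `negatives` (list by
#'   type), `occurrences`, `motif_pairs`, `modules`, `homogeneous`,
#'   `preference`, `enrichment`, `cv` (list by type), `counts`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  bundle <- if (is.character(input)) {
    read_bundle(input, resolution = config$resolution)
  } else {
    input
  }
  cfg <- config
  res <- cfg$resolution %||% bundle$config$resolution
  log <- function(...) message("[epmotifs] ", ...)

  promoters <- make_promoters(bundle$tss)
  interacting <- call_interacting_bins(bundle$contacts,
                                       cutoff = cfg$interaction_cutoff)
  log("interacting bin pairs: ", nrow(interacting), " / ",
      nrow(bundle$contacts), " contact records")
  positives <- build_ep_pairs(interacting, bundle$enhancers, promoters, res,
                              label = "positive",
                              min_distance = cfg$min_distance,
                              max_distance = cfg$max_distance)
  if (nrow(positives) == 0L) stop("ep_pairs stage: no positive EP pairs")
  positives <- add_ep_sequences(positives, bundle$genome)
  log("positive EP pairs: ", nrow(positives))

  negatives <- list()
  if (3 %in% cfg$negative_types) {
    neg3 <- make_type3(bundle$contacts, bundle$enhancers, promoters, res,
                       cutoff = cfg$noninteraction_cutoff,
                       exclude_pairs = positives,
                       min_distance = cfg$min_distance,
                       max_distance = cfg$max_distance)
    if (cfg$balance && nrow(neg3) > nrow(positives)) {
      neg3 <- with_local_seed(cfg$seed + 3L, {
        dplyr::slice_sample(neg3, n = nrow(positives))
      })
    }
    if (nrow(neg3) > 0L) {
      negatives$type3 <- add_ep_sequences(neg3, bundle$genome)
    }
    log("type-3 negatives: ", nrow(neg3))
  }
  if (1 %in% cfg$negative_types) {
    negatives$type1 <- make_type1(positives, seed = cfg$seed + 1L)
    log("type-1 negatives: ", nrow(negatives$type1))
  }
  if (2 %in% cfg$negative_types) {
    negatives$type2 <- make_type2(positives, bundle$genome,
                                  seed = cfg$seed + 2L,
                                  min_distance = cfg$min_distance,
                                  max_distance = cfg$max_distance)
    log("type-2 negatives: ", nrow(negatives$type2))
  }

  all_pairs <- dplyr::bind_rows(c(list(positive = positives), negatives))
  seqs <- dplyr::bind_rows(
    tibble::tibble(id = all_pairs$enh_id, seq = all_pairs$enh_seq),
    tibble::tibble(id = all_pairs$prom_id, seq = all_pairs$prom_seq)
  ) |> dplyr::distinct(.data$id, .keep_all = TRUE)
  occurrences <- scan_motifs(bundle$motifs, seqs, p_threshold = cfg$scan_p)
  log("scanned ", nrow(seqs), " sequences with ", length(bundle$motifs),
      " motifs: ", nrow(occurrences), " instances at p<", cfg$scan_p)

  motif_pairs <- discover_motif_pairs(
    positives, occurrences, p_threshold = cfg$presence_p,
    min_support = cfg$min_support, max_size = cfg$max_module_size,
    alpha = cfg$alpha, method = cfg$correction
  )
  modules <- attr(motif_pairs, "modules")
  profiles <- attr(motif_pairs, "profiles")
  log("significant modules: ", nrow(modules), "; oriented motif pairs: ",
      nrow(motif_pairs), " (", sum(motif_pairs$significant), " significant)")

  homogeneous <- homogeneous_tests(profiles, occurrences,
                                   ep_pairs = positives,
                                   alpha = cfg$alpha,
                                   p_threshold = cfg$presence_p)
  preference <- preference_tests(profiles, ep_pairs = positives)

  enrichment <- NULL
  sig_pairs <- dplyr::filter(motif_pairs, .data$significant)
  if (nrow(sig_pairs) > 0L && !is.null(bundle$tf_interactions)) {
    tf_map <- map_motifs_to_tfs(
      bundle$motifs[unique(c(sig_pairs$motif_E, sig_pairs$motif_P))],
      bundle$motifs, mode = "best",
      evalue_cutoff = cfg$similarity_evalue, seed = cfg$seed + 4L
    )
    tf_pairs <- sig_pairs |>
      dplyr::mutate(
        tf_a = purrr::map_chr(.data$motif_E,
                              ~ (tf_map[[.x]] %||% NA_character_)[1L]),
        tf_b = purrr::map_chr(.data$motif_P,
                              ~ (tf_map[[.x]] %||% NA_character_)[1L])
      ) |>
      dplyr::filter(!is.na(.data$tf_a), !is.na(.data$tf_b))
    if (nrow(tf_pairs) > 0L) {
      enrichment <- hypergeom_enrichment(tf_pairs, bundle$tf_interactions,
                                         db_tfs = names(bundle$motifs),
                                         mode = cfg$enrichment_mode)
      log("TF-interaction enrichment p = ",
          format(enrichment$pvalue, digits = 3))
    }
  }

  cv <- list()
  if (nrow(sig_pairs) > 0L) {
    for (nt in names(negatives)) {
      neg <- negatives[[nt]]
      if (nrow(neg) < cfg$n_folds) next
      feats <- build_features(dplyr::bind_rows(positives, neg), sig_pairs,
                              occurrences)
      cv[[nt]] <- cross_validate(feats, n_folds = cfg$n_folds,
                                 seed = cfg$seed + 5L)
      log("CV vs ", nt, ": F1 = ", sprintf("%.3f", cv[[nt]]$mean["f1"]),
          ", selected pairs = ", cv[[nt]]$n_selected)
    }
  }

  counts <- list(
    contact_records = nrow(bundle$contacts),
    interacting_bins = nrow(interacting),
    positives = nrow(positives),
    negatives = purrr::map_int(negatives, nrow),
    motifs_scanned = length(bundle$motifs),
    occurrences = nrow(occurrences),
    modules_significant = nrow(modules),
    modules_tested = attr(modules, "n_tested"),
    motif_pairs_tested = nrow(motif_pairs),
    motif_pairs_significant = sum(motif_pairs$significant)
  )

  run <- structure(
    list(positives = positives, negatives = negatives,
         occurrences = occurrences, motif_pairs = motif_pairs,
         modules = modules, profiles = profiles,
         homogeneous = homogeneous, preference = preference,
         enrichment = enrichment, cv = cv, counts = counts, config = cfg),
    class = "ep_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write pipeline outputs to a directory
#'
#' @param run An `ep_run` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ep_cols <- c("ep_id", "chrom", "enh_start", "enh_end", "prom_start",
               "prom_end", "gene_id", "tss", "strand", "distance",
               "contact", "label")
  all_pairs <- dplyr::bind_rows(c(list(run$positives), unname(run$negatives)))
  write_tsv_hash(all_pairs[, ep_cols], file.path(out_dir, "ep_pairs.tsv"))
  write_tsv_hash(run$occurrences, file.path(out_dir, "occurrences.tsv"))
  mp <- run$motif_pairs
  write_tsv_hash(mp, file.path(out_dir, "motif_pairs.tsv"))
  mods <- run$modules
  if (nrow(mods) > 0L) {
    mods$motifs <- purrr::map_chr(mods$motifs, paste, collapse = ",")
  } else {
    mods$motifs <- character(0)
  }
  write_tsv_hash(mods, file.path(out_dir, "modules.tsv"))
  write_tsv_hash(run$homogeneous, file.path(out_dir, "homogeneous.tsv"))
  write_tsv_hash(run$preference, file.path(out_dir, "preference.tsv"))
  if (!is.null(run$enrichment)) {
    write_tsv_hash(run$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  cv_json <- purrr::map(run$cv, function(x) {
    list(folds = x$folds, mean = as.list(x$mean),
         selected_pairs = x$selected_pairs, n_selected = x$n_selected)
  })
  jsonlite::write_json(
    list(counts = run$counts, cv = cv_json,
         config = unclass(run$config)),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(out_dir)
}
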