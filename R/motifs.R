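DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param name Motif name (unique within a library).
#' @param probs 4 x width numeric matrix of per-position base probabilities,
#'   rows A/C/G/T. Regularized with `pseudocount` and renormalized so all
#'   entries are positive and columns sum to 1.
#' @param pseudocount Added to every entry before renormalization.
#' @param source `"library"` or `"discovered"`.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, pseudocount = 0.01, source = "library") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4L) stop("motif width must be >= 4")
  if (any(probs < 0)) stop("negative probabilities in motif ", name)
  probs <- probs + pseudocount
  probs <- sweep(probs, 2L, colSums(probs), "/")
  rownames(probs) <- DNA_BASES
  structure(
    list(name = name, width = ncol(probs), probs = probs,
         pseudocount = pseudocount, source = source),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$name, " width", x$width, " consensus",
      consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param x A `pwm` object.
#' @return Single character string of the most probable base per position.
#' @export
consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 2L, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param x A `pwm` object.
#' @return A `pwm` with columns reversed and complementary rows swapped.
#' @export
revcomp_pwm <- function(x) {
  p <- x$probs[4:1, rev(seq_len(x$width)), drop = FALSE]
  rownames(p) <- DNA_BASES
  x$probs <- p
  x
}

#' Read a motif library
#'
#' Supports JASPAR-style count blocks (`>name` followed by four `A [ ... ]`
#' rows, brackets optional) and MEME minimal format (`MOTIF name` followed by
#' a `letter-probability matrix` block). Counts/probabilities are regularized
#' with `pseudocount` via [pwm()].
#'
#' @param path Path to the motif file.
#' @param format `"jaspar"` or `"meme"`.
#' @param pseudocount Regularization added per entry.
#' @return Named list of `pwm` objects.
#' @export
read_motifs <- function(path, format = c("jaspar", "meme"),
                        pseudocount = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readr::read_lines(path)
  pwms <- if (format == "jaspar") {
    parse_jaspar(lines, pseudocount)
  } else {
    parse_meme(lines, pseudocount)
  }
  nm <- purrr::map_chr(pwms, "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0L) {
    stop("duplicate motif name(s): ", paste(dup, collapse = ", "))
  }
  setNames(pwms, nm)
}

parse_jaspar <- function(lines, pseudocount) {
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no JASPAR motif headers ('>') found")
  purrr::map(seq_along(hdr), function(i) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 4L) stop("JASPAR block with fewer than 4 rows")
    rows <- purrr::map(block[1:4], function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?", "", l)
      l <- gsub("\\]", "", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("JASPAR row-length mismatch in motif block ", i)
    name <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1L]][1L]
    counts <- do.call(rbind, rows)
    probs <- sweep(counts, 2L, pmax(colSums(counts), 1e-12), "/")
    pwm(name, probs, pseudocount = pseudocount)
  })
}

parse_meme <- function(lines, pseudocount) {
  hdr <- which(startsWith(trimws(lines), "MOTIF"))
  if (length(hdr) == 0L) stop("no MEME 'MOTIF' records found")
  purrr::map(seq_along(hdr), function(i) {
    name <- strsplit(trimws(lines[hdr[i]]), "[ \t]+")[[1L]][2L]
    from <- hdr[i]
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    lp <- which(grepl("letter-probability matrix", block))
    if (length(lp) != 1L) stop("missing letter-probability matrix for ", name)
    rows <- list()
    for (l in block[-seq_len(lp)]) {
      t <- trimws(l)
      if (!nzchar(t)) break
      vals <- suppressWarnings(as.numeric(strsplit(t, "[ \t]+")[[1L]]))
      if (anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
    }
    if (length(rows) == 0L) stop("empty probability matrix for ", name)
    if (length(unique(lengths(rows))) != 1L || lengths(rows)[1L] != 4L) {
      stop("MEME probability rows must have 4 columns (motif ", name, ")")
    }
    pwm(name, t(do.call(rbind, rows)), pseudocount = pseudocount)
  })
}

#' Write motifs in JASPAR count-style format
#'
#' Probabilities are scaled to pseudo-counts (x100) for readability.
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(pwms, path) {
  out <- purrr::map(pwms, function(m) {
    counts <- round(m$probs * 100, 4)
    c(paste0(">", m$name),
      purrr::map_chr(1:4, function(r) {
        paste0(DNA_BASES[r], " [ ",
               paste(format(counts[r, ], trim = TRUE), collapse = " "), " ]")
      }))
  })
  readr::write_lines(unlist(out), path)
  invisible(path)
}

encode_dna <- function(seq) {
  v <- utf8ToInt(seq)
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  out <- code[v]
  out[out == 0L] <- NA_integer_
  out
}

.dist_cache <- new.env(parent = emptyenv())

# Exact score distribution of a log-odds matrix under an i.i.d. background.
# width <= enum_limit: full enumeration of all 4^w words (bitwise-exact
# against window scoring, which adds columns left to right).
# wider motifs: dynamic programming on a 1/1000-bit score lattice.
# The (scores, tail) part is invariant to column order and to base
# relabelling at equal background weight, so it is cached on that canonical
# form (motif libraries often contain many matrices of identical shape).
score_distribution <- function(lod, bg, enum_limit = 10L, granularity = 1e-3) {
  w <- ncol(lod)
  key <- paste(
    granularity, enum_limit,
    paste(sort(apply(round(lod * 1e9), 2L, function(col) {
      o <- order(col, bg)
      paste(col[o], signif(bg[o], 12), collapse = ";")
    })), collapse = "|"),
    sep = "@"
  )
  cached <- .dist_cache[[key]]
  if (!is.null(cached)) {
    cached$lod <- if (cached$exact) lod else round(lod / granularity) *
        granularity
    return(cached)
  }
  out <- score_distribution_impl(lod, bg, enum_limit, granularity)
  .dist_cache[[key]] <- out
  out
}

score_distribution_impl <- function(lod, bg, enum_limit, granularity) {
  w <- ncol(lod)
  if (w <= enum_limit) {
    sc <- 0; wt <- 1
    for (j in seq_len(w)) {
      sc <- as.vector(outer(lod[, j], sc, "+"))
      wt <- as.vector(outer(bg, wt, "*"))
    }
    ord <- order(sc, decreasing = TRUE)
    sc <- sc[ord]; wt <- wt[ord]
    keep <- !duplicated(sc)
    tail_w <- cumsum(wt)[c(which(keep)[-1L] - 1L, length(wt))]
    list(scores = rev(sc[keep]), tail = rev(tail_w), exact = TRUE,
         lod = lod)
  } else {
    li <- round(lod / granularity)
    vec <- 1
    vec_lo <- 0L
    for (j in seq_len(w)) {
      cols <- li[, j]
      new_lo <- vec_lo + min(cols)
      new <- numeric(length(vec) - 1L + max(cols) - min(cols) + 1L)
      for (b in 1:4) {
        idx <- seq_along(vec) + (vec_lo + cols[b] - new_lo)
        new[idx] <- new[idx] + vec * bg[b]
      }
      vec <- new
      vec_lo <- new_lo
    }
    tail_w <- rev(cumsum(rev(vec)))
    nz <- which(vec > 0)
    list(scores = (vec_lo + nz - 1) * granularity,
         tail = tail_w[nz], exact = FALSE,
         lod = li * granularity)
  }
}

lookup_pvalue <- function(dist, scores) {
  # P(S >= s); fuzz guards lattice rounding at bin edges
  idx <- findInterval(scores - 1e-9, dist$scores) + 1L
  idx[idx > length(dist$tail)] <- length(dist$tail)
  dist$tail[pmin(pmax(idx, 1L), length(dist$tail))]
}

#' Scan sequences with PWMs (FIMO-style log-odds scan)
#'
#' Scores every window on both strands with the log2 likelihood ratio against
#' an i.i.d. background and converts scores to p-values using the exact score
#' distribution of the matrix (full word enumeration for widths <= 10, a
#' 1/1000-bit lattice dynamic program for wider motifs). Windows containing
#' `N` are skipped. Hits with `pvalue < p_threshold` are returned sorted by
#' sequence and offset.
#'
#' @param pwms A `pwm` object or (named) list of them.
#' @param seqs Tibble with columns `id`, `seq`.
#' @param background Base frequencies (A, C, G, T); default uniform.
#' @param p_threshold Report hits with p-value strictly below this (default
#'   1e-4).
#' @return Tibble with columns `motif`, `seq_id`, `start` (0-based), `strand`,
#'   `score` (bits), `pvalue`; attribute `scanned_ids` lists every sequence ID
#'   scanned (hit or not).
#' @export
scan_motifs <- function(pwms, seqs, background = rep(0.25, 4),
                        p_threshold = 1e-4) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(abs(sum(background) - 1) < 1e-6)
  enc <- purrr::map(seqs$seq, encode_dna)
  # one concatenated vector, sequences separated by NA runs longer than any
  # motif, so windows never straddle two sequences
  sep <- max(purrr::map_int(pwms, "width"))
  lens <- lengths(enc)
  starts <- cumsum(c(1L, head(lens + sep, -1L)))
  total <- sum(lens) + sep * length(enc)
  concat <- rep(NA_integer_, total)
  for (i in seq_along(enc)) {
    if (lens[i] > 0L) {
      concat[starts[i]:(starts[i] + lens[i] - 1L)] <- enc[[i]]
    }
  }
  res <- purrr::map(pwms, function(m) {
    hits_for_pwm(m, seqs$id, concat, starts, background, p_threshold)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0L) {
    out <- dplyr::arrange(out, .data$motif, .data$seq_id, .data$start)
  }
  attr(out, "scanned_ids") <- seqs$id
  attr(out, "motifs") <- purrr::map_chr(pwms, "name")
  out
}

hits_for_pwm <- function(m, ids, concat, starts, bg, p_threshold) {
  mats <- list(`+` = m$probs, `-` = revcomp_pwm(m)$probs)
  out <- list()
  nw <- length(concat) - m$width + 1L
  if (nw < 1L) return(dplyr::bind_rows(out))
  for (strand in names(mats)) {
    lod <- log2(sweep(mats[[strand]], 1L, bg, "/"))
    dist <- score_distribution(lod, bg)
    lod_eff <- dist$lod                     # lattice-rounded when inexact
    # minimal score whose tail p-value is below the threshold
    ok <- dist$tail < p_threshold
    if (!any(ok)) next
    min_score <- dist$scores[which(ok)[1L]]
    s <- .scan_scores(concat, lod_eff)
    hit <- which(!is.na(s) & s >= min_score - 1e-9)
    if (length(hit) == 0L) next
    si <- findInterval(hit, starts)
    out[[length(out) + 1L]] <- tibble::tibble(
      motif = m$name, seq_id = ids[si], start = hit - starts[si],
      strand = strand, score = s[hit],
      pvalue = lookup_pvalue(dist, s[hit])
    )
  }
  dplyr::bind_rows(out)
}

# All column-column Pearson correlations between two probability matrices
# (4 observations per column); zero-variance columns yield 0, not NA.
column_cor <- function(pa, pb) {
  C <- suppressWarnings(cor(pa, pb))
  C[is.na(C)] <- 0
  C
}

# Best ungapped alignment given the column-correlation matrix; the
# alignment is selected by the SUM of column correlations (so longer
# agreeing overlaps beat short perfect ones, as in ungapped
# Smith-Waterman-style motif aligners), while `score` reports the mean
# correlation of the chosen alignment. Offset is the shift of b
# relative to a.
best_offset_score <- function(C, min_overlap = 4L) {
  wa <- nrow(C); wb <- ncol(C)
  best <- list(sum = -Inf, score = -Inf, offset = 0L)
  for (off in seq.int(-(wb - min_overlap), wa - min_overlap)) {
    ia <- max(1L, 1L + off):min(wa, wb + off)
    if (length(ia) < min_overlap) next
    v <- C[cbind(ia, ia - off)]
    s <- sum(v)
    if (s > best$sum) best <- list(sum = s, score = s / length(v),
                                   offset = off)
  }
  best
}

# Mean column-wise Pearson correlation of two aligned probability matrices
# over all ungapped offsets with >= min_overlap columns; both orientations.
best_alignment <- function(pa, pb, min_overlap = 4L) {
  wb <- ncol(pb)
  same <- best_offset_score(column_cor(pa, pb), min_overlap)
  rc <- best_offset_score(
    column_cor(pa, pb[4:1, rev(seq_len(wb)), drop = FALSE]), min_overlap)
  if (rc$sum > same$sum) {
    list(sum = rc$sum, score = rc$score, offset = rc$offset,
         orientation = "revcomp")
  } else {
    list(sum = same$sum, score = same$score, offset = same$offset,
         orientation = "same")
  }
}

#' Pairwise motif similarity with a permutation E-value
#'
#' All ungapped offsets with >= 4 overlapping columns are scored in both
#' orientations by column-wise Pearson correlation; the best alignment is
#' the one maximizing the correlation *sum* (so a long agreeing overlap
#' beats a short perfect one), and the reported score is that alignment's
#' mean correlation (in \[-1, 1\]). The empirical p-value is the fraction of
#' within-motif column permutations of the first motif whose best alignment
#' sum is at least the observed one; the E-value scales it by
#' `n_comparisons` (the number of motif pairs compared in the calling
#' context).
#'
#' @param pwm_a,pwm_b `pwm` objects.
#' @param n_shuffles Number of column permutations (>= 200).
#' @param n_comparisons Bonferroni-style scaling applied to the p-value.
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: `motif_a`, `motif_b`, `best_offset`,
#'   `best_orientation`, `score`, `pvalue`, `evalue`.
#' @export
motif_similarity <- function(pwm_a, pwm_b, n_shuffles = 1000,
                             n_comparisons = 1, seed = 1) {
  if (pwm_a$width < 4L && pwm_b$width < 4L) {
    stop("no alignment with >= 4 overlapping columns possible")
  }
  if (n_shuffles < 200L) stop("n_shuffles must be >= 200")
  obs <- best_alignment(pwm_a$probs, pwm_b$probs)
  wa <- pwm_a$width
  wb <- pwm_b$width
  # permuting A's columns permutes rows of the correlation matrices, so the
  # correlations are computed once and reindexed per shuffle
  C_same <- column_cor(pwm_a$probs, pwm_b$probs)
  C_rc <- column_cor(pwm_a$probs,
                     pwm_b$probs[4:1, rev(seq_len(wb)), drop = FALSE])
  null_sums <- with_local_seed(seed, {
    purrr::map_dbl(seq_len(n_shuffles), function(i) {
      perm <- sample.int(wa)
      max(best_offset_score(C_same[perm, , drop = FALSE])$sum,
          best_offset_score(C_rc[perm, , drop = FALSE])$sum)
    })
  })
  # strictly-better shuffles only: a permutation that merely ties the
  # observed optimum (e.g. a column order restoring the identical motif)
  # is evidence for similarity, and counting ties would floor the p-value
  # of any self-comparison at the identity-permutation probability
  p <- mean(null_sums > obs$sum + 1e-12)
  tibble::tibble(
    motif_a = pwm_a$name, motif_b = pwm_b$name,
    best_offset = obs$offset, best_orientation = obs$orientation,
    score = obs$score, pvalue = p, evalue = p * n_comparisons
  )
}

#' Remove redundant motifs from a library
#'
#' Computes all pairwise similarities (E-values scaled by the number of pairs
#' compared), single-links motifs with `evalue < evalue_cutoff`, and keeps the
#' lexicographically smallest name per cluster.
#'
#' @param pwms Named list of `pwm` objects.
#' @param evalue_cutoff Similarity E-value below which motifs are "similar"
#'   (default 1e-5).
#' @param n_shuffles,seed Passed to [motif_similarity()].
#' @return Named list of representative `pwm`s; attribute `clusters` is a
#'   tibble mapping each motif to its representative.
#' @export
deduplicate_motifs <- function(pwms, evalue_cutoff = 1e-5,
                               n_shuffles = 1000, seed = 1) {
  stopifnot(length(pwms) >= 1L)
  nm <- purrr::map_chr(pwms, "name")
  m <- length(pwms)
  if (m == 1L) {
    out <- pwms
    attr(out, "clusters") <- tibble::tibble(motif = nm, representative = nm)
    return(out)
  }
  npairs <- m * (m - 1) / 2
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idx <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      idx <- idx + 1L
      sim <- motif_similarity(pwms[[i]], pwms[[j]], n_shuffles = n_shuffles,
                              n_comparisons = npairs, seed = seed + idx)
      if (sim$evalue < evalue_cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(m), find, integer(1L))
  rep_name <- vapply(split(nm, root), function(g) sort(g)[1L], character(1L))
  clusters <- tibble::tibble(
    motif = nm,
    representative = rep_name[as.character(root)]
  )
  out <- pwms[sort(unique(clusters$representative))]
  attr(out, "clusters") <- clusters
  out
}
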