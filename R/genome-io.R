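#' Read a FASTA file into a tibble of sequences
#'
#' Sequences are uppercased and any character outside `A/C/G/T/N` (IUPAC
#' ambiguity codes, masked lowercase already handled by uppercasing) is mapped
#' to `N` with a warning. `N` positions never match a motif position during
#' scanning, so repeat-masked input is tolerated rather than rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (header up to first whitespace) and
#'   `seq` (uppercase character).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  bad <- stringr::str_count(seqs, "[^ACGTN]")
  if (any(bad > 0L)) {
    warning(sum(bad), " non-ACGTN character(s) mapped to N in ",
            sum(bad > 0L), " sequence(s)")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' `N` stays `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' Coordinates are 0-based half-open (BED convention), which is also the
#' internal convention of the whole package. Missing strand becomes `"."`.
#'
#' @param path Path to a BED file. Lines starting with `#` are skipped.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- stringr::str_split(lines[keep], "\t")
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("BED line ", lineno[which(n < 3L)[1L]], " has fewer than 3 fields")
  }
  get <- function(i, default) {
    purrr::map_chr(fields, function(f) if (length(f) >= i) f[[i]] else default)
  }
  out <- tibble::tibble(
    chrom  = get(1L, NA_character_),
    start  = as.integer(get(2L, NA_character_)),
    end    = as.integer(get(3L, NA_character_)),
    name   = get(4L, "."),
    score  = suppressWarnings(as.numeric(get(5L, "0"))),
    strand = get(6L, ".")
  )
  bad <- which(!(out$strand %in% c("+", "-", ".")))
  if (length(bad) > 0L) out$strand[bad] <- "."
  inv <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end)
  if (length(inv) > 0L) {
    stop("invalid interval (start >= end) at line ", lineno[inv[1L]],
         " of ", path)
  }
  out
}

#' Write intervals to a BED6 file
#'
#' @param intervals Tibble with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- tibble::tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = intervals$name %||% rep(".", nrow(intervals)),
    score = intervals$score %||% rep(0, nrow(intervals)),
    strand = intervals$strand %||% rep(".", nrow(intervals))
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' The contract is a BED6-like file where `start` is the 0-based TSS position
#' and `end = start + 1`; the name column carries the gene ID and strand must
#' be `+` or `-`.
#'
#' @param path Path to the TSS table.
#' @return Tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  bed <- read_bed(path)
  if (any(!(bed$strand %in% c("+", "-")))) {
    stop("TSS table requires explicit +/- strand for every record")
  }
  tibble::tibble(
    gene_id = bed$name,
    chrom = bed$chrom,
    tss = bed$start,
    strand = bed$strand
  )
}

#' Build promoter windows around TSSs
#'
#' The promoter is the region from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS (defaults 1000 and 100, giving an 1100-bp window).
#' On the `-` strand the window is mirrored so "upstream" is biological
#' upstream; `ignore_strand = TRUE` restores the unstranded reading.
#' Windows are clipped at position 0.
#'
#' @param tss Tibble from [read_tss()] (columns `gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param upstream,downstream Window extents in bp.
#' @param ignore_strand Treat all genes as `+` strand.
#' @return Tibble of promoter intervals with columns `chrom`, `start`, `end`,
#'   `gene_id`, `tss`, `strand`.
#' @export
make_promoters <- function(tss, upstream = 1000L, downstream = 100L,
                           ignore_strand = FALSE) {
  stopifnot(all(tss$tss >= 0L))
  plus <- ignore_strand | tss$strand == "+"
  start <- ifelse(plus, tss$tss - upstream, tss$tss - downstream)
  end <- ifelse(plus, tss$tss + downstream, tss$tss + upstream)
  out_strand <- if (ignore_strand) rep("+", nrow(tss)) else tss$strand
  tibble::tibble(
    chrom = tss$chrom,
    start = as.integer(pmax(0L, start)),
    end = as.integer(end),
    gene_id = tss$gene_id,
    tss = tss$tss,
    strand = out_strand
  )
}

#' Extract interval sequences from a genome
#'
#' Intervals on the `-` strand return the reverse complement. Sequence IDs
#' encode `chrom:start-end(strand)`.
#'
#' @param genome Tibble with columns `id`, `seq` (e.g. from [read_fasta()]).
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `strand`.
#' @return Tibble with columns `id`, `seq`.
#' @export
extract_sequences <- function(genome, intervals) {
  chrom_seq <- setNames(genome$seq, genome$id)
  missing <- setdiff(unique(intervals$chrom), names(chrom_seq))
  if (length(missing) > 0L) {
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  }
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  lens <- nchar(chrom_seq)[intervals$chrom]
  if (any(intervals$end > lens)) {
    stop("interval end beyond chromosome length for ",
         intervals$chrom[which(intervals$end > lens)[1L]])
  }
  seqs <- stringr::str_sub(chrom_seq[intervals$chrom],
                           intervals$start + 1L, intervals$end)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  tibble::tibble(
    id = interval_id(intervals$chrom, intervals$start, intervals$end, strand),
    seq = unname(seqs)
  )
}

interval_id <- function(chrom, start, end, strand = ".") {
  paste0(chrom, ":", start, "-", end, "(", strand, ")")
}
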