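#' Trim the 3' adapter from small-RNA reads
#'
#' Finds the leftmost exact occurrence of the adapter's first `min_prefix`
#' nucleotides in each read and returns the insert before it. If no such
#' occurrence exists, progressively shorter adapter prefixes (down to
#' `min_anchor` nt) are tried anchored at the read's 3' terminus, covering
#' reads whose insert is long enough that only the start of the adapter was
#' sequenced. Reads with no identifiable adapter are rejected (`NA`).
#'
#' @param reads Character vector of raw read sequences.
#' @param adapter 3' adapter sequence (A/C/G/T, length >= `min_prefix`).
#' @param min_prefix Adapter prefix length searched internally (default 8).
#' @param min_anchor Shortest adapter prefix accepted at the 3' terminus
#'   (default 5).
#' @return Character vector of inserts, `NA` where no adapter was found. An
#'   insert may be empty when the read begins with the adapter.
#' @export
trim_adapter <- function(reads, adapter, min_prefix = 8L, min_anchor = 5L) {
  if (length(reads) == 0) return(character(0))
  if (any(!nzchar(reads) | is.na(reads))) abort("empty read")
  if (grepl("[^ACGT]", adapter)) {
    abort("adapter must contain only A/C/G/T symbols")
  }
  if (nchar(adapter) < min_prefix) abort("adapter shorter than min_prefix")
  prefix <- substr(adapter, 1L, min_prefix)
  pos <- unname(stringr::str_locate(reads, stringr::fixed(prefix))[, "start"])
  insert <- ifelse(is.na(pos), NA_character_, substr(reads, 1L, pos - 1L))
  todo <- is.na(pos)
  k <- min_prefix - 1L
  while (any(todo) && k >= min_anchor) {
    suf <- substr(adapter, 1L, k)
    hit <- todo & endsWith(reads, suf)
    insert[hit] <- substr(reads[hit], 1L, nchar(reads[hit]) - k)
    todo <- todo & !hit
    k <- k - 1L
  }
  insert
}

#' Collapse trimmed inserts into a sequence tally
#'
#' @param inserts Character vector of trimmed inserts (`NA` = rejected read).
#' @return Tibble with unique `sequence` and its read `count`, sorted by
#'   decreasing count; the number of rejected reads is attached as attribute
#'   `n_rejected`.
#' @export
tally_sequences <- function(inserts) {
  n_rejected <- sum(is.na(inserts))
  kept <- inserts[!is.na(inserts)]
  tab <- table(kept)
  out <- tibble::tibble(sequence = names(tab),
                        count = as.integer(tab)) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Retain tally sequences within a length range
#'
#' Small-RNA quantification keeps inserts of 18-28 nt inclusive; everything
#' shorter (adapter dimers, degradation) or longer is discarded with its
#' counts.
#'
#' @param tally Tibble with `sequence` and `count`.
#' @param min_len,max_len Inclusive length bounds (defaults 18 and 28).
#' @return The filtered tally, counts preserved.
#' @export
length_filter <- function(tally, min_len = 18L, max_len = 28L) {
  if (min_len > max_len) abort("min_len must be <= max_len")
  dplyr::filter(tally, nchar(.data$sequence) >= min_len,
                nchar(.data$sequence) <= max_len)
}

#' Perfect-match mapping of a sequence tally to a genome
#'
#' Reports every zero-mismatch occurrence of each sequence on either strand
#' of the genome. Sequences with no perfect match are dropped, mirroring a
#' no-mismatch short-read aligner run. The 5' position of a minus-strand
#' alignment is its genomic end coordinate.
#'
#' @param tally Tibble with a `sequence` column (a character vector also
#'   works).
#' @param genome A `toy_genome`.
#' @return Tibble of alignments: `sequence`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive), `five_prime_pos`.
#' @export
map_exact <- function(tally, genome) {
  stopifnot(inherits(genome, "toy_genome"))
  seqs <- if (is.character(tally)) unique(tally) else unique(tally$sequence)
  if (length(seqs) == 0) {
    return(tibble::tibble(sequence = character(0), chrom = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), five_prime_pos = integer(0)))
  }
  rc <- revcomp(seqs)
  width <- nchar(seqs)
  hits <- list()
  for (chrom in names(genome$sequences)) {
    subject <- genome$sequences[[chrom]]
    for (str in c("+", "-")) {
      pats <- if (str == "+") seqs else rc
      locs <- stringr::str_locate_all(subject, stringr::fixed(pats))
      nhit <- vapply(locs, nrow, integer(1))
      if (sum(nhit) == 0) next
      idx <- rep(seq_along(seqs), nhit)
      s <- unlist(lapply(locs, function(m) m[, "start"]), use.names = FALSE)
      hits[[length(hits) + 1L]] <- tibble::tibble(
        sequence = seqs[idx], chrom = chrom, strand = str,
        start = as.integer(s),
        end = as.integer(s + width[idx] - 1L),
        five_prime_pos = as.integer(if (str == "+") s else
          s + width[idx] - 1L))
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(sequence = character(0), chrom = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), five_prime_pos = integer(0)))
  }
  dplyr::bind_rows(hits) %>%
    dplyr::arrange(.data$sequence, .data$chrom, .data$strand, .data$start)
}

#' 5'-anchored window quantification of mature miRNA abundance
#'
#' For each miRNA locus, collects the distinct sequences with at least one
#' perfect-match alignment on the locus's chromosome and strand whose 5' end
#' lies within `window` nt of the annotated mature 5' end. Within that window
#' the sequence with the maximal count is designated the reference sequence,
#' and the miRNA's abundance is the summed count of all window sequences
#' sharing the reference's observed 5' position (which may differ from the
#' annotated one). Loci with empty windows get abundance 0 and a missing
#' reference.
#'
#' Offsets are reported in mature-RNA orientation: `offset = five_prime_pos -
#' locus 5'` on the plus strand and its negation on the minus strand, so
#' negative offsets are upstream of the annotated end on both strands. A
#' multi-mapping sequence contributes its full count to every miRNA whose
#' window captures one of its alignments; multiple alignments inside one
#' window count once, keyed at the alignment closest to the annotated end.
#' Reference-count ties break by smaller |offset|, then longer sequence, then
#' lexicographic order.
#'
#' @param alignments Alignment tibble from [map_exact()] (or SAM ingestion).
#' @param tally Tibble with per-`sequence` `count`.
#' @param loci Loci tibble from [plant_mirna_loci()] / [read_mirna_gff3()].
#' @param window Window half-width in nt around the annotated 5' end
#'   (default 3).
#' @return Tibble with one row per locus: `mirna_id`, `reference_sequence`,
#'   `reference_offset`, `reference_five_prime_pos`, `abundance`,
#'   `n_window_sequences`; the full window membership (`mirna_id`,
#'   `sequence`, `count`, `offset`, `five_prime_pos`) is attached as
#'   attribute `window_detail`.
#' @export
quantify_mirna <- function(alignments, tally, loci, window = 3L) {
  if (anyDuplicated(loci$mirna_id)) abort("duplicate mirna_ids in loci")
  if (window < 0) abort("window must be >= 0")
  loci_key <- loci %>%
    dplyr::select("mirna_id", "chrom", "strand",
                  locus_fp = "five_prime_pos")
  counts <- dplyr::distinct(tally[, c("sequence", "count")])
  if (anyDuplicated(counts$sequence)) {
    abort("tally must have one count per sequence")
  }
  detail <- alignments %>%
    dplyr::inner_join(loci_key, by = c("chrom", "strand"),
                      relationship = "many-to-many") %>%
    dplyr::mutate(offset = ifelse(.data$strand == "+",
                                  .data$five_prime_pos - .data$locus_fp,
                                  .data$locus_fp - .data$five_prime_pos)) %>%
    dplyr::filter(abs(.data$offset) <= window) %>%
    # one row per (miRNA, sequence): keep the alignment closest to the
    # annotated 5' end, preferring the upstream one on exact ties
    dplyr::arrange(abs(.data$offset), .data$offset) %>%
    dplyr::distinct(.data$mirna_id, .data$sequence, .keep_all = TRUE) %>%
    dplyr::inner_join(counts, by = "sequence") %>%
    dplyr::select("mirna_id", "sequence", "count", "offset",
                  "five_prime_pos")

  per_locus <- detail %>%
    dplyr::group_by(.data$mirna_id) %>%
    dplyr::arrange(dplyr::desc(.data$count), abs(.data$offset),
                   dplyr::desc(nchar(.data$sequence)), .data$sequence,
                   .by_group = TRUE) %>%
    dplyr::summarise(
      reference_sequence = .data$sequence[1],
      reference_offset = .data$offset[1],
      reference_five_prime_pos = .data$five_prime_pos[1],
      abundance = sum(.data$count[.data$five_prime_pos ==
                                    .data$five_prime_pos[1]]),
      n_window_sequences = dplyr::n(),
      .groups = "drop")

  out <- tibble::tibble(mirna_id = loci$mirna_id) %>%
    dplyr::left_join(per_locus, by = "mirna_id") %>%
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0L),
                  n_window_sequences =
                    dplyr::coalesce(.data$n_window_sequences, 0L))
  attr(out, "window_detail") <- detail
  out
}

#' Quantify one small-RNA sample end to end
#'
#' Convenience wrapper chaining adapter trimming, tally collapse, length
#' filtering, perfect-match mapping and 5'-window quantification.
#'
#' @param reads Character vector of raw reads, or a tibble with a `sequence`
#'   column (e.g. from [read_fastq()]).
#' @param genome A `toy_genome`.
#' @param loci miRNA loci tibble.
#' @param adapter 3' adapter sequence.
#' @param window Window half-width (default 3).
#' @param min_len,max_len Insert length bounds (defaults 18, 28).
#' @return The quantification tibble of [quantify_mirna()].
#' @export
quant_smallrna <- function(reads, genome, loci, adapter, window = 3L,
                           min_len = 18L, max_len = 28L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  tally <- trim_adapter(reads, adapter) %>%
    tally_sequences() %>%
    length_filter(min_len = min_len, max_len = max_len)
  aln <- map_exact(tally, genome)
  quantify_mirna(aln, tally, loci, window = window)
}

#' Ingest pre-mapped alignments from a SAM file, keeping perfect matches only
#'
#' Accepts alignments produced by an external mapper. Records are kept only
#' when the CIGAR is a single full-length match and the `NM` tag (or, absent
#' that, the `MD` tag) certifies zero mismatches. The reported `sequence` is
#' the read in its original orientation (reverse-complemented back for
#' minus-strand records), and the per-sequence count is the number of
#' distinct read names carrying it.
#'
#' @param path SAM file path (header with `@SQ` lines required).
#' @return A list with `alignments` (as [map_exact()]) and `tally`
#'   (`sequence`, `count`).
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "qwidth", "seq", "cigar"),
    tag = c("NM", "MD"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos) & grepl("^[0-9]+M$", b$cigar)
  nm <- b$tag$NM
  md <- b$tag$MD
  perfect <- rep(FALSE, length(b$pos))
  if (!is.null(nm)) perfect <- !is.na(nm) & nm == 0
  if (!is.null(md)) {
    md_ok <- !is.na(md) & grepl("^[0-9]+$", md)
    perfect <- perfect | (if (is.null(nm)) md_ok else (is.na(nm) & md_ok))
  }
  keep <- keep & perfect
  if (!any(keep)) {
    return(list(alignments = tibble::tibble(
      sequence = character(0), chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0), five_prime_pos = integer(0)),
      tally = tibble::tibble(sequence = character(0), count = integer(0))))
  }
  strand <- as.character(b$strand)[keep]
  seq_ref <- as.character(b$seq)[keep]
  seq_read <- ifelse(strand == "-", revcomp(seq_ref), seq_ref)
  start <- b$pos[keep]
  end <- start + b$qwidth[keep] - 1L
  aln <- tibble::tibble(
    qname = b$qname[keep], sequence = seq_read,
    chrom = as.character(b$rname)[keep], strand = strand,
    start = start, end = end,
    five_prime_pos = ifelse(strand == "+", start, end))
  tally <- aln %>%
    dplyr::distinct(.data$qname, .data$sequence) %>%
    dplyr::count(.data$sequence, name = "count")
  list(alignments = dplyr::select(dplyr::distinct(
    dplyr::select(aln, -"qname")), dplyr::everything()),
    tally = tally)
}
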