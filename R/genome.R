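#' Generate a toy genome of uniform-random sequence
#'
#' Builds one or more chromosomes of i.i.d. uniform A/C/G/T bases. The result
#' stands in for a reference genome in simulations: long enough to make short
#' (18-28 nt) sequences unique with high probability, small enough that exact
#' substring search over both strands is instantaneous.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_len Length of each chromosome in nucleotides (>= 200).
#' @param seed Integer seed; the genome is bit-reproducible for a fixed seed.
#'
#' @return An object of class `toy_genome`: a list with `sequences` (named
#'   character vector of uppercase A/C/G/T strings) and `seed`.
#' @examples
#' g <- make_toy_genome(1, 1000, seed = 7)
#' nchar(g$sequences)
#' @export
make_toy_genome <- function(n_chrom = 1L, chrom_len = 100000L, seed = 1L) {
  stopifnot_scalar_count(n_chrom, "n_chrom", min = 1L)
  stopifnot_scalar_count(chrom_len, "chrom_len", min = 200L)
  sequences <- with_seed(seed, {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(DNA_BASES, chrom_len, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(sequences) <- paste0("chr", seq_len(n_chrom))
  structure(list(sequences = sequences, seed = as.integer(seed)),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %d chromosome(s), lengths: %s, seed %d\n",
              length(x$sequences),
              paste(nchar(x$sequences), collapse = ", "), x$seed))
  invisible(x)
}

genome_lengths <- function(genome) nchar(genome$sequences)

genome_substr <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome$sequences[[chrom]], start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# number of perfect-match occurrences of `seq` in the genome, both strands
count_genome_occurrences <- function(genome, seq) {
  sum(stringr::str_count(genome$sequences, stringr::fixed(seq))) +
    sum(stringr::str_count(genome$sequences, stringr::fixed(revcomp(seq))))
}

#' Plant mature-miRNA loci on a toy genome
#'
#' Places `n_mirna` non-overlapping mature miRNA loci at random positions,
#' alternating strands so roughly half lie on each. Each planted mature
#' sequence is checked to occur exactly once in the genome (over both
#' strands); placements whose sequence is duplicated elsewhere, or that fall
#' within `margin` nt of an existing locus, are rejected and redrawn up to a
#' bounded number of retries.
#'
#' The annotated 5' end (`five_prime_pos`) follows the strand convention of
#' mature-miRNA annotation: it equals `start` on the plus strand and `end` on
#' the minus strand.
#'
#' @param genome A `toy_genome`.
#' @param n_mirna Number of loci to place.
#' @param lengths Integer vector of admissible mature lengths (default 20:22).
#' @param seed Integer seed.
#' @param margin Minimum clearance in nt kept around each locus so isomiR
#'   end-variation windows of neighbouring loci cannot collide (default 10).
#'
#' @return A tibble with columns `mirna_id`, `chrom`, `strand`, `start`,
#'   `end`, `five_prime_pos`, `mature_seq` (1-based inclusive coordinates).
#' @export
plant_mirna_loci <- function(genome, n_mirna, lengths = 20:22, seed = 1L,
                             margin = 10L) {
  stopifnot(inherits(genome, "toy_genome"))
  stopifnot_scalar_count(n_mirna, "n_mirna", min = 1L)
  if (any(lengths < 18L) || any(lengths > 24L)) {
    abort("`lengths` must lie within 18..24 nt (mature miRNA range)")
  }
  chrom_len <- genome_lengths(genome)
  if (n_mirna * (max(lengths) + 2 * margin) > sum(chrom_len)) {
    abort(sprintf(
      "cannot place %d loci of up to %d nt (+%d nt margin) on %d nt of genome",
      n_mirna, max(lengths), margin, sum(chrom_len)))
  }
  occupied <- lapply(names(chrom_len), function(x) integer(0))
  names(occupied) <- names(chrom_len)

  with_seed(seed, {
    out <- vector("list", n_mirna)
    max_tries <- 200L * n_mirna
    tries <- 0L
    i <- 1L
    while (i <= n_mirna) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf(
          "failed to place %d unique non-overlapping loci after %d tries",
          n_mirna, max_tries))
      }
      chrom <- sample(names(chrom_len), 1L)
      len <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
      lo <- margin + 1L
      hi <- chrom_len[[chrom]] - len - margin
      if (hi < lo) next
      start <- sample(lo:hi, 1L)
      end <- start + len - 1L
      span <- (start - margin):(end + margin)
      if (any(span %in% occupied[[chrom]])) next
      strand <- if (i %% 2L == 1L) "+" else "-"
      mature_seq <- genome_substr(genome, chrom, start, end, strand)
      if (count_genome_occurrences(genome, mature_seq) != 1L) next
      occupied[[chrom]] <- c(occupied[[chrom]], span)
      out[[i]] <- tibble::tibble(
        mirna_id = sprintf("mir-%03d", i),
        chrom = chrom, strand = strand,
        start = start, end = end,
        five_prime_pos = if (strand == "+") start else end,
        mature_seq = mature_seq
      )
      i <- i + 1L
    }
    dplyr::bind_rows(out)
  })
}

#' Write a toy genome to FASTA
#' @param genome A `toy_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA into a `toy_genome` container
#' @param path FASTA file path.
#' @return A `toy_genome` (seed `NA`).
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  sequences <- as.character(dna)
  names(sequences) <- sub("\\s.*$", "", names(dna))
  structure(list(sequences = toupper(sequences), seed = NA_integer_),
            class = "toy_genome")
}

#' Write miRNA loci as miRBase-dialect GFF3
#'
#' Emits one `miRNA`-type feature per locus with `ID` and `Name` attributes,
#' 1-based inclusive coordinates, as in miRBase mature-miRNA GFF3.
#'
#' @param loci Loci tibble from [plant_mirna_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand
  )
  gr$type <- "miRNA"
  gr$ID <- loci$mirna_id
  gr$Name <- loci$mirna_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read mature-miRNA loci from miRBase-dialect GFF3
#'
#' Keeps `miRNA`-type features only. If a genome is supplied, the mature
#' sequence is re-extracted from it (reverse-complemented on the minus
#' strand); otherwise `mature_seq` is `NA`.
#'
#' @param path GFF3 path.
#' @param genome Optional `toy_genome` for sequence extraction.
#' @return A loci tibble as produced by [plant_mirna_loci()].
#' @export
read_mirna_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "miRNA"]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  loci <- tibble::tibble(
    mirna_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start, end = end,
    five_prime_pos = ifelse(strand == "+", start, end),
    mature_seq = NA_character_
  )
  if (!is.null(genome)) {
    loci$mature_seq <- purrr::pmap_chr(
      loci[c("chrom", "start", "end", "strand")],
      function(chrom, start, end, strand) {
        genome_substr(genome, chrom, start, end, strand)
      })
  }
  loci
}
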