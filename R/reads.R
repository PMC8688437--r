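#' Simulation settings for isomiR-structured small-RNA reads
#'
#' The defaults emulate the isomiR structure of real small-RNA libraries:
#' most reads start exactly at the annotated mature 5' end, with rapidly
#' decaying mass at templated 5' offsets out to +/-3 nt, and uniform 3'
#' length variation of +/-2 nt extended with genomic template sequence. A 3'
#' sequencing adapter is appended to every insert and per-base substitution
#' errors are applied at a fixed rate.
#'
#' @param offset_probs Named probabilities over 5' offsets -3..+3 (mature-RNA
#'   orientation; negative = upstream). Must sum to 1.
#' @param three_prime_probs Named probabilities over 3' length changes -2..+2.
#'   Must sum to 1.
#' @param adapter 3' adapter sequence (>= 8 nt, A/C/G/T).
#' @param error_rate Per-base substitution error probability in `[0, 1]`.
#'
#' @return A list of class `smallrna_sim_spec`.
#' @export
smallrna_sim_spec <- function(offset_probs = c(`-3` = 0.005, `-2` = 0.015,
                                               `-1` = 0.08, `0` = 0.80,
                                               `1` = 0.08, `2` = 0.015,
                                               `3` = 0.005),
                              three_prime_probs = stats::setNames(rep(0.2, 5),
                                                                  -2:2),
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              error_rate = 0.001) {
  off <- as.integer(names(offset_probs))
  if (any(is.na(off)) || any(off < -3L) || any(off > 3L)) {
    abort("offset_probs must be named with offsets in -3..3")
  }
  if (abs(sum(offset_probs) - 1) > 1e-8) abort("offset_probs must sum to 1")
  if (abs(sum(three_prime_probs) - 1) > 1e-8) {
    abort("three_prime_probs must sum to 1")
  }
  if (nchar(adapter) < 8L) abort("adapter must be at least 8 nt")
  if (grepl("[^ACGT]", adapter)) abort("adapter must contain only A/C/G/T")
  if (error_rate < 0 || error_rate > 1) abort("error_rate must be in [0, 1]")
  structure(list(offset_probs = offset_probs,
                 three_prime_probs = three_prime_probs,
                 adapter = adapter, error_rate = error_rate),
            class = "smallrna_sim_spec")
}

# Substitution errors: the per-read error count is Binomial(length, rate),
# positions uniform without replacement, each hit base replaced by a uniform
# draw from the other three — equivalent to i.i.d. per-base errors.
apply_base_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) {
    return(list(seqs = seqs, error_free = rep(TRUE, length(seqs))))
  }
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, error_rate)
  for (i in which(n_err > 0)) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(len[i], n_err[i])
    b[pos] <- vapply(b[pos], function(orig) {
      sample(setdiff(DNA_BASES, orig), 1L)
    }, character(1))
    seqs[i] <- paste(b, collapse = "")
  }
  list(seqs = seqs, error_free = n_err == 0L)
}

#' Simulate isomiR-structured small-RNA reads from planted loci
#'
#' For each (miRNA, sample) pair, draws a Poisson number of reads around the
#' requested expectation. Each read is a templated genomic sequence whose 5'
#' end sits at a sampled offset (-3..+3 nt, mature orientation) from the
#' annotated 5' end and whose 3' end varies by a sampled amount, with the 3'
#' adapter appended and per-base substitution errors applied. The returned
#' truth table records, per miRNA, sample and 5' offset, the number of
#' error-free reads — sufficient to predict every downstream quantification
#' result exactly.
#'
#' @param loci Loci tibble from [plant_mirna_loci()].
#' @param genome The `toy_genome` the loci live on.
#' @param expected_counts Tibble with columns `mirna_id`, `sample_id`,
#'   `expected_count` (nonnegative).
#' @param spec A [smallrna_sim_spec()].
#' @param seed Integer seed.
#'
#' @return A list with `reads` (tibble: `read_id`, `sample_id`, `mirna_id`,
#'   `sequence` including adapter, `insert`, `offset5`, `offset3`,
#'   `error_free`) and `truth` (tibble: `mirna_id`, `sample_id`, `offset`,
#'   `n_reads`, `n_error_free`).
#' @export
simulate_smallrna_reads <- function(loci, genome, expected_counts,
                                    spec = smallrna_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "smallrna_sim_spec"))
  if (any(expected_counts$expected_count < 0)) {
    abort("expected_count must be nonnegative")
  }
  missing_loci <- setdiff(expected_counts$mirna_id, loci$mirna_id)
  if (length(missing_loci) > 0) {
    abort(paste("expected_counts references unknown miRNAs:",
                paste(missing_loci, collapse = ", ")))
  }
  offsets <- as.integer(names(spec$offset_probs))
  tails <- as.integer(names(spec$three_prime_probs))
  loci_idx <- split(seq_len(nrow(loci)), loci$mirna_id)

  with_seed(seed, {
    per_cell <- purrr::pmap(expected_counts, function(mirna_id, sample_id,
                                                      expected_count) {
      n <- stats::rpois(1L, expected_count)
      if (n == 0L) return(NULL)
      lc <- loci[loci_idx[[mirna_id]][1], ]
      o5 <- sample(offsets, n, replace = TRUE, prob = spec$offset_probs)
      o3 <- sample(tails, n, replace = TRUE, prob = spec$three_prime_probs)
      if (lc$strand == "+") {
        rs <- lc$five_prime_pos + o5
        re <- lc$end + o3
      } else {
        rs <- lc$start - o3
        re <- lc$five_prime_pos - o5
      }
      ins <- substring(genome$sequences[[lc$chrom]], rs, re)
      if (lc$strand == "-") ins <- revcomp(ins)
      err <- apply_base_errors(ins, spec$error_rate)
      tibble::tibble(sample_id = sample_id, mirna_id = mirna_id,
                     insert = err$seqs,
                     sequence = paste0(err$seqs, spec$adapter),
                     offset5 = o5, offset3 = o3,
                     error_free = err$error_free)
    })
    reads <- dplyr::bind_rows(per_cell)
    if (nrow(reads) > 0) {
      reads$read_id <- sprintf("read_%07d", seq_len(nrow(reads)))
      reads <- dplyr::relocate(reads, "read_id")
    }
    truth <- reads %>%
      dplyr::group_by(.data$mirna_id, .data$sample_id, offset = .data$offset5) %>%
      dplyr::summarise(n_reads = dplyr::n(),
                       n_error_free = sum(.data$error_free),
                       .groups = "drop")
    list(reads = reads, truth = truth)
  })
}

#' Write reads as 4-line FASTQ (Phred+33, constant quality)
#' @param reads Read tibble with `read_id` and `sequence` columns.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a per-read tibble
#' @param path FASTQ path (Phred+33).
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub("\\s.*$", "", names(dna)),
                 sequence = unname(as.character(dna)))
}
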