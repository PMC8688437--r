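# Independent brute-force oracles used across tests. These deliberately use
# plain loops and direct summation, not the package's vectorized paths.

# All-pairs scan re-deriving the 5'-window quantification contract:
# per locus, collect sequences with an alignment on the locus chromosome and
# strand within the window, keyed at the alignment closest to the annotated
# 5' end (upstream preferred on ties); reference = max count, ties broken by
# smaller |offset|, longer sequence, lexicographic; abundance = sum of counts
# at the reference's observed 5' position.
brute_force_quantify <- function(alignments, tally, loci, window = 3) {
  counts <- stats::setNames(tally$count, tally$sequence)
  aln <- as.data.frame(alignments)
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    al <- aln[aln$chrom == lc$chrom & aln$strand == lc$strand, , drop = FALSE]
    members <- NULL
    if (nrow(al) > 0) {
      off <- if (lc$strand == "+") {
        al$five_prime_pos - lc$five_prime_pos
      } else {
        lc$five_prime_pos - al$five_prime_pos
      }
      al <- al[abs(off) <= window, , drop = FALSE]
      off <- off[abs(off) <= window]
      if (nrow(al) > 0) {
        rows <- lapply(split(seq_len(nrow(al)), al$sequence), function(ix) {
          best <- ix[order(abs(off[ix]), off[ix])][1]
          data.frame(sequence = al$sequence[best],
                     count = unname(counts[al$sequence[best]]),
                     offset = off[best],
                     five_prime_pos = al$five_prime_pos[best],
                     stringsAsFactors = FALSE)
        })
        members <- rows
      }
    }
    if (is.null(members)) {
      out[[i]] <- data.frame(mirna_id = lc$mirna_id,
                             reference_sequence = NA_character_,
                             reference_offset = NA_integer_,
                             reference_five_prime_pos = NA_integer_,
                             abundance = 0L, n_window_sequences = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    w <- do.call(rbind, members)
    ord <- order(-w$count, abs(w$offset), -nchar(w$sequence), w$sequence)
    ref <- w[ord[1], ]
    out[[i]] <- data.frame(
      mirna_id = lc$mirna_id,
      reference_sequence = ref$sequence,
      reference_offset = ref$offset,
      reference_five_prime_pos = ref$five_prime_pos,
      abundance = sum(w$count[w$five_prime_pos == ref$five_prime_pos]),
      n_window_sequences = nrow(w),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Random quantification instance: loci and per-sequence alignments drawn
# directly (no genome/mapping involved).
random_quant_instance <- function(n_loci, n_seq, seed) {
  set.seed(seed)
  chroms <- c("chr1", "chr2")
  loci <- tibble::tibble(
    mirna_id = sprintf("m%03d", seq_len(n_loci)),
    chrom = sample(chroms, n_loci, replace = TRUE),
    strand = sample(c("+", "-"), n_loci, replace = TRUE),
    five_prime_pos = sample.int(100000L, n_loci))
  loci$start <- loci$five_prime_pos
  loci$end <- loci$five_prime_pos
  seqlen <- sample(18:28, n_seq, replace = TRUE)
  seqs <- make.unique(stringi::stri_rand_strings(n_seq, seqlen, "[ACGT]"),
                      sep = "")
  n_aln <- sample(1:3, n_seq, replace = TRUE)
  idx <- rep(seq_len(n_seq), n_aln)
  anchor <- sample.int(n_loci, length(idx), replace = TRUE)
  alignments <- dplyr::distinct(tibble::tibble(
    sequence = seqs[idx],
    chrom = loci$chrom[anchor],
    strand = sample(c("+", "-"), length(idx), replace = TRUE),
    five_prime_pos = loci$five_prime_pos[anchor] +
      sample(-8:8, length(idx), replace = TRUE)))
  alignments$start <- alignments$five_prime_pos
  alignments$end <- alignments$five_prime_pos
  tally <- tibble::tibble(sequence = seqs,
                          count = sample.int(100L, n_seq, replace = TRUE))
  list(loci = loci, alignments = alignments, tally = tally)
}

# Direct hypergeometric upper-tail summation.
hyper_tail_direct <- function(k, n_a, n_b, N) {
  j <- k:min(n_a, n_b)
  sum(stats::dhyper(j, n_a, N - n_a, n_b))
}

# Exhaustive concordant/tied pair counting for the AUC.
auc_pair_counting <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(controls))
}

# Exhaustive two-sample KS statistic: max |F1 - F2| over all data points.
ks_stat_enumerate <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (t in pts) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# Tiny deterministic genome + loci fixture shared across files.
tiny_genome_fixture <- function(chrom_len = 8000, n_mirna = 6, seed = 11) {
  g <- make_toy_genome(1, chrom_len, seed = seed)
  loci <- plant_mirna_loci(g, n_mirna, seed = seed + 1)
  list(genome = g, loci = loci)
}

TEST_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"
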