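test_that("adapter trimming follows the prefix-then-anchored-suffix rule", {
  insert <- "ACGTACGTACGTACGTACGT"
  read <- paste0(insert, TEST_ADAPTER)
  expect_identical(trim_adapter(read, TEST_ADAPTER), insert)
  # read equal to adapter from position 1: empty insert, not a rejection
  expect_identical(trim_adapter(TEST_ADAPTER, TEST_ADAPTER), "")
  # only 6 nt of adapter sequenced, anchored at the 3' terminus
  short <- paste0(insert, substr(TEST_ADAPTER, 1, 6))
  expect_identical(trim_adapter(short, TEST_ADAPTER), insert)
  # a 4 nt adapter remnant is below the anchor minimum: rejected
  too_short <- paste0(insert, substr(TEST_ADAPTER, 1, 4))
  expect_identical(trim_adapter(too_short, TEST_ADAPTER), NA_character_)
  # no adapter at all
  expect_identical(trim_adapter("AAAACCCCGGGGTTTTAAAA", TEST_ADAPTER),
                   NA_character_)
  # leftmost occurrence wins when the 8-mer prefix appears twice
  double <- paste0("AAAA", substr(TEST_ADAPTER, 1, 8), "CCCC",
                   substr(TEST_ADAPTER, 1, 8))
  expect_identical(trim_adapter(double, TEST_ADAPTER), "AAAA")
  expect_error(trim_adapter("", TEST_ADAPTER), "empty read")
  expect_error(trim_adapter("ACGT", "TGGANTTC"), "A/C/G/T")
})

test_that("simulated error-free reads are all adapter-identified", {
  fx <- tiny_genome_fixture(seed = 31)
  ec <- tidyr::crossing(mirna_id = fx$loci$mirna_id, sample_id = "s1") %>%
    dplyr::mutate(expected_count = 150)
  sim <- simulate_smallrna_reads(fx$loci, fx$genome, ec,
                                 smallrna_sim_spec(error_rate = 0), seed = 6)
  trimmed <- trim_adapter(sim$reads$sequence, TEST_ADAPTER)
  expect_false(anyNA(trimmed))
  expect_identical(trimmed, sim$reads$insert)
})

test_that("length filter keeps the closed 18-28 nt range and is idempotent", {
  tly <- tibble::tibble(sequence = strrep("A", c(17, 18, 28, 29)),
                        count = c(1L, 2L, 3L, 4L))
  kept <- length_filter(tly)
  expect_equal(nchar(kept$sequence), c(18, 28))
  expect_equal(kept$count, c(2L, 3L))
  expect_identical(length_filter(kept), kept)
  empty <- tly[0, ]
  expect_equal(nrow(length_filter(empty)), 0)
})

test_that("exact mapping reports every perfect occurrence on both strands", {
  g <- make_toy_genome(1, 5000, seed = 19)
  plus_seq <- substr(g$sequences[[1]], 101, 122)
  minus_seq <- mirwin:::revcomp(substr(g$sequences[[1]], 201, 222))
  tly <- tibble::tibble(sequence = c(plus_seq, minus_seq),
                        count = c(1L, 1L))
  aln <- map_exact(tly, g)
  p <- aln[aln$sequence == plus_seq & aln$strand == "+", ]
  expect_equal(p$start, 101)
  expect_equal(p$five_prime_pos, 101)
  m <- aln[aln$sequence == minus_seq & aln$strand == "-", ]
  expect_equal(m$end, 222)
  expect_equal(m$five_prime_pos, 222)
  # one substitution kills the alignment
  mut <- plus_seq
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(plus_seq, 5, 5))[1]
  aln2 <- map_exact(tibble::tibble(sequence = mut, count = 1L), g)
  expect_equal(nrow(aln2), 0)
  # a repeated substring yields one alignment per occurrence
  rep_seq <- substr(g$sequences[[1]], 301, 320)
  g2 <- g
  g2$sequences[[1]] <- paste0(g$sequences[[1]], rep_seq)
  aln3 <- map_exact(tibble::tibble(sequence = rep_seq, count = 1L), g2)
  expect_equal(sum(aln3$strand == "+"), 2)
})

test_that("window quantification matches hand enumeration of the rule", {
  loci <- tibble::tibble(mirna_id = "mir-1", chrom = "chr1", strand = "+",
                         start = 100L, end = 121L, five_prime_pos = 100L,
                         mature_seq = NA_character_)
  aln <- tibble::tibble(sequence = c("A1", "B1", "C1"),
                        chrom = "chr1", strand = "+",
                        start = c(100L, 101L, 100L),
                        end = c(121L, 122L, 119L),
                        five_prime_pos = c(100L, 101L, 100L))
  aln$sequence <- c(strrep("A", 22), strrep("G", 22), strrep("C", 20))
  tly <- tibble::tibble(sequence = aln$sequence, count = c(50L, 10L, 5L))
  q <- quantify_mirna(aln, tly, loci)
  expect_equal(q$reference_sequence, strrep("A", 22))
  expect_equal(q$abundance, 55L)
  expect_equal(q$reference_offset, 0L)
  expect_equal(q$n_window_sequences, 3)
})

test_that("the +/-3 window boundary is inclusive and +/-4 is outside", {
  loci <- tibble::tibble(mirna_id = "mir-1", chrom = "chr1", strand = "+",
                         start = 100L, end = 121L, five_prime_pos = 100L,
                         mature_seq = NA_character_)
  mk <- function(fp) tibble::tibble(sequence = strrep("A", 20),
                                    chrom = "chr1", strand = "+",
                                    start = fp, end = fp + 19L,
                                    five_prime_pos = fp)
  tly <- tibble::tibble(sequence = strrep("A", 20), count = 7L)
  at3 <- quantify_mirna(mk(103L), tly, loci)
  expect_equal(at3$abundance, 7L)
  expect_equal(at3$reference_offset, 3L)
  at4 <- quantify_mirna(mk(104L), tly, loci)
  expect_equal(at4$abundance, 0L)
  expect_true(is.na(at4$reference_sequence))
  expect_error(quantify_mirna(mk(100L), tly,
                              dplyr::bind_rows(loci, loci)), "duplicate")
})

test_that("quantification equals the brute-force all-pairs oracle", {
  for (s in 1:25) {
    inst <- random_quant_instance(n_loci = sample(3:30, 1),
                                  n_seq = sample(50:800, 1), seed = 1000 + s)
    mine <- quantify_mirna(inst$alignments, inst$tally, inst$loci)
    oracle <- brute_force_quantify(inst$alignments, inst$tally, inst$loci)
    expect_equal(as.data.frame(mine[names(oracle)]), oracle,
                 ignore_attr = TRUE)
  }
})

test_that("mirrored plus and minus strand constructions agree", {
  base <- 500L
  loci_p <- tibble::tibble(mirna_id = "m", chrom = "chr1", strand = "+",
                           start = base, end = base + 21L,
                           five_prime_pos = base,
                           mature_seq = NA_character_)
  loci_m <- dplyr::mutate(loci_p, strand = "-", five_prime_pos = end)
  offs <- c(-2L, 0L, 1L, 3L)
  seqs <- vapply(seq_along(offs), function(i) strrep(c("A", "C", "G", "T")[i], 20),
                 character(1))
  aln_p <- tibble::tibble(sequence = seqs, chrom = "chr1", strand = "+",
                          start = base + offs, end = base + offs + 19L,
                          five_prime_pos = base + offs)
  aln_m <- tibble::tibble(sequence = seqs, chrom = "chr1", strand = "-",
                          start = base + 2L - offs,
                          end = base + 21L - offs,
                          five_prime_pos = base + 21L - offs)
  tly <- tibble::tibble(sequence = seqs, count = c(40L, 90L, 15L, 3L))
  qp <- quantify_mirna(aln_p, tly, loci_p)
  qm <- quantify_mirna(aln_m, tly, loci_m)
  expect_equal(qp$abundance, qm$abundance)
  expect_equal(qp$reference_offset, qm$reference_offset)
  expect_equal(qp$reference_sequence, qm$reference_sequence)
})

test_that("abundance is monotone in reference reads, inert outside windows", {
  inst <- random_quant_instance(10, 200, seed = 77)
  q0 <- quantify_mirna(inst$alignments, inst$tally, inst$loci)
  # adding counts to the reference sequence never decreases abundance
  ref <- q0$reference_sequence[which(!is.na(q0$reference_sequence))[1]]
  tly_up <- dplyr::mutate(inst$tally, count = count +
                            ifelse(sequence == ref, 1000L, 0L))
  q1 <- quantify_mirna(inst$alignments, tly_up, inst$loci)
  expect_true(all(q1$abundance >= q0$abundance))
  # a new sequence aligned far from every locus changes nothing
  far <- tibble::tibble(sequence = strrep("T", 25), chrom = "chr1",
                        strand = "+", start = 999000L, end = 999024L,
                        five_prime_pos = 999000L)
  q2 <- quantify_mirna(dplyr::bind_rows(inst$alignments, far),
                       dplyr::bind_rows(inst$tally,
                                        tibble::tibble(sequence = strrep("T", 25),
                                                       count = 500L)),
                       inst$loci)
  expect_equal(q2$abundance, q0$abundance)
  expect_equal(q2$reference_sequence, q0$reference_sequence)
})

test_that("end-to-end quantification recovers the simulation truth", {
  fx <- tiny_genome_fixture(chrom_len = 30000, n_mirna = 8, seed = 41)
  ec <- tidyr::crossing(mirna_id = fx$loci$mirna_id, sample_id = "s1") %>%
    dplyr::mutate(expected_count = 400)
  spec <- smallrna_sim_spec(offset_probs = c(`0` = 1), error_rate = 0)
  sim <- simulate_smallrna_reads(fx$loci, fx$genome, ec, spec, seed = 12)
  q <- quant_smallrna(sim$reads$sequence, fx$genome, fx$loci, TEST_ADAPTER)
  truth0 <- sim$truth %>%
    dplyr::filter(offset == 0) %>%
    dplyr::select(mirna_id, n_error_free)
  merged <- dplyr::left_join(q, truth0, by = "mirna_id")
  expect_equal(merged$abundance, merged$n_error_free)
  expect_true(all(merged$reference_offset == 0))
})

test_that("SAM ingestion keeps only perfect full-length matches", {
  g <- make_toy_genome(1, 3000, seed = 23)
  s1 <- substr(g$sequences[[1]], 101, 120)            # plus, perfect
  s2 <- mirwin:::revcomp(substr(g$sequences[[1]], 201, 220))  # minus, perfect
  s3 <- substr(g$sequences[[1]], 301, 320)            # one mismatch (NM=1)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:3000",
    sprintf("r1\t0\tchr1\t101\t42\t20M\t*\t0\t0\t%s\t%s\tNM:i:0", s1,
            strrep("I", 20)),
    sprintf("r2\t16\tchr1\t201\t42\t20M\t*\t0\t0\t%s\t%s\tNM:i:0",
            mirwin:::revcomp(s2), strrep("I", 20)),
    sprintf("r3\t0\tchr1\t301\t42\t20M\t*\t0\t0\t%s\t%s\tNM:i:1", s3,
            strrep("I", 20)),
    sprintf("r4\t0\tchr1\t401\t42\t15M5S\t*\t0\t0\t%s\t%s\tNM:i:0", s3,
            strrep("I", 20))
  ), sam)
  res <- read_sam_alignments(sam)
  expect_equal(nrow(res$alignments), 2)
  expect_setequal(res$alignments$sequence, c(s1, s2))
  m <- res$alignments[res$alignments$strand == "-", ]
  expect_equal(m$five_prime_pos, 220)
  expect_equal(m$sequence, s2)
  expect_equal(sum(res$tally$count), 2)
})
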