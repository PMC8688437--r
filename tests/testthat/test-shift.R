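test_that("KS statistic and p-value behave on canonical cases", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(disjoint$statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1), "nonempty")
})

test_that("KS equals exhaustive enumeration and stats::ks.test", {
  for (s in 1:20) {
    set.seed(s)
    x <- round(stats::rnorm(4), 1)
    y <- round(stats::rnorm(4), 1)
    mine <- ks_two_sample(x, y)
    expect_equal(mine$statistic, ks_stat_enumerate(x, y))
  }
  set.seed(99)
  x <- stats::rnorm(300)
  y <- stats::rnorm(400, 0.3)
  mine <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("KS is symmetric and invariant under monotone transforms", {
  set.seed(3)
  x <- stats::rexp(50)
  y <- stats::rexp(80, 0.5)
  a <- ks_two_sample(x, y)
  b <- ks_two_sample(y, x)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  mono <- ks_two_sample(log(x), log(y))
  expect_equal(mono$statistic, a$statistic)
})

planted_lfc_table <- function(seed, n_targets = 200, n_bg = 5000,
                              delta = 0.5, sd = 0.5) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n_targets + n_bg)),
    logFC = c(stats::rnorm(n_targets, delta, sd), stats::rnorm(n_bg, 0, sd)))
}
planted_map <- function(n_targets = 200) {
  tibble::tibble(mirna_id = "mir-x",
                 gene_id = sprintf("g%05d", seq_len(n_targets)))
}

test_that("the shift test detects a planted repression-release signal", {
  res <- target_shift_test(planted_lfc_table(1), planted_map(), "mir-x",
                           mirna_lfc = -1)
  expect_lt(res$p_value, 1e-6)
  expect_true(res$direction_consistent)
  expect_gt(res$shift, 0)
  expect_false(res$underpowered)
  # the two samples partition the expressed genes
  expect_equal(res$n_targets_expressed + res$n_background, 5200)
})

test_that("the shift test is calibrated under the null", {
  p <- vapply(1:200, function(s) {
    target_shift_test(planted_lfc_table(s, delta = 0), planted_map(),
                      "mir-x", -1)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p <= 0.05) - 0.05) , 0.04)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("degenerate target sets are flagged, not fatal", {
  lfc <- planted_lfc_table(2)
  map_absent <- tibble::tibble(mirna_id = "mir-x", gene_id = "not_a_gene")
  res <- target_shift_test(lfc, map_absent, "mir-x", -1)
  expect_true(res$underpowered)
  expect_true(is.na(res$p_value))
  map_small <- tibble::tibble(mirna_id = "mir-x",
                              gene_id = sprintf("g%05d", 1:5))
  res2 <- target_shift_test(lfc, map_small, "mir-x", -1)
  expect_true(res2$underpowered)
  expect_false(is.na(res2$p_value))
})

test_that("shift_analysis tests each DE miRNA and supports plotting", {
  lfc <- planted_lfc_table(4)
  map <- dplyr::bind_rows(planted_map(),
                          tibble::tibble(mirna_id = "mir-null",
                                         gene_id = sprintf("g%05d", 3001:3200)))
  de <- tibble::tibble(mirna_id = c("mir-x", "mir-null"), logFC = c(-1, 0.4))
  res <- shift_analysis(lfc, map, de)
  expect_equal(nrow(res), 2)
  expect_lt(res$p_value[res$mirna_id == "mir-x"], 1e-6)
  expect_gt(res$p_value[res$mirna_id == "mir-null"], 0.01)
  expect_s3_class(plot_cdf_shift(res, "mir-x"), "ggplot")
})

test_that("hypergeometric overlap equals direct tail summation", {
  # exhaustive check over a grid of small instances
  for (N in c(10, 23, 41, 60)) {
    for (na in c(2, 5, N %/% 2)) {
      for (nb in c(3, N %/% 3)) {
        for (k in 0:min(na, nb)) {
          p1 <- mirwin:::hypergeom_overlap_p(na, nb, k, N)
          expect_equal(p1, hyper_tail_direct(k, na, nb, N), tolerance = 1e-12)
        }
      }
    }
  }
  # the study-scale instance: 54 and 39 DE miRNAs sharing 15
  p <- mirwin:::hypergeom_overlap_p(54, 39, 15, 500)
  expect_equal(p, hyper_tail_direct(15, 54, 39, 500), tolerance = 1e-12)
  expect_lt(p, 0.05)
})

test_that("set overlap handles boundary cases", {
  ov0 <- concordant_de_overlap(sprintf("a%d", 1:5), sprintf("b%d", 1:5), 1000)
  expect_equal(ov0$n_overlap, 0)
  expect_gt(ov0$p_value, 0.99)
  u <- sprintf("x%d", 1:20)
  ov_all <- concordant_de_overlap(u, u, 20)
  expect_equal(ov_all$n_overlap, 20)
  expect_equal(ov_all$p_value, 1)
  expect_error(concordant_de_overlap(u, u, 10), "exceed")
})

test_that("Pearson concordance handles exact and sampled correlation", {
  line <- tibble::tibble(lfc_a = 1:10, lfc_b = 2 * (1:10))
  expect_equal(pearson_lfc_concordance(line)$r, 1)
  anti <- tibble::tibble(lfc_a = 1:10, lfc_b = -(1:10))
  expect_equal(pearson_lfc_concordance(anti)$r, -1)
  expect_warning(
    flat <- pearson_lfc_concordance(tibble::tibble(lfc_a = rep(1, 5),
                                                   lfc_b = 1:5)),
    "zero variance")
  expect_true(is.na(flat$r))
  # n = 15 pairs at rho = 0.85: the estimator is centred on the truth
  rho <- 0.85
  rs <- vapply(1:1000, function(s) {
    set.seed(s)
    z <- stats::rnorm(15)
    w <- rho * z + sqrt(1 - rho^2) * stats::rnorm(15)
    pearson_lfc_concordance(tibble::tibble(lfc_a = z, lfc_b = w))$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.03)
})

test_that("set enrichment ranks a perfectly enriched set first", {
  universe <- sprintf("g%04d", 1:1000)
  sets <- list(hit = universe[1:20], decoyA = universe[101:150],
               decoyB = universe[201:260])
  res <- set_enrichment(universe[1:20], sets, universe)
  expect_identical(res$set[1], "hit")
  expect_lt(res$p_value[1], 1e-10)
  # invariant to the ordering of the annotation sets
  res2 <- set_enrichment(universe[1:20], rev(sets), universe)
  expect_equal(res2[order(res2$set), ]$fdr, res[order(res$set), ]$fdr)
  expect_error(set_enrichment("a", sets, character(0)), "empty universe")
})

test_that("random queries are rarely FDR-significant", {
  universe <- sprintf("g%04d", 1:1000)
  set.seed(123)
  sets <- lapply(1:8, function(i) sample(universe, 50))
  names(sets) <- sprintf("s%d", 1:8)
  n_sig <- vapply(1:100, function(s) {
    set.seed(s)
    q <- sample(universe, 40)
    any(set_enrichment(q, sets, universe)$fdr < 0.05)
  }, logical(1))
  expect_lte(mean(n_sig), 0.08)
})
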