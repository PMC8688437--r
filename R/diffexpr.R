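# --- count-matrix plumbing -------------------------------------------------

# Accept a features x samples integer matrix, or a data frame whose first
# column (or a column named feature_id/gene_id/mirna_id) holds feature ids.
as_count_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("f_%05d", seq_len(nrow(x)))
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  id_col <- intersect(c("feature_id", "gene_id", "mirna_id"), names(x))
  id_col <- if (length(id_col) > 0) id_col[1] else names(x)[1]
  m <- as.matrix(x[setdiff(names(x), id_col)])
  rownames(m) <- x[[id_col]]
  storage.mode(m) <- "double"
  m
}

as_group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.character(groups$group), groups$sample_id)
    g <- g[sample_ids]
  } else if (!is.null(names(groups))) {
    g <- as.character(groups)[match(sample_ids, names(groups))]
  } else {
    g <- as.character(groups)
  }
  if (length(g) != length(sample_ids) || anyNA(g)) {
    abort("group labels must cover all samples")
  }
  g
}

geomean <- function(x) exp(mean(log(x)))

# --- TMM -------------------------------------------------------------------

#' Trimmed mean of M-values normalization factors
#'
#' Computes between-library scaling factors robust to compositional bias.
#' The reference library is the one whose 75th-percentile count proportion is
#' closest to the mean of those percentiles. For every other library, M
#' (log2 ratio of library-size-scaled proportions versus the reference) and A
#' (mean log2 abundance) are computed over features nonzero in both; the most
#' extreme `trim_m` fraction by M and `trim_a` by A are doubly trimmed
#' (half of each fraction per tail), and the factor is two to the
#' precision-weighted mean of the surviving M values, with binomial
#' delta-method inverse variances as weights. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts Features x samples count matrix, or data frame with a
#'   feature-id column.
#' @param lib_sizes Optional library sizes (default column sums).
#' @param trim_m Total trim fraction on M (default 0.30, i.e. 15% per tail).
#' @param trim_a Total trim fraction on A (default 0.05).
#' @return Tibble with `sample_id`, `lib_size`, `tmm_factor`; the reference
#'   sample id is attached as attribute `ref_sample`.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) abort("TMM needs at least two samples")
  if (any(m < 0)) abort("counts must be nonnegative")
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  m <- m[rowSums(m) > 0, , drop = FALSE]

  f75 <- vapply(seq_len(ncol(m)),
                function(j) stats::quantile(m[, j] / lib_sizes[j], 0.75,
                                            names = FALSE),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    obs <- m[, j]; refc <- m[, ref]
    nO <- lib_sizes[j]; nR <- lib_sizes[ref]
    ok <- obs > 0 & refc > 0
    if (!any(ok)) {
      warn(sprintf("sample %d shares no nonzero feature with the reference",
                   j))
      return(1)
    }
    obs <- obs[ok]; refc <- refc[ok]
    M <- log2((obs / nO) / (refc / nR))
    A <- 0.5 * log2((obs / nO) * (refc / nR))
    # delta-method variances evaluated on counts-per-million so factors are
    # exactly invariant to uniform rescaling of any single library
    S <- 1e6
    xo <- obs * S / nO; xr <- refc * S / nR
    v <- (S - xo) / (S * xo) + (S - xr) / (S * xr)
    n <- length(M)
    loM <- floor(n * trim_m / 2) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a / 2) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    2^f
  }, numeric(1))

  factors <- factors / geomean(factors)
  sample_ids <- colnames(m)
  if (is.null(sample_ids)) sample_ids <- sprintf("s_%d", seq_len(ncol(m)))
  out <- tibble::tibble(sample_id = sample_ids, lib_size = lib_sizes,
                        tmm_factor = factors)
  attr(out, "ref_sample") <- sample_ids[ref]
  out
}

# --- dispersion ------------------------------------------------------------

#' Pooled method-of-moments common dispersion
#'
#' Estimates a single negative-binomial dispersion shared across features.
#' Counts are scaled to a common effective library size, then each feature
#' with at least one replicated group yields the moment estimate
#' `max(0, (s^2 - m) / m^2)` from its pooled within-group variance and mean;
#' the common value is the median over features with mean above 5 (low-count
#' features carry almost no dispersion information).
#'
#' @param counts Count matrix or data frame.
#' @param groups Group labels (vector, named vector, or tibble with
#'   `sample_id` and `group`).
#' @param factors Optional normalization tibble from [tmm_factors()].
#' @param min_mean Minimum normalized mean for a feature to enter the pooled
#'   median (default 5).
#' @return A single dispersion value (>= 0).
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL,
                                       min_mean = 5) {
  m <- as_count_matrix(counts)
  g <- as_group_vector(groups, colnames(m))
  if (is.null(factors)) factors <- tmm_factors(m)
  eff <- factors$lib_size * factors$tmm_factor
  y <- sweep(m, 2, geomean(eff) / eff, `*`)

  reps <- table(g)
  if (!any(reps >= 2)) {
    warn("no replicated group; returning dispersion 0 (Poisson fallback)")
    return(0)
  }
  lvl <- names(reps)[reps >= 2]
  df <- 0
  ssum <- rep(0, nrow(y))
  for (l in lvl) {
    yl <- y[, g == l, drop = FALSE]
    mu_l <- rowMeans(yl)
    ssum <- ssum + rowSums((yl - mu_l)^2)
    df <- df + ncol(yl) - 1L
  }
  s2 <- ssum / df
  mu <- rowMeans(y[, g %in% lvl, drop = FALSE])
  est <- pmax(0, (s2 - mu) / mu^2)
  use <- mu > min_mean
  if (!any(use)) return(0)
  max(0, stats::median(est[use]))
}

# --- exact test ------------------------------------------------------------

# Two-sided minimum-likelihood exact p for one feature: group sums s1 and
# t - s1 modelled as NB with sizes n1/phi and n2/phi and a common per-sample
# mean; the conditional distribution of s1 given t is free of that mean.
exact_nb_pvalue <- function(s1, t, n1, n2, phi) {
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    lp <- stats::dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- t / (n1 + n2)
    lp <- stats::dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(t - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  tot <- sum(pr)
  obs <- pr[s1 + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]) / tot)
}

#' Two-group negative-binomial exact test
#'
#' Tests each feature for a count difference between exactly two groups.
#' Counts are scaled to a common effective library size (the geometric mean
#' of effective sizes, i.e. library size times TMM factor) and rounded
#' half-up to pseudo-counts; each group's pseudo-count sum is modelled as
#' negative binomial with mean proportional to its replicate number and
#' dispersion `phi / replicates`, and the two-sided p-value sums, over the
#' conditional distribution of the first group's sum given the total, all
#' outcomes no more probable than the observed one. The log2 fold change is
#' `log2((mean normalized group-2 count + 0.5) / (mean group-1 count + 0.5))`
#' (second group versus first).
#'
#' @param counts Count matrix or data frame with feature-id column.
#' @param groups Group labels; the first factor level (or alphabetically
#'   first label) is the baseline group.
#' @param factors Optional [tmm_factors()] output (computed when `NULL`).
#' @param dispersion Optional common dispersion (estimated when `NULL`).
#' @return Tibble: `feature_id`, `logFC`, `PValue`, plus attributes
#'   `dispersion` and `factors`.
#' @export
nb_exact_test <- function(counts, groups, factors = NULL, dispersion = NULL) {
  m <- as_count_matrix(counts)
  g <- as_group_vector(groups, colnames(m))
  lev <- if (is.factor(groups)) levels(groups) else sort(unique(g))
  if (length(lev) != 2L) abort("exactly two groups are required")
  if (is.null(factors)) factors <- tmm_factors(m)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(m, g, factors)
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  eff <- factors$lib_size * factors$tmm_factor
  scale_to <- geomean(eff)
  norm <- sweep(m, 2, scale_to / eff, `*`)
  pseudo <- round_half_up(norm)

  i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  s1 <- rowSums(pseudo[, i1, drop = FALSE])
  s2 <- rowSums(pseudo[, i2, drop = FALSE])
  t_tot <- s1 + s2
  pv <- vapply(seq_len(nrow(m)), function(i) {
    exact_nb_pvalue(s1[i], t_tot[i], n1, n2, dispersion)
  }, numeric(1))
  lfc <- unname(log2((rowMeans(norm[, i2, drop = FALSE]) + 0.5) /
                       (rowMeans(norm[, i1, drop = FALSE]) + 0.5)))
  out <- tibble::tibble(feature_id = rownames(m), logFC = lfc, PValue = pv)
  attr(out, "dispersion") <- dispersion
  attr(out, "factors") <- factors
  attr(out, "group_levels") <- lev
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotone enforcement, preserving input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential expression at an FDR threshold
#'
#' Adds BH-adjusted FDR and an up/down/ns label: "up" when FDR is strictly
#' below the threshold with positive log fold change, "down" with negative,
#' "ns" otherwise (an FDR exactly at the threshold is not called).
#'
#' @param results Tibble from [nb_exact_test()] (columns `feature_id`,
#'   `logFC`, `PValue`).
#' @param fdr_threshold FDR cutoff (default 0.05, strict `<`).
#' @return The results tibble with `FDR` and `call` columns; summary counts
#'   (`total`, `up`, `down`) attached as attribute `summary`.
#' @export
call_de <- function(results, fdr_threshold = 0.05) {
  out <- results %>%
    dplyr::mutate(FDR = bh_fdr(.data$PValue),
                  call = dplyr::case_when(
                    .data$FDR < fdr_threshold & .data$logFC > 0 ~ "up",
                    .data$FDR < fdr_threshold & .data$logFC < 0 ~ "down",
                    TRUE ~ "ns"))
  attr(out, "summary") <- tibble::tibble(
    total = sum(out$call != "ns"),
    up = sum(out$call == "up"),
    down = sum(out$call == "down"))
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Full differential-expression analysis of a two-group count matrix
#'
#' Chains TMM normalization, common-dispersion estimation, the two-group
#' negative-binomial exact test and BH FDR calling into one fitted object
#' with [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams nb_exact_test
#' @param fdr_threshold FDR cutoff for calls (default 0.05).
#' @return An object of class `mirwin_de`.
#' @export
de_analysis <- function(counts, groups, fdr_threshold = 0.05,
                        dispersion = NULL) {
  m <- as_count_matrix(counts)
  factors <- tmm_factors(m)
  g <- as_group_vector(groups, colnames(m))
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(m, g, factors)
  }
  res <- nb_exact_test(m, groups, factors, dispersion)
  tab <- call_de(res, fdr_threshold)
  structure(list(table = tab, factors = factors, dispersion = dispersion,
                 fdr_threshold = fdr_threshold,
                 group_levels = attr(res, "group_levels"),
                 summary = attr(tab, "summary")),
            class = "mirwin_de")
}

#' @export
print.mirwin_de <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mirwin_de> %d features, dispersion %.4f; FDR < %g: %d DE (%d up, %d down)\n",
    nrow(x$table), x$dispersion, x$fdr_threshold, s$total, s$up, s$down))
  invisible(x)
}
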