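# --- Kolmogorov-Smirnov ----------------------------------------------------

# Asymptotic Kolmogorov survival function Q(lambda) = 2 * sum_{k>=1}
# (-1)^{k-1} exp(-2 k^2 lambda^2), truncated at 100 terms or 1e-12.
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  total <- 0
  for (k in 1:100) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-12) break
  }
  min(1, max(0, 2 * total))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the supremum absolute difference between the two empirical CDFs
#' (standard step construction; ties need no special handling) and an
#' asymptotic p-value from the Kolmogorov distribution evaluated at
#' `sqrt(m * n / (m + n)) * D`.
#'
#' @param x,y Nonempty numeric samples.
#' @return One-row tibble with `statistic` (D), `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) abort("samples must not contain NA")
  n_x <- length(x); n_y <- length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  ind <- c(rep(1 / n_x, n_x), rep(-1 / n_y, n_y))[ord]
  cdf_diff <- cumsum(ind)
  # at tied pooled values only the last cumulative value is a CDF evaluation
  srt <- pooled[ord]
  last_of_run <- c(srt[-1] != srt[-length(srt)], TRUE)
  d <- max(abs(cdf_diff[last_of_run]))
  lambda <- sqrt(n_x * n_y / (n_x + n_y)) * d
  tibble::tibble(statistic = d, p_value = kolmogorov_sf(lambda),
                 n_x = n_x, n_y = n_y)
}

# --- target CDF-shift test -------------------------------------------------

#' Target-gene versus background LFC CDF-shift test
#'
#' Tests whether the log2 fold changes of one miRNA's target genes are
#' shifted relative to all other expressed genes, the signature of released
#' (or gained) repression when the miRNA itself changes. The target sample
#' is the LFCs of expressed target genes; the background is the LFCs of all
#' remaining expressed genes (targets of the cognate miRNA excluded), so the
#' two samples partition the expressed genes. The comparison uses the
#' two-sample Kolmogorov-Smirnov test plus a signed shift (median target LFC
#' minus median background LFC). The shift is direction-consistent when its
#' sign opposes the miRNA's own fold change — a falling repressor releases
#' its targets upward.
#'
#' @param lfc_table Tibble of expressed genes with columns `gene_id` and
#'   `logFC` (e.g. from [nb_exact_test()] with `feature_id` renamed, or any
#'   two-column table).
#' @param target_map Tibble with `mirna_id`, `gene_id`.
#' @param mirna_id The miRNA to test.
#' @param mirna_lfc The miRNA's own log2 fold change in the same comparison.
#' @param min_targets Below this many expressed targets the result is
#'   flagged underpowered but still computed (default 10).
#' @return One-row tibble: `mirna_id`, `mirna_lfc`, `n_targets_expressed`,
#'   `n_background`, `statistic`, `p_value`, `shift`,
#'   `direction_consistent`, `underpowered`.
#' @export
target_shift_test <- function(lfc_table, target_map, mirna_id, mirna_lfc,
                              min_targets = 10L) {
  names(lfc_table)[names(lfc_table) == "feature_id"] <- "gene_id"
  targets <- target_map$gene_id[target_map$mirna_id == mirna_id]
  is_target <- lfc_table$gene_id %in% targets
  x <- lfc_table$logFC[is_target]
  y <- lfc_table$logFC[!is_target]
  if (length(x) == 0 || length(y) == 0) {
    return(tibble::tibble(mirna_id = mirna_id, mirna_lfc = mirna_lfc,
                          n_targets_expressed = length(x),
                          n_background = length(y),
                          statistic = NA_real_, p_value = NA_real_,
                          shift = NA_real_, direction_consistent = NA,
                          underpowered = TRUE))
  }
  ks <- ks_two_sample(x, y)
  shift <- stats::median(x) - stats::median(y)
  tibble::tibble(
    mirna_id = mirna_id, mirna_lfc = mirna_lfc,
    n_targets_expressed = length(x), n_background = length(y),
    statistic = ks$statistic, p_value = ks$p_value, shift = shift,
    direction_consistent = sign(shift) == -sign(mirna_lfc),
    underpowered = length(x) < min_targets)
}

#' Shift-test every differentially expressed miRNA
#'
#' Applies [target_shift_test()] to each miRNA in a DE table against one
#' gene-level LFC table.
#'
#' @param lfc_table Expressed-gene LFC tibble (`gene_id`, `logFC`).
#' @param target_map Tibble with `mirna_id`, `gene_id`.
#' @param mirna_de Tibble with `mirna_id` (or `feature_id`) and `logFC` for
#'   the miRNAs to test.
#' @return Tibble with one [target_shift_test()] row per miRNA, class
#'   `mirwin_shift`.
#' @export
shift_analysis <- function(lfc_table, target_map, mirna_de) {
  names(mirna_de)[names(mirna_de) == "feature_id"] <- "mirna_id"
  out <- purrr::pmap_dfr(mirna_de[c("mirna_id", "logFC")],
                         function(mirna_id, logFC) {
                           target_shift_test(lfc_table, target_map,
                                             mirna_id, logFC)
                         })
  class(out) <- c("mirwin_shift", class(out))
  attr(out, "lfc_table") <- lfc_table
  attr(out, "target_map") <- target_map
  out
}

# --- overlap / concordance / enrichment ------------------------------------

#' Hypergeometric test of overlap between two feature sets
#'
#' One-sided test of whether two sets drawn from a common universe share
#' more members than expected by chance: `p = P(X >= overlap)` for `X`
#' hypergeometric. Equivalent to a one-sided Fisher exact test on the 2x2
#' table.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @param universe_size Size of the common universe (>= size of each set).
#' @return One-row tibble: `n_a`, `n_b`, `n_overlap`, `universe`, `p_value`.
#' @export
concordant_de_overlap <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  k <- length(intersect(a, b))
  if (length(a) > universe_size || length(b) > universe_size) {
    abort("set sizes exceed the universe")
  }
  p <- stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  tibble::tibble(n_a = length(a), n_b = length(b), n_overlap = k,
                 universe = universe_size, p_value = p)
}

# Same tail from explicit sizes (no element identities needed).
hypergeom_overlap_p <- function(n_a, n_b, n_overlap, universe_size) {
  if (n_overlap > min(n_a, n_b) || max(n_a, n_b) > universe_size) {
    abort("inconsistent overlap sizes")
  }
  stats::phyper(n_overlap - 1, n_a, universe_size - n_a, n_b,
                lower.tail = FALSE)
}

#' Pearson concordance of paired log fold changes
#'
#' Correlates the fold changes of features measured in two comparisons (for
#' example the same miRNAs in two cell lines); the p-value comes from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param paired_lfcs Tibble/data frame whose first two numeric columns are
#'   the paired LFCs (or columns named `lfc_a`, `lfc_b`).
#' @return One-row tibble: `r`, `p_value`, `n`. `r` is `NA` with a warning
#'   when either coordinate has zero variance.
#' @export
pearson_lfc_concordance <- function(paired_lfcs) {
  if (all(c("lfc_a", "lfc_b") %in% names(paired_lfcs))) {
    x <- paired_lfcs$lfc_a; y <- paired_lfcs$lfc_b
  } else {
    num <- which(vapply(paired_lfcs, is.numeric, logical(1)))[1:2]
    x <- paired_lfcs[[num[1]]]; y <- paired_lfcs[[num[2]]]
  }
  if (length(x) < 3) abort("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance in one coordinate; correlation undefined")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Fisher-exact enrichment of a query set against annotation sets
#'
#' For each annotation set, tests one-sided over-representation of the query
#' within it (hypergeometric, identical to one-sided Fisher exact) and
#' adjusts across sets by Benjamini-Hochberg.
#'
#' @param query_set Character vector of query features.
#' @param annotation_sets Named list of character vectors.
#' @param universe Character vector, the feature universe; all sets must be
#'   subsets of it.
#' @return Tibble sorted by FDR then p: `set`, `n_set`, `n_query`,
#'   `n_overlap`, `p_value`, `fdr`.
#' @export
set_enrichment <- function(query_set, annotation_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query <- unique(intersect(query_set, universe))
  rows <- purrr::imap_dfr(annotation_sets, function(s, nm) {
    s <- unique(intersect(s, universe))
    k <- length(intersect(query, s))
    tibble::tibble(set = nm, n_set = length(s), n_query = length(query),
                   n_overlap = k,
                   p_value = stats::phyper(k - 1, length(s),
                                           length(universe) - length(s),
                                           length(query),
                                           lower.tail = FALSE))
  })
  rows$fdr <- bh_fdr(rows$p_value)
  dplyr::arrange(rows, .data$fdr, .data$p_value, .data$set)
}
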