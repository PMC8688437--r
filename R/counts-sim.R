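#' Random miRNA-to-target map
#'
#' Assigns each miRNA a random set of target genes, disjointly by default so
#' that planted repression-release shifts are attributable to a single miRNA.
#'
#' @param mirna_ids Character vector of miRNA ids.
#' @param gene_ids Character vector of the gene universe.
#' @param targets_per_mirna Number of targets per miRNA.
#' @param seed Integer seed.
#' @param disjoint Should target sets be disjoint across miRNAs?
#' @return Tibble with columns `mirna_id`, `gene_id`.
#' @export
make_target_map <- function(mirna_ids, gene_ids, targets_per_mirna = 200L,
                            seed = 1L, disjoint = TRUE) {
  need <- length(mirna_ids) * targets_per_mirna
  if (disjoint && need > length(gene_ids)) {
    abort("not enough genes for disjoint target sets")
  }
  with_seed(seed, {
    if (disjoint) {
      pick <- sample(gene_ids, need)
      tibble::tibble(
        mirna_id = rep(mirna_ids, each = targets_per_mirna),
        gene_id = pick
      )
    } else {
      dplyr::bind_rows(lapply(mirna_ids, function(m) {
        tibble::tibble(mirna_id = m,
                       gene_id = sample(gene_ids, targets_per_mirna))
      }))
    }
  })
}

#' Ground truth for a simulated two-group expression experiment
#'
#' Defines per-gene negative-binomial means, true log2 fold changes and a
#' shared dispersion for a knockdown-vs-control design, plus an optional
#' miRNA target map whose member genes carry an extra repression-release
#' shift `delta` (log2 units) on top of their own fold change — the structure
#' a target-gene CDF-shift test is designed to detect.
#'
#' Defaults reflect a typical bulk RNA-seq knockdown experiment: 3 vs 3
#' replicates, dispersion 0.1, 10% of genes differentially expressed at
#' |LFC| = 1, base means log-uniform on [20, 500].
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group.
#' @param frac_de Fraction of genes with a true fold change.
#' @param lfc_magnitude |LFC| of differentially expressed genes (signs split
#'   evenly).
#' @param dispersion Negative-binomial dispersion (>= 0; 0 gives Poisson).
#' @param mean_range Range of base means; means are log-uniform on it.
#' @param lib_size_factors Relative library sizes for the `2 * n_per_group`
#'   samples (default all 1).
#' @param target_map Optional tibble (`mirna_id`, `gene_id`); its genes get
#'   the planted shift.
#' @param delta Planted shift in log2 units, either a single value or a named
#'   vector keyed by miRNA id.
#' @param seed Integer seed.
#' @return A list of class `expression_sim_truth` with a per-gene `genes`
#'   tibble (`gene_id`, `base_mean`, `true_lfc`, `shift_delta`), design
#'   parameters, and the target map.
#' @export
expression_sim_truth <- function(n_genes = 10000L, n_per_group = 3L,
                                 frac_de = 0.10, lfc_magnitude = 1,
                                 dispersion = 0.1, mean_range = c(20, 500),
                                 lib_size_factors = NULL, target_map = NULL,
                                 delta = 0, seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_per_group, "n_per_group")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (is.null(lib_size_factors)) lib_size_factors <- rep(1, 2L * n_per_group)
  if (length(lib_size_factors) != 2L * n_per_group ||
      any(lib_size_factors <= 0)) {
    abort("lib_size_factors must be 2 * n_per_group positive values")
  }
  genes <- with_seed(seed, {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    base_mean <- exp(stats::runif(n_genes, log(mean_range[1]),
                                  log(mean_range[2])))
    n_de <- round(frac_de * n_genes)
    true_lfc <- rep(0, n_genes)
    if (n_de > 0) {
      de_idx <- sample.int(n_genes, n_de)
      true_lfc[de_idx] <- lfc_magnitude *
        rep_len(c(1, -1), n_de)[sample.int(n_de)]
    }
    tibble::tibble(gene_id = gene_id, base_mean = base_mean,
                   true_lfc = true_lfc, shift_delta = 0)
  })
  if (!is.null(target_map)) {
    bad <- setdiff(target_map$gene_id, genes$gene_id)
    if (length(bad) > 0) abort("target_map references unknown genes")
    dl <- if (is.null(names(delta))) {
      stats::setNames(rep(delta[1], length(unique(target_map$mirna_id))),
                      unique(target_map$mirna_id))
    } else {
      delta
    }
    per_gene <- target_map %>%
      dplyr::mutate(d = unname(dl[.data$mirna_id])) %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(shift_delta = sum(.data$d), .groups = "drop")
    genes <- genes %>%
      dplyr::select(-"shift_delta") %>%
      dplyr::left_join(per_gene, by = "gene_id") %>%
      dplyr::mutate(shift_delta = dplyr::coalesce(.data$shift_delta, 0))
  }
  structure(list(genes = genes, n_per_group = as.integer(n_per_group),
                 dispersion = dispersion,
                 lib_size_factors = lib_size_factors,
                 target_map = target_map, seed = as.integer(seed)),
            class = "expression_sim_truth")
}

#' Draw a negative-binomial count matrix from a simulation truth
#'
#' Group-1 (control) means are the library-size-scaled base means; group-2
#' (knockdown) means are multiplied by `2^(true_lfc + shift_delta)`. Counts
#' are negative binomial with the truth's dispersion (Poisson when the
#' dispersion is zero).
#'
#' @param truth An [expression_sim_truth()].
#' @param seed Optional seed overriding the truth's own.
#' @return A list of class `sim_counts`: integer `counts` matrix (genes x
#'   samples), a `groups` tibble (`sample_id`, `group`), and the `truth`.
#' @export
simulate_count_matrix <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "expression_sim_truth"))
  if (is.null(seed)) seed <- child_seed(truth$seed, 11L)
  n <- truth$n_per_group
  genes <- truth$genes
  mu1 <- genes$base_mean
  mu2 <- genes$base_mean * 2^(genes$true_lfc + genes$shift_delta)
  mu <- cbind(matrix(rep(mu1, n), ncol = n),
              matrix(rep(mu2, n), ncol = n))
  mu <- sweep(mu, 2, truth$lib_size_factors, `*`)
  phi <- truth$dispersion
  counts <- with_seed(seed, {
    if (phi == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
             nrow = nrow(mu))
    }
  })
  sample_id <- c(sprintf("ctrl_%d", seq_len(n)), sprintf("kd_%d", seq_len(n)))
  dimnames(counts) <- list(genes$gene_id, sample_id)
  groups <- tibble::tibble(sample_id = sample_id,
                           group = rep(c("control", "knockdown"), each = n))
  structure(list(counts = counts, groups = groups, truth = truth),
            class = "sim_counts")
}

#' Simulate a clinical biomarker table with target AUC and hazard ratio
#'
#' Expression follows a binormal model: controls ~ N(0, 1) and cases ~
#' N(mu, 1) with `mu = sqrt(2) * qnorm(auc_target)`, so the population AUC
#' equals `auc_target`. Survival times are exponential with the hazard of
#' above-median-expression subjects multiplied by `hr_target`, with
#' administrative censoring at `censor_time`.
#'
#' @param n Number of subjects (half cases, half controls).
#' @param auc_target Population AUC in `[0.5, 1]`.
#' @param hr_target True hazard ratio (above- vs below-median expression).
#' @param seed Integer seed.
#' @param baseline_hazard Event hazard per month for the low-expression group.
#' @param censor_time Administrative censoring time in months.
#' @return Tibble: `sample_id`, `label` ("case"/"control"), `expression`,
#'   `time` (months), `event` (1 = event, 0 = censored).
#' @export
simulate_clinical <- function(n = 200L, auc_target = 0.878, hr_target = 2,
                              seed = 1L, baseline_hazard = 0.02,
                              censor_time = 60) {
  stopifnot_scalar_count(n, "n", min = 2L)
  if (auc_target < 0.5 || auc_target > 1) {
    abort("auc_target must lie in [0.5, 1]")
  }
  if (hr_target <= 0) abort("hr_target must be positive")
  mu <- sqrt(2) * stats::qnorm(min(auc_target, 1 - 1e-12))
  with_seed(seed, {
    n_case <- n %/% 2L
    label <- rep(c("control", "case"), c(n - n_case, n_case))
    expression <- stats::rnorm(n, mean = ifelse(label == "case", mu, 0))
    high <- expression > stats::median(expression)
    rate <- baseline_hazard * ifelse(high, hr_target, 1)
    t_event <- stats::rexp(n, rate = rate)
    event <- as.integer(t_event <= censor_time)
    time <- pmin(t_event, censor_time)
    tibble::tibble(sample_id = sprintf("s_%05d", seq_len(n)),
                   label = label, expression = expression,
                   time = time, event = event)
  })
}
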