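#' Build a pipeline configuration
#'
#' A single flat-namespace list driving the whole workflow: simulation sizes
#' and planted effects, quantification parameters, testing thresholds and a
#' global seed from which every stage derives its own. The configuration is
#' serialized to canonical JSON for hashing in the run manifest.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed; all stage seeds cascade from it by fixed
#'   offsets.
#' @param cell_lines Names of the simulated cell lines.
#' @param n_chrom,chrom_len Toy genome dimensions.
#' @param n_mirna Number of planted miRNA loci.
#' @param n_planted_mirnas How many miRNAs carry a true knockdown fold
#'   change (the first ones).
#' @param planted_mirna_lfc log2 fold change of the planted miRNAs
#'   (knockdown vs control).
#' @param mirna_mean_range Range of per-miRNA mean read counts per sample.
#' @param n_per_group Replicates per condition.
#' @param n_genes Number of simulated genes.
#' @param frac_de Fraction of genes with a direct true fold change.
#' @param gene_lfc_magnitude |LFC| of those genes.
#' @param dispersion NB dispersion for gene counts.
#' @param targets_per_mirna Targets per planted miRNA in the map.
#' @param delta Magnitude of the repression-release shift planted on target
#'   genes (log2 units; sign set opposite the miRNA's own LFC).
#' @param adapter 3' adapter sequence for read simulation/trimming.
#' @param error_rate Per-base read error rate.
#' @param window,min_len,max_len Quantification parameters.
#' @param fdr_threshold DE call threshold.
#' @param min_targets Underpowered flag threshold for the shift test.
#' @param n_clinical,auc_target,hr_target Clinical-table simulation.
#' @param inputs Optional named list of pre-existing input paths (checked to
#'   exist during validation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cell_lines = c("lineA", "lineB"),
                            n_chrom = 1L, chrom_len = 60000L,
                            n_mirna = 20L, n_planted_mirnas = 2L,
                            planted_mirna_lfc = -1.5,
                            mirna_mean_range = c(100, 400),
                            n_per_group = 3L,
                            n_genes = 4000L, frac_de = 0.10,
                            gene_lfc_magnitude = 1, dispersion = 0.1,
                            targets_per_mirna = 200L, delta = 0.6,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            error_rate = 0.001,
                            window = 3L, min_len = 18L, max_len = 28L,
                            fdr_threshold = 0.05, min_targets = 10L,
                            n_clinical = 400L, auc_target = 0.878,
                            hr_target = 2,
                            inputs = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented range and that any
#' referenced input file exists. Violations are returned, not thrown, each
#' naming the offending field and the constraint it breaks.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(cond, msg) if (cond) v <<- c(v, msg)
  add(!is.numeric(config$seed) || config$seed != floor(config$seed),
      "seed must be an integer")
  add(config$window < 0, "window must be >= 0")
  add(config$min_len > config$max_len, "min_len must be <= max_len")
  add(config$min_len < 1, "min_len must be >= 1")
  add(config$fdr_threshold <= 0 || config$fdr_threshold >= 1,
      "fdr_threshold must lie in (0, 1)")
  add(config$error_rate < 0 || config$error_rate > 1,
      "error_rate must lie in [0, 1]")
  add(config$dispersion < 0, "dispersion must be >= 0")
  add(config$n_per_group < 2, "n_per_group must be >= 2")
  add(config$n_mirna < config$n_planted_mirnas,
      "n_planted_mirnas must not exceed n_mirna")
  add(nchar(config$adapter) < 8, "adapter must be at least 8 nt")
  add(config$chrom_len < 200, "chrom_len must be >= 200")
  add(config$auc_target < 0.5 || config$auc_target > 1,
      "auc_target must lie in [0.5, 1]")
  add(config$hr_target <= 0, "hr_target must be positive")
  if (!is.null(config$inputs)) {
    for (nm in names(config$inputs)) {
      p <- config$inputs[[nm]]
      add(!file.exists(p), sprintf("inputs$%s does not exist: %s", nm, p))
    }
  }
  v
}

config_json <- function(config) {
  plain <- unclass(config)
  plain <- plain[order(names(plain))]
  jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg))
}

run_stage <- function(stage, manifest_env, fun) {
  stage_log(stage, "status=start")
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(fun(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "mirwin_stage_error", stage = stage)
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest_env$stages[[stage]] <- list(elapsed_s = round(elapsed, 3))
  stage_log(stage, sprintf("status=ok elapsed=%.2fs", elapsed))
  result
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes, in dependency order: simulation of genome, loci, reads, gene
#' counts, target map and clinical table for each cell line; 5'-window
#' quantification of every FASTQ into a miRNA count matrix; differential
#' expression of miRNA and gene matrices; the target CDF-shift test of every
#' FDR-passing miRNA; cross-cell-line overlap and Pearson concordance; and
#' clinical ROC/Kaplan-Meier statistics. Every stage writes TSV outputs
#' under `config$out_dir` and is logged with a machine-readable summary
#' line; a failure halts the run with a condition naming the stage. A run
#' manifest (package version, config hash, per-file MD5 checksums, per-stage
#' wall time) is written as JSON — re-running with an identical config and
#' seed reproduces identical checksums.
#'
#' @param config A validated [pipeline_config()].
#' @return The manifest, invisibly (list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    abort(paste0("invalid config:\n", paste("-", violations, collapse = "\n")),
          class = "mirwin_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env()
  env$stages <- list()
  paths <- character(0)
  keep <- function(p) {
    paths <<- c(paths, p)
    p
  }
  out <- function(...) file.path(config$out_dir, ...)
  n <- config$n_per_group
  sample_ids <- c(sprintf("ctrl_%d", seq_len(n)), sprintf("kd_%d", seq_len(n)))
  groups <- tibble::tibble(sample_id = sample_ids,
                           group = rep(c("control", "knockdown"), each = n))

  # ---- simulate ----
  sim <- run_stage("simulate", env, function() {
    genome <- make_toy_genome(config$n_chrom, config$chrom_len,
                              seed = child_seed(config$seed, 1L))
    loci <- plant_mirna_loci(genome, config$n_mirna,
                             seed = child_seed(config$seed, 2L))
    keep(write_genome_fasta(genome, out("genome.fa")))
    keep(write_mirna_gff3(loci, out("mirna_loci.gff3")))
    planted <- loci$mirna_id[seq_len(config$n_planted_mirnas)]
    mirna_truth <- with_seed(child_seed(config$seed, 3L), {
      tibble::tibble(
        mirna_id = loci$mirna_id,
        base_count = stats::runif(nrow(loci), config$mirna_mean_range[1],
                                  config$mirna_mean_range[2]),
        true_lfc = ifelse(loci$mirna_id %in% planted,
                          config$planted_mirna_lfc, 0))
    })
    spec <- smallrna_sim_spec(adapter = config$adapter,
                              error_rate = config$error_rate)
    gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
    target_map <- make_target_map(planted, gene_ids,
                                  config$targets_per_mirna,
                                  seed = child_seed(config$seed, 4L))
    readr::write_tsv(target_map, keep(out("target_map.tsv")))
    readr::write_tsv(mirna_truth, keep(out("mirna_truth.tsv")))
    readr::write_tsv(groups, keep(out("sample_groups.tsv")))

    per_line <- lapply(seq_along(config$cell_lines), function(ci) {
      line <- config$cell_lines[ci]
      expected <- tidyr::crossing(mirna_truth,
                                  tibble::tibble(sample_id = sample_ids)) %>%
        dplyr::left_join(groups, by = "sample_id") %>%
        dplyr::mutate(expected_count = .data$base_count *
                        ifelse(.data$group == "knockdown",
                               2^.data$true_lfc, 1)) %>%
        dplyr::select("mirna_id", "sample_id", "expected_count")
      reads <- simulate_smallrna_reads(
        loci, genome, expected, spec,
        seed = child_seed(config$seed, 10L + ci))
      fq_paths <- vapply(sample_ids, function(s) {
        p <- out(sprintf("%s_%s.fastq", line, s))
        write_fastq(reads$reads[reads$reads$sample_id == s, ], p)
        keep(p)
      }, character(1))
      truth <- expression_sim_truth(
        n_genes = config$n_genes, n_per_group = n,
        frac_de = config$frac_de,
        lfc_magnitude = config$gene_lfc_magnitude,
        dispersion = config$dispersion, target_map = target_map,
        delta = -sign(config$planted_mirna_lfc) * config$delta,
        seed = child_seed(config$seed, 20L + ci))
      gene_counts <- simulate_count_matrix(truth)
      write_count_matrix_tsv(gene_counts$counts,
                             keep(out(sprintf("%s_gene_counts.tsv", line))),
                             id_name = "gene_id")
      list(line = line, fastq = fq_paths, gene_counts = gene_counts,
           read_truth = reads$truth)
    })
    clinical <- simulate_clinical(config$n_clinical, config$auc_target,
                                  config$hr_target,
                                  seed = child_seed(config$seed, 30L))
    readr::write_tsv(clinical, keep(out("clinical.tsv")))
    list(genome = genome, loci = loci, planted = planted,
         target_map = target_map, per_line = per_line, clinical = clinical)
  })

  # ---- quant ----
  mirna_counts <- run_stage("quant", env, function() {
    lapply(sim$per_line, function(pl) {
      mat <- vapply(sample_ids, function(s) {
        q <- quant_smallrna(read_fastq(file.path(
          config$out_dir, sprintf("%s_%s.fastq", pl$line, s))),
          sim$genome, sim$loci, config$adapter,
          window = config$window, min_len = config$min_len,
          max_len = config$max_len)
        stats::setNames(q$abundance, q$mirna_id)[sim$loci$mirna_id]
      }, numeric(nrow(sim$loci)))
      rownames(mat) <- sim$loci$mirna_id
      write_count_matrix_tsv(mat,
                             keep(out(sprintf("%s_mirna_counts.tsv",
                                              pl$line))),
                             id_name = "mirna_id")
      mat
    })
  })

  # ---- differential expression ----
  de <- run_stage("de", env, function() {
    lapply(seq_along(sim$per_line), function(ci) {
      line <- sim$per_line[[ci]]$line
      mir_de <- de_analysis(mirna_counts[[ci]], groups,
                            fdr_threshold = config$fdr_threshold)
      gene_de <- de_analysis(sim$per_line[[ci]]$gene_counts$counts, groups,
                             fdr_threshold = config$fdr_threshold)
      readr::write_tsv(mir_de$table,
                       keep(out(sprintf("%s_mirna_de.tsv", line))))
      readr::write_tsv(gene_de$table,
                       keep(out(sprintf("%s_gene_de.tsv", line))))
      list(mirna = mir_de, gene = gene_de)
    })
  })

  # ---- target CDF-shift ----
  shift <- run_stage("shift", env, function() {
    lapply(seq_along(de), function(ci) {
      line <- sim$per_line[[ci]]$line
      mir_tab <- de[[ci]]$mirna$table
      de_mirnas <- mir_tab[mir_tab$call != "ns", c("feature_id", "logFC")]
      lfc_table <- de[[ci]]$gene$table[, c("feature_id", "logFC")]
      res <- shift_analysis(lfc_table, sim$target_map, de_mirnas)
      readr::write_tsv(tibble::as_tibble(res),
                       keep(out(sprintf("%s_shift.tsv", line))))
      res
    })
  })

  # ---- cross-cell-line concordance ----
  concordance <- run_stage("concordance", env, function() {
    if (length(de) < 2) return(NULL)
    tabs <- lapply(de, function(d) d$mirna$table)
    de_sets <- lapply(tabs, function(t) t$feature_id[t$call != "ns"])
    detected <- lapply(tabs, function(t) t$feature_id)
    universe <- length(Reduce(intersect, detected))
    ov <- concordant_de_overlap(de_sets[[1]], de_sets[[2]], universe)
    shared <- intersect(de_sets[[1]], de_sets[[2]])
    conc <- if (length(shared) >= 3) {
      pearson_lfc_concordance(tibble::tibble(
        lfc_a = tabs[[1]]$logFC[match(shared, tabs[[1]]$feature_id)],
        lfc_b = tabs[[2]]$logFC[match(shared, tabs[[2]]$feature_id)]))
    } else {
      tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(shared))
    }
    res <- dplyr::bind_cols(ov, dplyr::rename(conc, pearson_r = "r",
                                              pearson_p = "p_value",
                                              n_shared = "n"))
    readr::write_tsv(res, keep(out("concordance.tsv")))
    res
  })

  # ---- clinical statistics ----
  clin <- run_stage("clinical", env, function() {
    roc <- roc_auc(sim$clinical)
    km <- km_logrank_median_split(sim$clinical)
    res <- tibble::tibble(auc = roc$auc, auc_ci_lo = roc$ci[1],
                          auc_ci_hi = roc$ci[2], logrank_chisq = km$chisq,
                          logrank_p = km$p_value, hazard_ratio = km$hr)
    readr::write_tsv(res, keep(out("clinical_stats.tsv")))
    res
  })

  # ---- report ----
  report <- run_stage("report", env, function() {
    hits <- lapply(shift, function(s) {
      s$mirna_id[!is.na(s$direction_consistent) & s$direction_consistent &
                   s$p_value < 0.05]
    })
    rep <- list(
      planted_mirnas = sim$planted,
      de_mirnas_per_line = lapply(de, function(d) d$mirna$summary),
      shift_hits_per_line = hits,
      planted_recovered_in_all_lines =
        all(vapply(hits, function(h) all(sim$planted %in% h), logical(1))))
    jsonlite::write_json(rep, keep(out("report.json")), auto_unbox = TRUE,
                         pretty = TRUE)
    rep
  })

  manifest <- list(
    tool = "mirwin",
    version = as.character(utils::packageVersion("mirwin")),
    config_hash = unname(tools::md5sum(local({
      tf <- tempfile()
      writeLines(config_json(config), tf)
      tf
    }))),
    seed = config$seed,
    stages = env$stages,
    checksums = as.list(tools::md5sum(sort(unique(paths)))))
  names(manifest$checksums) <- basename(sort(unique(paths)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(manifest, list(report = report, shift = shift, de = de,
                             concordance = concordance, clinical = clin)))
}

#' Demo configuration for the bundled synthetic run
#'
#' Small enough to finish in well under five minutes on one CPU while still
#' recovering its two planted miRNAs as direction-consistent shift hits.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(out_dir = tempfile("mirwin_demo_"), seed = 1L) {
  pipeline_config(out_dir = out_dir, seed = seed,
                  chrom_len = 40000L, n_mirna = 12L, n_genes = 3000L,
                  mirna_mean_range = c(80, 250), n_clinical = 300L)
}
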