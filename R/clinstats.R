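# --- ROC / AUC -------------------------------------------------------------

#' ROC curve and AUC with DeLong confidence interval
#'
#' Builds the ROC curve over all score thresholds and computes the area
#' under it — equivalently the Mann-Whitney probability that a random case
#' outscores a random control, with half credit for ties — together with a
#' DeLong placement-variance 95% confidence interval clipped to `[0, 1]`.
#' Cases are taken to score higher; an AUC below 0.5 therefore indicates an
#' inversely oriented marker and is reported as is.
#'
#' @param samples Tibble with `expression` (numeric score) and `label`
#'   columns; `label` must have exactly two levels, with `"case"` (or the
#'   alphabetically last level) as the positive class.
#' @param positive Label value of the positive class (default `"case"` when
#'   present).
#' @return An object of class `mirwin_roc`: list with `points` (tibble
#'   `fpr`, `tpr`, `threshold`), `auc`, `ci` (length-2), `n_case`,
#'   `n_control`.
#' @export
roc_auc <- function(samples, positive = NULL) {
  stopifnot(all(c("expression", "label") %in% names(samples)))
  lab <- as.character(samples$label)
  lev <- sort(unique(lab))
  if (length(lev) != 2L) abort("both classes must be present")
  if (is.null(positive)) positive <- if ("case" %in% lev) "case" else lev[2]
  negative <- setdiff(lev, positive)
  r <- pROC::roc(response = lab, predictor = samples$expression,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1, 3)]
  ci <- pmin(pmax(ci, 0), 1)
  points <- tibble::tibble(threshold = r$thresholds,
                           fpr = 1 - r$specificities,
                           tpr = r$sensitivities) %>%
    dplyr::arrange(.data$fpr, .data$tpr)
  structure(list(points = points, auc = as.numeric(pROC::auc(r)), ci = ci,
                 n_case = sum(lab == positive),
                 n_control = sum(lab == negative)),
            class = "mirwin_roc")
}

#' @export
print.mirwin_roc <- function(x, ...) {
  cat(sprintf("<mirwin_roc> AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci[1], x$ci[2], x$n_case, x$n_control))
  invisible(x)
}

# --- Kaplan-Meier / log-rank -----------------------------------------------

#' Median-split Kaplan-Meier analysis with log-rank test and hazard ratio
#'
#' Dichotomizes the cohort at the median of the expression value (ties at
#' the median go to the low group), estimates product-limit survival per
#' group, tests the difference with the log-rank statistic (chi-squared, 1
#' df) and reports the hazard ratio of the high- versus low-expression group
#' as `(O_high / E_high) / (O_low / E_low)` from the log-rank
#' observed-versus-expected decomposition.
#'
#' @param records Tibble with `expression`, `time` (>= 0) and `event`
#'   (1 = event, 0 = censored) columns.
#' @return Object of class `mirwin_km`: list with `fit` (a
#'   [survival::survfit] object), `groups` tibble, `chisq`, `p_value`, `hr`
#'   (NA when a group has no events), `obs`, `exp`.
#' @export
km_logrank_median_split <- function(records) {
  stopifnot(all(c("expression", "time", "event") %in% names(records)))
  if (any(records$time < 0)) abort("times must be nonnegative")
  if (!all(records$event %in% c(0, 1))) abort("event must be 0/1")
  med <- stats::median(records$expression)
  grp <- factor(ifelse(records$expression <= med, "low", "high"),
                levels = c("low", "high"))
  if (min(table(grp)) < 2) abort("need at least 2 records per group")
  dat <- data.frame(time = records$time, event = records$event, group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  if (sum(dat$event) == 0) {
    warn("all records censored; log-rank undefined")
    res <- list(fit = fit, groups = tibble::tibble(
      sample_id = records$sample_id %||% seq_len(nrow(records)),
      group = as.character(grp)),
      chisq = 0, p_value = 1, hr = NA_real_,
      obs = c(low = 0, high = 0), exp = c(low = NA, high = NA))
    return(structure(res, class = "mirwin_km"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  obs <- sd_$obs; expd <- sd_$exp
  names(obs) <- names(expd) <- levels(grp)
  hr <- if (all(expd > 0) && obs[["low"]] > 0) {
    (obs[["high"]] / expd[["high"]]) / (obs[["low"]] / expd[["low"]])
  } else {
    NA_real_
  }
  structure(list(
    fit = fit,
    groups = tibble::tibble(
      sample_id = records$sample_id %||% seq_len(nrow(records)),
      group = as.character(grp)),
    chisq = sd_$chisq,
    p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
    hr = unname(hr), obs = obs, exp = expd),
    class = "mirwin_km")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mirwin_km <- function(x, ...) {
  cat(sprintf("<mirwin_km> log-rank chisq = %.3f (p = %.3g), HR(high vs low) = %.3f\n",
              x$chisq, x$p_value, x$hr))
  invisible(x)
}

# --- qPCR ------------------------------------------------------------------

#' Relative expression by the 2^-ddCt method
#'
#' Computes `dCt = Ct_target - Ct_control` within each condition from
#' replicate means, `ddCt = dCt_treated - dCt_reference`, and the fold
#' change `2^-ddCt`. Replicate standard errors of the four Ct means are
#' propagated into a standard error for ddCt and a fold-change interval.
#'
#' @param measurements Tibble with columns `condition` (`"treated"` /
#'   `"reference"`), `role` (`"target"` / `"control"`), and `ct` (positive
#'   Ct values, replicated rows allowed).
#' @return One-row tibble: `ddct`, `fold_change`, `se_ddct`, `fold_lo`,
#'   `fold_hi` (fold interval at ddCt +/- 1 SE).
#' @export
ddct <- function(measurements) {
  stopifnot(all(c("condition", "role", "ct") %in% names(measurements)))
  if (any(measurements$ct <= 0)) abort("Ct values must be positive")
  need <- expand.grid(condition = c("treated", "reference"),
                      role = c("target", "control"),
                      stringsAsFactors = FALSE)
  cell <- function(cond, role) {
    v <- measurements$ct[measurements$condition == cond &
                           measurements$role == role]
    if (length(v) == 0) {
      abort(sprintf("missing Ct measurements for %s/%s", cond, role))
    }
    c(mean = mean(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  }
  cells <- Map(cell, need$condition, need$role)
  m <- vapply(cells, `[[`, numeric(1), "mean")
  se <- vapply(cells, `[[`, numeric(1), "se")
  # order: treated/target, reference/target, treated/control, reference/control
  dct_treated <- m[1] - m[3]
  dct_reference <- m[2] - m[4]
  dd <- unname(dct_treated - dct_reference)
  se_dd <- sqrt(sum(se^2))
  tibble::tibble(ddct = unname(dd), fold_change = 2^-dd,
                 se_ddct = se_dd,
                 fold_lo = 2^-(dd + se_dd), fold_hi = 2^-(dd - se_dd))
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Adjusts the input Ct for the fraction of chromatin it represents
#' (`Ct_input - log2(1 / input_fraction)`) and expresses immunoprecipitated
#' material relative to it: `100 * 2^(adjusted input Ct - IP Ct)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample(s).
#' @param ct_input Ct of the input sample(s).
#' @param input_fraction Fraction of chromatin used as input, in `(0, 1]`.
#' @return Percent-of-input values (vectorized).
#' @export
chip_percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    abort("input_fraction must lie in (0, 1]")
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Xenograft tumor volume
#'
#' Standard caliper formula `V = length * width^2 / 2` in cubic millimetres.
#'
#' @param length,width Tumor dimensions in mm (nonnegative; a width larger
#'   than the length triggers a warning, as the caliper convention expects
#'   width <= length).
#' @return Volumes in mm^3 (vectorized).
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) abort("dimensions must be nonnegative")
  if (any(width > length)) warn("width exceeds length; check caliper order")
  length * width^2 / 2
}
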