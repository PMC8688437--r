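#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression fit
#' @param x A `mirwin_de` object.
#' @param ... Unused.
#' @return The per-feature results tibble (`feature_id`, `logFC`, `PValue`,
#'   `FDR`, `call`).
#' @export
tidy.mirwin_de <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' One-row summary of a differential-expression fit
#' @param x A `mirwin_de` object.
#' @param ... Unused.
#' @return Tibble: `n_features`, `dispersion`, `fdr_threshold`, `n_de`,
#'   `n_up`, `n_down`.
#' @export
glance.mirwin_de <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$table), dispersion = x$dispersion,
                 fdr_threshold = x$fdr_threshold,
                 n_de = x$summary$total, n_up = x$summary$up,
                 n_down = x$summary$down)
}

#' Tidy a ROC analysis into its curve points
#' @param x A `mirwin_roc` object.
#' @param ... Unused.
#' @return Tibble of ROC points: `threshold`, `fpr`, `tpr`.
#' @export
tidy.mirwin_roc <- function(x, ...) x$points

#' One-row summary of a ROC analysis
#' @param x A `mirwin_roc` object.
#' @param ... Unused.
#' @return Tibble: `auc`, `ci_lo`, `ci_hi`, `n_case`, `n_control`.
#' @export
glance.mirwin_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lo = x$ci[1], ci_hi = x$ci[2],
                 n_case = x$n_case, n_control = x$n_control)
}

#' Tidy a Kaplan-Meier analysis into survival-curve steps
#' @param x A `mirwin_km` object.
#' @param ... Unused.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
tidy.mirwin_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- sub("^group=", "", as.character(s$strata))
  tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, survival = s$surv)
}

#' One-row summary of a Kaplan-Meier analysis
#' @param x A `mirwin_km` object.
#' @param ... Unused.
#' @return Tibble: `chisq`, `p_value`, `hr`, `n_low`, `n_high`.
#' @export
glance.mirwin_km <- function(x, ...) {
  tab <- table(x$groups$group)
  tibble::tibble(chisq = x$chisq, p_value = x$p_value, hr = x$hr,
                 n_low = as.integer(tab[["low"]]),
                 n_high = as.integer(tab[["high"]]))
}
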