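#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit] returning the step function as a
#' plain table. Censored subjects at a tied time remain at risk for events
#' at that time (the standard convention).
#'
#' @param times Positive event/censoring times.
#' @param events 1 = event observed, 0 = censored.
#' @return Object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `surv` (rows at event times only), plus attribute
#'   `n`.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))  # S = 2/3, 1/3, 0
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  if (any(times <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  attr(out, "n") <- length(times)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve, n = ", attr(x, "n"), ", ",
      sum(x$n_event), " events\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

# survdiff-based O/E/V for two groups; group is coerced so that the second
# entry of the returned quantities refers to the "high" (TRUE / second
# level) group.
logrank_tables <- function(times, events, group) {
  g <- if (is.factor(group)) group else factor(as.logical(group),
                                               levels = c(FALSE, TRUE),
                                               labels = c("low", "high"))
  if (nlevels(droplevels(g)) != 2) stop("exactly two non-empty groups are required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(obs = sd$obs, exp = sd$exp, var = sd$var[2, 2], chisq = sd$chisq,
       levels = levels(droplevels(g)))
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' @param times Positive times.
#' @param events 1 = event, 0 = censored.
#' @param group Binary group indicator (logical/0-1/two-level factor).
#' @return List with `chi2`, `p` (1 df chi-square), and observed/expected
#'   event counts per group.
#' @export
logrank_test <- function(times, events, group) {
  lt <- logrank_tables(times, events, group)
  list(chi2 = lt$chisq, p = stats::pchisq(lt$chisq, df = 1, lower.tail = FALSE),
       obs = lt$obs, exp = lt$exp)
}

#' Peto (log-rank) hazard ratio with 95% confidence interval
#'
#' Hazard ratio of the high-expression group versus the low group from the
#' log-rank observed/expected quantities: `HR = exp((O - E) / V)` with CI
#' `exp((O - E)/V +- 1.96/sqrt(V))`, where O, E, V refer to the high group.
#' This log-rank-based estimator is self-contained and deterministic; it
#' can differ slightly from a Cox partial-likelihood fit.
#'
#' @inheritParams logrank_test
#' @return Object of class `hazard_ratio`: list with `hr`, `ci_lower`,
#'   `ci_upper`, `chi2`, `p`.
#' @export
hazard_ratio <- function(times, events, group) {
  lt <- logrank_tables(times, events, group)
  if (any(lt$obs < 1)) stop("both groups need at least one observed event")
  if (lt$var <= 0) stop("zero log-rank variance: no informative event times")
  lhr <- (lt$obs[2] - lt$exp[2]) / lt$var
  hw <- 1.96 / sqrt(lt$var)
  structure(list(hr = exp(lhr), ci_lower = exp(lhr - hw), ci_upper = exp(lhr + hw),
                 chi2 = lt$chisq,
                 p = stats::pchisq(lt$chisq, df = 1, lower.tail = FALSE)),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("HR (high vs low) = %.3f (95%% CI %.3f-%.3f), log-rank p = %.3g\n",
              x$hr, x$ci_lower, x$ci_upper, x$p))
  invisible(x)
}

#' Best expression cutoff scan between the quartiles
#'
#' The KM-plotter-style procedure for one gene: every midpoint between
#' consecutive distinct expression values falling within the lower and
#' upper quartiles (median-unbiased quantiles, type 8) is tried as a
#' low/high split, the log-rank test is computed for each admissible split
#' (both groups at least `min_group`), and the cutoff minimizing the
#' log-rank p-value is selected (ties break toward the lower cutoff).
#' Because the minimum is taken over many tests, the selected p-value is
#' anti-conservative; `n_candidates` is reported so users can account for
#' the scan size.
#'
#' @param expression Per-sample expression values for one gene.
#' @param times,events Survival outcome, parallel to `expression`.
#' @param min_group Minimum size of each side of the split (default 5).
#' @param gene Gene name recorded in the result.
#' @param endpoint Endpoint label ("PFS" or "OS").
#' @return Object of class `cutoff_result`: list with `gene`, `cutoff`,
#'   `n_low`, `n_high`, `chi2`, `p`, `hr`, `ci_lower`, `ci_upper`,
#'   `endpoint`, `n_candidates`.
#' @export
best_cutoff_scan <- function(expression, times, events, min_group = 5,
                             gene = "gene", endpoint = "PFS") {
  stopifnot(length(expression) == length(times), length(times) == length(events))
  if (length(unique(expression)) < 2) stop("expression is constant; no cutoff exists")
  if (length(expression) < 2 * min_group) {
    stop("need at least 2 * min_group = ", 2 * min_group, " samples")
  }
  q <- stats::quantile(expression, c(0.25, 0.75), type = 8, names = FALSE)
  v <- sort(unique(expression))
  mids <- (v[-1] + v[-length(v)]) / 2
  mids <- mids[mids >= q[1] & mids <= q[2]]
  mids <- mids[vapply(mids, function(cu) {
    n_hi <- sum(expression > cu)
    n_hi >= min_group && (length(expression) - n_hi) >= min_group
  }, logical(1))]
  if (length(mids) == 0) stop("no admissible cutoff between the quartiles")
  ps <- vapply(mids, function(cu) {
    logrank_test(times, events, expression > cu)$p
  }, numeric(1))
  best <- which(ps == min(ps))[1]  # tie -> lower cutoff (mids are ascending)
  cu <- mids[best]
  hi <- expression > cu
  hr <- tryCatch(hazard_ratio(times, events, hi),
                 error = function(e) list(hr = NA_real_, ci_lower = NA_real_,
                                          ci_upper = NA_real_,
                                          chi2 = logrank_test(times, events, hi)$chi2))
  structure(list(gene = gene, cutoff = cu,
                 n_low = sum(!hi), n_high = sum(hi),
                 chi2 = hr$chi2, p = ps[best],
                 hr = hr$hr, ci_lower = hr$ci_lower, ci_upper = hr$ci_upper,
                 endpoint = endpoint, n_candidates = length(mids)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("%s [%s]: cutoff %.4g (n_low %d / n_high %d, scanned %d)\n",
              x$gene, x$endpoint, x$cutoff, x$n_low, x$n_high, x$n_candidates))
  cat(sprintf("  log-rank p = %.3g, HR = %.3f (%.3f-%.3f)\n",
              x$p, x$hr, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Flatten cutoff results to a data.frame
#'
#' @param results A `cutoff_result` or list of them.
#' @return data.frame with one row per gene.
#' @export
cutoff_results_table <- function(results) {
  if (inherits(results, "cutoff_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(gene = x$gene, endpoint = x$endpoint, cutoff = x$cutoff,
               n_low = x$n_low, n_high = x$n_high, n_candidates = x$n_candidates,
               chi2 = x$chi2, p = x$p, hr = x$hr,
               ci_lower = x$ci_lower, ci_upper = x$ci_upper,
               stringsAsFactors = FALSE)
  }))
}
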