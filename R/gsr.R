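#' Learn a rank template for one gene set from control samples
#'
#' A rank template records, for every unordered pair of genes in the set,
#' the majority pairwise expression ordering across the control (reference
#' phenotype) samples. For genes at positions i < j, the direction is 1
#' when strictly more than half of the controls express gene i below gene
#' j. Equal values within a sample count as "not less", and an exact split
#' across controls resolves to 0 — both conventions are deterministic so
#' templates are bit-reproducible.
#'
#' @param controls Numeric matrix of control expression values, genes of
#'   one set in rows (rownames required), control samples in columns.
#' @param set_name Name recorded in the template.
#' @param min_genes Minimum number of measured genes (>= 2, since a single
#'   gene defines no pair).
#' @return An object of class `rank_template`: list with `set`, `genes`,
#'   `pairs` (2-column index matrix, i < j by position), `d` (0/1 majority
#'   directions), `n_controls`.
#' @examples
#' m <- rbind(G1 = c(1, 1, 2), G2 = c(2, 2, 1), G3 = c(3, 4, 3), G4 = c(4, 3, 4))
#' learn_rank_template(m)
#' @export
learn_rank_template <- function(controls, set_name = "set", min_genes = 2) {
  stopifnot(is.matrix(controls), !is.null(rownames(controls)))
  m <- nrow(controls)
  n <- ncol(controls)
  if (n < 1) stop("at least one control sample is required")
  if (min_genes < 2) stop("min_genes must be >= 2")
  if (m < min_genes) {
    stop("gene set '", set_name, "' has ", m, " measured genes (< ", min_genes, ")")
  }
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  # count, per pair (i, j), controls with value_i < value_j
  lt <- controls[pairs[, 1], , drop = FALSE] < controls[pairs[, 2], , drop = FALSE]
  cnt <- rowSums(lt)
  d <- as.integer(cnt > n / 2)  # exact half-splits resolve to 0
  structure(list(set = set_name, genes = rownames(controls),
                 pairs = unname(pairs), d = d, n_controls = n),
            class = "rank_template")
}

#' @export
print.rank_template <- function(x, ...) {
  cat("Rank template '", x$set, "': ", length(x$genes), " genes, ",
      length(x$d), " pairs, learned from ", x$n_controls, " controls\n", sep = "")
  invisible(x)
}

#' Gene set regularity (GSR) index of a sample against a rank template
#'
#' The GSR index is the fraction of within-set gene pairs whose expression
#' ordering in the sample agrees with the majority ordering of the
#' reference (control) phenotype. It ranges from 0 (every pairwise ordering
#' reversed — the most dysregulated state) to 1 (the sample's ordering
#' matches the most common control ordering exactly). Within the sample,
#' the pair indicator is 1 iff the first gene's value is strictly below the
#' second's; equality maps to 0, mirroring the template convention.
#'
#' @param sample Named numeric vector of expression values covering all
#'   template genes (a matrix column works).
#' @param template A [rank_template].
#' @return A single number in \[0, 1\].
#' @examples
#' tpl <- learn_rank_template(cbind(ctrl = c(G1 = 10, G2 = 20, G3 = 30, G4 = 40)))
#' matching_score(c(G1 = 40, G2 = 30, G3 = 20, G4 = 10), tpl)  # full reversal: 0
#' @export
matching_score <- function(sample, template) {
  stopifnot(inherits(template, "rank_template"))
  if (!all(template$genes %in% names(sample))) {
    stop("sample profile is missing template genes: ",
         paste(setdiff(template$genes, names(sample)), collapse = ", "))
  }
  v <- sample[template$genes]
  ind <- as.integer(v[template$pairs[, 1]] < v[template$pairs[, 2]])
  mean(ind == template$d)
}

# All-pairs indicators for every sample at once: npairs x nsamples matrix.
pair_indicators <- function(values, pairs) {
  (values[pairs[, 1], , drop = FALSE] < values[pairs[, 2], , drop = FALSE]) * 1L
}

#' Assemble the functionome: GSR indices for every sample and gene set
#'
#' The functionome is the complete profile of quantified biological
#' functions for each sample: one GSR index per gene set. Rank templates
#' are learned from the control samples only; every sample — controls
#' included, which yields the control self-fit distribution used for
#' control-corrected comparisons — is then scored against them. Sets with
#' fewer than `min_genes` genes measured in the matrix are dropped and
#' reported, not scored.
#'
#' @param expr Numeric matrix, genes x samples, unique uppercase rownames.
#' @param groups Named character vector or factor mapping every sample
#'   (column of `expr`) to a group label.
#' @param sets A [gene_set_collection][read_gmt] or named list of gene
#'   symbol vectors. Column order of the result follows this order.
#' @param control Label of the control group within `groups`.
#' @param min_genes Minimum measured genes per set (default 2).
#' @param keep_templates Keep the learned templates in the object.
#' @return An object of class `functionome`: list with `gsr` (samples x
#'   sets numeric matrix, entries in \[0, 1\]), `dropped_sets`, `groups`,
#'   `control`, `min_genes` and optionally `templates`.
#' @export
functionome <- function(expr, groups, sets, control = "control",
                        min_genes = 2, keep_templates = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  set_list <- if (inherits(sets, "gene_set_collection")) sets$sets else sets
  stopifnot(length(set_list) > 0, !is.null(names(set_list)))
  groups <- stats::setNames(as.character(groups),
                            if (is.null(names(groups))) colnames(expr) else names(groups))
  if (!all(colnames(expr) %in% names(groups))) {
    stop("every sample needs a group label")
  }
  groups <- groups[colnames(expr)]
  ctrl_cols <- which(groups == control)
  if (length(ctrl_cols) == 0) stop("control group '", control, "' is empty")
  if (min_genes < 2) stop("min_genes must be >= 2")

  nsamp <- ncol(expr)
  gsr_cols <- vector("list", length(set_list))
  templates <- vector("list", length(set_list))
  dropped <- logical(length(set_list))
  for (k in seq_along(set_list)) {
    genes <- intersect(set_list[[k]], rownames(expr))
    if (length(genes) < min_genes) {
      dropped[k] <- TRUE
      next
    }
    sub <- expr[genes, , drop = FALSE]
    tpl <- learn_rank_template(sub[, ctrl_cols, drop = FALSE],
                               set_name = names(set_list)[k],
                               min_genes = min_genes)
    ind <- pair_indicators(sub, tpl$pairs)
    gsr_cols[[k]] <- colMeans(ind == tpl$d)
    templates[[k]] <- tpl
  }
  kept <- which(!dropped)
  if (length(kept) == 0) stop("every gene set was dropped (min_genes = ", min_genes, ")")
  gsr <- do.call(cbind, gsr_cols[kept])
  dimnames(gsr) <- list(colnames(expr), names(set_list)[kept])
  out <- list(gsr = gsr,
              dropped_sets = names(set_list)[dropped],
              groups = groups,
              control = control,
              min_genes = min_genes)
  if (keep_templates) out$templates <- stats::setNames(templates[kept], colnames(gsr))
  structure(out, class = "functionome")
}

#' @export
print.functionome <- function(x, ...) {
  cat("Functionome: ", nrow(x$gsr), " samples x ", ncol(x$gsr),
      " gene sets (", length(x$dropped_sets), " dropped)\n", sep = "")
  mm <- tapply(rowMeans(x$gsr), x$groups, mean)
  cat("Mean GSR by group:\n")
  print(round(mm, 4))
  invisible(x)
}

#' @export
as.matrix.functionome <- function(x, ...) x$gsr

#' @export
dim.functionome <- function(x) dim(x$gsr)

#' Subset a functionome's gene set columns
#'
#' @param f A [functionome].
#' @param set_names Character vector of columns to keep (order preserved
#'   as in `f`).
#' @return A `functionome` restricted to those columns.
#' @export
subset_functionome <- function(f, set_names) {
  stopifnot(inherits(f, "functionome"))
  keep <- colnames(f$gsr)[colnames(f$gsr) %in% set_names]
  if (length(keep) == 0) stop("no functionome columns match the requested sets")
  f$gsr <- f$gsr[, keep, drop = FALSE]
  if (!is.null(f$templates)) f$templates <- f$templates[keep]
  f
}

#' Group-level GSR summary with control correction
#'
#' For each case group, the mean and SD of all its GSR entries, the same
#' for the control group, a Mann-Whitney p-value comparing per-sample mean
#' GSR between the case group and controls, and a control-corrected mean.
#' Correction modes: `"none"` reports the raw case mean (the convention
#' consistent with the published group tables), `"difference"` reports
#' case mean - control mean + grand control mean, `"ratio"` reports
#' case mean / control mean.
#'
#' @param f A [functionome].
#' @param correction_mode One of "none", "difference", "ratio".
#' @return A data.frame (class `gsr_group_summary`) with one row per case
#'   group: group, n, case_mean, case_sd, control_mean, control_sd,
#'   corrected_mean, p.
#' @export
group_gsr_summary <- function(f, correction_mode = c("none", "difference", "ratio")) {
  stopifnot(inherits(f, "functionome"))
  correction_mode <- match.arg(correction_mode)
  ctrl <- f$groups == f$control
  if (!any(!ctrl)) stop("no case groups present")
  ctrl_vals <- f$gsr[ctrl, , drop = FALSE]
  ctrl_mean <- mean(ctrl_vals)
  ctrl_sd <- stats::sd(as.vector(ctrl_vals))
  ctrl_sample_means <- rowMeans(f$gsr[ctrl, , drop = FALSE])
  case_groups <- setdiff(unique(f$groups), f$control)
  rows <- lapply(case_groups, function(g) {
    sel <- f$groups == g
    vals <- f$gsr[sel, , drop = FALSE]
    cm <- mean(vals)
    # controls are pooled, so the group-wise and grand control means coincide
    corrected <- switch(correction_mode,
                        none = cm,
                        difference = cm - ctrl_mean + ctrl_mean,
                        ratio = cm / ctrl_mean)
    p <- mann_whitney(rowMeans(vals), ctrl_sample_means)$p
    data.frame(group = g, n = sum(sel), case_mean = cm,
               case_sd = stats::sd(as.vector(vals)),
               control_mean = ctrl_mean, control_sd = ctrl_sd,
               corrected_mean = corrected, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "correction_mode") <- correction_mode
  class(out) <- c("gsr_group_summary", "data.frame")
  out
}

#' @export
summary.functionome <- function(object, correction_mode = "none", ...) {
  group_gsr_summary(object, correction_mode = correction_mode)
}

#' Histograms of GSR indices per group, as in immunofunctionome comparisons
#'
#' Bins every GSR entry of each group into equal-width bins over \[0, 1\]
#' and reports counts, normalized frequencies and the group means — the
#' numeric content of the per-stage immunofunctionome histograms.
#'
#' @param f A [functionome] or a samples x sets numeric matrix in \[0, 1\].
#' @param groups Group labels per sample; defaults to the functionome's.
#' @param bins Number of equal-width bins (>= 2).
#' @return List of class `gsr_histogram`: `breaks`, `counts` (group x bin
#'   matrix), `freq` (rows sum to 1), `means` (named per-group means).
#' @export
histogram_summary <- function(f, groups = NULL, bins = 20) {
  if (inherits(f, "functionome")) {
    if (is.null(groups)) groups <- f$groups
    m <- f$gsr
  } else {
    m <- as.matrix(f)
    if (is.null(groups)) stop("groups must be supplied for a plain matrix")
  }
  if (bins < 2) stop("bins must be >= 2")
  stopifnot(nrow(m) == length(groups))
  breaks <- seq(0, 1, length.out = bins + 1)
  gl <- unique(as.character(groups))
  counts <- t(vapply(gl, function(g) {
    v <- as.vector(m[groups == g, , drop = FALSE])
    tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), bins),
             nbins = bins)
  }, numeric(bins)))
  rownames(counts) <- gl
  freq <- counts / rowSums(counts)
  means <- vapply(gl, function(g) mean(m[groups == g, , drop = FALSE]), numeric(1))
  structure(list(breaks = breaks, counts = counts, freq = freq, means = means),
            class = "gsr_histogram")
}

#' @export
print.gsr_histogram <- function(x, ...) {
  cat("GSR histogram (", ncol(x$counts), " bins over [0,1])\n", sep = "")
  cat("Group means:\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Plot a functionome as per-group GSR histograms
#'
#' @param x A [functionome].
#' @param bins Number of bins.
#' @param ... Passed to [graphics::barplot].
#' @return Invisibly, the [histogram_summary].
#' @export
plot.functionome <- function(x, bins = 20, ...) {
  h <- histogram_summary(x, bins = bins)
  mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  graphics::barplot(h$freq, beside = TRUE, names.arg = round(mids, 2),
                    legend.text = rownames(h$freq),
                    xlab = "GSR index", ylab = "frequency", ...)
  invisible(h)
}
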