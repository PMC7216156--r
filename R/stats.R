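#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The U statistic counts
#' pairs with `x < y` plus half of the tied pairs. The p-value is exact
#' (full enumeration of arrangements) when `length(x) * length(y) <= 400`
#' and the pooled sample has no ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` and `p`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y))
  U <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  exact <- length(x) * length(y) <= 400 && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  list(U = U, p = min(p, 1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment:
#' `q_(i) = min_(j >= i)(p_(j) * m / j)` clipped at 1, mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Term-wise dysregulation tests of case groups against controls
#'
#' For every gene set column of the functionome and every case group, a
#' two-sided Mann-Whitney test of the group's GSR indices against the
#' control group's, with Benjamini-Hochberg adjustment applied within each
#' case group's family of terms. The significance flag uses BH q by
#' default (the conservative reading of "p < 0.05 after FDR correction");
#' `rule = "p"` flags on the raw p-value instead.
#'
#' @param f A [functionome].
#' @param alpha Significance level (default 0.05).
#' @param rule `"q"` (default) or `"p"`.
#' @return data.frame of class `term_tests`: set_name, group, case_mean,
#'   control_mean, U, p, q, significant, direction (sign of case mean -
#'   control mean).
#' @export
test_all_terms <- function(f, alpha = 0.05, rule = c("q", "p")) {
  stopifnot(inherits(f, "functionome"))
  rule <- match.arg(rule)
  ctrl <- f$groups == f$control
  if (!any(ctrl)) stop("control group is empty")
  case_groups <- setdiff(unique(f$groups), f$control)
  if (length(case_groups) == 0) stop("no case groups present")
  out <- lapply(case_groups, function(g) {
    sel <- f$groups == g
    if (sum(sel) < 1) stop("group '", g, "' has no samples")
    res <- lapply(colnames(f$gsr), function(s) {
      xc <- f$gsr[sel, s]
      x0 <- f$gsr[ctrl, s]
      mw <- mann_whitney(xc, x0)
      data.frame(set_name = s, group = g,
                 case_mean = mean(xc), control_mean = mean(x0),
                 U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q <- bh_adjust(res$p)
    res$significant <- if (rule == "q") res$q < alpha else res$p < alpha
    res$direction <- sign(res$case_mean - res$control_mean)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "rule") <- rule
  class(out) <- c("term_tests", "data.frame")
  out
}

#' Cluster weight index (CWI)
#'
#' Evidence share of each term cluster: the weight of a cluster is the sum
#' of negative logarithms of its member terms' p-values, and the CWI is
#' that weight divided by the total over all clusters, so CWIs lie in
#' \[0, 1\] and sum to 1. The result does not depend on the logarithm base;
#' the natural log is used. Zero p-values are clamped to `p_floor` before
#' taking logs.
#'
#' @param p Numeric vector of p-values, one per term.
#' @param clusters Vector of cluster ids, parallel to `p` (NA = unclustered,
#'   excluded).
#' @param p_floor Lower clamp for p (default 1e-300).
#' @return data.frame of class `cluster_weights`: cluster, n_terms, weight,
#'   cwi; the term-to-cluster assignment is kept in attribute `members`.
#' @examples
#' cluster_weight_index(c(0.01, 0.1, 0.5), c("A", "A", "B"))
#' @export
cluster_weight_index <- function(p, clusters, p_floor = 1e-300) {
  stopifnot(length(p) == length(clusters))
  keep <- !is.na(clusters)
  p <- p[keep]; clusters <- as.character(clusters[keep])
  if (length(clusters) == 0) stop("cluster map is empty")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  w <- tapply(-log(pmax(p, p_floor)), clusters, sum)
  out <- data.frame(cluster = names(w), n_terms = as.integer(table(clusters)[names(w)]),
                    weight = as.numeric(w), cwi = as.numeric(w) / sum(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cwi, out$cluster), ]
  rownames(out) <- NULL
  attr(out, "members") <- split(seq_along(clusters), clusters)
  class(out) <- c("cluster_weights", "data.frame")
  out
}

#' Assign terms to the cluster of their nearest ancestor among cluster heads
#'
#' Clusters for the CWI live in the GO tree: each term belongs to the
#' cluster of the nearest cluster-head term reachable by child-to-parent
#' edges (the configured heads are conventionally the direct children of
#' the immune progenitor terms). Ties in graph distance break by head
#' order as supplied; terms under no head get NA.
#'
#' @param graph An [ontology_graph].
#' @param term_ids Terms to assign.
#' @param heads Candidate cluster-head term ids (order breaks ties).
#' @return Named character vector term_id -> head id (NA when unreachable).
#' @export
assign_clusters <- function(graph, term_ids, heads) {
  stopifnot(inherits(graph, "ontology_graph"))
  missing <- setdiff(c(term_ids, heads), names(graph$terms))
  if (length(missing)) stop("unknown term(s): ", paste(missing, collapse = ", "))
  d <- igraph::distances(graph$igraph, v = term_ids, to = heads, mode = "out")
  assign <- apply(d, 1, function(row) {
    if (all(!is.finite(row))) return(NA_character_)
    heads[which.min(row)]  # which.min takes the first (head-order) minimum
  })
  stats::setNames(as.character(assign), term_ids)
}

#' Order terms by relevance: cluster CWI, then p-value, then name
#'
#' The ranking used to pick each group's most relevant dysregulated terms:
#' terms sort by their cluster's CWI (descending), then by their own
#' p-value (ascending), then alphabetically — a fully deterministic order.
#'
#' @param tests A [term_tests][test_all_terms] subset for one group (or any
#'   data.frame with `set_name` and `p`).
#' @param cluster_of Named vector mapping set_name -> cluster id (NA allowed;
#'   unclustered terms get CWI 0).
#' @param weights Optional precomputed [cluster_weight_index]; computed from
#'   `tests` otherwise.
#' @return Character vector of set names in rank order.
#' @export
rank_terms <- function(tests, cluster_of, weights = NULL) {
  stopifnot(all(c("set_name", "p") %in% names(tests)))
  cl <- cluster_of[tests$set_name]
  if (is.null(weights)) weights <- cluster_weight_index(tests$p, cl)
  cwi <- stats::setNames(weights$cwi, weights$cluster)[as.character(cl)]
  cwi[is.na(cwi)] <- 0
  tests$set_name[order(-cwi, tests$p, tests$set_name)]
}

#' Cross-compare the top-k terms of several group rankings
#'
#' Takes the top `k` entries of each group's relevance-ordered term list
#' and intersects them across groups — the procedure behind selecting the
#' dysfunctional pathways common to every disease-stage group. Rankings
#' shorter than `k` are used in full with a warning.
#'
#' @param rankings Named list of ordered character vectors (most relevant
#'   first), e.g. from [rank_terms].
#' @param k Number of top entries per group (default 30).
#' @return Character vector of common terms; attribute `topk` keeps each
#'   group's truncated list.
#' @export
rank_and_crosscompare <- function(rankings, k = 30) {
  stopifnot(is.list(rankings), length(rankings) >= 1)
  topk <- lapply(names(rankings), function(nm) {
    r <- rankings[[nm]]
    if (length(r) < k) {
      warning("ranking '", nm, "' has only ", length(r), " entries (< k = ", k, ")")
      r
    } else {
      r[seq_len(k)]
    }
  })
  names(topk) <- names(rankings)
  common <- Reduce(intersect, topk)
  attr(common, "topk") <- topk
  common
}

#' Venn region counts for 2-3 named sets
#'
#' Counts every logical membership pattern among the given sets; counts
#' sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 vectors.
#' @return Named integer vector, one entry per non-empty membership
#'   pattern label (names joined by `&`, e.g. `"early&advanced"`).
#' @export
venn_regions <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (length(sets) < 2 || length(sets) > 3) stop("venn_regions supports 2 or 3 sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  # fixed region order: singletons, pairs, triple
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(r) {
    apply(utils::combn(nm, r), 2, paste, collapse = "&")
  }))
  out <- stats::setNames(integer(length(combos)), combos)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Immune-filtered differentially expressed genes of a term
#'
#' Per-gene case-versus-control Mann-Whitney tests over the genes of one
#' gene set (term), BH-adjusted within the term, then filtered against an
#' immune-related gene list: the selected genes are those significant and
#' present in the list, with their expression direction in cases.
#'
#' @param expr Genes x samples expression matrix.
#' @param groups Named group labels per sample.
#' @param genes_of_term Gene symbols of the term.
#' @param immune_list Non-empty character vector of immune gene symbols.
#' @param alpha Significance level (default 0.05).
#' @param control Control group label.
#' @param rule `"q"` (default) or `"p"`.
#' @return data.frame of class `deg_results`: gene, case_mean, control_mean,
#'   U, p, q, direction ("up"/"down" in cases), immune, selected.
#' @export
gene_level_deg <- function(expr, groups, genes_of_term, immune_list,
                           alpha = 0.05, control = "control",
                           rule = c("q", "p")) {
  rule <- match.arg(rule)
  if (length(immune_list) == 0) stop("immune gene list is empty")
  immune_list <- toupper(immune_list)
  genes <- intersect(toupper(genes_of_term), rownames(expr))
  if (length(genes) == 0) stop("none of the term's genes are measured")
  groups <- stats::setNames(as.character(groups),
                            if (is.null(names(groups))) colnames(expr) else names(groups))
  groups <- groups[colnames(expr)]
  ctrl <- groups == control
  case <- !ctrl
  if (!any(ctrl) || !any(case)) stop("both case and control samples are required")
  rows <- lapply(genes, function(g) {
    xc <- expr[g, case]; x0 <- expr[g, ctrl]
    mw <- mann_whitney(xc, x0)
    data.frame(gene = g, case_mean = mean(xc), control_mean = mean(x0),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  sig <- if (rule == "q") out$q < alpha else out$p < alpha
  out$direction <- ifelse(out$case_mean >= out$control_mean, "up", "down")
  out$immune <- out$gene %in% immune_list
  out$selected <- sig & out$immune
  class(out) <- c("deg_results", "data.frame")
  out
}
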