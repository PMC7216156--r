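#' Construct an ontology graph
#'
#' Holds GO-style terms and directed child-to-parent edges (`is_a`,
#' `part_of`). A normalized-name index supports matching MSigDB C5 set
#' names (which encode term names, not ids) back to term ids.
#'
#' @param terms Named character vector: term id -> term name.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return Object of class `ontology_graph` with fields `terms`, `edges`,
#'   `name_index`.
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(!is.null(names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  unknown <- setdiff(c(edges$child, edges$parent), names(terms))
  if (length(unknown)) {
    stop("edges reference unknown terms: ", paste(unknown, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = names(terms))
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle")
  structure(list(terms = terms, edges = edges,
                 name_index = stats::setNames(names(terms),
                                              normalize_term_name(terms)),
                 igraph = g),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph: ", length(x$terms), " terms, ", nrow(x$edges),
      " edges (", sum(x$edges$relation == "is_a"), " is_a, ",
      sum(x$edges$relation == "part_of"), " part_of)\n", sep = "")
  invisible(x)
}

#' Normalize a term or gene set name for matching
#'
#' Lowercases, turns underscores into spaces, strips a leading "go "
#' prefix and squeezes whitespace, so "GO_INFLAMMATORY_RESPONSE" and
#' "inflammatory response" compare equal.
#'
#' @param x Character vector of names.
#' @return Normalized character vector.
#' @export
normalize_term_name <- function(x) {
  x <- tolower(gsub("_", " ", x, fixed = TRUE))
  x <- sub("^go ", "", x)
  trimws(gsub(" +", " ", x))
}

#' All descendants (offspring) of ontology root terms
#'
#' Returns every term from which a root is reachable by following
#' child-to-parent edges — the offspring of the root in GO browser terms.
#' With more than one root the union is taken.
#'
#' @param graph An [ontology_graph].
#' @param roots Character vector of term ids present in the graph.
#' @param reflexive Include the roots themselves (default FALSE: "offspring"
#'   conventionally excludes the progenitor).
#' @return Character vector of term ids.
#' @export
descendants <- function(graph, roots, reflexive = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"))
  missing <- setdiff(roots, names(graph$terms))
  if (length(missing)) stop("unknown root term(s): ", paste(missing, collapse = ", "))
  res <- unique(unlist(lapply(roots, function(r) {
    names(igraph::subcomponent(graph$igraph, r, mode = "in"))
  })))
  if (!reflexive) res <- setdiff(res, roots)
  res
}

#' Map gene set names to ontology term ids by normalized name
#'
#' MSigDB C5 set names carry GO term names; this derives the set-name to
#' term-id mapping via [normalize_term_name]. Unmapped names are reported,
#' never silently dropped.
#'
#' @param set_names Character vector of gene set names.
#' @param graph An [ontology_graph].
#' @return Object of class `term_mapping`: list with `mapping` (named
#'   character, set name -> term id) and `unmapped`.
#' @export
map_sets_to_terms <- function(set_names, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  norm <- normalize_term_name(set_names)
  ids <- graph$name_index[norm]
  ok <- !is.na(ids)
  mapping <- stats::setNames(unname(ids[ok]), set_names[ok])
  if (anyDuplicated(mapping)) {
    warning("term mapping is not injective: ",
            paste(unique(mapping[duplicated(mapping)]), collapse = ", "))
  }
  structure(list(mapping = mapping, unmapped = set_names[!ok]),
            class = "term_mapping")
}

#' @export
print.term_mapping <- function(x, ...) {
  cat("Term mapping: ", length(x$mapping), " sets mapped, ",
      length(x$unmapped), " unmapped\n", sep = "")
  invisible(x)
}

#' Extract the immunofunctionome from a functionome
#'
#' Restricts the functionome to the gene sets whose mapped GO terms are
#' offspring of the given ancestor (progenitor) terms — by default the
#' immune ancestors "immune system process" (GO:0002376) and "inflammatory
#' response" (GO:0006954) in real GO data. Column order is preserved.
#'
#' @param f A [functionome].
#' @param graph An [ontology_graph].
#' @param mapping A [term_mapping][map_sets_to_terms] for `colnames(f$gsr)`.
#' @param roots Ancestor term ids.
#' @param reflexive Passed to [descendants].
#' @return A `functionome` restricted to the mapped offspring columns, with
#'   attribute `n_extracted`.
#' @export
extract_immunofunctionome <- function(f, graph, mapping, roots, reflexive = FALSE) {
  stopifnot(inherits(f, "functionome"), inherits(mapping, "term_mapping"))
  desc <- descendants(graph, roots, reflexive = reflexive)
  mapped <- mapping$mapping[names(mapping$mapping) %in% colnames(f$gsr)]
  if (length(mapped) == 0) stop("no functionome columns are covered by the term mapping")
  keep <- names(mapped)[mapped %in% desc]
  if (length(keep) == 0) stop("no functionome columns map to offspring of the roots")
  out <- subset_functionome(f, keep)
  attr(out, "n_extracted") <- ncol(out$gsr)
  attr(out, "roots") <- roots
  out
}
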