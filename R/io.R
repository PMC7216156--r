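#' Read a GMT gene set file
#'
#' Parses the tab-separated MSigDB dialect: each line holds a set name, a
#' description, and one or more member gene symbols. Gene symbols are
#' uppercased so joins against expression matrices and gene lists are
#' case-insensitive; duplicate genes within a set are removed (first
#' occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a list with elements
#'   `sets` (named list of character vectors of gene symbols) and `source`
#'   (provenance string).
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines(c("SETA\tdesc\tG1\tG2", "SETB\tdesc\tG2\tG3\tG4"), tf)
#' gs <- read_gmt(tf)
#' lengths(gs$sets)
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed GMT line ", which(nf < 3)[1],
         ": expected at least 3 tab-separated fields, got ", nf[nf < 3][1])
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name in GMT: ", nm[duplicated(nm)][1])
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nm
  structure(list(sets = sets, source = basename(path)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("Gene set collection (", length(x$sets), " sets, sizes ",
      min(sz), "-", max(sz), ") from ", x$source, "\n", sep = "")
  invisible(x)
}

#' Write a gene set collection to GMT
#'
#' @param x A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @param description Description field written in column 2 (recycled).
#' @return Invisibly, the path.
#' @export
write_gmt <- function(x, path, description = "na") {
  sets <- if (inherits(x, "gene_set_collection")) x$sets else x
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- mapply(function(nm, genes) {
    paste(c(nm, description, genes), collapse = "\t")
  }, names(sets), sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an OBO ontology file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 flat file into an ontology
#' graph. Only `is_a` and `relationship: part_of` tags become edges (both
#' conventionally count as parent links when collecting term offspring);
#' obsolete terms are excluded, together with any edge touching them.
#'
#' @param path Path to an OBO file.
#' @return An [ontology_graph] object.
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0)
  child <- character(0); parent <- character(0); rel <- character(0)
  for (k in seq_along(starts)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE))
    if (length(id) != 1) stop("OBO [Term] stanza ", k, " without a single id tag")
    if (any(grepl("^is_obsolete: *true", block))) next
    nm <- sub("^name: *", "", grep("^name: ", block, value = TRUE))
    if (length(nm) == 0) nm <- id
    ids <- c(ids, id); nms <- c(nms, nm[1])
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE)))
    pof <- grep("^relationship: *part_of ", block, value = TRUE)
    pof <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", pof))
    if (length(isa)) {
      child <- c(child, rep(id, length(isa))); parent <- c(parent, isa)
      rel <- c(rel, rep("is_a", length(isa)))
    }
    if (length(pof)) {
      child <- c(child, rep(id, length(pof))); parent <- c(parent, pof)
      rel <- c(rel, rep("part_of", length(pof)))
    }
  }
  terms <- stats::setNames(nms, ids)
  keep <- child %in% ids & parent %in% ids
  edges <- data.frame(child = child[keep], parent = parent[keep],
                      relation = rel[keep], stringsAsFactors = FALSE)
  ontology_graph(terms, edges)
}

#' Write an ontology graph as OBO text
#'
#' @param graph An [ontology_graph].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in names(graph$terms)) {
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    lines <- c("[Term]", paste0("id: ", id), paste0("name: ", graph$terms[[id]]))
    if (nrow(e)) {
      lines <- c(lines,
                 ifelse(e$relation == "is_a",
                        paste0("is_a: ", e$parent),
                        paste0("relationship: part_of ", e$parent)))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Read a gene expression matrix from TSV
#'
#' Expects a tab-separated file with gene (or probe) symbols in the first
#' column and one column per sample. Profiles with missing values are
#' rejected outright rather than imputed: the study design discards any
#' expression profile containing missing data. Symbols are uppercased.
#'
#' @param path Path to the TSV file.
#' @param collapse Probe-to-gene collapse rule. `"none"` (default) requires
#'   unique symbols; `"max_mean"` keeps, for each repeated symbol, the row
#'   with the highest mean expression (a common probe-collapse heuristic).
#' @return A numeric matrix, genes in rows (unique uppercased rownames),
#'   samples in columns.
#' @export
read_expression <- function(path, collapse = c("none", "max_mean")) {
  collapse <- match.arg(collapse)
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("expression file needs a symbol column plus >=1 sample")
  sym <- toupper(as.character(df[[1]]))
  vals <- df[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[nonnum], collapse = ", "))
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    stop("expression matrix contains missing data; profiles with missing ",
         "values are discarded at the source, not imputed")
  }
  rownames(m) <- sym
  if (collapse == "max_mean" && anyDuplicated(sym)) {
    mm <- rowMeans(m)
    ord <- order(-mm)  # highest mean first, then keep first occurrence
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    m <- m[order(match(rownames(m), sym)), , drop = FALSE]
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene symbols after collapse = '", collapse,
         "'; use collapse = 'max_mean' for probe-level input")
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_expression <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical / survival table from CSV
#'
#' Expected columns: `sample_id`, `time` (positive, months), `event`
#' (1 = progression/death observed, 0 = censored), optionally `group`.
#'
#' @param path Path to the CSV file.
#' @param endpoint Endpoint label attached as an attribute, e.g. "PFS" or "OS".
#' @return A data.frame with the validated columns.
#' @export
read_survival_table <- function(path, endpoint = "PFS") {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    stop("survival times must be positive")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1")
  attr(df, "endpoint") <- endpoint
  df
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a plain text file, one gene symbol per line.
#' @return Character vector of unique, uppercased symbols.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  x <- toupper(trimws(readLines(path)))
  unique(x[nzchar(x)])
}

#' Write a results table as TSV
#'
#' Writes any results data.frame (term tests, cutoff scans, summaries) with
#' a fixed column order (as given) and numeric values rounded to 6
#' significant digits, tab-separated with a header line.
#'
#' @param table A non-empty data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  if (nrow(table) == 0) stop("refusing to write an empty results table")
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], signif, digits = 6)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results]
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
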