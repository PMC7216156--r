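#' Specification for a synthetic GSR study
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' describe the package's reference simulated study: 200 gene sets of 5-10
#' genes with disjoint membership, 20 of them fully order-reversed in
#' cases, 30 controls and two case groups of 30, additive Gaussian noise
#' with SD 0.5 in units of the inter-gene baseline spacing (1.0), a
#' two-progenitor ontology with 20% of sets under the immune root, and an
#' exponential survival model with true hazard ratio 2 and 30% censoring
#' linked to one planted gene.
#'
#' @param n_sets Number of gene sets.
#' @param set_size Integer range `c(min, max)` of set sizes.
#' @param n_dysregulated Number of sets with planted order disruption.
#' @param disruption Fraction of each planted set's within-set ordering to
#'   reverse (1.0 = full reversal), or the string `"derangement"` for a
#'   random fixed-point-free permutation of the baselines.
#' @param noise_sd SD of the per-sample Gaussian noise, in units of the
#'   inter-gene baseline spacing.
#' @param n_controls Number of control samples.
#' @param n_cases Named integer vector of case group sizes, e.g.
#'   `c(early = 30, advanced = 30)`.
#' @param n_genes Total number of genes; NULL (default) means exactly the
#'   genes needed by the sets.
#' @param immune_fraction Fraction of sets attached under the immune
#'   progenitor of the synthetic ontology.
#' @param n_cluster_heads Number of direct children of the immune root that
#'   serve as CWI cluster heads.
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param true_hr Hazard ratio of high vs low expression of the linked gene.
#' @param censor_rate Target fraction of censored subjects.
#' @param linked_gene Gene whose expression drives the hazard; NULL picks
#'   the first gene of the first planted set.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sets = 200, set_size = c(5, 10),
                           n_dysregulated = 20, disruption = 1.0,
                           noise_sd = 0.5, n_controls = 30,
                           n_cases = c(early = 30, advanced = 30),
                           n_genes = NULL, immune_fraction = 0.2,
                           n_cluster_heads = 4, baseline_hazard = 0.05,
                           true_hr = 2, censor_rate = 0.3,
                           linked_gene = NULL) {
  stopifnot(n_dysregulated <= n_sets, noise_sd >= 0,
            identical(disruption, "derangement") ||
              (is.numeric(disruption) && disruption >= 0 && disruption <= 1))
  if (is.null(names(n_cases))) names(n_cases) <- paste0("case", seq_along(n_cases))
  structure(list(n_sets = n_sets, set_size = set_size,
                 n_dysregulated = n_dysregulated, disruption = disruption,
                 noise_sd = noise_sd, n_controls = n_controls,
                 n_cases = n_cases, n_genes = n_genes,
                 immune_fraction = immune_fraction,
                 n_cluster_heads = n_cluster_heads,
                 baseline_hazard = baseline_hazard, true_hr = true_hr,
                 censor_rate = censor_rate, linked_gene = linked_gene),
            class = "synthetic_spec")
}

synth_set_names <- function(n_sets) sprintf("GO_SYNTH_SET_%04d", seq_len(n_sets))

# fixed-point-free permutation of 1..m (m >= 2)
derangement <- function(m) {
  repeat {
    p <- sample.int(m)
    if (!any(p == seq_len(m))) return(p)
  }
}

#' Generate a synthetic expression matrix with planted set dysregulation
#'
#' Each gene set receives disjoint genes with strictly increasing baseline
#' means (spacing 1.0). Control samples are baseline plus Gaussian noise.
#' Case samples draw from the same model except that in the planted
#' (dysregulated) sets the baseline order is reversed or deranged — a
#' phenotype-level ordering change, matching the GSR model's assumption,
#' rather than per-sample shuffling. Deterministic given `(spec, seed)`;
#' uses the derived sub-seed `seed + 1`.
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer master seed.
#' @return List with `expression` (genes x samples matrix), `groups`
#'   (named character vector), `sets` (a `gene_set_collection`), `truth`
#'   (list: `dysregulated_sets`, `shifted_genes`, `linked_gene`, `true_hr`).
#' @export
generate_expression <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed + 1L)
  sizes <- sample(seq(spec$set_size[1], spec$set_size[2]), spec$n_sets,
                  replace = TRUE)
  total <- sum(sizes)
  n_genes <- if (is.null(spec$n_genes)) total else spec$n_genes
  if (n_genes < total) {
    stop("n_genes (", n_genes, ") is smaller than the genes required by the sets (",
         total, ")")
  }
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  set_names <- synth_set_names(spec$n_sets)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  sets <- lapply(seq_len(spec$n_sets), function(k) gene_ids[starts[k]:ends[k]])
  names(sets) <- set_names

  dys <- sort(sample(spec$n_sets, spec$n_dysregulated))
  base_ctrl <- numeric(n_genes)
  base_case <- numeric(n_genes)
  for (k in seq_len(spec$n_sets)) {
    idx <- starts[k]:ends[k]
    b <- seq_along(idx)  # strictly increasing means, spacing 1.0
    base_ctrl[idx] <- b
    if (k %in% dys) {
      m <- length(b)
      if (identical(spec$disruption, "derangement")) {
        base_case[idx] <- b[derangement(m)]
      } else {
        kk <- round(spec$disruption * m)
        bb <- b
        if (kk >= 2) {
          pos <- sort(sample(m, kk))
          bb[pos] <- rev(bb[pos])
        }
        base_case[idx] <- bb
      }
    } else {
      base_case[idx] <- b
    }
  }
  if (n_genes > total) {  # filler genes outside any set
    extra <- (total + 1L):n_genes
    base_ctrl[extra] <- stats::runif(length(extra), 0, 10)
    base_case[extra] <- base_ctrl[extra]
  }

  groups <- c(rep("control", spec$n_controls),
              rep(names(spec$n_cases), spec$n_cases))
  sample_ids <- sprintf("S%03d", seq_along(groups))
  names(groups) <- sample_ids
  nsamp <- length(groups)
  base <- ifelse(rep(groups == "control", each = n_genes),
                 rep(base_ctrl, nsamp), rep(base_case, nsamp))
  expr <- matrix(base + stats::rnorm(n_genes * nsamp, sd = spec$noise_sd),
                 nrow = n_genes, dimnames = list(gene_ids, sample_ids))

  linked <- spec$linked_gene
  if (is.null(linked)) {
    linked <- if (length(dys)) sets[[dys[1]]][1] else gene_ids[1]
  }
  truth <- list(dysregulated_sets = set_names[dys],
                shifted_genes = gene_ids[base_case != base_ctrl],
                linked_gene = linked, true_hr = spec$true_hr)
  list(expression = expr, groups = groups,
       sets = structure(list(sets = sets, source = "synthetic"),
                        class = "gene_set_collection"),
       truth = truth)
}

#' Generate a synthetic two-progenitor ontology over the gene sets
#'
#' Builds a DAG with an "immune" progenitor and a non-immune progenitor.
#' A configured fraction of the sets (exactly `round(immune_fraction *
#' n_sets)`) receive terms attached under the immune root via a layer of
#' cluster-head terms (the root's direct children); the remaining set
#' terms attach to the non-immune root. Head-to-root edges alternate
#' `is_a` and `part_of` so both relation types are exercised.
#' Deterministic given `(spec, seed)`; uses the derived sub-seed
#' `seed + 2`, so it can be regenerated independently of the expression
#' matrix (set names depend only on `n_sets`).
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer master seed.
#' @return List with `graph` ([ontology_graph]), `mapping`
#'   ([term_mapping] set name -> term id), `roots` (named: immune,
#'   other), `cluster_heads`, `immune_sets` (set names under the immune
#'   root).
#' @export
generate_ontology <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed + 2L)
  set_names <- synth_set_names(spec$n_sets)
  n_imm <- round(spec$immune_fraction * spec$n_sets)
  imm_idx <- sort(sample(spec$n_sets, n_imm))
  root_imm <- "GO:9000001"; root_other <- "GO:9000002"
  heads <- sprintf("GO:90001%02d", seq_len(spec$n_cluster_heads))
  set_terms <- sprintf("GO:8%06d", seq_len(spec$n_sets))
  terms <- c(stats::setNames("synthetic immune system process", root_imm),
             stats::setNames("synthetic non immune process", root_other),
             stats::setNames(sprintf("synthetic immune cluster %d",
                                     seq_along(heads)), heads),
             stats::setNames(normalize_term_name(set_names), set_terms))
  head_of <- sample(heads, n_imm, replace = TRUE)
  child <- c(heads,
             set_terms[imm_idx],
             set_terms[setdiff(seq_len(spec$n_sets), imm_idx)])
  parent <- c(rep(root_imm, length(heads)),
              head_of,
              rep(root_other, spec$n_sets - n_imm))
  relation <- c(rep(c("is_a", "part_of"), length.out = length(heads)),
                rep("is_a", spec$n_sets))
  graph <- ontology_graph(terms, data.frame(child = child, parent = parent,
                                            relation = relation,
                                            stringsAsFactors = FALSE))
  mapping <- map_sets_to_terms(set_names, graph)
  list(graph = graph, mapping = mapping,
       roots = c(immune = root_imm, other = root_other),
       cluster_heads = heads,
       immune_sets = set_names[imm_idx])
}

#' Generate synthetic survival outcomes linked to a gene's expression
#'
#' Event times are exponential with hazard
#' `h0 * HR^(expression > median)`; censoring is independent uniform on
#' `(0, b)` with `b` solved numerically so the expected censored fraction
#' equals `censor_rate`. Deterministic given `(spec, seed)`; uses the
#' derived sub-seed `seed + 3`.
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer master seed.
#' @param expression Named numeric vector: the linked gene's expression
#'   per subject (names become sample ids).
#' @param endpoint Endpoint label.
#' @return data.frame with columns `sample_id`, `time`, `event` and
#'   attribute `endpoint`.
#' @export
generate_survival <- function(spec, seed, expression, endpoint = "PFS") {
  stopifnot(inherits(spec, "synthetic_spec"), is.numeric(expression),
            !is.null(names(expression)))
  set.seed(seed + 3L)
  high <- expression > stats::median(expression)
  h <- spec$baseline_hazard * spec$true_hr^high
  tt <- stats::rexp(length(h), rate = h)
  if (spec$censor_rate > 0) {
    # P(censored) for C ~ U(0, b): mean over subjects of (1 - exp(-h b))/(h b)
    pcens <- function(b) mean((1 - exp(-h * b)) / (h * b)) - spec$censor_rate
    b <- stats::uniroot(pcens, lower = 1e-6, upper = 1e8)$root
    cc <- stats::runif(length(h), 0, b)
    out <- data.frame(sample_id = names(expression),
                      time = pmin(tt, cc),
                      event = as.integer(tt <= cc),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(sample_id = names(expression), time = tt,
                      event = 1L, stringsAsFactors = FALSE)
  }
  attr(out, "endpoint") <- endpoint
  out
}

#' Generate a complete synthetic study
#'
#' Runs [generate_expression], [generate_ontology] and [generate_survival]
#' (survival over the case samples' expression of the linked gene) and
#' collects everything a pipeline run needs, including the immune gene
#' list (the genes of the sets under the immune root).
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer master seed.
#' @return List of class `synthetic_study` with elements `expression`,
#'   `groups`, `sets`, `ontology`, `mapping`, `roots`, `cluster_heads`,
#'   `immune_sets`, `immune_genes`, `survival`, `truth`, `spec`, `seed`.
#' @export
simulate_gsr_study <- function(spec = synthetic_spec(), seed) {
  ex <- generate_expression(spec, seed)
  on <- generate_ontology(spec, seed)
  cases <- names(ex$groups)[ex$groups != "control"]
  surv <- generate_survival(spec, seed,
                            ex$expression[ex$truth$linked_gene, cases])
  immune_genes <- unique(unlist(ex$sets$sets[on$immune_sets]))
  truth <- ex$truth
  truth$immune_sets <- on$immune_sets
  structure(list(expression = ex$expression, groups = ex$groups,
                 sets = ex$sets, ontology = on$graph, mapping = on$mapping,
                 roots = on$roots, cluster_heads = on$cluster_heads,
                 immune_sets = on$immune_sets, immune_genes = immune_genes,
                 survival = surv, truth = truth, spec = spec, seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits exactly the on-disk formats the readers consume: `expression.tsv`,
#' `sets.gmt`, `ontology.obo`, `immune_genes.txt`, `clinical.csv`
#' (sample_id, group for all samples), `survival.csv` (sample_id, time,
#' event for case samples) and `truth.json`.
#'
#' @param study A [simulate_gsr_study] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_synthetic_inputs <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             obo = file.path(dir, "ontology.obo"),
             immune = file.path(dir, "immune_genes.txt"),
             clinical = file.path(dir, "clinical.csv"),
             survival = file.path(dir, "survival.csv"),
             truth = file.path(dir, "truth.json"))
  write_expression(study$expression, paths["expression"])
  write_gmt(study$sets, paths["gmt"])
  write_obo(study$ontology, paths["obo"])
  writeLines(study$immune_genes, paths["immune"])
  utils::write.csv(data.frame(sample_id = names(study$groups),
                              group = unname(study$groups)),
                   paths["clinical"], row.names = FALSE, quote = FALSE)
  utils::write.csv(study$survival, paths["survival"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
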