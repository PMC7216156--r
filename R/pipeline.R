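#' Validate a pipeline configuration
#'
#' Collects paths and analysis settings for [run_pipeline] and validates
#' them before any computation: all input paths must exist, alpha must lie
#' in (0, 1).
#'
#' @param expression,gmt,obo,immune_list,clinical,survival Input paths:
#'   expression TSV, gene sets GMT, ontology OBO, immune gene list (one
#'   symbol per line), clinical CSV (`sample_id,group`), survival CSV
#'   (`sample_id,time,event`; optional, NULL disables the survival stage).
#' @param out_dir Output directory for stage artifacts.
#' @param roots Ancestor term ids defining the immunofunctionome. For real
#'   GO data the immune progenitors are `GO:0002376` ("immune system
#'   process") and `GO:0006954` ("inflammatory response").
#' @param control Control group label.
#' @param min_genes Minimum measured genes per set.
#' @param alpha Significance level.
#' @param rule Significance rule, `"q"` (BH, default) or `"p"`.
#' @param correction_mode Group-mean correction mode for [group_gsr_summary].
#' @param top_k Top-k per group for the cross-comparison (default 30).
#' @param collapse Probe collapse rule for [read_expression].
#' @param folds,repeats Cross-validation settings.
#' @param min_group Minimum group size in the survival cutoff scan.
#' @param endpoint Survival endpoint label.
#' @param seed Integer seed (classification and any derived randomness).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, gmt, obo, immune_list, clinical,
                            survival = NULL, out_dir, roots,
                            control = "control", min_genes = 2,
                            alpha = 0.05, rule = "q",
                            correction_mode = "none", top_k = 30,
                            collapse = "none", folds = 5, repeats = 3,
                            min_group = 5, endpoint = "PFS", seed) {
  paths <- c(expression = expression, gmt = gmt, obo = obo,
             immune_list = immune_list, clinical = clinical)
  if (!is.null(survival)) paths <- c(paths, survival = survival)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ",
         paste(names(missing), "=", missing, collapse = "; "))
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  structure(list(paths = as.list(paths), out_dir = out_dir, roots = roots,
                 control = control, min_genes = min_genes, alpha = alpha,
                 rule = rule, correction_mode = correction_mode,
                 top_k = top_k, collapse = collapse, folds = folds,
                 repeats = repeats, min_group = min_group,
                 endpoint = endpoint, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full immunofunctionome analysis pipeline
#'
#' Executes the stages in order: ingest inputs, assemble the functionome,
#' extract the immunofunctionome, cross-validated classification, per-group
#' term tests, CWI ranking, top-k cross-comparison, immune-filtered
#' gene-level DEGs for the top-ranked common term, and the survival cutoff
#' scan for the selected genes. Each stage writes a plain TSV/JSON
#' artifact under `config$out_dir`; a failure aborts with the stage name.
#' The run is deterministic given the config (including its seed), and the
#' manifest records every setting so a run is fully reconstructable.
#'
#' @param config A [pipeline_config].
#' @return The run manifest (list, also written as `manifest.json`):
#'   settings, stage artifact paths, and per-stage counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(settings = config[setdiff(names(config), "paths")],
                   inputs = config$paths, stages = list(),
                   package_version = as.character(utils::packageVersion("gsrome")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  log_stage <- function(name, path, counts) {
    manifest$stages[[name]] <<- c(list(artifact = path), counts)
    message(sprintf("[%s] %s", name,
                    paste(names(counts), unlist(counts), sep = "=", collapse = " ")))
  }

  ## 1. ingest
  inp <- stage("ingest", {
    expr <- read_expression(config$paths$expression, collapse = config$collapse)
    sets <- read_gmt(config$paths$gmt)
    graph <- read_obo(config$paths$obo)
    immune <- read_gene_list(config$paths$immune_list)
    clin <- utils::read.csv(config$paths$clinical, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "group") %in% names(clin)))
    groups <- stats::setNames(clin$group, clin$sample_id)
    surv <- if (!is.null(config$paths$survival)) {
      read_survival_table(config$paths$survival, endpoint = config$endpoint)
    }
    list(expr = expr, sets = sets, graph = graph, immune = immune,
         groups = groups, surv = surv)
  })
  log_stage("ingest", NA, list(genes = nrow(inp$expr), samples = ncol(inp$expr),
                               sets = length(inp$sets$sets),
                               terms = length(inp$graph$terms),
                               immune_genes = length(inp$immune)))

  ## 2. functionome
  f <- stage("functionome", functionome(inp$expr, inp$groups, inp$sets,
                                        control = config$control,
                                        min_genes = config$min_genes))
  stage("functionome", {
    write_results(data.frame(sample_id = rownames(f$gsr), f$gsr,
                             check.names = FALSE), art("functionome.tsv"))
    writeLines(f$dropped_sets, art("dropped_sets.txt"))
  })
  log_stage("functionome", art("functionome.tsv"),
            list(sets_scored = ncol(f$gsr), sets_dropped = length(f$dropped_sets)))

  ## 3. immunofunctionome
  mapping <- stage("immunofunctionome", map_sets_to_terms(colnames(f$gsr), inp$graph))
  fi <- stage("immunofunctionome",
              extract_immunofunctionome(f, inp$graph, mapping, config$roots))
  stage("immunofunctionome", {
    write_results(data.frame(sample_id = rownames(fi$gsr), fi$gsr,
                             check.names = FALSE), art("immunofunctionome.tsv"))
    write_results(data.frame(set_name = colnames(fi$gsr),
                             term_id = unname(mapping$mapping[colnames(fi$gsr)]),
                             name = unname(inp$graph$terms[mapping$mapping[colnames(fi$gsr)]])),
                  art("immune_terms.tsv"))
  })
  log_stage("immunofunctionome", art("immunofunctionome.tsv"),
            list(terms_extracted = ncol(fi$gsr), unmapped = length(mapping$unmapped)))

  ## 4. group summary (control-corrected means, histogram content)
  gs <- stage("group_summary", group_gsr_summary(fi, config$correction_mode))
  stage("group_summary", write_results(gs, art("group_summary.tsv")))
  log_stage("group_summary", art("group_summary.tsv"),
            list(groups = nrow(gs)))

  ## 5. classification
  cv <- stage("classification", {
    y <- factor(ifelse(fi$groups == config$control, "control", "case"),
                levels = c("control", "case"))
    cross_validated_classifier(fi, labels = y, k = config$folds,
                               repeats = config$repeats, seed = config$seed)
  })
  stage("classification",
        jsonlite::write_json(list(summary = as.list(round(cv$summary, 6)),
                                  per_repeat = cv$per_repeat,
                                  per_class = as.list(round(cv$per_class, 6))),
                             art("classification.json"), auto_unbox = TRUE,
                             digits = NA))
  log_stage("classification", art("classification.json"),
            list(auc = round(unname(cv$summary["auc"]), 4)))

  ## 6. per-group term tests on the immunofunctionome
  tests <- stage("term_tests", test_all_terms(fi, alpha = config$alpha,
                                              rule = config$rule))
  stage("term_tests", write_results(tests, art("term_tests.tsv")))
  log_stage("term_tests", art("term_tests.tsv"),
            list(tests = nrow(tests), significant = sum(tests$significant)))

  ## 7. CWI ranking per group + cross-comparison
  heads <- stage("cwi_ranking", {
    kids <- inp$graph$edges$child[inp$graph$edges$parent %in% config$roots]
    sort(unique(kids))
  })
  ranked <- stage("cwi_ranking", {
    cluster_of_term <- assign_clusters(inp$graph,
                                       unname(mapping$mapping[colnames(fi$gsr)]),
                                       heads)
    cluster_of <- stats::setNames(cluster_of_term[mapping$mapping[colnames(fi$gsr)]],
                                  colnames(fi$gsr))
    by_group <- split(seq_len(nrow(tests)), tests$group)
    weights <- lapply(by_group, function(i) {
      cluster_weight_index(tests$p[i], cluster_of[tests$set_name[i]])
    })
    rankings <- lapply(names(by_group), function(g) {
      i <- by_group[[g]]
      rank_terms(tests[i, ], cluster_of, weights[[g]])
    })
    names(rankings) <- names(by_group)
    for (g in names(weights)) {
      w <- weights[[g]]; w$group <- g
      weights[[g]] <- w
    }
    write_results(do.call(rbind, weights), art("cluster_weights.tsv"))
    list(rankings = rankings, weights = weights)
  })
  common <- stage("crosscompare", {
    common <- rank_and_crosscompare(ranked$rankings, k = config$top_k)
    if (length(ranked$rankings) %in% 2:3) {
      vr <- venn_regions(attr(common, "topk"))
      jsonlite::write_json(as.list(vr), art("venn_regions.json"),
                           auto_unbox = TRUE)
    }
    write_results(data.frame(rank = seq_along(common), set_name = common),
                  art("common_terms.tsv"))
    common
  })
  log_stage("crosscompare", art("common_terms.tsv"),
            list(top_k = config$top_k, common = length(common)))

  ## 8. gene-level immune DEGs for the top-ranked common term
  degs <- stage("gene_deg", {
    top_term <- if (length(common)) common[1] else ranked$rankings[[1]][1]
    d <- gene_level_deg(inp$expr, inp$groups, inp$sets$sets[[top_term]],
                        inp$immune, alpha = config$alpha,
                        control = config$control, rule = config$rule)
    d$term <- top_term
    write_results(d, art("immune_degs.tsv"))
    d
  })
  log_stage("gene_deg", art("immune_degs.tsv"),
            list(term = degs$term[1], genes = nrow(degs),
                 selected = sum(degs$selected)))

  ## 9. survival cutoff scan for the selected genes
  if (!is.null(inp$surv)) {
    scan <- stage("survival_scan", {
      genes <- degs$gene[degs$selected]
      if (length(genes) == 0) genes <- degs$gene[which.min(degs$p)]
      sv <- inp$surv[inp$surv$sample_id %in% colnames(inp$expr), ]
      res <- lapply(genes, function(g) {
        tryCatch(best_cutoff_scan(inp$expr[g, sv$sample_id], sv$time, sv$event,
                                  min_group = config$min_group, gene = g,
                                  endpoint = config$endpoint),
                 error = function(e) NULL)
      })
      res <- res[!vapply(res, is.null, logical(1))]
      if (length(res)) write_results(cutoff_results_table(res),
                                     art("survival_scan.tsv"))
      res
    })
    log_stage("survival_scan", art("survival_scan.tsv"),
              list(genes_scanned = length(scan)))
  }

  manifest_path <- art("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
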