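make_graph <- function(edges, extra_terms = character(0)) {
  ids <- unique(c(edges$child, edges$parent, extra_terms))
  ontology_graph(stats::setNames(paste("term", ids), ids), edges)
}

test_that("descendants follows child-to-parent reachability", {
  # chain C -> B -> A
  g <- make_graph(data.frame(child = c("C", "B"), parent = c("B", "A"),
                             relation = "is_a"))
  expect_setequal(descendants(g, "A", reflexive = TRUE), c("A", "B", "C"))
  expect_setequal(descendants(g, "A"), c("B", "C"))
  # leaf root
  expect_identical(descendants(g, "C", reflexive = TRUE), "C")
  expect_length(descendants(g, "C"), 0)
  # union over roots equals result on the root set (roots excluded when
  # non-reflexive)
  expect_setequal(descendants(g, c("A", "B"), reflexive = TRUE),
                  union(descendants(g, "A", reflexive = TRUE),
                        descendants(g, "B", reflexive = TRUE)))
  expect_setequal(descendants(g, c("A", "B")),
                  setdiff(union(descendants(g, "A"), descendants(g, "B")),
                          c("A", "B")))
  expect_error(descendants(g, "ZZ"), "unknown root")
})

test_that("descendants equals a transitive-closure oracle on random DAGs", {
  set.seed(55)
  for (trial in 1:40) {
    n <- sample(5:50, 1)
    dag <- random_dag(n, p_edge = 0.08)
    if (nrow(dag$edges) == 0) next
    g <- ontology_graph(stats::setNames(dag$nodes, dag$nodes), dag$edges)
    roots <- sample(dag$nodes, sample(1:2, 1))
    expect_setequal(descendants(g, roots),
                    oracle_descendants(dag$nodes, dag$edges, roots))
    expect_setequal(descendants(g, roots, reflexive = TRUE),
                    oracle_descendants(dag$nodes, dag$edges, roots,
                                       reflexive = TRUE))
  }
})

test_that("descendants is monotone under edge addition", {
  set.seed(66)
  dag <- random_dag(20, p_edge = 0.1)
  g <- ontology_graph(stats::setNames(dag$nodes, dag$nodes), dag$edges)
  root <- dag$nodes[20]
  before <- descendants(g, root)
  # add an edge from a node outside the closure into the root
  outside <- setdiff(dag$nodes[-20], before)
  if (length(outside)) {
    e2 <- rbind(dag$edges, data.frame(child = outside[1], parent = root,
                                      relation = "is_a"))
    g2 <- ontology_graph(stats::setNames(dag$nodes, dag$nodes), e2)
    after <- descendants(g2, root)
    expect_true(all(before %in% after))
    expect_true(outside[1] %in% after)
  }
})

test_that("cycles and unknown edge endpoints are rejected", {
  e <- data.frame(child = c("A", "B"), parent = c("B", "A"), relation = "is_a")
  expect_error(ontology_graph(c(A = "a", B = "b"), e), "cycle")
  e2 <- data.frame(child = "A", parent = "Q", relation = "is_a")
  expect_error(ontology_graph(c(A = "a"), e2), "unknown")
})

test_that("set names map to term ids by normalized name", {
  g <- ontology_graph(c("GO:1" = "immune system process",
                        "GO:2" = "inflammatory response"),
                      data.frame(child = "GO:2", parent = "GO:1",
                                 relation = "is_a"))
  mp <- map_sets_to_terms(c("GO_IMMUNE_SYSTEM_PROCESS",
                            "GO_INFLAMMATORY_RESPONSE",
                            "GO_NOT_A_TERM"), g)
  expect_identical(unname(mp$mapping["GO_IMMUNE_SYSTEM_PROCESS"]), "GO:1")
  expect_identical(unname(mp$mapping["GO_INFLAMMATORY_RESPONSE"]), "GO:2")
  expect_identical(mp$unmapped, "GO_NOT_A_TERM")
  expect_identical(normalize_term_name("GO_T_CELL_ACTIVATION"),
                   "t cell activation")
})

test_that("immunofunctionome extraction selects exactly the planted immune sets", {
  sp <- synthetic_spec(n_sets = 100, n_dysregulated = 10, n_controls = 8,
                       n_cases = c(case = 8), immune_fraction = 0.1)
  st <- simulate_gsr_study(sp, seed = 17)
  expect_length(st$immune_sets, 10)
  f <- functionome(st$expression, st$groups, st$sets)
  fi <- extract_immunofunctionome(f, st$ontology, st$mapping,
                                  st$roots["immune"])
  expect_setequal(colnames(fi$gsr), st$immune_sets)
  expect_identical(attr(fi, "n_extracted"), 10L)
  # column order preserved relative to the functionome
  expect_identical(colnames(fi$gsr),
                   colnames(f$gsr)[colnames(f$gsr) %in% st$immune_sets])

  # roots = both progenitors -> identity on mapped columns
  fall <- extract_immunofunctionome(f, st$ontology, st$mapping,
                                    unname(st$roots))
  expect_identical(colnames(fall$gsr), colnames(f$gsr))

  # idempotent
  fi2 <- extract_immunofunctionome(fi, st$ontology, st$mapping,
                                   st$roots["immune"])
  expect_identical(fi2$gsr, fi$gsr)
})
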