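test_that("Mann-Whitney matches enumerated exact p-values", {
  expect_equal(mann_whitney(1, 2), list(U = 1, p = 1))
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  # U counts pairs x < y plus half-ties
  expect_equal(mann_whitney(c(1, 2), c(2, 3))$U, 3.5)
  # identical multisets -> p = 1 under the tie convention
  expect_equal(mann_whitney(c(1, 2, 2, 5), c(2, 1, 5, 2))$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals full enumeration for all sizes <= 5", {
  set.seed(12)
  for (nx in 1:5) {
    for (ny in 1:5) {
      for (rep in 1:3) {
        x <- sample(seq(1, 100), nx)
        y <- sample(setdiff(seq(1, 100), x), ny)
        expect_equal(mann_whitney(x, y)$p, oracle_mw_exact(x, y),
                     info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
      }
    }
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (trial in 1:300) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
  }
})

test_that("term tests flag planted sets and stay calibrated under the null", {
  # planted: fully reversed sets at 15/15 must be discovered
  sp <- synthetic_spec(n_sets = 60, n_dysregulated = 10, n_controls = 15,
                       n_cases = c(case = 15))
  st <- simulate_gsr_study(sp, seed = 19)
  f <- functionome(st$expression, st$groups, st$sets)
  tt <- test_all_terms(f)
  hits <- tt$set_name[tt$significant]
  expect_true(all(st$truth$dysregulated_sets %in% hits))
  expect_true(all(tt$direction[tt$set_name %in% st$truth$dysregulated_sets] == -1))
  expect_true(all(tt$q >= tt$p))

  # null: no planted effects, few raw discoveries, ~no BH discoveries
  sp0 <- synthetic_spec(n_sets = 100, n_dysregulated = 0, n_controls = 15,
                        n_cases = c(case = 15))
  frac <- bh_hits <- numeric(5)
  for (s in 1:5) {
    st0 <- simulate_gsr_study(sp0, seed = 300 + s)
    f0 <- functionome(st0$expression, st0$groups, st0$sets)
    t0 <- test_all_terms(f0)
    frac[s] <- mean(t0$p < 0.05)
    bh_hits[s] <- sum(t0$significant)
  }
  expect_lt(mean(frac), 0.12)
  expect_lt(mean(bh_hits), 1)
})

test_that("cluster weight index normalizes, orders and ignores log base", {
  cw <- cluster_weight_index(c(0.01, 0.1, 0.5), c("A", "A", "B"))
  expect_equal(sum(cw$cwi), 1, tolerance = 1e-12)
  expect_equal(cw$cwi[cw$cluster == "A"],
               (-log(0.01) - log(0.1)) / (-log(0.01) - log(0.1) - log(0.5)),
               tolerance = 1e-12)
  expect_equal(cw$cwi[cw$cluster == "A"], 0.9088, tolerance = 1e-3)
  # one cluster -> CWI 1
  expect_equal(cluster_weight_index(c(0.2, 0.4), c("A", "A"))$cwi, 1)
  # base invariance: scaling all weights by 1/log(10) leaves ratios intact
  w10 <- tapply(-log10(c(0.01, 0.1, 0.5)), c("A", "A", "B"), sum)
  expect_equal(sort(cw$cwi), sort(as.numeric(w10 / sum(w10))), tolerance = 1e-12)
  # p = 0 is clamped, not infinite
  expect_true(all(is.finite(cluster_weight_index(c(0, 0.5), c("A", "B"))$weight)))
  expect_error(cluster_weight_index(numeric(0), character(0)), "empty")
})

test_that("terms are assigned to the nearest cluster-head ancestor", {
  # A -> H1 -> R, B -> H2 -> R; D reaches H1 in 3 steps but H2 in 2;
  # C2 ties at distance 2 to both heads (tie breaks by head order)
  e <- data.frame(child  = c("H1", "H2", "A", "B", "C", "C2", "C2", "D", "D2", "D"),
                  parent = c("R", "R", "H1", "H2", "H1", "C", "B", "D2", "C", "B"),
                  relation = "is_a")
  ids <- c("R", "H1", "H2", "A", "B", "C", "C2", "D", "D2")
  g <- ontology_graph(stats::setNames(letters[seq_along(ids)], ids), e)
  cl <- assign_clusters(g, c("A", "B", "C2", "D"), heads = c("H1", "H2"))
  expect_identical(unname(cl), c("H1", "H2", "H1", "H2"))
  expect_true(is.na(assign_clusters(g, "R", heads = c("H1", "H2"))[[1]]))
})

test_that("top-k cross-comparison intersects rankings deterministically", {
  r <- list(a = paste0("T", 1:40), b = paste0("T", 1:40), c = paste0("T", 1:40))
  expect_length(rank_and_crosscompare(r, k = 30), 30)
  r2 <- list(a = paste0("T", 1:30), b = paste0("U", 1:30))
  expect_length(rank_and_crosscompare(r2, k = 30), 0)
  expect_warning(rank_and_crosscompare(list(a = "T1", b = paste0("T", 1:30)),
                                       k = 30),
                 "only")
  # tie-break within a ranking: CWI desc, then p asc, then name asc
  tests <- data.frame(set_name = c("B", "A", "C"), p = c(0.01, 0.01, 0.5))
  cl <- c(B = "X", A = "X", C = "X")
  expect_identical(rank_terms(tests, cl), c("A", "B", "C"))
})

test_that("venn regions count every membership pattern", {
  v <- venn_regions(list(A = c(1, 2), B = c(2, 3)))
  expect_identical(v, c(A = 1L, B = 1L, "A&B" = 1L))
  v3 <- venn_regions(list(A = 1:2, B = 1:2, C = 1:2))
  expect_equal(sum(v3), 2)
  expect_equal(unname(v3["A&B&C"]), 2L)
  expect_error(venn_regions(list(a = 1, b = 1, c = 1, d = 1)), "2 or 3")
  # random sets vs per-element membership enumeration
  set.seed(31)
  for (trial in 1:20) {
    sets <- list(A = sample(30, 12), B = sample(30, 12), C = sample(30, 12))
    v <- venn_regions(sets)
    expect_equal(sum(v), length(unique(unlist(sets))))
    # check one region against direct counting
    expect_equal(unname(v["A&B&C"]),
                 length(intersect(intersect(sets$A, sets$B), sets$C)))
    expect_equal(unname(v["A"]),
                 length(setdiff(setdiff(sets$A, sets$B), sets$C)))
  }
})

test_that("gene-level DEGs recover planted shifts and respect the immune filter", {
  set.seed(91)
  n <- 40
  genes <- paste0("G", 1:6)
  expr <- matrix(rnorm(6 * 2 * n, mean = 5), 6, 2 * n,
                 dimnames = list(genes, paste0("S", 1:(2 * n))))
  groups <- stats::setNames(rep(c("control", "case"), each = n), colnames(expr))
  shifted <- c("G2", "G5")
  expr[shifted, groups == "case"] <- expr[shifted, groups == "case"] + 2
  d <- gene_level_deg(expr, groups, genes, immune_list = genes)
  expect_setequal(d$gene[d$selected], shifted)
  expect_true(all(d$direction[d$gene %in% shifted] == "up"))
  # immune list disjoint from the term's genes -> nothing selected
  d2 <- gene_level_deg(expr, groups, genes, immune_list = "OTHER")
  expect_equal(sum(d2$selected), 0)
  expect_error(gene_level_deg(expr, groups, genes, character(0)), "empty")
  expect_error(gene_level_deg(expr, groups, "ABSENT", genes), "measured")
})
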