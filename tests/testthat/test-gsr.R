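test_that("rank templates record the majority pairwise ordering", {
  # single control: every direction from that one ordering
  tpl <- learn_rank_template(cbind(c1 = c(G1 = 1, G2 = 2)))
  expect_identical(tpl$d, 1L)

  # three controls, four genes: majority over all 6 pairs (counted by hand)
  m <- rbind(G1 = c(1, 1, 2), G2 = c(2, 2, 1), G3 = c(3, 4, 3), G4 = c(4, 3, 4))
  tpl <- learn_rank_template(m)
  expect_identical(tpl$d, rep(1L, 6))

  # two controls with opposite orderings: all pairs tied -> all 0
  m2 <- rbind(G1 = c(1, 3), G2 = c(2, 2), G3 = c(3, 1))
  expect_identical(learn_rank_template(m2)$d, c(0L, 0L, 0L))

  expect_error(learn_rank_template(rbind(G1 = 1)), "measured genes")
})

test_that("matching_score hits the exact endpoints and enumerated fractions", {
  tpl <- learn_rank_template(cbind(ctrl = c(G1 = 10, G2 = 20, G3 = 30, G4 = 40)))
  expect_identical(matching_score(c(G1 = 1, G2 = 2, G3 = 3, G4 = 4), tpl), 1)
  expect_identical(matching_score(c(G1 = 40, G2 = 30, G3 = 20, G4 = 10), tpl), 0)
  # only the (G1, G2) pair flipped: 5 of 6 pairs agree
  expect_equal(matching_score(c(G1 = 20, G2 = 10, G3 = 30, G4 = 40), tpl), 5 / 6)
  expect_error(matching_score(c(G1 = 1, G2 = 2), tpl), "missing")
})

test_that("matching_score equals the all-pairs enumeration oracle exactly", {
  set.seed(101)
  for (trial in 1:200) {
    m <- sample(2:8, 1)
    n_ctrl <- sample(1:6, 1)
    ctrl <- matrix(rnorm(m * n_ctrl), m,
                   dimnames = list(paste0("G", 1:m), NULL))
    smp <- stats::setNames(rnorm(m), rownames(ctrl))
    tpl <- learn_rank_template(ctrl)
    expect_identical(matching_score(smp, tpl), oracle_gsr(ctrl, smp))
  }
})

test_that("GSR is invariant under strictly increasing transforms", {
  set.seed(7)
  ctrl <- matrix(rnorm(5 * 4), 5, dimnames = list(paste0("G", 1:5), NULL))
  tpl <- learn_rank_template(ctrl)
  smp <- stats::setNames(rnorm(5), rownames(ctrl))
  base <- matching_score(smp, tpl)
  for (f in list(exp, function(x) x^3, function(x) 2 * x + 1)) {
    expect_identical(matching_score(f(smp), tpl), base)
  }
  # transforming the controls leaves the template unchanged too
  expect_identical(learn_rank_template(exp(ctrl))$d, tpl$d)
})

test_that("GSR is invariant to consistent gene relabelling within a set", {
  set.seed(8)
  st <- tiny_study(list(rnorm(6, 1:6, 0.3), rnorm(6, 1:6, 0.3), rnorm(6, 1:6, 0.3)),
                   list(rnorm(6, 6:1, 0.3)))
  f1 <- functionome(st$expr, st$groups, st$sets, control = "control")
  # rename genes by a random bijection, consistently in matrix and set
  relabel <- stats::setNames(paste0("H", sample(6)), rownames(st$expr))
  expr2 <- st$expr
  rownames(expr2) <- unname(relabel[rownames(st$expr)])
  sets2 <- list(SET1 = unname(relabel[st$sets$SET1]))
  f2 <- functionome(expr2, st$groups, sets2)
  expect_equal(unname(f1$gsr), unname(f2$gsr))
})

test_that("functionome assembles GSR in [0,1], keeps GMT order, drops small sets", {
  set.seed(21)
  sp <- synthetic_spec(n_sets = 30, n_dysregulated = 5, n_controls = 10,
                       n_cases = c(case = 10))
  st <- simulate_gsr_study(sp, seed = 13)
  sets <- st$sets$sets
  sets$TOO_SMALL <- c(sets[[1]][1], "NOT_MEASURED")
  f <- functionome(st$expression, st$groups, sets)
  expect_true(all(f$gsr >= 0 & f$gsr <= 1))
  expect_identical(colnames(f$gsr), names(sets)[seq_len(30)])
  expect_identical(f$dropped_sets, "TOO_SMALL")
  expect_error(functionome(st$expression, rep("case", ncol(st$expression)),
                           sets), "control")
})

test_that("a case equal to a control profile gets that control's GSR", {
  set.seed(31)
  ctrl <- lapply(1:4, function(i) rnorm(5, 1:5, 0.5))
  st <- tiny_study(ctrl, list(ctrl[[2]]))
  f <- functionome(st$expr, st$groups, st$sets)
  expect_identical(f$gsr["X1", ], f$gsr["C2", ])
})

test_that("zero-noise planted reversal gives GSR exactly 0 (cases) and 1 (controls)", {
  sp <- synthetic_spec(n_sets = 10, n_dysregulated = 3, noise_sd = 0,
                       n_controls = 5, n_cases = c(case = 5), disruption = 1)
  st <- simulate_gsr_study(sp, seed = 5)
  f <- functionome(st$expression, st$groups, st$sets)
  dys <- st$truth$dysregulated_sets
  cases <- st$groups != "control"
  expect_true(all(f$gsr[cases, dys] == 0))
  expect_true(all(f$gsr[!cases, ] == 1))
  # non-planted sets stay fully regular for everyone at zero noise
  expect_true(all(f$gsr[, setdiff(colnames(f$gsr), dys)] == 1))
})

test_that("control mean GSR dominates case mean under planted disruption", {
  for (s in 1:3) {
    sp <- synthetic_spec(n_sets = 40, n_dysregulated = 8, n_controls = 12,
                         n_cases = c(case = 12))
    st <- simulate_gsr_study(sp, seed = 100 + s)
    f <- functionome(st$expression, st$groups, st$sets)
    cases <- st$groups != "control"
    expect_gt(mean(f$gsr[!cases, ]), mean(f$gsr[cases, ]))
  }
})

test_that("group summaries compute corrected means in all three modes", {
  set.seed(41)
  ctrl <- lapply(1:6, function(i) rnorm(5, 1:5, 0.4))
  # case group duplicates the controls -> identical GSR distribution
  st <- tiny_study(ctrl, ctrl)
  f <- functionome(st$expr, st$groups, st$sets)
  gs_none <- group_gsr_summary(f, "none")
  gs_ratio <- group_gsr_summary(f, "ratio")
  gs_diff <- group_gsr_summary(f, "difference")
  expect_equal(gs_ratio$corrected_mean, 1)
  expect_equal(gs_none$corrected_mean, gs_none$control_mean)
  expect_equal(gs_diff$corrected_mean, gs_diff$case_mean)
  expect_equal(gs_none$p, 1)  # identical distributions
  expect_error(group_gsr_summary(f, "bogus"))

  # planted dysregulation pushes every corrected case mean below control
  sp <- synthetic_spec(n_sets = 50, n_dysregulated = 5, n_controls = 15,
                       n_cases = c(case = 15))
  st2 <- simulate_gsr_study(sp, seed = 9)
  f2 <- functionome(st2$expression, st2$groups, st2$sets)
  gs2 <- group_gsr_summary(f2, "none")
  expect_lt(gs2$case_mean, gs2$control_mean)
})

test_that("histogram summaries bin GSR mass correctly", {
  m <- matrix(1, 4, 10, dimnames = list(paste0("S", 1:4), paste0("T", 1:10)))
  h <- histogram_summary(m, groups = rep(c("a", "b"), 2), bins = 5)
  expect_true(all(h$counts[, 5] == 20))
  expect_true(all(h$counts[, 1:4] == 0))
  expect_equal(unname(h$means), c(1, 1))
  expect_error(histogram_summary(m, rep("a", 4), bins = 1), "bins")

  set.seed(3)
  mu <- matrix(runif(2000), 20, 100,
               dimnames = list(paste0("S", 1:20), paste0("T", 1:100)))
  hu <- histogram_summary(mu, groups = rep("g", 20), bins = 10)
  expect_true(all(abs(hu$freq - 0.1) < 0.03))  # roughly flat
  expect_equal(sum(hu$freq), 1)
})
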