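# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with explicit loops, never calling the
# package's own implementation paths.

# GSR matching: loop over all unordered pairs of a template learned by
# counting, per pair, how many controls order the genes one way.
oracle_gsr <- function(controls, sample_values) {
  m <- nrow(controls)
  n <- ncol(controls)
  agree <- 0L
  npair <- 0L
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      cnt <- 0L
      for (s in seq_len(n)) if (controls[i, s] < controls[j, s]) cnt <- cnt + 1L
      d <- as.integer(cnt > n / 2)
      ind <- as.integer(sample_values[i] < sample_values[j])
      if (ind == d) agree <- agree + 1L
      npair <- npair + 1L
    }
  }
  agree / npair
}

# BH step-up from the definition: q_(i) = min_{j >= i} p_(j) * m / j, clipped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of which pooled ranks
# belong to x (untied inputs only).
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  u_obs <- sum(outer(x, y, "<"))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) {
    sum(outer(pool[ix], pool[-ix], "<"))
  })
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Transitive closure by boolean matrix powers; descendants of r = nodes
# with a path to r along child->parent edges.
oracle_descendants <- function(nodes, edges, roots, reflexive = FALSE) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) A[edges$child[k], edges$parent[k]] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  res <- unique(unlist(lapply(roots, function(r) nodes[R[, r]])))
  if (reflexive) res <- unique(c(res, roots)) else res <- setdiff(res, roots)
  res
}

# Product-limit estimate by hand at each distinct event time.
oracle_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = et, surv = NA_real_)
  for (k in seq_along(et)) {
    n_risk <- sum(times >= et[k])
    d <- sum(times == et[k] & events == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

# Log-rank O/E/V from per-event-time 2x2 hypergeometric tables; returns
# quantities for the group == TRUE side.
oracle_logrank <- function(times, events, group) {
  group <- as.logical(group)
  et <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V, chi2 = (O1 - E1)^2 / V)
}

# Small random DAG over node ids "T01".. with edges only from lower to
# higher index (guaranteed acyclic).
random_dag <- function(n_nodes, p_edge = 0.1) {
  nodes <- sprintf("T%02d", seq_len(n_nodes))
  child <- character(0); parent <- character(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) {
        child <- c(child, nodes[i]); parent <- c(parent, nodes[j])
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(child = child, parent = parent,
                          relation = rep("is_a", length(child)),
                          stringsAsFactors = FALSE))
}

# Tiny deterministic expression fixture: one set, controls with a fixed
# ordering, cases given explicitly.
tiny_study <- function(control_profiles, case_profiles, genes = NULL) {
  m <- rbind()
  ctrl <- do.call(cbind, control_profiles)
  case <- do.call(cbind, case_profiles)
  expr <- cbind(ctrl, case)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(expr)))
  rownames(expr) <- genes
  colnames(expr) <- c(paste0("C", seq_len(ncol(ctrl))),
                      paste0("X", seq_len(ncol(case))))
  groups <- stats::setNames(rep(c("control", "case"), c(ncol(ctrl), ncol(case))),
                            colnames(expr))
  list(expr = expr, groups = groups,
       sets = list(SET1 = genes))
}
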