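# Independent oracles and small fixture builders used across the suite.

# Closed-form RWR solution r (I - (1-r) W)^-1 F0, with the walk operator
# assembled densely and independently of build_walk_matrix().
rwr_closed_form <- function(net, heat0, r) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ed <- network_edges(net)
  for (i in seq_len(nrow(ed))) {
    A[ed$source[i], ed$target[i]] <- 1
    A[ed$target[i], ed$source[i]] <- 1
  }
  deg <- colSums(A)
  W <- A
  for (j in seq_len(n)) {
    if (deg[j] == 0) W[j, j] <- 1 else W[, j] <- A[, j] / deg[j]
  }
  f0 <- stats::setNames(numeric(n), nodes)
  f0[names(heat0)] <- heat0
  drop(r * solve(diag(n) - (1 - r) * W, f0))
}

# Student t CDF by numerical integration of the density (gamma-function
# form), independent of stats::pt.
t_cdf_brute <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  if (t <= 0) {
    stats::integrate(dens, -Inf, t, rel.tol = 1e-13, abs.tol = 1e-14)$value
  } else {
    1 - t_cdf_brute(-t, df)
  }
}

# Two-sided equal-variance t-test p-value from first principles.
t_p_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * t_cdf_brute(-abs(tt), nx + ny - 2)
}

# Random simple undirected network with named nodes (may contain isolated
# nodes).
random_net <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("G%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = TRUE)
  gene_network(el, nodes = igraph::V(g)$name)
}

# A plate in which one agent of interest carries prescribed
# log2-vs-median values and nine filler agents sit exactly at the plate
# median.
plate_with_vprime <- function(vprime, agent = "X", plate_id = "P1",
                              perturbed = FALSE) {
  out <- lapply(seq_along(vprime), function(r) {
    data.frame(
      plate_id = plate_id, replicate = r,
      well = sprintf("A%d", 1:10),
      agent_id = c(agent, sprintf("F%02d", 1:9)),
      agent_type = "COMPOUND",
      dose = NA_real_, perturbed = perturbed,
      value = c(100 * 2^vprime[r], rep(100, 9)),
      stringsAsFactors = FALSE)
  })
  plate_screen_table(do.call(rbind, out))
}

tiny_set <- function(scores, cell_line = "L1", construct = "ACTIVATING",
                     platform = "ABUNDANCE", id = "set") {
  kinase_set(scores, dataset_id = id, cell_line = cell_line,
             construct = construct, platform = platform)
}
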