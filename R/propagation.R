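#' Propagation configuration
#'
#' Parameters for random-walk-with-restart propagation and permutation
#' significance. The restart probability defaults to 0.2, the value used for
#' the kinome integration; `alpha_is_retention = TRUE` flips the
#' interpretation so that 0.2 is read as the retention weight (restart
#' probability 0.8).
#'
#' @param restart_prob Restart probability in (0, 1]; default 0.2.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Maximum iterations; default 1000.
#' @param n_permutations Number of permutations B (>= 100); default 1000.
#' @param seed Integer RNG seed for the permutation null.
#' @param p_threshold Significance cutoff in (0, 1); default 0.05.
#' @param permutation_scheme `"LABEL_SHUFFLE"` (shuffle each line's input
#'   heats over that line's measured genes) or `"DEGREE_BINNED"` (shuffle
#'   only within network-degree deciles, guarding against hub-adjacency
#'   inflation).
#' @param alpha_is_retention Interpret `restart_prob` as the retention
#'   weight instead of the restart probability; default `FALSE`.
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(restart_prob = 0.2, tol = 1e-10,
                               max_iter = 1000L, n_permutations = 1000L,
                               seed = 1L, p_threshold = 0.05,
                               permutation_scheme = c("LABEL_SHUFFLE",
                                                      "DEGREE_BINNED"),
                               alpha_is_retention = FALSE) {
  permutation_scheme <- match.arg(permutation_scheme)
  if (!is.numeric(restart_prob) || restart_prob <= 0 || restart_prob > 1) {
    stop("restart_prob must lie in (0, 1]")
  }
  if (tol <= 0) stop("tol must be positive")
  if (max_iter < 1) stop("max_iter must be a positive integer")
  if (n_permutations < 100) stop("config error: n_permutations must be >= 100")
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)")
  }
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), p_threshold = p_threshold,
                 permutation_scheme = permutation_scheme,
                 alpha_is_retention = isTRUE(alpha_is_retention)),
            class = "propagation_config")
}

effective_restart <- function(cfg) {
  if (cfg$alpha_is_retention) 1 - cfg$restart_prob else cfg$restart_prob
}

#' Column-stochastic walk operator of a network
#'
#' Degree-normalized adjacency \eqn{W = A D^{-1}}: entry (i, j) is
#' 1/degree(j) when i and j are connected. Isolated nodes receive a
#' self-transition of 1 so that every column sums to 1 and diffused heat is
#' conserved.
#'
#' @param net A [gene_network].
#' @return A sparse `dgCMatrix` with node-name dimnames.
#' @export
build_walk_matrix <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  deg <- Matrix::colSums(A)
  isolated <- deg == 0
  inv <- ifelse(isolated, 0, 1 / pmax(deg, 1))
  W <- A %*% Matrix::Diagonal(n, inv)
  if (any(isolated)) {
    W <- W + Matrix::sparseMatrix(i = which(isolated), j = which(isolated),
                                  x = 1, dims = c(n, n))
  }
  dimnames(W) <- list(igraph::V(g)$name, igraph::V(g)$name)
  W
}

# Iterate F <- (1 - r) W F + r F0 to the fixed point; F0 may hold one
# column per restart vector so permutation batches share the iteration.
rwr_iterate <- function(W, F0, r, tol, max_iter) {
  F0 <- as.matrix(F0)
  f <- F0
  for (it in seq_len(max_iter)) {
    f_new <- (1 - r) * as.matrix(W %*% f) + r * F0
    resid <- max(colSums(abs(f_new - f)))
    f <- f_new
    if (resid < tol) {
      return(list(heats = f, iterations = it, residual = resid))
    }
  }
  stop(sprintf(
    "convergence error: RWR did not converge in %d iterations (L1 residual %.3g)",
    max_iter, resid))
}

#' Random walk with restart over a gene network
#'
#' Iterates \eqn{F \leftarrow (1 - r) W F + r F_0} with the
#' column-stochastic operator from [build_walk_matrix] until the L1 change
#' falls below `tol`. Input genes absent from the network are dropped with a
#' warning; network nodes without input heat start at 0. Total heat is
#' conserved: `sum(result) == sum(retained input)`.
#'
#' @param heat0 Named non-negative numeric vector of input heats.
#' @param net A [gene_network].
#' @param cfg A [propagation_config].
#' @return Named numeric vector of propagated heats over all network nodes,
#'   with attributes `iterations` and `residual`.
#' @export
propagate <- function(heat0, net, cfg = propagation_config()) {
  stopifnot(inherits(net, "gene_network"))
  if (is.null(names(heat0))) stop("heat0 must be a named vector")
  if (any(!is.finite(heat0)) || any(heat0 < 0)) {
    stop("heat0 must be finite and non-negative")
  }
  names(heat0) <- toupper(names(heat0))
  nodes <- network_nodes(net)
  unknown <- setdiff(names(heat0), nodes)
  if (length(unknown)) {
    warning(length(unknown), " input gene(s) absent from the network dropped: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
    heat0 <- heat0[names(heat0) %in% nodes]
  }
  f0 <- stats::setNames(numeric(length(nodes)), nodes)
  f0[names(heat0)] <- heat0
  W <- build_walk_matrix(net)
  res <- rwr_iterate(W, matrix(f0, ncol = 1), effective_restart(cfg),
                     cfg$tol, cfg$max_iter)
  out <- stats::setNames(as.numeric(res$heats), nodes)
  attr(out, "iterations") <- res$iterations
  attr(out, "residual") <- res$residual
  out
}

#' Multiply propagated heats across same-construct cell lines
#'
#' @param heats Named list of propagated heat vectors (one per cell line,
#'   all over the same network node set).
#' @return Named numeric vector: the per-gene product over lines.
#' @export
combine_lines <- function(heats) {
  if (length(heats) == 0L) stop("contract error: empty cell-line set")
  nodes <- names(heats[[1]])
  for (h in heats) {
    if (!identical(sort(names(h)), sort(nodes))) {
      stop("contract error: heat vectors defined on different node sets")
    }
  }
  out <- rep(1, length(nodes))
  names(out) <- nodes
  for (h in heats) out <- out * as.numeric(h[nodes])
  out
}

# One permutation draw of a line's restart vector: shuffle the measured
# heats over the measured genes' positions (optionally within degree bins).
permute_heat_matrix <- function(f0, measured_idx, B, degree_bins = NULL) {
  n <- length(f0)
  out <- matrix(rep(f0, B), nrow = n)
  vals <- f0[measured_idx]
  if (is.null(degree_bins)) {
    for (b in seq_len(B)) {
      out[measured_idx, b] <- vals[sample.int(length(vals))]
    }
  } else {
    split_idx <- split(seq_along(measured_idx), degree_bins)
    for (b in seq_len(B)) {
      perm <- vals
      for (grp in split_idx) {
        if (length(grp) > 1L) perm[grp] <- vals[grp][sample.int(length(grp))]
      }
      out[measured_idx, b] <- perm
    }
  }
  out
}

#' Permutation significance of cross-line heat products
#'
#' Builds an empirical null for the per-gene product of propagated heats by
#' shuffling each line's input heats over that line's measured genes
#' (independently per line and permutation), re-propagating, and
#' re-multiplying. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{b : product_b \ge observed\}) / (1 + B)}, so
#' p lies in (0, 1]. Deterministic given `cfg$seed`.
#'
#' @param observed_products Named numeric vector from [combine_lines].
#' @param inputs Named list of the per-line *input* heat vectors (the
#'   measured `|z|` heats actually handed to [propagate]).
#' @param net A [gene_network].
#' @param cfg A [propagation_config]; `n_permutations`, `seed` and
#'   `permutation_scheme` are used here.
#' @return Named numeric vector of p-values over network nodes.
#' @export
permutation_significance <- function(observed_products, inputs, net, cfg) {
  stopifnot(inherits(net, "gene_network"), inherits(cfg, "propagation_config"))
  if (length(inputs) == 0L) stop("contract error: empty cell-line set")
  nodes <- network_nodes(net)
  B <- cfg$n_permutations
  W <- build_walk_matrix(net)
  r <- effective_restart(cfg)
  deg <- igraph::degree(net$graph)
  set.seed(cfg$seed)
  prod_mat <- matrix(1, nrow = length(nodes), ncol = B)
  for (line in names(inputs)) {
    h <- inputs[[line]]
    names(h) <- toupper(names(h))
    h <- h[names(h) %in% nodes]
    f0 <- stats::setNames(numeric(length(nodes)), nodes)
    f0[names(h)] <- h
    measured_idx <- match(names(h), nodes)
    bins <- NULL
    if (cfg$permutation_scheme == "DEGREE_BINNED" && length(measured_idx) > 1) {
      d <- deg[measured_idx]
      qs <- unique(stats::quantile(d, probs = seq(0, 1, 0.1)))
      bins <- cut(d, breaks = qs, include.lowest = TRUE)
    }
    F0 <- permute_heat_matrix(f0, measured_idx, B, bins)
    perm <- rwr_iterate(W, F0, r, cfg$tol, cfg$max_iter)$heats
    prod_mat <- prod_mat * perm
  }
  obs <- stats::setNames(numeric(length(nodes)), nodes)
  common <- intersect(names(observed_products), nodes)
  obs[common] <- observed_products[common]
  p <- (1 + rowSums(prod_mat >= obs)) / (1 + B)
  stats::setNames(as.numeric(p), nodes)
}

#' Final signed scores across constructs
#'
#' Per gene, the mean of (i) the mean z-score over activating-construct
#' lines and (ii) the sign-flipped mean z-score over inhibiting-construct
#' lines; with a single construct present the (possibly flipped)
#' construct mean is returned unchanged. Genes absent from every line are
#' omitted; within a construct, the mean runs over the lines in which the
#' gene was measured.
#'
#' @param z_sets List of z-scored [kinase_set] objects (one per cell line).
#' @return Named numeric vector of final signed scores.
#' @export
final_signed_scores <- function(z_sets) {
  stopifnot(length(z_sets) > 0,
            all(vapply(z_sets, inherits, logical(1), "kinase_set")))
  constructs <- vapply(z_sets, function(s) s$construct, character(1))
  genes <- sort(unique(unlist(lapply(z_sets, function(s) names(s$scores)))))
  construct_mean <- function(which_sets) {
    if (length(which_sets) == 0L) return(NULL)
    m <- vapply(which_sets, function(s) unname(s$scores[genes]),
                numeric(length(genes)))
    m <- matrix(m, nrow = length(genes))
    rowMeans(m, na.rm = TRUE)
  }
  act <- construct_mean(z_sets[constructs == "ACTIVATING"])
  inh <- construct_mean(z_sets[constructs == "INHIBITING"])
  parts <- cbind(if (!is.null(act)) act else NULL,
                 if (!is.null(inh)) -inh else NULL)
  final <- rowMeans(parts, na.rm = TRUE)
  names(final) <- genes
  final[is.finite(final)]
}

#' Extract the focus-gene first-neighbor subnetwork
#'
#' Nodes are the focus gene plus its direct network neighbors that are
#' significant in at least one construct (and, when a kinase whitelist is
#' supplied, on the whitelist); edges are all network edges among those
#' nodes, i.e. the induced subgraph, capturing both spokes and
#' interconnections.
#'
#' @param net A [gene_network] containing the focus gene.
#' @param significant Character vector (or list of character vectors, one
#'   per construct, internally unioned) of significant genes.
#' @param focus Focus gene symbol; default `"PRKACA"`.
#' @param kinase_whitelist Optional character vector restricting neighbor
#'   membership (e.g. a kinome list).
#' @return List with elements `nodes` (character) and `edges` (data frame
#'   `source`, `target`).
#' @export
extract_subnetwork <- function(net, significant, focus = "PRKACA",
                               kinase_whitelist = NULL) {
  stopifnot(inherits(net, "gene_network"))
  focus <- toupper(focus)
  if (!(focus %in% network_nodes(net))) {
    stop("contract error: focus gene ", focus, " not in the network")
  }
  if (is.list(significant)) significant <- unlist(significant, use.names = FALSE)
  significant <- toupper(unique(as.character(significant)))
  nb <- igraph::neighbors(net$graph, focus)$name
  keep <- intersect(nb, significant)
  if (!is.null(kinase_whitelist)) {
    keep <- intersect(keep, toupper(kinase_whitelist))
  }
  nodes <- union(focus, keep)
  sub <- igraph::induced_subgraph(net$graph, nodes)
  el <- igraph::as_edgelist(sub, names = TRUE)
  if (nrow(el) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  } else {
    src <- pmin(el[, 1], el[, 2])
    tgt <- pmax(el[, 1], el[, 2])
    ord <- order(src, tgt)
    edges <- data.frame(source = src[ord], target = tgt[ord],
                        stringsAsFactors = FALSE)
  }
  list(nodes = sort(nodes), edges = edges)
}
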