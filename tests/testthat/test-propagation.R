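test_that("walk matrix is column-stochastic with isolated self-transitions", {
  net <- gene_network(rbind(c("A", "B")), nodes = "C")
  W <- build_walk_matrix(net)
  expect_equal(as.numeric(Matrix::colSums(W)), c(1, 1, 1))
  expect_equal(W["B", "A"], 1)
  expect_equal(W["A", "B"], 1)
  expect_equal(W["C", "C"], 1)

  tri <- build_walk_matrix(gene_network(rbind(c("A", "B"), c("B", "C"),
                                              c("A", "C"))))
  expect_true(all(abs(tri@x - 0.5) < 1e-15))
})

test_that("two-node propagation reproduces the closed-form heats", {
  net <- gene_network(rbind(c("A", "B")))
  f <- propagate(c(A = 1), net, propagation_config(restart_prob = 0.2))
  expect_equal(unname(f["A"]), 5 / 9, tolerance = 1e-10)
  expect_equal(unname(f["B"]), 4 / 9, tolerance = 1e-10)
})

test_that("restart-only limit returns the input and isolated heat persists", {
  net <- gene_network(rbind(c("A", "B")), nodes = "C")
  f <- propagate(c(A = 1, C = 0.4), net,
                 propagation_config(restart_prob = 1))
  expect_equal(unname(f[c("A", "B", "C")]), c(1, 0, 0.4))
  f2 <- propagate(c(C = 0.7), net, propagation_config())
  expect_equal(unname(f2["C"]), 0.7, tolerance = 1e-10)
})

test_that("input genes outside the network are dropped with a warning", {
  net <- gene_network(rbind(c("A", "B")))
  expect_warning(f <- propagate(c(A = 1, ZZZ = 2), net,
                                propagation_config()),
                 "absent from the network")
  expect_equal(sum(f), 1, tolerance = 1e-9)
})

test_that("iterative propagation matches the matrix-inverse solution", {
  for (s in 1:25) {
    net <- random_net(n = 10 + (s %% 40), p = 0.08, seed = 1000 + s)
    nodes <- network_nodes(net)
    set.seed(s)
    h0 <- stats::setNames(stats::runif(length(nodes)), nodes)
    f <- propagate(h0, net, propagation_config())
    oracle <- rwr_closed_form(net, h0, 0.2)
    expect_lt(max(abs(f[nodes] - oracle[nodes])), 1e-8)
  }
})

test_that("heat is conserved and propagation is monotone in its input", {
  for (s in 1:10) {
    net <- random_net(n = 30, p = 0.07, seed = 2000 + s)
    nodes <- network_nodes(net)
    set.seed(s)
    h0 <- stats::setNames(stats::runif(length(nodes)), nodes)
    f <- propagate(h0, net, propagation_config())
    expect_lt(abs(sum(f) - sum(h0)), 1e-9)
    bump <- h0
    g <- sample(nodes, 1)
    bump[g] <- bump[g] + 0.5
    f2 <- propagate(bump, net, propagation_config())
    # both runs sit within ~tol/r of their exact fixed points
    expect_true(all(f2 - f > -1e-8))
  }
})

test_that("non-convergence is reported as an error with the residual", {
  net <- gene_network(rbind(c("A", "B")))
  expect_error(propagate(c(A = 1), net,
                         propagation_config(tol = 1e-12, max_iter = 3)),
               "convergence error")
})

test_that("cross-line products multiply aligned heats", {
  h <- list(L1 = c(A = 0.2, B = 1), L2 = c(A = 0.5, B = 0))
  prod <- combine_lines(h)
  expect_equal(prod, c(A = 0.1, B = 0))
  expect_equal(combine_lines(h["L1"]), h$L1)
  expect_error(combine_lines(list()), "contract error")
  expect_error(combine_lines(list(L1 = c(A = 1), L2 = c(B = 1))),
               "different node sets")
})

test_that("permutation p-values are valid, seeded, and reproducible", {
  net <- random_net(25, 0.15, seed = 77)
  nodes <- network_nodes(net)
  set.seed(8)
  h <- list(L1 = stats::setNames(stats::runif(length(nodes)), nodes),
            L2 = stats::setNames(stats::runif(length(nodes)), nodes))
  cfg <- propagation_config(n_permutations = 100, seed = 99)
  heats <- lapply(h, function(x) {
    f <- propagate(x, net, cfg); attributes(f) <- list(names = names(f)); f
  })
  obs <- combine_lines(heats)
  p1 <- permutation_significance(obs, h, net, cfg)
  p2 <- permutation_significance(obs, h, net, cfg)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_true(all(p1 >= 1 / 101))
  pd <- permutation_significance(obs, h, net,
    propagation_config(n_permutations = 100, seed = 99,
                       permutation_scheme = "DEGREE_BINNED"))
  expect_true(all(pd > 0 & pd <= 1))
  expect_error(propagation_config(n_permutations = 50), "config error")
})

test_that("constant input heats make every permutation tie the observation", {
  net <- random_net(15, 0.2, seed = 5)
  nodes <- network_nodes(net)
  h <- list(L1 = stats::setNames(rep(0.3, length(nodes)), nodes))
  cfg <- propagation_config(n_permutations = 100, seed = 1)
  f <- propagate(h$L1, net, cfg)
  attributes(f) <- list(names = names(f))
  p <- permutation_significance(f, h, net, cfg)
  expect_true(all(p == 1))
})

test_that("final signed scores flip and average the inhibiting construct", {
  act <- tiny_set(c(A = 1, B = 0.7), construct = "ACTIVATING")
  inh <- tiny_set(c(A = -1, B = 1), construct = "INHIBITING")
  final <- final_signed_scores(list(act, inh))
  expect_equal(final[["A"]], 1)    # concordant: (1 + 1)/2
  expect_equal(final[["B"]], -0.15) # discordant: (0.7 - 1)/2
  only_act <- final_signed_scores(list(act))
  expect_equal(only_act, act$scores[names(only_act)])
  only_inh <- final_signed_scores(list(inh))
  expect_equal(only_inh[["A"]], 1)
})

test_that("exact negation of activating lines reduces to activating means", {
  set.seed(31)
  acts <- lapply(1:3, function(i) {
    tiny_set(stats::setNames(rnorm(40), paste0("G", 1:40)),
             cell_line = paste0("ACT", i), construct = "ACTIVATING")
  })
  inhs <- lapply(seq_along(acts), function(i) {
    s <- acts[[i]]
    s$cell_line <- paste0("INH", i); s$construct <- "INHIBITING"
    s$scores <- -s$scores
    s
  })
  final <- final_signed_scores(c(acts, inhs))
  act_mean <- rowMeans(sapply(acts, function(s) s$scores[names(final)]))
  expect_equal(final, act_mean[names(final)], tolerance = 1e-12)
})

test_that("subnetwork extraction keeps significant first neighbors only", {
  net <- gene_network(rbind(c("PRKACA", "N1"), c("PRKACA", "N2"),
                            c("PRKACA", "N3"), c("N1", "N2"),
                            c("N3", "FAR"), c("FAR", "FAR2")))
  sub <- extract_subnetwork(net, c("N1", "N2", "N3", "FAR2"))
  expect_setequal(sub$nodes, c("PRKACA", "N1", "N2", "N3"))
  expect_equal(nrow(sub$edges), 4L)  # 3 spokes + 1 interconnection

  none <- extract_subnetwork(net, character(0))
  expect_equal(none$nodes, "PRKACA")
  expect_equal(nrow(none$edges), 0L)

  wl <- extract_subnetwork(net, c("N1", "N2"), kinase_whitelist = "N1")
  expect_setequal(wl$nodes, c("PRKACA", "N1"))
  expect_error(extract_subnetwork(net, "N1", focus = "MISSING"),
               "contract error")
})
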