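test_that("kinase sets upper-case symbols and reject malformed scores", {
  s <- tiny_set(c(braf = 1, Gsk3b = -0.2))
  expect_setequal(names(s$scores), c("BRAF", "GSK3B"))
  expect_error(tiny_set(c(BRAF = 1, braf = 2)), "duplicate")
  expect_error(tiny_set(c(BRAF = NaN)), "non-finite")
  expect_error(tiny_set(numeric(0)), "empty")
})

test_that("score tables average duplicate genes and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tscore", "Braf\t1.0", "BRAF\t3.0"), path)
  expect_warning(
    s <- read_kinase_scores(path, "ABUNDANCE", "ACTIVATING", "L1"),
    "duplicate")
  expect_equal(s$scores, c(BRAF = 2.0))

  s2 <- tiny_set(c(AURKA = 0.5, GSK3B = -0.2))
  write_kinase_scores(s2, path)
  back <- read_kinase_scores(path, "ABUNDANCE", "ACTIVATING", "L1")
  expect_equal(sort(back$scores), sort(s2$scores))
  # idempotent ingest
  again <- read_kinase_scores(path, "ABUNDANCE", "ACTIVATING", "L1")
  expect_true(back == again)
})

test_that("score table format errors name the problem", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tvalue", "BRAF\t1.0"), path)
  expect_error(read_kinase_scores(path, "ABUNDANCE", "ACTIVATING", "L1"),
               "'score'")
  writeLines("gene\tscore", path)
  expect_error(read_kinase_scores(path, "ABUNDANCE", "ACTIVATING", "L1"),
               "empty-input")
  writeLines(c("gene\tscore", "BRAF\tabc"), path)
  expect_error(read_kinase_scores(path, "ABUNDANCE", "ACTIVATING", "L1"),
               "row 1")
})

test_that("network ingest collapses reversed edges and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A x B", "B x A"), path)
  net <- read_network(path, "SIF")
  expect_equal(nrow(network_edges(net)), 1L)
  expect_setequal(network_nodes(net), c("A", "B"))

  writeLines("A x A", path)
  expect_message(net2 <- read_network(path, "SIF"), "self-loop")
  expect_equal(network_nodes(net2), "A")
  expect_equal(nrow(network_edges(net2)), 0L)

  writeLines(c("A x B", "A x C", "A x D"), path)
  star <- read_network(path, "SIF")
  expect_equal(length(network_nodes(star)), 4L)
  expect_equal(nrow(network_edges(star)), 3L)
})

test_that("network parse errors carry line numbers and empty files error", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A x B", "A B"), path)
  expect_error(read_network(path, "SIF"), "line 2")
  writeLines(character(0), path)
  expect_error(read_network(path, "SIF"), "empty-input")
})

test_that("edge-list round trip preserves the network", {
  net <- gene_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")),
                      nodes = "d")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path, "EDGE_TSV")
  expect_equal(network_edges(back), network_edges(net))
})

test_that("plate, phosphosite and substrate-map validators enforce contracts", {
  df <- data.frame(protein = "VASP", residue = "S", position = 239,
                   log2fc = 1.2)
  expect_s3_class(phosphosite_table(df), "phosphosite_table")
  expect_error(phosphosite_table(rbind(df, df)), "duplicate")
  expect_error(phosphosite_table(transform(df, residue = "Q")), "S, T, Y")

  ks <- kinase_substrate_map(data.frame(
    kinase = "prkaca", protein = "vasp", residue = "S", position = 239))
  expect_equal(ks$kinase, "PRKACA")

  base <- data.frame(plate_id = "P1", replicate = 1,
                     well = sprintf("A%d", 1:10),
                     agent_id = sprintf("A%03d", 1:10),
                     agent_type = "COMPOUND", dose = NA_real_,
                     perturbed = FALSE, value = rnorm(10, 100, 5))
  expect_s3_class(plate_screen_table(base), "plate_screen_table")
  expect_error(plate_screen_table(rbind(base, base)), "duplicate")
  small <- base[1:6, ]
  expect_error(plate_screen_table(small), "fewer than 8")
})

test_that("time courses require strictly increasing times", {
  expect_error(time_course(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  tc <- time_course(c(0, 1, 2), c(1, 0.5, 0.25), label = "chase")
  expect_equal(length(tc$time), 3L)
})

test_that("node-table export round-trips final scores exactly", {
  sc <- synthetic_scenario(n_nodes = 60, module_size = 5, seed = 4)
  gen <- generate_network(sc)
  sets <- generate_kinase_datasets(gen, sc)
  res <- run_propagation_pipeline(sets, gen$network,
                                  propagation_config(n_permutations = 100,
                                                     seed = 4))
  node_path <- withr::local_tempfile(fileext = ".tsv")
  write_node_table(res, node_path)
  back <- read_node_table(node_path)
  common <- intersect(back$gene, names(res$final_scores))
  expect_equal(stats::setNames(back$final_score[match(common, back$gene)],
                               common),
               res$final_scores[common])
  expect_setequal(back$gene[back$in_subnetwork], res$subnetwork_nodes)
  edges <- utils::read.table(sub("\\.tsv$", "_edges.tsv", node_path),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  expect_equal(edges, res$subnetwork_edges,
               ignore_attr = TRUE)
})
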