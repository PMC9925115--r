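#' Run the kinome propagation pipeline on in-memory objects
#'
#' End-to-end core: per cell line, unit-max-normalize each platform, merge
#' the platforms, z-score across genes; propagate the absolute z-scores
#' over the network per line; multiply propagated heats across
#' same-construct lines; assess significance by permutation; average the
#' (sign-flipped for inhibiting lines) z-scores into final signed scores;
#' and extract the focus gene's first-neighbor subnetwork among significant
#' genes.
#'
#' Genes measured but absent from the network are dropped after z-scoring
#' (so the z distribution reflects all measured kinases); counts are
#' recorded in the result's `meta`. Permutation seeds are derived from
#' `cfg$seed` with a fixed per-construct offset, so the two construct nulls
#' are independent substreams and the whole run is reproducible.
#'
#' @param sets List of [kinase_set] objects covering one or two platforms
#'   per cell line.
#' @param net A [gene_network].
#' @param cfg A [propagation_config].
#' @param focus Focus gene symbol (default `"PRKACA"`).
#' @param kinase_whitelist Optional whitelist passed to
#'   [extract_subnetwork].
#' @return A `propagation_result`: list with `per_line_heats`,
#'   `input_heats`, `z_sets`, `products`, `p_values`, `significant`,
#'   `final_scores`, `subnetwork_nodes`, `subnetwork_edges`, `config`,
#'   `meta`.
#' @export
run_propagation_pipeline <- function(sets, net, cfg = propagation_config(),
                                     focus = "PRKACA",
                                     kinase_whitelist = NULL) {
  stopifnot(length(sets) > 0,
            all(vapply(sets, inherits, logical(1), "kinase_set")),
            inherits(net, "gene_network"),
            inherits(cfg, "propagation_config"))
  lines <- vapply(sets, function(s) s$cell_line, character(1))
  constructs <- vapply(sets, function(s) s$construct, character(1))
  line_construct <- tapply(constructs, lines, function(x) unique(x))
  if (any(lengths(line_construct) > 1)) {
    stop("contract error: a cell line carries more than one construct")
  }
  nodes <- network_nodes(net)

  # per line: normalize -> merge -> z-score
  z_sets <- list()
  for (line in sort(unique(lines))) {
    line_sets <- sets[lines == line]
    ord <- order(vapply(line_sets, function(s) s$platform, character(1)))
    line_sets <- lapply(line_sets[ord], normalize_unit_max)
    merged <- if (length(line_sets) == 1L) {
      line_sets[[1]]
    } else if (length(line_sets) == 2L) {
      merge_platforms(line_sets[[1]], line_sets[[2]])
    } else {
      stop("contract error: more than two platforms for cell line ", line)
    }
    z_sets[[line]] <- zscore_within_line(merged)
  }

  # per line: propagate |z| restricted to the network
  per_line_heats <- list()
  input_heats <- list()
  dropped <- integer(0)
  iterations <- integer(0)
  for (line in names(z_sets)) {
    z <- z_sets[[line]]$scores
    in_net <- names(z) %in% nodes
    dropped[line] <- sum(!in_net)
    h0 <- abs(z[in_net])
    input_heats[[line]] <- h0
    heats <- propagate(h0, net, cfg)
    iterations[line] <- attr(heats, "iterations")
    attributes(heats) <- list(names = names(heats))
    per_line_heats[[line]] <- heats
  }

  # per construct: products and permutation p-values
  construct_of <- vapply(z_sets, function(s) s$construct, character(1))
  products <- list()
  p_values <- list()
  significant <- list()
  for (con in intersect(c("ACTIVATING", "INHIBITING"), unique(construct_of))) {
    line_names <- names(z_sets)[construct_of == con]
    products[[con]] <- combine_lines(per_line_heats[line_names])
    cfg_con <- cfg
    cfg_con$seed <- cfg$seed +
      match(con, c("ACTIVATING", "INHIBITING")) * 1000L
    p_values[[con]] <- permutation_significance(
      products[[con]], input_heats[line_names], net, cfg_con)
    significant[[con]] <- names(p_values[[con]])[p_values[[con]] < cfg$p_threshold]
  }

  final_scores <- final_signed_scores(unname(z_sets))
  sub <- extract_subnetwork(net, significant, focus = focus,
                            kinase_whitelist = kinase_whitelist)
  structure(list(
    per_line_heats = per_line_heats,
    input_heats = input_heats,
    z_sets = z_sets,
    products = products,
    p_values = p_values,
    significant = significant,
    final_scores = final_scores,
    subnetwork_nodes = sub$nodes,
    subnetwork_edges = sub$edges,
    config = cfg,
    meta = list(dropped_genes = dropped, iterations = iterations,
                focus = toupper(focus),
                n_lines = length(z_sets))
  ), class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result> %d line(s); significant: %s; subnetwork: %d nodes / %d edges\n",
    x$meta$n_lines,
    paste(sprintf("%s=%d", names(x$significant),
                  lengths(x$significant)), collapse = ", "),
    length(x$subnetwork_nodes), nrow(x$subnetwork_edges)))
  invisible(x)
}

#' Read a run manifest from YAML or JSON
#'
#' @param path Manifest file (`.yaml`/`.yml` or `.json`).
#' @return Manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported manifest format: ", path)
  }
}

#' Validate a run manifest
#'
#' Checks file existence, tag completeness and configuration ranges
#' without mutating any state.
#'
#' @param manifest Manifest list (see [run_pipeline]).
#' @return Character vector of problems; empty when valid.
#' @export
validate_manifest <- function(manifest) {
  problems <- character(0)
  if (is.null(manifest$network$path)) {
    problems <- c(problems, "network.path is missing")
  } else if (!file.exists(manifest$network$path)) {
    problems <- c(problems, paste0("network file not found: ",
                                   manifest$network$path))
  }
  if (!is.null(manifest$network$dialect) &&
      !manifest$network$dialect %in% c("SIF", "EDGE_TSV")) {
    problems <- c(problems, "network.dialect must be SIF or EDGE_TSV")
  }
  st <- manifest$score_tables
  if (is.null(st) || length(st) == 0L) {
    problems <- c(problems, "score_tables is empty")
  } else {
    for (i in seq_along(st)) {
      e <- st[[i]]
      for (field in c("path", "platform", "construct", "cell_line")) {
        if (is.null(e[[field]])) {
          problems <- c(problems,
                        sprintf("score_tables[%d].%s is missing", i, field))
        }
      }
      if (!is.null(e$path) && !file.exists(e$path)) {
        problems <- c(problems, paste0("score table not found: ", e$path))
      }
      if (!is.null(e$platform) &&
          !e$platform %in% c("ACTIVITY_INFERENCE", "ABUNDANCE")) {
        problems <- c(problems,
                      sprintf("score_tables[%d].platform invalid: %s", i,
                              e$platform))
      }
      if (!is.null(e$construct) &&
          !e$construct %in% c("ACTIVATING", "INHIBITING")) {
        problems <- c(problems,
                      sprintf("score_tables[%d].construct invalid: %s", i,
                              e$construct))
      }
    }
  }
  cfg <- manifest$config
  if (!is.null(cfg$restart_prob) &&
      (cfg$restart_prob <= 0 || cfg$restart_prob > 1)) {
    problems <- c(problems, "config.restart_prob must lie in (0, 1]")
  }
  if (!is.null(cfg$n_permutations) && cfg$n_permutations < 100) {
    problems <- c(problems, "config.n_permutations must be >= 100")
  }
  if (!is.null(cfg$p_threshold) &&
      (cfg$p_threshold <= 0 || cfg$p_threshold >= 1)) {
    problems <- c(problems, "config.p_threshold must lie in (0, 1)")
  }
  problems
}

manifest_config <- function(manifest) {
  cfg <- manifest$config
  if (is.null(cfg)) cfg <- list()
  do.call(propagation_config, cfg[intersect(names(cfg), names(formals(propagation_config)))])
}

#' Run the full pipeline from a manifest
#'
#' Reads the network and all tagged score tables, runs
#' [run_propagation_pipeline], and (when `out_dir` is set) writes the
#' Cytoscape-ready node/edge tables plus a JSON run report (seed,
#' permutation count, convergence iterations, dropped-gene counts).
#' Re-running with the same manifest reproduces the outputs byte for byte.
#'
#' @param manifest Manifest list or path to a YAML/JSON manifest with
#'   fields `network` (`path`, `dialect`), `score_tables` (list of `path`,
#'   `platform`, `construct`, `cell_line`), optional `config` (arguments of
#'   [propagation_config]), optional `focus_gene`, optional `out_dir`.
#' @return The `propagation_result`, invisibly when writing outputs.
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  problems <- validate_manifest(manifest)
  if (length(problems)) {
    stop("invalid manifest:\n  - ", paste(problems, collapse = "\n  - "))
  }
  net <- read_network(manifest$network$path,
                      dialect = manifest$network$dialect %||% "EDGE_TSV")
  sets <- lapply(manifest$score_tables, function(e) {
    read_kinase_scores(e$path, platform = e$platform,
                       construct = e$construct, cell_line = e$cell_line,
                       dataset_id = e$dataset_id %||% basename(e$path))
  })
  cfg <- manifest_config(manifest)
  result <- run_propagation_pipeline(
    sets, net, cfg,
    focus = manifest$focus_gene %||% "PRKACA",
    kinase_whitelist = manifest$kinase_whitelist)
  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_node_table(result, file.path(manifest$out_dir, "nodes.tsv"),
                     file.path(manifest$out_dir, "edges.tsv"))
    report <- list(
      seed = cfg$seed,
      n_permutations = cfg$n_permutations,
      restart_prob = cfg$restart_prob,
      p_threshold = cfg$p_threshold,
      permutation_scheme = cfg$permutation_scheme,
      iterations = as.list(result$meta$iterations),
      dropped_genes = as.list(result$meta$dropped_genes),
      n_significant = as.list(lengths(result$significant)),
      subnetwork_nodes = length(result$subnetwork_nodes)
    )
    jsonlite::write_json(report, file.path(manifest$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(result))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete synthetic input bundle
#'
#' Generates a scenario's network and kinase datasets, writes every table
#' as TSV plus a YAML manifest wired to them, and serializes the scenario
#' itself alongside. The manifest can be fed directly to [run_pipeline].
#'
#' @param sc A [synthetic_scenario].
#' @param dir Output directory (created if needed).
#' @param config Optional list of [propagation_config] overrides stored in
#'   the manifest.
#' @return Path to the written manifest, invisibly; the planted module is
#'   written to `module.txt` for scoring.
#' @export
write_synthetic_bundle <- function(sc, dir, config = list()) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_network(sc)
  sets <- generate_kinase_datasets(gen, sc)
  net_path <- file.path(dir, "network.tsv")
  write_network(gen$network, net_path)
  entries <- lapply(names(sets), function(id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    write_kinase_scores(sets[[id]], p)
    list(path = p, platform = sets[[id]]$platform,
         construct = sets[[id]]$construct,
         cell_line = sets[[id]]$cell_line, dataset_id = id)
  })
  manifest <- list(network = list(path = net_path, dialect = "EDGE_TSV"),
                   score_tables = entries,
                   focus_gene = sc$focus_gene,
                   config = config,
                   out_dir = file.path(dir, "out"))
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  yaml::write_yaml(unclass(sc), file.path(dir, "scenario.yaml"))
  writeLines(gen$module, file.path(dir, "module.txt"))
  invisible(manifest_path)
}
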