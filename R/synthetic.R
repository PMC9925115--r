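#' Synthetic benchmark scenario
#'
#' Parameterization of a generated benchmark mirroring the study design:
#' 3 cell lines with an activating construct and 2 with an inhibiting
#' construct, each measured on two platforms with partial overlapping
#' coverage, and a planted module of truly responsive kinases wired to the
#' focus gene. Every generator is a pure function of (scenario, seed).
#'
#' @param n_nodes Number of network genes (default 300).
#' @param topology `"ERDOS_RENYI"` or `"SMALL_WORLD"`.
#' @param edge_param Expected mean degree (default 8).
#' @param focus_gene Focus node symbol (default `"PRKACA"`).
#' @param module_size Planted module size, all adjacent to the focus
#'   (default 15).
#' @param n_activating_lines,n_inhibiting_lines Cell-line counts (defaults
#'   3 and 2, the study design).
#' @param effect Planted effect size in noise-sd units (default 2).
#' @param noise_sd Gaussian measurement noise sd (default 1).
#' @param detect_prob Probability that a platform observes a given kinase
#'   (default 0.7).
#' @param seed Integer seed.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_nodes = 300L,
                               topology = c("ERDOS_RENYI", "SMALL_WORLD"),
                               edge_param = 8,
                               focus_gene = "PRKACA",
                               module_size = 15L,
                               n_activating_lines = 3L,
                               n_inhibiting_lines = 2L,
                               effect = 2.0,
                               noise_sd = 1.0,
                               detect_prob = 0.7,
                               seed = 1L) {
  topology <- match.arg(topology)
  if (module_size >= n_nodes) stop("config error: module_size must be < n_nodes")
  if (detect_prob <= 0 || detect_prob > 1) {
    stop("config error: detect_prob must lie in (0, 1]")
  }
  if (noise_sd <= 0) stop("config error: noise_sd must be positive")
  if (n_activating_lines + n_inhibiting_lines < 1) {
    stop("config error: need at least one cell line")
  }
  structure(list(n_nodes = as.integer(n_nodes), topology = topology,
                 edge_param = edge_param, focus_gene = toupper(focus_gene),
                 module_size = as.integer(module_size),
                 n_activating_lines = as.integer(n_activating_lines),
                 n_inhibiting_lines = as.integer(n_inhibiting_lines),
                 effect = effect, noise_sd = noise_sd,
                 detect_prob = detect_prob, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a random gene network with a planted focus-adjacent module
#'
#' Background topology is Erdos-Renyi or Watts-Strogatz; the focus gene is
#' then wired to every planted module member, so recovery of the module by
#' propagation is well-posed. Module labels are returned for scoring.
#'
#' @param sc A [synthetic_scenario].
#' @return List with `network` (a [gene_network]), `module` (character
#'   vector of planted member symbols), and `focus`.
#' @export
generate_network <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  set.seed(sc$seed)
  n <- sc$n_nodes
  g <- switch(sc$topology,
    ERDOS_RENYI = igraph::sample_gnp(n, p = min(1, sc$edge_param / (n - 1))),
    SMALL_WORLD = igraph::sample_smallworld(1, n,
                                            nei = max(1, round(sc$edge_param / 2)),
                                            p = 0.05))
  names_all <- c(sc$focus_gene,
                 sprintf("KIN%03d", seq_len(n - 1)))
  igraph::V(g)$name <- names_all
  module <- character(0)
  if (sc$module_size > 0) {
    module <- sample(names_all[-1], sc$module_size)
    new_edges <- rbind(sc$focus_gene, module)
    g <- igraph::add_edges(g, as.vector(new_edges))
  }
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  net <- gene_network(el, nodes = names_all)
  list(network = net, module = sort(module), focus = sc$focus_gene)
}

#' Generate per-line, per-platform kinase measurement sets
#'
#' For each cell line and each of the two platforms, every gene is observed
#' with probability `detect_prob`; observed scores are
#' `sign_g * effect * c + N(0, noise_sd)` where `sign_g` is a fixed per-gene
#' sign for module members (0 for background genes) and `c` is +1 for
#' activating and -1 for inhibiting lines.
#'
#' @param net_gen Output of [generate_network].
#' @param sc A [synthetic_scenario].
#' @return Named list of [kinase_set] objects (2 platforms per line).
#' @export
generate_kinase_datasets <- function(net_gen, sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  genes <- network_nodes(net_gen$network)
  genes <- setdiff(genes, net_gen$focus)  # the focus itself is the query
  set.seed(sc$seed + 1L)
  sign_g <- stats::setNames(numeric(length(genes)), genes)
  if (length(net_gen$module)) {
    sign_g[net_gen$module] <- sample(c(-1, 1), length(net_gen$module),
                                     replace = TRUE)
  }
  lines <- c(
    stats::setNames(rep("ACTIVATING", sc$n_activating_lines),
                    sprintf("ACT%d", seq_len(sc$n_activating_lines))),
    stats::setNames(rep("INHIBITING", sc$n_inhibiting_lines),
                    sprintf("INH%d", seq_len(sc$n_inhibiting_lines)))
  )
  out <- list()
  for (line in names(lines)) {
    cc <- if (lines[[line]] == "ACTIVATING") 1 else -1
    for (platform in c("ACTIVITY_INFERENCE", "ABUNDANCE")) {
      seen <- stats::runif(length(genes)) <= sc$detect_prob
      if (!any(seen)) next
      mu <- sign_g[seen] * sc$effect * cc
      score <- mu + stats::rnorm(sum(seen), 0, sc$noise_sd)
      id <- paste(line, platform, sep = "_")
      out[[id]] <- kinase_set(stats::setNames(score, genes[seen]),
                              dataset_id = id, cell_line = line,
                              construct = lines[[line]], platform = platform)
    }
  }
  out
}

#' Generate a synthetic kinase-substrate map
#'
#' Disjoint substrate sets: each kinase gets `substrates_per_kinase`
#' dedicated substrate sites on pseudo-proteins.
#'
#' @param n_kinases Number of kinases.
#' @param substrates_per_kinase Sites per kinase (default 10).
#' @param seed Integer seed.
#' @return A [kinase_substrate_map].
#' @export
synthetic_ks_map <- function(n_kinases, substrates_per_kinase = 10, seed = 1L) {
  set.seed(seed)
  kin <- sprintf("KIN%03d", seq_len(n_kinases))
  df <- do.call(rbind, lapply(seq_along(kin), function(i) {
    data.frame(kinase = kin[i],
               protein = sprintf("SUB%03d_%02d", i,
                                 seq_len(substrates_per_kinase)),
               residue = sample(c("S", "T", "Y"), substrates_per_kinase,
                                replace = TRUE),
               position = sample.int(900, substrates_per_kinase) + 10L,
               stringsAsFactors = FALSE)
  }))
  kinase_substrate_map(df)
}

#' Generate a phosphosite table with planted kinase activities
#'
#' Substrate sites of a kinase with activity shift `delta` are drawn
#' `N(delta * noise_sd, noise_sd)`; all other mapped sites and
#' `n_background` unmapped background sites are `N(0, noise_sd)`. A site
#' shared by several shifted kinases receives the mean of their shifts.
#'
#' @param ksmap A [kinase_substrate_map].
#' @param active Named numeric vector of activity shifts (in noise-sd
#'   units) per kinase; may be empty.
#' @param sc A [synthetic_scenario] (supplies `noise_sd` and `seed`).
#' @param n_background Number of unmapped background sites (default 200).
#' @return A [phosphosite_table].
#' @export
generate_phosphosites <- function(ksmap, active, sc, n_background = 200L) {
  stopifnot(inherits(ksmap, "kinase_substrate_map"),
            inherits(sc, "synthetic_scenario"))
  set.seed(sc$seed + 2L)
  sites <- unique(as.data.frame(ksmap)[, c("protein", "residue", "position")])
  key <- paste(sites$protein, sites$residue, sites$position, sep = "_")
  shift <- stats::setNames(numeric(nrow(sites)), key)
  count <- stats::setNames(numeric(nrow(sites)), key)
  if (length(active)) {
    names(active) <- toupper(names(active))
    for (k in names(active)) {
      sub_k <- ksmap$kinase == k
      kk <- paste(ksmap$protein[sub_k], ksmap$residue[sub_k],
                  ksmap$position[sub_k], sep = "_")
      shift[kk] <- shift[kk] + active[[k]]
      count[kk] <- count[kk] + 1
    }
    shift <- ifelse(count > 0, shift / pmax(count, 1), 0)
  }
  bg <- data.frame(protein = sprintf("BG%04d", seq_len(n_background)),
                   residue = "S", position = 1L, stringsAsFactors = FALSE)
  all_sites <- rbind(sites, bg)
  mu <- c(shift * sc$noise_sd, numeric(n_background))
  all_sites$log2fc <- stats::rnorm(nrow(all_sites), mu, sc$noise_sd)
  phosphosite_table(all_sites)
}

well_names_384 <- function(n) {
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  paste0(rows, cols)[seq_len(n)]
}

#' Generate a synthetic 384-well plate screen
#'
#' One plate per replicate: baseline well values are
#' `N(baseline_mean, baseline_sd)`, planted agents are shifted by
#' `effect * baseline_sd`, and each plate then receives a random
#' multiplicative scale (uniform on `plate_scale_range`) and additive shift
#' (`N(0, plate_shift_sd * baseline_mean)`) emulating batch effects that
#' within-plate z-scoring must remove.
#'
#' @param n_agents Number of screened agents (default 352, plus controls to
#'   fill 384 wells).
#' @param planted Named numeric vector of planted effects in plate-sd units
#'   (e.g. `c(A001 = -3)`); may be empty.
#' @param n_replicates Biological replicates / plates (default 3).
#' @param plate_shift_sd Additive plate shift sd as a fraction of
#'   `baseline_mean` (default 0.1).
#' @param plate_scale_range Range of the multiplicative plate scale
#'   (default `c(0.8, 1.25)`).
#' @param seed Integer seed.
#' @param agent_type `"COMPOUND"` or `"SIRNA"`.
#' @param perturbed Value of the perturbation flag column (default
#'   `FALSE`).
#' @param baseline_mean,baseline_sd Baseline readout location and spread.
#' @return A [plate_screen_table].
#' @export
generate_plate_screen <- function(n_agents = 352L, planted = numeric(0),
                                  n_replicates = 3L, plate_shift_sd = 0.1,
                                  plate_scale_range = c(0.8, 1.25),
                                  seed = 1L, agent_type = "COMPOUND",
                                  perturbed = FALSE,
                                  baseline_mean = 1000, baseline_sd = 100) {
  if (n_agents > 352L) stop("config error: at most 352 agents per 384-well plate")
  agents <- sprintf("A%03d", seq_len(n_agents))
  if (length(planted)) {
    if (!all(names(planted) %in% agents)) {
      stop("config error: planted agents not among screened agents")
    }
  }
  n_controls <- 384L - n_agents
  set.seed(seed)
  out <- vector("list", n_replicates)
  eff <- stats::setNames(numeric(n_agents), agents)
  if (length(planted)) eff[names(planted)] <- planted
  for (r in seq_len(n_replicates)) {
    ids <- c(agents, sprintf("CTRL%02d", seq_len(n_controls)))
    types <- c(rep(agent_type, n_agents), rep("CONTROL", n_controls))
    mu <- baseline_mean + c(eff, numeric(n_controls)) * baseline_sd
    raw <- stats::rnorm(384L, mu, baseline_sd)
    scale_r <- stats::runif(1, plate_scale_range[1], plate_scale_range[2])
    shift_r <- stats::rnorm(1, 0, plate_shift_sd * baseline_mean)
    val <- pmax(scale_r * raw + shift_r, 1e-6)
    out[[r]] <- data.frame(plate_id = "P1", replicate = r,
                           well = well_names_384(384L), agent_id = ids,
                           agent_type = types, dose = NA_real_,
                           perturbed = perturbed, value = val,
                           stringsAsFactors = FALSE)
  }
  plate_screen_table(do.call(rbind, out))
}

#' Generate logistic growth curves
#'
#' Logistic confluence curves sampled every `interval` hours for
#' `duration` hours (default: 120 h at 2 h cadence, 61 points) with
#' multiplicative log-normal noise.
#'
#' @param rates Named numeric vector of per-hour logistic growth rates
#'   (>= 0), one curve per name.
#' @param duration,interval Time span and cadence in hours.
#' @param noise_sd Log-scale noise sd (default 0.05); 0 gives noiseless
#'   curves.
#' @param seed Integer seed.
#' @param initial,capacity Initial and plateau confluence (defaults 5 and
#'   100 percent).
#' @return Named list of [time_course] objects.
#' @export
generate_growth_curves <- function(rates, duration = 120, interval = 2,
                                   noise_sd = 0.05, seed = 1L,
                                   initial = 5, capacity = 100) {
  if (any(rates < 0)) stop("config error: growth rates must be >= 0")
  set.seed(seed)
  t <- seq(0, duration, by = interval)
  lapply(stats::setNames(names(rates), names(rates)), function(lab) {
    r <- rates[[lab]]
    v <- capacity / (1 + ((capacity - initial) / initial) * exp(-r * t))
    if (noise_sd > 0) v <- v * exp(stats::rnorm(length(t), 0, noise_sd))
    time_course(t, v, label = lab)
  })
}

#' Score planted-module recovery of a propagation result
#'
#' The method's module-membership call is the extracted subnetwork: direct
#' network neighbors of the focus gene that are significant in at least one
#' construct. Predicted members are therefore the result's subnetwork nodes
#' with the focus gene itself excluded (it is the query, not a module
#' member).
#'
#' @param result A `propagation_result` (see [run_propagation_pipeline]),
#'   or directly a character vector of predicted member symbols.
#' @param module Character vector of planted module members.
#' @param focus Focus gene symbol; taken from the result's metadata when a
#'   result object is given.
#' @return Named numeric vector `c(recall = , precision = )`; precision is
#'   `NA` when nothing is predicted.
#' @export
module_recovery <- function(result, module, focus = NULL) {
  if (inherits(result, "propagation_result")) {
    if (is.null(focus)) focus <- result$meta$focus
    pred <- result$subnetwork_nodes
  } else {
    pred <- as.character(result)
  }
  if (is.null(focus)) stop("focus must be supplied with a plain prediction")
  pred <- setdiff(unique(toupper(pred)), toupper(focus))
  tp <- length(intersect(pred, toupper(module)))
  c(recall = tp / length(module),
    precision = if (length(pred)) tp / length(pred) else NA_real_)
}
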