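#' Kinase measurement set
#'
#' A single platform x cell line x construct table of per-kinase scores.
#' Scores are effect sizes for the activity-inference platform and log2 fold
#' changes for the kinase-abundance (inhibitor-bead) platform. Gene symbols
#' are upper-cased on construction and must be unique; scores must be finite.
#'
#' @param scores Named numeric vector, names are gene symbols.
#' @param dataset_id Free-text identifier of the dataset.
#' @param cell_line Cell line name.
#' @param construct One of `"ACTIVATING"` (inducible PKA catalytic subunit)
#'   or `"INHIBITING"` (inducible dominant-negative regulatory subunit).
#' @param platform One of `"ACTIVITY_INFERENCE"`, `"ABUNDANCE"`, or
#'   `"MERGED"` (the union of the two platforms for one line).
#' @param zscored Logical; `TRUE` once scores have been standardized across
#'   genes within the line.
#' @param allow_empty Permit a zero-gene set (used by inference when no
#'   kinase passes the substrate threshold).
#' @return An object of class `kinase_set`.
#' @export
kinase_set <- function(scores, dataset_id, cell_line, construct, platform,
                       zscored = FALSE, allow_empty = FALSE) {
  construct <- match.arg(construct, c("ACTIVATING", "INHIBITING"))
  platform <- match.arg(platform, c("ACTIVITY_INFERENCE", "ABUNDANCE", "MERGED"))
  if (!is.numeric(scores)) stop("scores must be a named numeric vector")
  if (length(scores) == 0L && !allow_empty) {
    stop("empty kinase set: no scores supplied")
  }
  if (length(scores) > 0L) {
    if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
      stop("all scores must carry gene-symbol names")
    }
    names(scores) <- toupper(names(scores))
    if (anyDuplicated(names(scores))) {
      stop("duplicate gene symbols in kinase set: ",
           paste(unique(names(scores)[duplicated(names(scores))]), collapse = ", "))
    }
    if (any(!is.finite(scores))) stop("non-finite scores in kinase set")
  }
  structure(
    list(scores = scores, dataset_id = as.character(dataset_id),
         cell_line = as.character(cell_line), construct = construct,
         platform = platform, zscored = isTRUE(zscored)),
    class = "kinase_set"
  )
}

#' @export
print.kinase_set <- function(x, ...) {
  cat(sprintf("<kinase_set> %s | %s | %s | %s | %d genes%s\n",
              x$dataset_id, x$cell_line, x$construct, x$platform,
              length(x$scores), if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' @export
`==.kinase_set` <- function(e1, e2) {
  identical(e1$cell_line, e2$cell_line) &&
    identical(e1$construct, e2$construct) &&
    identical(e1$platform, e2$platform) &&
    identical(sort(names(e1$scores)), sort(names(e2$scores))) &&
    isTRUE(all.equal(e1$scores[sort(names(e1$scores))],
                     e2$scores[sort(names(e2$scores))]))
}

#' Undirected gene interaction network
#'
#' Simple undirected graph over upper-cased gene symbols; the propagation
#' substrate. Self-loops are dropped on construction, duplicate and reversed
#' edges are collapsed, and isolated nodes are retained.
#'
#' @param edges Two-column character matrix or data frame of endpoints.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   nodes.
#' @return An object of class `gene_network` wrapping an igraph graph.
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  edges <- toupper(edges)
  nodes <- toupper(unique(c(as.vector(edges), as.character(nodes))))
  if (length(nodes) == 0L) stop("empty network: no nodes")
  self <- edges[, 1] == edges[, 2]
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped at network ingest")
    edges <- edges[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' @rdname gene_network
#' @param net A `gene_network`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::V(net$graph)$name
}

#' @rdname gene_network
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  if (nrow(el) == 0L) {
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  src <- pmin(el[, 1], el[, 2])
  tgt <- pmax(el[, 1], el[, 2])
  ord <- order(src, tgt)
  data.frame(source = src[ord], target = tgt[ord], stringsAsFactors = FALSE)
}

#' Phosphosite log2 fold-change table
#'
#' One row per measured phosphorylation site: protein symbol, residue
#' (S/T/Y), sequence position, and log2 fold change versus control.
#' Site triples must be unique and fold changes finite.
#'
#' @param df Data frame with columns `protein`, `residue`, `position`,
#'   `log2fc`.
#' @return The validated data frame with class `phosphosite_table`.
#' @export
phosphosite_table <- function(df) {
  need <- c("protein", "residue", "position", "log2fc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phosphosite table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$protein <- toupper(as.character(df$protein))
  df$residue <- toupper(as.character(df$residue))
  if (nrow(df) == 0L) stop("empty phosphosite table")
  if (!all(df$residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y")
  }
  df$position <- as.integer(df$position)
  if (any(is.na(df$position)) || any(df$position < 1L)) {
    stop("position must be a positive integer")
  }
  if (any(!is.finite(df$log2fc))) stop("non-finite log2fc values")
  key <- paste(df$protein, df$residue, df$position, sep = "_")
  if (anyDuplicated(key)) {
    stop("duplicate phosphosite(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("phosphosite_table", "data.frame")
  df
}

#' Kinase-to-substrate map
#'
#' Long-format map from kinase gene symbol to substrate phosphosites
#' (protein, residue, position), standing in for curated kinase-substrate
#' knowledge bases.
#'
#' @param df Data frame with columns `kinase`, `protein`, `residue`,
#'   `position`.
#' @return The validated data frame with class `kinase_substrate_map`.
#' @export
kinase_substrate_map <- function(df) {
  need <- c("kinase", "protein", "residue", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("kinase-substrate map missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$kinase <- toupper(as.character(df$kinase))
  df$protein <- toupper(as.character(df$protein))
  df$residue <- toupper(as.character(df$residue))
  if (!all(df$residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y")
  }
  df$position <- as.integer(df$position)
  if (any(is.na(df$position)) || any(df$position < 1L)) {
    stop("position must be a positive integer")
  }
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("kinase_substrate_map", "data.frame")
  df
}

#' Long-format plate screen table
#'
#' Well-level measurements from 384-well screens: one row per
#' (plate, replicate, well) with the screened agent, its type
#' (compound / siRNA / control), optional dose, a perturbation flag
#' (e.g. doxycycline induction), and the readout (luminescence or percent
#' confluence).
#'
#' @param df Data frame with columns `plate_id`, `replicate`, `well`,
#'   `agent_id`, `agent_type`, `dose`, `perturbed`, `value`.
#' @return The validated data frame with class `plate_screen_table`.
#' @export
plate_screen_table <- function(df) {
  need <- c("plate_id", "replicate", "well", "agent_id", "agent_type",
            "dose", "perturbed", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate screen table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  if (nrow(df) == 0L) stop("empty plate screen table")
  df$agent_type <- toupper(as.character(df$agent_type))
  if (!all(df$agent_type %in% c("COMPOUND", "SIRNA", "CONTROL"))) {
    stop("agent_type must be COMPOUND, SIRNA or CONTROL")
  }
  df$replicate <- as.integer(df$replicate)
  df$perturbed <- as.logical(df$perturbed)
  if (any(!is.finite(df$value))) stop("non-finite well values")
  if (any(df$value < 0)) stop("negative well values")
  key <- paste(df$plate_id, df$replicate, df$well, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, replicate, well): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  plate_key <- paste(df$plate_id, df$replicate, sep = "|")
  n_nc <- tapply(df$agent_type != "CONTROL", plate_key, sum)
  if (any(n_nc < 8L)) {
    stop("plate(s) with fewer than 8 non-control wells: ",
         paste(names(n_nc)[n_nc < 8L], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("plate_screen_table", "data.frame")
  df
}

#' Time course
#'
#' Ordered (time in hours, value) pairs, used for growth-curve AUC and
#' decay-kinetics fitting. Times must be strictly increasing.
#'
#' @param time Numeric vector of non-negative times in hours.
#' @param value Numeric vector of measurements.
#' @param label Free-text label for the condition.
#' @return An object of class `time_course`.
#' @export
time_course <- function(time, value, label = "") {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (any(!is.finite(time)) || any(!is.finite(value))) {
    stop("non-finite time-course entries")
  }
  if (any(time < 0)) stop("negative times")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 label = as.character(label)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> '%s': %d points over [%g, %g] h\n",
              x$label, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}
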