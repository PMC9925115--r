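read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("format error in ", path, ": missing required column(s) ",
         paste(sprintf("'%s'", miss), collapse = ", "))
  }
  df
}

num_col <- function(df, col, path) {
  suppressWarnings(x <- as.numeric(df[[col]]))
  bad <- which(is.na(x) & !(df[[col]] %in% c("NA", "")))
  if (length(bad)) {
    stop("parse error in ", path, ": non-numeric '", col,
         "' at data row ", bad[1], " (value '", df[[col]][bad[1]], "')")
  }
  x
}

#' Read a kinase score table
#'
#' Reads a tab-separated table with header columns `gene` and `score` into a
#' [kinase_set]. Gene symbols are upper-cased; rows that collapse onto the
#' same symbol are averaged with a warning.
#'
#' @param path Path to the TSV file.
#' @param platform,construct,cell_line,dataset_id Annotations for the set;
#'   see [kinase_set]. `dataset_id` defaults to the file name.
#' @return A [kinase_set].
#' @export
read_kinase_scores <- function(path, platform, construct, cell_line,
                               dataset_id = basename(path)) {
  df <- read_tsv_checked(path, c("gene", "score"))
  if (nrow(df) == 0L) stop("empty-input error: ", path, " has no data rows")
  score <- num_col(df, "score", path)
  gene <- toupper(df$gene)
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    warning(length(dup), " duplicate gene(s) averaged in ", path, ": ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    score <- tapply(score, gene, mean)
    gene <- names(score)
    score <- as.numeric(score)
  }
  names(score) <- gene
  kinase_set(score, dataset_id = dataset_id, cell_line = cell_line,
             construct = construct, platform = platform)
}

#' Write a kinase score table
#'
#' @param set A [kinase_set].
#' @param path Output TSV path (columns `gene`, `score`).
#' @export
write_kinase_scores <- function(set, path) {
  stopifnot(inherits(set, "kinase_set"))
  df <- data.frame(gene = names(set$scores), score = unname(set$scores),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene interaction network
#'
#' Supports the SIF dialect (three whitespace-separated fields per line:
#' source, interaction type, target; no header) and a two-column tab-separated
#' edge list with header columns `source` and `target`. The result is an
#' undirected simple graph: self-loops are dropped (count reported) and
#' duplicate or reversed edges collapsed.
#'
#' @param path Path to the network file.
#' @param dialect `"SIF"` or `"EDGE_TSV"`.
#' @return A [gene_network].
#' @export
read_network <- function(path, dialect = c("SIF", "EDGE_TSV")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "SIF") {
    lines <- readLines(path, warn = FALSE)
    lines_keep <- which(nzchar(trimws(lines)))
    if (length(lines_keep) == 0L) stop("empty-input error: ", path)
    parts <- strsplit(trimws(lines[lines_keep]), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf != 3L)) {
      bad <- lines_keep[which(nf != 3L)[1]]
      stop("parse error in ", path, ": expected 3 fields at line ", bad)
    }
    m <- do.call(rbind, parts)
    edges <- m[, c(1, 3), drop = FALSE]
  } else {
    df <- read_tsv_checked(path, c("source", "target"))
    if (nrow(df) == 0L) stop("empty-input error: ", path, " has no data rows")
    edges <- as.matrix(df[, c("source", "target")])
  }
  gene_network(edges)
}

#' Write a gene interaction network as a two-column edge list
#'
#' @param net A [gene_network].
#' @param path Output TSV path (header `source`, `target`). Isolated nodes
#'   are not representable in an edge list and are omitted.
#' @export
write_network <- function(net, path) {
  utils::write.table(network_edges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phosphosite table
#'
#' TSV with header columns `protein`, `residue`, `position`, `log2fc`.
#'
#' @param path Path to the TSV file.
#' @return A [phosphosite_table].
#' @export
read_phosphosites <- function(path) {
  df <- read_tsv_checked(path, c("protein", "residue", "position", "log2fc"))
  if (nrow(df) == 0L) stop("empty-input error: ", path, " has no data rows")
  df$position <- num_col(df, "position", path)
  df$log2fc <- num_col(df, "log2fc", path)
  phosphosite_table(df)
}

#' @rdname read_phosphosites
#' @param sites A [phosphosite_table].
#' @export
write_phosphosites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a kinase-substrate map
#'
#' TSV with header columns `kinase`, `protein`, `residue`, `position`.
#'
#' @param path Path to the TSV file.
#' @return A [kinase_substrate_map].
#' @export
read_kinase_substrate_map <- function(path) {
  df <- read_tsv_checked(path, c("kinase", "protein", "residue", "position"))
  if (nrow(df) == 0L) stop("empty-input error: ", path, " has no data rows")
  df$position <- num_col(df, "position", path)
  kinase_substrate_map(df)
}

#' @rdname read_kinase_substrate_map
#' @param ksmap A [kinase_substrate_map].
#' @export
write_kinase_substrate_map <- function(ksmap, path) {
  utils::write.table(as.data.frame(ksmap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format plate screen table
#'
#' TSV with header columns `plate_id`, `replicate`, `well`, `agent_id`,
#' `agent_type`, `dose`, `perturbed`, `value`.
#'
#' @param path Path to the TSV file.
#' @return A [plate_screen_table].
#' @export
read_plate_screen <- function(path) {
  df <- read_tsv_checked(path, c("plate_id", "replicate", "well", "agent_id",
                                 "agent_type", "dose", "perturbed", "value"))
  if (nrow(df) == 0L) stop("empty-input error: ", path, " has no data rows")
  df$replicate <- num_col(df, "replicate", path)
  df$dose <- suppressWarnings(as.numeric(df$dose))
  df$perturbed <- df$perturbed %in% c("TRUE", "True", "true", "1")
  df$value <- num_col(df, "value", path)
  plate_screen_table(df)
}

#' @rdname read_plate_screen
#' @param plates A [plate_screen_table].
#' @export
write_plate_screen <- function(plates, path) {
  utils::write.table(as.data.frame(plates), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a propagation result as Cytoscape-loadable node and edge tables
#'
#' Writes a node-attribute TSV with columns `gene`, `final_score`,
#' `product_activating`, `product_inhibiting`, `p_activating`,
#' `p_inhibiting`, `in_subnetwork`, and a companion edge TSV (`source`,
#' `target`) restricted to the extracted focus subnetwork.
#'
#' @param result A `propagation_result` (see [run_pipeline]).
#' @param path Node-table TSV path.
#' @param edge_path Edge-table TSV path; defaults to `path` with an
#'   `_edges.tsv` suffix.
#' @return Invisibly, `c(path, edge_path)`.
#' @export
write_node_table <- function(result, path,
                             edge_path = sub("\\.tsv$", "_edges.tsv", path)) {
  stopifnot(inherits(result, "propagation_result"))
  if (identical(edge_path, path)) edge_path <- paste0(path, "_edges.tsv")
  genes <- sort(unique(c(names(result$final_scores),
                         names(result$products$ACTIVATING),
                         names(result$products$INHIBITING))))
  pick <- function(v) if (is.null(v)) rep(NA_real_, length(genes)) else unname(v[genes])
  df <- data.frame(
    gene = genes,
    final_score = pick(result$final_scores),
    product_activating = pick(result$products$ACTIVATING),
    product_inhibiting = pick(result$products$INHIBITING),
    p_activating = pick(result$p_values$ACTIVATING),
    p_inhibiting = pick(result$p_values$INHIBITING),
    in_subnetwork = genes %in% result$subnetwork_nodes,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- result$subnetwork_edges
  if (is.null(ed)) ed <- data.frame(source = character(), target = character())
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, edge_path))
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "final_score", "product_activating",
                                 "product_inhibiting", "p_activating",
                                 "p_inhibiting", "in_subnetwork"))
  for (col in c("final_score", "product_activating", "product_inhibiting",
                "p_activating", "p_inhibiting")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$in_subnetwork <- df$in_subnetwork %in% c("TRUE", "True", "true", "1")
  df
}
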