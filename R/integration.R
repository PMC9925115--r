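#' Summarize kinase scores across datasets
#'
#' Cross-dataset summary of one platform/construct group: every gene
#' observed in at least `min_datasets` of the supplied sets is reported with
#' the mean and sample standard deviation of its scores over the sets in
#' which it appears.
#'
#' @param sets List of [kinase_set] objects (one platform/construct group,
#'   grouping chosen by the caller).
#' @param min_datasets Minimum number of sets a gene must appear in
#'   (default 2).
#' @return Data frame with columns `gene`, `n_datasets`, `mean_score`,
#'   `sd_score` (0 when a gene appears once).
#' @export
summarize_across_datasets <- function(sets, min_datasets = 2) {
  if (length(sets) == 0L) stop("empty-input error: no kinase sets supplied")
  stopifnot(all(vapply(sets, inherits, logical(1), "kinase_set")))
  gene <- unlist(lapply(sets, function(s) names(s$scores)), use.names = FALSE)
  score <- unlist(lapply(sets, function(s) unname(s$scores)), use.names = FALSE)
  n <- tapply(score, gene, length)
  keep <- names(n)[n >= min_datasets]
  keep <- sort(keep)
  if (length(keep) == 0L) {
    return(data.frame(gene = character(), n_datasets = integer(),
                      mean_score = numeric(), sd_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  sel <- gene %in% keep
  mean_score <- tapply(score[sel], gene[sel], mean)
  sd_score <- tapply(score[sel], gene[sel], stats::sd)
  sd_score[is.na(sd_score)] <- 0
  data.frame(gene = keep,
             n_datasets = as.integer(n[keep]),
             mean_score = as.numeric(mean_score[keep]),
             sd_score = as.numeric(sd_score[keep]),
             stringsAsFactors = FALSE)
}

#' Scale a kinase set to unit maximum absolute score
#'
#' Divides every score by the maximum absolute score, so that the largest
#' magnitude becomes exactly 1 while signs and relative magnitudes are
#' preserved. This puts the two platforms (activity effect sizes versus
#' abundance log2 fold changes) on a common, unitless scale before merging.
#' Idempotent.
#'
#' @param s A [kinase_set] with at least one nonzero score.
#' @return A [kinase_set] with `max(abs(scores)) == 1`.
#' @export
normalize_unit_max <- function(s) {
  stopifnot(inherits(s, "kinase_set"))
  m <- max(abs(s$scores))
  if (m == 0) stop("degenerate-input error: all scores are zero")
  s$scores <- s$scores / m
  s
}

#' Merge the two platforms of one cell line
#'
#' Union of the gene sets of the two (already unit-max normalized)
#' platforms; genes present on both platforms are averaged, genes on a
#' single platform are carried through unchanged. Commutative in its two
#' arguments.
#'
#' @param a,b Two [kinase_set] objects from the same cell line and construct.
#' @return A [kinase_set] with platform `"MERGED"`.
#' @export
merge_platforms <- function(a, b) {
  stopifnot(inherits(a, "kinase_set"), inherits(b, "kinase_set"))
  if (!identical(a$cell_line, b$cell_line) ||
      !identical(a$construct, b$construct)) {
    stop("contract error: cell_line/construct mismatch between platforms (",
         a$cell_line, "/", a$construct, " vs ", b$cell_line, "/", b$construct, ")")
  }
  genes <- sort(unique(c(names(a$scores), names(b$scores))))
  va <- a$scores[genes]
  vb <- b$scores[genes]
  merged <- rowMeans(cbind(va, vb), na.rm = TRUE)
  names(merged) <- genes
  kinase_set(merged, dataset_id = paste(a$dataset_id, b$dataset_id, sep = "+"),
             cell_line = a$cell_line, construct = a$construct,
             platform = "MERGED")
}

#' Standardize scores across genes within one cell line
#'
#' Subtracts the mean and divides by the sample standard deviation over
#' genes, so that the merged per-line vector has mean 0 and sd 1. Requires
#' at least 3 genes and nonzero spread.
#'
#' @param merged A [kinase_set] (typically the output of [merge_platforms]).
#' @return A z-scored [kinase_set] (`zscored = TRUE`).
#' @export
zscore_within_line <- function(merged) {
  stopifnot(inherits(merged, "kinase_set"))
  if (length(merged$scores) < 3L) {
    stop("precondition error: need at least 3 genes to z-score, got ",
         length(merged$scores))
  }
  s <- stats::sd(merged$scores)
  if (!is.finite(s) || s == 0) {
    stop("degenerate-input error: zero standard deviation across genes")
  }
  merged$scores <- (merged$scores - mean(merged$scores)) / s
  merged$zscored <- TRUE
  merged
}
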