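#' Infer per-kinase activity from phosphosite fold changes
#'
#' Substrate-enrichment z-statistic (KSEA-style): for kinase K with m
#' measured substrate sites,
#' \deqn{score_K = (\bar{x}_K - \bar{x}) \sqrt{m} / s,}
#' where \eqn{\bar{x}_K} is the mean log2 fold change over K's measured
#' substrates and \eqn{\bar{x}}, \eqn{s} are the mean and sample standard
#' deviation over all measured sites. This emulates the role of external
#' kinase-activity inference tools so the pipeline is testable end to end;
#' it is not a reimplementation of any particular web service.
#'
#' Kinases with fewer than `min_substrates` measured substrates are omitted
#' (reported via `message()`). The statistic is invariant to shifting all
#' fold changes by a constant or rescaling them by a positive factor.
#'
#' @param sites A [phosphosite_table].
#' @param ksmap A [kinase_substrate_map].
#' @param min_substrates Minimum number of measured substrate sites required
#'   to score a kinase (default 3).
#' @param construct,cell_line,dataset_id Annotations carried into the
#'   resulting [kinase_set].
#' @return A [kinase_set] with platform `"ACTIVITY_INFERENCE"`; empty (with a
#'   warning) when no kinase in the map has measured substrates.
#' @export
infer_kinase_activity <- function(sites, ksmap, min_substrates = 3,
                                  construct = "ACTIVATING",
                                  cell_line = "unknown",
                                  dataset_id = "activity_inference") {
  stopifnot(inherits(sites, "phosphosite_table"),
            inherits(ksmap, "kinase_substrate_map"))
  if (min_substrates < 1) stop("min_substrates must be >= 1")
  all_fc <- sites$log2fc
  mu <- mean(all_fc)
  s <- stats::sd(all_fc)
  if (!is.finite(s) || s == 0) {
    stop("degenerate-input error: zero standard deviation across phosphosites")
  }
  site_key <- paste(sites$protein, sites$residue, sites$position, sep = "_")
  map_key <- paste(ksmap$protein, ksmap$residue, ksmap$position, sep = "_")
  measured <- match(map_key, site_key)
  hit <- !is.na(measured)
  if (!any(hit)) {
    warning("no kinase in the map has measured substrates; empty result")
    return(kinase_set(stats::setNames(numeric(0), character(0)),
                      dataset_id = dataset_id, cell_line = cell_line,
                      construct = construct, platform = "ACTIVITY_INFERENCE",
                      allow_empty = TRUE))
  }
  kin <- ksmap$kinase[hit]
  fc <- all_fc[measured[hit]]
  m <- tapply(fc, kin, length)
  xbar <- tapply(fc, kin, mean)
  keep <- m >= min_substrates
  if (any(!keep)) {
    message(sum(!keep), " kinase(s) below the substrate threshold omitted: ",
            paste(utils::head(names(m)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  scores <- (xbar[keep] - mu) * sqrt(m[keep]) / s
  kinase_set(stats::setNames(as.numeric(scores), names(scores)),
             dataset_id = dataset_id, cell_line = cell_line,
             construct = construct, platform = "ACTIVITY_INFERENCE",
             allow_empty = TRUE)
}
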