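#' Within-plate z-scores averaged across replicates
#'
#' For every physical plate (a `plate_id` x `replicate` combination) the
#' well z-score is computed against the mean and sample standard deviation
#' of that plate's non-control wells, removing plate-level location and
#' scale effects ("internal normalization"). Per agent, z-scores are then
#' averaged across replicates.
#'
#' @param plates A [plate_screen_table].
#' @param include_controls Use control wells in the plate mean/sd as well
#'   (default `FALSE`: statistics over non-control wells only).
#' @return Data frame of class `screen_hits` with columns `agent_id`,
#'   `mean_z`, `n_replicates`; the per-well z-scores are attached as
#'   attribute `well_z`.
#' @export
plate_zscores <- function(plates, include_controls = FALSE) {
  stopifnot(inherits(plates, "plate_screen_table"))
  df <- as.data.frame(plates)
  plate_key <- paste(df$plate_id, df$replicate, sep = "|")
  df$z <- NA_real_
  for (pk in unique(plate_key)) {
    rows <- plate_key == pk
    use <- rows & (include_controls | df$agent_type != "CONTROL")
    mu <- mean(df$value[use])
    s <- stats::sd(df$value[use])
    if (!is.finite(s) || s == 0) {
      stop("degenerate-plate error: zero standard deviation on plate ", pk)
    }
    df$z[rows] <- (df$value[rows] - mu) / s
  }
  nc <- df[df$agent_type != "CONTROL", ]
  mean_z <- tapply(nc$z, nc$agent_id, mean)
  n_rep <- tapply(nc$z, nc$agent_id, length)
  out <- data.frame(agent_id = names(mean_z),
                    mean_z = as.numeric(mean_z),
                    n_replicates = as.integer(n_rep),
                    stringsAsFactors = FALSE)
  out <- out[order(out$agent_id), ]
  rownames(out) <- NULL
  attr(out, "well_z") <- df
  class(out) <- c("screen_hits", "data.frame")
  out
}

#' Call screen hits by z-score thresholds
#'
#' Direction is `DOWN` when `mean_z` (or `delta_log2fc`) is strictly below
#' `down_threshold`, `UP` when strictly above `up_threshold`, else `NONE`.
#'
#' @param hits A `screen_hits` data frame (from [plate_zscores] or
#'   [differential_response]).
#' @param down_threshold,up_threshold Strict thresholds; defaults -1 / +1.
#' @return `hits` with an added `direction` factor column.
#' @export
call_hits <- function(hits, down_threshold = -1, up_threshold = 1) {
  stopifnot(is.data.frame(hits))
  if (down_threshold >= up_threshold) {
    stop("down_threshold must be below up_threshold")
  }
  stat <- if ("mean_z" %in% names(hits)) hits$mean_z else hits$delta_log2fc
  if (is.null(stat)) stop("hits must carry mean_z or delta_log2fc")
  hits$direction <- factor(
    ifelse(stat < down_threshold, "DOWN",
           ifelse(stat > up_threshold, "UP", "NONE")),
    levels = c("DOWN", "NONE", "UP"))
  hits
}

#' Count down- and up-hits in a called hit table
#'
#' @param hits Output of [call_hits].
#' @return Named integer vector `c(down = , up = )`.
#' @export
screen_hit_counts <- function(hits) {
  stopifnot("direction" %in% names(hits))
  c(down = sum(hits$direction == "DOWN"),
    up = sum(hits$direction == "UP"))
}

#' Differential screen response (log2 fold change versus plate median)
#'
#' For each physical plate, well values are normalized as
#' `log2(value / median over non-control wells)`; per agent, the
#' differential response is the mean normalized value in the perturbed arm
#' minus the mean in the control arm, with a two-sided equal-variance
#' Student's t-test across replicates (Welch optional). No multiplicity
#' correction is applied. A pooled within-arm variance of zero yields
#' `p = NA` with the `degenerate` flag set.
#'
#' @param plates_ctrl,plates_perturbed [plate_screen_table] objects for the
#'   two arms, covering the same agents with at least 2 replicates each.
#' @param welch Use Welch's unequal-variance t-test instead (default
#'   `FALSE`).
#' @return Data frame of class `screen_hits` with columns `agent_id`,
#'   `delta_log2fc`, `p`, `degenerate`.
#' @export
differential_response <- function(plates_ctrl, plates_perturbed,
                                  welch = FALSE) {
  norm_arm <- function(plates) {
    stopifnot(inherits(plates, "plate_screen_table"))
    df <- as.data.frame(plates)
    if (any(df$value <= 0)) {
      stop("domain error: non-positive well values (log2 undefined)")
    }
    plate_key <- paste(df$plate_id, df$replicate, sep = "|")
    for (pk in unique(plate_key)) {
      rows <- plate_key == pk
      med <- stats::median(df$value[rows & df$agent_type != "CONTROL"])
      df$v[rows] <- log2(df$value[rows] / med)
    }
    df[df$agent_type != "CONTROL", ]
  }
  ctrl <- norm_arm(plates_ctrl)
  pert <- norm_arm(plates_perturbed)
  agents <- sort(unique(ctrl$agent_id))
  if (!setequal(agents, unique(pert$agent_id))) {
    stop("contract error: the two arms cover different agents")
  }
  out <- data.frame(agent_id = agents, delta_log2fc = NA_real_, p = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(agents)) {
    x <- pert$v[pert$agent_id == agents[i]]
    y <- ctrl$v[ctrl$agent_id == agents[i]]
    if (length(x) < 2L || length(y) < 2L) {
      stop("insufficient-replication error: agent ", agents[i],
           " has fewer than 2 replicates in one arm")
    }
    out$delta_log2fc[i] <- mean(x) - mean(y)
    pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
      (length(x) + length(y) - 2)
    if (!welch && pooled_var == 0) {
      out$degenerate[i] <- TRUE
    } else {
      out$p[i] <- stats::t.test(x, y, var.equal = !welch)$p.value
    }
  }
  class(out) <- c("screen_hits", "data.frame")
  out
}

#' Area under a growth curve
#'
#' Trapezoidal area of confluence versus time over the recorded interval,
#' in confluence-hours.
#'
#' @param curve A [time_course] with at least 2 points.
#' @return Numeric scalar.
#' @export
growth_auc <- function(curve) {
  stopifnot(inherits(curve, "time_course"))
  if (length(curve$time) < 2L) stop("need at least 2 time points for an AUC")
  pracma::trapz(curve$time, curve$value)
}

#' Viability relative to an untreated control
#'
#' @param treated Named numeric vector of treated readouts (names are
#'   doses).
#' @param untreated_value Positive readout of the untreated control.
#' @return Named numeric vector of viability fractions.
#' @export
relative_viability <- function(treated, untreated_value) {
  if (!is.finite(untreated_value) || untreated_value <= 0) {
    stop("domain error: untreated control value must be positive")
  }
  treated / untreated_value
}

#' Four-parameter logistic dose-response fit
#'
#' Fits \eqn{v(d) = bottom + (top - bottom) / (1 + (d / EC50)^{hill})} by
#' least squares on the log10-dose axis (via [minpack.lm::nlsLM]),
#' initialized at `top = max(v)`, `bottom = min(v)`, `ec50` at the geometric
#' mid-dose, `hill = 1`.
#'
#' @param doses Positive doses (molar); at least 5 distinct values.
#' @param viability Viability fractions, same length as `doses`.
#' @return List of class `dose_response_fit` with `ec50`, `hill`, `top`,
#'   `bottom`, `converged`, and `ec50_in_range` (whether the fitted EC50
#'   lies within the tested dose range).
#' @export
fit_dose_response <- function(doses, viability) {
  if (length(doses) != length(viability)) stop("length mismatch")
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 5L) {
    stop("insufficient-data error: need at least 5 distinct doses")
  }
  ld <- log10(doses)
  start <- list(top = max(viability), bottom = min(viability),
                lec50 = mean(range(ld)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lec50))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                bottom = NA_real_, converged = FALSE, ec50_in_range = FALSE)
    class(out) <- "dose_response_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  ec50 <- 10^cf[["lec50"]]
  # report with top >= bottom, flipping the Hill sign if needed
  top <- cf[["top"]]; bottom <- cf[["bottom"]]; hill <- cf[["hill"]]
  if (bottom > top) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  out <- list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
              converged = isTRUE(fit$convInfo$isConv),
              ec50_in_range = ec50 >= min(doses) && ec50 <= max(doses))
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> EC50 = %.4g (in range: %s), hill = %.3g, top = %.3g, bottom = %.3g, converged = %s\n",
    x$ec50, x$ec50_in_range, x$hill, x$top, x$bottom, x$converged))
  invisible(x)
}

#' Protein half-life from a decay time course
#'
#' Log-linear least squares `ln(value) = a - k t`; the half-life is
#' `ln(2) / k`. A non-positive decay rate is reported as non-decaying with
#' an infinite half-life.
#'
#' @param decay A [time_course] with at least 3 strictly positive values.
#' @return List of class `half_life_fit` with `half_life` (hours), `rate`
#'   (per hour), and `non_decaying`.
#' @export
half_life <- function(decay) {
  stopifnot(inherits(decay, "time_course"))
  if (length(decay$time) < 3L) stop("need at least 3 points to fit a decay")
  if (any(decay$value <= 0)) {
    stop("domain error: non-positive values in decay curve")
  }
  fit <- stats::lm(log(decay$value) ~ decay$time)
  k <- -unname(stats::coef(fit)[2])
  non_decaying <- k <= 0
  out <- list(half_life = if (non_decaying) Inf else log(2) / k,
              rate = k, non_decaying = non_decaying)
  class(out) <- "half_life_fit"
  out
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$non_decaying) {
    cat("<half_life_fit> non-decaying (rate <= 0)\n")
  } else {
    cat(sprintf("<half_life_fit> t1/2 = %.4g h (rate %.4g /h)\n",
                x$half_life, x$rate))
  }
  invisible(x)
}
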