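simple_plate <- function(values, replicate = 1, agent_type = "COMPOUND",
                         plate_id = "P1") {
  data.frame(plate_id = plate_id, replicate = replicate,
             well = sprintf("A%d", seq_along(values)),
             agent_id = sprintf("A%03d", seq_along(values)),
             agent_type = agent_type, dose = NA_real_, perturbed = FALSE,
             value = values, stringsAsFactors = FALSE)
}

test_that("plate z-scores standardize within plate and average replicates", {
  # 8 wells so the plate is valid; first three agents at 1, 2, 3 around
  # five fillers chosen symmetrically so their z-values are easy to check
  vals <- c(10, 20, 30, 20, 20, 20, 20, 20)
  pl <- plate_screen_table(rbind(simple_plate(vals, 1), simple_plate(vals, 2)))
  z <- plate_zscores(pl)
  expect_equal(z$mean_z[z$agent_id == "A001"],
               (10 - 20) / stats::sd(vals))
  expect_equal(z$n_replicates, rep(2L, 8))
  # per-plate z has mean 0 and sd 1 over non-control wells
  wz <- attr(z, "well_z")
  one <- wz$z[wz$replicate == 1 & wz$agent_type != "CONTROL"]
  expect_equal(mean(one), 0, tolerance = 1e-10)
  expect_equal(stats::sd(one), 1, tolerance = 1e-10)
  # identical replicates -> mean z equals the per-replicate z
  expect_equal(z$mean_z, wz$z[wz$replicate == 1], tolerance = 1e-12)
})

test_that("constant plates raise a degenerate-plate error naming the plate", {
  pl <- plate_screen_table(simple_plate(rep(5, 9)))
  expect_error(plate_zscores(pl), "degenerate-plate.*P1")
})

test_that("plate z-scores are invariant to per-plate affine transforms", {
  set.seed(9)
  vals <- rnorm(20, 100, 10)
  p1 <- simple_plate(vals, 1)
  p2 <- simple_plate(7 * vals + 300, 2)
  z <- plate_zscores(plate_screen_table(rbind(p1, p2)))
  z1 <- plate_zscores(plate_screen_table(p1))
  expect_equal(z$mean_z, z1$mean_z, tolerance = 1e-10)
})

test_that("hit calling uses strict thresholds", {
  hits <- data.frame(agent_id = c("a", "b", "c", "d"),
                     mean_z = c(-1.5, -0.5, 1.2, -1.0))
  out <- call_hits(hits)
  expect_equal(as.character(out$direction), c("DOWN", "NONE", "UP", "NONE"))
  out2 <- call_hits(hits, down_threshold = -2, up_threshold = 2)
  expect_true(all(out2$direction == "NONE"))
  expect_equal(unname(screen_hit_counts(out)), c(1L, 1L))
})

test_that("differential response matches its independent t oracle", {
  # frozen case: delta = -1, t = -sqrt(150) on 4 df
  ctrl <- plate_with_vprime(c(0.1, -0.1, 0.0))
  pert <- plate_with_vprime(c(-0.9, -1.1, -1.0), perturbed = TRUE)
  out <- differential_response(ctrl, pert)
  row <- out[out$agent_id == "X", ]
  expect_equal(row$delta_log2fc, -1, tolerance = 1e-12)
  expect_equal(row$p, 2.552167494419268e-04, tolerance = 1e-12)
  expect_equal(row$p, t_p_brute(c(-0.9, -1.1, -1.0), c(0.1, -0.1, 0.0)),
               tolerance = 1e-12)

  # identical arms: delta 0, p = 1 where variance is nonzero
  same <- differential_response(ctrl, plate_with_vprime(c(0.1, -0.1, 0.0),
                                                        perturbed = TRUE))
  srow <- same[same$agent_id == "X", ]
  expect_equal(srow$delta_log2fc, 0, tolerance = 1e-12)
  expect_equal(srow$p, 1, tolerance = 1e-12)

  # zero pooled variance: NA p with the degenerate flag
  d0 <- differential_response(plate_with_vprime(c(0, 0, 0)),
                              plate_with_vprime(c(-1, -1, -1)))
  drow <- d0[d0$agent_id == "X", ]
  expect_equal(drow$delta_log2fc, -1, tolerance = 1e-12)
  expect_true(is.na(drow$p) && drow$degenerate)
})

test_that("differential deltas are invariant to per-plate scaling", {
  ctrl <- plate_with_vprime(c(0.2, 0.1, 0.0))
  pert <- plate_with_vprime(c(-0.5, -0.6, -0.7), perturbed = TRUE)
  scale_arm <- function(pl, k) {
    df <- as.data.frame(pl)
    for (r in unique(df$replicate)) {
      df$value[df$replicate == r] <- df$value[df$replicate == r] * k[r]
    }
    plate_screen_table(df)
  }
  base <- differential_response(ctrl, pert)
  scaled <- differential_response(scale_arm(ctrl, c(2, 5, 0.3)),
                                  scale_arm(pert, c(10, 0.2, 1)))
  expect_equal(base$delta_log2fc, scaled$delta_log2fc, tolerance = 1e-10)
  expect_error(
    differential_response(scale_arm(ctrl, c(-1, 1, 1)), pert),
    "negative|domain")
})

test_that("growth AUC is the trapezoidal area", {
  expect_equal(growth_auc(time_course(c(0, 2), c(10, 10))), 20)
  expect_equal(growth_auc(time_course(c(0, 2), c(0, 20))), 20)
  expect_equal(growth_auc(time_course(c(0, 1), c(0, 4))), 2)
})

test_that("relative viability divides by the untreated control", {
  expect_equal(relative_viability(c(`0` = 10, `1` = 5), 10),
               c(`0` = 1, `1` = 0.5))
  expect_error(relative_viability(c(`0` = 10), 0), "domain error")
})

test_that("noiseless four-parameter logistic data is recovered exactly", {
  doses <- 10^seq(0, 4, length.out = 9) # nM
  v <- 0 + (1 - 0) / (1 + (doses / 100)^1)
  fit <- fit_dose_response(doses, v)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 100, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_true(fit$ec50_in_range)
})

test_that("flat dose-response curves are flagged rather than trusted", {
  doses <- 10^seq(0, 4, length.out = 8)
  fit <- fit_dose_response(doses, rep(1, 8))
  expect_true(!fit$converged || !fit$ec50_in_range)
  expect_error(fit_dose_response(c(1, 2, 3, 4), c(1, 1, 1, 1)),
               "insufficient-data")
})

test_that("EC50 is recovered within 15 percent under 5 percent noise", {
  doses <- rep(10^seq(0.5, 4, length.out = 8), each = 3) # 8 doses x 3 reps, nM
  errs <- sapply(1:5, function(s) {
    set.seed(s)
    v <- (1 / (1 + (doses / 217.3)^1.2)) * exp(rnorm(length(doses), 0, 0.05))
    fit <- fit_dose_response(doses, v)
    abs(fit$ec50 - 217.3) / 217.3
  })
  expect_true(all(errs < 0.15))
})

test_that("half-life fits the log-linear decay", {
  fit <- half_life(time_course(c(0, 1, 2), c(1, 0.5, 0.25)))
  expect_equal(fit$half_life, 1, tolerance = 1e-12)
  flat <- half_life(time_course(c(0, 1, 2, 3), rep(2, 4)))
  expect_true(flat$non_decaying && is.infinite(flat$half_life))
  expect_error(half_life(time_course(c(0, 1, 2), c(1, -1, 0.2))),
               "domain error")
  errs <- sapply(1:5, function(s) {
    set.seed(100 + s)
    t <- seq(0, 24, length.out = 7)
    v <- exp(-0.1 * t) * exp(rnorm(7, 0, 0.05))
    abs(half_life(time_course(t, v))$half_life - log(2) / 0.1) / (log(2) / 0.1)
  })
  expect_true(all(errs < 0.10))
})
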