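test_that("ouabain occupancy follows the binding hyperbola", {
  expect_equal(ouabain_occupancy(0, 1000), 0)
  expect_equal(ouabain_occupancy(1000, 1000), 0.5)
  expect_equal(ouabain_occupancy(100, 1000), 1 / 11)
  expect_error(ouabain_occupancy(100, 0), class = "pumploop_argument_error")
  expect_error(ouabain_occupancy(-1, 10), class = "pumploop_argument_error")
})

test_that("loop derivatives encode the coupled balances", {
  zero <- loop_params(synth_rate = 0, k_12 = 0, k_21 = 0, g_ros_shift = 0,
                      rho_basal = 0, g_src_ros = 0, delta_ros = 0,
                      g_endo = 0, delta_srcp = 0, k_src_act = 0,
                      g_cts_shift = 0, a_ros = 0, deg_endo = 0)
  st <- c(N_E1 = 1e6, N_E2 = 1e6, N_endo = 100, Src_p = 0.1, ROS = 1, Age = 0)
  expect_equal(unname(loop_derivatives(st, zero)), rep(0, 6))

  # with Src decoupled from ROS, the ROS balance is a plain linear relaxation
  p <- loop_params(g_src_ros = 0)
  st2 <- st
  st2[["Src_p"]] <- 0
  st2[["ROS"]] <- p$rho_basal / p$delta_ros
  d <- loop_derivatives(st2, p)
  expect_equal(unname(d[["ROS"]]), 0, tolerance = 1e-15)

  expect_error(loop_derivatives(c(st[1:5], Age = -1), loop_params()),
               class = "pumploop_validation_error")
  expect_error(loop_derivatives(c(A = 1), loop_params()),
               class = "pumploop_structural_error")
})

test_that("pump mass balance holds symbolically for arbitrary states", {
  # oracle: summing the three pump equations must leave synth - deg*N_endo
  withr::with_seed(17, {
    p <- loop_params()
    for (i in 1:20) {
      st <- c(N_E1 = runif(1, 0, 2e6), N_E2 = runif(1, 0, 2e6),
              N_endo = runif(1, 0, 1e5), Src_p = runif(1),
              ROS = runif(1, 0, 5), Age = runif(1, 0, 100))
      d <- loop_derivatives(st, p, t = 3000,
                            perturbations = perturbation("ouabain", 2500, 100))
      lhs <- d[["N_E1"]] + d[["N_E2"]] + d[["N_endo"]]
      rhs <- p$synth_rate - p$deg_endo * st[["N_endo"]]
      expect_equal(unname(lhs), unname(rhs), tolerance = 1e-9 * max(1, abs(rhs)))
    }
  })
})

test_that("basal calibration hits the target E1 fraction and is stationary", {
  p <- calibrate_basal(loop_params())
  cal <- attr(p, "calibration")
  expect_true(cal$e1_fraction >= 0.49 && cal$e1_fraction <= 0.51)
  expect_lt(cal$residual, 1e-6)

  # independent recomputation of the fixed-point residual
  fp <- basal_fixed_point(p)
  d <- loop_derivatives(fp, p)
  scale <- pmax(abs(fp), 1)
  expect_lt(max(abs(d[names(d) != "Age"]) / scale[names(d) != "Age"]), 1e-9)

  # a parameter set already on target is returned unchanged
  p2 <- calibrate_basal(p)
  expect_equal(p2$k_21, p$k_21, tolerance = 1e-14)

  expect_error(calibrate_basal(loop_params(), target_e1 = 0.5,
                               bracket = c(1e-6, 2e-6)),
               class = "pumploop_argument_error")
})

test_that("an unperturbed calibrated loop sits at its fixed point", {
  p <- calibrate_basal(loop_params())
  traj <- simulate_loop(p, t_max = 500, dt_out = 10)
  fp <- basal_fixed_point(p)
  for (v in c("N_E1", "N_E2", "N_endo", "Src_p", "ROS")) {
    expect_equal(traj[[v]], rep(fp[[v]], nrow(traj)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(traj$e1_fraction, rep(0.5, nrow(traj)), tolerance = 1e-6)
})

test_that("the ouabain scenario reproduces the directional responses", {
  p <- calibrate_basal(loop_params())
  traj <- simulate_loop(p, perturbation("ouabain", 2500, 100), t_max = 5000)
  m <- loop_metrics(traj)

  expect_equal(m$basal_e1_fraction, 0.5, tolerance = 0.01)
  expect_lt(m$min_e1_post, m$basal_e1_fraction - 0.05)   # E1 down
  expect_gt(m$ros_fold, 1.05)                            # ROS up
  expect_gt(m$src_fold, 1.05)                            # Src_p up
  expect_gt(m$pump_loss_frac, 0.005)                     # plasma pumps down
  expect_gt(m$aging_slope_post, m$aging_slope_pre * 1.02)  # aging accelerates
  expect_false(attr(traj, "runaway"))

  # non-negativity along the whole trajectory
  for (v in c("N_E1", "N_E2", "N_endo", "Src_p", "ROS", "Age")) {
    expect_true(all(traj[[v]] >= 0))
  }

  # pump mass balance at every sample:
  # plasma + endosomal + degraded - synthesized stays constant
  bal <- traj$N_E1 + traj$N_E2 + traj$N_endo + traj$cum_deg -
    p$synth_rate * traj$t
  expect_lt(max(abs(bal - bal[1])), 1e-5 * (traj$N_E1[1] + traj$N_E2[1]))
})

test_that("solver output is converged with respect to the time grid", {
  p <- calibrate_basal(loop_params())
  pert <- perturbation("ouabain", 100, 100)
  coarse <- simulate_loop(p, pert, t_max = 400, dt_out = 4)
  fine <- simulate_loop(p, pert, t_max = 400, dt_out = 2)
  sub <- fine[fine$t %in% coarse$t, ]
  for (v in c("N_E1", "N_E2", "N_endo", "Src_p", "ROS", "Age")) {
    rel <- abs(sub[[v]] - coarse[[v]]) / pmax(abs(coarse[[v]]), 1e-8)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("trajectory metrics agree with a recomputation from the CSV", {
  p <- calibrate_basal(loop_params())
  traj <- simulate_loop(p, perturbation("ouabain", 1000, 100), t_max = 2000,
                        dt_out = 5)
  m <- loop_metrics(traj)

  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  raw <- read_trajectory(f)
  pre <- raw[raw$t < 1000, ]
  post <- raw[raw$t >= 1000, ]
  basal <- pre[nrow(pre), ]
  expect_identical(m$basal_e1_fraction, basal$N_E1 / (basal$N_E1 + basal$N_E2))
  expect_identical(m$peak_ros, max(post$ROS))
  expect_identical(m$min_e1_post, min(post$N_E1 / (post$N_E1 + post$N_E2)))
  expect_identical(m$pump_loss_frac,
                   ((basal$N_E1 + basal$N_E2) - min(post$N_E1 + post$N_E2)) /
                     (basal$N_E1 + basal$N_E2))

  # constant trajectory: unit fold-changes, no pump loss
  flat <- simulate_loop(p, perturbation("ouabain", 500, 0), t_max = 1000,
                        dt_out = 10)
  mf <- loop_metrics(flat)
  expect_equal(mf$ros_fold, 1, tolerance = 1e-6)
  expect_equal(mf$src_fold, 1, tolerance = 1e-6)
  expect_equal(mf$pump_loss_frac, 0, tolerance = 1e-6)

  # unperturbed run: post-onset metrics absent
  m0 <- loop_metrics(simulate_loop(p, t_max = 200, dt_out = 20))
  expect_true(is.na(m0$ros_fold) && is.na(m0$min_e1_post))
})

test_that("steady-state ROS rises monotonically with ouabain dose", {
  p <- calibrate_basal(loop_params())
  dr <- ros_dose_response(p, doses = c(0, 250, 500, 750, 1000))
  expect_true(all(diff(dr$ros) > 0))
  expect_true(all(diff(dr$e1_fraction) < 0))
})

test_that("the feed-forward gain has a stability boundary", {
  p <- calibrate_basal(loop_params())
  st <- basal_fixed_point(p)
  lo <- leading_eigenvalue(p, state = st, gain_scale = 1)
  hi <- leading_eigenvalue(p, state = st, gain_scale = 50)
  expect_lt(lo, 0)
  expect_gt(hi, 0)
  crit <- uniroot(function(s) leading_eigenvalue(p, state = st, gain_scale = s),
                  c(1, 50))$root
  expect_true(crit > 1 && crit < 50)
})

test_that("loop gains are identifiable from a synthetic trajectory", {
  p <- calibrate_basal(loop_params())
  traj <- simulate_loop(p, perturbation("ouabain", 150, 200), t_max = 600,
                        dt_out = 4)
  fit <- fit_loop_params(traj)
  expect_true(all(fit$rel_error < 0.05))
})

test_that("a ROS bolus decays back toward the basal state", {
  p <- calibrate_basal(loop_params())
  traj <- simulate_loop(p, perturbation("ros_bolus", 100, 2), t_max = 600,
                        dt_out = 2)
  ros0 <- traj$ROS[traj$t == 98]
  expect_gt(traj$ROS[traj$t == 102], ros0 + 1.5)
  expect_lt(tail(traj$ROS, 1), ros0 * 1.05)
})
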