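#' Simulate the oxidant amplification loop
#'
#' Integrates the loop ODEs with `deSolve::ode` (lsoda, stiff-capable),
#' splitting the integration at perturbation onsets so that step inputs
#' (sustained ouabain) and instantaneous events (ROS boluses) are handled
#' exactly. The trajectory also carries `cum_deg`, the cumulative count of
#' degraded endocytosed pumps, so that pump mass balance
#' (`N_E1 + N_E2 + N_endo + cum_deg - synth_rate * t = const`) can be
#' checked at every sample.
#'
#' @param params A [loop_params()] (calibrated or explicit).
#' @param perturbations Optional [perturbation()] tibble (bind rows for
#'   several).
#' @param t_max Final time (ticks) when `t_grid` is not given.
#' @param dt_out Output sampling interval (ticks).
#' @param t_grid Explicit increasing output time grid (overrides
#'   `t_max`/`dt_out`).
#' @param init Initial state; default is the basal fixed point of
#'   `params`, so an unperturbed run is a stationary trajectory.
#' @param rtol,atol Solver tolerances (defaults `1e-8` relative).
#' @param ros_runaway ROS level above which the run is flagged as runaway
#'   (supercritical feed-forward gain); flagged in the result, not an
#'   error.
#' @return A `loop_trajectory` tibble with columns `t`, the six states,
#'   `cum_deg` and `e1_fraction`; attributes `params`, `perturbations`,
#'   `runaway`.
#' @export
#' @examples
#' p <- calibrate_basal(loop_params())
#' traj <- simulate_loop(p, perturbation("ouabain", 2500, 100), t_max = 5000)
#' glance(traj)
simulate_loop <- function(params, perturbations = NULL, t_max = 5000,
                          dt_out = 1, t_grid = NULL, init = NULL,
                          rtol = 1e-8, atol = NULL, ros_runaway = 1e6) {
  if (is.null(t_grid)) t_grid <- seq(0, t_max, by = dt_out)
  if (any(diff(t_grid) <= 0)) {
    abort("t_grid must be strictly increasing", class = "pumploop_argument_error")
  }
  if (!is.null(perturbations)) perturbations <- as_tibble(perturbations)
  init <- init %||% basal_fixed_point(params)
  init <- init[loop_state_names()]
  if (any(init < 0)) abort("negative initial state", class = "pumploop_validation_error")
  y <- c(init, cum_deg = 0)
  if (is.null(atol)) {
    atol <- pmax(1e-10 * pmax(abs(y), 1), 1e-12)
  }
  rhs <- function(t, y, parms) {
    d <- loop_rhs(pmax(y, 0), params, parms$occ)
    list(c(d, cum_deg = params$deg_endo * max(y[["N_endo"]], 0)))
  }
  onsets <- if (is.null(perturbations)) numeric() else
    sort(unique(perturbations$onset_time))
  onsets <- onsets[onsets > min(t_grid) & onsets < max(t_grid)]
  breaks <- unique(c(min(t_grid), onsets, max(t_grid)))
  rows <- list()
  for (seg in seq_len(length(breaks) - 1)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1]
    # events at the segment start
    if (!is.null(perturbations)) {
      bolus <- perturbations$kind == "ros_bolus" &
        perturbations$onset_time == t0
      if (any(bolus)) y[["ROS"]] <- y[["ROS"]] + sum(perturbations$magnitude[bolus])
    }
    occ <- ouabain_occupancy(active_ouabain(perturbations, t0),
                             params$IC50_ouabain)
    times <- unique(c(t0, t_grid[t_grid > t0 & t_grid < t1], t1))
    sol <- deSolve::ode(y = y, times = times, parms = list(occ = occ),
                        func = rhs, method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      abort("loop ODE solver failed; try smaller tolerances or check parameters",
            class = "pumploop_solver_error")
    }
    sol <- as.data.frame(sol)
    names(sol)[1] <- "t"
    y <- unlist(sol[nrow(sol), -1])
    keep <- sol$t %in% t_grid & (seg == 1 | sol$t > t0)
    rows[[seg]] <- sol[keep, , drop = FALSE]
  }
  out <- as_tibble(bind_rows(rows))
  # clip integrator noise at the non-negativity boundary
  statecols <- c(loop_state_names(), "cum_deg")
  out[statecols] <- lapply(out[statecols], function(v) pmax(v, 0))
  out$e1_fraction <- out$N_E1 / pmax(out$N_E1 + out$N_E2, .Machine$double.eps)
  runaway <- any(!is.finite(out$ROS)) || max(out$ROS, na.rm = TRUE) > ros_runaway
  if (runaway) warn("ROS exceeded the runaway threshold: feed-forward gain looks supercritical")
  new_tibble(out, nrow = nrow(out), class = "loop_trajectory",
             params = params, perturbations = perturbations,
             runaway = runaway)
}

#' Calibrate the basal state of the loop
#'
#' Finds the value of one free rate parameter (by default the E2 -> E1
#' conversion rate `k_21`) at which the unperturbed loop settles with the
#' target fraction of plasma-membrane pumps in the E1 state, and verifies
#' that the state is stationary at the perturbation horizon. Root finding
#' runs on the exact algebraic fixed point ([basal_fixed_point()]); the
#' returned parameter set is then checked by direct simulation: the
#' relative residual `|dstate/dt| / scale` at `t = horizon` must be below
#' `residual_tol` and the E1 fraction within 0.01 of the target. The
#' procedure is deterministic.
#'
#' @param params Starting [loop_params()].
#' @param target_e1 Target basal plasma E1 fraction (default 0.5).
#' @param horizon Stability horizon in ticks (default 2500, the
#'   perturbation onset convention).
#' @param free Name of the single free parameter (default `"k_21"`).
#' @param bracket Search interval for the free parameter.
#' @param tol Root tolerance on the E1 fraction.
#' @param residual_tol Stationarity residual bound at the horizon.
#' @return Calibrated `loop_params` with a `calibration` attribute
#'   (tibble: achieved `e1_fraction`, `residual`, the free parameter and
#'   its value). If the starting parameters already meet the target within
#'   `tol`, they are returned unchanged.
#' @export
calibrate_basal <- function(params = loop_params(), target_e1 = 0.5,
                            horizon = 2500, free = "k_21",
                            bracket = c(1e-6, 10), tol = 1e-10,
                            residual_tol = 1e-6) {
  if (!free %in% names(params) || !is.numeric(params[[free]])) {
    abort("free parameter not found in params", class = "pumploop_argument_error")
  }
  e1_of <- function(v) {
    p <- params
    p[[free]] <- v
    attr(basal_fixed_point(p), "e1_fraction")
  }
  current <- e1_of(params[[free]])
  if (abs(current - target_e1) > tol) {
    f <- function(v) e1_of(v) - target_e1
    lo <- f(bracket[1]); hi <- f(bracket[2])
    if (is.na(lo) || is.na(hi) || lo * hi > 0) {
      abort(sprintf(
        "cannot bracket the E1 target: f(%g) = %.4g, f(%g) = %.4g",
        bracket[1], lo, bracket[2], hi),
        class = "pumploop_argument_error")
    }
    root <- uniroot(f, bracket, tol = tol)
    params[[free]] <- root$root
  }
  fp <- basal_fixed_point(params)
  # verify stationarity by direct simulation to the horizon
  traj <- simulate_loop(params, t_max = horizon, dt_out = horizon / 10)
  final <- unlist(traj[nrow(traj), loop_state_names()])
  d <- loop_rhs(final, params, occ = 0)
  scale <- pmax(abs(final), 1)[names(d)]
  scale[["Age"]] <- max(abs(d[["Age"]]), 1)  # Age is a pure accumulator
  d[["Age"]] <- 0
  residual <- max(abs(d) / scale)
  achieved <- final[["N_E1"]] / (final[["N_E1"]] + final[["N_E2"]])
  if (residual > residual_tol || abs(achieved - target_e1) > 0.01) {
    abort(sprintf(
      "calibration verification failed: residual %.3e, E1 fraction %.4f",
      residual, achieved),
      class = "pumploop_convergence_error")
  }
  attr(params, "calibration") <- tibble(
    free = free, value = params[[free]],
    e1_fraction = achieved, residual = residual,
    target_e1 = target_e1, horizon = horizon
  )
  params
}

#' Summary metrics of a loop trajectory
#'
#' Reads out the standard panel of loop observables: the basal
#' (pre-perturbation) plasma E1 fraction, the post-perturbation minimum E1
#' fraction, peak ROS and its fold-change over basal, peak Src_p
#' fold-change, the fractional loss of plasma-membrane pumps, and the
#' aging slope before and after onset. For an unperturbed trajectory the
#' post-onset metrics are `NA`.
#'
#' @param traj A [simulate_loop()] trajectory.
#' @return One-row tibble of metrics.
#' @export
loop_metrics <- function(traj) {
  pert <- attr(traj, "perturbations")
  onset <- if (!is.null(pert) && nrow(pert) > 0) min(pert$onset_time) else NA_real_
  pre <- if (is.na(onset)) traj else filter(traj, .data$t < onset)
  if (nrow(pre) == 0) pre <- traj[1, ]
  basal <- pre[nrow(pre), ]
  slope <- function(d) {
    if (nrow(d) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(Age ~ t, data = d))[2])
  }
  out <- tibble(
    basal_e1_fraction = basal$e1_fraction,
    basal_ros = basal$ROS,
    basal_src_p = basal$Src_p,
    basal_plasma_pumps = basal$N_E1 + basal$N_E2,
    aging_slope_pre = slope(pre),
    min_e1_post = NA_real_, peak_ros = NA_real_, ros_fold = NA_real_,
    src_fold = NA_real_, pump_loss_frac = NA_real_,
    aging_slope_post = NA_real_
  )
  if (!is.na(onset)) {
    post <- filter(traj, .data$t >= onset)
    if (nrow(post) > 0) {
      out$min_e1_post <- min(post$e1_fraction)
      out$peak_ros <- max(post$ROS)
      out$ros_fold <- out$peak_ros / basal$ROS
      out$src_fold <- max(post$Src_p) / basal$Src_p
      out$pump_loss_frac <-
        (out$basal_plasma_pumps - min(post$N_E1 + post$N_E2)) /
        out$basal_plasma_pumps
      out$aging_slope_post <- slope(post)
    }
  }
  out
}

#' @method glance loop_trajectory
#' @export
glance.loop_trajectory <- function(x, ...) loop_metrics(x)

#' @method tidy loop_trajectory
#' @export
tidy.loop_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[c("t", loop_state_names())], -"t",
                      names_to = "variable", values_to = "value")
}

#' @method autoplot loop_trajectory
#' @export
autoplot.loop_trajectory <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(variable = factor(.data$variable, levels = loop_state_names()))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (ticks)", y = NULL) +
    ggplot2::theme_minimal()
  pert <- attr(object, "perturbations")
  if (!is.null(pert) && nrow(pert) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = pert$onset_time,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Write / read a loop trajectory as tidy CSV
#'
#' Columns: `t`, `N_E1`, `N_E2`, `N_endo`, `Src_p`, `ROS`, `Age`,
#' `cum_deg`; full double precision.
#'
#' @param traj A [simulate_loop()] trajectory.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` a plain tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("t", loop_state_names(), "cum_deg")
  df <- as.data.frame(lapply(as_tibble(traj)[cols], function(v) sprintf("%.17g", v)))
  names(df) <- cols
  write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  as_tibble(read.csv(path, check.names = FALSE))
}

#' Steady-state ROS as a function of ouabain dose
#'
#' Evaluates the loop's stationary ROS level under sustained ouabain at
#' each concentration, via the exact algebraic fixed point.
#'
#' @param params A [loop_params()].
#' @param doses Ouabain concentrations in uM.
#' @return Tibble with `dose`, `ros`, `e1_fraction`.
#' @export
ros_dose_response <- function(params, doses) {
  map(doses, function(d) {
    fp <- basal_fixed_point(params, ouabain_conc = d)
    tibble(dose = d, ros = fp[["ROS"]], e1_fraction = attr(fp, "e1_fraction"))
  }) %>% bind_rows()
}

#' Recover loop gains from an observed trajectory
#'
#' Least-squares refit of selected loop parameters (by default the
#' Src -> ROS gain `g_src_ros` and the ROS detoxification rate
#' `delta_ros`) to an observed trajectory, holding all other parameters at
#' the values stored on the trajectory. The objective is the summed squared
#' relative error of the ROS and Src_p time courses; optimisation runs on
#' the log scale with `stats::optim` (Nelder-Mead), so estimates stay
#' positive.
#'
#' @param traj A [simulate_loop()] trajectory (its `params` and
#'   `perturbations` attributes supply the fixed context).
#' @param fit Character vector of parameter names to refit.
#' @param start Named numeric starting values (default: 25% above the
#'   stored values, a deliberately perturbed start).
#' @param series State columns entering the objective.
#' @return Tibble with `parameter`, `true` (stored value), `estimate`,
#'   `rel_error`; attribute `objective` holds the final SSE.
#' @export
fit_loop_params <- function(traj, fit = c("g_src_ros", "delta_ros"),
                            start = NULL, series = c("ROS", "Src_p")) {
  params <- attr(traj, "params")
  pert <- attr(traj, "perturbations")
  if (is.null(params)) {
    abort("trajectory carries no params attribute", class = "pumploop_structural_error")
  }
  t_grid <- traj$t
  obs <- as.matrix(as_tibble(traj)[series])
  scale <- pmax(colMeans(abs(obs)), .Machine$double.eps)
  init <- unlist(traj[1, loop_state_names()])
  objective <- function(logv) {
    p <- params
    for (i in seq_along(fit)) p[[fit[i]]] <- exp(logv[i])
    sim <- try(simulate_loop(p, perturbations = pert, t_grid = t_grid,
                             init = init, rtol = 1e-8), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e10)
    pred <- as.matrix(as_tibble(sim)[series])
    sum(sweep(pred - obs, 2, scale, "/")^2)
  }
  truth <- unlist(params[fit])
  if (is.null(start)) start <- truth * 1.25
  opt <- optim(log(start[fit]), objective, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-12))
  est <- exp(opt$par)
  structure(
    tibble(parameter = fit, true = unname(truth), estimate = unname(est),
           rel_error = abs(unname(est) - unname(truth)) / unname(truth)),
    objective = opt$value
  )
}
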