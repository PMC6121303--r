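loop_state_names <- function() c("N_E1", "N_E2", "N_endo", "Src_p", "ROS", "Age")

#' Parameters of the oxidant amplification loop
#'
#' Rate parameters of the feed-forward loop coupling pump conformation
#' (E1/E2), Src kinase phosphorylation, reactive oxygen species (ROS), pump
#' endocytosis and cumulative aging. Time is in arbitrary simulation ticks
#' and ROS/Src units are arbitrary; defaults are package-chosen and are
#' normally finalised by [calibrate_basal()] against the two anchors of the
#' model (basal E1 fraction of about one half, stable basal state well
#' before the perturbation horizon at t = 2500).
#'
#' Model assumptions encoded here: a basal pump synthesis rate
#' (`synth_rate`); ROS (and cardiotonic steroids, via receptor occupancy)
#' shift the pump toward E2 (`g_ros_shift`, `g_cts_shift`); a basal ROS
#' source (`rho_basal`); phosphorylated Src drives ROS production
#' (`g_src_ros`, lumping the Src-EGFR cascade); first-order ROS
#' detoxification (`delta_ros`); ROS-proportional pump endocytosis
#' (`g_endo`); first-order decay of phosphorylated Src (`delta_srcp`).
#'
#' @param synth_rate Basal pump synthesis (pumps/tick).
#' @param k_12,k_21 Basal E1 -> E2 and E2 -> E1 conversion rates (1/tick);
#'   `k_21` is the parameter freed by default in [calibrate_basal()].
#' @param g_ros_shift Gain of ROS on the E1 -> E2 rate (1/tick per ROS
#'   unit).
#' @param rho_basal Basal ROS production (ROS units/tick).
#' @param g_src_ros Gain of phosphorylated Src on ROS production.
#' @param delta_ros First-order ROS detoxification rate (1/tick).
#' @param g_endo ROS -> endocytosis coupling (1/tick per ROS unit, applied
#'   to each plasma pump).
#' @param delta_srcp First-order decay rate of phosphorylated Src (1/tick).
#' @param k_src_act Activation rate of dis-inhibited controllable Src
#'   (1/tick).
#' @param src_total Total Src pool (arb units).
#' @param frac_src_controlled Fraction of Src under control of the
#'   signaling pump pool (default 0.5).
#' @param pump_total_surface Nominal surface pump count (default 2e6,
#'   i.e. "2 M" pumps per cell).
#' @param IC50_ouabain Ouabain half-inhibition concentration in uM
#'   (default 1000, so 100 uM is 10% of the IC50).
#' @param g_cts_shift Gain of ouabain receptor occupancy on the E1 -> E2
#'   rate (1/tick at full occupancy).
#' @param a_ros Aging gain from ROS.
#' @param endo_aging_factor Relative aging efficiency of the endocytic flux
#'   versus free ROS (default 1000).
#' @param deg_endo Degradation rate of endocytosed pumps (1/tick).
#' @param src_sensing `"total"` (default): the dis-inhibited fraction of
#'   controllable Src is `1 - N_E1 / (N_E1 + N_E2 + N_endo)`, so
#'   endocytosed pumps count as fully dis-inhibiting; `"plasma"` uses the
#'   plasma-membrane pool only.
#' @param ros_shift_mode `"additive"` (default): ROS/ouabain terms add to
#'   the E1 -> E2 rate; `"multiplicative"`: they scale `k_12`.
#' @param endo_from `"both"` (default): endocytosis draws proportionally
#'   from E1 and E2 plasma pools; `"E2_only"` restricts it to E2.
#' @return A `loop_params` list.
#' @export
#' @examples
#' p <- loop_params()
#' glance(calibrate_basal(p))
loop_params <- function(synth_rate = 170,
                        k_12 = 0.01,
                        k_21 = 0.011,
                        g_ros_shift = 0.002,
                        rho_basal = 0.02,
                        g_src_ros = 0.05,
                        delta_ros = 0.05,
                        g_endo = 1.6e-4,
                        delta_srcp = 0.04,
                        k_src_act = 0.02,
                        src_total = 1,
                        frac_src_controlled = 0.5,
                        pump_total_surface = 2e6,
                        IC50_ouabain = 1000,
                        g_cts_shift = 0.3,
                        a_ros = 1e-3,
                        endo_aging_factor = 1000,
                        deg_endo = 0.01,
                        src_sensing = c("total", "plasma"),
                        ros_shift_mode = c("additive", "multiplicative"),
                        endo_from = c("both", "E2_only")) {
  p <- list(
    synth_rate = synth_rate, k_12 = k_12, k_21 = k_21,
    g_ros_shift = g_ros_shift, rho_basal = rho_basal,
    g_src_ros = g_src_ros, delta_ros = delta_ros, g_endo = g_endo,
    delta_srcp = delta_srcp, k_src_act = k_src_act, src_total = src_total,
    frac_src_controlled = frac_src_controlled,
    pump_total_surface = pump_total_surface,
    IC50_ouabain = IC50_ouabain, g_cts_shift = g_cts_shift,
    a_ros = a_ros, endo_aging_factor = endo_aging_factor,
    deg_endo = deg_endo,
    src_sensing = match.arg(src_sensing),
    ros_shift_mode = match.arg(ros_shift_mode),
    endo_from = match.arg(endo_from)
  )
  num <- p[setdiff(names(p), c("src_sensing", "ros_shift_mode", "endo_from"))]
  if (any(unlist(num) < 0)) {
    abort("all rates and gains must be non-negative", class = "pumploop_argument_error")
  }
  if (p$frac_src_controlled > 1) {
    abort("frac_src_controlled must lie in [0, 1]", class = "pumploop_argument_error")
  }
  structure(p, class = "loop_params")
}

#' @export
print.loop_params <- function(x, ...) {
  cat("<loop_params>\n")
  num <- x[vapply(x, is.numeric, logical(1))]
  print(tibble(parameter = names(num), value = unlist(num)), n = Inf)
  cat("  src_sensing = ", x$src_sensing,
      ", ros_shift_mode = ", x$ros_shift_mode,
      ", endo_from = ", x$endo_from, "\n", sep = "")
  cal <- attr(x, "calibration")
  if (!is.null(cal)) cat("  calibrated: yes\n")
  invisible(x)
}

#' @method tidy loop_params
#' @export
tidy.loop_params <- function(x, ...) {
  num <- x[vapply(x, is.numeric, logical(1))]
  tibble(parameter = names(num), value = unlist(num))
}

#' @method glance loop_params
#' @export
glance.loop_params <- function(x, ...) {
  cal <- attr(x, "calibration")
  if (is.null(cal)) {
    tibble(calibrated = FALSE, basal_e1_fraction = NA_real_,
           residual = NA_real_)
  } else {
    tibble(calibrated = TRUE, basal_e1_fraction = cal$e1_fraction,
           residual = cal$residual)
  }
}

#' Ouabain receptor occupancy
#'
#' Fractional occupancy of the cardiotonic-steroid site under
#' instantaneous-equilibrium hyperbolic binding (Hill coefficient 1):
#' `conc / (conc + IC50)`. At 100 uM against the default IC50 of 1000 uM
#' (i.e. about 10% of the IC50) the occupancy is 1/11.
#'
#' @param conc Ouabain concentration in uM (>= 0); vectorised.
#' @param IC50 Half-occupancy concentration in uM (> 0).
#' @return Occupancy fraction in `[0, 1]`.
#' @export
#' @examples
#' ouabain_occupancy(100, 1000)  # 1/11
ouabain_occupancy <- function(conc, IC50) {
  if (!is.numeric(IC50) || any(IC50 <= 0)) {
    abort("IC50 must be > 0", class = "pumploop_argument_error")
  }
  if (any(conc < 0)) abort("conc must be >= 0", class = "pumploop_argument_error")
  conc / (conc + IC50)
}

#' Define a perturbation
#'
#' @param kind `"ouabain"` (a sustained bath concentration from
#'   `onset_time` onward) or `"ros_bolus"` (an instantaneous addition to
#'   the ROS state at `onset_time`).
#' @param onset_time Time of application (ticks, >= 0).
#' @param magnitude Concentration in uM (ouabain) or ROS units (bolus),
#'   >= 0.
#' @return A one-row `perturbation` tibble.
#' @export
#' @examples
#' perturbation("ouabain", onset_time = 2500, magnitude = 100)
perturbation <- function(kind = c("ouabain", "ros_bolus"), onset_time, magnitude) {
  kind <- match.arg(kind)
  if (onset_time < 0 || magnitude < 0) {
    abort("onset_time and magnitude must be >= 0", class = "pumploop_argument_error")
  }
  structure(tibble(kind = kind, onset_time = onset_time, magnitude = magnitude),
            class = c("perturbation", class(tibble())))
}

# active ouabain concentration at time t (sustained step inputs)
active_ouabain <- function(perturbations, t) {
  if (is.null(perturbations) || nrow(perturbations) == 0) return(0)
  on <- perturbations$kind == "ouabain" & perturbations$onset_time <= t
  sum(perturbations$magnitude[on])
}

# E1 -> E2 conversion rate given ROS level and ouabain occupancy
e1_to_e2_rate <- function(params, ROS, occ) {
  if (params$ros_shift_mode == "additive") {
    params$k_12 + params$g_ros_shift * ROS + params$g_cts_shift * occ
  } else {
    params$k_12 * (1 + params$g_ros_shift * ROS + params$g_cts_shift * occ)
  }
}

#' Right-hand side of the oxidant-loop ODE system
#'
#' Computes the instantaneous rates of change of the loop state
#' `(N_E1, N_E2, N_endo, Src_p, ROS, Age)`:
#' pump synthesis feeds E1; ROS and ouabain occupancy accelerate E1 -> E2;
#' endocytosis removes plasma pumps at a ROS-proportional rate into the
#' endosomal pool, which degrades first-order; the dis-inhibited fraction
#' of the controllable Src pool (E1 pumps tonically inhibit Src; E2 and
#' endocytosed pumps do not) is activated at `k_src_act` and decays
#' first-order; ROS balances a basal source, a Src-driven source and
#' first-order detoxification; aging accumulates from ROS plus the
#' endocytic flux weighted by `endo_aging_factor`.
#'
#' @param state Named non-negative numeric vector with entries `N_E1`,
#'   `N_E2`, `N_endo`, `Src_p`, `ROS`, `Age`.
#' @param params A [loop_params()].
#' @param t Time (ticks); used to resolve active perturbations.
#' @param perturbations Optional [perturbation()] tibble (ouabain steps).
#' @return Named numeric vector of time derivatives.
#' @export
loop_derivatives <- function(state, params, t = 0, perturbations = NULL) {
  state <- state[loop_state_names()]
  if (anyNA(state)) {
    abort("state must contain N_E1, N_E2, N_endo, Src_p, ROS, Age",
          class = "pumploop_structural_error")
  }
  if (any(state < -1e-9)) {
    abort("negative state input", class = "pumploop_validation_error")
  }
  occ <- ouabain_occupancy(active_ouabain(perturbations, t), params$IC50_ouabain)
  d <- loop_rhs(state, params, occ)
  d[loop_state_names()]
}

# core RHS; state may carry extra bookkeeping entries (ignored here)
loop_rhs <- function(state, params, occ) {
  N1 <- state[["N_E1"]]; N2 <- state[["N_E2"]]; Ne <- state[["N_endo"]]
  Sp <- state[["Src_p"]]; R <- state[["ROS"]]
  s12 <- e1_to_e2_rate(params, R, occ)
  endo1 <- if (params$endo_from == "both") params$g_endo * R * N1 else 0
  endo2 <- params$g_endo * R * N2
  plasma <- N1 + N2
  denom <- if (params$src_sensing == "total") plasma + Ne else plasma
  disinhib <- if (denom > 0) 1 - N1 / denom else 1
  endo_flux <- endo1 + endo2
  c(
    N_E1 = params$synth_rate + params$k_21 * N2 - s12 * N1 - endo1,
    N_E2 = s12 * N1 - params$k_21 * N2 - endo2,
    N_endo = endo_flux - params$deg_endo * Ne,
    Src_p = params$k_src_act * params$frac_src_controlled * params$src_total *
      disinhib - params$delta_srcp * Sp,
    ROS = params$rho_basal + params$g_src_ros * Sp - params$delta_ros * R,
    Age = params$a_ros * (R + params$endo_aging_factor * endo_flux)
  )
}

#' Basal fixed point of the loop
#'
#' Solves the algebraic steady state of the loop ODEs (optionally under a
#' sustained ouabain occupancy) by damped fixed-point iteration on the ROS
#' level: given ROS, the pump subsystem is linear and solved exactly; the
#' Src and ROS balances then update ROS. Converges for all stable
#' parameterisations; a supercritical feed-forward gain (no stable fixed
#' point in the iteration) raises a convergence error.
#'
#' @param params A [loop_params()].
#' @param ouabain_conc Sustained ouabain concentration (uM, default 0).
#' @param tol Relative convergence tolerance on ROS.
#' @param max_iter Iteration cap.
#' @return Named state vector (with `Age = 0`) plus attribute
#'   `e1_fraction` (plasma-membrane E1 fraction `N_E1 / (N_E1 + N_E2)`).
#' @export
basal_fixed_point <- function(params, ouabain_conc = 0, tol = 1e-12,
                              max_iter = 10000) {
  occ <- ouabain_occupancy(ouabain_conc, params$IC50_ouabain)
  if (params$g_endo <= 0 || params$deg_endo <= 0) {
    if (params$synth_rate > 0) {
      abort("no finite pump steady state: synthesis without endocytic degradation",
            class = "pumploop_argument_error")
    }
  }
  R <- params$rho_basal / max(params$delta_ros, .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    st <- pump_fixed_point(params, R, occ)
    denom <- if (params$src_sensing == "total") {
      st[["N_E1"]] + st[["N_E2"]] + st[["N_endo"]]
    } else {
      st[["N_E1"]] + st[["N_E2"]]
    }
    disinhib <- if (denom > 0) 1 - st[["N_E1"]] / denom else 1
    Sp <- params$k_src_act * params$frac_src_controlled * params$src_total *
      disinhib / params$delta_srcp
    R_new <- (params$rho_basal + params$g_src_ros * Sp) / params$delta_ros
    if (!is.finite(R_new)) {
      abort("fixed-point iteration diverged (supercritical gain?)",
            class = "pumploop_convergence_error")
    }
    if (abs(R_new - R) <= tol * max(1, abs(R))) {
      R <- R_new
      break
    }
    R <- 0.5 * R + 0.5 * R_new
    if (it == max_iter) {
      abort("basal fixed point did not converge", class = "pumploop_convergence_error")
    }
  }
  st <- pump_fixed_point(params, R, occ)
  denom <- if (params$src_sensing == "total") {
    st[["N_E1"]] + st[["N_E2"]] + st[["N_endo"]]
  } else {
    st[["N_E1"]] + st[["N_E2"]]
  }
  disinhib <- if (denom > 0) 1 - st[["N_E1"]] / denom else 1
  Sp <- params$k_src_act * params$frac_src_controlled * params$src_total *
    disinhib / params$delta_srcp
  out <- c(st, Src_p = unname(Sp), ROS = unname(R), Age = 0)[loop_state_names()]
  plasma <- out[["N_E1"]] + out[["N_E2"]]
  structure(out, e1_fraction = if (plasma > 0) out[["N_E1"]] / plasma else NA_real_)
}

# exact steady state of the (linear, given ROS) pump subsystem
pump_fixed_point <- function(params, R, occ) {
  s12 <- e1_to_e2_rate(params, R, occ)
  gE <- params$g_endo * R
  g1 <- if (params$endo_from == "both") gE else 0
  if (params$synth_rate == 0) {
    return(c(N_E1 = 0, N_E2 = 0, N_endo = 0))
  }
  # synth + k21 N2 = (s12 + g1) N1 ;  s12 N1 = (k21 + gE) N2
  ratio <- s12 / (params$k_21 + gE)              # N2 / N1
  denom <- s12 + g1 - params$k_21 * ratio
  if (denom <= 0) {
    abort("pump subsystem has no positive steady state for these parameters",
          class = "pumploop_convergence_error")
  }
  N1 <- params$synth_rate / denom
  N2 <- ratio * N1
  Ne <- (g1 * N1 + gE * N2) / params$deg_endo
  c(N_E1 = N1, N_E2 = N2, N_endo = Ne)
}

#' Jacobian of the loop at a state
#'
#' Central-difference Jacobian of [loop_derivatives()] with respect to the
#' five dynamic states (Age, a pure accumulator, is excluded), optionally
#' with the two feed-forward gains `g_src_ros` and `g_ros_shift` scaled by
#' a common factor. Used to probe the stability boundary of the oxidant
#' amplification loop: the leading eigenvalue crosses zero where the loop
#' gain turns supercritical.
#'
#' @param params A [loop_params()].
#' @param state State vector at which to linearise (default: the basal
#'   fixed point of `params`).
#' @param gain_scale Common multiplier applied to `g_src_ros` and
#'   `g_ros_shift` before differentiation (default 1).
#' @param ouabain_conc Sustained ouabain concentration (uM).
#' @return 5x5 Jacobian matrix over `(N_E1, N_E2, N_endo, Src_p, ROS)`.
#' @export
loop_jacobian <- function(params, state = NULL, gain_scale = 1, ouabain_conc = 0) {
  sp <- params
  sp$g_src_ros <- sp$g_src_ros * gain_scale
  sp$g_ros_shift <- sp$g_ros_shift * gain_scale
  if (is.null(state)) state <- basal_fixed_point(params)
  occ <- ouabain_occupancy(ouabain_conc, params$IC50_ouabain)
  vars <- setdiff(loop_state_names(), "Age")
  J <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (j in seq_along(vars)) {
    h <- max(1e-6 * abs(state[[vars[j]]]), 1e-8)
    up <- state; up[vars[j]] <- up[vars[j]] + h
    dn <- state; dn[vars[j]] <- max(dn[vars[j]] - h, 0)
    step <- up[vars[j]] - dn[vars[j]]
    J[, j] <- (loop_rhs(up, sp, occ)[vars] - loop_rhs(dn, sp, occ)[vars]) / step
  }
  J
}

#' Leading eigenvalue of the loop Jacobian
#'
#' @inheritParams loop_jacobian
#' @return Largest real part among the Jacobian eigenvalues.
#' @export
leading_eigenvalue <- function(params, state = NULL, gain_scale = 1,
                               ouabain_conc = 0) {
  max(Re(eigen(loop_jacobian(params, state, gain_scale, ouabain_conc),
               only.values = TRUE)$values))
}
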