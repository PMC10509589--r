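# Pressure-target derivation, branch-flow normalisation, 0D lumped network
# simulation and three-element Windkessel (WK3) tuning. This module works in
# clinical units throughout (mmHg, ml/s, mmHg s/ml, ml/mmHg), matching how
# the parameters are reported; conversion to SI happens only at interfaces.

#' Aortic pressure targets from a brachial cuff measurement
#'
#' Diastolic pressure transfers unchanged; the aortic systolic target is the
#' standard brachial-to-central estimate `0.83 Ps' + 0.15 Pd'`.
#'
#' @param brachial length-2 numeric `(Ps', Pd')` in mmHg.
#' @param round_targets round the systolic target to integer mmHg for
#'   reporting.
#' @return object of class `hd_pressure_targets`: `ps`, `pd`, `pulse`,
#'   `map` (mean arterial pressure `Pd + pulse/3`), `brachial`.
#' @export
derive_pressure_targets <- function(brachial, round_targets = FALSE) {
  ps_b <- brachial[1]; pd_b <- brachial[2]
  if (!(ps_b >= pd_b) || pd_b <= 0)
    stop_hp("need Ps' >= Pd' > 0 (got %g/%g)", ps_b, pd_b,
            class = "pressure_target_error")
  if (ps_b == pd_b)
    warning("degenerate brachial measurement: Ps' equals Pd'")
  ps <- 0.83 * ps_b + 0.15 * pd_b
  pd <- pd_b
  if (ps_b > pd_b && ps <= pd)
    stop_hp("systolic target (%.1f) not above diastolic (%.1f)", ps, pd,
            class = "pressure_target_error")
  if (round_targets) ps <- round(ps)
  structure(list(ps = ps, pd = pd, pulse = ps - pd, map = pd + (ps - pd) / 3,
                 brachial = c(ps_b, pd_b)),
            class = "hd_pressure_targets")
}

#' Normalise branch mean flows to an aortic plane difference
#'
#' Scales the measured mean flow of each branch in a group so that the group
#' total equals the mean flow difference between the aortic planes upstream
#' and downstream of the group.
#'
#' @param measured named numeric vector of branch mean flows (ml/s).
#' @param plane_difference upstream-downstream aortic mean flow difference
#'   (ml/s).
#' @return scaled branch flows (ml/s), summing exactly to
#'   `plane_difference`.
#' @export
normalize_branch_flows <- function(measured, plane_difference) {
  s <- sum(measured)
  if (s <= 0) stop_hp("group flow sum must be positive", class = "flow_error")
  if (plane_difference <= 0)
    stop_hp("plane difference must be positive", class = "flow_error")
  measured * (plane_difference / s)
}

#' WK3 outlet parameter set
#'
#' @param outlet outlet names.
#' @param q_target target mean flows (ml/s).
#' @param rho fraction of the total resistance attributed to the proximal
#'   element R1.
#' @param r_total total resistance R1 + R2 (mmHg s/ml).
#' @param c_wk3 compliance (ml/mmHg).
#' @return data.frame of class `hd_wk3_params` with columns `outlet`,
#'   `q_target`, `rho`, `r1`, `r2`, `c`.
#' @export
wk3_params <- function(outlet, q_target, rho, r_total, c_wk3) {
  stopifnot(all(r_total > 0), all(c_wk3 > 0), all(rho > 0), all(rho < 1))
  out <- data.frame(outlet = outlet, q_target = q_target, rho = rho,
                    r1 = rho * r_total, r2 = (1 - rho) * r_total, c = c_wk3)
  class(out) <- c("hd_wk3_params", "data.frame")
  out
}

as_inflow_fun <- function(inflow, period) {
  if (is.function(inflow)) return(inflow)
  if (is.data.frame(inflow)) {
    t <- inflow$time_s %||% inflow[[1]]
    q <- inflow$q_mls %||% inflow$value %||% inflow[[2]]
    f <- stats::approxfun(c(t, t[1] + period), c(q, q[1]))
    return(function(tt) f(tt %% period))
  }
  stop_hp("inflow must be a function or a waveform data.frame",
          class = "flow_error")
}

#' Simulate the 0D lumped outlet network
#'
#' Outlets are WK3 elements in parallel on a single zero-resistance
#' junction; the inlet flow is imposed. Each capacitor obeys
#' `C dPc/dt = Q_i - Pc/R2` with outlet flow `Q_i = (P_j - Pc)/R1`, where
#' the junction pressure `P_j` closes the flow split. Integration is
#' implicit first-order at `dt` (the junction closure is solved exactly each
#' step). Cycles repeat until systolic and diastolic junction pressure
#' change by less than `tol` between cycles.
#'
#' @param inflow waveform data.frame (`time_s`, `q_mls`) or function of time
#'   (ml/s), periodic with period `period`.
#' @param params an `hd_wk3_params`.
#' @param period cycle period (s).
#' @param dt timestep (s).
#' @param n_cycles_max maximum cycles before a convergence error.
#' @param tol relative cycle-to-cycle change defining periodicity.
#' @param pc0 optional initial capacitor pressures (mmHg).
#' @return object of class `hd_network_state`: final-cycle `time`,
#'   `p_junction` (mmHg), `q_outlet` (matrix, ml/s), `pc`, `ps`, `pd`,
#'   `cycles`, `mass_error` (relative per-cycle mass defect).
#' @export
simulate_network <- function(inflow, params, period, dt = 1e-3,
                             n_cycles_max = 100L, tol = 0.01, pc0 = NULL) {
  qfun <- as_inflow_fun(inflow, period)
  no <- nrow(params)
  r1 <- params$r1; r2 <- params$r2; cc <- params$c
  nstep <- max(2L, round(period / dt))
  dt <- period / nstep
  tgrid <- dt * seq_len(nstep)
  qin <- qfun(tgrid)
  qbar <- mean(qin)

  if (is.null(pc0)) {
    share <- (1 / (r1 + r2)) / sum(1 / (r1 + r2))
    pc0 <- qbar * share * r2
  }
  pc <- pc0
  a <- cc / dt
  b <- a + 1 / r2 + 1 / r1
  junc_coef <- sum((1 / r1) * (1 - 1 / (r1 * b)))

  ps_prev <- NA_real_; pd_prev <- NA_real_
  trace <- NULL
  for (cyc in seq_len(n_cycles_max)) {
    pj_series <- numeric(nstep)
    q_out <- matrix(0, nstep, no)
    pc_series <- matrix(0, nstep, no)
    for (s in seq_len(nstep)) {
      rhs <- qin[s] + sum(a * pc / (r1 * b))
      pj <- rhs / junc_coef
      pc <- (a * pc + pj / r1) / b
      pj_series[s] <- pj
      q_out[s, ] <- (pj - pc) / r1
      pc_series[s, ] <- pc
    }
    ps <- max(pj_series); pd <- min(pj_series)
    trace <- rbind(trace, c(cyc, ps, pd))
    if (!is.na(ps_prev) &&
        abs(ps - ps_prev) < tol * abs(ps_prev) &&
        abs(pd - pd_prev) < tol * abs(pd_prev)) {
      vol_in <- sum(qin) * dt
      vol_out <- sum(sweep(pc_series, 2L, r2, `/`)) * dt
      storage <- sum(cc * (pc_series[nstep, ] - pc0_cycle))
      return(structure(list(
        time = tgrid, p_junction = pj_series, q_outlet = q_out,
        pc = pc_series, ps = ps, pd = pd, cycles = cyc,
        q_mean_outlet = colMeans(q_out),
        mass_error = abs(vol_in - vol_out - storage) / vol_in),
        class = "hd_network_state"))
    }
    ps_prev <- ps; pd_prev <- pd
    pc0_cycle <- pc
  }
  stop_hp(paste("0D network not periodic after %d cycles;",
                "last cycles (ps, pd): %s"), n_cycles_max,
          paste(apply(utils::tail(trace, 3L), 1L, function(r)
            sprintf("(%.2f, %.2f)", r[2], r[3])), collapse = " "),
          class = "convergence_error")
}

#' Tune WK3 parameters to pressure and flow targets
#'
#' Total resistances come from the mean pressure identity
#' `R_tot,i = MAP / Q_i` (zero distal reference pressure), split by `rho`.
#' A global capacitance scale is then found by bracketed root finding on the
#' simulated pulse pressure, with an outer global resistance correction so
#' that both simulated systolic and diastolic pressures land within `tol` of
#' the targets.
#'
#' @param inflow inlet waveform (data.frame or function, ml/s).
#' @param targets an `hd_pressure_targets`.
#' @param q_targets named vector of outlet mean-flow targets (ml/s); their
#'   sum must match the inflow mean within 2%.
#' @param rho per-outlet R1 fraction (recycled).
#' @param period cycle period (s).
#' @param tol relative pressure tolerance (default 1%).
#' @param dt integration timestep (s).
#' @return list: `params` (`hd_wk3_params`), `achieved` (ps, pd), `state`
#'   (final `hd_network_state`), `r_scale`, `c_scale`.
#' @export
tune_wk3 <- function(inflow, targets, q_targets, rho = 0.1, period,
                     tol = 0.01, dt = 1e-3) {
  qfun <- as_inflow_fun(inflow, period)
  qbar <- mean(qfun(period * (0:999) / 1000))
  if (abs(sum(q_targets) - qbar) > 0.02 * abs(qbar))
    stop_hp("outlet flow targets (%.2f ml/s) do not sum to inflow mean (%.2f ml/s)",
            sum(q_targets), qbar, class = "flow_conservation_error")
  rho <- rep_len(rho, length(q_targets))
  r_tot <- targets$map / q_targets
  r_par <- targets$map / sum(q_targets)

  base_c <- (1.5 / r_par) * (1 / r_tot) / sum(1 / r_tot)  # 1.5 s decay time
  mk <- function(r_scale, c_scale)
    wk3_params(names(q_targets) %||% paste0("out", seq_along(q_targets)),
               q_targets, rho, r_scale * r_tot, c_scale * base_c)

  if (targets$pulse < 1e-9) {
    p <- mk(1, 1)
    st <- simulate_network(inflow, p, period, dt = dt)
    return(list(params = p, achieved = c(ps = st$ps, pd = st$pd), state = st,
                r_scale = 1, c_scale = 1))
  }

  r_scale <- 1
  st <- NULL; c_scale <- 1
  for (outer in 1:8) {
    pp_of <- function(ls) {
      p <- mk(r_scale, exp(ls))
      st <- simulate_network(inflow, p, period, dt = dt)
      st$ps - st$pd - targets$pulse
    }
    lo <- log(c_scale) - log(64); hi <- log(c_scale) + log(64)
    flo <- pp_of(lo); fhi <- pp_of(hi)
    if (flo * fhi > 0)
      stop_hp("capacitance bracket not found (pulse misfit %.2f / %.2f mmHg)",
              flo, fhi, class = "tuning_infeasible_error")
    # pulse pressure decreases with compliance: flo > 0 > fhi
    root <- stats::uniroot(pp_of, c(lo, hi), tol = 1e-4)
    c_scale <- exp(root$root)
    p <- mk(r_scale, c_scale)
    st <- simulate_network(inflow, p, period, dt = dt)
    if (abs(st$ps - targets$ps) <= tol * targets$ps &&
        abs(st$pd - targets$pd) <= tol * targets$pd) break
    # shift the mean via a global resistance correction
    need_map <- r_scale * targets$map + (targets$ps - st$ps + targets$pd - st$pd) / 2
    r_scale <- need_map / targets$map
  }
  list(params = p, achieved = c(ps = st$ps, pd = st$pd), state = st,
       r_scale = r_scale, c_scale = c_scale)
}
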