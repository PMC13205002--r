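#' @title Passive myelinated-fiber cable response
#' @description A-beta afferents are represented SENN-style as a chain of
#'   nodes of Ranvier coupled by axial conductances. The printed governing
#'   equation is a passive linear cable,
#'   dVn/dt = (1/Cm) * (Ga * D2(Vn) - Gm * Vn),
#'   where the extracellular potentials enter through their axial second
#'   difference (the activating function): the axial term is applied to
#'   (Vn + Ve,n). Vn is the deviation from rest; the absolute membrane
#'   potential is v_rest + Vn.
#' @name neural_response
NULL

#' Fiber geometry
#'
#' @param diameter_um axonal diameter in micrometres (default 9)
#' @param internode_mm node-of-Ranvier spacing; defaults to 100 x diameter
#' @param n_nodes odd node count >= 5
#' @param depth_mm placement depth below the surface; must lie within the
#'   dermis span (0.118 to 1.498 mm)
#' @param nodal_gap_um active nodal length in micrometres
#' @param orientation `"x"` (the 3-electrode axis) or `"y"`
#' @return a `fiber_geometry` object
#' @export
fiber_geometry <- function(diameter_um = 9, internode_mm = diameter_um / 10,
                           n_nodes = 21L, depth_mm = 0.8,
                           nodal_gap_um = 2.5, orientation = "x") {
  n_nodes <- as.integer(n_nodes)
  stopifnot(diameter_um > 0, internode_mm > 0, nodal_gap_um > 0,
            n_nodes >= 5, n_nodes %% 2L == 1L,
            orientation %in% c("x", "y"))
  if (depth_mm < 0.118 || depth_mm > 1.498)
    stop("fiber depth must lie within the dermis span [0.118, 1.498] mm")
  structure(list(diameter_um = diameter_um, internode_mm = internode_mm,
                 n_nodes = n_nodes, depth_mm = depth_mm,
                 nodal_gap_um = nodal_gap_um, orientation = orientation),
            class = "fiber_geometry")
}

#' Cable electrical parameters
#'
#' Defaults are derived from classical SENN constants: axoplasm resistivity
#' 110 ohm cm, nodal membrane capacitance 2 uF/cm^2, nodal membrane
#' conductance 30.4 mS/cm^2, nodal area pi * d * gap, and axial conductance
#' Ga = pi d^2 / (4 rho_i L).
#'
#' @param c_m nodal membrane capacitance in F
#' @param g_a internodal axial conductance in S
#' @param g_m nodal membrane conductance in S
#' @param v_rest resting potential in mV
#' @param v_th activation threshold in mV
#' @param k_slope sigmoid slope in 1/mV (used by the scoring stage)
#' @return a `cable_params` object
#' @export
cable_params <- function(c_m, g_a, g_m, v_rest = -70, v_th = -55,
                         k_slope = 0.05) {
  stopifnot(c_m > 0, g_a > 0, g_m > 0, v_th > v_rest)
  structure(list(c_m = c_m, g_a = g_a, g_m = g_m, v_rest = v_rest,
                 v_th = v_th, k_slope = k_slope),
            class = "cable_params")
}

#' Cable parameters from fiber geometry and membrane constants
#'
#' @param fiber a `fiber_geometry`
#' @param config run configuration supplying the membrane constants
#' @return a `cable_params`
#' @export
derive_cable_params <- function(fiber, config = default_run_config()) {
  fc <- config$fiber
  d_m <- fiber$diameter_um * 1e-6
  L_m <- fiber$internode_mm * 1e-3
  gap_m <- fiber$nodal_gap_um * 1e-6
  rho <- fc$axoplasm_resistivity_ohm_cm / 100     # ohm m
  area <- pi * d_m * gap_m                        # m^2
  g_a <- pi * d_m^2 / (4 * rho * L_m)
  c_m <- fc$membrane_capacitance_uF_cm2 * 1e-6 * 1e4 * area
  g_m <- fc$membrane_conductance_mS_cm2 * 1e-3 * 1e4 * area
  cable_params(c_m, g_a, g_m,
               v_rest = config$cable$v_rest_mv,
               v_th = config$cable$v_th_mv,
               k_slope = config$cable$k_per_mv)
}

#' Node-of-Ranvier positions under the array
#'
#' Collinear nodes at the fiber depth, centred laterally under the array
#' centroid and oriented along the chosen axis.
#'
#' @param f a `fiber_geometry`
#' @param layout an `array_layout`
#' @return n_nodes x 3 matrix of (x, y, z) coordinates in mm
#' @export
node_positions <- function(f, layout) {
  stopifnot(inherits(f, "fiber_geometry"), inherits(layout, "array_layout"))
  ctr <- colMeans(layout$centers)
  s <- (seq_len(f$n_nodes) - (f$n_nodes + 1) / 2) * f$internode_mm
  if (f$orientation == "x")
    cbind(x = ctr[1] + s, y = rep(ctr[2], f$n_nodes), z = f$depth_mm)
  else
    cbind(x = rep(ctr[1], f$n_nodes), y = ctr[2] + s, z = f$depth_mm)
}

#' Biphasic rectangular stimulation waveform
#'
#' @param phase_width_us single-phase width in microseconds (10-500, the
#'   device range)
#' @param amplitude_ma phase amplitude in mA
#' @param polarity `"cathodic_first"` or `"anodic_first"`
#' @param window_us total simulated window in microseconds
#' @return a `stim_waveform` with a `current_ma(t)` evaluator (t in s)
#' @export
biphasic_waveform <- function(phase_width_us = 100, amplitude_ma = 2,
                              polarity = "cathodic_first",
                              window_us = 600) {
  if (phase_width_us < 10 || phase_width_us > 500)
    stop("phase width must lie within the 10-500 us device range")
  stopifnot(polarity %in% c("cathodic_first", "anodic_first"),
            window_us >= 2 * phase_width_us)
  pw <- phase_width_us * 1e-6
  sgn <- if (polarity == "cathodic_first") -1 else 1
  structure(list(
    phase_width_us = phase_width_us, amplitude_ma = amplitude_ma,
    polarity = polarity, window_us = window_us,
    current_ma = function(t) {
      ifelse(t >= 0 & t < pw, sgn * amplitude_ma,
             ifelse(t >= pw & t < 2 * pw, -sgn * amplitude_ma, 0))
    }), class = "stim_waveform")
}

#' Extracellular drive series at the fiber nodes
#'
#' By quasi-static separability the time course factors out of the field
#' solve: Ve,n(t) = Phi(x_n) * i(t) / I_solve, where Phi was solved at
#' current I_solve.
#'
#' @param p a `potential_field`
#' @param nodes node coordinate matrix from [node_positions()]
#' @param waveform a `stim_waveform`
#' @param dt time step in s
#' @return a `drive_series`: matrix `ve` (n_nodes x n_t, V), `dt`, `times`,
#'   and the waveform
#' @export
extracellular_drive <- function(p, nodes, waveform, dt = 5e-7) {
  stopifnot(inherits(p, "potential_field"),
            inherits(waveform, "stim_waveform"))
  phi_n <- sample_potential(p, nodes)
  times <- seq(0, waveform$window_us * 1e-6, by = dt)
  scale <- if (p$injected_current_mA == 0) 0 * times else
    waveform$current_ma(times) / p$injected_current_mA
  ve <- outer(phi_n, scale)
  structure(list(ve = ve, dt = dt, times = times, waveform = waveform,
                 phi_nodes = phi_n),
            class = "drive_series")
}

# second-difference operator with sealed ends applied to the rows of x
.axial_diff <- function(x) {
  n <- nrow(x)
  if (n == 1) return(0 * x)   # single sealed node: no axial flux
  out <- x
  out[1, ] <- x[2, ] - x[1, ]
  out[n, ] <- x[n - 1, ] - x[n, ]
  if (n > 2)
    out[2:(n - 1), ] <- x[1:(n - 2), ] - 2 * x[2:(n - 1), ] + x[3:n, ]
  out
}

.axial_diff_vec <- function(v) as.vector(.axial_diff(matrix(v, ncol = 1)))

#' Integrate the passive nodal cable
#'
#' Fixed-step explicit (classical Runge-Kutta) integration of
#' dV/dt = (Ga/Cm) * D2(V + Ve) - (Gm/Cm) * V with sealed ends (zero axial
#' flux at the terminal nodes). The step must satisfy the stability margin
#' dt <= 0.1 * Cm / (Gm + 2 Ga).
#'
#' @param params a `cable_params`
#' @param drive a `drive_series`
#' @param duration simulated duration in s; defaults to the drive window
#' @param v0 initial nodal deviations in V (default: rest, all zero)
#' @return a `cable_trajectory`: matrix `v` (n_nodes x n_t, deviation from
#'   rest in V), `times`, and the parameters
#' @export
integrate_cable <- function(params, drive, duration = NULL, v0 = NULL) {
  stopifnot(inherits(params, "cable_params"), inherits(drive, "drive_series"))
  dt <- drive$dt
  dt_max <- 0.1 * params$c_m / (params$g_m + 2 * params$g_a)
  if (dt > dt_max)
    stop(sprintf("dt = %.3e s violates the stability margin %.3e s",
                 dt, dt_max))
  nt <- if (is.null(duration)) ncol(drive$ve)
        else min(ncol(drive$ve), floor(duration / dt) + 1L)
  nn <- nrow(drive$ve)
  a <- params$g_a / params$c_m
  b <- params$g_m / params$c_m
  ve <- drive$ve
  v <- matrix(0, nn, nt)
  if (!is.null(v0)) {
    stopifnot(length(v0) == nn)
    v[, 1] <- v0
  }
  deriv <- function(vn, veC) a * .axial_diff_vec(vn + veC) - b * vn
  for (s in seq_len(nt - 1L)) {
    ve0 <- ve[, s]; ve1 <- ve[, s + 1L]; vem <- (ve0 + ve1) / 2
    vn <- v[, s]
    k1 <- deriv(vn, ve0)
    k2 <- deriv(vn + dt / 2 * k1, vem)
    k3 <- deriv(vn + dt / 2 * k2, vem)
    k4 <- deriv(vn + dt * k3, ve1)
    vnext <- vn + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(vnext)) || max(abs(vnext)) > 1e9)
      stop(sprintf("cable integration diverged at step %d (dt = %.3e s)",
                   s, dt))
    v[, s + 1L] <- vnext
  }
  structure(list(v = v, times = drive$times[seq_len(nt)], params = params,
                 dt = dt),
            class = "cable_trajectory")
}

#' Peak membrane response features
#'
#' @param trajectory a `cable_trajectory` (deviations in V)
#' @param params a `cable_params`
#' @return a `neural_features` list: `v_peak_mv` (absolute membrane
#'   potential maximum over nodes and time), `t_peak_s`, `activated`
#'   (v_peak >= v_th)
#' @export
neural_features <- function(trajectory, params = trajectory$params) {
  stopifnot(inherits(trajectory, "cable_trajectory"))
  v <- trajectory$v
  if (!length(v)) stop("empty trajectory")
  idx <- arrayInd(which.max(v), dim(v))
  v_peak_mv <- params$v_rest + max(v) * 1e3
  structure(list(v_peak_mv = v_peak_mv,
                 t_peak_s = trajectory$times[idx[2]],
                 activated = v_peak_mv >= params$v_th),
            class = "neural_features")
}
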