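#' Alexander-Minetti muscle metabolic-rate curve
#'
#' Dimensionless metabolic rate of muscle force production as a function of
#' normalized shortening velocity `x = omega / omega_max`.  The rational
#' form has a strictly positive isometric rate `Phi(0) = 0.054`: holding a
#' force costs energy even without movement, which is what makes isometric
#' weight support at a flexed knee metabolically expensive.
#'
#' @param x Normalized contraction velocity, `|x| < 1`.
#' @return Dimensionless metabolic rate (> 0 on the valid domain).
#' @export
alexander_minetti_phi <- function(x) {
  if (any(abs(x) >= 1))
    stop("normalized muscle velocity out of range: |omega/omega_max| >= 1",
         call. = FALSE)
  (0.054 + 0.506 * x + 2.46 * x^2) /
    (1 - 1.13 * x + 12.8 * x^2 - 1.64 * x^3)
}

#' Default variable-efficiency table
#'
#' Muscle efficiency as a function of step frequency, transcribed from
#' inverse-dynamics efficiency estimates at different walking speeds
#' (roughly 20% at slow walks rising to 33% at fast walks) mapped to step
#' frequency through a standard preferred speed-frequency relation.
#' @return Data frame with columns `frequency` (Hz) and `eta`.
#' @export
default_efficiency_table <- function() {
  data.frame(
    frequency = c(1.2, 1.4, 1.6, 1.8, 2.0, 2.2, 2.4),
    eta       = c(0.200, 0.225, 0.250, 0.275, 0.295, 0.315, 0.330)
  )
}

#' Muscle and posture parameters of the cost model
#'
#' @param knee_angle Mid-stance knee flexion angle in degrees (default 8.4).
#' @param omega_max Maximum rotational velocity of the knee-extensor (vasti)
#'   group, rad/s.
#' @param efficiency_mode `"constant"` or `"variable"`.
#' @param eta Constant muscle efficiency (default 0.25).
#' @param efficiency_table Data frame (`frequency`, `eta`) for the variable
#'   mode; linearly interpolated, clamped at the table ends.
#' @param phi Metabolic-rate curve; a function of normalized velocity.
#' @return Object of class `"walk_muscle"`.
#' @export
walk_muscle <- function(knee_angle = 8.4, omega_max = 22,
                        efficiency_mode = c("constant", "variable"),
                        eta = 0.25,
                        efficiency_table = default_efficiency_table(),
                        phi = alexander_minetti_phi) {
  efficiency_mode <- match.arg(efficiency_mode)
  if (knee_angle < 0 || knee_angle > 30)
    stop("knee_angle must be within [0, 30] degrees", call. = FALSE)
  if (omega_max <= 0) stop("omega_max must be > 0", call. = FALSE)
  if (eta <= 0 || eta >= 1) stop("eta must be in (0, 1)", call. = FALSE)
  if (efficiency_mode == "variable") {
    if (is.null(efficiency_table) || nrow(efficiency_table) == 0L)
      stop("variable efficiency mode needs a non-empty efficiency_table",
           call. = FALSE)
    if (any(efficiency_table$eta <= 0 | efficiency_table$eta >= 1))
      stop("efficiency_table eta values must be in (0, 1)", call. = FALSE)
  }
  structure(list(knee_angle = knee_angle, omega_max = omega_max,
                 efficiency_mode = efficiency_mode, eta = eta,
                 efficiency_table = efficiency_table, phi = phi),
            class = "walk_muscle")
}

#' Muscle efficiency at a step frequency
#'
#' Constant mode returns `eta`; variable mode linearly interpolates the
#' efficiency table over step frequency, clamping to the end values outside
#' the table's range.
#' @param f Step frequency, Hz (> 0).
#' @param muscle A `"walk_muscle"`.
#' @return Dimensionless efficiency in (0, 1).
#' @export
efficiency <- function(f, muscle) {
  stopifnot(inherits(muscle, "walk_muscle"))
  if (any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  if (muscle$efficiency_mode == "constant") return(rep(muscle$eta, length(f)))
  tab <- muscle$efficiency_table
  stats::approx(tab$frequency, tab$eta, xout = f, rule = 2)$y
}

#' Centre-of-mass velocity-redirection cost
#'
#' Vertical push-off work to redirect the CoM velocity at the step-to-step
#' transition: `E_CR = 1/2 M (v_x tan(alpha))^2`, where `v_x` is the
#' horizontal pelvis velocity at push-off and `alpha` the attack angle of
#' the leading leg.  Only the vertical velocity component is charged; the
#' horizontal and lateral consequences are already in the 3LP component.
#'
#' @param M Body mass at the pelvis (proxy for the CoM), kg.
#' @param v_x Horizontal pelvis velocity at push-off, m/s.
#' @param alpha Attack angle, rad; `|alpha| < pi/2`.
#' @return Energy, J per step.
#' @export
com_redirection_cost <- function(M, v_x, alpha) {
  if (any(abs(alpha) >= pi / 2))
    stop("invalid geometry: |alpha| must be < pi/2", call. = FALSE)
  0.5 * M * (v_x * tan(alpha))^2
}

#' Ground-clearance cost
#'
#' Potential-energy cost of lifting the swing leg: a heel lift of `c`
#' (fraction of leg length) raises the leg CoM by `u * c`; the rest of the
#' body moves down and back up by the compensating amount to keep the CoM
#' height constant, so the nominal cost is `2 m_l u c g`.  In simulated
#' reduced gravity the leg half keeps full gravity while the rest-of-body
#' half uses the reduced value.
#'
#' @param body A `"walk_body"`.
#' @param c Heel-lift height as a fraction of leg length (>= 0);
#'   default 0.165, the middle of reported maximum heel-lift heights.
#' @param g Gravity, m/s^2.
#' @param leg_gravity_factor,body_gravity_factor Gravity scale factors in
#'   (0, 1] applied to the leg-lift and rest-of-body halves.
#' @return Energy, J per step.
#' @export
ground_clearance_cost <- function(body, c = 0.165, g = 9.81,
                                  leg_gravity_factor = 1,
                                  body_gravity_factor = 1) {
  stopifnot(inherits(body, "walk_body"))
  if (c < 0) stop("heel-lift fraction c must be >= 0", call. = FALSE)
  if (leg_gravity_factor <= 0 || leg_gravity_factor > 1 ||
      body_gravity_factor <= 0 || body_gravity_factor > 1)
    stop("gravity factors must be in (0, 1]", call. = FALSE)
  dh <- body$u * c
  body$m_l * dh * g * (leg_gravity_factor + body_gravity_factor)
}

#' Weight-support cost
#'
#' Metabolic cost of the knee-extensor (vasti) force that keeps the flexed
#' stance knee from collapsing: the required knee torque is
#' `tau_vas(t) = M g cos(beta(t)) l_u sin(theta(t)/2)` with `beta(t)` the
#' stance-leg angle from vertical, and the metabolic rate of producing it is
#' `tau_vas * omega_max * Phi(omega/omega_max)` with `omega = d theta/dt`.
#' With the default constant knee angle the integrand is purely isometric
#' (`Phi(0)`).  Already metabolic: not divided by muscle efficiency.
#'
#' @param body A `"walk_body"`.
#' @param gait A `"periodic_gait"` supplying `beta(t)` and the time grid.
#' @param muscle A `"walk_muscle"` (knee angle, `omega_max`, `Phi`).
#' @param theta_trace Optional knee-angle time series, rad, on the gait's
#'   time grid (used for flat-trajectory walking); default is the constant
#'   `muscle$knee_angle`.
#' @param g Gravity, m/s^2.
#' @param gravity_factor Scale in (0, 1] applied to the cost in simulated
#'   reduced gravity (the `(1 + gamma)/2` rule is applied by the caller).
#' @return Energy, J per step.
#' @export
weight_support_cost <- function(body, gait, muscle, theta_trace = NULL,
                                g = 9.81, gravity_factor = 1) {
  stopifnot(inherits(body, "walk_body"), inherits(gait, "periodic_gait"),
            inherits(muscle, "walk_muscle"))
  tt <- gait$time
  if (is.null(theta_trace)) {
    theta <- rep(muscle$knee_angle * pi / 180, length(tt))
    omega <- rep(0, length(tt))
  } else {
    theta <- theta_trace
    if (length(theta) != length(tt))
      stop("theta_trace must match the gait time grid", call. = FALSE)
    if (any(theta < 0))
      stop("theta_trace contains negative knee angles", call. = FALSE)
    omega <- finite_diff(theta, tt)
  }
  if (any(abs(omega) / muscle$omega_max >= 1))
    stop("knee angular velocity exceeds omega_max", call. = FALSE)
  M <- effective_mass(body)
  tau_vas <- M * g * cos(gait$beta) * body$l_u * sin(theta / 2)
  rate <- tau_vas * muscle$omega_max * muscle$phi(omega / muscle$omega_max)
  gravity_factor * trapz(tt, rate)
}

#' Combine the four components into a metabolic cost breakdown
#'
#' `E_walking = (E_3LP + E_CR + E_GC)/eta + E_WS`: the three mechanical-work
#' components are scaled by muscle efficiency, while the weight-support term
#' is already metabolic.
#'
#' @param E_3LP,E_CR,E_GC,E_WS Component energies, J per step (>= 0).
#' @param eta Muscle efficiency in (0, 1).
#' @param frequency Step frequency, Hz; needed for rates.
#' @param M Body mass, kg.
#' @param speed Walking speed, m/s; the cost of transport is undefined at
#'   zero speed (the metabolic rate is still reported).
#' @param g Gravity, m/s^2 (for the dimensionless cost of transport).
#' @param E_3LP_swing Optional swing-leg portion of `E_3LP` (for
#'   swing/stance attribution).
#' @return Object of class `"cost_breakdown"`: component energies,
#'   `eta_used`, `E_walking` (J/step), `metabolic_rate` (W/kg),
#'   `CoT` (J/kg/m) and `dimensionless_CoT`.
#' @export
total_cost <- function(E_3LP, E_CR, E_GC, E_WS, eta, frequency = NA,
                       M = NA, speed = NA, g = 9.81, E_3LP_swing = NA) {
  comps <- c(E_3LP, E_CR, E_GC, E_WS)
  if (any(comps < 0)) stop("component energies must be >= 0", call. = FALSE)
  if (eta <= 0 || eta >= 1) stop("eta must be in (0, 1)", call. = FALSE)
  E_walking <- (E_3LP + E_CR + E_GC) / eta + E_WS
  rate <- if (is.na(frequency) || is.na(M)) NA_real_ else
    E_walking * frequency / M
  CoT <- if (is.na(speed)) NA_real_ else if (speed == 0) {
    NA_real_
  } else rate / speed
  structure(list(E_3LP = E_3LP, E_CR = E_CR, E_GC = E_GC, E_WS = E_WS,
                 E_3LP_swing = E_3LP_swing, eta_used = eta,
                 E_walking = E_walking, metabolic_rate = rate,
                 CoT = CoT, dimensionless_CoT = CoT / g,
                 frequency = frequency, speed = speed, M = M, g = g),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Walking metabolic cost breakdown (per step)\n")
  cat(sprintf("  E_3LP %.2f J, E_CR %.2f J, E_GC %.2f J (mechanical, / eta = %.3f)\n",
              x$E_3LP, x$E_CR, x$E_GC, x$eta_used))
  cat(sprintf("  E_WS %.2f J (metabolic)\n", x$E_WS))
  cat(sprintf("  E_walking %.2f J/step", x$E_walking))
  if (!is.na(x$metabolic_rate))
    cat(sprintf(", rate %.3f W/kg", x$metabolic_rate))
  if (!is.na(x$CoT))
    cat(sprintf(", CoT %.3f J/kg/m (dimensionless %.3f)", x$CoT,
                x$dimensionless_CoT))
  cat("\n")
  invisible(x)
}

#' Evaluate the four-component cost of one walking condition
#'
#' Solves the periodic 3LP gait and assembles the full cost breakdown,
#' applying the condition rules: extra foot lift adds to the heel-lift
#' fraction; simulated reduced gravity scales the ground-clearance and
#' weight-support costs by `(1 + gamma)/2` (legs keep full gravity);
#' flat-trajectory walking cancels the CoM-redirection component and
#' replaces the constant knee angle with the inverse-kinematics trace.
#'
#' @param body A `"walk_body"`.
#' @param cond A `"gait_conditions"`.
#' @param muscle A `"walk_muscle"`.
#' @param heel_lift Nominal heel-lift height as fraction of leg length.
#' @param gait Optionally a pre-solved `"periodic_gait"` for these
#'   conditions.
#' @param ... Passed to [find_periodic_gait()].
#' @return A `"cost_breakdown"`.
#' @export
walk_cost <- function(body, cond, muscle = walk_muscle(), heel_lift = 0.165,
                      gait = NULL, ...) {
  if (is.null(gait)) gait <- find_periodic_gait(body, cond, ...)
  gamma <- cond$gravity_fraction
  e3 <- e3lp_cost(gait, body, per_pendulum = TRUE)

  E_CR <- if (cond$flat_walking) 0 else
    com_redirection_cost(effective_mass(body), gait$v_x, gait$alpha)

  c_eff <- heel_lift + cond$extra_foot_lift / body$L
  E_GC <- ground_clearance_cost(body, c_eff, cond$g,
                                leg_gravity_factor = 1,
                                body_gravity_factor = gamma)

  theta_trace <- if (cond$flat_walking)
    flat_knee_trace(body, gait, theta_min = muscle$knee_angle * pi / 180) else
      NULL
  E_WS <- weight_support_cost(body, gait, muscle, theta_trace = theta_trace,
                              g = cond$g,
                              gravity_factor = (1 + gamma) / 2)

  eta <- efficiency(cond$frequency, muscle)
  # rates and CoT are normalized by the subject's unloaded body mass, the
  # convention of loading studies; the dynamics and Eq-level costs use the
  # full carried mass
  total_cost(e3$total, E_CR, E_GC, E_WS, eta,
             frequency = cond$frequency, M = body$total_mass,
             speed = cond$speed, g = cond$g, E_3LP_swing = e3$swing_leg)
}

#' Component shares of the metabolic total
#'
#' Fractions of `E_walking` attributable to each component: the three
#' mechanical components divided by efficiency, weight support as-is.
#' @param breakdown A `"cost_breakdown"` with `E_walking > 0`.
#' @return Named numeric vector (`threelp`, `com_redirection`,
#'   `ground_clearance`, `weight_support`) summing to 1.
#' @export
component_shares <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  if (breakdown$E_walking <= 0)
    stop("shares undefined: E_walking is zero", call. = FALSE)
  eta <- breakdown$eta_used
  shares <- c(threelp = breakdown$E_3LP / eta,
              com_redirection = breakdown$E_CR / eta,
              ground_clearance = breakdown$E_GC / eta,
              weight_support = breakdown$E_WS) / breakdown$E_walking
  shares
}

#' Swing-attributed share of the metabolic total
#'
#' Convention: swing work is the swing leg's own share of the 3LP
#' kinetic-energy cost plus the leg-lift half of the ground-clearance cost
#' (the work done on the swing leg itself).  The rest-of-body half of
#' ground clearance, the trailing-leg push-off (CoM redirection) and weight
#' support are stance-side work.
#' @param breakdown A `"cost_breakdown"` carrying `E_3LP_swing`.
#' @return Fraction of `E_walking` in `[0, 1]`.
#' @export
swing_share <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  if (is.na(breakdown$E_3LP_swing))
    stop("breakdown lacks the swing-leg 3LP portion", call. = FALSE)
  ((breakdown$E_3LP_swing + breakdown$E_GC / 2) / breakdown$eta_used) /
    breakdown$E_walking
}

#' Serialize a cost breakdown
#'
#' One-row data frame with units in the column names, and a JSON string of
#' the same fields.
#' @param x A `"cost_breakdown"`.
#' @param row.names,optional,... S3 compatibility; unused.
#' @export
as.data.frame.cost_breakdown <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(E_3LP_J = x$E_3LP, E_CR_J = x$E_CR, E_GC_J = x$E_GC,
             E_WS_J = x$E_WS, eta = x$eta_used, E_walking_J = x$E_walking,
             rate_W_per_kg = x$metabolic_rate, CoT_J_per_kg_m = x$CoT,
             dimensionless_CoT = x$dimensionless_CoT,
             speed_m_s = x$speed, frequency_Hz = x$frequency)
}

#' @rdname as.data.frame.cost_breakdown
#' @export
breakdown_json <- function(x) {
  stopifnot(inherits(x, "cost_breakdown"))
  jsonlite::toJSON(as.list(as.data.frame(x)), auto_unbox = TRUE, digits = NA)
}

# Stance knee-angle trace for flat-trajectory walking: two-segment
# (thigh + shank) inverse kinematics with the hip at a constant height.
# The height is anchored so that the knee at the step's maximum leg splay
# is at the nominal mid-stance angle (flat walkers keep the knee flexed
# throughout; anchoring at full extension would make the angular velocity
# singular at the straight-knee limit).
flat_knee_trace <- function(body, gait, theta_min = 8.4 * pi / 180) {
  x <- gait$pelvis_x
  x_max <- max(abs(x))
  d_max <- sqrt(body$l_u^2 + body$l_s^2 -
                  2 * body$l_u * body$l_s * cos(pi - theta_min))
  if (x_max >= d_max)
    stop("no-gait-found: step too long for flat-trajectory walking",
         call. = FALSE)
  h0 <- sqrt(d_max^2 - x_max^2)
  d <- pmin(sqrt(h0^2 + x^2), d_max)
  vapply(d, knee_ik, numeric(1), l_u = body$l_u, l_s = body$l_s)
}

#' Knee angle from two-segment inverse kinematics
#'
#' Law-of-cosines knee flexion of a thigh + shank chain spanning a
#' hip-to-foot distance `d`: zero when the leg is straight
#' (`d = l_u + l_s`), increasing as the span shrinks.
#' @param d Hip-to-foot distance, m.
#' @param l_u Thigh length, m.
#' @param l_s Shank length, m.
#' @return Knee flexion angle, rad.
#' @export
knee_ik <- function(d, l_u, l_s) {
  if (d > l_u + l_s + 1e-12)
    stop("unreachable: span exceeds thigh + shank length", call. = FALSE)
  if (d < abs(l_u - l_s))
    stop("degenerate: span below |thigh - shank| length", call. = FALSE)
  d <- min(d, l_u + l_s)
  pi - acos((l_u^2 + l_s^2 - d^2) / (2 * l_u * l_s))
}

# trapezoid integral on a (possibly non-uniform) grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# centered finite difference on a non-uniform grid
finite_diff <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}
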