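#' Gait conditions
#'
#' Bundles the inputs that define one walking condition for the 3LP gait
#' solver and the cost components.
#'
#' @param speed Mean forward walking speed, m/s (>= 0).
#' @param frequency Step frequency, Hz (> 0).  Step length is
#'   `speed / frequency`.
#' @param step_width Imposed lateral distance between successive footholds,
#'   m, or `NULL` (default) to let the width emerge from the
#'   minimum-torque solution.
#' @param g Gravitational acceleration, m/s^2.
#' @param upward_force Constant vertical support force applied at the
#'   pelvis, N (simulated body-weight support); must not exceed body weight.
#' @param gravity_fraction Fraction of normal gravity experienced by the
#'   body in a simulated reduced-gravity condition (the legs always keep
#'   full gravity).  Implies an upward pelvis force of
#'   `(1 - gravity_fraction) * M * g` in the gait solve and scales the
#'   ground-clearance and weight-support costs by `(1 + gravity_fraction)/2`.
#' @param extra_foot_lift Additional swing-foot lift height, m, added to the
#'   nominal heel-lift fraction in the ground-clearance cost.
#' @param flat_walking Logical; if `TRUE` the stance knee angle follows the
#'   constant-pelvis-height inverse kinematics (see [knee_ik()]) and the
#'   CoM-redirection component is cancelled.
#' @return An object of class `"gait_conditions"`.
#' @export
walk_conditions <- function(speed, frequency, step_width = NULL, g = 9.81,
                            upward_force = 0, gravity_fraction = 1,
                            extra_foot_lift = 0, flat_walking = FALSE) {
  if (!is.numeric(speed) || speed < 0) stop("speed must be >= 0", call. = FALSE)
  if (!is.numeric(frequency) || frequency <= 0)
    stop("frequency must be > 0", call. = FALSE)
  if (!is.numeric(g) || g <= 0) stop("g must be > 0", call. = FALSE)
  if (gravity_fraction <= 0 || gravity_fraction > 1)
    stop("gravity_fraction must be in (0, 1]", call. = FALSE)
  if (extra_foot_lift < 0) stop("extra_foot_lift must be >= 0", call. = FALSE)
  structure(list(speed = speed, frequency = frequency,
                 step_width = step_width, g = g,
                 upward_force = upward_force,
                 gravity_fraction = gravity_fraction,
                 extra_foot_lift = extra_foot_lift,
                 flat_walking = isTRUE(flat_walking)),
            class = "gait_conditions")
}

#' Find a periodic 3LP gait
#'
#' Solves the linear boundary-value problem for one steady step of the 3LP
#' model at a given speed and step frequency.  Free swing-hip torques
#' (piecewise linear in time, sagittal and lateral separately) and the
#' initial pelvis state are chosen so that the end-of-step state equals the
#' left-right mirrored start state, the swing foot lands one step length
#' ahead with zero terminal velocity, and the mean forward pelvis velocity
#' equals the requested speed.  Remaining redundancy is resolved by
#' minimizing the time-integral of squared hip torque.  The stance-ankle
#' torque is prescribed by a linear fore-aft centre-of-pressure ramp whose
#' excursion (fraction of foot length) is a free model parameter.
#'
#' @param body A `"walk_body"` from [scale_body()].
#' @param cond A `"gait_conditions"` from [walk_conditions()].
#' @param n_segments Number of piecewise-linear segments per torque profile.
#' @param n_samples Number of time samples per step for the output traces.
#' @param cop_excursion Fore-aft centre-of-pressure excursion under the
#'   stance foot, as a fraction of foot length.
#' @return An object of class `"periodic_gait"`: time grid, pelvis and
#'   swing-foot positions/velocities in both planes, leg angles, torque
#'   traces, step length/width, attack angle `alpha`, push-off pelvis
#'   velocity `v_x` and the stance-leg angle trace `beta`.
#' @export
find_periodic_gait <- function(body, cond, n_segments = 3L, n_samples = 201L,
                               cop_excursion = 0.8) {
  stopifnot(inherits(body, "walk_body"), inherits(cond, "gait_conditions"))
  T_step <- 1 / cond$frequency
  ell <- cond$speed / cond$frequency
  M_eff <- effective_mass(body)
  F_up <- cond$upward_force + (1 - cond$gravity_fraction) * M_eff * cond$g
  if (F_up > M_eff * cond$g)
    stop("upward support force exceeds body weight", call. = FALSE)
  if (ell > 1.4 * body$L)
    stop("no-gait-found: step length ", format(ell), " m exceeds the ",
         "small-angle validity bound of 1.4 leg lengths", call. = FALSE)

  n_k <- n_segments + 1L
  maps <- gait_maps(body, T_step, cond$g, F_up, n_k, n_samples,
                    cop_excursion)
  mats <- maps$mats
  times <- maps$times
  F_z <- maps$F_z
  cop_amp <- maps$cop_amp
  P_sag <- maps$P_sag
  P_lat <- maps$P_lat
  PTs <- P_sag[[length(times)]]
  PTl <- P_lat[[length(times)]]

  ## sagittal unknowns p = (x_p0, vx_p0, theta_sag);  z0 = (x_p0, -ell, vx_p0, 0)
  n_par <- 4L + n_k + 1L
  Js <- matrix(0, n_par, 2L + n_k + 1L)
  Js[1, 1] <- 1; Js[3, 2] <- 1
  Js[2, 2L + n_k + 1L] <- -ell
  Js[4L + seq_len(n_k), 2L + seq_len(n_k)] <- diag(n_k)
  Js[n_par, 2L + n_k + 1L] <- 1
  Zs <- PTs %*% Js                      # rows of z(T) over (p, 1)
  Cs <- rbind(
    Zs[1, ] - c(1, 0, rep(0, n_k), ell),   # x_p(T) - x_p0 - ell = 0
    Zs[3, ] - c(0, 1, rep(0, n_k), 0),     # vx_p(T) - vx_p0     = 0
    Zs[2, ] - c(0, 0, rep(0, n_k), ell),   # x_sw(T) - ell       = 0
    Zs[4, ]                                # vx_sw(T)            = 0
  )
  ds <- -Cs[, ncol(Cs)]
  Cs <- Cs[, -ncol(Cs), drop = FALSE]
  Q <- maps$Q
  Ws <- diag(1e-12, 2L + n_k)
  Ws[2L + seq_len(n_k), 2L + seq_len(n_k)] <- Q
  ps <- min_effort_solve(Cs, ds, Ws)
  if (is.null(ps))
    stop("no-gait-found: singular sagittal boundary-value system",
         call. = FALSE)

  ## lateral unknowns p = (y_p0, vy_p0, W, theta_lat); z0 = (y_p0, W, vy_p0, 0)
  n_ul <- 3L + n_k
  Jl <- matrix(0, n_par, n_ul + 1L)
  Jl[1, 1] <- 1; Jl[3, 2] <- 1; Jl[2, 3] <- 1
  Jl[4L + seq_len(n_k), 3L + seq_len(n_k)] <- diag(n_k)
  Jl[n_par, n_ul + 1L] <- 1
  Zl <- PTl %*% Jl
  eW <- c(0, 0, 1, rep(0, n_k), 0)
  e_yp0 <- c(1, 0, 0, rep(0, n_k), 0)
  e_vyp0 <- c(0, 1, 0, rep(0, n_k), 0)
  Cl <- rbind(
    Zl[1, ] + e_yp0 - eW,                      # y_p(T) + y_p0 - W  = 0
    Zl[3, ] + e_vyp0,                          # vy_p(T) + vy_p0    = 0
    Zl[2, ] - eW,                              # y_sw(T) - W        = 0
    Zl[4, ]                                    # vy_sw(T)           = 0
  )
  if (!is.null(cond$step_width))
    Cl <- rbind(Cl, eW - c(rep(0, n_ul), cond$step_width))
  dl <- -Cl[, ncol(Cl)]
  Cl <- Cl[, -ncol(Cl), drop = FALSE]
  Wl <- diag(1e-12, n_ul)
  Wl[3L + seq_len(n_k), 3L + seq_len(n_k)] <- Q
  pl <- min_effort_solve(Cl, dl, Wl)
  if (is.null(pl))
    stop(if (is.null(cond$step_width)) "no-gait-found: singular lateral system"
         else "imposed step width is infeasible", call. = FALSE)

  ## reconstruct trajectories
  ws <- c(Js %*% c(ps, 1))
  wl <- c(Jl %*% c(pl, 1))
  zs <- t(vapply(P_sag, function(P) c(P %*% ws), numeric(4)))
  zl <- t(vapply(P_lat, function(P) c(P %*% wl), numeric(4)))
  theta_s <- ps[2L + seq_len(n_k)]
  theta_l <- pl[3L + seq_len(n_k)]
  W <- pl[3L]

  hipw <- t(vapply(times, hat_weights, numeric(n_k),
                   T_step = T_step, n_knots = n_k))
  tau_hip_sag <- c(hipw %*% theta_s)
  tau_hip_lat <- c(hipw %*% theta_l)
  tau_ank_sag <- -F_z * cop_amp * (times / T_step - 0.5)

  beta <- sqrt((zs[, 1] / body$L)^2 + ((zl[, 1] - mats$d) / body$L)^2)
  # attack angle: inclination of the leading (landing) leg from vertical at
  # the end of the step.  The redirected pelvis velocity must be orthogonal
  # to the leading leg, so the vertical velocity change is
  # v_z = v_x tan(alpha) -- the half-angle geometry of step-to-step
  # transition work.
  n_end <- nrow(zs)
  alpha <- atan2(zs[n_end, 2] - zs[n_end, 1], body$L)

  structure(list(
    T_step = T_step, time = times,
    step_length = ell, step_width = W,
    pelvis_x = zs[, 1], pelvis_vx = zs[, 3],
    swingfoot_x = zs[, 2], swingfoot_vx = zs[, 4],
    pelvis_y = zl[, 1], pelvis_vy = zl[, 3],
    swingfoot_y = zl[, 2], swingfoot_vy = zl[, 4],
    stance_angle_sag = zs[, 1] / body$L,
    swing_angle_sag = (zs[, 2] - zs[, 1]) / body$L,
    beta = beta,
    tau_hip_sag = tau_hip_sag, tau_hip_lat = tau_hip_lat,
    tau_ankle_sag = tau_ank_sag,
    theta_hip_sag = theta_s, theta_hip_lat = theta_l,
    alpha = alpha, v_x = zs[nrow(zs), 3],
    conditions = cond, n_segments = n_segments,
    cop_excursion = cop_excursion,
    torque_effort = sum(theta_s * c(Q %*% theta_s)) +
      sum(theta_l * c(Q %*% theta_l)),
    upward_force = F_up
  ), class = "periodic_gait")
}

#' Kinetic-energy traces of a periodic gait
#'
#' Translational and rotational kinetic energy of the three pendulums along
#' the step, split by plane (sagittal/lateral) and by pendulum
#' (stance leg, torso, swing leg).  There is no potential-energy term: all
#' mass heights are constant in the 3LP model.
#'
#' Energies are evaluated in the gait frame, i.e. the frame translating
#' forward at the steady walking speed: uniform progression is conserved
#' from step to step and carries no actuation cost, so the swing/torso
#' component measures the oscillatory motion about it (the cost of the mean
#' motion's step-to-step redirection is carried by the CoM-redirection
#' component instead).
#'
#' @param gait A `"periodic_gait"`.
#' @param body The `"walk_body"` the gait was solved for.
#' @return A data frame with the time grid and one column per
#'   (energy type, plane, pendulum) combination, in joules, plus the four
#'   channel sums `trans_sag`, `rot_sag`, `trans_lat`, `rot_lat`.
#' @export
kinetic_energy_trace <- function(gait, body) {
  stopifnot(inherits(gait, "periodic_gait"), inherits(body, "walk_body"))
  L <- body$L; s <- body$u / L; r <- 1 - s
  I_c <- max(body$I_leg - body$m_l * body$u^2, 0)
  m_l <- body$m_l; m_t <- body$torso_mass

  ke <- function(vp, vsw, v_frame) {
    v_st <- r * vp - v_frame
    v_to <- vp - v_frame
    v_sw <- r * vp + s * vsw - v_frame
    w_st <- vp / L
    w_sw <- (vsw - vp) / L
    data.frame(
      trans_stance = 0.5 * m_l * v_st^2,
      trans_torso  = 0.5 * m_t * v_to^2,
      trans_swing  = 0.5 * m_l * v_sw^2,
      rot_stance   = 0.5 * I_c * w_st^2,
      rot_swing    = 0.5 * I_c * w_sw^2
    )
  }
  sag <- ke(gait$pelvis_vx, gait$swingfoot_vx, gait$conditions$speed)
  lat <- ke(gait$pelvis_vy, gait$swingfoot_vy, 0)
  names(sag) <- paste0(names(sag), "_sag")
  names(lat) <- paste0(names(lat), "_lat")
  out <- cbind(data.frame(time = gait$time), sag, lat)
  out$trans_sag <- sag$trans_stance_sag + sag$trans_torso_sag +
    sag$trans_swing_sag
  out$rot_sag <- sag$rot_stance_sag + sag$rot_swing_sag
  out$trans_lat <- lat$trans_stance_lat + lat$trans_torso_lat +
    lat$trans_swing_lat
  out$rot_lat <- lat$rot_stance_lat + lat$rot_swing_lat
  out
}

# positive-part integral of the rate of a sampled energy trace:
# sum of positive increments of the series
positive_increments <- function(x) sum(pmax(diff(x), 0))

#' Swing- and torso-dynamics cost of a periodic gait
#'
#' Integral over one step of the positive part of the kinetic-energy rate,
#' evaluated separately for translational and rotational energies in the
#' sagittal and lateral planes and summed.  Equals the sum of positive
#' increments of the sampled kinetic-energy series.
#'
#' @inheritParams kinetic_energy_trace
#' @param per_pendulum If `TRUE`, also return the cost computed on each
#'   pendulum's own energy trace (used for swing/stance attribution).
#' @return Energy in joules per step (non-negative); with
#'   `per_pendulum = TRUE` a list with `total` and `swing_leg`.
#' @export
e3lp_cost <- function(gait, body, per_pendulum = FALSE) {
  tr <- kinetic_energy_trace(gait, body)
  total <- positive_increments(tr$trans_sag) + positive_increments(tr$rot_sag) +
    positive_increments(tr$trans_lat) + positive_increments(tr$rot_lat)
  if (!per_pendulum) return(total)
  swing <- positive_increments(tr$trans_swing_sag) +
    positive_increments(tr$rot_swing_sag) +
    positive_increments(tr$trans_swing_lat) +
    positive_increments(tr$rot_swing_lat)
  list(total = total, swing_leg = swing)
}

#' @export
print.periodic_gait <- function(x, ...) {
  cat("Periodic 3LP gait\n")
  cat(sprintf("  speed %.3f m/s, frequency %.3f Hz (T = %.3f s)\n",
              x$conditions$speed, x$conditions$frequency, x$T_step))
  cat(sprintf("  step length %.3f m, step width %.3f m%s\n", x$step_length,
              x$step_width,
              if (is.null(x$conditions$step_width)) " (emergent)" else
                " (imposed)"))
  cat(sprintf("  attack angle %.2f deg, push-off pelvis velocity %.3f m/s\n",
              x$alpha * 180 / pi, x$v_x))
  invisible(x)
}

#' Export a gait as a tidy data frame
#'
#' One row per time sample: positions, velocities, leg angles and torques.
#' @param x A `"periodic_gait"`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.periodic_gait <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(time = x$time,
             pelvis_x = x$pelvis_x, pelvis_y = x$pelvis_y,
             pelvis_vx = x$pelvis_vx, pelvis_vy = x$pelvis_vy,
             swingfoot_x = x$swingfoot_x, swingfoot_y = x$swingfoot_y,
             swingfoot_vx = x$swingfoot_vx, swingfoot_vy = x$swingfoot_vy,
             stance_angle_sag = x$stance_angle_sag,
             swing_angle_sag = x$swing_angle_sag,
             beta = x$beta,
             tau_hip_sag = x$tau_hip_sag, tau_hip_lat = x$tau_hip_lat,
             tau_ankle_sag = x$tau_ankle_sag)
}
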