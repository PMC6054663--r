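# Linearized equations of motion of the 3LP walking model.
#
# Three pendulums at constant heights: a stance leg pivoting about the fixed
# foot, a torso point mass at the pelvis, and a swing leg hanging from the
# pelvis.  With heights constant, the potential energy is expanded to second
# order in the leg angles, which yields the first-order gravity moments (the
# same device that gives the linear inverted pendulum its g/L term) while the
# kinetic energy stays quadratic in the horizontal velocities.  Sagittal and
# lateral directions decouple; the pelvis half-width enters the lateral
# equations only as a constant (affine) forcing term.
#
# Generalized coordinates per direction: q = (pelvis position, swing-foot
# position), measured horizontally from the stance-foot contact point.
# State z = (q, dq/dt), so  dz/dt = A z + f(t)  with
#   f(t) = const + B_hip * tau_hip(t) + B_ankle * tau_ankle(t).
# Swing-hip torque is a free piecewise-linear profile; stance-ankle torque is
# prescribed by a linear fore-aft centre-of-pressure ramp.

# Mass, stiffness and input matrices for one direction.
# upward_force is a constant vertical support force at the pelvis (reduced
# effective torso weight); it never changes the leg gravity terms.
threelp_matrices <- function(body, g = 9.81, upward_force = 0) {
  L   <- body$L
  m_l <- body$m_l
  m_t <- body$torso_mass
  s   <- body$u / L
  r   <- 1 - s
  I_c <- body$I_leg - body$m_l * body$u^2   # leg inertia about its own CoM
  if (I_c < 0) I_c <- 0

  Ma <- matrix(c(
    m_t + 2 * m_l * r^2 + 2 * I_c / L^2,  m_l * r * s - I_c / L^2,
    m_l * r * s - I_c / L^2,              m_l * s^2 + I_c / L^2
  ), 2, 2, byrow = TRUE)

  # generalized gravity forces: F = K q (+ constants in the lateral plane)
  G1 <- (m_l * g * r + (m_t * g - upward_force) + m_l * g) / L
  G2 <- m_l * g * s / L
  K <- matrix(c(
    G1 - G2,  G2,
    G2,      -G2
  ), 2, 2, byrow = TRUE)

  B_hip   <- c(-1, 1) / L   # swing-hip torque between torso and swing leg
  B_ankle <- c(1, 0) / L    # ground moment about the stance contact point

  d <- body$pelvis_width / 2
  c_lat <- c(-(G1 + G2) * d, G2 * d)   # constant forcing, lateral plane only

  Mi <- solve(Ma)
  A <- rbind(cbind(matrix(0, 2, 2), diag(2)),
             cbind(Mi %*% K, matrix(0, 2, 2)))
  list(A = A, Mi = Mi, Ma = Ma, K = K,
       b_hip = c(0, 0, Mi %*% B_hip),
       b_ankle = c(0, 0, Mi %*% B_ankle),
       c_sag = c(0, 0, 0, 0),
       c_lat = c(0, 0, Mi %*% c_lat),
       r = r, s = s, I_c = I_c, d = d, L = L, g = g)
}

# Exact propagators for dz/dt = A z + f0 + f1 (t - t0) over an interval h:
# z(h) = E z0 + G0 f0 + G1 f1, from one augmented matrix exponential.
lti_propagators <- function(A, h) {
  n <- nrow(A)
  M <- matrix(0, 3 * n, 3 * n)
  M[1:n, 1:n] <- A
  M[1:n, (n + 1):(2 * n)] <- diag(n)
  M[(n + 1):(2 * n), (2 * n + 1):(3 * n)] <- diag(n)
  Em <- as.matrix(Matrix::expm(M * h))
  list(E = Em[1:n, 1:n],
       G0 = Em[1:n, (n + 1):(2 * n)],
       G1 = Em[1:n, (2 * n + 1):(3 * n)])
}

# Piecewise-linear hat-function weights of the torque knots at time t.
# knots are equally spaced over [0, T]; returns a length-n_k vector.
hat_weights <- function(t, T_step, n_knots) {
  tk <- seq(0, T_step, length.out = n_knots)
  w <- numeric(n_knots)
  if (t <= 0) { w[1] <- 1; return(w) }
  if (t >= T_step) { w[n_knots] <- 1; return(w) }
  i <- findInterval(t, tk, rightmost.closed = TRUE)
  h <- tk[i + 1L] - tk[i]
  w[i] <- (tk[i + 1L] - t) / h
  w[i + 1L] <- (t - tk[i]) / h
  w
}

# Gram matrix of the hat basis: integral of tau(t)^2 over the step as a
# quadratic form in the knot values.  Using this (rather than the plain sum
# of squared knots) makes the minimum-torque solution approximately
# invariant to knot refinement.
hat_gram <- function(T_step, n_knots) {
  h <- T_step / (n_knots - 1L)
  Q <- matrix(0, n_knots, n_knots)
  for (i in seq_len(n_knots - 1L)) {
    idx <- c(i, i + 1L)
    Q[idx, idx] <- Q[idx, idx] + h / 6 * matrix(c(2, 1, 1, 2), 2, 2)
  }
  Q
}

# Propagate the affine parameter-to-state map along the merged time grid.
#
# The state at every grid time is expressed as  z(t) = P(t) %*% c(z0, theta, 1)
# where theta are the free hip-torque knot values.  Prescribed forcing
# (gravity constants + ankle CoP ramp) accumulates in the final column.
# Returns a list of P matrices (4 x (4 + n_k + 1)), one per grid time.
propagate_map <- function(A, b_hip, forcing_const, ankle_fun, times, n_knots,
                          T_step) {
  n_par <- 4L + n_knots + 1L
  P <- vector("list", length(times))
  P0 <- matrix(0, 4, n_par)
  P0[, 1:4] <- diag(4)
  P[[1L]] <- P0
  prop_cache <- list()
  for (j in seq_len(length(times) - 1L)) {
    t0 <- times[j]; t1 <- times[j + 1L]
    h <- t1 - t0
    key <- sprintf("%.15g", h)
    if (is.null(prop_cache[[key]])) prop_cache[[key]] <- lti_propagators(A, h)
    pr <- prop_cache[[key]]

    # forcing as an affine map of the parameter vector, f(t) = F0 + F1 (t-t0)
    w0 <- hat_weights(t0, T_step, n_knots)
    w1 <- hat_weights(t1, T_step, n_knots)
    F0 <- matrix(0, 4, n_par)
    F1 <- matrix(0, 4, n_par)
    F0[, 4L + seq_len(n_knots)] <- outer(b_hip, w0)
    F1[, 4L + seq_len(n_knots)] <- outer(b_hip, (w1 - w0) / h)
    a0 <- ankle_fun(t0); a1 <- ankle_fun(t1)
    F0[, n_par] <- forcing_const + a0
    F1[, n_par] <- (a1 - a0) / h

    P[[j + 1L]] <- pr$E %*% P[[j]] + pr$G0 %*% F0 + pr$G1 %*% F1
  }
  P
}

# Cache of propagated transition maps.  The maps depend on the body, the
# gravity/support environment, the step time and the torque parametrization
# but not on walking speed, so one entry serves a whole constant-frequency
# row of a cost surface.
.map_cache <- new.env(parent = emptyenv())

gait_maps <- function(body, T_step, g, F_up, n_knots, n_samples,
                      cop_excursion) {
  key <- sprintf("%.10g|%.10g|%.10g|%d|%d|%.10g|%.10g|%.10g|%.10g|%.10g|%.10g|%.10g",
                 T_step, g, F_up, n_knots, n_samples, cop_excursion,
                 body$m_l, body$u, body$I_leg, body$torso_mass, body$L,
                 body$pelvis_width)
  hit <- .map_cache[[key]]
  if (!is.null(hit)) return(hit)

  mats <- threelp_matrices(body, g = g, upward_force = F_up)
  knots <- seq(0, T_step, length.out = n_knots)
  times <- sort(unique(round(c(seq(0, T_step, length.out = n_samples), knots),
                             12)))
  M_eff <- effective_mass(body)
  F_z <- M_eff * g - F_up
  cop_amp <- cop_excursion * body$foot_length
  tau_ankle <- function(t) {
    p <- cop_amp * (t / T_step - 0.5)
    mats$b_ankle * (-F_z * p)
  }
  zero_ankle <- function(t) rep(0, 4)

  out <- list(
    mats = mats, times = times, F_z = F_z, cop_amp = cop_amp,
    P_sag = propagate_map(mats$A, mats$b_hip, mats$c_sag, tau_ankle,
                          times, n_knots, T_step),
    P_lat = propagate_map(mats$A, mats$b_hip, mats$c_lat, zero_ankle,
                          times, n_knots, T_step),
    Q = hat_gram(T_step, n_knots)
  )
  if (length(ls(.map_cache)) > 300L)
    rm(list = ls(.map_cache), envir = .map_cache)
  assign(key, out, envir = .map_cache)
  out
}

# Minimum-effort solution of C p = d, minimizing  t(p) %*% W %*% p  where W
# penalizes only the torque-knot entries (tiny ridge elsewhere for numerical
# safety).  Standard KKT solve; returns NULL if the system is singular.
min_effort_solve <- function(C, d, W) {
  n <- ncol(C); m <- nrow(C)
  KKT <- rbind(cbind(2 * W, t(C)), cbind(C, matrix(0, m, m)))
  rhs <- c(rep(0, n), d)
  sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
  if (is.null(sol) || anyNA(sol) || any(!is.finite(sol))) return(NULL)
  sol[seq_len(n)]
}
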