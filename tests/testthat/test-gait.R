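test_that("a periodic gait has the imposed step length and mean speed", {
  g <- default_gait()
  expect_equal(g$step_length, 1.25 / 1.8)
  expect_equal(g$T_step, 1 / 1.8)
  # mean forward pelvis velocity equals the walking speed (exact from the
  # net displacement; the trapezoid of the sampled trace agrees closely)
  n <- length(g$time)
  expect_equal((g$pelvis_x[n] - g$pelvis_x[1]) / g$T_step, 1.25,
               tolerance = 1e-9)
  dt <- diff(g$time)
  vbar <- sum((g$pelvis_vx[-1] + g$pelvis_vx[-n]) / 2 * dt) / g$T_step
  expect_equal(vbar, 1.25, tolerance = 1e-4)
  # swing foot lands one step ahead with zero terminal velocity
  expect_equal(g$swingfoot_x[length(g$time)], g$step_length,
               tolerance = 1e-8)
  expect_lt(abs(g$swingfoot_vx[length(g$time)]), 1e-8)
  expect_lt(abs(g$swingfoot_vy[length(g$time)]), 1e-8)
})

test_that("returned gaits are mirrored-periodic to solver tolerance", {
  for (vf in list(c(0.6, 1.2), c(1.25, 1.8), c(1.6, 2.2))) {
    g <- find_periodic_gait(default_body(), walk_conditions(vf[1], vf[2]))
    expect_lt(periodicity_residual(g), 1e-6)
  }
})

test_that("forward ODE integration reproduces the end state", {
  skip_if_not_installed("deSolve")
  b <- default_body()
  g <- default_gait()
  mats <- walkcost:::threelp_matrices(b, g = 9.81, upward_force = 0)
  n_k <- length(g$theta_hip_sag)

  run_plane <- function(z0, theta, const_force, ankle) {
    tau_h <- stats::approxfun(seq(0, g$T_step, length.out = n_k), theta,
                              rule = 2)
    deriv <- function(t, z, p) {
      f <- mats$A %*% z + mats$b_hip * tau_h(t) + const_force +
        mats$b_ankle * ankle(t)
      list(as.numeric(f))
    }
    out <- deSolve::ode(z0, c(0, g$T_step), deriv, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-11)
    out[nrow(out), -1]
  }

  M <- effective_mass(b)
  cop_amp <- 0.8 * b$foot_length
  ankle_sag <- function(t) -M * 9.81 * cop_amp * (t / g$T_step - 0.5)
  z_sag <- run_plane(c(g$pelvis_x[1], g$swingfoot_x[1],
                       g$pelvis_vx[1], g$swingfoot_vx[1]),
                     g$theta_hip_sag, c(0, 0, 0, 0), ankle_sag)
  n <- length(g$time)
  expect_equal(unname(z_sag),
               c(g$pelvis_x[n], g$swingfoot_x[n],
                 g$pelvis_vx[n], g$swingfoot_vx[n]),
               tolerance = 1e-7)

  z_lat <- run_plane(c(g$pelvis_y[1], g$swingfoot_y[1],
                       g$pelvis_vy[1], g$swingfoot_vy[1]),
                     g$theta_hip_lat, mats$c_lat, function(t) 0)
  expect_equal(unname(z_lat),
               c(g$pelvis_y[n], g$swingfoot_y[n],
                 g$pelvis_vy[n], g$swingfoot_vy[n]),
               tolerance = 1e-7)
})

test_that("step length beyond the leg-splay bound raises no-gait-found", {
  expect_error(find_periodic_gait(default_body(), walk_conditions(2.0, 1.0)),
               "no-gait-found")
})

test_that("imposed step width is honoured and emergent width is returned", {
  b <- default_body()
  gw <- find_periodic_gait(b, walk_conditions(1.25, 1.8, step_width = 0.10))
  expect_equal(gw$step_width, 0.10, tolerance = 1e-8)
  ge <- find_periodic_gait(b, walk_conditions(1.25, 1.8))
  expect_true(is.finite(ge$step_width))
  expect_gt(ge$step_width, 0)
})

test_that("upper-body support force lowers the required torques", {
  b <- default_body()
  g0 <- find_periodic_gait(b, walk_conditions(1.25, 1.8))
  M <- effective_mass(b)
  g1 <- find_periodic_gait(b, walk_conditions(
    1.25, 1.8, upward_force = 0.5 * M * 9.81))
  t0 <- torque_magnitudes(g0)
  t1 <- torque_magnitudes(g1)
  expect_lt(t1[["ankle"]], t0[["ankle"]])
  expect_lt(sum(t1), sum(t0))
})

test_that("gait energies scale with M g L at fixed dimensionless gait", {
  b1 <- scale_body(70, 1.75)
  b2 <- scale_body(90, 1.90)
  # same dimensionless speed v/sqrt(gL) and frequency f sqrt(L/g)
  v1 <- 1.2; f1 <- 1.8
  scale_v <- sqrt(b2$L / b1$L)
  g1 <- find_periodic_gait(b1, walk_conditions(v1, f1))
  g2 <- find_periodic_gait(b2, walk_conditions(v1 * scale_v, f1 / scale_v))
  e1 <- e3lp_cost(g1, b1)
  e2 <- e3lp_cost(g2, b2)
  ratio_expected <- (90 * b2$L) / (70 * b1$L)
  expect_equal(e2 / e1, ratio_expected, tolerance = 1e-3)
})

test_that("the gait is invariant to torque-knot refinement", {
  b <- default_body()
  cond <- walk_conditions(1.0, 1.6)
  e <- vapply(c(3L, 6L, 12L), function(ns)
    e3lp_cost(find_periodic_gait(b, cond, n_segments = ns), b), numeric(1))
  expect_lt(max(abs(e - e[1])) / e[1], 0.01)
})
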