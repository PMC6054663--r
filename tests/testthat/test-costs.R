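test_that("CoM-redirection work matches the closed form", {
  # direct arithmetic oracle
  expect_equal(com_redirection_cost(70, 1.2, 0.3),
               0.5 * 70 * (1.2 * tan(0.3))^2)
  expect_equal(com_redirection_cost(70, 1.2, 0), 0)
  expect_equal(com_redirection_cost(70, 0, 0.4), 0)
  # even in alpha, strictly increasing in |alpha|
  a <- seq(0.05, 1.2, by = 0.05)
  e <- com_redirection_cost(70, 1.2, a)
  expect_equal(com_redirection_cost(70, 1.2, -a), e)
  expect_true(all(diff(e) > 0))
  expect_error(com_redirection_cost(70, 1.2, pi / 2), "geometry")
})

test_that("ground-clearance work is 2 m_l u c g and linear in c", {
  b <- default_body()
  b$m_l <- 11.3; b$u <- 0.4   # the hand-computed oracle configuration
  expect_equal(ground_clearance_cost(b, c = 0.165, g = 9.81),
               2 * 11.3 * 0.4 * 0.165 * 9.81)
  expect_equal(ground_clearance_cost(b, c = 0), 0)
  expect_equal(ground_clearance_cost(b, c = 0.33),
               2 * ground_clearance_cost(b, c = 0.165))
  # reduced gravity: leg half at full g, body half at reduced g
  expect_equal(ground_clearance_cost(b, c = 0.165, body_gravity_factor = 0.5),
               (1 + 0.5) / 2 * ground_clearance_cost(b, c = 0.165))
  expect_error(ground_clearance_cost(b, c = -0.1), ">= 0")
})

test_that("isometric weight support matches its factorized closed form", {
  b <- default_body()
  g <- default_gait()
  mu <- walk_muscle()
  E <- weight_support_cost(b, g, mu)
  dt <- diff(g$time)
  cosb <- cos(g$beta)
  int_cos <- sum((cosb[-1] + cosb[-length(cosb)]) / 2 * dt)
  theta <- mu$knee_angle * pi / 180
  closed <- mu$omega_max * alexander_minetti_phi(0) *
    effective_mass(b) * 9.81 * b$l_u * sin(theta / 2) * int_cos
  expect_equal(E, closed, tolerance = 1e-9)
  # zero knee angle and vanishing gravity both kill the cost
  expect_equal(weight_support_cost(b, g, mu,
                                   theta_trace = rep(0, length(g$time))), 0)
  expect_lt(weight_support_cost(b, g, mu, g = 1e-9), 1e-6)
  expect_error(weight_support_cost(b, g, mu,
                                   theta_trace = rep(-0.1, length(g$time))),
               "negative")
  fast <- seq(0, 30, length.out = length(g$time))   # omega >> omega_max
  expect_error(weight_support_cost(b, g, mu, theta_trace = fast),
               "omega_max")
})

test_that("the metabolic-rate curve has the isometric intercept", {
  expect_equal(alexander_minetti_phi(0), 0.054)
  x <- seq(-0.9, 0.9, by = 0.05)
  expect_true(all(alexander_minetti_phi(x) > 0))
  expect_error(alexander_minetti_phi(1), "out of range")
})

test_that("muscle efficiency interpolates over step frequency", {
  mu <- walk_muscle()
  expect_equal(efficiency(1.3, mu), 0.25)
  expect_equal(efficiency(2.9, mu), 0.25)
  tab <- data.frame(frequency = c(1.5, 2.0), eta = c(0.2, 0.3))
  muv <- walk_muscle(efficiency_mode = "variable", efficiency_table = tab)
  expect_equal(efficiency(1.5, muv), 0.2)   # node identity
  expect_equal(efficiency(1.75, muv), 0.25) # midpoint
  expect_equal(efficiency(1.0, muv), 0.2)   # clamped below
  expect_equal(efficiency(3.0, muv), 0.3)   # clamped above
  expect_error(walk_muscle(efficiency_mode = "variable",
                           efficiency_table = data.frame()), "table")
})

test_that("total cost combines components exactly", {
  expect_equal(total_cost(0, 0, 0, 0, 0.25)$E_walking, 0)
  expect_equal(total_cost(1, 1, 1, 2, 0.25)$E_walking, 3 / 0.25 + 2)
  cb <- total_cost(5, 3, 10, 4, 0.25, frequency = 1.8, M = 70, speed = 1.25)
  expect_equal(cb$E_walking, (5 + 3 + 10) / 0.25 + 4)
  expect_equal(cb$metabolic_rate, cb$E_walking * 1.8 / 70)
  expect_equal(cb$CoT, cb$E_walking * 1.8 / (70 * 1.25))
  expect_equal(cb$dimensionless_CoT, cb$CoT / 9.81)
  # perturbing a mechanical component by delta moves the total by delta/eta
  cb2 <- total_cost(5 + 0.7, 3, 10, 4, 0.25, frequency = 1.8, M = 70,
                    speed = 1.25)
  expect_equal(cb2$E_walking - cb$E_walking, 0.7 / 0.25)
  cb3 <- total_cost(5, 3, 10, 4 + 0.7, 0.25, frequency = 1.8, M = 70,
                    speed = 1.25)
  expect_equal(cb3$E_walking - cb$E_walking, 0.7)
  # CoT undefined at zero speed, rate still defined
  cb0 <- total_cost(1, 1, 1, 1, 0.25, frequency = 1.5, M = 70, speed = 0)
  expect_true(is.na(cb0$CoT))
  expect_false(is.na(cb0$metabolic_rate))
  expect_error(total_cost(-1, 0, 0, 0, 0.25), ">= 0")
  expect_error(total_cost(1, 1, 1, 1, 1.2), "eta")
})

test_that("component shares sum to one and isolate single components", {
  cb <- total_cost(5, 3, 10, 4, 0.25, frequency = 1.8, M = 70, speed = 1.25)
  sh <- component_shares(cb)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  only_gc <- total_cost(0, 0, 10, 0, 0.25, frequency = 1.8, M = 70,
                        speed = 1.25)
  expect_equal(unname(component_shares(only_gc)["ground_clearance"]), 1)
  zero <- total_cost(0, 0, 0, 0, 0.25)
  expect_error(component_shares(zero), "zero")
})

test_that("a cost breakdown serializes with units in the names", {
  cb <- walk_cost(default_body(), walk_conditions(1.25, 1.8))
  d <- as.data.frame(cb)
  expect_true(all(c("E_GC_J", "rate_W_per_kg", "CoT_J_per_kg_m") %in%
                    names(d)))
  j <- jsonlite::fromJSON(breakdown_json(cb))
  expect_equal(j$CoT_J_per_kg_m, cb$CoT, tolerance = 1e-12)
})
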