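# coarse frequency grid keeps the experiment suite quick; the optima are
# refined continuously from it
fgrid <- seq(1.1, 2.7, by = 0.2)

test_that("knee inverse kinematics follows the law of cosines", {
  expect_equal(knee_ik(0.9, 0.45, 0.45), 0)
  # numeric law-of-cosines oracle
  th <- pi - acos((0.45^2 + 0.45^2 - 0.85^2) / (2 * 0.45 * 0.45))
  expect_equal(knee_ik(0.85, 0.45, 0.45), th)
  d <- seq(0.88, 0.4, by = -0.04)
  expect_true(all(diff(vapply(d, knee_ik, numeric(1), 0.45, 0.45)) > 0))
  expect_error(knee_ik(0.95, 0.45, 0.45), "unreachable")
  expect_error(knee_ik(0.05, 0.45, 0.35), "degenerate")
})

test_that("fit_and_compare recovers affine relations exactly", {
  fake <- structure(list(
    spec = experiment_spec("foot_lift", values = c(0, 0.05, 0.1)),
    results = data.frame(value = c(0, 0.05, 0.1), mode = "constant",
                         feasible = TRUE,
                         rate_W_per_kg = NA_real_)
  ), class = "walk_experiment")
  emp <- c(2.0, 8.0)   # empirical rate = 2 + 8 x
  evalp <- 2 + 8 * fake$results$value
  # model identical to empirical
  fake$results$rate_W_per_kg <- evalp
  fc <- fit_and_compare(fake, emp)
  expect_equal(fc$trend, 1)
  expect_equal(fc$offset, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 1)
  # model = 2 * empirical + 1
  fake$results$rate_W_per_kg <- 2 * evalp + 1
  fc <- fit_and_compare(fake, emp)
  expect_equal(fc$trend, 2)
  expect_equal(fc$offset, 1)
  expect_equal(fc$r_squared, 1)
  # degenerate empirical curve
  expect_error(fit_and_compare(fake, c(3.0)), "degenerate")
})

test_that("R^2 agrees with a normal-equations oracle on a curved model", {
  fake <- structure(list(
    spec = experiment_spec("foot_lift", values = c(0, 1, 2)),
    results = data.frame(value = c(0, 1, 2), mode = "constant",
                         feasible = TRUE,
                         rate_W_per_kg = c(1, 2, 5))   # quadratic model
  ), class = "walk_experiment")
  emp <- c(0, 1)   # linear probe: empirical = x
  fc <- fit_and_compare(fake, emp)
  X <- cbind(1, c(0, 1, 2))
  y <- c(1, 2, 5)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(fc$r_squared, r2)
  expect_equal(fc$trend, beta[2, 1])
})

test_that("experiment plumbing adds no cost at the neutral value", {
  b <- default_body()
  base <- optimal_frequency(b, 1.25, frequencies = fgrid, details = TRUE)
  # reduced gravity at fraction 1 is the unmodified model
  ex <- run_experiment(experiment_spec("reduced_gravity", values = 1.0),
                       frequencies = fgrid)
  d <- ex$results[ex$results$mode == "constant", ]
  expect_equal(d$rate_W_per_kg, base$breakdown$metabolic_rate,
               tolerance = 1e-6)
  # obesity at the nominal mass reproduces normal walking
  ex2 <- run_experiment(experiment_spec("obesity", values = 1.25,
                                        mass_override = 70),
                        frequencies = fgrid)
  d2 <- ex2$results[ex2$results$mode == "constant", ]
  expect_equal(d2$rate_W_per_kg, base$breakdown$metabolic_rate,
               tolerance = 1e-6)
})

test_that("free-parameter changes act on the intended component only", {
  b <- default_body()
  cond <- walk_conditions(1.1, 1.7)
  cb1 <- walk_cost(b, cond, heel_lift = 0.165)
  cb2 <- walk_cost(b, cond, heel_lift = 0.33)
  expect_equal(cb2$E_GC, 2 * cb1$E_GC)
  expect_equal(cb2$E_CR, cb1$E_CR)
  expect_equal(cb2$E_3LP, cb1$E_3LP)
  # eta rescales the mechanical components exactly
  mu20 <- walk_muscle(eta = 0.20)
  cb3 <- walk_cost(b, cond, muscle = mu20)
  mech <- cb1$E_3LP + cb1$E_CR + cb1$E_GC
  expect_equal(cb3$E_walking - cb1$E_walking, mech / 0.2 - mech / 0.25)
})

test_that("a zero-width sensitivity range produces identical rows", {
  sw <- sensitivity_sweep("c", c(0.165, 0.165),
                          experiments = list(experiment_spec(
                            "foot_lift", values = c(0, 0.05))),
                          frequencies = fgrid)
  expect_equal(nrow(sw), 1L)   # min == mid == max collapses to one value
  sw2 <- sensitivity_sweep("c", c(0.11, 0.22),
                           experiments = list(experiment_spec(
                             "foot_lift", values = c(0, 0.05))),
                           frequencies = fgrid)
  expect_equal(nrow(sw2), 3L)
  expect_error(sensitivity_sweep("eta", c(0.1, 1.5)), "bounds")
})
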