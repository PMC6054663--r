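small_surface <- function() {
  if (is.null(.fixtures$small_surface))
    .fixtures$small_surface <- compute_surface(
      default_body(), speeds = seq(0.5, 1.4, by = 0.15),
      frequencies = seq(1.1, 2.3, by = 0.2), refine = FALSE)
  .fixtures$small_surface
}

test_that("a 1x1 grid reduces to a single cost evaluation", {
  b <- default_body()
  s <- compute_surface(b, speeds = 1.25, frequencies = 1.8, refine = FALSE)
  cb <- walk_cost(b, walk_conditions(1.25, 1.8))
  expect_equal(s$CoT[1, 1], cb$CoT, tolerance = 1e-10)
  expect_equal(s$E_GC[1, 1], cb$E_GC)
  expect_equal(s$optimum$CoT, cb$CoT, tolerance = 1e-10)
})

test_that("the optimum cell attains the feasible minimum", {
  s <- small_surface()
  expect_true(all(is.finite(s$CoT[s$feasible])))
  expect_equal(min(s$CoT, na.rm = TRUE), s$optimum$CoT, tolerance = 1e-9)
})

test_that("cells without a gait are masked, never dropped", {
  s <- compute_surface(default_body(), speeds = c(0.9, 2.0),
                       frequencies = c(1.0, 1.6), refine = FALSE)
  expect_false(s$feasible[2, 1])   # 2 m/s at 1 Hz: step too long
  expect_true(is.na(s$CoT[2, 1]))
  expect_true(s$feasible[1, 1])
  expect_error(compute_surface(default_body(), speeds = 3.0,
                               frequencies = 1.0),
               "empty surface")
})

test_that("raising muscle efficiency never raises the cost of transport", {
  b <- default_body()
  s1 <- compute_surface(b, speeds = c(0.8, 1.2), frequencies = c(1.4, 2.0),
                        muscle = walk_muscle(eta = 0.25), refine = FALSE)
  s2 <- compute_surface(b, speeds = c(0.8, 1.2), frequencies = c(1.4, 2.0),
                        muscle = walk_muscle(eta = 0.30), refine = FALSE)
  expect_true(all(s2$CoT <= s1$CoT + 1e-12, na.rm = TRUE))
})

test_that("optimal frequency is a local minimum with convex neighbourhood", {
  b <- default_body()
  f_star <- optimal_frequency(b, 1.0)
  cot <- function(f) walk_cost(b, walk_conditions(1.0, f))$CoT
  df <- 0.05
  expect_lte(cot(f_star), cot(f_star + df) + 1e-9)
  expect_lte(cot(f_star), cot(f_star - df) + 1e-9)
  # second differences positive within +/- 0.3 Hz
  fs <- seq(f_star - 0.3, f_star + 0.3, by = 0.1)
  cs <- vapply(fs, cot, numeric(1))
  expect_true(all(diff(cs, differences = 2) > -1e-6))
})

test_that("constrained optimum curves pass through the global optimum", {
  s <- small_surface()
  idx <- which(s$CoT == min(s$CoT, na.rm = TRUE), arr.ind = TRUE)[1, ]
  v_star <- s$speeds[idx[1]]; f_star <- s$frequencies[idx[2]]

  sp <- constrained_optima(s, "speed")
  row <- sp[abs(sp$value - v_star) < 1e-9, ]
  expect_equal(row$frequency, f_star)

  fr <- constrained_optima(s, "frequency")
  row <- fr[abs(fr$value - f_star) < 1e-9, ]
  expect_equal(row$speed, v_star)

  sl <- constrained_optima(s, "step_length")
  # the step-length curve lies on v = s f within grid tolerance
  expect_true(all(abs(sl$speed / sl$frequency - sl$value) <=
                    diff(s$speeds)[1] / min(s$frequencies) + 1e-9))
  # the three curves intersect near the global optimum
  best_sl <- sl[which.min(sl$CoT), ]
  expect_lte(abs(best_sl$speed - v_star), 2 * diff(s$speeds)[1])
  expect_lte(abs(best_sl$frequency - f_star), 2 * diff(s$frequencies)[1])
  expect_error(constrained_optima(s, "speed", values = 9),
               "outside")
})

test_that("the surface exports long-format rows with unit-named columns", {
  s <- small_surface()
  d <- as.data.frame(s)
  expect_equal(nrow(d), length(s$speeds) * length(s$frequencies))
  expect_true(all(c("speed_m_s", "frequency_Hz", "E_3LP_J", "CoT_J_per_kg_m",
                    "feasible") %in% names(d)))
  expect_equal(sum(d$feasible), sum(s$feasible))
})

test_that("prediction returns the optimum frequency per speed", {
  s <- small_surface()
  p <- predict(s, speeds = c(0.8, 1.1))
  expect_equal(nrow(p), 2L)
  expect_true(all(p$CoT > 0))
  # consistent with a direct optimal-frequency call (different coarse scan
  # grids, so agreement is to the refinement resolution)
  expect_equal(p$frequency[1], optimal_frequency(default_body(), 0.8),
               tolerance = 1e-2)
})
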