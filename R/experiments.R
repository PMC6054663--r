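#' Specification of a replicated gait experiment
#'
#' Bundles the condition mapping for the six literature conditions the
#' model replicates by changing only the experimental variable: imposed
#' step width, added segment mass, extra swing-foot lift, simulated reduced
#' gravity (upper-body unloading), flat-trajectory walking, and walking
#' with obesity (body-mass override).
#'
#' @param name One of `"step_width"`, `"added_mass"`, `"foot_lift"`,
#'   `"reduced_gravity"`, `"flat_walking"`, `"obesity"`.
#' @param subject_mass,subject_height Average subject anthropometry, kg / m.
#' @param speed Fixed walking speed(s), m/s.  For `flat_walking` and
#'   `obesity` the speed itself is the experimental variable.
#' @param values Values of the experimental variable (widths m, added kg,
#'   lifts m, gravity fractions, or speeds m/s).  Defaults follow the
#'   original studies' designs.
#' @param segment For `added_mass`: loaded segment (added mass is total
#'   across both legs for leg segments).
#' @param mass_override For `obesity`: the obese-group body mass, kg.
#' @return Object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(name = c("step_width", "added_mass", "foot_lift",
                                     "reduced_gravity", "flat_walking",
                                     "obesity"),
                            subject_mass = 70, subject_height = 1.75,
                            speed = 1.25, values = NULL, segment = "foot",
                            mass_override = 106) {
  name <- match.arg(name)
  if (is.null(values)) {
    L <- 0.53 * subject_height
    values <- switch(name,
      step_width = round(c(0, 0.1, 0.2, 0.3, 0.45) * L, 3),
      added_mass = c(0, 2, 4, 8),
      foot_lift = c(0, 0.025, 0.05, 0.075, 0.1),
      reduced_gravity = c(0.25, 0.5, 0.75, 1.0),
      flat_walking = c(0.7, 1.0, 1.3, 1.6),
      obesity = c(0.75, 1.0, 1.25, 1.5, 1.75))
  }
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (name == "reduced_gravity" && any(values <= 0 | values > 1))
    stop("gravity fractions must be in (0, 1]", call. = FALSE)
  if (any(values < 0)) stop("negative experimental values", call. = FALSE)
  structure(list(name = name, subject_mass = subject_mass,
                 subject_height = subject_height, speed = speed,
                 values = values, segment = segment,
                 mass_override = mass_override,
                 degree = if (name %in% c("step_width", "obesity")) 2L else 1L),
            class = "experiment_spec")
}

#' Run a replicated experiment
#'
#' For each value of the experimental variable, builds the modified body
#' and conditions, finds the CoT-optimal step frequency at the imposed
#' speed, and records the predicted metabolic rate and component breakdown
#' under both constant and variable muscle efficiency.  A polynomial of the
#' degree used by the original study (quadratic for step width and obesity,
#' linear otherwise) is fitted to each predicted curve.
#'
#' @param spec An `"experiment_spec"`.
#' @param muscle Base `"walk_muscle"`; both efficiency modes are derived
#'   from it.
#' @param heel_lift Heel-lift fraction of leg length.
#' @param ratios Anthropometric ratio table.
#' @param frequencies Frequency scan grid for the optimal-frequency search.
#' @param ... Passed to [find_periodic_gait()].
#' @return Object of class `"walk_experiment"`: a results data frame (one
#'   row per value and efficiency mode: metabolic rate W/kg, optimal
#'   frequency, component energies, feasibility flag) and the per-mode
#'   polynomial fits.
#' @export
run_experiment <- function(spec, muscle = walk_muscle(), heel_lift = 0.165,
                           ratios = body_ratio_table(),
                           frequencies = seq(1.0, 3.0, by = 0.1), ...) {
  stopifnot(inherits(spec, "experiment_spec"))
  modes <- c("constant", "variable")
  rows <- list()
  for (val in spec$values) {
    setup <- experiment_setup(spec, val, ratios)
    for (mode in modes) {
      mu <- muscle
      mu$efficiency_mode <- mode
      row <- data.frame(value = val, mode = mode, feasible = FALSE,
                        rate_W_per_kg = NA_real_, f_opt_Hz = NA_real_,
                        CoT = NA_real_, E_3LP = NA_real_, E_CR = NA_real_,
                        E_GC = NA_real_, E_WS = NA_real_)
      v_here <- if (spec$name %in% c("flat_walking", "obesity")) val else
        spec$speed[1]
      res <- tryCatch(
        optimal_frequency(setup$body, v_here, muscle = mu,
                          cond = setup$cond, frequencies = frequencies,
                          heel_lift = heel_lift, details = TRUE, ...),
        error = function(e) NULL)
      if (!is.null(res)) {
        cb <- res$breakdown
        row$feasible <- TRUE
        row$rate_W_per_kg <- cb$metabolic_rate
        row$f_opt_Hz <- res$frequency
        row$CoT <- cb$CoT
        row$E_3LP <- cb$E_3LP; row$E_CR <- cb$E_CR
        row$E_GC <- cb$E_GC; row$E_WS <- cb$E_WS
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  fits <- lapply(stats::setNames(modes, modes), function(mode) {
    d <- results[results$mode == mode & results$feasible, ]
    if (nrow(d) <= spec$degree) return(NULL)
    fit_polynomial(d$value, d$rate_W_per_kg, spec$degree)
  })
  structure(list(spec = spec, results = results, fits = fits),
            class = "walk_experiment")
}

# body/conditions mapping for one experimental value
experiment_setup <- function(spec, val, ratios) {
  body <- scale_body(spec$subject_mass, spec$subject_height, ratios)
  cond <- walk_conditions(spec$speed[1], 1.8)  # speed/frequency overridden
  switch(spec$name,
    step_width = { cond$step_width <- val },
    added_mass = {
      per_leg <- if (spec$segment == "waist") val else val / 2
      body <- add_point_mass(body, spec$segment, per_leg)
    },
    foot_lift = { cond$extra_foot_lift <- val },
    reduced_gravity = {
      cond$gravity_fraction <- val
    },
    flat_walking = { cond$flat_walking <- TRUE },
    obesity = { body <- scale_body(spec$mass_override, spec$subject_height,
                                   ratios) })
  list(body = body, cond = cond)
}

#' @export
print.walk_experiment <- function(x, ...) {
  cat(sprintf("Replicated experiment: %s\n", x$spec$name))
  d <- x$results[x$results$mode == "constant", ]
  cat(sprintf("  %d values of the experimental variable, speed(s) %s m/s\n",
              length(x$spec$values),
              paste(unique(x$spec$speed), collapse = ", ")))
  for (i in seq_len(nrow(d)))
    cat(sprintf("  value %7.3f -> rate %6.3f W/kg at f* %.2f Hz%s\n",
                d$value[i], d$rate_W_per_kg[i], d$f_opt_Hz[i],
                if (!d$feasible[i]) "  (no gait)" else ""))
  if (!is.null(x$fits$constant))
    cat(sprintf("  fit (constant eta), degree %d: %s, R^2 = %.4f\n",
                x$spec$degree,
                paste(sprintf("%.4g", x$fits$constant$coefficients),
                      collapse = ", "),
                x$fits$constant$r_squared))
  invisible(x)
}

# least-squares polynomial fit with R^2 (computed directly from the
# residual ratio; exact fits are legitimate here)
fit_polynomial <- function(x, y, degree) {
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  list(coefficients = unname(stats::coef(fit)),
       r_squared = r_squared(y, stats::fitted(fit)),
       degree = degree)
}

r_squared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / tss
}

#' Compare model predictions with an empirical polynomial
#'
#' Evaluates the supplied empirical polynomial (coefficients in increasing
#' powers, as published by the original study) at the experiment's variable
#' values and fits `model = a * empirical + b` by least squares.  A trend
#' `a` of one with offset `b` of zero means perfect agreement.
#'
#' @param experiment A `"walk_experiment"`.
#' @param empirical_poly Numeric coefficients of the empirical metabolic
#'   curve, increasing powers of the experimental variable.
#' @param mode Efficiency mode of the model curve to compare.
#' @return List with `trend`, `offset` and `r_squared`, plus the paired
#'   values.
#' @export
fit_and_compare <- function(experiment, empirical_poly,
                            mode = c("constant", "variable")) {
  stopifnot(inherits(experiment, "walk_experiment"))
  mode <- match.arg(mode)
  d <- experiment$results[experiment$results$mode == mode &
                            experiment$results$feasible, ]
  if (nrow(d) < 2L) stop("not enough feasible points", call. = FALSE)
  emp <- vapply(d$value, function(v)
    sum(empirical_poly * v^(seq_along(empirical_poly) - 1L)), numeric(1))
  if (stats::sd(emp) == 0)
    stop("degenerate empirical curve: constant values", call. = FALSE)
  fit <- stats::lm(d$rate_W_per_kg ~ emp)
  list(trend = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       r_squared = r_squared(d$rate_W_per_kg, stats::fitted(fit)),
       model = d$rate_W_per_kg, empirical = emp, value = d$value)
}

#' Sensitivity of experiment predictions to the free model parameters
#'
#' Re-runs a set of replicated experiments at the minimum, middle and
#' maximum of a free parameter's reported range (mid-stance knee angle,
#' heel-lift fraction, constant efficiency, or CoP excursion) and tabulates
#' the fitted model-curve coefficients.
#'
#' @param parameter `"theta"` (deg), `"c"` (fraction of leg length),
#'   `"eta"`, or `"cop"` (fraction of foot length).
#' @param range Numeric `c(min, max)` within physical bounds.
#' @param experiments List of `"experiment_spec"` objects.
#' @param muscle Base `"walk_muscle"`.
#' @param ... Passed to [run_experiment()].
#' @return Data frame: experiment, parameter value, polynomial coefficients
#'   of the constant-efficiency model curve and R^2.
#' @export
sensitivity_sweep <- function(parameter = c("theta", "c", "eta", "cop"),
                              range, experiments = list(experiment_spec()),
                              muscle = walk_muscle(), ...) {
  parameter <- match.arg(parameter)
  if (length(range) != 2L || range[1] > range[2])
    stop("range must be c(min, max)", call. = FALSE)
  ok <- switch(parameter,
    theta = all(range >= 0 & range <= 30),
    c = all(range >= 0 & range <= 0.5),
    eta = all(range > 0 & range < 1),
    cop = all(range >= 0 & range <= 1.2))
  if (!ok) stop("range outside physical bounds for ", parameter,
                call. = FALSE)
  pvals <- unique(c(range[1], mean(range), range[2]))
  rows <- list()
  for (pv in pvals) {
    mu <- muscle; heel <- 0.165; dots <- list(...)
    extra <- list()
    if (parameter == "theta") mu$knee_angle <- pv
    if (parameter == "eta") mu$eta <- pv
    if (parameter == "c") heel <- pv
    if (parameter == "cop") extra$cop_excursion <- pv
    for (spec in experiments) {
      ex <- do.call(run_experiment,
                    c(list(spec = spec, muscle = mu, heel_lift = heel),
                      extra, dots))
      ft <- ex$fits$constant
      if (is.null(ft)) next
      co <- ft$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = spec$name, parameter = parameter, value = pv,
        intercept = co[1], slope = co[2],
        quadratic = if (length(co) > 2) co[3] else NA_real_,
        r_squared = ft$r_squared)
    }
  }
  do.call(rbind, rows)
}
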