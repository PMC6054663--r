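#' Compute a cost-of-transport surface over speed and step frequency
#'
#' Solves a periodic 3LP gait for every (speed, frequency) grid cell,
#' assembles the four-component cost breakdown per cell, and locates the
#' minimum cost of transport, refined off-grid by nested golden-section
#' search.  Cells without a periodic gait (e.g. step length beyond the
#' small-angle validity bound) are flagged infeasible, never interpolated
#' over.
#'
#' @param body A `"walk_body"`.
#' @param speeds,frequencies Strictly increasing grids, m/s and Hz.
#' @param muscle A `"walk_muscle"`; its efficiency mode sets `eta` per cell.
#' @param cond Template `"gait_conditions"` whose speed/frequency are
#'   overridden cell by cell (carries width, gravity, lift, flat flags).
#' @param heel_lift Heel-lift fraction of leg length.
#' @param refine If `TRUE` (default), polish the grid optimum by nested
#'   continuous minimization to about 1e-3 resolution.
#' @param ... Passed to [find_periodic_gait()].
#' @return Object of class `"cost_surface"`: the grids, per-cell component
#'   energies and derived costs, a feasibility mask, and `optimum`
#'   (`speed`, `frequency`, `CoT`, `breakdown`).
#' @export
compute_surface <- function(body, speeds = seq(0.4, 2.0, by = 0.05),
                            frequencies = seq(1.0, 3.0, by = 0.05),
                            muscle = walk_muscle(),
                            cond = NULL, heel_lift = 0.165,
                            refine = TRUE, ...) {
  stopifnot(inherits(body, "walk_body"))
  if (length(speeds) == 0L || length(frequencies) == 0L)
    stop("speed and frequency grids must be non-empty", call. = FALSE)
  if (is.unsorted(speeds, strictly = TRUE) ||
      is.unsorted(frequencies, strictly = TRUE))
    stop("grids must be strictly increasing", call. = FALSE)

  nv <- length(speeds); nf <- length(frequencies)
  dims <- c(nv, nf)
  E3 <- E3s <- ECR <- EGC <- EWS <- array(NA_real_, dims)
  feasible <- array(FALSE, dims)

  for (i in seq_len(nv)) {
    for (j in seq_len(nf)) {
      cb <- tryCatch(
        walk_cost(body, cell_conditions(cond, speeds[i], frequencies[j]),
                  muscle = muscle, heel_lift = heel_lift, ...),
        error = function(e) NULL)
      if (!is.null(cb)) {
        feasible[i, j] <- TRUE
        E3[i, j] <- cb$E_3LP; E3s[i, j] <- cb$E_3LP_swing
        ECR[i, j] <- cb$E_CR; EGC[i, j] <- cb$E_GC; EWS[i, j] <- cb$E_WS
      }
    }
  }
  if (!any(feasible))
    stop("empty surface: no feasible gait in the requested grids",
         call. = FALSE)

  eta <- matrix(rep(efficiency(frequencies, muscle), each = nv), nv, nf)
  E_walk <- (E3 + ECR + EGC) / eta + EWS
  M <- body$total_mass
  fgrid <- matrix(rep(frequencies, each = nv), nv, nf)
  vgrid <- matrix(rep(speeds, nf), nv, nf)
  rate <- E_walk * fgrid / M
  CoT <- rate / vgrid
  CoT[!feasible] <- NA_real_

  idx <- which(CoT == min(CoT, na.rm = TRUE), arr.ind = TRUE)[1, ]
  opt_v <- speeds[idx[1]]; opt_f <- frequencies[idx[2]]

  surface <- structure(list(
    speeds = speeds, frequencies = frequencies,
    E_3LP = E3, E_3LP_swing = E3s, E_CR = ECR, E_GC = EGC, E_WS = EWS,
    eta = eta, E_walking = E_walk, metabolic_rate = rate, CoT = CoT,
    feasible = feasible, body = body, muscle = muscle,
    cond = cond, heel_lift = heel_lift, dots = list(...)
  ), class = "cost_surface")

  opt <- list(speed = opt_v, frequency = opt_f, CoT = CoT[idx[1], idx[2]])
  if (refine) {
    opt <- refine_optimum(body, muscle, cond, heel_lift, opt_v, opt_f,
                          speeds, frequencies, ...)
  }
  opt$breakdown <- walk_cost(body,
                             cell_conditions(cond, opt$speed, opt$frequency),
                             muscle = muscle, heel_lift = heel_lift, ...)
  opt$CoT <- opt$breakdown$CoT
  surface$optimum <- opt
  surface
}

# build per-cell conditions from an optional template
cell_conditions <- function(cond, speed, frequency) {
  if (is.null(cond)) return(walk_conditions(speed, frequency))
  cond$speed <- speed
  cond$frequency <- frequency
  cond
}

# nested continuous minimization around the grid optimum: inner golden
# search over frequency at fixed speed, outer over speed
refine_optimum <- function(body, muscle, cond, heel_lift, v0, f0,
                           speeds, frequencies, ...) {
  dv <- if (length(speeds) > 1) diff(speeds)[1] else 0.1
  df <- if (length(frequencies) > 1) diff(frequencies)[1] else 0.1
  f_lo <- max(min(frequencies), f0 - 2 * df)
  f_hi <- min(max(frequencies), f0 + 2 * df)
  v_lo <- max(min(speeds), v0 - 2 * dv)
  v_hi <- min(max(speeds), v0 + 2 * dv)

  cot_at <- function(v, f) {
    cb <- tryCatch(
      walk_cost(body, cell_conditions(cond, v, f), muscle = muscle,
                heel_lift = heel_lift, ...),
      error = function(e) NULL)
    if (is.null(cb) || is.na(cb$CoT)) Inf else cb$CoT
  }
  best_f <- function(v) {
    o <- stats::optimize(function(f) cot_at(v, f), c(f_lo, f_hi), tol = 1e-3)
    list(f = o$minimum, CoT = o$objective)
  }
  ov <- stats::optimize(function(v) best_f(v)$CoT, c(v_lo, v_hi), tol = 1e-3)
  bf <- best_f(ov$minimum)
  list(speed = ov$minimum, frequency = bf$f, CoT = bf$CoT)
}

#' Energetically optimal step frequency at a given speed
#'
#' Coarse grid scan over frequency followed by golden-section refinement of
#' the cost of transport; deterministic given the configuration.
#'
#' @param body A `"walk_body"`.
#' @param speed Walking speed, m/s (> 0).
#' @param muscle A `"walk_muscle"`.
#' @param cond Optional `"gait_conditions"` template.
#' @param frequencies Scan grid, Hz.
#' @param heel_lift Heel-lift fraction.
#' @param details If `TRUE` return a list with the refined frequency and
#'   its `"cost_breakdown"`; otherwise just the frequency.
#' @param ... Passed to [find_periodic_gait()].
#' @return Optimal step frequency in Hz (or a list, see `details`).
#' @export
optimal_frequency <- function(body, speed, muscle = walk_muscle(),
                              cond = NULL,
                              frequencies = seq(1.0, 3.0, by = 0.1),
                              heel_lift = 0.165, details = FALSE, ...) {
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  cot_at <- function(f) {
    cb <- tryCatch(
      walk_cost(body, cell_conditions(cond, speed, f), muscle = muscle,
                heel_lift = heel_lift, ...),
      error = function(e) NULL)
    if (is.null(cb) || is.na(cb$CoT)) Inf else cb$CoT
  }
  coarse <- vapply(frequencies, cot_at, numeric(1))
  if (all(!is.finite(coarse)))
    stop("no-gait-found: no feasible frequency at this speed", call. = FALSE)
  k <- which.min(coarse)
  lo <- frequencies[max(1L, k - 1L)]
  hi <- frequencies[min(length(frequencies), k + 1L)]
  o <- stats::optimize(cot_at, c(lo, hi), tol = 1e-3)
  if (!details) return(o$minimum)
  cb <- walk_cost(body, cell_conditions(cond, speed, o$minimum),
                  muscle = muscle, heel_lift = heel_lift, ...)
  list(frequency = o$minimum, CoT = o$objective, breakdown = cb)
}

#' Optimal-gait curves under speed, frequency or step-length constraints
#'
#' For each value of the constrained variable, the minimizing feasible cell
#' along the free dimension.  The step-length constraint traces the lines
#' `speed = s * frequency` through the surface.
#'
#' @param surface A `"cost_surface"`.
#' @param constraint `"speed"`, `"frequency"` or `"step_length"`.
#' @param values Constraint values; defaults to the corresponding grid (for
#'   step length, the range of feasible cell step lengths).
#' @return Data frame: constraint value, optimal speed, frequency, CoT.
#' @export
constrained_optima <- function(surface,
                               constraint = c("speed", "frequency",
                                              "step_length"),
                               values = NULL) {
  stopifnot(inherits(surface, "cost_surface"))
  constraint <- match.arg(constraint)
  sp <- surface$speeds; fr <- surface$frequencies
  CoT <- surface$CoT

  if (constraint == "speed") {
    if (is.null(values)) values <- sp
    if (any(values < min(sp) | values > max(sp)))
      stop("constraint value outside the speed grid", call. = FALSE)
    rows <- lapply(values, function(v) {
      i <- which.min(abs(sp - v))
      if (all(is.na(CoT[i, ]))) return(NULL)
      j <- which.min(CoT[i, ])
      data.frame(value = v, speed = sp[i], frequency = fr[j],
                 CoT = CoT[i, j])
    })
  } else if (constraint == "frequency") {
    if (is.null(values)) values <- fr
    if (any(values < min(fr) | values > max(fr)))
      stop("constraint value outside the frequency grid", call. = FALSE)
    rows <- lapply(values, function(f) {
      j <- which.min(abs(fr - f))
      if (all(is.na(CoT[, j]))) return(NULL)
      i <- which.min(CoT[, j])
      data.frame(value = f, speed = sp[i], frequency = fr[j],
                 CoT = CoT[i, j])
    })
  } else {
    sgrid <- outer(sp, 1 / fr)          # step length per cell
    if (is.null(values)) {
      feas <- sgrid[surface$feasible]
      values <- seq(min(feas), max(feas), length.out = 25)
    }
    if (any(values < min(sgrid) | values > max(sgrid)))
      stop("constraint value outside the surface's step lengths",
           call. = FALSE)
    tol <- max(diff(sp)[1] / min(fr), 1e-3)
    rows <- lapply(values, function(s) {
      on_line <- abs(sgrid - s) <= tol & surface$feasible
      if (!any(on_line)) return(NULL)
      CoTl <- ifelse(on_line, CoT, NA_real_)
      idx <- which(CoTl == min(CoTl, na.rm = TRUE), arr.ind = TRUE)[1, ]
      data.frame(value = s, speed = sp[idx[1]], frequency = fr[idx[2]],
                 CoT = CoT[idx[1], idx[2]])
    })
  }
  do.call(rbind, rows)
}

#' @export
print.cost_surface <- function(x, ...) {
  cat("Cost-of-transport surface\n")
  cat(sprintf("  speeds %.2f..%.2f m/s (%d), frequencies %.2f..%.2f Hz (%d)\n",
              min(x$speeds), max(x$speeds), length(x$speeds),
              min(x$frequencies), max(x$frequencies), length(x$frequencies)))
  cat(sprintf("  efficiency mode: %s\n", x$muscle$efficiency_mode))
  cat(sprintf("  feasible cells: %d / %d\n", sum(x$feasible),
              length(x$feasible)))
  cat(sprintf("  optimum: CoT %.3f J/kg/m at %.3f m/s, %.3f Hz\n",
              x$optimum$CoT, x$optimum$speed, x$optimum$frequency))
  invisible(x)
}

#' @export
summary.cost_surface <- function(object, ...) {
  opt <- object$optimum
  shares <- component_shares(opt$breakdown)
  cat("Cost-of-transport surface optimum\n")
  print(opt$breakdown)
  cat("  component shares of the metabolic total:\n")
  for (nm in names(shares))
    cat(sprintf("    %-18s %5.1f%%\n", nm, 100 * shares[nm]))
  cat(sprintf("  swing-attributed share: %.1f%%\n",
              100 * swing_share(opt$breakdown)))
  invisible(object)
}

#' Long-format export of a cost surface
#'
#' One row per grid cell with component energies (J/step), efficiency,
#' metabolic rate (W/kg), cost of transport (J/kg/m), dimensionless CoT and
#' the feasibility flag.
#' @param x A `"cost_surface"`.
#' @param row.names,optional,... S3 compatibility; unused.
#' @export
as.data.frame.cost_surface <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  nv <- length(x$speeds); nf <- length(x$frequencies)
  g <- if (is.null(x$cond)) 9.81 else x$cond$g
  data.frame(
    speed_m_s = rep(x$speeds, nf),
    frequency_Hz = rep(x$frequencies, each = nv),
    E_3LP_J = c(x$E_3LP), E_CR_J = c(x$E_CR), E_GC_J = c(x$E_GC),
    E_WS_J = c(x$E_WS), eta = c(x$eta),
    rate_W_per_kg = c(x$metabolic_rate),
    CoT_J_per_kg_m = c(x$CoT),
    dimensionless_CoT = c(x$CoT) / g,
    feasible = c(x$feasible)
  )
}

#' Predict the energetic optimum at new speeds
#'
#' For each requested speed, the cost-minimizing step frequency and its
#' cost of transport (continuous refinement, not grid lookup).
#' @param object A `"cost_surface"`.
#' @param speeds Speeds, m/s.
#' @param ... Unused.
#' @return Data frame: speed, optimal frequency, CoT.
#' @export
predict.cost_surface <- function(object, speeds = object$speeds, ...) {
  rows <- lapply(speeds, function(v) {
    r <- tryCatch(
      optimal_frequency(object$body, v, muscle = object$muscle,
                        cond = object$cond,
                        frequencies = object$frequencies,
                        heel_lift = object$heel_lift, details = TRUE),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(speed = v, frequency = r$frequency, CoT = r$CoT)
  })
  do.call(rbind, rows)
}

#' Contour plot of a cost surface
#'
#' Filled contours of the cost of transport with the optimum marked.
#' @param x A `"cost_surface"`.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.cost_surface <- function(x, ...) {
  z <- x$CoT
  graphics::filled.contour(
    x$speeds, x$frequencies, z,
    color.palette = grDevices::hcl.colors,
    xlab = "speed (m/s)", ylab = "step frequency (Hz)",
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(x$optimum$speed, x$optimum$frequency, pch = 4,
                       lwd = 2)
    }, ...)
  invisible(x)
}
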