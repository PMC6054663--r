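# shared fixtures, built lazily and reused across test files
.fixtures <- new.env(parent = emptyenv())

default_body <- function() {
  if (is.null(.fixtures$body)) .fixtures$body <- scale_body(70, 1.75)
  .fixtures$body
}

default_gait <- function() {
  if (is.null(.fixtures$gait))
    .fixtures$gait <- find_periodic_gait(default_body(),
                                         walk_conditions(1.25, 1.8))
  .fixtures$gait
}

# default-grid surfaces used by the acceptance criteria (computed once)
default_surface <- function(mode = "constant") {
  key <- paste0("surface_", mode)
  if (is.null(.fixtures[[key]])) {
    t0 <- Sys.time()
    .fixtures[[key]] <- compute_surface(
      default_body(), muscle = walk_muscle(efficiency_mode = mode))
    .fixtures[[paste0(key, "_secs")]] <-
      as.numeric(Sys.time() - t0, units = "secs")
  }
  .fixtures[[key]]
}

surface_seconds <- function(mode = "constant") {
  default_surface(mode)
  .fixtures[[paste0("surface_", mode, "_secs")]]
}

# mirrored-periodicity residual of a gait, computed from its stored traces:
# next-step state in the new stance frame must equal the start state
periodicity_residual <- function(g) {
  n <- length(g$time)
  ell <- g$step_length
  W <- g$step_width
  res_sag <- c(
    (g$pelvis_x[n] - ell) - g$pelvis_x[1],   # pelvis state repeats in the
    g$pelvis_vx[n] - g$pelvis_vx[1],         # new stance frame
    g$swingfoot_x[n] - ell,                  # foot lands one step ahead
    g$swingfoot_vx[n]                        # with zero velocity
  )
  res_lat <- c(
    -(g$pelvis_y[n] - W) - g$pelvis_y[1],    # mirrored pelvis state
    -g$pelvis_vy[n] - g$pelvis_vy[1],
    g$swingfoot_y[n] - W,                    # foot lands at the step width
    g$swingfoot_vy[n]
  )
  sqrt(sum(c(res_sag, res_lat)^2))
}

# integrated absolute torque over the step (sagittal + lateral hip, ankle)
torque_magnitudes <- function(g) {
  tm <- function(x) sum(abs(x[-1] + x[-length(x)]) / 2 * diff(g$time))
  c(hip = tm(g$tau_hip_sag) + tm(g$tau_hip_lat), ankle = tm(g$tau_ankle_sag))
}
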