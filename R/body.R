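#' Anthropometric segment-ratio table
#'
#' Segment masses as fractions of body mass and segment lengths as fractions
#' of stature, in the style of classic gait-analysis anthropometry tables.
#' The model lumps each lower limb into a single pendulum, so only the
#' fractions needed to place the leg centre of mass and compute its inertia
#' are kept.  The table ships as an editable YAML file; `body_ratio_table()`
#' loads and validates it.
#'
#' Mass fractions must satisfy `2 * (thigh + shank + foot) + torso == 1`
#' (torso here is the head-arms-trunk remainder).
#'
#' @param path Path to a YAML ratio table; default is the packaged table.
#' @return A named list of class `"body_ratios"`.
#' @export
body_ratio_table <- function(path = system.file("extdata", "body_ratios.yaml",
                                                package = "walkcost")) {
  raw <- yaml::read_yaml(path)
  required <- c("thigh_mass", "shank_mass", "foot_mass", "torso_mass",
                "leg_length", "thigh_length", "shank_length", "pelvis_width",
                "thigh_com", "shank_com", "foot_length")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("ratio table is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  r <- lapply(raw[required], as.numeric)
  msum <- 2 * (r$thigh_mass + r$shank_mass + r$foot_mass) + r$torso_mass
  if (abs(msum - 1) > 1e-6) {
    stop("mass fractions do not sum to 1 (2*legs + torso = ",
         format(msum), ")", call. = FALSE)
  }
  if (r$thigh_length + r$shank_length > r$leg_length + 1e-9) {
    stop("thigh + shank length fractions exceed leg length fraction",
         call. = FALSE)
  }
  structure(r, class = "body_ratios")
}

#' Build a scaled body model
#'
#' Scales a three-pendulum body model (two legs, one torso) to a subject's
#' mass and height.  Each leg is a pendulum of mass `m_l` with its centre of
#' mass `u` metres below the hip and an inertia about the hip computed from
#' the thigh, shank and foot point masses at their centre-of-mass distances.
#' The torso (head-arms-trunk) is a point mass at the pelvis.
#'
#' @param mass Body mass in kg (> 0).
#' @param height Stature in m (> 0).
#' @param ratios A `"body_ratios"` table, see [body_ratio_table()].
#' @return An object of class `"walk_body"` with fields
#'   `total_mass`, `height`, `L` (leg length, m), `l_u` (thigh length, m),
#'   `l_s` (shank length, m), `pelvis_width` (m), `foot_length` (m),
#'   `m_l` (per-leg mass, kg), `u` (leg CoM below hip, m), `I_leg`
#'   (leg inertia about the hip, kg m^2), `torso_mass` (kg) and
#'   `added_masses` (data frame of point masses attached later).
#' @examples
#' b <- scale_body(70, 1.75)
#' b$m_l                       # per-leg mass
#' b$torso_mass + 2 * b$m_l    # equals total mass
#' @export
scale_body <- function(mass, height, ratios = body_ratio_table()) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("'mass' must be a single positive number", call. = FALSE)
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0)
    stop("'height' must be a single positive number", call. = FALSE)
  r <- ratios

  L   <- r$leg_length * height
  l_u <- r$thigh_length * height
  l_s <- r$shank_length * height

  m_th <- r$thigh_mass * mass
  m_sh <- r$shank_mass * mass
  m_ft <- r$foot_mass * mass
  m_l  <- m_th + m_sh + m_ft

  # point-mass distances below the hip joint
  d_th <- r$thigh_com * l_u
  d_sh <- l_u + r$shank_com * l_s
  d_ft <- L                       # foot lumped at the end of the leg pendulum

  u     <- (m_th * d_th + m_sh * d_sh + m_ft * d_ft) / m_l
  I_leg <- m_th * d_th^2 + m_sh * d_sh^2 + m_ft * d_ft^2

  structure(list(
    total_mass   = mass,
    height       = height,
    L            = L,
    l_u          = l_u,
    l_s          = l_s,
    pelvis_width = r$pelvis_width * height,
    foot_length  = r$foot_length * height,
    m_l          = m_l,
    u            = u,
    I_leg        = I_leg,
    torso_mass   = r$torso_mass * mass,
    attach       = c(foot = d_ft, shank = d_sh, thigh = d_th),
    added_masses = data.frame(segment = character(), mass = numeric(),
                              distance = numeric(),
                              stringsAsFactors = FALSE)
  ), class = "walk_body")
}

#' Attach a point mass to the body model
#'
#' Adds load to one segment.  Waist loads augment the torso point mass only;
#' foot, shank and thigh loads augment the leg pendulum mass, shift its
#' centre of mass and add a parallel-axis `m d^2` term to the leg inertia at
#' the segment's attachment distance from the hip.
#'
#' @param body A `"walk_body"` object.
#' @param segment One of `"foot"`, `"shank"`, `"thigh"`, `"waist"`.
#' @param m Added mass in kg per loaded segment (>= 0).  Leg loads are per
#'   leg (the model loads both legs symmetrically).
#' @return The modified `"walk_body"`.
#' @export
add_point_mass <- function(body, segment, m) {
  stopifnot(inherits(body, "walk_body"))
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0)
    stop("added mass must be a single non-negative number", call. = FALSE)
  segment <- match.arg(segment, c("foot", "shank", "thigh", "waist"))
  if (m == 0) return(body)

  if (segment == "waist") {
    body$torso_mass <- body$torso_mass + m
    d <- 0
  } else {
    d <- unname(body$attach[segment])
    m_new     <- body$m_l + m
    body$u    <- (body$m_l * body$u + m * d) / m_new
    body$I_leg <- body$I_leg + m * d^2
    body$m_l  <- m_new
  }
  body$added_masses <- rbind(
    body$added_masses,
    data.frame(segment = segment, mass = m, distance = d,
               stringsAsFactors = FALSE)
  )
  body
}

#' Effective total mass carried by the model
#'
#' Torso plus both legs including any attached point masses (waist loads
#' count once, leg loads twice).
#' @param body A `"walk_body"`.
#' @return Mass in kg.
#' @export
effective_mass <- function(body) {
  stopifnot(inherits(body, "walk_body"))
  body$torso_mass + 2 * body$m_l
}

#' @export
print.walk_body <- function(x, ...) {
  cat("3LP body model\n")
  cat(sprintf("  input mass %.1f kg, height %.2f m\n", x$total_mass, x$height))
  cat(sprintf("  leg: length %.3f m, mass %.2f kg, CoM %.3f m below hip, ",
              x$L, x$m_l, x$u))
  cat(sprintf("inertia %.3f kg m^2 (about hip)\n", x$I_leg))
  cat(sprintf("  torso %.2f kg at pelvis, pelvis width %.3f m\n",
              x$torso_mass, x$pelvis_width))
  if (nrow(x$added_masses) > 0) {
    cat("  added point masses:\n")
    for (i in seq_len(nrow(x$added_masses)))
      cat(sprintf("    %.2f kg at %s\n", x$added_masses$mass[i],
                  x$added_masses$segment[i]))
  }
  cat(sprintf("  effective mass %.2f kg\n", effective_mass(x)))
  invisible(x)
}
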