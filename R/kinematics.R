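#' Three-stage schedule of the adhesion experiment
#'
#' The in vitro experiment has three stages: chemically dominated attachment
#' (0 to `t_attach`), mechanical translocation (`t_attach` to `t_transloc`),
#' and the diffusion-dominated tail (`t_transloc` to `t_end`). Each stage uses
#' its own mechanical time step, and the chemo-transport problem is
#' sub-incremented `substeps` times within each mechanical step.
#'
#' @param t_attach,t_transloc,t_end Stage boundaries in seconds.
#' @param dt_stage Numeric vector of three per-stage mechanical steps [s].
#' @param substeps Chemo sub-incrementation factor (integer >= 1).
#' @return Object of class `"stage_plan"`.
#' @export
stage_plan <- function(t_attach = 300, t_transloc = 600, t_end = 7200,
                       dt_stage = c(0.5, 0.1, 0.05), substeps = 100L) {
  if (!(0 < t_attach && t_attach < t_transloc && t_transloc < t_end))
    stop("stage boundaries must satisfy 0 < t_attach < t_transloc < t_end",
         call. = FALSE)
  if (length(dt_stage) != 3L || any(dt_stage <= 0))
    stop("`dt_stage` must be three positive time steps", call. = FALSE)
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("`substeps` must be >= 1", call. = FALSE)
  structure(list(t_attach = t_attach, t_transloc = t_transloc, t_end = t_end,
                 dt_stage = as.numeric(dt_stage), substeps = substeps),
            class = "stage_plan")
}

#' Contact-disc radius as a function of time
#'
#' Piecewise-linear, continuous schedule: zero at `t = 0` (tangent sphere),
#' `a_attach` at the end of attachment, `a_final` at the end of translocation,
#' constant afterwards. Defaults are the half-diameters observed at the two
#' stage ends (6.7 µm and 39.6 µm contact diameters).
#'
#' @param t Time(s) in seconds (vectorized).
#' @param plan A [stage_plan()].
#' @param a_attach,a_final Contact radii [µm] at the stage ends.
#' @return Contact radius [µm] for each `t`.
#' @export
contact_radius_schedule <- function(t, plan, a_attach = 3.35, a_final = 19.8) {
  if (any(t < 0)) stop("negative time in contact schedule", call. = FALSE)
  a <- numeric(length(t))
  i1 <- t <= plan$t_attach
  a[i1] <- a_attach * t[i1] / plan$t_attach
  i2 <- t > plan$t_attach & t <= plan$t_transloc
  a[i2] <- a_attach + (a_final - a_attach) *
    (t[i2] - plan$t_attach) / (plan$t_transloc - plan$t_attach)
  a[t > plan$t_transloc] <- a_final
  a
}

#' Volume-conserving spherical-cap shape for a given contact radius
#'
#' The current cell shape is modelled as a flat contact disc of radius `a` on
#' the slide plane plus a spherical cap of height `h` above it. `h` is the
#' unique positive root of the cap-volume equation
#' `pi * h * (3 a^2 + h^2) / 6 = V`, which enforces volume conservation; the
#' cap sphere radius follows as `R_s = (a^2 + h^2) / (2 h)`.
#'
#' @param a Contact-disc radius [µm], `a >= 0`.
#' @param V Enclosed volume [µm³], `V > 0`.
#' @return Object of class `"cap_geometry"`: list with `a`, `h`, `R_s`, `V`
#'   and the total current membrane `area` (disc + cap surface) [µm²].
#' @export
cap_shape <- function(a, V) {
  if (!is.finite(a) || a < 0) stop("`a` must be >= 0", call. = FALSE)
  if (!is.finite(V) || V <= 0) stop("`V` must be > 0", call. = FALSE)
  b <- 6 * V / pi                      # h^3 + 3 a^2 h - b = 0
  if (a == 0) {
    h <- b^(1 / 3)
  } else {
    # depressed cubic with positive linear coefficient: single real root
    disc <- sqrt(b^2 / 4 + a^6)
    h <- (b / 2 + disc)^(1 / 3) - (disc - b / 2)^(1 / 3)
    # one Newton polish against round-off
    h <- h - (h^3 + 3 * a^2 * h - b) / (3 * h^2 + 3 * a^2)
  }
  if (!is.finite(h) || h <= 0)
    stop("cap height solve failed (no positive root)", call. = FALSE)
  R_s <- if (a > 0) (a^2 + h^2) / (2 * h) else h / 2
  structure(list(a = a, h = h, R_s = R_s, V = pi * h * (3 * a^2 + h^2) / 6,
                 area = pi * a^2 + 2 * pi * R_s * h),
            class = "cap_geometry")
}

#' Place reference nodes on the current spread shape
#'
#' Monotone area-fraction map: the reference node whose cumulative reference
#' area fraction (counted from the pole facing the slide, `theta = pi`) is `f`
#' is placed at the point of the current surface -- contact disc traversed
#' from its centre, then the spherical cap up to the apex -- with the same
#' cumulative current-area fraction. The areal stretch is spatially uniform
#' and equals the global area ratio (current area / `4 pi r0^2`); nodes whose
#' fraction falls inside the disc get a gap of exactly zero.
#'
#' @param mesh A [build_meridian_mesh()] mesh.
#' @param cap A [cap_shape()] geometry.
#' @param t Time stamp [s] stored in the frame.
#' @return Object of class `"kinematics_frame"`: list with `t`, meridian
#'   positions `rho` (axial distance) and `y` (height) [µm], per-node gap
#'   `g_N` [µm], per-node areal stretch `lambda_a`, logical `contact`
#'   (node lies on the contact disc), contact radius `a`, and current total
#'   membrane `area` [µm²].
#' @export
map_reference_to_current <- function(mesh, cap, t = NA_real_) {
  stopifnot(inherits(mesh, "sphere_mesh"), inherits(cap, "cap_geometry"))
  f <- (1 + cos(mesh$theta)) / 2    # cumulative area fraction from theta = pi
  A <- cap$area
  f_disc <- pi * cap$a^2 / A
  on_disc <- f <= f_disc + 1e-15
  rho <- numeric(mesh$n)
  y <- numeric(mesh$n)
  rho[on_disc] <- sqrt(pmax(f[on_disc], 0) * A / pi)
  if (any(!on_disc)) {
    yc <- cap$h - cap$R_s           # cap sphere centre height
    yy <- (f[!on_disc] - f_disc) * A / (2 * pi * cap$R_s)  # zone area ~ height
    yy <- pmin(yy, cap$h)
    rho[!on_disc] <- sqrt(pmax(cap$R_s^2 - (yy - yc)^2, 0))
    y[!on_disc] <- yy
  }
  g_N <- y                          # plane slide at y = 0, outward normal e2
  g_N[on_disc] <- 0
  structure(list(t = t, rho = rho, y = y, g_N = g_N,
                 lambda_a = rep(A / mesh$area, mesh$n),
                 contact = on_disc, a = cap$a, area = A),
            class = "kinematics_frame")
}

#' Gap function of a kinematics frame
#'
#' With the slide occupying the plane `y = 0` and the cell above it, the gap
#' of each membrane node is simply its height. Negative heights mean the
#' membrane penetrated the rigid slide and are a contract violation.
#'
#' @param frame A [map_reference_to_current()] frame.
#' @return Per-node gap [µm].
#' @export
gap_function <- function(frame) {
  stopifnot(inherits(frame, "kinematics_frame"))
  if (any(frame$y < -1e-12))
    stop("interpenetration: negative membrane height", call. = FALSE)
  frame$g_N
}

#' Hertz-Signorini-Moreau complementarity check
#'
#' Frictionless unilateral contact requires, at every node, a non-negative
#' gap, a non-positive (compressive) normal traction, and a vanishing product:
#' `g_N >= 0`, `p_N <= 0`, `p_N * g_N = 0`.
#'
#' @param g_N Per-node gaps [µm].
#' @param p_N Per-node normal pressures (compression negative).
#' @param tol Tolerance on the sign conditions.
#' @param tol_c Tolerance on the complementarity product.
#' @return Integer indices of the violating nodes (empty if none).
#' @export
hsm_check <- function(g_N, p_N, tol = 1e-10, tol_c = 1e-8) {
  if (length(g_N) != length(p_N))
    stop("`g_N` and `p_N` must have equal length", call. = FALSE)
  bad <- (g_N < -tol) | (p_N > tol) | (abs(g_N * p_N) > tol_c)
  which(bad)
}

#' @export
print.kinematics_frame <- function(x, ...) {
  cat("Kinematics frame at t =", x$t, "s: contact radius", format(x$a),
      "µm, membrane area", format(x$area, digits = 8), "µm²\n")
  cat("  areal stretch", format(x$lambda_a[1], digits = 6),
      "| contact nodes:", sum(x$contact), "\n")
  invisible(x)
}
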