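#' Integrate nodal densities to molecule totals
#'
#' Referential concentrations integrate over the reference area without a
#' Jacobian: `N_x = sum(weights * c_x)`. Works for both model variants (the
#' split variant sums its mobile and immobile pools).
#'
#' @param state A `"field_state"`.
#' @param mesh The matching [build_meridian_mesh()] mesh.
#' @param frame Optional kinematics frame (provides the contact area).
#' @return One-row data frame: `t` (s), `N_R_free`, `N_C`, `N_L_free`,
#'   `N_L_available` (molecule counts), `contact_area` (µm², `NA` without a
#'   frame).
#' @export
integrate_totals <- function(state, mesh, frame = NULL) {
  w <- mesh$weights
  if (length(w) != length(state$S_L))
    stop("state and mesh sizes differ", call. = FALSE)
  data.frame(
    t = state$t,
    N_R_free = sum(w * state_free(state)),
    N_C = sum(w * state_complex(state)),
    N_L_free = sum(w * state$c_L),
    N_L_available = sum(w * state$S_L),
    contact_area = if (is.null(frame)) NA_real_ else pi * frame$a^2)
}

#' Complex-count curve normalized at a reference time
#'
#' Total complexes over the membrane, divided by their value at `t_norm`
#' (1800 s by default, matching how fluorescence time series of the same
#' experiment are normalized).
#'
#' @param traj A [run_simulation()] trajectory.
#' @param t_norm Normalization time [s]; must match an output time within
#'   half the output cadence.
#' @return Data frame with `t` and the dimensionless `N_C_norm`.
#' @export
normalized_complex_curve <- function(traj, t_norm = 1800) {
  i <- which.min(abs(traj$times - t_norm))
  if (abs(traj$times[i] - t_norm) > max(diff(traj$times)))
    stop("`t_norm` outside the trajectory range", call. = FALSE)
  norm <- traj$totals$N_C[i]
  if (!is.finite(norm) || norm <= 0)
    stop("undefined normalization: N_C(t_norm) is not positive", call. = FALSE)
  data.frame(t = traj$times, N_C_norm = traj$totals$N_C / norm)
}

#' Radial profile of the complex density
#'
#' Tabulates the current-configuration complex density (referential density
#' divided by the areal stretch) against the current radial coordinate of
#' each node — the view in which the "coffee ring" at the contact-area
#' boundary shows up.
#'
#' @param state A `"field_state"`.
#' @param frame The matching kinematics frame.
#' @return Data frame with `rho` (µm), `g_N` (µm), `c_C_current`
#'   (molecules/µm², current configuration), and logical `contact`; the
#'   contact radius is attached as attribute `"a"`.
#' @export
ring_profile <- function(state, frame) {
  cc <- state_complex(state)
  out <- data.frame(rho = frame$rho, g_N = frame$g_N,
                    c_C_current = cc / frame$lambda_a,
                    contact = frame$contact)
  attr(out, "a") <- frame$a
  out
}

#' Apical residual free-receptor fraction
#'
#' Mean current-configuration free-receptor density over the apical membrane
#' (nodes with gap above `g_min`), relative to the initial uniform density.
#' The mean is weighted by current area, i.e.
#' `sum(w * c_free) / sum(w * lambda_a)` over the apical nodes.
#'
#' @param state A `"field_state"`.
#' @param frame The matching kinematics frame.
#' @param mesh The mesh.
#' @param g_min Gap threshold defining "apical" [µm].
#' @param c_ref Reference initial density [molecules/µm²].
#' @return Dimensionless fraction (1 = initial density).
#' @export
apical_free_fraction <- function(state, frame, mesh, g_min = 1,
                                 c_ref = 19.1) {
  idx <- frame$g_N > g_min
  if (!any(idx)) stop("no apical nodes above the gap threshold", call. = FALSE)
  w <- mesh$weights[idx]
  cur <- sum(w * state_free(state)[idx]) / sum(w * frame$lambda_a[idx])
  cur / c_ref
}

#' Fraction of total receptors still unbound
#'
#' @param traj A [run_simulation()] trajectory.
#' @param when Output-time index (defaults to the last).
#' @return `N_R_free / (N_R_free + N_C)` at that time.
#' @export
unbound_fraction <- function(traj, when = nrow(traj$totals)) {
  tt <- traj$totals[when, ]
  tt$N_R_free / (tt$N_R_free + tt$N_C)
}
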