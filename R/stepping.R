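#' Initial field state for the base (single-pool) model
#'
#' Receptors are uniform on the suspended cell; ligand and complex densities
#' start at zero, so the conserved difference `c_D = c_R - c_L` equals the
#' initial receptor density and the available-ligand baseline `S_L` is zero
#' (the supply ramps in as the membrane approaches the slide).
#'
#' @param mesh A [build_meridian_mesh()] mesh.
#' @param c_R0 Initial receptor density [molecules/µm²]. Alternatively give
#'   `N_total` to derive it as `N_total / (4 pi r0^2)`.
#' @param N_total Total receptor count on the membrane (default 24000).
#' @return Object of class `"field_state"` with `t`, `c_D`, `c_R`, `c_L`,
#'   `c_C`, `S_L` (all referential densities, molecules/µm²).
#' @export
init_state_base <- function(mesh, c_R0 = NULL, N_total = 24000) {
  if (is.null(c_R0)) c_R0 <- N_total / mesh$area
  z <- numeric(mesh$n)
  structure(list(t = 0, c_D = rep(c_R0, mesh$n), c_R = rep(c_R0, mesh$n),
                 c_L = z, c_C = z, S_L = z, model = "base"),
            class = "field_state")
}

#' Initial field state for the mobile/immobile split model
#'
#' A fraction of the receptors (23% for VEGFR2 by FRAP) is immobile at every
#' material point; the immobile nodal total `c_i` is conserved in time, the
#' mobile total `c_m` diffuses through its free part.
#'
#' @inheritParams init_state_base
#' @param immobile_frac Immobile fraction of the initial receptor density.
#' @return Object of class `"field_state"` (split variant) with conserved
#'   totals `c_m`, `c_i` and components `c_R_m`, `c_R_i`, `c_L`, `c_C_m`,
#'   `c_C_i`, `S_L`.
#' @export
init_state_split <- function(mesh, c_R0 = NULL, N_total = 24000,
                             immobile_frac = 0.23) {
  if (immobile_frac < 0 || immobile_frac > 1)
    stop("`immobile_frac` must be in [0, 1]", call. = FALSE)
  if (is.null(c_R0)) c_R0 <- N_total / mesh$area
  z <- numeric(mesh$n)
  ci <- immobile_frac * c_R0
  cm <- c_R0 - ci
  structure(list(t = 0, c_m = rep(cm, mesh$n), c_i = rep(ci, mesh$n),
                 c_R_m = rep(cm, mesh$n), c_R_i = rep(ci, mesh$n),
                 c_L = z, c_C_m = z, c_C_i = z, S_L = z, model = "split"),
            class = "field_state")
}

#' Advance the base model over one mechanical step
#'
#' Integrates the conserved difference `c_D` with the trapezoidal rule for
#' the diffusive flux over `substeps` chemo sub-increments, the supply `S_L`
#' and the equilibrium coefficient interpolated linearly between the two
#' kinematics frames. After every linear update the nodal equilibrium
#' constraint is re-solved; the staggered iteration runs to a relative
#' update below 1e-10 (at most 50 iterations).
#'
#' @param state A base-model [init_state_base()] state at `frame_prev`.
#' @param frame_prev,frame_next Kinematics frames bracketing the step.
#' @param dt Mechanical time step [s].
#' @param ops [assemble_operators()] operators.
#' @param p [chemistry_params()].
#' @param substeps Chemo sub-incrementation factor.
#' @return The updated `"field_state"` at `state$t + dt`.
#' @export
step_base <- function(state, frame_prev, frame_next, dt, ops, p,
                      substeps = 1L) {
  stopifnot(state$model == "base")
  SL1 <- available_ligands(frame_next$g_N, p)
  al0 <- alpha_coefficient(frame_prev$lambda_a, p)
  al1 <- alpha_coefficient(frame_next$lambda_a, p)
  out <- cpp_advance_base(state$c_D, state$S_L, SL1, al0, al1,
                          ops$Md, ops$Ml, ops$Mu, ops$Kd, ops$Kl, ops$Ku,
                          dt, as.integer(substeps), 1e-10, 50L)
  structure(list(t = state$t + dt, c_D = out$c_D, c_R = out$c_R,
                 c_L = out$c_L, c_C = out$c_C, S_L = SL1, model = "base"),
            class = "field_state")
}

#' Advance the mobile/immobile split model over one mechanical step
#'
#' Same trapezoidal scheme as [step_base()], but the diffusive flux is
#' carried by the free mobile receptors only; the immobile nodal total is
#' pointwise constant in time (no flux, no supply of receptors).
#'
#' @inheritParams step_base
#' @param state A split-model [init_state_split()] state.
#' @return The updated split `"field_state"`.
#' @export
step_split <- function(state, frame_prev, frame_next, dt, ops, p,
                       substeps = 1L) {
  stopifnot(state$model == "split")
  SL1 <- available_ligands(frame_next$g_N, p)
  al0 <- alpha_coefficient(frame_prev$lambda_a, p)
  al1 <- alpha_coefficient(frame_next$lambda_a, p)
  out <- cpp_advance_split(state$c_m, state$c_i, state$S_L, SL1, al0, al1,
                           ops$Md, ops$Ml, ops$Mu, ops$Kd, ops$Kl, ops$Ku,
                           dt, as.integer(substeps), 1e-10, 50L)
  structure(list(t = state$t + dt, c_m = out$c_m, c_i = state$c_i,
                 c_R_m = out$c_R_m, c_R_i = out$c_R_i, c_L = out$c_L,
                 c_C_m = out$c_C_m, c_C_i = out$c_C_i, S_L = SL1,
                 model = "split"),
            class = "field_state")
}

## free receptor / complex densities regardless of variant
state_free <- function(state) {
  if (state$model == "split") state$c_R_m + state$c_R_i else state$c_R
}
state_complex <- function(state) {
  if (state$model == "split") state$c_C_m + state$c_C_i else state$c_C
}
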