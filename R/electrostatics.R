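#' Parameters of the screened-Coulomb binding-traction model
#'
#' Short-range receptor-ligand attraction derived from screened electrostatic
#' interactions between the membrane and the coated slide: an interaction
#' constant `C`, the inverse Debye length `K`, the receptor-ligand density
#' `rho_rl`, and the minimum approach distance `h0` below which the model is
#' not defined. Defaults are the literature values for this system; `K = 1`
#' is interpreted as 1/µm.
#'
#' @param C Interaction constant [fN µm^-5].
#' @param K Inverse Debye length [1/µm].
#' @param rho_rl Receptor-ligand density [molecules/µm²]. The literature
#'   treats this as the constant 1e5; [effective_rho_rl()] offers the
#'   field-dependent alternative.
#' @param h0 Minimum approach distance [µm] (9 nm).
#' @return Object of class `"traction_params_gn"`.
#' @export
traction_params_gn <- function(C = 1.17e-7, K = 1, rho_rl = 1e5, h0 = 0.009) {
  if (any(c(C, K, rho_rl, h0) <= 0))
    stop("all screened-Coulomb parameters must be positive", call. = FALSE)
  structure(list(C = C, K = K, rho_rl = rho_rl, h0 = h0),
            class = "traction_params_gn")
}

#' Parameters of the exponential spreading-traction model
#'
#' The long-range attractive traction used in cytoskeleton-free spreading
#' models: scale `Q` and decay length `delta_p`.
#'
#' @param Q Traction scale [fN/µm²].
#' @param delta_p Decay length [µm].
#' @return Object of class `"traction_params_exp"`.
#' @export
traction_params_exp <- function(Q = 5e7, delta_p = 0.13) {
  if (Q <= 0 || delta_p <= 0)
    stop("`Q` and `delta_p` must be positive", call. = FALSE)
  structure(list(Q = Q, delta_p = delta_p), class = "traction_params_exp")
}

#' Screened-Coulomb binding traction
#'
#' Signed normal traction (attraction negative):
#' `-C (K g + 1) ((K g + 1)^2 + 1) g^-5 exp(-2 K g) rho_rl`.
#' Only defined for gaps at or above the minimum approach distance `h0`.
#'
#' @param g Gap(s) [µm], `g >= h0`.
#' @param p A [traction_params_gn()] object.
#' @return Traction [fN/µm²] (negative = attractive).
#' @export
traction_gn <- function(g, p = traction_params_gn()) {
  if (any(g < p$h0))
    stop("gap below the minimum approach distance h0", call. = FALSE)
  kg1 <- p$K * g + 1
  -p$C * kg1 * (kg1^2 + 1) * g^(-5) * exp(-2 * p$K * g) * p$rho_rl
}

#' Exponential spreading traction
#'
#' Signed normal traction `-Q (g / delta_p) exp(-g / delta_p)`; zero at
#' contact, peak magnitude `Q / e` at `g = delta_p`, vanishing at long range.
#'
#' @param g Gap(s) [µm], non-negative.
#' @param p A [traction_params_exp()] object.
#' @return Traction [fN/µm²] (negative = attractive).
#' @export
traction_exp <- function(g, p = traction_params_exp()) {
  if (any(g < 0)) stop("negative gap", call. = FALSE)
  -p$Q * (g / p$delta_p) * exp(-g / p$delta_p)
}

#' Tabulate and compare the two binding-traction models
#'
#' Evaluates both tractions on a gap grid (the screened-Coulomb model is
#' `NA` below its minimum approach distance) together with the pointwise
#' magnitude ratio exponential/screened-Coulomb. The ratio is how far apart
#' the two literature models are over the physiological gap range — several
#' orders of magnitude, which is the quantitative basis for concluding that
#' screened electrostatics cannot drive cell spreading.
#'
#' @param g_grid Gap values [µm].
#' @param p_gn,p_exp Parameter sets of the two models.
#' @return Data frame with `g`, `traction_gn`, `traction_exp`, `ratio`.
#' @export
traction_profile <- function(g_grid, p_gn = traction_params_gn(),
                             p_exp = traction_params_exp()) {
  tg <- rep(NA_real_, length(g_grid))
  ok <- g_grid >= p_gn$h0
  tg[ok] <- traction_gn(g_grid[ok], p_gn)
  te <- traction_exp(g_grid, p_exp)
  data.frame(g = g_grid, traction_gn = tg, traction_exp = te,
             ratio = abs(te) / abs(tg))
}

#' Field-dependent receptor-ligand density
#'
#' The constant `rho_rl = 1e5` of the screened-Coulomb model is defensible
#' only if it counts all receptors on the membrane; the local alternative is
#' the pointwise minimum of the free receptor and ligand densities.
#'
#' @param state A `"field_state"`.
#' @return Per-node density [molecules/µm²].
#' @export
effective_rho_rl <- function(state) {
  pmin(state_free(state), state$c_L)
}
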