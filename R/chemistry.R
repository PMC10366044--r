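#' Parameters of the receptor-ligand reaction R + L <-> C
#'
#' Collects the constitutive constants of the surface chemistry: standard
#' Gibbs free energy and temperature (or directly the invariant equilibrium
#' constant), saturation limits, the maximum available-ligand density on the
#' slide, the chemical length scale that tunes ligand availability with the
#' gap, and the receptor diffusivity. Defaults are the calibrated
#' VEGFR2-gremlin values for an endothelial cell of radius 10 µm.
#'
#' When both `dG0` and `K_eq` are supplied they must agree through
#' `K_eq = exp(-dG0 / (R T))` within 0.1% relative.
#'
#' @param dG0 Standard Gibbs free energy of binding [J/mol].
#' @param T Absolute temperature [K].
#' @param K_eq Invariant equilibrium constant (dimensionless). Computed from
#'   `dG0` and `T` when `NULL`.
#' @param cLmax Ligand saturation limit [molecules/µm²].
#' @param cRmax,cCmax Receptor and complex saturation limits
#'   [molecules/µm²]; equal by default, in which case they cancel from the
#'   equilibrium coefficient.
#' @param cLav Maximum available-ligand density at contact [molecules/µm²].
#' @param ell_chem Chemical length scale [µm].
#' @param D_R Receptor diffusivity [µm²/s].
#' @param kf,kb Optional forward/backward kinetic constants (diagnostic
#'   finite-kinetics rate only; the solver assumes instantaneous equilibrium).
#' @return Object of class `"chemistry_params"`.
#' @export
chemistry_params <- function(dG0 = -32949.0, T = 310.15, K_eq = NULL,
                             cLmax = 16000, cRmax = 16000, cCmax = cRmax,
                             cLav = 90, ell_chem = 0.2, D_R = 0.198,
                             kf = NULL, kb = NULL) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  K_from_G <- if (!is.null(dG0)) equilibrium_constant(dG0, T) else NULL
  if (is.null(K_eq)) {
    if (is.null(K_from_G))
      stop("supply either `dG0` (with `T`) or `K_eq`", call. = FALSE)
    K_eq <- K_from_G
  } else if (!is.null(K_from_G) &&
             abs(K_eq - K_from_G) > 1e-3 * abs(K_eq)) {
    stop("`K_eq` inconsistent with exp(-dG0/(R*T)) beyond 0.1% relative",
         call. = FALSE)
  }
  if (any(c(cLmax, cRmax, cCmax, ell_chem, D_R) <= 0) || cLav < 0)
    stop("saturations, lengths and diffusivity must be positive", call. = FALSE)
  if (cLav > cLmax)
    stop("`cLav` cannot exceed the ligand saturation `cLmax`", call. = FALSE)
  structure(list(dG0 = dG0, T = T, K_eq = K_eq, cLmax = cLmax, cRmax = cRmax,
                 cCmax = cCmax, cLav = cLav, ell_chem = ell_chem, D_R = D_R,
                 kf = kf, kb = kb),
            class = "chemistry_params")
}

#' Invariant equilibrium constant from the Gibbs free energy
#'
#' `K_eq = exp(-dG0 / (R T))` with the universal gas constant
#' `R = 8.314462 J/(mol K)`.
#'
#' @param dG0 Standard Gibbs free energy [J/mol].
#' @param T Absolute temperature [K].
#' @return Dimensionless equilibrium constant.
#' @examples
#' equilibrium_constant(-32949.0, 310.15)  # ~= 354058
#' @export
equilibrium_constant <- function(dG0, T) {
  if (any(T <= 0)) stop("temperature must be positive", call. = FALSE)
  exp(-dG0 / (R_GAS * T))
}

#' Gap-dependent available-ligand density
#'
#' Ligands adsorbed on the slide can engage a receptor only when the membrane
#' is close: the available density decays exponentially with the gap over the
#' chemical length scale, `S_L = cLav * exp(-g_N / ell_chem)`. It is maximal
#' at contact and vanishes at long range.
#'
#' @param g_N Gap(s) [µm], non-negative.
#' @param p A [chemistry_params()] object.
#' @return Available-ligand density [molecules/µm²] per gap value.
#' @export
available_ligands <- function(g_N, p) {
  if (any(g_N < -1e-12)) stop("negative gap", call. = FALSE)
  p$cLav * exp(-pmax(g_N, 0) / p$ell_chem)
}

#' Equilibrium coefficient of the referential constraint
#'
#' The instantaneous-equilibrium closure `c_C = c_R c_L / alpha` uses
#' `alpha = (cRmax * cLmax / cCmax) * lambda_a / K_eq`, where `lambda_a` is
#' the local areal stretch (Nanson factor) of the membrane motion. With
#' `cRmax = cCmax` this reduces to `cLmax * lambda_a / K_eq`.
#'
#' @param lambda_a Areal stretch(es), positive.
#' @param p A [chemistry_params()] object.
#' @return Coefficient alpha [molecules/µm²].
#' @export
alpha_coefficient <- function(lambda_a, p) {
  if (any(lambda_a <= 0)) stop("`lambda_a` must be positive", call. = FALSE)
  (p$cRmax * p$cLmax / p$cCmax) * lambda_a / p$K_eq
}

#' Solve the nodal equilibrium constraint of the base model
#'
#' Given the conserved difference `c_D = c_R - c_L`, the available-ligand
#' density `S_L`, and the equilibrium coefficient `alpha`, the free-receptor
#' density is the unique non-negative root of
#' `c_R^2 + (alpha - c_D) c_R - alpha (S_L + c_D) = 0`; the ligand and
#' complex densities follow from `c_L = S_L alpha / (alpha + c_R)` and
#' `c_C = S_L c_R / (alpha + c_R)` (so that `c_L + c_C = S_L` holds exactly).
#' All inputs are vectorized with recycling.
#'
#' @param c_D Difference density `c_R - c_L` [molecules/µm²].
#' @param S_L Available-ligand density [molecules/µm²], non-negative.
#' @param alpha Equilibrium coefficient [molecules/µm²], positive.
#' @param tol Clamp tolerance for round-off negatives.
#' @return List with components `c_R`, `c_L`, `c_C`.
#' @export
solve_equilibrium_base <- function(c_D, S_L, alpha, tol = 1e-12) {
  n <- max(length(c_D), length(S_L), length(alpha))
  c_D <- rep_len(c_D, n); S_L <- rep_len(S_L, n); alpha <- rep_len(alpha, n)
  if (any(S_L < 0)) stop("`S_L` must be non-negative", call. = FALSE)
  if (any(alpha <= 0)) stop("`alpha` must be positive", call. = FALSE)
  tot <- S_L + c_D                    # nodal receptor total c_R + c_C
  scale <- pmax(1, abs(c_D), S_L)
  if (any(tot < -1e-9 * scale))
    stop("infeasible state: S_L + c_D < 0 (negative nodal receptor total)",
         call. = FALSE)
  tot <- pmax(tot, 0)
  q <- alpha - c_D
  s <- sqrt(q^2 + 4 * alpha * tot)
  # cancellation-safe branch of the quadratic formula
  c_R <- ifelse(q > 0, 2 * alpha * tot / (q + s), (s - q) / 2)
  c_R[c_R < 0 & c_R > -tol] <- 0
  if (any(c_R < 0)) stop("negative root beyond clamp tolerance", call. = FALSE)
  res <- c_R^2 + q * c_R - alpha * tot
  if (any(abs(res) > 1e-9 * pmax(1, alpha, abs(c_D), S_L)^2))
    stop("equilibrium residual above tolerance", call. = FALSE)
  c_L <- S_L * alpha / (alpha + c_R)
  list(c_R = c_R, c_L = c_L, c_C = S_L - c_L)
}

#' Solve the nodal equilibrium constraint of the mobile/immobile split model
#'
#' The mobile and immobile receptor pools share the same ligand field and the
#' same closure `c_C^x = c_R^x c_L / alpha`. With conserved nodal totals
#' `c_m = c_R^m + c_C^m` and `c_i = c_R^i + c_C^i`, ligand bookkeeping
#' `c_L + c_C = S_L` reduces to a single scalar equation in `c_L`,
#' `c_L (1 + (c_m + c_i) / (alpha + c_L)) = S_L`, whose left side is
#' monotone increasing; the root on `[0, S_L]` is computed in closed form.
#'
#' @param c_m,c_i Conserved mobile/immobile totals [molecules/µm²].
#' @param S_L Available-ligand density [molecules/µm²].
#' @param alpha Equilibrium coefficient [molecules/µm²].
#' @return List with `c_R_m`, `c_R_i`, `c_L`, `c_C_m`, `c_C_i`. The splits
#'   satisfy `c_R_m + c_C_m = c_m` and `c_R_i + c_C_i = c_i` exactly.
#' @export
solve_equilibrium_split <- function(c_m, c_i, S_L, alpha) {
  n <- max(length(c_m), length(c_i), length(S_L), length(alpha))
  c_m <- rep_len(c_m, n); c_i <- rep_len(c_i, n)
  S_L <- rep_len(S_L, n); alpha <- rep_len(alpha, n)
  if (any(c_m < 0) || any(c_i < 0) || any(S_L < 0))
    stop("`c_m`, `c_i`, `S_L` must be non-negative", call. = FALSE)
  if (any(alpha <= 0)) stop("`alpha` must be positive", call. = FALSE)
  ctot <- c_m + c_i
  B <- alpha + ctot - S_L             # c_L^2 + B c_L - S_L alpha = 0
  s <- sqrt(B^2 + 4 * S_L * alpha)
  c_L <- ifelse(B >= 0, 2 * S_L * alpha / (B + s), (s - B) / 2)
  c_L <- pmin(c_L, S_L)
  frac <- alpha / (alpha + c_L)       # free fraction of each pool
  c_R_m <- c_m * frac
  c_R_i <- c_i * frac
  list(c_R_m = c_R_m, c_R_i = c_R_i, c_L = c_L,
       c_C_m = c_m - c_R_m, c_C_i = c_i - c_R_i)
}

#' Saturation-aware law of mass action (diagnostic)
#'
#' Net forward rate of R + L <-> C expressed in occupancy ratios relative to
#' the species saturation limits:
#' `w = kf * thL/(1-thL) * thR/(1-thR) - kb * thC/(1-thC)`.
#' The production solver assumes instantaneous equilibrium; this rate exists
#' for diagnostics and finite-kinetics convergence checks only.
#'
#' @param theta_R,theta_L,theta_C Saturation fractions in `[0, 1)`.
#' @param kf,kb Forward/backward kinetic constants.
#' @return Net forward reaction rate.
#' @export
mass_action_rate <- function(theta_R, theta_L, theta_C, kf, kb) {
  th <- c(theta_R, theta_L, theta_C)
  if (any(th < 0) || any(th >= 1))
    stop("saturation fractions must lie in [0, 1)", call. = FALSE)
  kf * (theta_L / (1 - theta_L)) * (theta_R / (1 - theta_R)) -
    kb * (theta_C / (1 - theta_C))
}

#' @export
print.chemistry_params <- function(x, ...) {
  cat("Receptor-ligand chemistry:\n")
  cat("  K_eq =", format(x$K_eq, digits = 8),
      if (!is.null(x$dG0)) paste0("(dG0 = ", x$dG0, " J/mol at T = ", x$T, " K)"),
      "\n")
  cat("  cLav =", x$cLav, "molecules/µm², ell_chem =", x$ell_chem,
      "µm, D_R =", x$D_R, "µm²/s\n")
  invisible(x)
}
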