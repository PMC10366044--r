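# Shared fixtures and independent oracles used across the suite.

V_SPHERE <- 4 / 3 * pi * 10^3   # reference cell volume, r0 = 10 µm

# interval bisection, independent of any closed-form solve in the package
bisect <- function(f, lo, hi, iters = 200) {
  flo <- f(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (flo * f(mid) <= 0) hi <- mid else {
      lo <- mid
      flo <- f(lo)
    }
  }
  (lo + hi) / 2
}

# oracle for the base equilibrium: root of the quadratic constraint by bisection
oracle_eq_base <- function(c_D, S_L, alpha) {
  f <- function(cR) cR^2 + (alpha - c_D) * cR - alpha * (S_L + c_D)
  hi <- max(S_L + c_D, 0)
  if (hi == 0 || f(hi) == 0) return(hi)
  bisect(f, 0, hi)
}

# oracle for the split ligand equation: monotone scalar equation by bisection
oracle_eq_split_cL <- function(c_m, c_i, S_L, alpha) {
  if (S_L == 0) return(0)
  f <- function(cL) cL * (1 + (c_m + c_i) / (alpha + cL)) - S_L
  if (f(S_L) < 0) return(S_L)
  bisect(f, 0, S_L)
}

# oracle for the cap height: bisection on the monotone cubic
oracle_cap_height <- function(a, V) {
  f <- function(h) h * (3 * a^2 + h^2) - 6 * V / pi
  bisect(f, 0, max(2 * (6 * V / pi)^(1 / 3), 1))
}

# brute-force explicit-Euler reference for the base chemo-transport model
# over the attachment stage: same semi-discrete spatial operators, its own
# first-order time marching and its own inline equilibrium closure.
euler_reference_base <- function(n_nodes, t_end, dt_mech, refine,
                                 cLav = 90, N_total = 24000) {
  mesh <- build_meridian_mesh(10, n_nodes)
  p <- chemistry_params(cLav = cLav)
  plan <- stage_plan(300, 600, 7200, c(dt_mech, 0.1, 0.05), 1L)
  ops <- assemble_operators(mesh, p$D_R)
  K <- op_matrix(ops, "K")
  w <- mesh$weights
  closure_cR <- function(cD, SL, al) {
    q <- al - cD
    s <- sqrt(q^2 + 4 * al * pmax(SL + cD, 0))
    pmax(ifelse(q > 0, 2 * al * pmax(SL + cD, 0) / (q + s), (s - q) / 2), 0)
  }
  cD <- rep(N_total / mesh$area, n_nodes)
  SL0 <- numeric(n_nodes)
  al0 <- alpha_coefficient(rep(1, n_nodes), p)
  nmech <- round(t_end / dt_mech)
  dt_sub <- dt_mech / refine
  for (m in seq_len(nmech)) {
    fr <- map_reference_to_current(
      mesh, cap_shape(contact_radius_schedule(m * dt_mech, plan), V_SPHERE))
    SL1 <- available_ligands(fr$g_N, p)
    al1 <- alpha_coefficient(fr$lambda_a, p)
    dSL <- (SL1 - SL0) / refine
    dal <- (al1 - al0) / refine
    al <- al0
    SL <- SL0
    for (k in seq_len(refine)) {
      al <- al + dal
      cR <- closure_cR(cD, SL, al)
      cD <- cD - dt_sub * as.vector(K %*% cR) / w - dSL
      SL <- SL + dSL
    }
    SL0 <- SL1
    al0 <- al1
  }
  cR <- closure_cR(cD, SL0, al0)
  cL <- SL0 * al0 / (al0 + cR)
  sum(w * (SL0 - cL))   # total complex count
}

# short-run configuration helper (defaults scaled for test runtimes)
test_config <- function(n_nodes = 100L, substeps = 5L, t_stop = NULL,
                        model = "base", cLav = 90, output_every = 10) {
  cfg <- default_config()
  cfg$n_nodes <- as.integer(n_nodes)
  cfg$stages$substeps <- as.integer(substeps)
  cfg$t_stop <- t_stop
  cfg$model <- model
  cfg$chemistry$cLav <- cLav
  cfg$output_every <- output_every
  cfg
}
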