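p_tab <- chemistry_params()

test_that("equilibrium constant follows the Gibbs energy", {
  # calibrated binding energy at 37 C reproduces the published constant
  expect_equal(equilibrium_constant(-32949.0, 310.15), 354058.32,
               tolerance = 5e-4)
  expect_identical(equilibrium_constant(0, 310.15), 1)
  expect_equal(equilibrium_constant(-8.314462 * 310.15 * log(2), 310.15), 2,
               tolerance = 1e-12)
  expect_error(equilibrium_constant(-1000, -5), "positive")
})

test_that("parameter container validates consistency", {
  expect_equal(p_tab$K_eq, 354058.32, tolerance = 5e-4)
  expect_error(chemistry_params(K_eq = 1e5), "inconsistent")
  expect_silent(chemistry_params(K_eq = 354058.32))
  expect_error(chemistry_params(cLav = 20000), "cannot exceed")
  expect_error(chemistry_params(T = 0), "positive")
  expect_error(chemistry_params(D_R = -1), "positive")
})

test_that("available ligands decay exponentially with the gap", {
  expect_equal(available_ligands(0, p_tab), 90)
  expect_equal(available_ligands(0.2, p_tab), 33.10914971, tolerance = 1e-9)
  expect_lt(available_ligands(50, p_tab), 1e-100)
  expect_error(available_ligands(-0.1, p_tab), "negative gap")
})

test_that("equilibrium coefficient scales with the areal stretch", {
  a1 <- alpha_coefficient(1, p_tab)
  expect_equal(a1, 16000 / p_tab$K_eq, tolerance = 1e-12)
  expect_equal(a1, 0.04519, tolerance = 1e-4)
  expect_equal(alpha_coefficient(2, p_tab), 2 * a1, tolerance = 1e-12)
  # infinitely strong binding: alpha -> 0
  p_strong <- chemistry_params(dG0 = NULL, K_eq = 1e30)
  expect_lt(alpha_coefficient(1, p_strong), 1e-20)
  expect_error(alpha_coefficient(0, p_tab), "positive")
})

test_that("base equilibrium solve matches the bisection oracle", {
  al <- alpha_coefficient(1, p_tab)
  # first instant of contact with uniform initial receptors
  eq <- solve_equilibrium_base(-70.9, 90, al)
  expect_equal(eq$c_R, 0.01216412, tolerance = 1e-6)
  expect_equal(eq$c_L, 70.91216412, tolerance = 1e-8)
  expect_equal(eq$c_C, 19.08783588, tolerance = 1e-8)
  # quadratic factors as (c_R - c_D)(c_R + alpha) when S_L = 0
  eq0 <- solve_equilibrium_base(19.1, 0, al)
  expect_equal(eq0$c_R, 19.1, tolerance = 1e-12)
  expect_identical(eq0$c_L, 0)
  expect_identical(eq0$c_C, 0)
  # no-binding limit alpha -> infinity: c_R -> S_L + c_D, c_C -> 0
  eqb <- solve_equilibrium_base(5, 40, 1e12)
  expect_equal(eqb$c_R, 45, tolerance = 1e-6)
  expect_lt(eqb$c_C, 1e-6)
  # randomized cross-check against the oracle + closure identity
  set.seed(42)
  for (i in 1:50) {
    S_L <- runif(1, 0, 90)
    c_D <- runif(1, -S_L, 25)
    al_i <- 10^runif(1, -3, 1)
    eq <- solve_equilibrium_base(c_D, S_L, al_i)
    expect_equal(eq$c_R, oracle_eq_base(c_D, S_L, al_i), tolerance = 1e-8)
    # closure c_C * alpha = c_R * c_L
    expect_equal(eq$c_C * al_i, eq$c_R * eq$c_L,
                 tolerance = 1e-9 * max(1, eq$c_C * al_i))
    # ligand bookkeeping
    expect_equal(eq$c_L + eq$c_C, S_L, tolerance = 1e-9)
    expect_true(all(c(eq$c_R, eq$c_L, eq$c_C) >= 0))
  }
  expect_error(solve_equilibrium_base(-5, 1, 0.04), "infeasible")
})

test_that("complexes respond monotonically to supply and receptor excess", {
  al <- 0.04519
  SL_grid <- seq(0, 90, length.out = 30)
  cC <- vapply(SL_grid,
               function(s) solve_equilibrium_base(5, s, al)$c_C, numeric(1))
  expect_true(all(diff(cC) >= -1e-12))
  cD_grid <- seq(-50, 50, length.out = 30)
  cC2 <- vapply(cD_grid,
                function(d) solve_equilibrium_base(d, 60, al)$c_C, numeric(1))
  expect_true(all(diff(cC2) >= -1e-12))
  # complexes never exceed available ligands
  expect_true(all(cC <= SL_grid + 1e-12), label = "c_C bounded by S_L")
})

test_that("split equilibrium matches its oracle and conserves the pools", {
  al <- alpha_coefficient(1, p_tab)
  eq <- solve_equilibrium_split(14.707, 4.393, 90, al)
  cL_star <- oracle_eq_split_cL(14.707, 4.393, 90, al)
  expect_equal(eq$c_L, cL_star, tolerance = 1e-8)
  expect_equal(eq$c_C_m + eq$c_C_i, 19.08783588, tolerance = 1e-6)
  expect_equal(eq$c_R_m + eq$c_R_i, 0.01216412, tolerance = 1e-6)
  # free receptors split in the ratio of the pools
  expect_equal(eq$c_R_m / eq$c_R_i, 14.707 / 4.393, tolerance = 1e-9)
  # degenerate split (no immobile pool) reproduces the base solve with the
  # same nodal receptor total (c_D = total - S_L)
  eqs <- solve_equilibrium_split(19.1, 0, 90, al)
  eqb <- solve_equilibrium_base(19.1 - 90, 90, al)
  expect_equal(eqs$c_R_m, eqb$c_R, tolerance = 1e-9)
  expect_equal(eqs$c_L, eqb$c_L, tolerance = 1e-9)
  # S_L = 0: everything stays free
  eq0 <- solve_equilibrium_split(3, 2, 0, al)
  expect_identical(eq0$c_L, 0)
  expect_equal(eq0$c_R_m, 3)
  expect_equal(eq0$c_R_i, 2)
  # randomized: exact pool conservation and shared ligand field
  set.seed(7)
  for (i in 1:30) {
    cm <- runif(1, 0, 20); ci <- runif(1, 0, 10)
    SL <- runif(1, 0, 90); al_i <- 10^runif(1, -3, 0)
    eq <- solve_equilibrium_split(cm, ci, SL, al_i)
    expect_identical(eq$c_R_m + eq$c_C_m, cm)
    expect_identical(eq$c_R_i + eq$c_C_i, ci)
    expect_equal(eq$c_L + eq$c_C_m + eq$c_C_i, SL, tolerance = 1e-9)
    expect_equal(eq$c_L, oracle_eq_split_cL(cm, ci, SL, al_i),
                 tolerance = 1e-8)
  }
})

test_that("saturation-aware mass action rate behaves as the law prescribes", {
  expect_equal(mass_action_rate(0.5, 0.5, 0.5, 2, 1), 1)
  expect_gt(mass_action_rate(0.3, 0.4, 0, 1, 1), 0)   # pure forward
  # occupancies on the equilibrium manifold give zero net rate
  kf <- 3; kb <- 1.5
  thR <- 0.2; thL <- 0.3
  x <- (kf / kb) * (thL / (1 - thL)) * (thR / (1 - thR))
  thC <- x / (1 + x)
  expect_equal(mass_action_rate(thR, thL, thC, kf, kb), 0, tolerance = 1e-12)
  expect_error(mass_action_rate(1, 0.5, 0.5, 1, 1), "\\[0, 1\\)")
})
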