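test_that("electron transport follows the light-response quadratic", {
  expect_equal(electron_transport(1500, 0), 0)
  # saturates at Jmax under very high light
  expect_equal(electron_transport(1e7, 200), 200, tolerance = 1e-3)
  # smaller quadratic root, checked against an independent polyroot oracle
  I2 <- 1500 * 0.8 * (1 - 0.15) / 2
  roots <- Re(polyroot(c(I2 * 200, -(I2 + 200), 0.1)))
  expect_equal(electron_transport(1500, 200, 0.8, 0.15, 0.1), min(roots),
               tolerance = 1e-10)
  expect_equal(electron_transport(1500, 200, 0.8, 0.15, 0.1), 146.7,
               tolerance = 1e-3)
  # J never exceeds either capacity
  expect_lte(electron_transport(1500, 200, 0.8, 0.15, 0.1), min(I2, 200))
})

test_that("Rubisco rate has the Michaelis-Menten form with O2 inhibition", {
  p <- species_params("F. floridana")
  Keff <- p$Kc * (1 + p$O / p$Ko)
  expect_equal(rubisco_limited_vm(Keff, p), p$Vm_max / 2)
  expect_equal(rubisco_limited_vm(0, p), 0)
  expect_equal(rubisco_limited_vm(30, p), 2700 / 438.796,
               tolerance = 1e-4)
})

test_that("PEPC rate saturates at the PEP-regeneration cap", {
  p <- species_params("F. floridana")  # Vp_max 15, Kp 80, Vpr 8
  expect_equal(pepc_rate(1e6, p), 8)  # regeneration-limited
  expect_equal(pepc_rate(79, p), 79 * 15 / 159, tolerance = 1e-12)
  p2 <- species_params("F. floridana", Vpr = 100)
  expect_equal(pepc_rate(80, p2), 15 / 2)  # half-saturation
  expect_equal(pepc_rate(500, species_params("F. pringlei")), 0)
})

test_that("state evaluation reproduces a hand-worked example and conserves A", {
  p <- species_params("F. floridana")
  st <- net_assimilation_given_cm(113, p)
  expect_equal(st$Vp, 8)
  expect_equal(st$Wc, 113 * 90 / (113 + 395 * (1 + 19000 / 544000)),
               tolerance = 1e-12)
  expect_equal(st$L, 3.2)
  expect_equal(st$A, st$Vm - 0.85 + 8 - 3.2, tolerance = 1e-12)
  expect_equal(st$As + st$Am, st$A, tolerance = 1e-14)
  expect_equal(st$bs_share, 100 * 4.8 / st$A, tolerance = 1e-12)

  # pure C3 mesophyll limit: A = Vm - Rm
  pc <- species_params("F. pringlei")
  stc <- net_assimilation_given_cm(300, pc)
  expect_equal(stc$A, stc$Vm - 0.3, tolerance = 1e-12)
  expect_equal(stc$Vp, 0)
  expect_equal(stc$L, 0)
})

test_that("conservation and leak-rate invariants hold on random states", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_params()
    st <- net_assimilation_given_cm(runif(1, 0, 900), p)
    expect_lt(abs(st$A - st$As - st$Am), 1e-10)
    expect_gte(st$L, 0)
    expect_equal(st$L, p$phi * (st$Vp + p$beta * st$Fm), tolerance = 1e-12)
    expect_gte(st$Vp, 0); expect_gte(st$Vm, 0)
  }
})

test_that("implicit Cm solver satisfies its defining residual", {
  p <- species_params("F. floridana")
  st <- solve_assimilation(800, p)
  expect_lt(abs(st$Cm - (800 - st$A / st$gm)), 1e-6)
  expect_equal(st$Vp, 8)  # PEP-regeneration-limited at high Ci
  # infinite gm collapses Cm to Ci
  sti <- solve_assimilation(400, p, gm = Inf)
  expect_equal(sti$Cm, 400)
  expect_lte(st$Cm, 800)
})

test_that("solver agrees with a dense bisection oracle on random draws", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_params()
    Ci <- runif(1, 20, 900)
    gm <- gm_polynomial(Ci, p$c_gm)
    cm_pkg <- solve_assimilation(Ci, p, gm)$Cm
    cm_orc <- oracle_solve_cm(Ci, p, gm)
    expect_lt(abs(cm_pkg - cm_orc), 1e-4)
  }
})

test_that("model reduces to the single-compartment C3 form", {
  p <- species_params("F. floridana", Vp_max = 0, Vpr = 0, phi = 0)
  for (Ci in c(30, 100, 250, 500, 900)) {
    st <- solve_assimilation(Ci, p, gm = Inf)
    Wc <- Ci * p$Vm_max / (Ci + p$Kc * (1 + p$O / p$Ko))
    Wj <- electron_transport(p$irradiance, p$Jm, p$absorptance, p$F_spec,
                             p$theta) / 4
    expect_equal(st$A, min(Wc, Wj) - p$rm_fraction * p$Rd,
                 tolerance = 1e-10)
  }
})

test_that("curve evaluation is elementwise and order-preserving", {
  p <- species_params("F. pringlei")
  expect_equal(nrow(assimilation_curve(numeric(0), p)), 0)
  one <- assimilation_curve(300, p)
  expect_equal(one, solve_assimilation(300, p))
  grid <- seq(50, 800, by = 50)
  cur <- assimilation_curve(grid, p)
  expect_equal(cur$Ci, grid)
  expect_true(all(diff(cur$A) >= -1e-10))  # C3 response is non-decreasing
})

test_that("compensation point is found by root or interpolation", {
  lin <- data.frame(Ci = seq(0, 100, by = 10))
  lin$A <- 0.1 * (lin$Ci - 50)
  expect_equal(compensation_point(lin), 50)
  # with photorespiration enabled, C4-like leaves compensate lower than C3
  o <- 20000
  pc3 <- species_params("F. pringlei", O = o, gamma_star = 0.000193 * o,
                        Rd = 1)
  pc4 <- species_params("F. bidentis", O = o, gamma_star = 0.000193 * o,
                        Rd = 1)
  expect_lt(compensation_point(pc4), compensation_point(pc3))
  # no respiration, no photorespiration, no C4 cycle: A > 0 for all Ci > 0
  p0 <- species_params("F. pringlei", Rd = 0)
  expect_equal(compensation_point(p0), 0, tolerance = 1e-6)
  expect_error(compensation_point(species_params("F. bidentis"),
                                  bracket = c(50, 200)), "sign")
})
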