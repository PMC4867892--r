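p_flor <- species_params("F. floridana")

test_that("combined diffusional fractionation weights the two paths", {
  expect_equal(combined_a_prime(400, 400, 300), 4.4)   # no boundary drop
  expect_equal(combined_a_prime(400, 300, 300), 2.9)   # no stomatal drop
  expect_equal(combined_a_prime(400, 380, 300),
               (2.9 * 20 + 4.4 * 80) / 100)
  expect_error(combined_a_prime(400, 380, 400), "Ca = Ci")
})

test_that("ternary factor is proportional to E and inverse in g_ac", {
  expect_equal(ternary_t(4.4, 0, 0.4), 0)
  expect_equal(ternary_t(4.4, 0.004, 0.4), 1.0044 * 0.004 / 0.8,
               tolerance = 1e-12)
  expect_equal(ternary_t(4.4, 0.004, 0.8), ternary_t(4.4, 0.004, 0.4) / 2)
  expect_error(ternary_t(4.4, 0.004, 0), "g_ac")
})

test_that("biochemical fractionation matches hand-worked cases", {
  # pure Rubisco limit
  pr0 <- species_params("F. pringlei", Rd = 0)
  st <- list(A = 10, As = 0, Vp = 0, Fm = 0, Fs = 0)
  expect_equal(delta_bio_forward(st, pr0), 29)
  # C3 with mesophyll respiration: e = 2.91, Rm = 0.3 (pringlei preset)
  pr <- species_params("F. pringlei")
  expect_equal(delta_bio_forward(st, pr), 29 - 2.91 * 0.3 / 10,
               tolerance = 1e-12)
  # C4 leaf with everything routed through the bundle sheath (bidentis-like)
  pb <- species_params("F. bidentis")
  st4 <- list(A = 20, As = 20, Vp = 22, Fm = 0, Fs = 0)
  expect_equal(delta_bio_forward(st4, pb),
               (29 - 3.54 * 0.2 / 20) +
                 1 * ((29 - 1.8) * 0.28 + (-5.7 - 29)) -
                 3.54 * 0.2 * 0.28 / 20,
               tolerance = 1e-12)
  expect_error(delta_bio_forward(list(A = -1, As = 0, Vp = 0, Fm = 0,
                                      Fs = 0), pb), "A <= 0")
})

test_that("full and photorespiration-free fractionation forms coincide at Fm = Fs = 0", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_params()
    st <- net_assimilation_given_cm(runif(1, 40, 900), p)
    if (st$A <= 0) next
    # closed form of the simplified expression, written independently
    Rm <- p$rm_fraction * p$Rd; Rs <- p$Rd - Rm
    simplified <- (p$b3 - p$e_resp * Rm / st$A) +
      (st$As / st$A) * ((p$b3 - p$s_leak) * p$phi + (p$b4 - p$b3)) -
      p$e_resp * Rs / st$A * p$phi
    if (st$Vp == 0) {
      simplified <- (p$b3 - p$e_resp * Rm / st$A) +
        (st$As / st$A) * (p$b3 - p$s_leak) * p$phi -
        p$e_resp * Rs / st$A * p$phi
    }
    expect_equal(delta_bio_forward(st, p), simplified, tolerance = 1e-12)
  }
})

test_that("discrimination model has the right limits", {
  # infinite gm, no ternary effect: the classic linear Ci/Ca form
  expect_equal(delta_model(29, 20, Inf, 400, 280, 4.4, 0, p_flor),
               4.4 * 0.3 + 29 * 0.7, tolerance = 1e-12)
  expect_equal(delta_model(29, 20, Inf, 400, 0, 4.4, 0, p_flor), 4.4)
  expect_error(delta_model(29, 20, 0.4, 400, 280, 4.4, 1, p_flor), "t")
})

test_that("discrimination model and its inversion are exact inverses", {
  set.seed(13)
  n <- 1000
  Dbio <- runif(n, -5, 30)
  A <- runif(n, 1, 50)
  gm <- runif(n, 0.05, 1.5)
  Ca <- runif(n, 100, 1000)
  Ci <- runif(n, 0.3, 0.9) * Ca
  ap <- runif(n, 2.9, 4.4)
  t <- runif(n, 0, 0.03)
  D <- delta_model(Dbio, A, gm, Ca, Ci, ap, t, p_flor)
  back <- delta_bio_invert(D, A, gm, Ca, Ci, ap, t, p_flor)
  expect_lt(max(abs(back - Dbio)), 1e-9)
})

test_that("inverted fractionation denominator is the mesophyll drawdown", {
  # Ci/Ca - A/(gm*Ca) with A=20, gm=0.4, Ca=400 shifts Ci/Ca by 0.125
  p <- p_flor
  D1 <- delta_bio_invert(15, 20, 0.4, 400, 280, 4.4, 0, p)
  num <- 15 - 4.4 * (400 - 280) / 400 - (0.7 + 1.1) * 20 / (0.4 * 400)
  expect_equal(D1, num / (280 / 400 - 0.125), tolerance = 1e-12)
})

test_that("discrimination increases with biochemical fractionation when Cm > 0", {
  d <- delta_model(seq(0, 30, by = 1), 20, 0.4, 400, 280, 4.1, 0.005,
                   p_flor)
  expect_true(all(diff(d) > 0))
})

test_that("TDL two-point formula matches its arithmetic oracle", {
  expect_equal(delta_from_tdl(400, 350, -5, -5), 0)
  expect_equal(400 / (400 - 350), 8)
  expect_equal(delta_from_tdl(400, 350, -5, -2.5),
               1000 * 8 * 2.5 / (1000 - 2.5 - 20), tolerance = 1e-12)
  expect_error(delta_from_tdl(400, 400, -5, -2.5), "drawdown")
})

test_that("theoretical endmember lines match their printed forms", {
  expect_equal(theoretical_c3_delta(0), 4.4)
  expect_equal(theoretical_c4_delta(0, 0.25), 4.4)
  expect_equal(theoretical_c3_delta(1), 29)
  expect_equal(theoretical_c4_delta(1, 0.25), 1.1, tolerance = 1e-12)
  # the full model collapses onto the C3 line at gm -> Inf, t = 0, Dbio = b3
  x <- seq(0.05, 1, by = 0.05)
  full <- delta_model(29, 20, Inf, 400, 400 * x, 4.4, 0, p_flor)
  expect_lt(max(abs(full - theoretical_c3_delta(x))), 1e-12)
})
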