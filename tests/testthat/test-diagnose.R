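test_that("noiseless intermediate data are diagnosed as C4-active", {
  d <- noiseless_dataset("F. floridana")
  dg <- diagnose_c4(d, "c3-c4")
  expect_s3_class(dg, "c3c4_diagnosis")
  expect_equal(dg$preferred, "C4-active")
  expect_gt(dg$objective_ratio, 100)
  expect_true(dg$decisive)
  expect_output(print(dg), "C4-active")
})

test_that("data generated without a C4 cycle are not forced into one", {
  d <- noiseless_dataset("F. floridana (strict C3)")
  dg <- diagnose_c4(d, "c3-c4")
  expect_equal(dg$preferred, "no-C4")
})

test_that("a generating hypothesis inside the candidate set is not rejected", {
  d <- generate_dataset(species_params("F. brownii (strict C4)"),
                        ci_over_ca = 0.4, noise_sd_A = 0, noise_sd_D = 0,
                        seed = 1)
  dg <- diagnose_c4(d, "c4-like")
  expect_equal(dg$preferred, "strict-C4")
  d2 <- generate_dataset(species_params("F. brownii"), ci_over_ca = 0.4,
                         noise_sd_A = 0, noise_sd_D = 0, seed = 1)
  dg2 <- diagnose_c4(d2, "c4-like")
  expect_equal(dg2$preferred, "mesophyll-Rubisco")
})

test_that("bundle-sheath contribution behaves across presets", {
  # no C4 cycle, no photorespiration: nothing is assimilated in the sheath
  bs0 <- bundle_sheath_contribution(species_params("F. pringlei"),
                                    c(100, 300, 600))
  expect_equal(bs0$bs_share, rep(0, 3))
  # F. floridana: contribution declines with Ci in the Vpr-limited region
  # and flattens once both carboxylation caps are binding
  grid <- seq(150, 800, by = 50)
  bs <- bundle_sheath_contribution(species_params("F. floridana"), grid)
  expect_true(all(diff(bs$bs_share) <= 1e-9))
  expect_true(all(diff(bs$bs_share_net_Rs) <= 1e-9))
  expect_gt(bs$bs_share[1], bs$bs_share[nrow(bs)])
  # F. brownii at high Ci: about a quarter of fixation is mesophyll Rubisco
  bb <- bundle_sheath_contribution(species_params("F. brownii"), 800)
  expect_equal(bb$mesophyll_share, 25, tolerance = 4 / 25)
  # negative-assimilation points are flagged and dropped
  expect_warning(
    out <- bundle_sheath_contribution(
      species_params("F. floridana", Rd = 40), c(5, 600)),
    "dropped")
  expect_equal(nrow(out), 1)
})

test_that("O2-response normalization is anchored at the low-O2 reference", {
  curves <- list("20" = data.frame(A = c(10, 20)),
                 "200" = data.frame(A = c(5, 10)))
  out <- o2_response_normalization(curves)
  expect_equal(out[["20"]]$A_pct, c(100, 100))
  expect_equal(out[["200"]]$A_pct, c(50, 50))
  # the printed C3 example: 28.7 at reference, 14.35 at high O2 -> 50%
  out2 <- o2_response_normalization(list("19" = data.frame(A = 28.7),
                                         "300" = data.frame(A = 14.35)))
  expect_equal(out2[["300"]]$A_pct, 50)
  all_equal <- list("20" = data.frame(A = c(7, 7)),
                    "100" = data.frame(A = c(7, 7)))
  expect_equal(o2_response_normalization(all_equal)[["100"]]$A_pct,
               c(100, 100))
  expect_error(o2_response_normalization(list("100" = data.frame(A = 1))),
               "reference")
})

test_that("compensation point interpolation matches the model root", {
  expect_equal(gamma_from_aci(data.frame(Ci = c(40, 60), A = c(-1, 1))), 50)
  expect_equal(gamma_from_aci(data.frame(Ci = c(30, 55, 80),
                                         A = c(-2, 0, 3))), 55)
  expect_error(gamma_from_aci(data.frame(Ci = c(100, 200), A = c(1, 2))),
               "bracket")
  # on a fine noiseless C3 curve the interpolation approaches the true root
  o <- 20000
  p <- species_params("F. pringlei", O = o, gamma_star = 0.000193 * o)
  grid <- seq(1, 101, by = 5)
  cur <- assimilation_curve(grid, p)
  expect_lt(abs(gamma_from_aci(data.frame(Ci = cur$Ci, A = cur$A)) -
                  compensation_point(p)), 0.5)
})

test_that("O2 series drives the compensation point apart for C3 and C4", {
  s <- generate_o2_series(species_params("F. pringlei"),
                          po2_mbar = c(20, 100, 300))
  expect_length(s, 3)
  g3 <- vapply(s, function(d) gamma_from_aci(d[, c("Ci", "A")]), 0)
  expect_true(all(diff(g3) > 0))  # C3: Gamma rises steeply with O2
  s4 <- generate_o2_series(species_params("F. bidentis"),
                           po2_mbar = c(20, 100, 300),
                           ci_grid = c(0.05, 1, 5, 20, 60, 150))
  g4 <- vapply(s4, function(d) gamma_from_aci(d[, c("Ci", "A")]), 0)
  expect_lt(max(g4) - min(g4), 2)  # C4-like: Gamma nearly O2-insensitive
  expect_lt(max(g4), min(g3))
})
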