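test_that("compute_plc implements the loss formula with clamping", {
  p <- c(-0.8, -1.6, -2.4, -3.2)
  res <- compute_plc(p, c(2, 2, 1, 0))
  expect_equal(res$kmax, 2)
  expect_equal(res$plc, c(0, 0, 50, 100))

  # replicate means; mild flow increase at step 2 clamps to 0
  k <- rbind(c(2, 2, 2), c(2.2, 2.1, 2.3), c(1, 1, 1), c(0, 0, 0))
  expect_equal(compute_plc(p, k)$plc, c(0, 0, 50, 100))

  # kmax rule switch
  expect_equal(compute_plc(p, k, kmax_rule = "max")$kmax, 2.2)
  expect_error(compute_plc(p, matrix(0, 4, 1)), "kmax")
  expect_error(compute_plc(p[1:3], matrix(1, 3, 1)), ">= 4")
  expect_error(compute_plc(rev(p), matrix(1, 4, 1)), "decreasing")
})

test_that("noiseless sigmoid parameters are recovered to 1e-6", {
  p <- seq(-0.8, -12, by = -0.8)
  for (p50 in c(-3, -5, -7.8)) {
    for (s in c(15, 30, 60)) {
      fit <- fit_vc(p, predict_plc(list(p50 = p50, slope = s), p))
      expect_true(fit$converged)
      expect_equal(fit$p50, p50, tolerance = 1e-6)
      expect_equal(fit$slope, s, tolerance = 1e-4)
    }
  }
})

test_that("sigmoid analytics: 50% at P50, slope -S at the inflection", {
  fit <- list(p50 = -4, slope = 30)
  expect_identical(predict_plc(fit, -4), 50)
  # near-zero pressure limit
  expect_equal(predict_plc(fit, -1e-12), 100 / (1 + exp(30 / 25 * 4)),
               tolerance = 1e-9)
  h <- 1e-6
  slope <- (predict_plc(fit, -4 + h) - predict_plc(fit, -4 - h)) / (2 * h)
  expect_equal(slope, -30, tolerance = 1e-6 * 30)
})

test_that("fit_vc is shift-equivariant in pressure", {
  p <- seq(-0.8, -10, by = -0.8)
  plc <- predict_plc(list(p50 = -4.2, slope = 40), p)
  base <- fit_vc(p, plc)
  shifted <- fit_vc(p - 1.5, plc)
  expect_equal(shifted$p50, base$p50 - 1.5, tolerance = 1e-5)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-3)
})

test_that("low-information curves are flagged, not rejected", {
  p <- seq(-0.8, -3.2, by = -0.8)
  plc <- predict_plc(list(p50 = -8, slope = 30), p)  # far tail only
  fit <- fit_vc(p, plc)
  expect_true(fit$low_information)
})

test_that("compute_ks honours both division conventions", {
  expect_equal(as.numeric(compute_ks(1, 0.27, 1e-5)), 2.7e4)
  expect_equal(as.numeric(compute_ks(1, 0.27, 1e-5, mode = "literal")),
               1 / (0.27 * 1e-5))
  expect_equal(as.numeric(compute_ks(2, 0.27, 1e-5)),
               2 * as.numeric(compute_ks(1, 0.27, 1e-5)))
  # modes differ by exactly L^2
  expect_equal(as.numeric(compute_ks(3, 0.5, 2e-5, "literal")) /
                 as.numeric(compute_ks(3, 0.5, 2e-5, "standard")),
               1 / 0.5^2)
  expect_error(compute_ks(-1, 0.27, 1e-5), "> 0")
})

test_that("fit_vc_table and species means reproduce hand computation", {
  p <- seq(-0.8, -8, by = -0.8)
  mk <- function(bid, sp, p50) {
    plc <- predict_plc(list(p50 = p50, slope = 30), p)
    data.frame(branch_id = bid, species = sp, pressure_MPa = p,
               k_rep1 = 2 * (1 - plc / 100), k_rep2 = 2 * (1 - plc / 100),
               k_rep3 = 2 * (1 - plc / 100),
               length_m = 0.27, sapwood_area_m2 = 1e-5)
  }
  curves <- rbind(mk("b1", "spA", -3.6), mk("b2", "spA", -4.4),
                  mk("b3", "spB", -6.0))
  fits <- fit_vc_table(curves)
  expect_equal(nrow(fits), 3L)
  # first-step PLC referencing leaves a small deterministic bias (< 0.1)
  expect_equal(sort(fits$P50_MPa), c(-6.0, -4.4, -3.6), tolerance = 0.02)
  sp <- species_vc_means(fits)
  # species mean is exactly the arithmetic mean of its branch fits
  expect_equal(sp$P50_MPa[sp$species == "spA"],
               mean(fits$P50_MPa[fits$species == "spA"]), tolerance = 1e-12)
  expect_equal(sp$P50_abs_MPa, abs(sp$P50_MPa))
  expect_equal(sp$n_branches, c(2L, 1L))
})
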