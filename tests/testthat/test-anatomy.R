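test_that("pit ratio formulas behave at their fixed points", {
  expect_equal(torus_overlap(5, 5), 0)
  expect_equal(margo_flexibility(8, 8), 0)
  expect_equal(valve_effect(0, 0.5), 0)
  expect_equal(valve_effect(0.4, 0.45), 0.18)
})

test_that("aperture resistance follows its algebra", {
  # linear in viscosity
  expect_equal(pit_aperture_resistance(3, 2.5, eta_Pa_s = 0), 0)
  r1 <- pit_aperture_resistance(3, 2.5, eta_Pa_s = 0.001)
  expect_equal(pit_aperture_resistance(3, 2.5, eta_Pa_s = 0.002), 2 * r1)
  # conventional flag scales only the channel term, by pi^3
  orifice <- 24 * 0.001 * 1e-6 / (3e-6)^3
  r_conv <- pit_aperture_resistance(3, 2.5, convention = "conventional")
  expect_equal(r_conv - orifice, (r1 - orifice) * pi^3, tolerance = 1e-10)
  # strictly decreasing in DPA, increasing in Tw, over a grid
  for (tw in c(2.3, 2.6, 3.0)) {
    r <- pit_aperture_resistance(seq(2, 6, by = 0.5), tw)
    expect_true(all(diff(r) < 0))
  }
  for (dpa in c(2.5, 4, 5.5)) {
    r <- pit_aperture_resistance(dpa, seq(2, 3.2, by = 0.2))
    expect_true(all(diff(r) > 0))
  }
  expect_error(pit_aperture_resistance(-1, 2), "> 0")
})

test_that("published subfamily means are reproduced by the trait formulas", {
  t4 <- subfamily_means()
  to <- torus_overlap(t4$DT_um, t4$DPA_um)
  mf <- margo_flexibility(t4$DPM_um, t4$DT_um)
  # ratio-of-means vs mean-of-ratios slack: +/- 0.02
  expect_true(all(abs(to - t4$TO) <= 0.02))
  expect_true(all(abs(mf - t4$MF) <= 0.02))
  expect_true(all(abs(valve_effect(t4$TO, t4$MF) - t4$VE) <= 0.02))
  # aperture resistance from mean dimensions within 5% of the published
  # species means, under the as-printed convention only
  rpa <- pit_aperture_resistance(t4$DPA_um, t4$Tw_um)
  expect_true(all(abs(rpa / t4$RPA_MPa_s_m3 - 1) < 0.05))
  rpa_conv <- pit_aperture_resistance(t4$DPA_um, t4$Tw_um,
                                      convention = "conventional")
  expect_false(any(abs(rpa_conv / t4$RPA_MPa_s_m3 - 1) < 0.05))
})

test_that("derive_pit_traits averages valid pits and flags violations", {
  pits <- data.frame(
    branch_id = c("b1", "b1", "b1", "b2"), species = "sp",
    DPM_um = c(12, 12, 12, 10), DT_um = c(6, 6, 13, 5),
    DPA_um = c(3, 3, 3, 2))
  expect_warning(out <- derive_pit_traits(pits, Tw_um = 2.5), "excluded")
  b1 <- out[out$branch_id == "b1", ]
  expect_equal(b1$n_excluded, 1L)          # DT > DPM pit dropped
  expect_equal(b1$TO, torus_overlap(6, 3))
  expect_equal(b1$VE, valve_effect(torus_overlap(6, 3),
                                   margo_flexibility(12, 6)))
  # per-pit invariant VE = TO * MF is exact (single-pit branch)
  b2 <- out[out$branch_id == "b2", ]
  expect_identical(b2$VE, b2$TO * b2$MF)
})

test_that("hydraulic diameter is the 4-norm mean and dominates the mean", {
  expect_equal(hydraulic_diameter(rep(7, 5)), 7)
  expect_equal(hydraulic_diameter(c(10, 20)), 85000^0.25)
  set.seed(4)
  for (i in 1:20) {
    d <- rlnorm(50, log(12), 0.3)
    expect_gte(hydraulic_diameter(d), mean(d))
  }
  expect_error(hydraulic_diameter(numeric(0)), "empty")
})

test_that("thickness-to-span and circle algebra", {
  expect_equal(thickness_to_span(2.5, 10), 0.25)
  expect_equal(thickness_to_span(5, 10), 1)
  expect_equal(thickness_to_span(2.5, 20), 0.25 / 4)
  expect_equal(diameter_from_area(pi * 25), 10)
})

test_that("tracheid summaries: density, brute-force mean, undersampling", {
  set.seed(9)
  areas <- rlnorm(3000, log(120), 0.4)
  s <- tracheid_summaries(area_um2 = areas, section_area_mm2 = 1,
                          Tw_um = 2.5, zone = "whole")
  expect_equal(s$TD_per_mm2, 3000)
  expect_equal(s$D_um, mean(2 * sqrt(areas / pi)), tolerance = 1e-12)
  expect_false(s$undersampled)
  expect_warning(
    tracheid_summaries(area_um2 = areas[1:50], section_area_mm2 = 0.02,
                       Tw_um = 2.5, zone = "earlywood"),
    "minimum")
  # pooled Dh lies between the zone-specific values
  ew <- rlnorm(300, log(200), 0.2)
  lw <- rlnorm(300, log(60), 0.2)
  dh <- function(a) hydraulic_diameter(diameter_from_area(a))
  pooled <- dh(c(ew, lw))
  expect_true(pooled >= min(dh(ew), dh(lw)) && pooled <= max(dh(ew), dh(lw)))
})

test_that("wood density divides mass by volume with a sanity band", {
  expect_equal(wood_density(5, 10), 0.5)
  expect_equal(wood_density(0.59 * 7.3, 7.3), 0.59)
  expect_warning(wood_density(20, 10), "sanity band")
  expect_error(wood_density(-1, 10), "> 0")
})

test_that("anatomy_trait_table assembles branch and species tables", {
  tr <- simulate_tree(6, seed = 3)
  ana <- generate_anatomy_table(tr, synth_config(n_species = 6, seed = 3))
  tab <- anatomy_trait_table(ana$pits, ana$tracheids, ana$wood)
  expect_setequal(tab$species$species, tr$tip.label)
  expect_true(all(c("TO", "MF", "VE", "RPA_MPa_s_m3", "Dh_um", "TD_per_mm2",
                    "Tw_um", "TSR", "Dh_um_E", "Dh_um_L", "WD_g_cm3") %in%
                    names(tab$species)))
  expect_equal(nrow(tab$branch), 6 * 3)
  expect_true(all(is.finite(tab$species$VE)))
})
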