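# Cross predictions, cleavage-rate inversion, pooled rates with SEM.

test_that("drive-female and drive-male crosses reproduce the measured inheritance pattern", {
  p <- tare_params()
  pf <- predict_cross("h:D/W;sex:F", "h:W/W;sex:M", p)
  expect_equal(pf$carrier_tare, 0.5 / (1 - 0.5 * 0.888 * 0.632 -
                                         0.5 * 0.112 * 0.632^2),
               tolerance = 1e-12)
  expect_equal(round(100 * pf$carrier_tare), 72)
  expect_equal(pf$survival, 0.6970243, tolerance = 1e-6)
  # male drive parents transmit Mendelian: no maternal deposition
  pm <- predict_cross("h:W/W;sex:F", "h:D/W;sex:M", p)
  expect_identical(pm$carrier_tare, 0.5)
  expect_identical(pm$survival, 1)
})

test_that("heterozygote x heterozygote cross matches its closed form", {
  p <- tare_params()
  hh <- predict_cross("h:D/W;sex:F", "h:D/W;sex:M", p)
  expect_equal(hh$carrier_tare,
               tetherdrive:::carrier_frac_hethet_cross(0.888, 0.632),
               tolerance = 1e-12)
})

test_that("cleavage-rate inversion round-trips through the cross predictions", {
  for (gc in c(0.888, 0.3, 0.95)) for (ec in c(0.632, 0.1, 0.8)) {
    p <- drive_params(c_germ_tare = gc, c_embryo_tare = ec)
    inh_f <- predict_cross("h:D/W;sex:F", "h:W/W;sex:M", p)$carrier_tare
    inh_hh <- predict_cross("h:D/W;sex:F", "h:D/W;sex:M", p)$carrier_tare
    est <- estimate_cleavage_rates(inh_f, inh_hh)
    expect_true(est$identifiable)
    expect_equal(est$c_germ, gc, tolerance = 1e-9)
    expect_equal(est$c_embryo, ec, tolerance = 1e-9)
    expect_equal(est$fitted_inh_f, inh_f, tolerance = 1e-9)
    expect_equal(est$fitted_inh_hh, inh_hh, tolerance = 1e-9)
  }
})

test_that("Mendelian inheritance carries no cleavage signal", {
  est <- estimate_cleavage_rates(0.5, 0.75)
  expect_false(est$identifiable)
  expect_equal(est$c_embryo, 0)
  expect_true(is.na(est$c_germ))
  # rates below the Mendelian floor have no solution
  est2 <- estimate_cleavage_rates(0.45, 0.7)
  expect_false(est2$identifiable)
})

test_that("tethered double-heterozygote cross reduces to the TARE-only prediction when homing is inert", {
  p1 <- tare_params()
  p2 <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632,
                     homing_germ_cut = 0, c_embryo_homing = 0,
                     homing_locus_rule = "female_fertility")
  tare_only <- predict_cross("h:D/W;sex:F", "h:W/W;sex:M", p1)
  tethered <- predict_cross("h:D/W;hom:D/W;sex:F", "h:W/W;hom:W/W;sex:M", p2)
  expect_equal(tethered$carrier_tare, tare_only$carrier_tare,
               tolerance = 1e-12)
  expect_equal(tethered$survival, tare_only$survival, tolerance = 1e-12)
  expect_equal(tethered$carrier_homing, 0.5, tolerance = 1e-12)
})

test_that("male double heterozygotes transmit the two drives in phase (no male recombination)", {
  # drives in repulsion phase in the father, homing cutting switched off to
  # isolate linkage: without male crossing over (and without conversion
  # creating cis-drive haplotypes) offspring never receive both from him
  hp <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632,
                     homing_germ_cut = 0,
                     homing_locus_rule = "haplolethal_rescue")
  off <- predict_cross("h:W/W;hom:W/W;sex:F", "h:D/W;hom:W/D;sex:M", hp)
  expect_equal(off$phenotype[["both"]], 0)
  # germline conversion in the male creates cis double-drive haplotypes
  # even without recombination
  off2 <- predict_cross("h:W/W;hom:W/W;sex:F", "h:D/W;hom:W/D;sex:M",
                        haplolethal_params())
  expect_gt(off2$phenotype[["both"]], 0)
})

test_that("pooled rates and SEM behave at the edges", {
  r1 <- rate_with_sem(72, 100)
  expect_equal(r1$rate, 0.72)
  expect_true(is.na(r1$sem))
  expect_equal(r1$flag, "single_batch")
  r2 <- rate_with_sem(c(30, 30), c(50, 50))
  expect_equal(r2$sem, 0)
  r3 <- rate_with_sem(c(0, 0), c(0, 0))
  expect_equal(r3$flag, "no_offspring")
  # pooled rate is the count ratio, not the mean of vial rates
  r4 <- rate_with_sem(c(10, 90), c(20, 100))
  expect_equal(r4$rate, 100 / 120)
})

test_that("the between-vial SEM is calibrated on overdispersed vials", {
  p <- tare_params()
  truth <- predict_cross("h:D/W;sex:F", "h:W/W;sex:M", p)$carrier_tare
  set.seed(123)
  hits <- replicate(200, {
    d <- gen_cross_dataset("h:D/W;sex:F", "h:W/W;sex:M", p, n_vials = 20,
                           mean_offspring = 50, icc = 0.05)
    tot <- d$n_egfp + d$n_dsred + d$n_both + d$n_neither
    r <- rate_with_sem(d$n_egfp + d$n_both, tot)
    abs(r$rate - truth) <= 2 * r$sem
  })
  # a 2-SEM band with 20 batches covers slightly below the normal 95%
  expect_gte(mean(hits), 0.90)
})
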