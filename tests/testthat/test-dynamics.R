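# Deterministic generation dynamics, fixed points, thresholds, equilibria.

test_that("wild-type-only and drive-fixed populations are exact fixed points", {
  p <- tare_params()
  fit <- fitness_model(0.867)
  wt <- population_state("h:W/W;sex:F", p)
  nxt <- next_generation(wt, fit)
  expect_equal(nxt$freq_f, wt$freq_f, tolerance = 1e-14)
  expect_equal(attr(nxt, "output"), 1, tolerance = 1e-14)
  dd <- population_state("h:D/D;sex:F", p)
  nxt2 <- next_generation(dd, fit)
  expect_equal(nxt2$freq_f, dd$freq_f, tolerance = 1e-14)
})

test_that("frequencies stay normalised along a trajectory", {
  p <- tare_params()
  st <- population_state(c("W/W" = 0.5, "D/D" = 0.3, "D/W" = 0.2), p)
  tr <- iterate_generations(st, fitness_model(0.8), 25)
  final <- attr(tr, "final_state")
  expect_equal(sum(final$freq_f), 1, tolerance = 1e-9)
  expect_true(all(tr$carrier_freq_tare >= 0 & tr$carrier_freq_tare <= 1))
  expect_equal(nrow(tr), 26)
})

test_that("a release above the computed threshold spreads in the next generation", {
  p <- tare_params()
  fit <- fitness_model(0.867)
  st <- population_state(c("W/W" = 0.8, "D/D" = 0.2), p)
  nxt <- next_generation(st, fit)
  eng <- st$engine
  expect_gt(sum(nxt$freq_f * eng$carrier_tare), 0.2)
})

test_that("two-locus engine with inert homing locus reproduces the single-locus model", {
  p1 <- tare_params()
  # same rates, homing locus present but never cut and never selected
  p2 <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632,
                     homing_germ_cut = 0, c_embryo_homing = 0,
                     homing_locus_rule = "female_fertility")
  st1 <- population_state(c("W/W" = 0.7, "D/D" = 0.3), p1)
  st2 <- population_state(c("W:W/W:W" = 0.7, "D:W/D:W" = 0.3), p2)
  fit <- fitness_model(0.85)
  tr1 <- iterate_generations(st1, fit, 15)
  tr2 <- iterate_generations(st2, fit, 15)
  expect_equal(tr2$carrier_freq_tare, tr1$carrier_freq_tare,
               tolerance = 1e-12)
  expect_equal(tr2$allele_freq_tare_drive, tr1$allele_freq_tare_drive,
               tolerance = 1e-12)
})

test_that("cost-free TARE drive has a zero introduction threshold", {
  p <- tare_params()
  thr <- find_introduction_threshold(p, fitness_model(1), tol = 1e-3)
  expect_equal(as.numeric(thr), 0)
  expect_equal(attr(thr, "flag"), "always_spreads")
  # without embryo cutting a cost-free drive still spreads from anywhere
  p0 <- drive_params(c_germ_tare = 0.5, c_embryo_tare = 0)
  thr0 <- find_introduction_threshold(p0, fitness_model(1), tol = 1e-3)
  expect_equal(as.numeric(thr0), 0)
})

test_that("threshold is monotone in fitness and embryo cleavage on a coarse grid", {
  p <- tare_params()
  thr <- vapply(c(0.785, 0.867, 0.954),
                function(f) as.numeric(find_introduction_threshold(
                  p, fitness_model(f), tol = 1e-3)), 0)
  # non-increasing in f_hom: costlier drives need larger releases
  expect_true(all(diff(thr) < 0))
  # embryo cutting is the TARE toxin: more of it eases invasion, so the
  # threshold falls as c_embryo rises
  thr_e <- vapply(c(0, 0.632, 1), function(e) {
    pe <- drive_params(c_germ_tare = 0.888, c_embryo_tare = e)
    as.numeric(find_introduction_threshold(pe, fitness_model(0.867),
                                           tol = 1e-3))
  }, 0)
  expect_true(all(diff(thr_e) < 0))
})

test_that("deterministic mean of the stochastic simulator matches next_generation", {
  p <- tare_params()
  fit <- fitness_model(0.867)
  st <- population_state(c("W/W" = 0.55, "D/D" = 0.45), p)
  det <- next_generation(st, fit)
  det_cf <- sum(det$freq_f * st$engine$carrier_tare)
  set.seed(402)
  census <- 2000
  reps <- 400
  cfg <- cage_config(1, census = census, ne_fraction = 1,
                     releases = list(release_event(0, "h:D/D;sex:F", 0.45)))
  cf1 <- replicate(reps, {
    tr <- simulate_cage(p, fit, cfg)
    cf <- carrier_frequencies(tr)$carrier_freq_tare
    cf[2]
  })
  # drift (ne = census) plus census observation noise per replicate
  mc_se <- sqrt(det_cf * (1 - det_cf) * 2 / census / reps)
  expect_lt(abs(mean(cf1) - det_cf), 3 * mc_se)
})

test_that("haplolethal homing drive fixes in a TARE-fixed background", {
  hp <- haplolethal_params()
  eq <- find_equilibrium(hp, fitness_model(0.867), release = 0.06,
                         horizon = 120)
  expect_gt(as.numeric(eq), 0.999)
})

test_that("suppression drive with low conversion and a cost has an interior equilibrium", {
  sp <- suppression_params()
  eq <- find_equilibrium(sp, fitness_model(0.867, f_homing = 0.85),
                         release = 0.33, horizon = 300)
  expect_true(attr(eq, "converged"))
  expect_gt(as.numeric(eq), 0.2)
  expect_lt(as.numeric(eq), 0.95)
  # conversion 0: the costly homing allele declines below its release
  sp0 <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632,
                      homing_germ_cut = 0,
                      homing_locus_rule = "female_fertility")
  eq0 <- find_equilibrium(sp0, fitness_model(1, f_homing = 0.8),
                          release = 0.33, horizon = 300)
  expect_lt(as.numeric(eq0), 0.33)
})

test_that("a population of sterile females signals extinction", {
  sp <- suppression_params()
  st <- population_state("h:D/D;hom:D/D;sex:F", sp)
  expect_error(next_generation(st, fitness_model(1)), "extinct")
})
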