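# Transition likelihood, fitness/Ne estimation, component comparison,
# threshold CI propagation.

make_counts <- function(carriers, census) {
  c(n_egfp_only = carriers, n_dsred_only = 0, n_both = 0,
    n_neither = census - carriers)
}

test_that("the transition likelihood peaks at the deterministic expectation", {
  p <- tare_params()
  fit <- fitness_model(0.867)
  census <- 2000
  y0 <- make_counts(800, census)
  ll0 <- transition_loglik(y0, y0, census, census, p, fit,
                           ne_fraction = 0.9)
  expected <- attr(ll0, "expected")
  mode_carriers <- round(census * (expected[["n_egfp_only"]] +
                                     expected[["n_both"]]))
  lls <- vapply(seq(mode_carriers - 400, mode_carriers + 400, by = 50),
                function(k) as.numeric(
                  transition_loglik(y0, make_counts(k, census), census,
                                    census, p, fit, ne_fraction = 0.9)),
                0)
  expect_equal(which.max(lls), which(seq(-400, 400, by = 50) == 0))
})

test_that("exact summation and the normal approximation agree closely", {
  # agreement regime: the drift count must be fine enough that the compound
  # pmf (a mixture over latent drift outcomes, component spacing N/Ne) is
  # smooth at the census scale; at Ne = 500, N = 5000 the branches coincide
  p <- tare_params()
  fit <- fitness_model(0.867)
  census <- 5000
  ne <- 500
  y0 <- make_counts(2250, census)
  # place the observed counts 0-2 predictive sd around the expected mean:
  # the normal branch is a bulk approximation, not a tail one
  pe <- attr(transition_loglik(y0, y0, census, census, p, fit, 0.1),
             "expected")[["n_egfp_only"]]
  sd1 <- sqrt(pe * (1 - pe) * census * (1 + (census - 1) / ne))
  for (dev in c(0, 1, 2)) {
    y1 <- make_counts(round(census * pe + dev * sd1), census)
    le <- transition_loglik(y0, y1, census, census, p, fit, 0.1,
                            method = "exact")
    ln <- transition_loglik(y0, y1, census, census, p, fit, 0.1,
                            method = "normal")
    expect_lt(abs(as.numeric(le) - as.numeric(ln)), 0.1)
  }
})

test_that("impossible counts return -Inf with a diagnostic", {
  p <- tare_params()  # single locus: DsRed carriers cannot exist
  census <- 1000
  y0 <- make_counts(400, census)
  y_bad <- c(n_egfp_only = 300, n_dsred_only = 100, n_both = 0,
             n_neither = 600)
  ll <- transition_loglik(y0, y_bad, census, census, p,
                          fitness_model(0.867), 0.05)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "diagnostic"), "zero model probability")
})

test_that("fitness and Ne are recovered from a synthetic cage set", {
  p <- tare_params()
  set.seed(11)
  cages <- gen_cage_dataset(p, fitness_model(0.867))
  fit <- fit_fitness(cages, p)
  expect_gte(fit$f_hom, fit$ci_f[1])
  expect_lte(fit$f_hom, fit$ci_f[2])
  expect_gte(0.867, fit$ci_f[1])
  expect_lte(0.867, fit$ci_f[2])
  expect_gt(fit$ne_fraction, 0.015)
  expect_lt(fit$ne_fraction, 0.08)
  expect_equal(fit$transitions_discarded, 8L)
  expect_true(is.finite(fit$logLik))
})

test_that("likelihood is invariant to cage ordering", {
  p <- tare_params()
  set.seed(4)
  cages <- gen_cage_dataset(p, fitness_model(0.867), n_cages = 3,
                            n_generations = 6, census = 800,
                            ne_fraction = 0.05,
                            release_props = c(0.3, 0.5, 0.6))
  f1 <- fit_fitness(cages, p, profile = character(0))
  f2 <- fit_fitness(rev(cages), p, profile = character(0))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$f_hom, f2$f_hom, tolerance = 1e-4)
})

test_that("cost-free data give an estimate near one and a near-zero threshold", {
  p <- tare_params()
  set.seed(2)
  cages <- gen_cage_dataset(p, fitness_model(1), n_cages = 4,
                            n_generations = 8, census = 3491,
                            release_props = c(0.3, 0.4, 0.5, 0.6))
  fit <- fit_fitness(cages, p, profile = "f")
  expect_gt(fit$f_hom, 0.9)
  thr <- threshold_ci(fit, p, tol = 1e-3)
  expect_lte(thr[["lower"]], thr[["point"]])
  expect_lte(thr[["point"]], thr[["upper"]])
  expect_lt(thr[["point"]], 0.04)
})

test_that("fecundity and mating components are frequency-equivalent without maternal deposition", {
  # weighting mothers or fathers by the same fitness gives identical
  # offspring frequencies only when nothing else distinguishes the sexes;
  # embryo cleavage is mother-conditioned, so it is switched off here
  # (with it on, down-weighting drive mothers also reduces embryo cutting
  # and the two components genuinely differ)
  p <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0)
  set.seed(6)
  cages <- gen_cage_dataset(p, fitness_model(0.8, "female_fecundity"),
                            n_cages = 2, n_generations = 6, census = 1500,
                            ne_fraction = 0.05,
                            release_props = c(0.3, 0.5))
  ff <- fit_fitness(cages, p, component = "female_fecundity",
                    profile = character(0))
  fm <- fit_fitness(cages, p, component = "male_mating",
                    profile = character(0))
  expect_equal(ff$logLik, fm$logLik, tolerance = 1e-6)
  expect_equal(ff$f_hom, fm$f_hom, tolerance = 1e-4)
})

test_that("one-sex costs fit near the square of the two-sex fitness", {
  # a per-pair cost f^2 (one parent at f^2) matches both parents at f
  p <- tare_params()
  set.seed(8)
  cages <- gen_cage_dataset(p, fitness_model(0.867))
  cmp <- compare_components(cages, p, profile = character(0))
  expect_setequal(cmp$component,
                  c("both_sexes", "female_fecundity", "male_mating",
                    "offspring_viability"))
  both <- cmp$f_hom[cmp$component == "both_sexes"]
  fec <- cmp$f_hom[cmp$component == "female_fecundity"]
  expect_lt(abs(fec - both^2), 0.02)
  expect_lte(min(cmp$delta_logLik), 1e-9)
})

test_that("threshold CI mapping is monotone and degenerate at fitness one", {
  p <- tare_params()
  fake <- structure(list(f_hom = 0.867, ci_f = c(0.785, 0.954),
                         component = "both_sexes"),
                    class = "likelihood_fit")
  thr <- threshold_ci(fake, p, tol = 1e-3)
  expect_lt(thr[["lower"]], thr[["point"]])
  expect_lt(thr[["point"]], thr[["upper"]])
  fake1 <- structure(list(f_hom = 1, ci_f = c(1, 1),
                          component = "both_sexes"),
                     class = "likelihood_fit")
  expect_equal(unname(threshold_ci(fake1, p, tol = 1e-3)), c(0, 0, 0))
})
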