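# Synthetic cross and cage datasets with known ground truth.
#
# Defaults reproduce the study conditions of the cage experiments these
# models describe: four cages averaging ~3,491 adults per generation, an
# effective size of 3.6% of census, germline/embryo cleavage 0.888/0.632,
# codominant drive fitness 0.867, and TARE-homozygote releases spanning the
# bistable range (two well above threshold, two near it).

#' Generate a synthetic cross dataset
#'
#' Simulates per-vial offspring phenotype counts around the exact cross
#' prediction, with optional between-vial overdispersion: each vial's
#' offspring total is Poisson around `mean_offspring`, its class
#' probabilities are drawn from a Dirichlet scaled so that `icc` is the
#' intra-vial correlation (beta-binomial style batch effects), and counts
#' are multinomial. `icc = 0` gives plain multinomial vials.
#'
#' @param mother,father parental genotypes (objects or strings).
#' @param params a [drive_params()] object (ground truth).
#' @param n_vials number of vials (batches).
#' @param mean_offspring mean adult offspring per vial.
#' @param icc intra-vial (batch) correlation in `[0, 1)`.
#' @param eggs if `TRUE`, also simulate egg and pupa counts: eggs are the
#'   conceived total (offspring scaled up by the cross's relative survival
#'   and a baseline viability), pupae binomial around the model survival.
#' @param baseline_viability egg-to-pupa survival unrelated to the drive.
#' @return A data frame in the cross CSV schema (`vial_id`,
#'   `mother_genotype`, `father_genotype`, `n_egfp`, `n_dsred`, `n_both`,
#'   `n_neither`, `n_eggs`, `n_pupae`) with the truth attached as attribute
#'   `"truth"`.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' set.seed(1)
#' gen_cross_dataset("h:D/W;sex:F", "h:W/W;sex:M", tare, n_vials = 5)
#' @export
gen_cross_dataset <- function(mother, father, params, n_vials = 20,
                              mean_offspring = 50, icc = 0.02,
                              eggs = FALSE, baseline_viability = 0.9) {
  if (is.character(mother)) mother <- parse_genotype(mother)
  if (is.character(father)) father <- parse_genotype(father)
  stopifnot(n_vials >= 0, icc >= 0, icc < 1)
  pred <- predict_cross(mother, father, params)
  p <- pred$phenotype
  rows <- vector("list", n_vials)
  for (v in seq_len(n_vials)) {
    n <- stats::rpois(1, mean_offspring)
    pv <- p
    if (icc > 0 && n > 0) {
      conc <- (1 - icc) / icc
      a <- p * conc
      gam <- stats::rgamma(4, shape = ifelse(a > 0, a, 0), rate = 1)
      gam[a == 0] <- 0
      if (sum(gam) > 0) pv <- gam / sum(gam)
    }
    cnt <- if (n > 0) stats::rmultinom(1, n, pv)[, 1] else rep(0L, 4)
    n_eggs <- n_pupae <- NA_integer_
    if (eggs) {
      surv <- pred$survival * baseline_viability
      n_eggs <- n + stats::rnbinom(1, size = 5,
                                   mu = max(n / max(surv, 1e-6) - n, 0))
      n_pupae <- n + stats::rbinom(1, max(n_eggs - n, 0), 0.1)
      n_pupae <- min(n_pupae, n_eggs)
    }
    rows[[v]] <- data.frame(vial_id = v,
                            mother_genotype = format(mother),
                            father_genotype = format(father),
                            n_egfp = cnt[1], n_dsred = cnt[2],
                            n_both = cnt[3], n_neither = cnt[4],
                            n_eggs = n_eggs, n_pupae = n_pupae)
  }
  out <- if (n_vials > 0) do.call(rbind, rows) else
    data.frame(vial_id = integer(0), mother_genotype = character(0),
               father_genotype = character(0), n_egfp = integer(0),
               n_dsred = integer(0), n_both = integer(0),
               n_neither = integer(0), n_eggs = integer(0),
               n_pupae = integer(0))
  structure(out, truth = list(params = params, prediction = pred,
                              icc = icc))
}

#' Generate a synthetic multi-cage dataset
#'
#' Wraps [simulate_cage()] to produce a set of cage trajectories with known
#' ground truth. Default release proportions follow the cage experiment
#' design: TARE-homozygote founding releases at carrier frequencies
#' spanning the introduction threshold (0.1, 0.2) and well above it
#' (0.61, 0.71).
#'
#' @param params a [drive_params()] object (ground truth).
#' @param fitness a [fitness_model()] (ground truth).
#' @param n_cages number of replicate cages.
#' @param n_generations generation transitions per cage.
#' @param census mean census size per generation.
#' @param ne_fraction effective size as a fraction of census.
#' @param release_props TARE-homozygote release proportion per cage
#'   (recycled to `n_cages`).
#' @param homing_releases optional list of [release_event()]s appended to
#'   every cage (e.g. a homing release after TARE fixation).
#' @return A list of `"cage_trajectory"` data frames with attribute
#'   `"truth"`.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' set.seed(7)
#' cages <- gen_cage_dataset(tare, fitness_model(0.867), n_cages = 2,
#'                           n_generations = 5, census = 400)
#' @export
gen_cage_dataset <- function(params, fitness = fitness_model(0.867),
                             n_cages = 4, n_generations = 12,
                             census = 3491, ne_fraction = 0.036,
                             release_props = c(0.1, 0.2, 0.61, 0.71),
                             homing_releases = list()) {
  stopifnot(n_cages >= 1)
  release_props <- rep_len(release_props, n_cages)
  rel_geno <- if (params$homing_locus_rule == "none")
    "h:D/D;sex:F" else "h:D/D;hom:W/W;sex:F"
  trajs <- lapply(seq_len(n_cages), function(i) {
    cfg <- cage_config(n_generations, census = census,
                       ne_fraction = ne_fraction,
                       releases = c(list(release_event(0, rel_geno,
                                                       release_props[i])),
                                    homing_releases))
    simulate_cage(params, fitness, cfg)
  })
  structure(trajs, truth = list(params = params, fitness = fitness,
                                ne_fraction = ne_fraction,
                                release_props = release_props))
}
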