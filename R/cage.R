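#' Cage experiment configuration
#'
#' Describes a discrete-generation cage population: the census sizes
#' observed each generation, the effective population size as a fraction of
#' census (genetic drift is much stronger in cage populations than their
#' census size suggests), and the release schedule.
#'
#' @param n_generations number of generation transitions to simulate.
#' @param census either a single mean census size (used for every
#'   generation) or an integer vector of length `n_generations + 1`.
#' @param ne_fraction effective population size as a fraction of census, in
#'   (0, 1].
#' @param releases list of [release_event()]s. A release at generation 0
#'   founds the drive cohort.
#' @return A list with class `"cage_config"`.
#' @examples
#' cage_config(10, census = 3491, ne_fraction = 0.036,
#'             releases = list(release_event(0, "h:D/D;sex:F", 0.6)))
#' @export
cage_config <- function(n_generations, census = 3491, ne_fraction = 0.036,
                        releases = list()) {
  stopifnot(n_generations >= 1)
  if (length(census) == 1) census <- rep(census, n_generations + 1)
  if (length(census) != n_generations + 1)
    stop("census must have length 1 or n_generations + 1", call. = FALSE)
  census <- as.integer(round(census))
  if (any(census < 1)) stop("census sizes must be >= 1", call. = FALSE)
  if (ne_fraction <= 0 || ne_fraction > 1)
    stop("ne_fraction must be in (0, 1]", call. = FALSE)
  for (r in releases) stopifnot(inherits(r, "release_event"))
  structure(list(n_generations = as.integer(n_generations), census = census,
                 ne_fraction = ne_fraction, releases = releases),
            class = "cage_config")
}

#' Simulate a cage trajectory
#'
#' Wright-Fisher-style finite-population simulation of a cage experiment.
#' Each transition: (1) the deterministic expected offspring genotype
#' distribution is computed; (2) drift: `round(ne_fraction * mean(census_t,
#' census_t1))` individuals are drawn multinomially from it and their
#' empirical frequencies become the realised genotype distribution (the
#' effective size of a transition is referenced to the average census of
#' the two generations it joins); (3) any release for the new generation is
#' mixed into the realised frequencies, so released individuals are part of
#' that generation's census; (4) observation: the census is drawn
#' multinomially from the realised frequencies and phenotyped (EGFP = at
#' least one TARE drive allele, DsRed = at least one homing drive allele).
#'
#' @param params a [drive_params()] object.
#' @param fitness a [fitness_model()].
#' @param cage a [cage_config()].
#' @param initial optional named genotype-frequency vector (or
#'   [population_state()]) for generation 0; by default a wild-type
#'   population into which the generation-0 releases are mixed.
#' @return A `"cage_trajectory"`: a data frame with columns `generation`,
#'   `census`, `n_egfp_only`, `n_dsred_only`, `n_both`, `n_neither`
#'   (phenotype counts summing to the census). The latent realised genotype
#'   frequencies are attached as attribute `"latent"` (matrix, one row per
#'   generation) with genotype labels, and `"suppressed"` is `TRUE` for a
#'   trajectory truncated by reproductive collapse.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' cfg <- cage_config(5, census = 500, ne_fraction = 0.1,
#'                    releases = list(release_event(0, "h:D/D;sex:F", 0.6)))
#' set.seed(1)
#' simulate_cage(tare, fitness_model(0.867), cfg)
#' @export
simulate_cage <- function(params, fitness, cage, initial = NULL) {
  stopifnot(inherits(params, "drive_params"),
            inherits(fitness, "fitness_model"),
            inherits(cage, "cage_config"))
  eng <- build_engine(params)
  rel_by_gen <- split(cage$releases,
                      vapply(cage$releases, `[[`, 0L, "generation"))
  freq <- if (is.null(initial)) {
    engine_wild_freq(eng)
  } else if (inherits(initial, "population_state")) {
    initial$freq_f
  } else {
    population_state(initial, params)$freq_f
  }
  apply_releases <- function(freq, gen) {
    for (r in rel_by_gen[[as.character(gen)]])
      freq <- engine_mix_release(eng, freq,
                                 engine_genotype_index(eng, r$genotype),
                                 r$proportion)
    freq
  }
  freq <- apply_releases(freq, 0L)
  n_gen <- cage$n_generations
  latent <- matrix(NA_real_, n_gen + 1, eng$nG,
                   dimnames = list(NULL, eng$labels))
  counts <- matrix(0L, n_gen + 1, 4,
                   dimnames = list(NULL, c("n_egfp_only", "n_dsred_only",
                                           "n_both", "n_neither")))
  observe <- function(freq, census) {
    gcounts <- stats::rmultinom(1, census, freq)[, 1]
    c(n_egfp_only = sum(gcounts[eng$carrier_tare & !eng$carrier_homing]),
      n_dsred_only = sum(gcounts[!eng$carrier_tare & eng$carrier_homing]),
      n_both = sum(gcounts[eng$carrier_tare & eng$carrier_homing]),
      n_neither = sum(gcounts[!eng$carrier_tare & !eng$carrier_homing]))
  }
  latent[1, ] <- freq
  counts[1, ] <- observe(freq, cage$census[1])
  suppressed <- FALSE
  last <- n_gen + 1
  for (t in seq_len(n_gen)) {
    res <- engine_next_gen(eng, freq, freq, fitness)
    if (res$extinct) { suppressed <- TRUE; last <- t; break }
    ne <- max(1L, as.integer(round(cage$ne_fraction *
                                     mean(cage$census[t:(t + 1)]))))
    drawn <- stats::rmultinom(1, ne, res$freq)[, 1]
    freq <- drawn / ne
    freq <- apply_releases(freq, t)
    latent[t + 1, ] <- freq
    counts[t + 1, ] <- observe(freq, cage$census[t + 1])
  }
  keep <- seq_len(last)
  out <- data.frame(generation = keep - 1L,
                    census = cage$census[keep])
  out <- cbind(out, as.data.frame(counts[keep, , drop = FALSE]))
  structure(out, class = c("cage_trajectory", "data.frame"),
            latent = latent[keep, , drop = FALSE], suppressed = suppressed)
}

#' Carrier frequencies of a cage trajectory
#'
#' @param traj a `"cage_trajectory"` data frame (or any data frame with the
#'   cage phenotype-count columns).
#' @return A data frame: `generation`, `carrier_freq_tare` (EGFP carriers /
#'   census), `carrier_freq_homing` (DsRed carriers / census).
#' @export
carrier_frequencies <- function(traj) {
  data.frame(generation = traj$generation,
             carrier_freq_tare = (traj$n_egfp_only + traj$n_both) /
               traj$census,
             carrier_freq_homing = (traj$n_dsred_only + traj$n_both) /
               traj$census)
}

#' Summarise replicate cage trajectories
#'
#' Per-generation mean and 2.5/50/97.5% quantiles of the TARE-carrier
#' frequency across replicate trajectories. Ragged replicate lengths
#' (e.g. suppressed cages) are truncated to the shortest and flagged.
#'
#' @param trajectories list of `"cage_trajectory"` objects.
#' @return A data frame `generation`, `mean`, `q025`, `median`, `q975`,
#'   with attribute `"truncated"` if lengths differed.
#' @export
summarize_replicates <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  lens <- vapply(trajectories, nrow, 0L)
  n <- min(lens)
  freqs <- vapply(trajectories, function(tr) {
    cf <- carrier_frequencies(tr)$carrier_freq_tare
    cf[seq_len(n)]
  }, numeric(n))
  freqs <- matrix(freqs, nrow = n)
  out <- data.frame(generation = trajectories[[1]]$generation[seq_len(n)],
                    mean = rowMeans(freqs),
                    q025 = apply(freqs, 1, stats::quantile, 0.025),
                    median = apply(freqs, 1, stats::quantile, 0.5),
                    q975 = apply(freqs, 1, stats::quantile, 0.975))
  structure(out, truncated = length(unique(lens)) > 1)
}

#' @export
plot.cage_trajectory <- function(x, ...) {
  cf <- carrier_frequencies(x)
  graphics::plot(cf$generation, cf$carrier_freq_tare, type = "b", lwd = 2,
                 ylim = c(0, 1), xlab = "generation",
                 ylab = "drive carrier frequency", col = "forestgreen", ...)
  if (any(cf$carrier_freq_homing > 0))
    graphics::lines(cf$generation, cf$carrier_freq_homing, type = "b",
                    lwd = 2, col = "firebrick")
  invisible(x)
}
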