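#' Population state
#'
#' Genotype frequencies among adults of one discrete generation. Offspring
#' sex is independent of genotype in this model and sexes are at 1:1, so
#' male and female frequencies coincide except immediately after a
#' sex-biased manipulation; both are stored.
#'
#' @param freq named numeric vector of genotype frequencies (names in the
#'   genotype-label syntax, e.g. `"D/W"` or `"D:W/W:W"`), or a single
#'   genotype string/`"drive_genotype"` for a monomorphic population, or a
#'   named list mapping genotype strings to frequencies.
#' @param params a [drive_params()] object (fixes the genotype space).
#' @param generation integer generation index.
#' @param two_locus force a two-locus genotype space; by default inferred
#'   from `params$homing_locus_rule`.
#' @return A list with class `"population_state"`.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' st <- population_state(c("W/W" = 0.8, "D/D" = 0.2), tare)
#' @export
population_state <- function(freq, params, generation = 0L,
                             two_locus = NULL) {
  eng <- build_engine(params, two_locus = two_locus)
  v <- numeric(eng$nG)
  if (inherits(freq, "drive_genotype") ||
      (is.character(freq) && length(freq) == 1 && is.null(names(freq)))) {
    g <- if (is.character(freq)) parse_genotype(freq) else freq
    v[engine_genotype_index(eng, g)] <- 1
  } else {
    freq <- unlist(freq)
    if (is.null(names(freq)))
      stop("'freq' must be named by genotype label", call. = FALSE)
    for (nm in names(freq)) {
      k <- match_genotype_label(eng, nm)
      v[k] <- v[k] + freq[[nm]]
    }
  }
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  if (any(v[!eng$viable] > 0))
    stop("population contains nonviable genotypes", call. = FALSE)
  structure(list(freq_f = v, freq_m = v, generation = as.integer(generation),
                 engine = eng),
            class = "population_state")
}

# match "D/W" style labels irrespective of haplotype order
match_genotype_label <- function(eng, label) {
  k <- match(label, eng$labels)
  if (!is.na(k)) return(k)
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    k <- match(paste0(parts[2], "/", parts[1]), eng$labels)
    if (!is.na(k)) return(k)
  }
  stop("unknown genotype label '", label, "' for this configuration",
       call. = FALSE)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> generation %d\n", x$generation))
  keep <- x$freq_f > 1e-12
  d <- data.frame(genotype = x$engine$labels[keep],
                  freq = round(x$freq_f[keep], 6))
  print(d[order(-d$freq), ], row.names = FALSE)
  invisible(x)
}

state_summary <- function(eng, freq, output = NA_real_) {
  c(carrier_freq_tare = sum(freq * eng$carrier_tare),
    carrier_freq_homing = sum(freq * eng$carrier_homing),
    allele_freq_tare_drive = sum(freq * eng$n_tareD) / 2,
    allele_freq_homing_drive = sum(freq * eng$n_homD) / 2,
    load = 1 - output)
}

#' Advance one deterministic generation
#'
#' Infinite-population expectation of one discrete, non-overlapping
#' generation with random mating at a 1:1 sex ratio. Mothers are weighted by
#' the female-side fitness component (sterile females contribute nothing),
#' fathers competitively by the male-side component; offspring pool through
#' the exact cross distributions, maternal-deposition cleavage and viability
#' selection, an offspring-viability fitness component multiplies survival,
#' and the result is renormalised.
#'
#' @param state a [population_state()].
#' @param fitness a [fitness_model()].
#' @return A new `"population_state"` with attribute `"output"`, the total
#'   viable reproductive output relative to an all-wild-type population
#'   (`1 - output` is the genetic load).
#' @export
next_generation <- function(state, fitness = fitness_model()) {
  stopifnot(inherits(state, "population_state"),
            inherits(fitness, "fitness_model"))
  eng <- state$engine
  res <- engine_next_gen(eng, state$freq_f, state$freq_m, fitness)
  if (res$extinct)
    stop("population extinct: no viable offspring produced", call. = FALSE)
  out <- state
  out$freq_f <- out$freq_m <- res$freq
  out$generation <- state$generation + 1L
  attr(out, "output") <- res$output
  out
}

#' Iterate deterministic generations
#'
#' @param state a [population_state()] starting point.
#' @param fitness a [fitness_model()].
#' @param n_gens number of generations to advance.
#' @return An object of class `"drive_trajectory"`: a data frame with one
#'   row per generation (including the input) and columns `generation`,
#'   `carrier_freq_tare`, `carrier_freq_homing`, `allele_freq_tare_drive`,
#'   `allele_freq_homing_drive`, `load`. The final state is attached as
#'   attribute `"final_state"`; if the population goes extinct the
#'   trajectory is truncated and attribute `"extinct"` is `TRUE`.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' st <- population_state(c("W/W" = 0.5, "D/D" = 0.5), tare)
#' iterate_generations(st, fitness_model(0.867), 10)
#' @export
iterate_generations <- function(state, fitness = fitness_model(), n_gens) {
  stopifnot(inherits(state, "population_state"), n_gens >= 0)
  eng <- state$engine
  rows <- vector("list", n_gens + 1)
  rows[[1]] <- c(generation = state$generation,
                 state_summary(eng, state$freq_f, output = 1))
  cur_f <- state$freq_f; cur_m <- state$freq_m
  extinct <- FALSE
  if (n_gens > 0) for (t in seq_len(n_gens)) {
    res <- engine_next_gen(eng, cur_f, cur_m, fitness)
    if (res$extinct) { extinct <- TRUE; rows <- rows[seq_len(t)]; break }
    cur_f <- cur_m <- res$freq
    rows[[t + 1]] <- c(generation = state$generation + t,
                       state_summary(eng, cur_f, res$output))
  }
  out <- as.data.frame(do.call(rbind, rows))
  final <- state
  final$freq_f <- cur_f; final$freq_m <- cur_m
  final$generation <- as.integer(out$generation[nrow(out)])
  structure(out, class = c("drive_trajectory", "data.frame"),
            final_state = final, extinct = extinct)
}

#' @export
plot.drive_trajectory <- function(x, ...) {
  graphics::plot(x$generation, x$carrier_freq_tare, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "generation",
                 ylab = "drive carrier frequency",
                 col = "forestgreen", ...)
  if (any(x$carrier_freq_homing > 0))
    graphics::lines(x$generation, x$carrier_freq_homing, lwd = 2,
                    col = "firebrick")
  invisible(x)
}

# spread/decline classification used by the threshold bisection. After the
# horizon the transient from the pure homozygote release has long passed,
# so the direction of motion is decisive; requiring an absolute gain would
# misclassify cost-free drives released at tiny frequencies, whose rise is
# real but slower than any fixed margin.
classify_release <- function(eng, release_index, p, fitness, horizon,
                             spread_hi = 0.99) {
  freq <- engine_mix_release(eng, engine_wild_freq(eng), release_index, p)
  init <- sum(freq * eng$carrier_tare)
  prev <- init
  cf <- init
  increasing <- FALSE
  for (t in seq_len(horizon)) {
    res <- engine_next_gen(eng, freq, freq, fitness)
    if (res$extinct) return(FALSE)
    freq <- res$freq
    cf <- sum(freq * eng$carrier_tare)
    if (cf >= spread_hi) return(TRUE)
    if (cf < 1e-9) return(FALSE)
    increasing <- cf > prev
    prev <- cf
  }
  cf > init && increasing
}

#' Introduction threshold of the TARE drive
#'
#' The TARE drive is bistable when it carries a fitness cost: released above
#' an unstable equilibrium frequency it spreads towards fixation, below it
#' declines. This locates that boundary by bisection on the release
#' proportion of TARE drive homozygotes mixed into a wild-type population.
#' A release is classified as spreading if the drive-carrier frequency
#' reaches `0.99` within the horizon, or ends above its initial value and
#' is still rising at the horizon (by then the release transient has
#' passed, so the direction of motion identifies the basin).
#'
#' @param params a [drive_params()] object.
#' @param fitness a [fitness_model()].
#' @param tol bisection tolerance on the release proportion.
#' @param horizon generations simulated per classification.
#' @return The threshold release proportion. `0` when every positive release
#'   spreads. The attribute `"flag"` is `"interior"`, `"always_spreads"`, or
#'   `"never_spreads"`.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' find_introduction_threshold(tare, fitness_model(1), tol = 1e-3)  # 0
#' @export
find_introduction_threshold <- function(params, fitness, tol = 1e-4,
                                        horizon = 1000L) {
  stopifnot(inherits(params, "drive_params"),
            inherits(fitness, "fitness_model"), tol > 0)
  eng <- build_engine(params)
  rel <- release_index_tare_homozygote(eng)
  if (classify_release(eng, rel, tol, fitness, horizon))
    return(structure(0, flag = "always_spreads"))
  if (!classify_release(eng, rel, 1 - tol, fitness, horizon))
    return(structure(1, flag = "never_spreads"))
  lo <- tol; hi <- 1 - tol
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify_release(eng, rel, mid, fitness, horizon)) hi <- mid
    else lo <- mid
  }
  structure((lo + hi) / 2, flag = "interior")
}

release_index_tare_homozygote <- function(eng) {
  hd <- which(eng$haps$tare == "D" & eng$haps$homing %in% c("W", "A"))
  eng$gidx[hd, hd]
}

#' Long-run carrier frequency of a homing drive
#'
#' Iterates the deterministic dynamics of a split homing drive released into
#' a population in which the TARE drive is fixed, and reports the long-run
#' homing-drive carrier frequency. For the suppression drive, drive
#' conversion pushes the allele up while its fitness cost and the sterility
#' of females lacking a functional fertility-gene copy push it down, which
#' can balance at an interior equilibrium below fixation.
#'
#' @param params a [drive_params()] with an active homing locus.
#' @param fitness a [fitness_model()].
#' @param release release proportion of TARE-homozygous,
#'   homing-heterozygous individuals (the cage release genotype), or a
#'   [release_event()] for a different genotype.
#' @param horizon generations iterated.
#' @param tol convergence: largest change of carrier frequency across the
#'   last 5 generations.
#' @return Carrier frequency of the homing drive after `horizon`
#'   generations, with attributes `"converged"` (logical) and
#'   `"trajectory"` (the [iterate_generations()] output).
#' @export
find_equilibrium <- function(params, fitness, release = 0.33,
                             horizon = 300L, tol = 1e-6) {
  stopifnot(inherits(params, "drive_params"),
            inherits(fitness, "fitness_model"))
  if (params$homing_locus_rule == "none")
    stop("find_equilibrium needs an active homing locus", call. = FALSE)
  eng <- build_engine(params)
  # background: TARE fixed
  dd <- which(eng$haps$tare == "D" & eng$haps$homing == "W")
  freq <- numeric(eng$nG); freq[eng$gidx[dd, dd]] <- 1
  if (inherits(release, "release_event")) {
    k <- engine_genotype_index(eng, release$genotype)
    freq <- engine_mix_release(eng, freq, k, release$proportion)
  } else {
    dh <- which(eng$haps$tare == "D" & eng$haps$homing == "D")
    k <- eng$gidx[dd, dh]
    freq <- engine_mix_release(eng, freq, k, release)
  }
  cf <- numeric(horizon + 1)
  cf[1] <- sum(freq * eng$carrier_homing)
  extinct <- FALSE
  for (t in seq_len(horizon)) {
    res <- engine_next_gen(eng, freq, freq, fitness)
    if (res$extinct) { extinct <- TRUE; cf <- cf[seq_len(t)]; break }
    freq <- res$freq
    cf[t + 1] <- sum(freq * eng$carrier_homing)
  }
  n <- length(cf)
  converged <- !extinct && n > 6 &&
    max(abs(diff(cf[(n - 5):n]))) < tol
  structure(cf[n], converged = converged, extinct = extinct,
            trajectory = cf)
}
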