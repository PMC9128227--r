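# Likelihood of cage phenotype trajectories.
#
# The observation model mirrors the cage simulator stage for stage. A
# generation transition is: deterministic expectation -> multinomial drift
# of Ne = round(ne_fraction * mean(census_t, census_t1)) individuals ->
# multinomial census observation from the realised frequencies. Because
# multinomials aggregate, collapsing genotypes to phenotype classes is
# exact, so the likelihood of the observed phenotype counts is the compound
# of a Multinomial(Ne, p) drift draw and a Multinomial(N, X/Ne) census
# draw over phenotype classes.

PHENO_CLASSES <- c("n_egfp_only", "n_dsred_only", "n_both", "n_neither")

# log-likelihood of observed class counts y (summing to N) given expected
# class probabilities p, drift size ne. Exact summation over the latent
# drift count when only two classes are live and ne is small enough to
# enumerate; otherwise a moment-matched multivariate normal with
# overdispersion factor 1 + (N - 1)/ne (the exact covariance of the
# two-stage draw).
ll_compound <- function(y, N, p, ne, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(p), sum(y) == N)
  live <- p > 1e-300 | y > 0
  if (any(y > 0 & p <= 1e-300)) return(-Inf)
  y <- y[live]; p <- p[live]; p <- p / sum(p)
  k <- length(y)
  if (k <= 1) return(0)
  if (method == "auto")
    method <- if (k == 2 && ne <= 5000) "exact" else "normal"
  if (method == "exact") {
    if (k != 2) stop("exact summation implemented for two live classes",
                     call. = FALSE)
    x <- 0:ne
    terms <- stats::dbinom(x, ne, p[1], log = TRUE) +
      stats::dbinom(y[1], N, x / ne, log = TRUE)
    m <- max(terms)
    if (!is.finite(m)) return(-Inf)
    return(m + log(sum(exp(terms - m))))
  }
  # normal branch on the first k-1 classes
  phi <- 1 + (N - 1) / ne
  mu <- N * p
  V <- phi * N * (diag(p, nrow = k) - tcrossprod(p))
  i <- seq_len(k - 1)
  d <- y[i] - mu[i]
  Vi <- V[i, i, drop = FALSE]
  ch <- tryCatch(chol(Vi), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (sum(z^2) + 2 * sum(log(diag(ch))) + (k - 1) * log(2 * pi))
}

# within-class recalibration of a latent genotype-frequency vector to
# observed phenotype-class frequencies (model-implied composition within
# each class is preserved)
recalibrate_latent <- function(eng, latent, obs_freq, class_of) {
  out <- numeric(length(latent))
  for (cl in seq_along(obs_freq)) {
    sel <- class_of == cl
    m <- sum(latent[sel])
    if (obs_freq[cl] > 0) {
      if (m <= 0) return(NULL)  # impossible counts under the model
      out[sel] <- latent[sel] * obs_freq[cl] / m
    }
  }
  out / sum(out)
}

engine_class_of <- function(eng) {
  ifelse(eng$carrier_tare & eng$carrier_homing, 3L,
         ifelse(eng$carrier_tare, 1L,
                ifelse(eng$carrier_homing, 2L, 4L)))
}

# latent initial genotype frequencies: carriers at the release genotype,
# the rest wild type
init_latent <- function(eng, carrier_freq, release_index) {
  freq <- engine_wild_freq(eng) * (1 - carrier_freq)
  freq[release_index] <- freq[release_index] + carrier_freq
  freq
}

#' Log-likelihood of one generation transition
#'
#' Reconstructs the genotype composition at the start of the transition
#' from the observed phenotype counts (model-implied proportions within
#' each phenotype class, by default a drive-homozygote release into a
#' wild-type background), propagates one deterministic generation, and
#' evaluates the compound drift + census-observation likelihood of the
#' next generation's counts.
#'
#' @param counts_t,counts_t1 named integer vectors with elements
#'   `n_egfp_only`, `n_dsred_only`, `n_both`, `n_neither`, summing to the
#'   censuses.
#' @param census_t,census_t1 census sizes.
#' @param params a [drive_params()] object.
#' @param fitness a [fitness_model()].
#' @param ne_fraction effective population size as a fraction of census.
#' @param latent optional genotype-frequency vector over the engine's
#'   genotype space to use as the pre-recalibration composition at `t`
#'   (as produced by a running model prediction).
#' @param method likelihood evaluation: `"exact"` enumerates the latent
#'   drift count (two live phenotype classes), `"normal"` uses the
#'   moment-matched normal approximation, `"auto"` picks by problem size.
#' @return The log-likelihood, with attributes `"expected"` (expected class
#'   probabilities at `t1`) and `"method"`. Counts impossible under the
#'   model give `-Inf` with attribute `"diagnostic"`.
#' @export
transition_loglik <- function(counts_t, counts_t1, census_t, census_t1,
                              params, fitness, ne_fraction,
                              latent = NULL,
                              method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "drive_params"),
            inherits(fitness, "fitness_model"),
            ne_fraction > 0, ne_fraction <= 1)
  eng <- build_engine(params)
  y_t <- as_class_counts(counts_t)
  y_t1 <- as_class_counts(counts_t1)
  if (sum(y_t) != census_t || sum(y_t1) != census_t1)
    stop("phenotype counts must sum to the census", call. = FALSE)
  class_of <- engine_class_of(eng)
  if (is.null(latent))
    latent <- init_latent(eng, (y_t[1] + y_t[3]) / census_t,
                          release_index_tare_homozygote(eng))
  q <- recalibrate_latent(eng, latent, y_t / census_t, class_of)
  if (is.null(q))
    return(structure(-Inf,
                     diagnostic = "observed phenotype class has zero model probability"))
  res <- engine_next_gen(eng, q, q, fitness)
  if (res$extinct)
    return(structure(-Inf, diagnostic = "model predicts reproductive collapse"))
  p <- vapply(1:4, function(cl) sum(res$freq[class_of == cl]), 0)
  ne <- max(1L, as.integer(round(ne_fraction * mean(c(census_t, census_t1)))))
  ll <- ll_compound(y_t1, census_t1, p, ne, method = method)
  out <- structure(ll, expected = stats::setNames(p, PHENO_CLASSES),
                   method = method, next_latent = res$freq)
  if (!is.finite(ll))
    attr(out, "diagnostic") <-
      "observed phenotype class has zero model probability"
  out
}

as_class_counts <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, intersect(PHENO_CLASSES, names(x))])
  if (!is.null(names(x))) {
    out <- stats::setNames(numeric(4), PHENO_CLASSES)
    out[intersect(names(x), PHENO_CLASSES)] <-
      x[intersect(names(x), PHENO_CLASSES)]
    return(out)
  }
  if (length(x) == 4) return(stats::setNames(as.numeric(x), PHENO_CLASSES))
  stop("phenotype counts must be named by class or length 4", call. = FALSE)
}

# --- joint likelihood over cages ------------------------------------------

# Precompute per-cage observation tables once.
cage_obs_tables <- function(trajectories) {
  lapply(trajectories, function(tr) {
    y <- t(apply(tr[, PHENO_CLASSES], 1, as.numeric))
    colnames(y) <- PHENO_CLASSES
    list(y = y, census = tr$census, n_trans = nrow(tr) - 1)
  })
}

# For a fitness value, run the latent recursion through every cage and
# return per-transition expected class probabilities (independent of
# ne_fraction, so they are cached across the ne profile).
cage_expected_probs <- function(eng, obs, fitness, release_index) {
  class_of <- engine_class_of(eng)
  lapply(obs, function(ob) {
    nt <- ob$n_trans
    P <- matrix(NA_real_, nt, 4)
    ok <- rep(TRUE, nt)
    cf0 <- (ob$y[1, 1] + ob$y[1, 3]) / ob$census[1]
    latent <- init_latent(eng, cf0, release_index)
    for (t in seq_len(nt)) {
      q <- recalibrate_latent(eng, latent, ob$y[t, ] / ob$census[t], class_of)
      if (is.null(q)) { ok[t:nt] <- FALSE; break }
      res <- engine_next_gen(eng, q, q, fitness)
      if (res$extinct) { ok[t:nt] <- FALSE; break }
      P[t, ] <- vapply(1:4, function(cl) sum(res$freq[class_of == cl]), 0)
      latent <- res$freq
    }
    list(P = P, ok = ok)
  })
}

cage_loglik_given_probs <- function(obs, probs, ne_fraction, discard_first) {
  total <- 0
  for (i in seq_along(obs)) {
    ob <- obs[[i]]; pr <- probs[[i]]
    for (t in seq_len(ob$n_trans)) {
      if (t <= discard_first) next
      if (!pr$ok[t]) return(-Inf)
      ne <- max(1L, as.integer(round(ne_fraction *
                                       mean(ob$census[t:(t + 1)]))))
      ll <- ll_compound(ob$y[t + 1, ], ob$census[t + 1], pr$P[t, ], ne)
      if (!is.finite(ll)) return(-Inf)
      total <- total + ll
    }
  }
  total
}

#' Maximum-likelihood drive fitness and effective population size
#'
#' Jointly estimates the drive homozygote fitness and the effective
#' population size (as a fraction of census) from one or more cage
#' phenotype trajectories, by maximising the transition likelihood across
#' all cages combined (a single estimate per parameter for all cages). The
#' genotype composition within each phenotype class is tracked by the
#' model's own running prediction, initialised from the release genotype;
#' the first `discard_first` transitions of each cage are discounted
#' (released cohorts show transient parental effects). Profile-likelihood
#' 95% confidence intervals use the chi-squared cutoff of 1.92 log-units.
#'
#' @param trajectories a `"cage_trajectory"` or list of them (data frames
#'   with the cage CSV columns).
#' @param params a [drive_params()] object (cleavage rates held fixed at
#'   their experimental estimates).
#' @param component fitness component to estimate (see [fitness_model()]).
#' @param discard_first transitions discounted per cage (default 2).
#' @param f_bounds,ne_bounds search bounds for fitness and ne fraction.
#' @param profile which parameters get profile CIs (default both).
#' @return A list with class `"likelihood_fit"`: `f_hom`, `ne_fraction`,
#'   `component`, `logLik`, `ci_f`, `ci_ne`, `n_transitions`,
#'   `transitions_discarded`, `per_transition` (log-likelihood table at the
#'   optimum) and `flags`.
#' @export
fit_fitness <- function(trajectories, params,
                        component = c("both_sexes", "female_fecundity",
                                      "male_mating", "offspring_viability"),
                        discard_first = 2L,
                        f_bounds = c(0.2, 1.5),
                        ne_bounds = c(5e-4, 1),
                        profile = c("f", "ne")) {
  component <- match.arg(component)
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  obs <- cage_obs_tables(trajectories)
  n_trans <- sum(vapply(obs, function(o) max(o$n_trans - discard_first, 0L),
                        0))
  if (n_trans < 1)
    stop("no transitions left after discounting the first ", discard_first,
         " per cage", call. = FALSE)
  eng <- build_engine(params)
  rel <- release_index_tare_homozygote(eng)

  prob_cache <- new.env(parent = emptyenv())
  probs_for <- function(f) {
    key <- sprintf("%.12g", f)
    if (!is.null(prob_cache[[key]])) return(prob_cache[[key]])
    pr <- cage_expected_probs(eng, obs,
                              fitness_model(f, component), rel)
    prob_cache[[key]] <- pr
    pr
  }
  ll_f_ne <- function(f, ne) cage_loglik_given_probs(obs, probs_for(f), ne,
                                                     discard_first)
  profile_ne <- function(f) {
    opt <- stats::optimize(function(ln) ll_f_ne(f, exp(ln)),
                           log(ne_bounds), maximum = TRUE, tol = 1e-4)
    list(value = opt$objective, ne = exp(opt$maximum))
  }
  # coarse multi-start grid, then local refinement of the best bracket
  grid <- seq(f_bounds[1], f_bounds[2], length.out = 13)
  gval <- vapply(grid, function(f) profile_ne(f)$value, 0)
  if (all(!is.finite(gval)))
    stop("likelihood is -Inf everywhere on the fitness grid; check inputs",
         call. = FALSE)
  i0 <- which.max(gval)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(function(f) profile_ne(f)$value, c(lo, hi),
                         maximum = TRUE, tol = 1e-5)
  f_hat <- opt$maximum
  pr_hat <- profile_ne(f_hat)
  ne_hat <- pr_hat$ne
  logL <- pr_hat$value
  flags <- character(0)

  cutoff <- logL - stats::qchisq(0.95, 1) / 2
  ci_f <- c(NA_real_, NA_real_)
  if ("f" %in% profile) {
    prof_f <- function(f) profile_ne(f)$value - cutoff
    ci_f <- profile_roots(prof_f, f_hat, f_bounds)
    if (any(attr(ci_f, "at_bound"))) flags <- c(flags, "f_ci_at_bound")
  }
  ci_ne <- c(NA_real_, NA_real_)
  if ("ne" %in% profile) {
    prof_ne_fun <- function(ne) {
      o <- stats::optimize(function(f) ll_f_ne(f, ne),
                           c(max(f_bounds[1], f_hat - 0.3),
                             min(f_bounds[2], f_hat + 0.3)),
                           maximum = TRUE, tol = 1e-4)
      o$objective - cutoff
    }
    ci_ne <- profile_roots(prof_ne_fun, ne_hat, ne_bounds, log_scale = TRUE)
    if (any(attr(ci_ne, "at_bound"))) flags <- c(flags, "ne_ci_at_bound")
  }

  # per-transition table at the optimum
  pr <- probs_for(f_hat)
  rows <- list()
  for (i in seq_along(obs)) {
    ob <- obs[[i]]
    for (t in seq_len(ob$n_trans)) {
      ne <- max(1L, as.integer(round(ne_hat * mean(ob$census[t:(t + 1)]))))
      ll <- if (pr[[i]]$ok[t])
        ll_compound(ob$y[t + 1, ], ob$census[t + 1], pr[[i]]$P[t, ], ne)
      else -Inf
      rows[[length(rows) + 1]] <-
        data.frame(cage = i, transition = t, discarded = t <= discard_first,
                   logLik = ll)
    }
  }
  structure(list(f_hom = f_hat, ne_fraction = ne_hat, component = component,
                 logLik = logL, ci_f = as.numeric(ci_f),
                 ci_ne = as.numeric(ci_ne),
                 n_transitions = n_trans,
                 transitions_discarded =
                   sum(vapply(obs, function(o)
                     as.integer(min(discard_first, o$n_trans)), 0L)),
                 per_transition = do.call(rbind, rows),
                 flags = flags),
            class = "likelihood_fit")
}

# find the two roots of a profile-likelihood function around the estimate
profile_roots <- function(fn, est, bounds, log_scale = FALSE, n_scan = 12) {
  tf <- if (log_scale) log else identity
  itf <- if (log_scale) exp else identity
  root_side <- function(side) {
    ends <- if (side < 0) c(tf(bounds[1]), tf(est)) else c(tf(est), tf(bounds[2]))
    xs <- seq(ends[1], ends[2], length.out = n_scan)
    if (side > 0) xs <- xs else xs <- rev(xs)  # scan outward from estimate
    prev_x <- tf(est); prev_v <- fn(est)
    for (x in xs[-1]) {
      v <- fn(itf(x))
      if (is.finite(v) && v < 0) {
        r <- stats::uniroot(function(z) fn(itf(z)), sort(c(prev_x, x)),
                            tol = 1e-6)
        return(list(x = itf(r$root), at_bound = FALSE))
      }
      prev_x <- x; prev_v <- v
    }
    list(x = bounds[if (side < 0) 1 else 2], at_bound = TRUE)
  }
  lo <- root_side(-1); hi <- root_side(1)
  structure(c(lo$x, hi$x), at_bound = c(lo$at_bound, hi$at_bound))
}

#' @export
print.likelihood_fit <- function(x, ...) {
  cat("<likelihood fit>\n")
  cat(sprintf("  fitness (homozygote, %s): %.4f  [%.4f, %.4f]\n",
              x$component, x$f_hom, x$ci_f[1], x$ci_f[2]))
  cat(sprintf("  ne fraction of census:    %.4f  [%.4f, %.4f]\n",
              x$ne_fraction, x$ci_ne[1], x$ci_ne[2]))
  cat(sprintf("  log-likelihood %.3f over %d transitions (%d discarded)\n",
              x$logLik, x$n_transitions, x$transitions_discarded))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Compare fitness components
#'
#' Fits each fitness component to the same trajectories and tabulates the
#' estimates with the log-likelihood difference to the best component.
#'
#' @inheritParams fit_fitness
#' @param components components to fit.
#' @return A data frame (one row per component: `component`, `f_hom`,
#'   `ne_fraction`, `logLik`, `delta_logLik`, `ci_f_lo`, `ci_f_hi`) with the
#'   full fits attached as attribute `"fits"`.
#' @export
compare_components <- function(trajectories, params, discard_first = 2L,
                               components = c("both_sexes",
                                              "female_fecundity",
                                              "male_mating",
                                              "offspring_viability"),
                               ...) {
  fits <- lapply(components, function(cmp)
    fit_fitness(trajectories, params, component = cmp,
                discard_first = discard_first, ...))
  ll <- vapply(fits, `[[`, 0, "logLik")
  out <- data.frame(component = components,
                    f_hom = vapply(fits, `[[`, 0, "f_hom"),
                    ne_fraction = vapply(fits, `[[`, 0, "ne_fraction"),
                    logLik = ll,
                    delta_logLik = max(ll) - ll,
                    ci_f_lo = vapply(fits, function(f) f$ci_f[1], 0),
                    ci_f_hi = vapply(fits, function(f) f$ci_f[2], 0))
  attr(out, "fits") <- fits
  out
}

#' Introduction-threshold confidence interval from a fitness fit
#'
#' Maps the fitness point estimate and profile CI through
#' [find_introduction_threshold()]. The map is monotone decreasing (a
#' costlier drive needs a larger release), so the lower fitness bound gives
#' the upper threshold bound and vice versa.
#'
#' @param fit a `"likelihood_fit"`.
#' @param params a [drive_params()] object.
#' @param ... passed to [find_introduction_threshold()].
#' @return Named numeric vector `lower`, `point`, `upper` (thresholds).
#' @export
threshold_ci <- function(fit, params, ...) {
  stopifnot(inherits(fit, "likelihood_fit"))
  thr <- function(f) as.numeric(find_introduction_threshold(
    params, fitness_model(f, fit$component), ...))
  c(lower = thr(fit$ci_f[2]), point = thr(fit$f_hom),
    upper = thr(fit$ci_f[1]))
}
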