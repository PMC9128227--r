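#' Predict phenotype proportions for a cross
#'
#' Computes the exact phenotype-class probabilities among viable adult
#' offspring of a single cross, and the relative egg-to-adult survival
#' (total viable-offspring weight, 1 for a cross without drive-induced
#' lethality). Phenotypes follow the fluorescent markers: EGFP marks TARE
#' drive carriers, DsRed marks homing drive carriers.
#'
#' @param mother,father parental genotypes (objects or strings).
#' @param params a [drive_params()] object.
#' @return A list with class `"cross_prediction"`: `phenotype` (named
#'   probabilities `egfp_only`, `dsred_only`, `both`, `neither` among viable
#'   offspring), `carrier_tare` and `carrier_homing` (marginal carrier
#'   fractions), `survival` (relative egg-to-adult survival) and
#'   `offspring` (the full [offspring_distribution()]).
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' # TARE/+ female x wild male: 71.7% carriers, survival 0.697
#' predict_cross("h:D/W;sex:F", "h:W/W;sex:M", tare)
#' @export
predict_cross <- function(mother, father, params) {
  if (is.character(mother)) mother <- parse_genotype(mother)
  if (is.character(father)) father <- parse_genotype(father)
  off <- offspring_distribution(mother, father, params)
  eng <- build_engine(params, two_locus = mother$haps[1, "homing"] != "A")
  pheno <- c(egfp_only = 0, dsred_only = 0, both = 0, neither = 0)
  if (nrow(off$dist)) {
    idx <- vapply(off$dist$genotype, function(l) match_genotype_label(eng, l),
                  integer(1))
    tare <- eng$carrier_tare[idx]
    homing <- eng$carrier_homing[idx]
    cls <- ifelse(tare & homing, "both",
                  ifelse(tare, "egfp_only",
                         ifelse(homing, "dsred_only", "neither")))
    for (cl in names(pheno)) pheno[cl] <- sum(off$dist$prob[cls == cl])
  }
  structure(list(phenotype = pheno,
                 carrier_tare = pheno[["egfp_only"]] + pheno[["both"]],
                 carrier_homing = pheno[["dsred_only"]] + pheno[["both"]],
                 survival = off$weight,
                 offspring = off),
            class = "cross_prediction")
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat("<cross prediction>\n")
  cat(sprintf("  TARE (EGFP) carriers:  %.4f\n", x$carrier_tare))
  if (x$carrier_homing > 0)
    cat(sprintf("  homing (DsRed) carriers: %.4f\n", x$carrier_homing))
  cat(sprintf("  relative survival:     %.4f\n", x$survival))
  invisible(x)
}

# closed-form carrier fractions among viable offspring used for inversion.
# Drive female x wild male: gametes D 1/2, W (1-g)/2, R g/2; embryo cutting
# acts on every remaining wild-type allele (maternal and paternal copies).
carrier_frac_female_cross <- function(g, e) {
  0.5 / (1 - 0.5 * g * e - 0.5 * (1 - g) * e^2)
}

# Drive het x drive het (mother and father both TARE/+), equal germline
# rates in the sexes, embryo cutting only through the mother.
carrier_frac_hethet_cross <- function(g, e) {
  viable <- 0.75 +
    0.25 * (1 - g)^2 * (1 - e^2) +
    0.5 * g * (1 - g) * (1 - e)
  0.75 / viable
}

#' Estimate cleavage rates from inheritance rates
#'
#' Inverts the observed drive-inheritance rates of the two diagnostic
#' crosses into germline and embryo cleavage-rate estimates. The
#' drive-female x wild-type cross responds to both rates (embryo cutting
#' removes non-carrier offspring); the heterozygote x heterozygote cross
#' adds an independent constraint because drive fathers contribute
#' germline-disrupted alleles that meet maternally cut alleles. Model
#' assumptions, surfaced as flags on the result: equal germline cut rates
#' in the two sexes, and embryo cutting only in the progeny of females.
#'
#' @param inh_f drive-carrier fraction among viable adult offspring of
#'   drive-heterozygous females crossed to wild-type males.
#' @param inh_hh drive-carrier fraction among viable adult offspring of the
#'   drive-heterozygote x drive-heterozygote cross.
#' @return A list with class `"cleavage_estimate"`: `c_germ`, `c_embryo`,
#'   `residual` (root-finding residual), `identifiable`, `flags`, and the
#'   fitted inheritance rates. When `inh_f` is Mendelian (0.5) the embryo
#'   rate is 0 and the germline rate is unidentifiable (`NA`, flagged).
#' @examples
#' p <- predict_cross("h:D/W;sex:F", "h:W/W;sex:M",
#'                    drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632))
#' hh <- predict_cross("h:D/W;sex:F", "h:D/W;sex:M",
#'                    drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632))
#' estimate_cleavage_rates(p$carrier_tare, hh$carrier_tare)
#' @export
estimate_cleavage_rates <- function(inh_f, inh_hh) {
  stopifnot(is.numeric(inh_f), is.numeric(inh_hh),
            inh_f > 0, inh_f < 1, inh_hh > 0, inh_hh < 1)
  flags <- c(equal_sex_germline = TRUE, maternal_embryo_only = TRUE)
  mk <- function(c_germ, c_embryo, residual, identifiable, note = NULL) {
    structure(list(c_germ = c_germ, c_embryo = c_embryo,
                   residual = residual, identifiable = identifiable,
                   flags = flags, note = note,
                   fitted_inh_f = if (identifiable)
                     carrier_frac_female_cross(c_germ, c_embryo) else NA_real_,
                   fitted_inh_hh = if (identifiable)
                     carrier_frac_hethet_cross(c_germ, c_embryo) else NA_real_),
              class = "cleavage_estimate")
  }
  # inh_f = 0.5/(1 - (g e + (1-g) e^2)/2)  =>  g e + (1-g) e^2 = 2 - 1/inh_f
  A <- 2 - 1 / inh_f
  if (abs(A) < 1e-12)
    return(mk(NA_real_, 0, 0, FALSE,
              "Mendelian female-cross inheritance: embryo cutting 0, germline rate unidentifiable"))
  if (A < 0 || inh_hh < 0.75)
    return(mk(NA_real_, NA_real_, NA_real_, FALSE,
              "inheritance rates below the Mendelian floor: no solution in [0,1]^2"))
  g_of_e <- function(e) (A - e^2) / (e * (1 - e))
  resid <- function(e) {
    g <- g_of_e(e)
    carrier_frac_hethet_cross(g, e) - inh_hh
  }
  # admissible e: g(e) in [0, 1] and e in (0, 1)
  lo <- A + 1e-12            # g <= 1 requires e >= A (since A = g e + (1-g) e^2 <= e)
  hi <- sqrt(A) - 1e-12      # g >= 0 requires e^2 <= A
  if (hi <= lo)
    return(mk(1, A, 0, TRUE, "degenerate: single admissible point"))
  flo <- resid(lo); fhi <- resid(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    # no sign change: report the closer endpoint as a flagged failure
    e <- if (abs(flo) < abs(fhi)) lo else hi
    return(mk(g_of_e(e), e, resid(e), FALSE,
              "no root in the admissible region; residual reported"))
  }
  sol <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)
  e <- sol$root
  mk(min(max(g_of_e(e), 0), 1), e, sol$f.root, TRUE)
}

#' @export
print.cleavage_estimate <- function(x, ...) {
  cat("<cleavage estimate>\n")
  if (x$identifiable) {
    cat(sprintf("  germline cleavage: %.4f\n  embryo cleavage:   %.4f\n",
                x$c_germ, x$c_embryo))
  } else {
    cat("  not identifiable:", x$note, "\n")
  }
  invisible(x)
}

#' Pooled rate and between-vial standard error
#'
#' Pools phenotype counts across vials into a single rate (total class
#' count over total offspring, the convention used for the reported
#' inheritance rates) and attaches a standard error of the mean computed
#' from the scatter of vial-level rates, weighting vials by size:
#' with vial weights \eqn{w_i = n_i / \sum n_i}, the weighted between-vial
#' variance is \eqn{s^2 = \sum w_i (r_i - \bar r)^2 / (1 - \sum w_i^2)} and
#' the SEM is \eqn{\sqrt{s^2 \sum w_i^2}}. This collapses to the usual
#' \eqn{sd/\sqrt{k}} for equal vials and captures between-vial (batch)
#' overdispersion that a single binomial would miss.
#'
#' @param counts integer vector of per-vial counts in the class of interest
#'   (e.g. drive carriers).
#' @param totals integer vector of per-vial total offspring.
#' @return A list: `rate`, `sem` (`NA` with `flag = "single_batch"` for one
#'   vial), `n_vials`, `n_total`, `flag`.
#' @examples
#' rate_with_sem(c(30, 41, 28), c(42, 55, 40))
#' @export
rate_with_sem <- function(counts, totals) {
  stopifnot(length(counts) == length(totals), all(counts >= 0),
            all(totals >= counts))
  if (sum(totals) == 0)
    return(list(rate = NA_real_, sem = NA_real_, n_vials = length(totals),
                n_total = 0L, flag = "no_offspring"))
  keep <- totals > 0
  counts <- counts[keep]; totals <- totals[keep]
  rate <- sum(counts) / sum(totals)
  if (length(totals) < 2)
    return(list(rate = rate, sem = NA_real_, n_vials = length(totals),
                n_total = sum(totals), flag = "single_batch"))
  w <- totals / sum(totals)
  r <- counts / totals
  s2 <- sum(w * (r - rate)^2) / (1 - sum(w^2))
  list(rate = rate, sem = sqrt(s2 * sum(w^2)), n_vials = length(totals),
       n_total = sum(totals), flag = "ok")
}
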