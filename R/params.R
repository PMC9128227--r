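#' Drive mechanism parameters
#'
#' Collects the per-allele cleavage, conversion and linkage probabilities
#' that define a TARE drive and (optionally) a tethered split homing drive.
#' All rates are probabilities per wild-type allele per event.
#'
#' Germline Cas9 activity occurs in drive carriers of both sexes and turns
#' wild-type TARE-locus alleles into disrupted alleles at rate
#' `c_germ_tare`. After fertilisation, Cas9/gRNA deposited by a
#' drive-carrying mother disrupts each remaining wild-type TARE-locus allele
#' in the zygote at rate `c_embryo_tare`, whether that allele came from the
#' mother or the father. The split homing drive has no Cas9 of its own:
#' cutting at the homing locus requires a TARE drive allele (Cas9) and a
#' homing drive allele (gRNAs) in the same individual. A germline cut there
#' is resolved by homology-directed repair into a drive copy with
#' probability `homing_conversion_frac`, otherwise it leaves a nonfunctional
#' resistance allele; embryo cuts at the homing locus always leave
#' resistance alleles.
#'
#' @param c_germ_tare germline disruption probability per wild-type
#'   TARE-locus allele in a drive-carrying parent.
#' @param c_embryo_tare embryo disruption probability per wild-type
#'   TARE-locus allele given a drive-carrying mother.
#' @param homing_germ_cut total germline cut probability per wild-type
#'   homing-locus allele (active only with TARE drive + homing drive).
#' @param homing_conversion_frac fraction of germline cuts at the homing
#'   locus resolved as drive copies.
#' @param c_embryo_homing embryo cut probability per wild-type homing-locus
#'   allele given the mother carries both drives.
#' @param recomb_female,recomb_male recombination probability between the two
#'   loci per meiosis. Drosophila males lack meiotic crossing over, so
#'   `recomb_male` defaults to 0.
#' @param homing_locus_rule `"none"` (single-locus TARE model),
#'   `"haplolethal_rescue"` (modification drive in a haplolethal gene:
#'   any nonfunctional resistance allele kills its carrier) or
#'   `"female_fertility"` (suppression drive in a haplosufficient female
#'   fertility gene: females with no functional copy are sterile).
#' @return A list with class `"drive_params"`.
#' @examples
#' # rates measured for the TARE drive from the heterozygote crosses
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' @export
drive_params <- function(c_germ_tare = 0,
                         c_embryo_tare = 0,
                         homing_germ_cut = 0,
                         homing_conversion_frac = 0,
                         c_embryo_homing = 0,
                         recomb_female = 0.5,
                         recomb_male = 0,
                         homing_locus_rule = c("none", "haplolethal_rescue",
                                               "female_fertility")) {
  homing_locus_rule <- match.arg(homing_locus_rule)
  p <- list(c_germ_tare = c_germ_tare,
            c_embryo_tare = c_embryo_tare,
            homing_germ_cut = homing_germ_cut,
            homing_conversion_frac = homing_conversion_frac,
            c_embryo_homing = c_embryo_homing,
            recomb_female = recomb_female,
            recomb_male = recomb_male,
            homing_locus_rule = homing_locus_rule)
  validate_drive_params(p)
  structure(p, class = "drive_params")
}

validate_drive_params <- function(p) {
  probs <- c("c_germ_tare", "c_embryo_tare", "homing_germ_cut",
             "homing_conversion_frac", "c_embryo_homing",
             "recomb_female", "recomb_male")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("drive_params: '", nm, "' must be a probability in [0, 1], got ",
           deparse(v), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params>\n")
  cat(sprintf("  TARE:   germline cleavage %.3f, embryo cleavage %.3f\n",
              x$c_germ_tare, x$c_embryo_tare))
  if (x$homing_locus_rule == "none") {
    cat("  homing locus: none (single-locus TARE model)\n")
  } else {
    cat(sprintf("  homing: rule %s, germline cut %.3f (conversion %.3f), embryo cut %.3f\n",
                x$homing_locus_rule, x$homing_germ_cut,
                x$homing_conversion_frac, x$c_embryo_homing))
    cat(sprintf("  recombination: female %.3f, male %.3f\n",
                x$recomb_female, x$recomb_male))
  }
  invisible(x)
}

#' Fitness model for drive alleles
#'
#' Relative fitness of drive-allele carriers under the codominant
#' multiplicative model: a drive homozygote has fitness `f_hom` relative to
#' wild type, and a heterozygote has fitness `sqrt(f_hom)`. The TARE
#' insertion site is haplosufficient, so genotypes carrying one wild-type
#' and one disrupted copy (but no drive allele) keep fitness 1. An optional
#' second coefficient applies the same scheme to homing-drive alleles.
#'
#' The `component` names the life-history stage that bears the cost:
#' `"female_fecundity"` scales mothers' offspring production,
#' `"male_mating"` scales fathers' mating success,
#' `"offspring_viability"` scales each offspring's survival,
#' `"both_sexes"` scales each parent's contribution by its own fitness.
#'
#' @param f_hom homozygote fitness of the TARE drive allele (> 0; wild type
#'   is 1).
#' @param component which fitness component carries the cost.
#' @param f_homing homozygote fitness of the homing drive allele (default 1).
#' @return A list with class `"fitness_model"`.
#' @examples
#' fitness_model(0.867)                        # cage-estimate scale cost
#' fitness_model(0.75, "female_fecundity")     # one-sex equivalent
#' @export
fitness_model <- function(f_hom = 1,
                          component = c("both_sexes", "female_fecundity",
                                        "male_mating", "offspring_viability"),
                          f_homing = 1) {
  component <- match.arg(component)
  if (!is.numeric(f_hom) || length(f_hom) != 1 || is.na(f_hom) || f_hom <= 0)
    stop("fitness_model: 'f_hom' must be a positive number", call. = FALSE)
  if (!is.numeric(f_homing) || length(f_homing) != 1 || is.na(f_homing) ||
      f_homing <= 0)
    stop("fitness_model: 'f_homing' must be a positive number", call. = FALSE)
  structure(list(f_hom = f_hom, component = component, f_homing = f_homing),
            class = "fitness_model")
}

#' @export
print.fitness_model <- function(x, ...) {
  cat(sprintf("<fitness_model> TARE homozygote %.4f (het %.4f), component %s",
              x$f_hom, sqrt(x$f_hom), x$component))
  if (x$f_homing != 1)
    cat(sprintf(", homing homozygote %.4f", x$f_homing))
  cat("\n")
  invisible(x)
}

#' Release event
#'
#' A release mixes individuals of a single genotype into the population so
#' that they make up `proportion` of the post-release population in the
#' stated generation (sexes released 1:1).
#'
#' @param generation integer generation index (0 = founding generation).
#' @param genotype a `"drive_genotype"` or genotype string.
#' @param proportion fraction of the post-release population, in (0, 1).
#' @return A list with class `"release_event"`.
#' @export
release_event <- function(generation, genotype, proportion) {
  if (is.character(genotype)) genotype <- parse_genotype(genotype)
  stopifnot(inherits(genotype, "drive_genotype"))
  if (!is.numeric(proportion) || proportion <= 0 || proportion >= 1)
    stop("release proportion must be in (0, 1)", call. = FALSE)
  if (generation < 0 || generation != round(generation))
    stop("release generation must be a non-negative integer", call. = FALSE)
  structure(list(generation = as.integer(generation), genotype = genotype,
                 proportion = proportion),
            class = "release_event")
}
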