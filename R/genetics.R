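# a genotype without a homing locus cannot be used with params that
# configure one (and vice versa the engine index lookup catches it)
check_locus_match <- function(g, params) {
  if (params$homing_locus_rule != "none" && g$haps[1, "homing"] == "A")
    stop("genotype has no homing locus but params configure one (rule '",
         params$homing_locus_rule, "')", call. = FALSE)
  invisible(g)
}

#' Gamete distribution of a parent
#'
#' Exact distribution of transmitted haplotypes for one parent, by
#' enumeration. In order: the two haplotypes recombine with the sex-specific
#' probability; if the parent carries a TARE drive allele, each wild-type
#' TARE-locus allele is independently disrupted in the germline; if the
#' parent carries both a TARE drive (Cas9) and a homing drive (gRNAs), each
#' wild-type homing-locus allele is independently cut, resolving to a drive
#' copy with the conversion fraction and to a resistance allele otherwise;
#' one haplotype is then drawn uniformly.
#'
#' @param parent a `"drive_genotype"` (or genotype string).
#' @param params a [drive_params()] object.
#' @return A named numeric vector of haplotype probabilities (summing to 1).
#'   Names use the `"<tare>:<homing>"` haplotype syntax, or the bare TARE
#'   allele for single-locus configurations.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' gamete_distribution(genotype("D", "W", sex = "F"), tare)
#' @export
gamete_distribution <- function(parent, params) {
  if (is.character(parent)) parent <- parse_genotype(parent)
  stopifnot(inherits(parent, "drive_genotype"),
            inherits(params, "drive_params"))
  check_locus_match(parent, params)
  eng <- build_engine(params, two_locus = parent$haps[1, "homing"] != "A")
  k <- engine_genotype_index(eng, parent)
  if (!eng$viable[k])
    stop("parent genotype is not viable: ", format(parent), call. = FALSE)
  G <- if (parent$sex == "F") eng$GF else eng$GM
  out <- G[k, ]
  names(out) <- ifelse(eng$haps$homing == "A", eng$haps$tare,
                       paste0(eng$haps$tare, ":", eng$haps$homing))
  out
}

#' Maternal-deposition (embryo) cleavage of a zygote
#'
#' Cas9 and gRNAs deposited in the egg by a drive-carrying mother act on the
#' zygote regardless of which alleles it inherited: every wild-type
#' TARE-locus allele (maternal or paternal copy) is independently disrupted
#' with the embryo cleavage rate; if the mother carries both drives, every
#' wild-type homing-locus allele is independently cut to a resistance
#' allele. Mothers without a TARE drive deposit nothing and the zygote is
#' returned unchanged.
#'
#' @param zygote,mother `"drive_genotype"` objects (or genotype strings);
#'   `mother` is the maternal parent of `zygote`.
#' @param params a [drive_params()] object.
#' @return A named numeric vector over genotype labels (probabilities
#'   summing to 1). Nonviable outcomes are retained here; viability is a
#'   separate rule ([is_viable()]).
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' apply_embryo_cleavage(genotype("R", "W", sex = "F"),
#'                       genotype("D", "W", sex = "F"), tare)
#' @export
apply_embryo_cleavage <- function(zygote, mother, params) {
  if (is.character(zygote)) zygote <- parse_genotype(zygote)
  if (is.character(mother)) mother <- parse_genotype(mother)
  stopifnot(inherits(zygote, "drive_genotype"),
            inherits(mother, "drive_genotype"),
            inherits(params, "drive_params"))
  check_locus_match(zygote, params)
  eng <- build_engine(params, two_locus = zygote$haps[1, "homing"] != "A")
  kz <- engine_genotype_index(eng, zygote)
  km <- engine_genotype_index(eng, mother)
  cl <- eng$mclass[km]
  out <- eng$E[[cl + 1]][kz, ]
  names(out) <- eng$labels
  out[out > 0]
}

#' Viability rule
#'
#' An individual is nonviable if it carries two disrupted TARE-locus alleles
#' (the target is essential; the drive's recoded copy rescues, a disrupted
#' copy does not), or, under the haplolethal homing rule, if it carries any
#' nonfunctional resistance allele at the homing locus (losing one copy of a
#' haplolethal gene is lethal and only the drive's recoded copy rescues).
#'
#' @param g a `"drive_genotype"` (or genotype string).
#' @param params a [drive_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_viable <- function(g, params) {
  if (is.character(g)) g <- parse_genotype(g)
  stopifnot(inherits(g, "drive_genotype"), inherits(params, "drive_params"))
  if (sum(g$haps[, "tare"] == "R") == 2) return(FALSE)
  if (params$homing_locus_rule == "haplolethal_rescue" &&
      any(g$haps[, "homing"] == "R")) return(FALSE)
  TRUE
}

#' Female fertility rule for the suppression drive
#'
#' The homing suppression drive disrupts a haplosufficient but essential
#' female fertility gene and carries no rescue, so a female is sterile
#' unless at least one homing-locus allele is wild type: both the drive
#' allele and resistance alleles disrupt the gene. Males are always fertile.
#'
#' @param g a `"drive_genotype"` (or genotype string).
#' @param params a [drive_params()] object with
#'   `homing_locus_rule = "female_fertility"`.
#' @return `TRUE` or `FALSE`.
#' @export
is_fertile_female <- function(g, params) {
  if (is.character(g)) g <- parse_genotype(g)
  stopifnot(inherits(g, "drive_genotype"), inherits(params, "drive_params"))
  if (params$homing_locus_rule != "female_fertility")
    stop("is_fertile_female applies only with homing_locus_rule = ",
         "'female_fertility'", call. = FALSE)
  if (g$sex == "M") return(TRUE)
  any(g$haps[, "homing"] == "W")
}

#' Offspring distribution of a cross
#'
#' Convolves the mother's and father's gamete distributions, applies
#' maternal-deposition cleavage, removes nonviable genotypes and
#' renormalises. Offspring sexes are assigned 1:1 independently of genotype,
#' so the genotype distribution is reported once and applies to both sexes.
#'
#' @param mother,father `"drive_genotype"` objects (or genotype strings);
#'   `mother$sex` must be `"F"` and `father$sex` `"M"`, both viable.
#' @param params a [drive_params()] object.
#' @return A list of class `"offspring_distribution"` with elements
#'   `dist` (data frame: `genotype`, `prob` over viable offspring, summing
#'   to 1) and `weight` (total survival weight: the fraction of conceived
#'   zygotes that are viable). A sterile mother under the suppression rule
#'   yields an empty distribution with weight 0.
#' @examples
#' tare <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
#' offspring_distribution(genotype("D", "W", sex = "F"),
#'                        genotype("W", "W", sex = "M"), tare)
#' @export
offspring_distribution <- function(mother, father, params) {
  if (is.character(mother)) mother <- parse_genotype(mother)
  if (is.character(father)) father <- parse_genotype(father)
  stopifnot(inherits(mother, "drive_genotype"),
            inherits(father, "drive_genotype"),
            inherits(params, "drive_params"))
  if (mother$sex != "F" || father$sex != "M")
    stop("mother must be female and father male", call. = FALSE)
  check_locus_match(mother, params)
  eng <- build_engine(params, two_locus = mother$haps[1, "homing"] != "A")
  km <- engine_genotype_index(eng, mother)
  kf <- engine_genotype_index(eng, father)
  if (!eng$viable[km] || !eng$viable[kf])
    stop("both parents must be viable", call. = FALSE)
  if (!eng$fertile_f[km]) {
    out <- list(dist = data.frame(genotype = character(0), prob = numeric(0)),
                weight = 0)
    class(out) <- "offspring_distribution"
    return(out)
  }
  z <- rowsum_by(as.vector(outer(eng$GF[km, ], eng$GM[kf, ])),
                 eng$fold, eng$nG)
  post <- as.vector(z %*% eng$E[[eng$mclass[km] + 1]])
  weight <- sum(post * eng$viable)
  dist <- post * eng$viable
  keep <- dist > 0
  out <- list(dist = data.frame(genotype = eng$labels[keep],
                                prob = dist[keep] / weight),
              weight = weight)
  class(out) <- "offspring_distribution"
  out
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat(sprintf("<offspring distribution> survival weight %.4f\n", x$weight))
  if (nrow(x$dist)) {
    d <- x$dist[order(-x$dist$prob), ]
    rownames(d) <- NULL
    print(d, ...)
  } else cat("  (sterile mother: no offspring)\n")
  invisible(x)
}
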