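#' Allele codes
#'
#' Alleles are single-character codes. At the TARE locus (the essential but
#' haplosufficient gene into which the drive is inserted, e.g. *hairy*):
#' `"W"` wild type, `"D"` the TARE drive allele (Cas9 + gRNAs + recoded
#' rescue), `"R"` a disrupted, nonfunctional copy. At the homing locus
#' (*RpL35A* for the haplolethal modification drive, *yellow-g* for the
#' suppression drive): `"W"` wild type, `"D"` the split homing drive (gRNAs
#' and rescue/cargo, no Cas9), `"R"` a nonfunctional resistance allele, and
#' `"A"` when no homing locus is configured. Functional resistance alleles
#' are not representable: multiplexed gRNAs make their formation rare enough
#' to neglect.
#'
#' @name allele-codes
#' @keywords internal
NULL

TARE_ALLELES <- c("W", "D", "R")
HOMING_ALLELES <- c("W", "D", "R", "A")

#' Construct a phased haplotype
#'
#' A haplotype is the pair of alleles carried on one chromosome copy: the
#' allele at the TARE locus and the allele at the homing locus. The two drive
#' elements of a tethered system sit on the same chromosome (e.g. *hairy* on
#' 3L and *RpL35A* on 3R), so phase matters: recombination between the loci
#' is sex-specific and absent in Drosophila males.
#'
#' @param tare one of `"W"`, `"D"`, `"R"`.
#' @param homing one of `"W"`, `"D"`, `"R"`, `"A"`; `"A"` (absent) marks a
#'   single-locus (TARE-only) configuration.
#' @return A character vector of length 2 with class `"drive_haplotype"`.
#' @examples
#' haplotype("D")            # TARE drive on a single-locus background
#' haplotype("W", "D")       # wild-type h, homing drive
#' @export
haplotype <- function(tare, homing = "A") {
  if (!tare %in% TARE_ALLELES)
    stop("invalid TARE-locus allele: ", tare, call. = FALSE)
  if (!homing %in% HOMING_ALLELES)
    stop("invalid homing-locus allele: ", homing, call. = FALSE)
  structure(c(tare = tare, homing = homing), class = "drive_haplotype")
}

#' Construct a genotype
#'
#' A genotype is an unordered pair of haplotypes plus a sex. Equality ignores
#' haplotype order; [format()] prints the canonical (sorted) form.
#'
#' @param hap1,hap2 haplotypes from [haplotype()], or allele strings such as
#'   `"D:W"` (TARE:homing) or `"D"` (single locus).
#' @param sex `"F"` or `"M"`.
#' @return A list with class `"drive_genotype"`: elements `haps` (2x2
#'   character matrix, one row per haplotype) and `sex`.
#' @examples
#' genotype("D", "W", sex = "F")          # TARE/+ female, single locus
#' genotype("D:W", "W:D", sex = "M")      # double heterozygote male, in phase
#' @export
genotype <- function(hap1, hap2, sex = c("F", "M")) {
  sex <- match.arg(sex)
  h1 <- as_haplotype(hap1)
  h2 <- as_haplotype(hap2)
  if ((h1["homing"] == "A") != (h2["homing"] == "A"))
    stop("an absent homing locus must be absent on both haplotypes",
         call. = FALSE)
  haps <- rbind(h1, h2)
  rownames(haps) <- NULL
  # canonical order for hashing/counting
  key <- paste(haps[, "tare"], haps[, "homing"])
  haps <- haps[order(key), , drop = FALSE]
  structure(list(haps = haps, sex = sex), class = "drive_genotype")
}

as_haplotype <- function(x) {
  if (inherits(x, "drive_haplotype")) return(x)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(haplotype(parts[1]))
    if (length(parts) == 2) return(haplotype(parts[1], parts[2]))
  }
  if (is.character(x) && length(x) == 2) return(haplotype(x[1], x[2]))
  stop("cannot interpret haplotype: ", deparse(x), call. = FALSE)
}

#' Parse a genotype string
#'
#' The stable text syntax is `"h:<a>/<a>;hom:<a>/<a>;sex:<F|M>"`, e.g.
#' `"h:D/W;hom:W/W;sex:F"`. The `hom:` field may be omitted for single-locus
#' genotypes. Alleles at position i of the `h` and `hom` fields belong to the
#' same haplotype (the string is phased).
#'
#' @param x a genotype string.
#' @return A `"drive_genotype"`.
#' @examples
#' parse_genotype("h:D/W;sex:F")
#' parse_genotype("h:D/W;hom:W/D;sex:M")
#' @export
parse_genotype <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  fields <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  kv <- strsplit(fields, ":", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  names(vals) <- keys
  if (!"h" %in% keys || !"sex" %in% keys)
    stop("genotype string needs 'h:' and 'sex:' fields: ", x, call. = FALSE)
  t_all <- strsplit(vals[["h"]], "/", fixed = TRUE)[[1]]
  m_all <- if ("hom" %in% keys)
    strsplit(vals[["hom"]], "/", fixed = TRUE)[[1]] else c("A", "A")
  if (length(t_all) != 2 || length(m_all) != 2)
    stop("each locus field needs two '/'-separated alleles: ", x, call. = FALSE)
  genotype(haplotype(t_all[1], m_all[1]), haplotype(t_all[2], m_all[2]),
           sex = vals[["sex"]])
}

#' @export
format.drive_genotype <- function(x, ...) {
  h <- paste(x$haps[, "tare"], collapse = "/")
  out <- paste0("h:", h)
  if (x$haps[1, "homing"] != "A")
    out <- paste0(out, ";hom:", paste(x$haps[, "homing"], collapse = "/"))
  paste0(out, ";sex:", x$sex)
}

#' @export
print.drive_genotype <- function(x, ...) {
  cat("<genotype> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.drive_haplotype <- function(x, ...) {
  if (x["homing"] == "A") unname(x["tare"])
  else paste0(x["tare"], ":", x["homing"])
}

#' @export
print.drive_haplotype <- function(x, ...) {
  cat("<haplotype> ", format(x), "\n", sep = "")
  invisible(x)
}

# number of TARE drive alleles carried
n_tare_drive <- function(g) sum(g$haps[, "tare"] == "D")
n_homing_drive <- function(g) sum(g$haps[, "homing"] == "D")
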