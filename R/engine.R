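# Internal numeric engine.
#
# Enumerates the haplotype and genotype spaces implied by a drive_params
# object and precomputes, as dense matrices, every per-mating quantity the
# recursions need: sex-specific gamete distributions, embryo-modification
# operators (one per maternal deposition class), viability, female
# fertility, carrier masks and drive-allele counts. All dynamic code
# (deterministic iteration, cage simulation, likelihood propagation) runs on
# plain numeric vectors indexed by this engine.

engine_haplotypes <- function(params, two_locus) {
  hom <- if (two_locus) c("W", "D", "R") else "A"
  expand.grid(tare = c("W", "D", "R"), homing = hom,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# gamete distribution of an ordered haplotype pair, by enumeration.
# Steps: recombine, then per-allele germline cleavage conditioned on the
# parent's drive content, then draw one haplotype uniformly.
gamete_dist_pair <- function(h1, h2, params, sex, haps) {
  nH <- nrow(haps)
  r <- if (sex == "F") params$recomb_female else params$recomb_male
  if (h1$homing == "A") r <- 0
  has_tare_D <- h1$tare == "D" || h2$tare == "D"
  has_hom_D <- h1$homing == "D" || h2$homing == "D"
  cut_hom <- has_tare_D && has_hom_D && params$homing_locus_rule != "none"
  out <- numeric(nH)
  # candidate transmitted haplotypes with recombination weights
  cand <- list(list(t = h1$tare, m = h1$homing, w = (1 - r) / 2),
               list(t = h2$tare, m = h2$homing, w = (1 - r) / 2),
               list(t = h1$tare, m = h2$homing, w = r / 2),
               list(t = h2$tare, m = h1$homing, w = r / 2))
  for (cd in cand) {
    if (cd$w == 0) next
    # per-allele germline modification of the transmitted haplotype
    t_out <- list(list(a = cd$t, p = 1))
    if (cd$t == "W" && has_tare_D && params$c_germ_tare > 0)
      t_out <- list(list(a = "W", p = 1 - params$c_germ_tare),
                    list(a = "R", p = params$c_germ_tare))
    m_out <- list(list(a = cd$m, p = 1))
    if (cd$m == "W" && cut_hom && params$homing_germ_cut > 0) {
      cp <- params$homing_germ_cut
      cv <- params$homing_conversion_frac
      m_out <- list(list(a = "W", p = 1 - cp),
                    list(a = "D", p = cp * cv),
                    list(a = "R", p = cp * (1 - cv)))
    }
    for (to in t_out) for (mo in m_out) {
      idx <- which(haps$tare == to$a & haps$homing == mo$a)
      out[idx] <- out[idx] + cd$w * to$p * mo$p
    }
  }
  out
}

# per-haplotype embryo transformation matrix (nH x nH) for a maternal class:
# class 1 cuts wild-type TARE alleles, class 2 additionally cuts wild-type
# homing alleles (always to resistance).
embryo_hap_matrix <- function(params, haps, cut_homing) {
  nH <- nrow(haps)
  M <- matrix(0, nH, nH)
  et <- params$c_embryo_tare
  eh <- if (cut_homing) params$c_embryo_homing else 0
  for (i in seq_len(nH)) {
    t_out <- if (haps$tare[i] == "W" && et > 0)
      list(list(a = "W", p = 1 - et), list(a = "R", p = et))
    else list(list(a = haps$tare[i], p = 1))
    m_out <- if (haps$homing[i] == "W" && eh > 0)
      list(list(a = "W", p = 1 - eh), list(a = "R", p = eh))
    else list(list(a = haps$homing[i], p = 1))
    for (to in t_out) for (mo in m_out) {
      j <- which(haps$tare == to$a & haps$homing == mo$a)
      M[i, j] <- M[i, j] + to$p * mo$p
    }
  }
  M
}

.engine_cache <- new.env(parent = emptyenv())

build_engine <- function(params, two_locus = NULL) {
  if (is.null(two_locus)) two_locus <- params$homing_locus_rule != "none"
  key <- paste(c(unlist(params, use.names = FALSE), two_locus),
               collapse = "|")
  cached <- .engine_cache[[key]]
  if (!is.null(cached)) return(cached)
  eng <- build_engine_impl(params, two_locus)
  # bounded cache: parameter sweeps should not accumulate engines
  if (length(ls(.engine_cache)) > 32)
    rm(list = ls(.engine_cache), envir = .engine_cache)
  .engine_cache[[key]] <- eng
  eng
}

build_engine_impl <- function(params, two_locus) {
  haps <- engine_haplotypes(params, two_locus)
  nH <- nrow(haps)
  # unordered genotype index: pairs (i, j) with i <= j
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(nH)) for (j in i:nH) {
    pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
  }
  nG <- length(pair_i)
  gidx <- matrix(0L, nH, nH)
  for (k in seq_len(nG)) {
    gidx[pair_i[k], pair_j[k]] <- k
    gidx[pair_j[k], pair_i[k]] <- k
  }
  hap_label <- ifelse(haps$homing == "A", haps$tare,
                      paste0(haps$tare, ":", haps$homing))
  glabel <- paste0(hap_label[pair_i], "/", hap_label[pair_j])

  n_tareD <- (haps$tare[pair_i] == "D") + (haps$tare[pair_j] == "D")
  n_homD <- (haps$homing[pair_i] == "D") + (haps$homing[pair_j] == "D")
  n_tareW <- (haps$tare[pair_i] == "W") + (haps$tare[pair_j] == "W")
  n_homW <- (haps$homing[pair_i] == "W") + (haps$homing[pair_j] == "W")
  n_homR <- (haps$homing[pair_i] == "R") + (haps$homing[pair_j] == "R")
  n_tareR <- (haps$tare[pair_i] == "R") + (haps$tare[pair_j] == "R")

  viable <- n_tareR < 2
  if (params$homing_locus_rule == "haplolethal_rescue")
    viable <- viable & (n_homR == 0)
  fertile_f <- rep(TRUE, nG)
  if (params$homing_locus_rule == "female_fertility")
    fertile_f <- n_homW > 0

  # maternal deposition class: 0 no TARE drive, 1 TARE drive only,
  # 2 TARE drive + homing drive (Cas9 and homing gRNAs both deposited)
  mclass <- integer(nG)
  mclass[n_tareD > 0] <- 1L
  if (params$homing_locus_rule != "none")
    mclass[n_tareD > 0 & n_homD > 0] <- 2L

  GF <- matrix(0, nG, nH)
  GM <- matrix(0, nG, nH)
  for (k in seq_len(nG)) {
    h1 <- list(tare = haps$tare[pair_i[k]], homing = haps$homing[pair_i[k]])
    h2 <- list(tare = haps$tare[pair_j[k]], homing = haps$homing[pair_j[k]])
    GF[k, ] <- gamete_dist_pair(h1, h2, params, "F", haps)
    GM[k, ] <- gamete_dist_pair(h1, h2, params, "M", haps)
  }

  # fold matrix: ordered hap pair (i, j), column-major over nH x nH, to
  # unordered genotype index
  fold <- as.vector(gidx)

  # genotype-level embryo operators per maternal class, from the
  # per-haplotype transformation (alleles are cut independently)
  E_geno <- function(Mh) {
    E <- matrix(0, nG, nG)
    for (k in seq_len(nG)) {
      z <- outer(Mh[pair_i[k], ], Mh[pair_j[k], ])
      E[k, ] <- rowsum_by(as.vector(z), fold, nG)
    }
    E
  }
  Mh1 <- embryo_hap_matrix(params, haps, cut_homing = FALSE)
  Mh2 <- embryo_hap_matrix(params, haps, cut_homing = TRUE)
  E <- list(diag(nG), E_geno(Mh1), E_geno(Mh2))

  list(params = params, two_locus = two_locus, haps = haps, nH = nH,
       nG = nG, pair_i = pair_i, pair_j = pair_j, gidx = gidx, fold = fold,
       labels = glabel, GF = GF, GM = GM, E = E,
       viable = viable, fertile_f = fertile_f, mclass = mclass,
       n_tareD = n_tareD, n_homD = n_homD,
       carrier_tare = n_tareD > 0, carrier_homing = n_homD > 0)
}

rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  for (u in seq_along(x)) out[idx[u]] <- out[idx[u]] + x[u]
  out
}

# fitness vector over engine genotypes under the codominant sqrt model
engine_fitness <- function(eng, fitness) {
  fitness$f_hom ^ (eng$n_tareD / 2) * fitness$f_homing ^ (eng$n_homD / 2)
}

# genotype index in an engine for a drive_genotype object
engine_genotype_index <- function(eng, g) {
  find_hap <- function(t, m) {
    if (m == "A" && eng$two_locus)
      stop("genotype has no homing locus but params configure one",
           call. = FALSE)
    if (m != "A" && !eng$two_locus)
      stop("genotype carries a homing locus but params configure none",
           call. = FALSE)
    which(eng$haps$tare == t & eng$haps$homing == m)
  }
  i <- find_hap(g$haps[1, "tare"], g$haps[1, "homing"])
  j <- find_hap(g$haps[2, "tare"], g$haps[2, "homing"])
  eng$gidx[i, j]
}

# One deterministic generation on raw frequency vectors.
# freq_f, freq_m: genotype frequencies among adult females / males (each
# summing to 1). Returns list(freq, output) where `output` is the total
# viable reproductive output relative to an all-wild-type population
# (female side absolute, male side competitive), or signals extinction.
engine_next_gen <- function(eng, freq_f, freq_m, fitness) {
  w <- engine_fitness(eng, fitness)
  comp <- fitness$component
  wF <- freq_f * eng$fertile_f
  if (comp %in% c("female_fecundity", "both_sexes")) wF <- wF * w
  wM <- freq_m
  if (comp %in% c("male_mating", "both_sexes")) wM <- wM * w
  sM <- sum(wM)
  if (sM <= 0 || sum(wF) <= 0)
    return(list(freq = NULL, output = 0, extinct = TRUE))
  wM <- wM / sM
  gm <- colSums(eng$GM * wM)
  off <- numeric(eng$nG)
  for (cl in 0:2) {
    sel <- eng$mclass == cl
    if (!any(sel) || sum(wF[sel]) == 0) next
    gf <- colSums(eng$GF[sel, , drop = FALSE] * wF[sel])
    z <- rowsum_by(as.vector(outer(gf, gm)), eng$fold, eng$nG)
    off <- off + as.vector(z %*% eng$E[[cl + 1]])
  }
  off <- off * eng$viable
  if (comp == "offspring_viability") off <- off * w
  total <- sum(off)
  if (total <= 0) return(list(freq = NULL, output = 0, extinct = TRUE))
  list(freq = off / total, output = total, extinct = FALSE)
}

# frequency vector for a pure wild-type population
engine_wild_freq <- function(eng) {
  wt <- which(eng$haps$tare == "W" &
                eng$haps$homing %in% c("W", "A"))
  freq <- numeric(eng$nG)
  freq[eng$gidx[wt, wt]] <- 1
  freq
}

# mix a release genotype into a frequency vector
engine_mix_release <- function(eng, freq, gindex, proportion) {
  freq <- freq * (1 - proportion)
  freq[gindex] <- freq[gindex] + proportion
  freq
}
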