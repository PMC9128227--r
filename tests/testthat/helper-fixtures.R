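# Shared fixtures: parameter sets at the experimentally measured rates and
# a brute-force cross oracle kept deliberately independent of the package's
# engine (it enumerates meiosis, germline cutting, gamete choice and embryo
# cutting as explicit outcome trees over ordered haplotypes).

tare_params <- function(...) {
  drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632, ...)
}

haplolethal_params <- function(...) {
  drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632,
               homing_germ_cut = 0.8, homing_conversion_frac = 0.85,
               c_embryo_homing = 0.05,
               homing_locus_rule = "haplolethal_rescue", ...)
}

suppression_params <- function(...) {
  drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632,
               homing_germ_cut = 0.5, homing_conversion_frac = 0.7,
               homing_locus_rule = "female_fertility", ...)
}

# --- brute-force oracle ----------------------------------------------------

# a haplotype is c(tare, homing); an outcome list is list(list(h=, p=), ...)
oracle_expand <- function(outcomes, fn) {
  res <- list()
  for (o in outcomes) {
    for (nxt in fn(o$h)) {
      res[[length(res) + 1]] <- list(h = nxt$h, p = o$p * nxt$p)
    }
  }
  res
}

# gametes of an ordered haplotype pair as an outcome list over haplotypes
oracle_gametes <- function(h1, h2, params, sex) {
  r <- if (sex == "F") params$recomb_female else params$recomb_male
  if (h1[2] == "A") r <- 0
  has_tD <- h1[1] == "D" || h2[1] == "D"
  has_hD <- h1[2] == "D" || h2[2] == "D"
  cut_hom <- has_tD && has_hD && params$homing_locus_rule != "none"
  pairs <- list(list(a = h1, b = h2, p = 1 - r),
                list(a = c(h1[1], h2[2]), b = c(h2[1], h1[2]), p = r))
  out <- list()
  for (pr in pairs) {
    if (pr$p == 0) next
    for (pick in list(list(h = pr$a, p = 0.5), list(h = pr$b, p = 0.5))) {
      start <- list(list(h = pick$h, p = pr$p * pick$p))
      # germline TARE cutting on the transmitted haplotype
      cut1 <- oracle_expand(start, function(h) {
        if (h[1] == "W" && has_tD)
          list(list(h = c("W", h[2]), p = 1 - params$c_germ_tare),
               list(h = c("R", h[2]), p = params$c_germ_tare))
        else list(list(h = h, p = 1))
      })
      # germline homing cutting/conversion
      cut2 <- oracle_expand(cut1, function(h) {
        if (h[2] == "W" && cut_hom) {
          cp <- params$homing_germ_cut
          cv <- params$homing_conversion_frac
          list(list(h = c(h[1], "W"), p = 1 - cp),
               list(h = c(h[1], "D"), p = cp * cv),
               list(h = c(h[1], "R"), p = cp * (1 - cv)))
        } else list(list(h = h, p = 1))
      })
      out <- c(out, cut2)
    }
  }
  out
}

oracle_embryo <- function(h, mother_haps, params) {
  has_tD <- any(mother_haps[, 1] == "D")
  has_hD <- any(mother_haps[, 2] == "D")
  outs <- list(list(h = h, p = 1))
  if (has_tD && h[1] == "W" && params$c_embryo_tare > 0)
    outs <- oracle_expand(outs, function(hh)
      list(list(h = c("W", hh[2]), p = 1 - params$c_embryo_tare),
           list(h = c("R", hh[2]), p = params$c_embryo_tare)))
  if (has_tD && has_hD && params$homing_locus_rule != "none" &&
      h[2] == "W" && params$c_embryo_homing > 0)
    outs <- oracle_expand(outs, function(hh)
      list(list(h = c(hh[1], "W"), p = 1 - params$c_embryo_homing),
           list(h = c(hh[1], "R"), p = params$c_embryo_homing)))
  outs
}

oracle_viable <- function(h1, h2, params) {
  if (h1[1] == "R" && h2[1] == "R") return(FALSE)
  if (params$homing_locus_rule == "haplolethal_rescue" &&
      (h1[2] == "R" || h2[2] == "R")) return(FALSE)
  TRUE
}

# full cross: returns list(dist = named probs over sorted "t:h/t:h" labels
# of viable offspring, weight = viable fraction)
oracle_cross <- function(mother_haps, father_haps, params) {
  gm <- oracle_gametes(mother_haps[1, ], mother_haps[2, ], params, "F")
  gf <- oracle_gametes(father_haps[1, ], father_haps[2, ], params, "M")
  acc <- new.env(parent = emptyenv())
  weight <- 0
  for (a in gm) for (b in gf) {
    ea <- oracle_embryo(a$h, mother_haps, params)
    eb <- oracle_embryo(b$h, mother_haps, params)
    for (x in ea) for (y in eb) {
      p <- a$p * b$p * x$p * y$p
      if (p == 0) next
      if (!oracle_viable(x$h, y$h, params)) next
      lab <- paste(sort(c(paste(x$h, collapse = ":"),
                          paste(y$h, collapse = ":"))), collapse = "/")
      acc[[lab]] <- (if (is.null(acc[[lab]])) 0 else acc[[lab]]) + p
      weight <- weight + p
    }
  }
  dist <- unlist(as.list(acc))
  list(dist = dist / weight, weight = weight)
}

# normalise package offspring_distribution labels to the oracle's sorted
# ordered-haplotype label form
canon_label <- function(lab, two_locus) {
  haps <- strsplit(lab, "/", fixed = TRUE)[[1]]
  if (!two_locus) haps <- paste0(haps, ":A")
  paste(sort(haps), collapse = "/")
}

# sweep every viable genotype pair of a configuration through the oracle
compare_with_oracle <- function(params, two_locus) {
  haps <- if (two_locus)
    expand.grid(t = c("W", "D", "R"), m = c("W", "D", "R"),
                stringsAsFactors = FALSE)
  else data.frame(t = c("W", "D", "R"), m = "A")
  nH <- nrow(haps)
  n_checked <- 0
  for (i1 in seq_len(nH)) for (j1 in i1:nH) {
    mh <- rbind(c(haps$t[i1], haps$m[i1]), c(haps$t[j1], haps$m[j1]))
    mother <- genotype(haplotype(mh[1, 1], mh[1, 2]),
                       haplotype(mh[2, 1], mh[2, 2]), sex = "F")
    if (!is_viable(mother, params)) next
    if (params$homing_locus_rule == "female_fertility" &&
        !is_fertile_female(mother, params)) next
    for (i2 in seq_len(nH)) for (j2 in i2:nH) {
      fh <- rbind(c(haps$t[i2], haps$m[i2]), c(haps$t[j2], haps$m[j2]))
      father <- genotype(haplotype(fh[1, 1], fh[1, 2]),
                         haplotype(fh[2, 1], fh[2, 2]), sex = "M")
      if (!is_viable(father, params)) next
      oracle <- oracle_cross(mh, fh, params)
      off <- offspring_distribution(mother, father, params)
      expect_equal(off$weight, oracle$weight, tolerance = 1e-12)
      got <- stats::setNames(off$dist$prob,
                             vapply(off$dist$genotype, canon_label, "",
                                    two_locus = two_locus))
      expect_equal(sort(names(got)), sort(names(oracle$dist)))
      expect_equal(got[names(oracle$dist)], oracle$dist, tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  n_checked
}

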