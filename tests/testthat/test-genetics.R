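# Gamete formation, embryo cleavage, viability and fertility rules.

test_that("gamete distribution of a TARE heterozygote reflects germline cleavage", {
  p <- tare_params()
  g <- gamete_distribution(genotype("D", "W", sex = "F"), p)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_equal(unname(g["D"]), 0.5)
  expect_equal(unname(g["W"]), 0.5 * (1 - 0.888))
  expect_equal(unname(g["R"]), 0.5 * 0.888)
  # males cut their germline at the same rate
  gm <- gamete_distribution(genotype("D", "W", sex = "M"), p)
  expect_equal(g, gm)
})

test_that("no cleavage without a drive allele, and Cas9-less homing is inert", {
  p <- tare_params()
  g <- gamete_distribution(genotype("W", "W", sex = "F"), p)
  expect_equal(unname(g["W"]), 1)
  # a disrupted allele does not cut
  g2 <- gamete_distribution(genotype("W", "R", sex = "F"), p)
  expect_equal(unname(g2["W"]), 0.5)
  expect_equal(unname(g2["R"]), 0.5)
  # homing drive without the TARE (Cas9) element segregates Mendelian
  hp <- haplolethal_params()
  g3 <- gamete_distribution(genotype("W:D", "W:W", sex = "F"), hp)
  expect_equal(unname(g3["W:D"]), 0.5)
  expect_equal(unname(g3["W:W"]), 0.5)
})

test_that("all-zero cleavage rates give exactly Mendelian inheritance", {
  p0 <- drive_params(homing_germ_cut = 0,
                     homing_locus_rule = "haplolethal_rescue")
  for (gt in list(genotype("D:W", "W:D", sex = "F"),
                  genotype("D:D", "R:W", sex = "M"))) {
    g <- gamete_distribution(gt, p0)
    # each allele transmitted with probability 1/2 regardless of content
    r <- if (gt$sex == "F") 0.5 else 0
    expected <- numeric(length(g))
    names(expected) <- names(g)
    h1 <- gt$haps[1, ]; h2 <- gt$haps[2, ]
    add <- function(t, m, p) {
      lab <- paste0(t, ":", m)
      expected[lab] <<- expected[lab] + p
    }
    add(h1["tare"], h1["homing"], (1 - r) / 2)
    add(h2["tare"], h2["homing"], (1 - r) / 2)
    add(h1["tare"], h2["homing"], r / 2)
    add(h2["tare"], h1["homing"], r / 2)
    expect_equal(g, expected[names(g)])
  }
})

test_that("embryo cleavage hits each wild-type allele independently", {
  p <- tare_params()
  mother <- genotype("D", "W", sex = "F")
  d1 <- apply_embryo_cleavage(genotype("R", "W", sex = "F"), mother, p)
  expect_equal(unname(d1["R/R"]), 0.632)
  expect_equal(unname(d1["W/R"]), 0.368)
  d2 <- apply_embryo_cleavage(genotype("W", "W", sex = "M"), mother, p)
  expect_equal(unname(d2["R/R"]), 0.632^2)
  expect_equal(unname(d2["W/W"]), 0.368^2)
  expect_equal(unname(d2["W/R"]), 2 * 0.632 * 0.368)
  # mothers without the drive deposit nothing
  d3 <- apply_embryo_cleavage(genotype("W", "W", sex = "M"),
                              genotype("W", "R", sex = "F"), p)
  expect_equal(unname(d3["W/W"]), 1)
})

test_that("viability rules: biallelic h disruption and haplolethal resistance", {
  p <- tare_params()
  expect_true(is_viable("h:D/R;sex:F", p))
  expect_false(is_viable("h:R/R;sex:F", p))
  hp <- haplolethal_params()
  expect_false(is_viable("h:D/W;hom:D/R;sex:M", hp))
  expect_true(is_viable("h:D/W;hom:D/W;sex:M", hp))
  # resistance at the homing locus is tolerated under the suppression rule
  sp <- suppression_params()
  expect_true(is_viable("h:D/W;hom:D/R;sex:M", sp))
})

test_that("suppression-drive female fertility requires a functional copy", {
  sp <- suppression_params()
  expect_false(is_fertile_female("h:D/D;hom:D/D;sex:F", sp))
  expect_false(is_fertile_female("h:D/D;hom:D/R;sex:F", sp))
  expect_true(is_fertile_female("h:D/D;hom:D/W;sex:F", sp))
  expect_true(is_fertile_female("h:D/D;hom:D/D;sex:M", sp))
  expect_error(is_fertile_female("h:D/D;sex:F", tare_params()),
               "female_fertility")
})

test_that("offspring distribution of the drive-female cross matches the printed rates", {
  p <- tare_params()
  off <- offspring_distribution(genotype("D", "W", sex = "F"),
                                genotype("W", "W", sex = "M"), p)
  expect_equal(off$weight, 1 - 0.5 * 0.888 * 0.632 - 0.5 * 0.112 * 0.632^2,
               tolerance = 1e-12)
  carriers <- grepl("D", off$dist$genotype)
  expect_equal(sum(off$dist$prob[carriers]), 0.5 / off$weight,
               tolerance = 1e-12)
  expect_equal(sum(off$dist$prob), 1, tolerance = 1e-12)
})

test_that("a sterile mother yields an empty distribution with weight zero", {
  sp <- suppression_params()
  off <- offspring_distribution(parse_genotype("h:D/D;hom:D/D;sex:F"),
                                parse_genotype("h:D/D;hom:W/W;sex:M"), sp)
  expect_equal(off$weight, 0)
  expect_equal(nrow(off$dist), 0)
})

test_that("genotype strings parse, canonicalise and validate", {
  g <- parse_genotype("h:W/D;sex:F")
  expect_equal(format(g), "h:D/W;sex:F")  # canonical order
  g2 <- parse_genotype("h:D/W;hom:W/D;sex:M")
  expect_equal(format(parse_genotype(format(g2))), format(g2))
  expect_error(genotype(haplotype("D", "W"), haplotype("W")), "absent")
  expect_error(parse_genotype("h:D/W"), "sex")
  expect_error(haplotype("X"), "invalid")
  # genotype/params mismatch is caught
  expect_error(gamete_distribution("h:D/W;sex:F", haplolethal_params()),
               "homing locus")
})

test_that("gamete and offspring distributions are proper distributions", {
  set.seed(42)
  hp <- haplolethal_params()
  eng_labels <- c("W", "D", "R")
  for (rep in 1:20) {
    h1 <- haplotype(sample(eng_labels, 1), sample(eng_labels, 1))
    h2 <- haplotype(sample(eng_labels, 1), sample(eng_labels, 1))
    g <- genotype(h1, h2, sex = sample(c("F", "M"), 1))
    if (!is_viable(g, hp)) next
    d <- gamete_distribution(g, hp)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
  }
})
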