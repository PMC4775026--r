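pv <- function(keys, gene, zygosity = "heterozygous") {
  data.frame(variant_key = keys, gene = gene, zygosity = zygosity,
             stringsAsFactors = FALSE)
}

test_that("classify_family assigns the three inheritance modes", {
  expect_equal(classify_family(pv("COL4A5:c.2741G>A", "COL4A5", "hemizygous"))$mode,
               "X_LINKED_AS")
  expect_equal(classify_family(pv(c("COL4A3:c.687G>A", "COL4A3:c.3490G>T"),
                                  "COL4A3"))$mode, "AUTOSOMAL_AS")
  expect_equal(classify_family(pv("COL4A3:c.3410G>A", "COL4A3"))$mode, "FBH")
  expect_equal(classify_family(pv("COL4A4:c.2320G>C", "COL4A4", "homozygous"))$mode,
               "AUTOSOMAL_AS")
  expect_equal(classify_family(NULL)$mode, "UNRESOLVED")
})

test_that("phase handling: proven cis demotes two same-gene variants to FBH", {
  two <- pv(c("COL4A3:c.687G>A", "COL4A3:c.3490G>T"), "COL4A3")
  expect_equal(classify_family(two, phase = "cis")$mode, "FBH")
  expect_equal(classify_family(two, phase = "trans")$mode, "AUTOSOMAL_AS")
  unknown <- classify_family(two, phase = "unknown")
  expect_equal(unknown$mode, "AUTOSOMAL_AS")
  expect_true(any(grepl("phase unknown", unknown$caveats)))
})

test_that("digenic genotypes are flagged with a warning, never folded silently", {
  digenic <- rbind(pv("COL4A3:c.3410G>A", "COL4A3"),
                   pv("COL4A4:c.2986G>A", "COL4A4"))
  expect_warning(d <- classify_family(digenic), "digenic")
  expect_equal(d$mode, "DIGENIC_FLAG")
})

test_that("COL4A5 plus autosomal variants yields a flagged composite, not an error", {
  mix <- rbind(pv("COL4A5:c.2741G>A", "COL4A5", "hemizygous"),
               pv("COL4A3:c.3410G>A", "COL4A3"))
  d <- classify_family(mix)
  expect_equal(d$mode, "X_LINKED_AS")
  expect_true(d$composite)
})

test_that("the mode vocabulary contains no autosomal-dominant AS", {
  expect_error(alportdx:::new_family_diagnosis("F", "AD_AS", character()))
})

test_that("the packaged 17-case roster reproduces the reference categorization", {
  expected <- c(
    F1 = "X_LINKED_AS", F2 = "FBH", F3 = "AUTOSOMAL_AS", F4 = "AUTOSOMAL_AS",
    F5 = "X_LINKED_AS", F6 = "X_LINKED_AS", F7 = "X_LINKED_AS", F8 = "FBH",
    F9 = "X_LINKED_AS", F10 = "X_LINKED_AS", F11 = "X_LINKED_AS", F12 = "FBH",
    F13 = "FBH", F14 = "X_LINKED_AS", I1 = "X_LINKED_AS", I2 = "X_LINKED_AS",
    I3 = "FBH")
  res <- classified_fixture()
  got <- vapply(res$diagnoses, function(d) d$mode, character(1))
  names(got) <- vapply(res$diagnoses, function(d) d$family_id, character(1))
  expect_equal(got[names(expected)], expected)
  expect_equal(as.integer(res$mode_tally[c("X_LINKED_AS", "AUTOSOMAL_AS", "FBH")]),
               c(10L, 2L, 5L))
})

test_that("functional trimer fraction reproduces the dosage model anchors", {
  expect_equal(functional_trimer_fraction(dosage_genotype()), 1.0)
  expect_equal(functional_trimer_fraction(dosage_genotype(col4a3_wt = 1)), 0.5)
  expect_equal(functional_trimer_fraction(
    dosage_genotype(col4a5_wt = 1, sex = "female", x_wt_active_fraction = 0.5)), 0.5)
  expect_equal(functional_trimer_fraction(
    dosage_genotype(sex = "male", col4a5_wt = 0)), 0.0)
  expect_equal(functional_trimer_fraction(dosage_genotype(col4a3_wt = 0)), 0.0)
  # skewed X-inactivation moves a carrier female across the spectrum
  expect_equal(functional_trimer_fraction(
    dosage_genotype(col4a5_wt = 1, sex = "female", x_wt_active_fraction = 0.9)), 0.9)
})

test_that("dosage genotypes respect ploidy and clamp degenerate X fractions", {
  expect_error(dosage_genotype(sex = "male", col4a5_wt = 2), "hemizygous")
  expect_error(dosage_genotype(col4a3_wt = 3), "col4a3_wt")
  expect_error(dosage_genotype(x_wt_active_fraction = 1.5), "0, 1")
  g <- dosage_genotype(sex = "female", col4a5_wt = 2, x_wt_active_fraction = 0.3)
  expect_equal(g$x_wt_active_fraction, 1)
  g0 <- dosage_genotype(sex = "female", col4a5_wt = 0, x_wt_active_fraction = 0.3)
  expect_equal(functional_trimer_fraction(g0), 0)
})

test_that("removing a functional allele never increases the trimer fraction", {
  for (sex in c("male", "female")) {
    a5_max <- if (sex == "male") 1L else 2L
    for (a3 in 0:2) for (a4 in 0:2) for (a5 in 0:a5_max) {
      f <- functional_trimer_fraction(dosage_genotype(a3, a4, a5, sex))
      expect_gte(f, 0); expect_lte(f, 1)
      if (a3 > 0) {
        expect_lte(functional_trimer_fraction(dosage_genotype(a3 - 1L, a4, a5, sex)), f)
      }
      if (a4 > 0) {
        expect_lte(functional_trimer_fraction(dosage_genotype(a3, a4 - 1L, a5, sex)), f)
      }
      if (a5 > 0) {
        expect_lte(functional_trimer_fraction(dosage_genotype(a3, a4, a5 - 1L, sex)), f)
      }
    }
  }
})

test_that("homotypic assembly model shows the dominant-negative contrast", {
  expect_equal(homotypic_assembly_fraction(2, 0.5), 0.25)
  expect_equal(homotypic_assembly_fraction(3, 0.5), 0.125)
  expect_equal(homotypic_assembly_fraction(2, 1.0), 1.0)
  # a heterozygote loses more than the 50% a null allele would leave
  expect_lt(homotypic_assembly_fraction(2, 0.5), 0.5)
  expect_lt(homotypic_assembly_fraction(3, 0.5), homotypic_assembly_fraction(2, 0.5))
  expect_error(homotypic_assembly_fraction(4, 0.5), "chains_per_molecule")
  expect_error(homotypic_assembly_fraction(2, 1.2), "wt_chain_fraction")
})

test_that("phenotype classes partition the dose spectrum monotonically", {
  expect_equal(phenotype_class(c(1, 0.75, 0.5, 0.25, 0.2, 0)),
               c("NORMAL", "NORMAL", "FBH_TBMN_SPECTRUM", "FBH_TBMN_SPECTRUM",
                 "AS_SEVERE", "AS_SEVERE"))
  sev <- c(NORMAL = 0, FBH_TBMN_SPECTRUM = 1, AS_SEVERE = 2)
  f <- seq(0, 1, by = 0.01)
  ranks <- sev[phenotype_class(f)]
  expect_true(all(diff(ranks) <= 0))
  expect_error(phenotype_class(1.2), "f")
  custom <- phenotype_thresholds(normal_min = 0.9, severe_max = 0.1)
  expect_equal(phenotype_class(0.8, custom), "FBH_TBMN_SPECTRUM")
})
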