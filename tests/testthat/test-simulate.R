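test_that("X-linked transmission: father-to-son never, father-to-daughter always", {
  set.seed(101)
  sons <- transmit_x(father_count = 1, mother_count = 0, child_sex = "male", n = 10000)
  expect_equal(sum(sons), 0L)
  daughters <- transmit_x(1, 0, "female", n = 10000)
  expect_true(all(daughters == 1L))
  # carrier mother transmits to half of children regardless of sex
  from_mo <- transmit_x(0, 1, "male", n = 10000)
  p <- mean(from_mo)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("offspring of two heterozygous carriers are compound het with probability 1/4", {
  set.seed(202)
  n <- 10000
  from_fa <- transmit_autosomal(1, 0, n = n)
  from_mo <- transmit_autosomal(0, 1, n = n)
  p_hat <- mean(from_fa > 0 & from_mo > 0)
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("simulated families are structurally valid and reproducible", {
  sim1 <- simulate_family(simulation_config("X_LINKED_AS", seed = 7))
  sim2 <- simulate_family(simulation_config("X_LINKED_AS", seed = 7))
  expect_identical(sim1$genotypes, sim2$genotypes)
  expect_identical(sim1$pedigree$members, sim2$pedigree$members)
  expect_equal(nrow(validate_pedigree(sim1$pedigree, sim1$genotypes)), 0L)
  expect_gte(nrow(sim1$pedigree$members), 4L)
})

test_that("FBH simulation: every affected member carries exactly one causal allele", {
  set.seed(33)
  for (i in 1:20) {
    cfg <- simulation_config("FBH")
    sim <- simulate_family(cfg)
    causal <- sim$truth$causal_variants
    gt <- sim$genotypes[sim$genotypes$variant_key == causal, ]
    counts <- stats::setNames(gt$allele_count, gt$individual_id)
    aff <- sim$pedigree$members$id[sim$pedigree$members$affection == "affected"]
    expect_true(all(counts[aff] == 1L))
    res <- rediagnose_simulated_family(sim, cfg)
    expect_equal(res$diagnosis$mode, "FBH")
  }
})

test_that("no X-linked causal allele ever passes father to son inside simulated pedigrees", {
  set.seed(44)
  violations <- 0L
  for (i in 1:40) {
    sim <- simulate_family(simulation_config("X_LINKED_AS"))
    causal <- sim$truth$causal_variants
    gt <- sim$genotypes[sim$genotypes$variant_key == causal, ]
    counts <- stats::setNames(gt$allele_count, gt$individual_id)
    m <- sim$pedigree$members
    for (j in seq_len(nrow(m))) {
      if (m$sex[j] != "male" || is.na(m$father_id[j])) next
      fa <- m$father_id[j]; mo <- m$mother_id[j]
      if (counts[[fa]] > 0L && counts[[mo]] == 0L && counts[[m$id[j]]] > 0L) {
        violations <- violations + 1L
      }
    }
  }
  expect_equal(violations, 0L)
})

test_that("control cohorts estimate MAFs without bias and stay X-aware", {
  cfg <- simulation_config("FBH", seed = 55)
  cohort <- simulate_control_cohort(cfg)
  est <- cohort$maf_estimates
  expect_equal(nrow(est), nrow(cfg$background_maf_table))
  # X-linked allele number counts one chromosome per male
  x_rows <- grepl("^COL4A5", est$variant_key)
  n_male <- sum(cohort$sexes == "male")
  expect_equal(est$allele_number[x_rows], 2L * 66L - n_male)
  expect_equal(est$allele_number[!x_rows], rep(132L, sum(!x_rows)))

  # a MAF-zero variant never appears
  cfg0 <- simulation_config("FBH", seed = 56,
                            background_maf_table = data.frame(
                              gene = "COL4A3", cdna = "c.3410G>A", maf = 0))
  expect_false(any(simulate_control_cohort(cfg0)$maf_estimates$in_cohort))

  # 500 replicate cohorts: mean estimate within one binomial SE of 0.798
  set.seed(57)
  cfg_rep <- simulation_config("FBH", background_maf_table = data.frame(
    gene = "COL4A3", cdna = "c.485A>G", maf = 0.798))
  means <- replicate(500, simulate_control_cohort(cfg_rep)$maf_estimates$estimated_maf)
  se_single <- sqrt(0.798 * (1 - 0.798) / 132)
  expect_lt(abs(mean(means) - 0.798), se_single)
})

test_that("pooled simulated control genotypes are Hardy-Weinberg consistent", {
  set.seed(58)
  mafs <- c(0.121, 0.355, 0.798)
  cfg <- simulation_config("FBH", background_maf_table = data.frame(
    gene = "COL4A3", cdna = c("c.1721C>T", "c.1000A>G", "c.485A>G"), maf = mafs))
  pooled <- matrix(0L, nrow = 0, ncol = 3)
  for (r in 1:100) {
    pooled <- rbind(pooled, simulate_control_cohort(cfg)$genotypes)
  }
  for (j in seq_along(mafs)) {
    obs <- tabulate(pooled[, j] + 1L, nbins = 3L)
    p <- mafs[j]
    exp_p <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((obs - sum(obs) * exp_p)^2 / (sum(obs) * exp_p))
    expect_lt(chi2, stats::qchisq(1 - 1e-4, df = 2))
  }
})

test_that("depth tracks have the requested moments and are seed-reproducible", {
  d1 <- simulate_depth_track(29400, mean = 150, dispersion = 5, seed = 9)
  d2 <- simulate_depth_track(29400, mean = 150, dispersion = 5, seed = 9)
  expect_identical(d1, d2)
  sd_mean <- sqrt((150 + 150^2 / 5) / 29400)
  expect_lt(abs(mean(d1) - 150), 3 * sd_mean)

  # large dispersion approaches Poisson: variance close to mean
  d3 <- simulate_depth_track(50000, mean = 100, dispersion = 1e6, seed = 10)
  expect_lt(abs(stats::var(d3) / mean(d3) - 1), 0.05)

  expect_error(simulate_depth_track(10, mean = 0, dispersion = 5), "positive")
  expect_error(simulate_depth_track(10, mean = 5, dispersion = 0), "positive")
})

test_that("simulated output re-parses losslessly through the io layer", {
  cfg <- simulation_config("X_LINKED_AS", seed = 77)
  sim <- simulate_family(cfg)
  ped_path <- withr::local_tempfile(fileext = ".ped")
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_ped(sim$pedigree, ped_path)
  sexes <- stats::setNames(sim$pedigree$members$sex, sim$pedigree$members$id)
  keys <- unique(sim$genotypes$variant_key)
  vt <- data.frame(gene = sub(":.*$", "", keys), cdna = sub("^[^:]+:", "", keys),
                   stringsAsFactors = FALSE)
  write_variant_vcf(vt, vcf_path, genotypes = sim$genotypes, sexes = sexes)

  ped_back <- read_ped(ped_path)[["SIM"]]
  expect_equal(ped_back$members, sim$pedigree$members)

  vcf_back <- read_variant_table(vcf_path)
  expect_setequal(vcf_back$variants$variant_key, keys)
  got <- vcf_back$genotypes
  for (r in seq_len(nrow(sim$genotypes))) {
    row <- sim$genotypes[r, ]
    match_row <- got[got$individual_id == row$individual_id &
                       got$variant_key == row$variant_key, ]
    expect_equal(nrow(match_row), 1L)
    expect_equal(match_row$allele_count, row$allele_count,
                 info = paste(row$individual_id, row$variant_key))
  }
})
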