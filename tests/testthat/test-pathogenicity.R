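make_cons <- function(category, secondary = FALSE) {
  alportdx:::new_consequence(category, secondary)
}

gt_for <- function(ids, key, counts) {
  do.call(rbind, Map(genotype_call, ids, key, counts))
}

test_that("autosomal exclusive segregation: carriers confined to affected members", {
  ped <- pedigree("A", data.frame(
    id = c("m1", "m2", "m3", "u1", "u2"),
    sex = c("male", "female", "male", "female", "male"),
    affection = c("affected", "affected", "affected", "unaffected", "unaffected"),
    father_id = NA, mother_id = NA, stringsAsFactors = FALSE))
  key <- "COL4A3:c.3410G>A"

  all_good <- gt_for(ped$members$id, key, c(1, 1, 1, 0, 0))
  expect_true(segregates_exclusively(key, all_good, ped, "COL4A3")$consistent)

  leaky <- gt_for(ped$members$id, key, c(1, 1, 1, 1, 0))
  strict <- segregates_exclusively(key, leaky, ped, "COL4A3")
  expect_false(strict$consistent)
  expect_true(any(grepl("unaffected member carries", strict$detail$reason)))

  tolerant_cfg <- classification_config(autosomal_segregation = "penetrance_tolerant")
  expect_true(segregates_exclusively(key, leaky, ped, "COL4A3", tolerant_cfg)$consistent)

  # an affected member explained by a second variant is not counter-evidence
  partial <- gt_for(ped$members$id, key, c(1, 0, 1, 0, 0))
  expect_true(segregates_exclusively(key, partial, ped, "COL4A3")$consistent)

  # but a variant absent from every affected member cannot segregate with disease
  absent <- gt_for(ped$members$id, key, c(0, 0, 0, 0, 0))
  expect_false(segregates_exclusively(key, absent, ped, "COL4A3")$consistent)
})

test_that("X-linked rules tolerate unaffected female carriers only", {
  ped <- pedigree("X", data.frame(
    id = c("f", "m", "s", "d"),
    sex = c("male", "female", "male", "female"),
    affection = c("unaffected", "unaffected", "affected", "unaffected"),
    father_id = c(NA, NA, "f", "f"), mother_id = c(NA, NA, "m", "m"),
    stringsAsFactors = FALSE))
  key <- "COL4A5:c.2741G>A"

  # carrier mother (non-penetrant), affected carrier son, carrier daughter
  res <- segregates_exclusively(key, gt_for(ped$members$id, key, c(0, 1, 1, 1)),
                                ped, "COL4A5")
  expect_true(res$consistent)
  expect_true(any(grepl("X-inactivation", res$detail$reason)))

  # unaffected male carrier falsifies
  res2 <- segregates_exclusively(key, gt_for(ped$members$id, key, c(1, 0, 1, 1)),
                                 ped, "COL4A5")
  expect_false(res2$consistent)

  # unknown-affection members are skipped
  ped$members$affection[1] <- "unknown"
  res3 <- segregates_exclusively(key, gt_for(ped$members$id, key, c(1, 0, 1, 1)),
                                 ped, "COL4A5")
  expect_true(res3$consistent)
  expect_true(is.na(res3$detail$ok[res3$detail$id == "f"]))
})

test_that("genotyped individuals missing from the pedigree raise an error", {
  ped <- make_trio()
  gt <- genotype_call("stranger", "COL4A3:c.3410G>A", 1)
  expect_error(segregates_exclusively("COL4A3:c.3410G>A", gt, ped, "COL4A3"),
               "not in pedigree")
})

test_that("segregation matches the brute-force oracle over nuclear pedigrees up to 6 members", {
  for (n_children in c(1L, 2L, 4L)) {
    n <- 2L + n_children
    ids <- c("fa", "mo", paste0("c", seq_len(n_children)))
    sexes <- c("male", "female",
               rep(c("male", "female"), length.out = n_children))
    ped <- pedigree("E", data.frame(
      id = ids, sex = sexes,
      affection = "unknown",
      father_id = c(NA, NA, rep("fa", n_children)),
      mother_id = c(NA, NA, rep("mo", n_children)),
      stringsAsFactors = FALSE))
    combos <- expand.grid(rep(list(0:3), n))  # 2 bits per member
    for (gene in c("COL4A3", "COL4A5")) {
      key <- paste0(gene, ":c.100A>G")
      for (r in seq_len(nrow(combos))) {
        state <- as.integer(combos[r, ])
        affection <- ifelse(state %% 2L == 0L, "unaffected", "affected")
        alleles <- state %/% 2L
        if (gene == "COL4A5") alleles <- pmin(alleles, ifelse(sexes == "male", 1L, 2L))
        ped$members$affection <- affection
        got <- segregates_exclusively(key, gt_for(ids, key, alleles), ped, gene)
        want <- oracle_segregation(
          data.frame(id = ids, sex = sexes, affection = affection,
                     allele_count = alleles, stringsAsFactors = FALSE), gene)
        if (got$consistent != want) {
          fail(sprintf("mismatch: gene=%s affection=%s alleles=%s",
                       gene, paste(affection, collapse = ","),
                       paste(alleles, collapse = ",")))
        }
      }
    }
  }
  succeed()
})

test_that("classify_variant reproduces the reference decisions", {
  cfg <- classification_config()
  # control-cohort polymorphism with MAF 0.121
  ann <- annotation_record("COL4A3:c.1721C>T", "polymorphism", "literature",
                           in_controls = TRUE, population_maf = 0.121)
  res <- classify_variant("COL4A3:c.1721C>T", "COL4A3", make_cons("MISSENSE"), ann)
  expect_equal(res$label, "POLYMORPHISM")

  # novel intronic splice-region variant, consistent segregation: presumed only
  ann2 <- annotation_record("COL4A5:c.1033-6A>G")
  res2 <- classify_variant("COL4A5:c.1033-6A>G", "COL4A5",
                           make_cons("SPLICE_REGION_INTRONIC"), ann2,
                           segregation = TRUE)
  expect_equal(res2$label, "PRESUMED_PATHOGENIC")
  expect_true(res2$novel)

  # published pathogenic missense
  ann3 <- annotation_record("COL4A4:c.2320G>C", "pathogenic", "literature")
  res3 <- classify_variant("COL4A4:c.2320G>C", "COL4A4", make_cons("MISSENSE"),
                           ann3, segregation = TRUE,
                           protein_change = parse_protein("p.Gly774Arg"))
  expect_equal(res3$label, "PATHOGENIC")
  expect_false(res3$novel)

  # novel canonical-consequence variant failing segregation stays VUS
  ann4 <- annotation_record("COL4A3:c.765+2T>C")
  res4 <- classify_variant("COL4A3:c.765+2T>C", "COL4A3", make_cons("SPLICE_DONOR"),
                           ann4, segregation = FALSE)
  expect_equal(res4$label, "VUS")

  # isolated individual: novel collagenous glycine capped at presumed
  ann5 <- annotation_record("COL4A5:c.1010G>T")
  res5 <- classify_variant("COL4A5:c.1010G>T", "COL4A5", make_cons("MISSENSE"),
                           ann5, segregation = NULL,
                           protein_change = parse_protein("p.Gly337Val"))
  expect_equal(res5$label, "PRESUMED_PATHOGENIC")

  expect_error(classify_variant("k", "COL4A3", make_cons("MISSENSE"), NULL),
               "annotation")
})

decision_grid <- function() {
  expand.grid(published = c("none", "polymorphism", "pathogenic"),
              in_controls = c(FALSE, TRUE),
              maf = c(NA, 0.001, 0.2),
              seg = c("none", "consistent", "inconsistent"),
              category = consequence_categories(),
              collagenous = c(FALSE, TRUE),
              stringsAsFactors = FALSE)
}

label_for <- function(row) {
  ann <- annotation_record("COL4A5:c.1871G>A", row$published,
                           in_controls = row$in_controls,
                           population_maf = row$maf)
  pc <- if (row$collagenous) parse_protein("p.Gly624Asp") else NULL
  seg <- switch(row$seg, none = NULL, consistent = TRUE, inconsistent = FALSE)
  classify_variant("COL4A5:c.1871G>A", "COL4A5", make_cons(row$category), ann,
                   segregation = seg, protein_change = pc)$label
}

test_that("decision table is complete and deterministic over all criteria combinations", {
  grid <- decision_grid()
  labels <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    labels[r] <- label_for(grid[r, ])
    expect_true(labels[r] %in% c("POLYMORPHISM", "PATHOGENIC",
                                 "PRESUMED_PATHOGENIC", "VUS"))
  }
  # deterministic: a second pass yields identical labels
  again <- vapply(seq_len(nrow(grid)), function(r) label_for(grid[r, ]), character(1))
  expect_identical(labels, again)
})

test_that("control-cohort presence never moves a variant toward pathogenic", {
  grid <- decision_grid()
  grid_f <- grid[!grid$in_controls, ]
  for (r in seq_len(nrow(grid_f))) {
    row <- grid_f[r, ]
    without <- label_for(row)
    row$in_controls <- TRUE
    with_ctrl <- label_for(row)
    expect_lte(label_rank(with_ctrl), label_rank(without))
  }
})

test_that("classify_cohort reproduces the packaged cohort counts", {
  cls <- classified_fixture()$classifications
  expect_equal(sum(cls$label == "POLYMORPHISM"), 21L)
  by_gene <- table(cls$gene[cls$label == "POLYMORPHISM"])
  expect_equal(as.integer(by_gene[c("COL4A3", "COL4A4", "COL4A5")]), c(11L, 9L, 1L))
  expect_equal(sum(cls$label != "POLYMORPHISM"), 17L)
  expect_equal(sum(cls$novel), 14L)
  expect_equal(sum(cls$label == "VUS"), 0L)
})

test_that("classify_cohort on an empty table returns an empty result", {
  empty <- data.frame(gene = character(), cdna = character(),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(classify_cohort(empty)), 0L)
})
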