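#' Simulation configuration
#'
#' Describes the world the synthetic-data generator emulates: a
#' multi-generation family segregating a causal COL4A variant configuration
#' under one of three inheritance modes, background polymorphisms at the
#' packaged population minor-allele frequencies, affection statuses derived
#' from the functional-trimer dosage model with Beta-distributed
#' X-inactivation skew, and a 66-person control cohort.
#'
#' @param mode Generating inheritance mode: \code{"X_LINKED_AS"},
#'   \code{"AUTOSOMAL_AS"} or \code{"FBH"}.
#' @param seed Integer seed fixing all randomness, or NA to use the current
#'   RNG state (useful inside replicate loops seeded once).
#' @param generations Number of generations to grow (default 3).
#' @param mean_sibship Mean number of children per couple (Poisson, minimum
#'   1; default 2.5).
#' @param background_maf_table data.frame (gene, cdna, maf) of background
#'   polymorphisms; defaults to the packaged population table (rows with a
#'   known MAF).
#' @param x_skew_beta_alpha Symmetry parameter of the Beta(alpha, alpha)
#'   distribution of the wild-type-active X fraction in heterozygous females.
#'   Default 5: mostly balanced inactivation with occasional marked skew.
#' @param thresholds [phenotype_thresholds()] mapping trimer dose to
#'   phenotype.
#' @param control_cohort_n Number of unrelated control individuals (default
#'   66).
#' @param causal_variants data.frame (gene, cdna, protein) of causal
#'   variants; defaults per mode use packaged mutation-table entries (one
#'   COL4A5 glycine substitution; two COL4A3 variants in trans; one
#'   heterozygous COL4A3 glycine substitution).
#' @param max_members Safety cap on family size (default 30).
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(mode = c("X_LINKED_AS", "AUTOSOMAL_AS", "FBH"),
                              seed = NA_integer_, generations = 3L,
                              mean_sibship = 2.5,
                              background_maf_table = NULL,
                              x_skew_beta_alpha = 5,
                              thresholds = phenotype_thresholds(),
                              control_cohort_n = 66L,
                              causal_variants = NULL,
                              max_members = 30L) {
  mode <- match.arg(mode)
  if (is.null(background_maf_table)) {
    tab <- fixture_polymorphisms()
    background_maf_table <- tab[!is.na(tab$maf), c("gene", "cdna", "maf")]
  }
  stopifnot(all(background_maf_table$maf >= 0 & background_maf_table$maf <= 1))
  if (is.null(causal_variants)) {
    causal_variants <- switch(mode,
      X_LINKED_AS = data.frame(gene = "COL4A5", cdna = "c.2741G>A",
                               protein = "p.Gly914Asp", stringsAsFactors = FALSE),
      AUTOSOMAL_AS = data.frame(gene = c("COL4A3", "COL4A3"),
                                cdna = c("c.687G>A", "c.3490G>T"),
                                protein = c(NA, "p.Gly1164Cys"),
                                stringsAsFactors = FALSE),
      FBH = data.frame(gene = "COL4A3", cdna = "c.3410G>A",
                       protein = "p.Gly1137Asp", stringsAsFactors = FALSE))
  }
  stopifnot(generations >= 2L, mean_sibship > 0, x_skew_beta_alpha > 0,
            control_cohort_n >= 1L)
  structure(list(mode = mode, seed = seed, generations = as.integer(generations),
                 mean_sibship = mean_sibship,
                 background_maf_table = background_maf_table,
                 x_skew_beta_alpha = x_skew_beta_alpha, thresholds = thresholds,
                 control_cohort_n = as.integer(control_cohort_n),
                 causal_variants = causal_variants,
                 max_members = as.integer(max_members)),
            class = "simulation_config")
}

maybe_seed <- function(seed) {
  if (!is.na(seed)) set.seed(as.integer(seed))
}

#' Mendelian transmission primitives
#'
#' `transmit_autosomal()` draws a child's allele count at an autosomal locus
#' from parental counts (one allele sampled per parent).  `transmit_x()`
#' draws a child's count at an X-linked locus: a carrier father transmits his
#' single X to every daughter and to no son; a mother transmits either X with
#' equal probability.  Both are vectorized over `n`.
#'
#' @param father_count,mother_count Parental allele counts (autosomal 0..2;
#'   X-linked father 0..1, mother 0..2).
#' @param child_sex For `transmit_x()`: "male" or "female".
#' @param n Number of independent transmissions to draw.
#' @return Integer vector of child allele counts.
#' @export
transmit_autosomal <- function(father_count, mother_count, n = 1L) {
  stopifnot(father_count %in% 0:2, mother_count %in% 0:2)
  stats::rbinom(n, 1L, father_count / 2) + stats::rbinom(n, 1L, mother_count / 2)
}

#' @rdname transmit_autosomal
#' @export
transmit_x <- function(father_count, mother_count, child_sex, n = 1L) {
  stopifnot(father_count %in% 0:1, mother_count %in% 0:2,
            child_sex %in% c("male", "female"))
  from_mother <- stats::rbinom(n, 1L, mother_count / 2)
  if (child_sex == "male") {
    from_mother                      # father contributes Y, never his X
  } else {
    from_mother + father_count       # father's X is obligately transmitted
  }
}

x_ploidy <- function(sex) ifelse(sex == "male", 1L, 2L)

#' Simulate one family segregating a causal COL4A genotype
#'
#' Grows a multi-generation pedigree from a founder couple, transmits the
#' causal variant(s) Mendelian-fashion (X-aware for COL4A5), draws background
#' polymorphism genotypes for founders at the population MAFs and transmits
#' them Mendelian-fashion, and derives every member's affection status from
#' the functional-trimer dosage model: a member is affected iff
#' [phenotype_class()] of their expected trimer fraction is not NORMAL.
#' Heterozygous-female COL4A5 trimer fractions are drawn from
#' Beta(alpha, alpha), so a minority of carrier females are non-penetrant.
#'
#' Mode seeding: X_LINKED_AS starts from a heterozygous founder mother;
#' AUTOSOMAL_AS from a founder couple each heterozygous for a different
#' variant of the same autosomal gene (trans by construction); FBH from a
#' single heterozygous founder mother.
#'
#' @param config A [simulation_config()].
#' @return List with \code{pedigree} (affection filled in), \code{genotypes}
#'   (data.frame individual_id, variant_key, allele_count; zero counts for
#'   causal variants are retained, background zeros dropped), and
#'   \code{truth}: the generating mode, causal variant keys, per-member
#'   trimer fraction and the ids of non-penetrant carriers.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  maybe_seed(config$seed)
  causal <- config$causal_variants
  causal_keys <- mapply(variant_key, causal$gene, causal$cdna, USE.NAMES = FALSE)
  bg <- config$background_maf_table
  bg_keys <- mapply(variant_key, bg$gene, bg$cdna, USE.NAMES = FALSE)

  # ---- containers -----------------------------------------------------------
  members <- data.frame(id = character(), sex = character(),
                        affection = character(), father_id = character(),
                        mother_id = character(), stringsAsFactors = FALSE)
  geno <- list()   # geno[[id]] = named integer vector over c(causal_keys, bg_keys)

  draw_background_founder <- function(sex) {
    counts <- integer(length(bg_keys))
    for (j in seq_along(bg_keys)) {
      ploidy <- if (is_x_linked(bg$gene[j])) x_ploidy(sex) else 2L
      counts[j] <- stats::rbinom(1L, ploidy, bg$maf[j])
    }
    counts
  }
  add_member <- function(id, sex, father_id = NA_character_,
                         mother_id = NA_character_, counts) {
    members[nrow(members) + 1L, ] <<- list(id, sex, "unknown", father_id, mother_id)
    geno[[id]] <<- stats::setNames(counts, c(causal_keys, bg_keys))
  }
  transmit_child <- function(father_id, mother_id, sex) {
    fa <- geno[[father_id]]; mo <- geno[[mother_id]]
    keys <- c(causal_keys, bg_keys)
    genes <- c(causal$gene, bg$gene)
    counts <- integer(length(keys))
    for (j in seq_along(keys)) {
      counts[j] <- if (is_x_linked(genes[j])) {
        transmit_x(fa[[j]], mo[[j]], sex)
      } else {
        transmit_autosomal(fa[[j]], mo[[j]])
      }
    }
    counts
  }

  # ---- founders -------------------------------------------------------------
  founder_causal <- function(role) {
    # returns causal allele counts for the founder father/mother per mode
    n <- nrow(causal)
    counts <- integer(n)
    if (config$mode == "X_LINKED_AS" && role == "mother") counts[1] <- 1L
    if (config$mode == "FBH" && role == "mother") counts[1] <- 1L
    if (config$mode == "AUTOSOMAL_AS") {
      if (role == "father") counts[1] <- 1L
      if (role == "mother") counts[2] <- 1L
    }
    counts
  }
  add_member("1-1", "male", counts = c(founder_causal("father"),
                                       draw_background_founder("male")))
  add_member("1-2", "female", counts = c(founder_causal("mother"),
                                         draw_background_founder("female")))

  # ---- grow generations -----------------------------------------------------
  couples <- list(c("1-1", "1-2"))
  counter <- 0L
  for (gen in 2:config$generations) {
    next_couples <- list()
    for (cp in couples) {
      if (nrow(members) >= config$max_members) break
      n_kids <- max(1L, stats::rpois(1L, config$mean_sibship))
      for (k in seq_len(n_kids)) {
        if (nrow(members) >= config$max_members) break
        counter <- counter + 1L
        sex <- sample(c("male", "female"), 1L)
        id <- sprintf("%d-%d", gen, counter)
        add_member(id, sex, father_id = cp[1], mother_id = cp[2],
                   counts = transmit_child(cp[1], cp[2], sex))
        if (gen < config$generations) {
          # marry in an unrelated, causal-free spouse
          counter <- counter + 1L
          spouse_sex <- if (sex == "male") "female" else "male"
          spouse_id <- sprintf("%d-%d", gen, counter)
          add_member(spouse_id, spouse_sex,
                     counts = c(integer(nrow(causal)),
                                draw_background_founder(spouse_sex)))
          pair <- if (sex == "male") c(id, spouse_id) else c(spouse_id, id)
          next_couples[[length(next_couples) + 1L]] <- pair
        }
      }
    }
    couples <- next_couples
  }

  # ---- affection from the dosage model -------------------------------------
  trimer <- numeric(nrow(members)); names(trimer) <- members$id
  for (i in seq_len(nrow(members))) {
    id <- members$id[i]; sex <- members$sex[i]
    counts <- geno[[id]][causal_keys]
    a3_mut <- sum(counts[causal$gene == "COL4A3"])
    a4_mut <- sum(counts[causal$gene == "COL4A4"])
    a5_mut <- sum(counts[causal$gene == "COL4A5"])
    a5_wt <- x_ploidy(sex) - a5_mut
    xfrac <- if (sex == "female" && a5_wt == 1L && a5_mut == 1L) {
      stats::rbeta(1L, config$x_skew_beta_alpha, config$x_skew_beta_alpha)
    } else 0.5
    g <- dosage_genotype(col4a3_wt = max(0L, 2L - a3_mut),
                         col4a4_wt = max(0L, 2L - a4_mut),
                         col4a5_wt = a5_wt, sex = sex,
                         x_wt_active_fraction = xfrac)
    trimer[i] <- functional_trimer_fraction(g)
    members$affection[i] <- if (phenotype_class(trimer[i], config$thresholds) ==
                                "NORMAL") "unaffected" else "affected"
  }

  ped <- pedigree("SIM", members)
  gt_rows <- lapply(members$id, function(id) {
    counts <- geno[[id]]
    keep <- counts > 0L | names(counts) %in% causal_keys
    data.frame(individual_id = id, variant_key = names(counts)[keep],
               allele_count = unname(counts[keep]), stringsAsFactors = FALSE)
  })
  genotypes <- do.call(rbind, gt_rows)
  carriers <- vapply(members$id, function(id) any(geno[[id]][causal_keys] > 0L),
                     logical(1))
  truth <- list(mode = config$mode, causal_variants = causal_keys,
                trimer_fraction = trimer,
                non_penetrant_carriers = members$id[carriers &
                                                      members$affection == "unaffected"])
  list(pedigree = ped, genotypes = genotypes, truth = truth)
}

#' Simulate a control cohort at stated allele frequencies
#'
#' Draws diploid genotypes (X-aware for COL4A5: one allele for males) for
#' \code{control_cohort_n} unrelated individuals at every variant in the
#' background MAF table, and estimates each MAF as allele count over allele
#' number.
#'
#' @param config A [simulation_config()].
#' @return List with \code{sexes}, \code{genotypes} (individuals x variants
#'   integer matrix of allele counts, columns named by variant key) and
#'   \code{maf_estimates} (data.frame: variant_key, gene, true_maf,
#'   allele_count, allele_number, estimated_maf, in_cohort).
#' @export
simulate_control_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  maybe_seed(config$seed)
  bg <- config$background_maf_table
  keys <- mapply(variant_key, bg$gene, bg$cdna, USE.NAMES = FALSE)
  n <- config$control_cohort_n
  sexes <- sample(c("male", "female"), n, replace = TRUE)
  gt <- matrix(0L, nrow = n, ncol = length(keys),
               dimnames = list(NULL, keys))
  for (j in seq_along(keys)) {
    ploidy <- if (is_x_linked(bg$gene[j])) x_ploidy(sexes) else rep(2L, n)
    gt[, j] <- stats::rbinom(n, ploidy, bg$maf[j])
  }
  allele_number <- vapply(seq_along(keys), function(j) {
    if (is_x_linked(bg$gene[j])) sum(x_ploidy(sexes)) else 2L * n
  }, integer(1))
  allele_count <- colSums(gt)
  est <- data.frame(variant_key = keys, gene = bg$gene, true_maf = bg$maf,
                    allele_count = allele_count, allele_number = allele_number,
                    estimated_maf = allele_count / allele_number,
                    in_cohort = allele_count > 0L,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(sexes = sexes, genotypes = gt, maf_estimates = est)
}

#' Simulate a per-base amplicon depth track
#'
#' Independent negative-binomial per-base depths, the standard
#' overdispersed model for amplicon coverage.
#'
#' @param n_bases Number of target bases (e.g. a [target_region_set()]'s
#'   \code{total_bp}).
#' @param mean Mean depth (> 0).
#' @param dispersion Negative-binomial size parameter (> 0); variance is
#'   \code{mean + mean^2 / dispersion}, approaching Poisson as dispersion
#'   grows.
#' @param seed Seed, or NA for the current RNG state.
#' @return Integer vector of depths, length \code{n_bases}.
#' @export
simulate_depth_track <- function(n_bases, mean, dispersion, seed = NA_integer_) {
  if (mean <= 0 || dispersion <= 0) {
    stop("mean and dispersion must be positive", call. = FALSE)
  }
  maybe_seed(seed)
  stats::rnbinom(n_bases, mu = mean, size = dispersion)
}

#' Re-diagnose a simulated family through the full pipeline
#'
#' Builds the observed variant table of a simulated family (every variant
#' carried by at least one member), annotates it honestly — background
#' variants matching the population table get their published-polymorphism
#' status and MAF, causal variants are unpublished with no population record —
#' and runs [diagnose_family()] (consequence, segregation, rule engine,
#' family classifier).  Used by the end-to-end mode-recovery validation.
#'
#' @param sim Output of [simulate_family()].
#' @param config The [simulation_config()] that generated it.
#' @return The [diagnose_family()] result list.
#' @export
rediagnose_simulated_family <- function(sim, config) {
  keys <- unique(sim$genotypes$variant_key[sim$genotypes$allele_count > 0L])
  if (!length(keys)) {
    return(list(classifications = data.frame(), segregation = list(),
                diagnosis = classify_family(NULL, family_id = sim$pedigree$family_id)))
  }
  bg <- config$background_maf_table
  bg_keys <- mapply(variant_key, bg$gene, bg$cdna, USE.NAMES = FALSE)
  vt <- data.frame(gene = sub(":.*$", "", keys), cdna = sub("^[^:]+:", "", keys),
                   stringsAsFactors = FALSE)
  m <- match(keys, bg_keys)
  vt$published_status <- ifelse(is.na(m), "none", "polymorphism")
  vt$maf <- bg$maf[m]
  vt$in_controls <- !is.na(m)
  cv <- config$causal_variants
  ck <- mapply(variant_key, cv$gene, cv$cdna, USE.NAMES = FALSE)
  vt$protein <- if ("protein" %in% names(cv)) cv$protein[match(keys, ck)] else
    NA_character_
  diagnose_family(vt, sim$pedigree, sim$genotypes)
}
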