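#' Family-level inheritance-mode diagnosis
#'
#' Given the pathogenic (or presumed pathogenic) variants identified in a
#' family, assigns the inheritance-mode diagnosis:
#' \itemize{
#'   \item any COL4A5 variant: \code{X_LINKED_AS};
#'   \item two distinct variants in the same autosomal gene, or one homozygous
#'     autosomal variant: \code{AUTOSOMAL_AS} (autosomal \emph{semi-dominant}
#'     Alport; heterozygous relatives express the intermediate FBH phenotype);
#'   \item exactly one heterozygous autosomal variant: \code{FBH};
#'   \item one variant in each of COL4A3 and COL4A4: \code{DIGENIC_FLAG},
#'     emitted with a warning (no validated case exercises it);
#'   \item none: \code{UNRESOLVED}.
#' }
#' The vocabulary deliberately contains no "autosomal dominant AS": the dosage
#' model gives that term no biological basis for a heterotrimeric collagen.
#' When both COL4A5 and autosomal variants are present the COL4A5 diagnosis is
#' returned with a composite flag rather than an error.
#'
#' @param variants data.frame with one row per pathogenic variant and columns
#'   \code{variant_key}, \code{gene}, \code{zygosity} ("heterozygous" /
#'   "homozygous" / "hemizygous").
#' @param phase For two same-gene autosomal variants: \code{"trans"} (proven
#'   on opposite haplotypes), \code{"cis"} (proven on one haplotype: the
#'   family is FBH, not autosomal AS) or \code{"unknown"} (default; autosomal
#'   AS is reported with a phase caveat).
#' @param family_id Identifier carried into the result.
#' @return Object of class \code{"family_diagnosis"}: list with
#'   \code{family_id}, \code{mode}, \code{supporting_variants},
#'   \code{composite} (logical), \code{caveats} (character).
#' @examples
#' v <- data.frame(variant_key = c("COL4A3:c.687G>A", "COL4A3:c.3490G>T"),
#'                 gene = "COL4A3", zygosity = "heterozygous")
#' classify_family(v, family_id = "F4")$mode
#' @export
classify_family <- function(variants, phase = c("unknown", "trans", "cis"),
                            family_id = NA_character_) {
  phase <- match.arg(phase)
  if (is.null(variants) || nrow(variants) == 0L) {
    return(new_family_diagnosis(family_id, "UNRESOLVED", character()))
  }
  stopifnot(all(c("variant_key", "gene") %in% names(variants)))
  zyg <- if ("zygosity" %in% names(variants)) variants$zygosity else
    rep("heterozygous", nrow(variants))
  keys <- variants$variant_key
  caveats <- character()

  x_rows <- variants$gene == "COL4A5"
  auto <- variants[!x_rows, , drop = FALSE]
  auto_zyg <- zyg[!x_rows]

  if (any(x_rows)) {
    composite <- nrow(auto) > 0L
    if (composite) {
      caveats <- c(caveats, sprintf(
        "composite genotype: autosomal pathogenic variant(s) %s present alongside COL4A5",
        paste(auto$variant_key, collapse = ", ")))
    }
    return(new_family_diagnosis(family_id, "X_LINKED_AS", keys,
                                composite = composite, caveats = caveats))
  }

  genes <- unique(auto$gene)
  per_gene <- table(auto$gene)
  if (length(genes) == 2L && all(c("COL4A3", "COL4A4") %in% genes) &&
      all(per_gene == 1L) && all(auto_zyg == "heterozygous")) {
    warning("digenic COL4A3 + COL4A4 genotype: no validated reference case; ",
            "review manually", call. = FALSE)
    return(new_family_diagnosis(family_id, "DIGENIC_FLAG", keys,
                                caveats = "digenic genotype, unvalidated mode"))
  }
  biallelic <- any(per_gene >= 2L) || any(auto_zyg == "homozygous")
  if (biallelic) {
    if (phase == "cis") {
      return(new_family_diagnosis(
        family_id, "FBH", keys,
        caveats = "two variants proven on one haplotype: single functional hit"))
    }
    if (phase == "unknown" && !any(auto_zyg == "homozygous")) {
      caveats <- c(caveats, "phase unknown: autosomal AS assumes trans configuration")
    }
    return(new_family_diagnosis(family_id, "AUTOSOMAL_AS", keys, caveats = caveats))
  }
  if (nrow(auto) == 1L) {
    return(new_family_diagnosis(family_id, "FBH", keys))
  }
  # >2 variants across genes etc.: conservative
  new_family_diagnosis(family_id, "UNRESOLVED", keys,
                       caveats = "variant configuration not interpretable")
}

new_family_diagnosis <- function(family_id, mode, supporting, composite = FALSE,
                                 caveats = character()) {
  stopifnot(mode %in% c("X_LINKED_AS", "AUTOSOMAL_AS", "FBH", "DIGENIC_FLAG",
                        "UNRESOLVED"))
  structure(list(family_id = family_id, mode = mode,
                 supporting_variants = supporting, composite = composite,
                 caveats = caveats),
            class = "family_diagnosis")
}

#' @export
print.family_diagnosis <- function(x, ...) {
  cat(sprintf("<family_diagnosis %s: %s [%s]>\n", x$family_id, x$mode,
              paste(x$supporting_variants, collapse = ", ")))
  if (length(x$caveats)) cat("  caveat:", paste(x$caveats, collapse = "; "), "\n")
  invisible(x)
}

#' Dosage genotype for the functional triple-helix model
#'
#' @param col4a3_wt,col4a4_wt Functional (wild-type) allele counts, 0..2.
#' @param col4a5_wt Functional COL4A5 allele count: 0..1 for males, 0..2 for
#'   females.
#' @param sex \code{"male"} or \code{"female"}.
#' @param x_wt_active_fraction For heterozygous females, the fraction of
#'   collagen-producing cells expressing the wild-type COL4A5 allele (1 minus
#'   the X-inactivation skew toward the wild-type X).  0.5 under balanced
#'   inactivation.  Forced to 1 when both X alleles are wild type and 0 when
#'   both are mutant.
#' @return Object of class \code{"dosage_genotype"}.
#' @export
dosage_genotype <- function(col4a3_wt = 2L, col4a4_wt = 2L, col4a5_wt = NULL,
                            sex = c("female", "male"), x_wt_active_fraction = 0.5) {
  sex <- match.arg(sex)
  if (is.null(col4a5_wt)) col4a5_wt <- if (sex == "male") 1L else 2L
  col4a3_wt <- as.integer(col4a3_wt); col4a4_wt <- as.integer(col4a4_wt)
  col4a5_wt <- as.integer(col4a5_wt)
  stopifnot(col4a3_wt %in% 0:2, col4a4_wt %in% 0:2)
  if (sex == "male" && !col4a5_wt %in% 0:1) {
    stop("males are hemizygous: col4a5_wt must be 0 or 1", call. = FALSE)
  }
  if (sex == "female" && !col4a5_wt %in% 0:2) {
    stop("col4a5_wt must be 0, 1 or 2 for females", call. = FALSE)
  }
  if (x_wt_active_fraction < 0 || x_wt_active_fraction > 1) {
    stop("x_wt_active_fraction must be in [0, 1]", call. = FALSE)
  }
  if (sex == "female") {
    if (col4a5_wt == 2L) x_wt_active_fraction <- 1
    if (col4a5_wt == 0L) x_wt_active_fraction <- 0
  }
  structure(list(col4a3_wt = col4a3_wt, col4a4_wt = col4a4_wt,
                 col4a5_wt = col4a5_wt, sex = sex,
                 x_wt_active_fraction = x_wt_active_fraction),
            class = "dosage_genotype")
}

#' Expected fraction of fully functional collagen IV triple helix
#'
#' The alpha3.alpha4.alpha5 protomer needs one functional chain of each kind.
#' With autosomal chains contributed equally by both alleles, a heterozygote
#' supplies half the functional chain dose; for COL4A5, males are hemizygous
#' (all-or-nothing) and a heterozygous female contributes the fraction of
#' cells whose active X carries the wild-type allele.  The model is
#' multiplicative:
#' \deqn{f = (a3_{wt}/2) (a4_{wt}/2) x}
#' with \eqn{x} the COL4A5 term (allele count for males,
#' \code{x_wt_active_fraction} for females).
#'
#' @param g A [dosage_genotype()].
#' @return Fraction in \[0, 1\].
#' @examples
#' functional_trimer_fraction(dosage_genotype(col4a3_wt = 1))           # 0.5
#' functional_trimer_fraction(dosage_genotype(sex = "male", col4a5_wt = 0))  # 0
#' @export
functional_trimer_fraction <- function(g) {
  stopifnot(inherits(g, "dosage_genotype"))
  x_term <- if (g$sex == "male") g$col4a5_wt else g$x_wt_active_fraction
  f <- (g$col4a3_wt / 2) * (g$col4a4_wt / 2) * x_term
  stopifnot(f >= 0, f <= 1)
  f
}

#' Functional-molecule fraction under homotypic random assembly
#'
#' Comparison model for collagens whose molecules are built from identical
#' chains of one autosomal gene (homodimer/homotrimer assembly, as in type I
#' or type VII collagen).  With random chain pickup, a molecule is functional
#' only if every chain drawn is wild type, so a heterozygote (wild-type chain
#' fraction 1/2) retains 1/4 of functional two-chain molecules and 1/8 of
#' three-chain molecules — the dominant-negative effect, stronger than the
#' ~50% retained under a null allele.  The heterotrimeric
#' alpha3.alpha4.alpha5 molecule does not follow this model, which is why a
#' single autosomal COL4A3/COL4A4 hit produces only the benign-hematuria dose
#' reduction.
#'
#' @param chains_per_molecule 2 or 3: chains drawn from the affected gene.
#' @param wt_chain_fraction Fraction of wild-type chains in the pool.
#' @return \code{wt_chain_fraction ^ chains_per_molecule}.
#' @examples
#' homotypic_assembly_fraction(2, 0.5)  # 0.25
#' @export
homotypic_assembly_fraction <- function(chains_per_molecule, wt_chain_fraction) {
  if (!chains_per_molecule %in% c(2L, 3L)) {
    stop("chains_per_molecule must be 2 or 3", call. = FALSE)
  }
  if (wt_chain_fraction < 0 || wt_chain_fraction > 1) {
    stop("wt_chain_fraction must be in [0, 1]", call. = FALSE)
  }
  wt_chain_fraction^chains_per_molecule
}

#' Default phenotype thresholds on the functional-trimer fraction
#'
#' The disease spectrum is continuous in the functional-collagen dose; these
#' cutoffs discretize it for simulation and reporting and are configurable.
#'
#' @param normal_min Minimum fraction called clinically normal (default 0.75).
#' @param severe_max Fraction below which severe Alport is expected (default
#'   0.25).
#' @return Named list.
#' @export
phenotype_thresholds <- function(normal_min = 0.75, severe_max = 0.25) {
  stopifnot(severe_max < normal_min, normal_min <= 1, severe_max >= 0)
  list(normal_min = normal_min, severe_max = severe_max)
}

#' Map a functional-trimer fraction to a phenotype class
#'
#' @param f Fraction in \[0, 1\] (vectorized).
#' @param thresholds A [phenotype_thresholds()].
#' @return Character vector: \code{"NORMAL"} (f >= normal_min),
#'   \code{"FBH_TBMN_SPECTRUM"} (intermediate) or \code{"AS_SEVERE"}
#'   (f < severe_max); severity is monotone non-increasing in f.
#' @examples
#' phenotype_class(c(1, 0.5, 0))
#' @export
phenotype_class <- function(f, thresholds = phenotype_thresholds()) {
  stopifnot(all(f >= 0 & f <= 1))
  ifelse(f >= thresholds$normal_min, "NORMAL",
         ifelse(f < thresholds$severe_max, "AS_SEVERE", "FBH_TBMN_SPECTRUM"))
}
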