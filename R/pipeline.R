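#' End-to-end diagnosis of one family
#'
#' Glue over the full pipeline: assigns consequences, evaluates exclusive
#' segregation of each variant against the pedigree, classifies each variant
#' with the rule engine, and calls the family inheritance mode from the
#' variants classified PATHOGENIC or PRESUMED_PATHOGENIC.
#'
#' @param variants data.frame with columns \code{gene}, \code{cdna}, optional
#'   \code{protein}, and the annotation columns accepted by
#'   [classify_cohort()] (\code{published_status}, \code{in_controls},
#'   \code{maf}, ...).
#' @param ped A [pedigree()], or NULL for an isolated individual (criterion 4
#'   becomes "not evaluable").
#' @param genotypes data.frame of genotype calls for the family, or NULL.
#' @param transcripts Named list of transcript models.
#' @param config A [classification_config()].
#' @param domains Collagenous domain map.
#' @return List with \code{classifications} (the [classify_cohort()] table),
#'   \code{segregation} (list of segregation results by variant key) and
#'   \code{diagnosis} (a \code{"family_diagnosis"}).
#' @export
diagnose_family <- function(variants, ped = NULL, genotypes = NULL,
                            transcripts = default_transcript_models(),
                            config = classification_config(),
                            domains = default_collagenous_domains()) {
  keys <- mapply(variant_key, variants$gene, variants$cdna, USE.NAMES = FALSE)
  segs <- list()
  seg_col <- rep(NA_character_, length(keys))
  if (!is.null(ped) && !is.null(genotypes) && nrow(genotypes)) {
    for (i in seq_along(keys)) {
      if (!keys[i] %in% genotypes$variant_key) next
      s <- segregates_exclusively(keys[i], genotypes, ped, variants$gene[i], config)
      segs[[keys[i]]] <- s
      seg_col[i] <- if (s$consistent) "consistent" else "inconsistent"
    }
  }
  vt <- variants
  vt$segregation <- seg_col
  cls <- classify_cohort(vt, transcripts = transcripts, config = config,
                         domains = domains)
  path <- cls[cls$label %in% c("PATHOGENIC", "PRESUMED_PATHOGENIC"), , drop = FALSE]
  zygosity <- vapply(path$variant_key, function(k) {
    if (is.null(genotypes) || !k %in% genotypes$variant_key) return("heterozygous")
    counts <- genotypes$allele_count[genotypes$variant_key == k]
    gene <- sub(":.*$", "", k)
    if (any(counts >= 2L)) "homozygous"
    else if (is_x_linked(gene)) "hemizygous"
    else "heterozygous"
  }, character(1))
  diag <- classify_family(
    data.frame(variant_key = path$variant_key, gene = path$gene,
               zygosity = zygosity, stringsAsFactors = FALSE),
    family_id = if (is.null(ped)) NA_character_ else ped$family_id)
  list(classifications = cls, segregation = segs, diagnosis = diag)
}

#' Reproduce the packaged reference analysis
#'
#' Runs the rule engine over the packaged fixture bundle (the merged
#' polymorphism and mutation tables) and the family classifier over the
#' packaged case roster, returning the headline counts: polymorphisms by
#' gene, novel mutations by gene, consequence tallies and the
#' inheritance-mode tally over the 17 cases.
#'
#' @param config A [classification_config()].
#' @return List with \code{classifications}, \code{summary},
#'   \code{diagnoses} (list of \code{"family_diagnosis"}), \code{mode_tally},
#'   \code{consequence_tally} and \code{novel_by_gene}.
#' @export
reproduce_reference_analysis <- function(config = classification_config()) {
  bundle <- fixture_bundle()
  cls <- classify_cohort(bundle$variants, transcripts = bundle$transcripts,
                         config = config, domains = bundle$domains)
  summ <- classification_summary(cls)

  roster <- bundle$roster
  diagnoses <- lapply(seq_len(nrow(roster)), function(i) {
    keys <- strsplit(roster$variant_keys[i], ";", fixed = TRUE)[[1]]
    sel <- cls[match(keys, cls$variant_key), , drop = FALSE]
    if (anyNA(sel$variant_key)) {
      stop("roster case ", roster$case_id[i], " references unknown variant(s)",
           call. = FALSE)
    }
    sel <- sel[sel$label %in% c("PATHOGENIC", "PRESUMED_PATHOGENIC"), , drop = FALSE]
    zyg <- ifelse(sel$gene == "COL4A5", "hemizygous", "heterozygous")
    classify_family(data.frame(variant_key = sel$variant_key, gene = sel$gene,
                               zygosity = zyg, stringsAsFactors = FALSE),
                    family_id = roster$case_id[i])
  })
  modes <- vapply(diagnoses, function(d) d$mode, character(1))
  mut <- cls[cls$label != "POLYMORPHISM", , drop = FALSE]
  consequence_tally <- list(
    missense = sum(mut$consequence == "MISSENSE"),
    splice = sum(mut$consequence %in% c("SPLICE_DONOR", "SPLICE_ACCEPTOR",
                                        "SPLICE_REGION_EXONIC",
                                        "SPLICE_REGION_INTRONIC")),
    deletion_with_splice = sum(mut$consequence == "DELETION_WITH_SPLICE"),
    collagenous_glycine = sum(mut$collagenous_glycine)
  )
  list(
    classifications = cls,
    summary = summ,
    diagnoses = diagnoses,
    mode_tally = table(factor(modes, levels = c("X_LINKED_AS", "AUTOSOMAL_AS",
                                                "FBH", "DIGENIC_FLAG",
                                                "UNRESOLVED"))),
    consequence_tally = consequence_tally,
    novel_by_gene = table(factor(mut$gene[mut$novel],
                                 levels = col4a_genes()$name))
  )
}
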