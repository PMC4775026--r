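#' Annotation evidence for one variant
#'
#' Collects the external evidence the four-criterion rule engine consumes:
#' database status, control-cohort presence and population allele frequency.
#'
#' @param variant_key Canonical key (see [variant_key()]).
#' @param published_status \code{"none"}, \code{"polymorphism"} or
#'   \code{"pathogenic"}.
#' @param source Free-text source label (database or citation), or NA.
#' @param in_controls Logical: was the variant observed in the control cohort?
#' @param population_maf Minor allele frequency in \[0, 1\], or NA when
#'   unknown.
#' @param note Optional free-text caveat (e.g. conflicting publications);
#'   carried into the criteria trace.
#' @return Object of class \code{"annotation_record"}.
#' @export
annotation_record <- function(variant_key, published_status = "none",
                              source = NA_character_, in_controls = FALSE,
                              population_maf = NA_real_, note = NA_character_) {
  published_status <- match.arg(published_status, c("none", "polymorphism", "pathogenic"))
  if (!is.na(population_maf) && (population_maf < 0 || population_maf > 1)) {
    stop("population_maf must be in [0, 1]", call. = FALSE)
  }
  structure(list(variant_key = variant_key, published_status = published_status,
                 source = source, in_controls = isTRUE(in_controls),
                 population_maf = population_maf, note = note),
            class = "annotation_record")
}

#' Rule-engine configuration
#'
#' @param common_maf_threshold Allele frequency at or above which a variant is
#'   a common allele (criterion 3 fails).  Default 0.01, the conventional
#'   rare-disease cutoff; the engine's published polymorphisms are caught by
#'   the control-cohort criterion regardless.
#' @param autosomal_segregation \code{"strict"} (an unaffected carrier of an
#'   autosomal variant falsifies co-segregation) or \code{"penetrance_tolerant"}
#'   (unaffected carriers are tolerated, for late-onset thin-membrane
#'   phenotypes).  Default strict.
#' @return Object of class \code{"classification_config"}.
#' @export
classification_config <- function(common_maf_threshold = 0.01,
                                  autosomal_segregation = c("strict", "penetrance_tolerant")) {
  autosomal_segregation <- match.arg(autosomal_segregation)
  stopifnot(common_maf_threshold > 0, common_maf_threshold <= 1)
  structure(list(common_maf_threshold = common_maf_threshold,
                 autosomal_segregation = autosomal_segregation),
            class = "classification_config")
}

#' Test exclusive segregation of a variant with affection status
#'
#' Implements the co-segregation criterion: the variant's presence must be
#' \emph{exclusive to affected family members}.  Concretely, consistency
#' requires (a) no disallowed unaffected carrier — for autosomal variants in
#' strict mode any unaffected carrier falsifies, and an unaffected male
#' carrier of a COL4A5 variant falsifies, while an \emph{unaffected female
#' COL4A5 carrier does not}, because random X-inactivation makes the female
#' carrier phenotype variable — and (b) at least one affected carrier, when
#' any genotyped member is affected at all.  An affected member who does
#' \emph{not} carry the variant is recorded but is not counter-evidence: in a
#' compound-heterozygous family each parent carries only one of the two
#' causal variants, yet both segregate exclusively with affection.  Members
#' with unknown affection, and members without a genotype record, are
#' skipped.
#'
#' @param variant_key Canonical variant key.
#' @param genotypes data.frame of genotype calls (\code{individual_id},
#'   \code{variant_key}, \code{allele_count}); rows for other variants are
#'   ignored.
#' @param ped A [pedigree()]; every genotyped individual must be a member.
#' @param gene Gene symbol (decides autosomal vs X-linked rules).
#' @param config A [classification_config()].
#' @return Object of class \code{"segregation_result"}: list with
#'   \code{variant_key}, \code{family_id}, \code{consistent} (logical) and
#'   \code{detail}, a per-individual data.frame with columns \code{id},
#'   \code{sex}, \code{affection}, \code{allele_count}, \code{ok},
#'   \code{reason}.
#' @export
segregates_exclusively <- function(variant_key, genotypes, ped, gene,
                                   config = classification_config()) {
  stopifnot(inherits(ped, "pedigree"))
  gene_info(gene)
  g <- genotypes[genotypes$variant_key == variant_key, , drop = FALSE]
  missing <- setdiff(g$individual_id, ped$members$id)
  if (length(missing)) {
    stop("genotyped individual(s) not in pedigree ", ped$family_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x_linked <- is_x_linked(gene)
  tolerant <- config$autosomal_segregation == "penetrance_tolerant"
  rows <- lapply(seq_len(nrow(g)), function(i) {
    id <- g$individual_id[i]
    ac <- g$allele_count[i]
    m <- ped$members[ped$members$id == id, ]
    if (m$affection == "unknown") {
      return(data.frame(id = id, sex = m$sex, affection = m$affection,
                        allele_count = ac, ok = NA,
                        reason = "unknown affection: skipped",
                        stringsAsFactors = FALSE))
    }
    carrier <- ac > 0L
    affected <- m$affection == "affected"
    if (affected && !carrier) {
      # neutral: this member may carry a second causal variant (compound het)
      ok <- NA
      reason <- "affected member without this variant: not counter-evidence"
    } else if (affected) {
      ok <- TRUE; reason <- "affected carrier"
    } else if (!carrier) {
      ok <- TRUE; reason <- "unaffected non-carrier"
    } else if (!x_linked) {
      ok <- tolerant
      reason <- if (tolerant) "unaffected carrier tolerated (penetrance-tolerant mode)"
        else "unaffected member carries an autosomal variant"
    } else if (m$sex == "male") {
      ok <- FALSE; reason <- "unaffected male carries the X-linked variant"
    } else {
      ok <- TRUE; reason <- "unaffected female carrier: allowed (X-inactivation)"
    }
    data.frame(id = id, sex = m$sex, affection = m$affection, allele_count = ac,
               ok = ok, reason = reason, stringsAsFactors = FALSE)
  })
  detail <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), sex = character(), affection = character(),
               allele_count = integer(), ok = logical(), reason = character(),
               stringsAsFactors = FALSE)
  has_affected <- any(detail$affection == "affected")
  has_affected_carrier <- any(detail$affection == "affected" & detail$allele_count > 0L)
  structure(list(variant_key = variant_key, family_id = ped$family_id,
                 consistent = !any(detail$ok %in% FALSE) &&
                   (!has_affected || has_affected_carrier),
                 detail = detail),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation %s in %s: %s>\n", x$variant_key, x$family_id,
              if (x$consistent) "consistent" else "inconsistent"))
  invisible(x)
}

canonical_pathogenic_consequence <- function(consequence, collagenous_gly) {
  cat <- consequence$category
  (cat == "MISSENSE" && (isTRUE(collagenous_gly) ||
                         isTRUE(consequence$secondary_splice_region))) ||
    cat %in% c("SPLICE_DONOR", "SPLICE_ACCEPTOR", "DELETION_WITH_SPLICE",
               "SPLICE_REGION_EXONIC")
}

#' Classify one variant with the four-criterion rule engine
#'
#' The four criteria are: (1) previously published or present in mutation
#' databases; (2) not found among population controls; (3) not a common
#' allele; (4) exclusive presence among affected family members genetically
#' proven.  The label is a deterministic function of the criteria outcomes
#' and the molecular consequence; no in-silico prediction score enters the
#' decision.
#'
#' Decision order: control-cohort presence, a published-polymorphism status or
#' a common allele frequency yields \code{POLYMORPHISM}; a
#' published-pathogenic variant whose carriers are confined to affected
#' members (where family data exist) yields \code{PATHOGENIC}; otherwise a
#' novel variant absent from controls, not common and with consistent
#' segregation yields \code{PATHOGENIC} for canonical consequences
#' (collagenous-glycine missense, canonical-splice-site disrupting missense,
#' splice donor/acceptor, splice-affecting deletion, exonic splice region) or
#' \code{PRESUMED_PATHOGENIC} for an intronic splice-region change; when no
#' family data exist criterion 4 is "not evaluable" and a novel variant can
#' reach at most \code{PRESUMED_PATHOGENIC}; anything else is \code{VUS}.
#'
#' @param variant_key Canonical key.
#' @param gene Gene symbol.
#' @param consequence A \code{"consequence"} from [classify_consequence()].
#' @param annotation An [annotation_record()].
#' @param segregation A \code{"segregation_result"}, a logical scalar
#'   (precomputed consistency), or NULL when no family data exist.
#' @param protein_change Optional \code{"protein_change"}; used for the
#'   collagenous-glycine rule.
#' @param config A [classification_config()].
#' @param domains Collagenous domain map.
#' @return Object of class \code{"classification_result"}: list with
#'   \code{variant_key}, \code{label}, \code{novel} (unpublished and
#'   mutation-classified), and \code{criteria_trace} (named list of
#'   per-criterion outcome and evidence strings).
#' @export
classify_variant <- function(variant_key, gene, consequence, annotation,
                             segregation = NULL, protein_change = NULL,
                             config = classification_config(),
                             domains = default_collagenous_domains()) {
  stopifnot(inherits(consequence, "consequence"))
  if (!inherits(annotation, "annotation_record")) {
    stop("annotation record is required for classification", call. = FALSE)
  }
  seg_state <- if (is.null(segregation)) {
    "not_evaluable"
  } else if (inherits(segregation, "segregation_result")) {
    if (segregation$consistent) "consistent" else "inconsistent"
  } else if (is.logical(segregation) && length(segregation) == 1L && !is.na(segregation)) {
    if (segregation) "consistent" else "inconsistent"
  } else {
    stop("segregation must be a segregation_result, a logical scalar, or NULL",
         call. = FALSE)
  }

  collagenous <- !is.null(protein_change) &&
    is_collagenous_glycine_substitution(protein_change, gene, domains)
  maf <- annotation$population_maf
  common <- !is.na(maf) && maf >= config$common_maf_threshold

  trace <- list(
    published = list(
      outcome = annotation$published_status != "none",
      evidence = sprintf("published_status=%s source=%s", annotation$published_status,
                         if (is.na(annotation$source)) "-" else annotation$source)),
    absent_from_controls = list(
      outcome = !annotation$in_controls,
      evidence = if (annotation$in_controls) "observed in control cohort" else
        "not observed in control cohort"),
    not_common_allele = list(
      outcome = !common,
      evidence = if (is.na(maf)) "population MAF unknown" else
        sprintf("population MAF %.4g vs threshold %.4g", maf, config$common_maf_threshold)),
    exclusive_segregation = list(
      outcome = if (seg_state == "not_evaluable") NA else seg_state == "consistent",
      evidence = seg_state)
  )
  if (!is.na(annotation$note)) trace$note <- list(outcome = NA, evidence = annotation$note)

  label <- if (annotation$in_controls ||
               annotation$published_status == "polymorphism" || common) {
    "POLYMORPHISM"
  } else if (annotation$published_status == "pathogenic" &&
             seg_state %in% c("consistent", "not_evaluable")) {
    "PATHOGENIC"
  } else if (seg_state == "consistent") {
    if (canonical_pathogenic_consequence(consequence, collagenous)) "PATHOGENIC"
    else if (consequence$category == "SPLICE_REGION_INTRONIC") "PRESUMED_PATHOGENIC"
    else "VUS"
  } else if (seg_state == "not_evaluable") {
    if (canonical_pathogenic_consequence(consequence, collagenous) ||
        consequence$category == "SPLICE_REGION_INTRONIC") "PRESUMED_PATHOGENIC"
    else "VUS"
  } else {
    "VUS"
  }

  structure(list(
    variant_key = variant_key, gene = gene, label = label,
    consequence = consequence$category,
    collagenous_glycine = collagenous,
    novel = annotation$published_status == "none" &&
      label %in% c("PATHOGENIC", "PRESUMED_PATHOGENIC"),
    criteria_trace = trace
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification %s: %s (%s%s)>\n", x$variant_key, x$label,
              x$consequence, if (x$novel) ", novel" else ""))
  invisible(x)
}

#' Classify a variant cohort table
#'
#' Applies [classify_variant()] row by row to a cohort table such as the
#' packaged fixture bundle, first assigning molecular consequences with the
#' transcript models.
#'
#' @param variants data.frame with columns \code{gene}, \code{cdna}, and
#'   optionally \code{protein} (HGVS p. description or NA),
#'   \code{published_status}, \code{source}, \code{in_controls}, \code{maf},
#'   \code{segregation} ("consistent" / "inconsistent" / NA = not evaluable)
#'   and \code{note}.  Missing evidence columns default to no evidence.
#' @param transcripts Named list of \code{"transcript_model"}s keyed by gene;
#'   defaults to the packaged models.
#' @param config A [classification_config()].
#' @param domains Collagenous domain map.
#' @return data.frame with one row per variant: key, gene, cdna, protein,
#'   consequence (primary category), secondary splice flag,
#'   collagenous-glycine flag, label, novel flag, and per-criterion trace
#'   columns.  The full \code{classification_result} objects are attached as
#'   attribute \code{"results"}.
#' @export
classify_cohort <- function(variants, transcripts = default_transcript_models(),
                            config = classification_config(),
                            domains = default_collagenous_domains()) {
  n <- nrow(variants)
  col_or <- function(name, default) {
    if (name %in% names(variants)) variants[[name]] else rep(default, n)
  }
  published <- col_or("published_status", "none")
  src <- col_or("source", NA_character_)
  in_ctrl <- col_or("in_controls", FALSE)
  maf <- col_or("maf", NA_real_)
  seg <- col_or("segregation", NA_character_)
  note <- col_or("note", NA_character_)
  prot <- col_or("protein", NA_character_)

  results <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gene <- variants$gene[i]
    parsed <- parse_cdna(variants$cdna[i], gene)
    pc <- if (!is.na(prot[i]) && nzchar(prot[i])) parse_protein(prot[i]) else NULL
    tx <- transcripts[[gene]]
    if (is.null(tx)) stop("no transcript model for gene ", gene, call. = FALSE)
    cons <- classify_consequence(parsed, pc, tx)
    ann <- annotation_record(variant_key(gene, variants$cdna[i]),
                             published_status = published[i], source = src[i],
                             in_controls = isTRUE(in_ctrl[i]),
                             population_maf = maf[i], note = note[i])
    seg_arg <- if (is.na(seg[i])) NULL else identical(seg[i], "consistent")
    res <- classify_variant(ann$variant_key, gene, cons, ann, seg_arg, pc,
                            config, domains)
    results[[i]] <- res
    tr <- res$criteria_trace
    rows[[i]] <- data.frame(
      variant_key = res$variant_key, gene = gene,
      cdna = gsub("[[:space:]]+", "", variants$cdna[i]),
      protein = prot[i],
      consequence = cons$category,
      secondary_splice_region = isTRUE(cons$secondary_splice_region),
      collagenous_glycine = res$collagenous_glycine,
      label = res$label, novel = res$novel,
      published = tr$published$outcome,
      absent_from_controls = tr$absent_from_controls$outcome,
      not_common_allele = tr$not_common_allele$outcome,
      exclusive_segregation = if (is.na(tr$exclusive_segregation$outcome))
        "not_evaluable" else if (tr$exclusive_segregation$outcome)
          "consistent" else "inconsistent",
      stringsAsFactors = FALSE
    )
  }
  out <- if (n) do.call(rbind, rows) else data.frame()
  attr(out, "results") <- results
  out
}

#' Summarize a cohort classification
#'
#' @param classified Output of [classify_cohort()].
#' @return List with \code{by_label} (label counts), \code{by_gene_label}
#'   (contingency table) and \code{novel} (count of novel mutations).
#' @export
classification_summary <- function(classified) {
  list(
    by_label = table(factor(classified$label,
                            levels = c("POLYMORPHISM", "PATHOGENIC",
                                       "PRESUMED_PATHOGENIC", "VUS"))),
    by_gene_label = table(classified$gene, classified$label),
    novel = sum(classified$novel)
  )
}
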