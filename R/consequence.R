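#' Default collagenous (Gly-X-Y) domain map
#'
#' The triple-helical region of each collagen IV alpha chain is a long
#' Gly-X-Y repeat flanked by a short N-terminal 7S domain and a C-terminal
#' NC1 domain of roughly 230 residues.  Glycine substitutions inside the
#' Gly-X-Y region are canonically pathogenic because every third residue of
#' the helix must be glycine.  Exact domain boundaries differ slightly
#' between annotation sources; these defaults are a documented approximation
#' covering the helical region and excluding the 7S and NC1 domains, and can
#' be overridden by supplying a different map.
#'
#' @return data.frame with columns \code{gene}, \code{start}, \code{end}
#'   (protein coordinates, 1-based inclusive).
#' @export
default_collagenous_domains <- function() {
  data.frame(
    gene  = c("COL4A3", "COL4A4", "COL4A5"),
    start = c(30L, 38L, 42L),
    end   = c(1438L, 1459L, 1456L),
    stringsAsFactors = FALSE
  )
}

#' Validate a collagenous domain map
#'
#' @param domains data.frame with columns \code{gene}, \code{start},
#'   \code{end}; per gene, intervals must be sorted, non-overlapping and lie
#'   within the protein length.
#' @return The map, invisibly, after validation.
#' @export
validate_domain_map <- function(domains) {
  stopifnot(all(c("gene", "start", "end") %in% names(domains)))
  for (g in unique(domains$gene)) {
    d <- domains[domains$gene == g, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$end < d$start)) stop("empty domain interval for ", g, call. = FALSE)
    if (any(d$start < 1L) || any(d$end > gene_info(g)$protein_length)) {
      stop("domain interval outside protein length for ", g, call. = FALSE)
    }
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)])) {
      stop("overlapping domain intervals for ", g, call. = FALSE)
    }
  }
  invisible(domains)
}

#' Is a protein change a glycine substitution in a collagenous domain?
#'
#' @param change A \code{"protein_change"} (see [parse_protein()]).
#' @param gene Gene symbol.
#' @param domains Domain map; defaults to [default_collagenous_domains()].
#' @return Logical: TRUE iff the reference residue is Gly and the position
#'   falls inside a collagenous interval of \code{gene}.
#' @examples
#' is_collagenous_glycine_substitution(parse_protein("p.Gly624Asp"), "COL4A5")
#' @export
is_collagenous_glycine_substitution <- function(change, gene,
                                                domains = default_collagenous_domains()) {
  stopifnot(inherits(change, "protein_change"))
  validate_domain_map(domains)
  if (change$ref_aa != "Gly") return(FALSE)
  d <- domains[domains$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop("no collagenous domain map for gene ", gene, call. = FALSE)
  any(change$position >= d$start & change$position <= d$end)
}

#' Molecular consequence categories
#'
#' @return Character vector of the recognized categories.
#' @export
consequence_categories <- function() {
  c("MISSENSE", "SPLICE_DONOR", "SPLICE_ACCEPTOR", "SPLICE_REGION_EXONIC",
    "SPLICE_REGION_INTRONIC", "INTRONIC", "DELETION_WITH_SPLICE", "SYNONYMOUS")
}

#' Assign a molecular consequence to a variant
#'
#' Categories are assigned in priority order:
#' \enumerate{
#'   \item a deletion whose span reaches into intronic bases (or up to a known
#'     exon boundary) is \code{DELETION_WITH_SPLICE};
#'   \item intronic offset +1/+2 is \code{SPLICE_DONOR}; -1/-2 is
#'     \code{SPLICE_ACCEPTOR} (the canonical dinucleotides);
#'   \item intronic offset of absolute value 3..8 is
#'     \code{SPLICE_REGION_INTRONIC};
#'   \item deeper intronic positions are \code{INTRONIC};
#'   \item an exonic change within 3 bases of a known exon boundary with no
#'     (or a synonymous) protein effect is \code{SPLICE_REGION_EXONIC};
#'   \item an exonic change altering the encoded residue is \code{MISSENSE};
#'   \item anything else exonic is \code{SYNONYMOUS}.
#' }
#' A missense change that also sits within 3 bases of an exon boundary keeps
#' \code{MISSENSE} as its primary category and carries
#' \code{secondary_splice_region = TRUE} (e.g. a substitution of the first
#' exonic base, which is part of the acceptor consensus).  Tallies that count
#' "missense vs splice" should use the primary category.
#'
#' @param parsed A \code{"parsed_cdna"} variant.
#' @param protein_change A \code{"protein_change"} or NULL when no protein
#'   effect is annotated.
#' @param transcript A \code{"transcript_model"} for the same gene; partial
#'   models are allowed (unknown boundaries simply cannot trigger exonic
#'   splice-region calls).
#' @return Object of class \code{"consequence"}: list with \code{category} and
#'   \code{secondary_splice_region} (logical).
#' @examples
#' tx <- transcript_model("COL4A5", exon_ends = 2395)
#' classify_consequence(parse_cdna("c.2395+1G>A", "COL4A5"), NULL, tx)$category
#' @export
classify_consequence <- function(parsed, protein_change = NULL, transcript) {
  stopifnot(inherits(parsed, "parsed_cdna"), inherits(transcript, "transcript_model"))
  if (!identical(parsed$gene, transcript$gene)) {
    stop("transcript model is for ", transcript$gene, ", variant is in ", parsed$gene,
         call. = FALSE)
  }
  if (!is.null(protein_change)) stopifnot(inherits(protein_change, "protein_change"))

  near_boundary <- function(pos) {
    any(transcript$exon_ends - pos >= 0L & transcript$exon_ends - pos <= 2L) ||
      any(pos - transcript$exon_starts >= 0L & pos - transcript$exon_starts <= 2L)
  }

  if (parsed$edit_type == "deletion") {
    touches_intron <- parsed$intron_offset != 0L || parsed$span_end_offset != 0L
    touches_boundary <- parsed$span_end_offset == 0L &&
      parsed$span_end_position %in% transcript$exon_ends
    cat <- if (touches_intron || touches_boundary) "DELETION_WITH_SPLICE" else {
      # purely exonic deletion: no dedicated frameshift category in this panel
      # vocabulary; report as missense-like disruption only via MISSENSE when a
      # protein change is given, else SYNONYMOUS is wrong -- use MISSENSE.
      "MISSENSE"
    }
    return(new_consequence(cat, FALSE))
  }

  off <- parsed$intron_offset
  if (off != 0L) {
    a <- abs(off)
    cat <- if (a <= 2L) {
      if (off > 0L) "SPLICE_DONOR" else "SPLICE_ACCEPTOR"
    } else if (a <= 8L) {
      "SPLICE_REGION_INTRONIC"
    } else {
      "INTRONIC"
    }
    return(new_consequence(cat, FALSE))
  }

  # exonic substitution; a complete model can reject out-of-range positions
  if (transcript$complete) {
    total_end <- max(c(transcript$exon_ends, transcript$exon_starts, 0L))
    if (total_end > 0L && parsed$position > total_end) {
      stop("position c.", parsed$position, " beyond transcript model for ",
           parsed$gene, call. = FALSE)
    }
  }
  boundary <- near_boundary(parsed$position)
  missense <- !is.null(protein_change) && protein_change$ref_aa != protein_change$alt_aa
  if (boundary && !missense) return(new_consequence("SPLICE_REGION_EXONIC", FALSE))
  if (missense) return(new_consequence("MISSENSE", boundary))
  new_consequence("SYNONYMOUS", FALSE)
}

new_consequence <- function(category, secondary) {
  stopifnot(category %in% consequence_categories())
  structure(list(category = category, secondary_splice_region = secondary),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence %s%s>\n", x$category,
              if (isTRUE(x$secondary_splice_region)) " (+splice region)" else ""))
  invisible(x)
}

#' Is a consequence splice-related?
#'
#' Convenience predicate used by reporting tallies: donor, acceptor,
#' intronic/exonic splice region and splice-affecting deletions.
#'
#' @param consequence A \code{"consequence"}.
#' @param include_secondary Count a missense change with a secondary splice
#'   flag as splice-related (default FALSE: primary category wins).
#' @return Logical.
#' @export
is_splice_related <- function(consequence, include_secondary = FALSE) {
  stopifnot(inherits(consequence, "consequence"))
  consequence$category %in% c("SPLICE_DONOR", "SPLICE_ACCEPTOR",
                              "SPLICE_REGION_EXONIC", "SPLICE_REGION_INTRONIC",
                              "DELETION_WITH_SPLICE") ||
    (include_secondary && isTRUE(consequence$secondary_splice_region))
}
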