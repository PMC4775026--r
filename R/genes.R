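#' Gene metadata for the type IV collagen panel
#'
#' The panel covers the three genes whose products form the alpha3.alpha4.alpha5
#' network of glomerular basement membrane collagen IV: \code{COL4A3} and
#' \code{COL4A4} (autosomal, chromosome 2) and \code{COL4A5} (X-linked).
#'
#' @return A data.frame with one row per gene and columns \code{name},
#'   \code{chromosome_class} (\code{"autosomal"} or \code{"x_linked"}),
#'   \code{exon_count} and \code{protein_length} (mature polypeptide length in
#'   residues, used to bound collagenous-domain intervals).
#' @examples
#' col4a_genes()
#' @export
col4a_genes <- function() {
  data.frame(
    name             = c("COL4A3", "COL4A4", "COL4A5"),
    chromosome_class = c("autosomal", "autosomal", "x_linked"),
    exon_count       = c(52L, 48L, 51L),
    protein_length   = c(1670L, 1690L, 1685L),
    stringsAsFactors = FALSE
  )
}

#' Look up one panel gene
#'
#' @param name Gene symbol; one of \code{"COL4A3"}, \code{"COL4A4"},
#'   \code{"COL4A5"}.
#' @return One-row data.frame as in [col4a_genes()].
#' @export
gene_info <- function(name) {
  g <- col4a_genes()
  i <- match(name, g$name)
  if (is.na(i)) {
    stop("unknown gene '", name, "'; panel genes are ",
         paste(g$name, collapse = ", "), call. = FALSE)
  }
  g[i, , drop = FALSE]
}

#' Is a gene X-linked?
#' @inheritParams gene_info
#' @return Logical scalar.
#' @export
is_x_linked <- function(name) {
  identical(gene_info(name)$chromosome_class, "x_linked")
}

#' Canonical variant key
#'
#' Builds the canonical string key \code{"GENE:c.HGVS"} used to identify a
#' variant throughout the pipeline.  Whitespace inside and around the HGVS
#' description is stripped (the source tables are inconsistent about spaces
#' after \code{"c."}); case is preserved.
#'
#' @param gene Gene symbol (validated against the panel).
#' @param cdna_hgvs cDNA-level HGVS description starting with \code{"c."}.
#' @return Character scalar key.
#' @examples
#' variant_key("COL4A5", "c.1871G>A")
#' variant_key("COL4A5", " c. 1871G>A ")  # same key
#' @export
variant_key <- function(gene, cdna_hgvs) {
  gene_info(gene)  # validates
  if (!is.character(cdna_hgvs) || length(cdna_hgvs) != 1L || !nzchar(trimws(cdna_hgvs))) {
    stop("cdna_hgvs must be a non-empty string", call. = FALSE)
  }
  paste0(gene, ":", gsub("[[:space:]]+", "", cdna_hgvs))
}

#' Partial transcript model from known exon boundaries
#'
#' A transcript model records, in cDNA (coding) coordinates, which positions
#' are known to be the last base of an exon (donor side) or the first base of
#' an exon (acceptor side).  A full model can be built from contiguous exon
#' intervals with [transcript_from_exons()]; the packaged default models are
#' partial, containing only the boundaries self-documented by intronic HGVS
#' descriptions (e.g. \code{c.765+2} implies an exon ends at c.765) plus a few
#' stated boundaries, which is all the consequence classifier needs.
#'
#' @param gene Gene symbol.
#' @param exon_ends Integer vector of coding positions that end an exon.
#' @param exon_starts Integer vector of coding positions that start an exon.
#' @param complete Logical; TRUE when the boundary lists describe every exon.
#' @return Object of class \code{"transcript_model"}.
#' @export
transcript_model <- function(gene, exon_ends = integer(), exon_starts = integer(),
                             complete = FALSE) {
  gene_info(gene)
  exon_ends <- sort(unique(as.integer(exon_ends)))
  exon_starts <- sort(unique(as.integer(exon_starts)))
  if (any(exon_ends < 1L) || any(exon_starts < 1L)) {
    stop("exon boundaries must be positive coding positions", call. = FALSE)
  }
  structure(
    list(gene = gene, exon_ends = exon_ends, exon_starts = exon_starts,
         complete = complete),
    class = "transcript_model"
  )
}

#' Build a complete transcript model from exon intervals
#'
#' @param gene Gene symbol.
#' @param exons Two-column matrix or data.frame of 1-based inclusive coding
#'   intervals, ordered; intervals must be contiguous (each exon starts one
#'   base after the previous ends) and the first exon must start at 1.
#' @return A complete \code{"transcript_model"}.
#' @export
transcript_from_exons <- function(gene, exons) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)", call. = FALSE)
  start <- as.integer(exons[, 1]); end <- as.integer(exons[, 2])
  if (start[1] != 1L) stop("first exon must start at coding position 1", call. = FALSE)
  if (any(end < start)) stop("exon intervals must have positive length", call. = FALSE)
  if (nrow(exons) > 1L && any(start[-1] != end[-nrow(exons)] + 1L)) {
    stop("exon intervals must be contiguous in coding coordinates", call. = FALSE)
  }
  transcript_model(gene,
                   exon_ends = end[-length(end)],
                   exon_starts = start[-1],
                   complete = TRUE)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s: %d known exon end(s), %d known exon start(s)%s>\n",
              x$gene, length(x$exon_ends), length(x$exon_starts),
              if (x$complete) ", complete" else ", partial"))
  invisible(x)
}
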