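#' Parse an HGVS cDNA variant description
#'
#' Parses the subset of HGVS cDNA notation used for panel reporting:
#' single-nucleotide substitutions (\code{c.1871G>A}, \code{c.765+2T>C},
#' \code{c.547-9A>C}) and deletions given as a single position
#' (\code{c.100del}) or a span (\code{c.1320_1369+2del}).  Coding positions
#' are 1-based HGVS coordinates; intronic bases carry a signed offset
#' (\code{+k} counted from the preceding exon end, \code{-k} from the
#' following exon start), offset 0 meaning exonic.
#'
#' @param hgvs_string String beginning with \code{"c."}.  Internal whitespace
#'   is tolerated and stripped.
#' @param gene Gene symbol the description refers to.
#' @return Object of class \code{"parsed_cdna"}: a list with fields
#'   \code{gene}, \code{position}, \code{intron_offset}, \code{edit_type}
#'   ("substitution" or "deletion"), \code{ref_base}, \code{alt_base},
#'   \code{span_end_position}, \code{span_end_offset} (the last two NA for
#'   substitutions).
#' @examples
#' parse_cdna("c.765+2T>C", "COL4A3")
#' parse_cdna("c.1320_1369+2del", "COL4A4")
#' @export
parse_cdna <- function(hgvs_string, gene) {
  gene_info(gene)
  s <- gsub("[[:space:]]+", "", hgvs_string)
  if (!startsWith(s, "c.")) {
    stop("HGVS cDNA description must begin with 'c.': '", hgvs_string, "'", call. = FALSE)
  }
  body <- substring(s, 3L)
  pos_re <- "([0-9]+)([+-][0-9]+)?"
  sub_re <- paste0("^", pos_re, "([ACGT])>([ACGT])$")
  del_re <- paste0("^", pos_re, "(?:_", pos_re, ")?del$")
  parse_pos <- function(p, o) {
    list(position = as.integer(p),
         offset = if (is.na(o) || o == "") 0L else as.integer(o))
  }
  m <- regmatches(body, regexec(sub_re, body))[[1]]
  if (length(m)) {
    at <- parse_pos(m[2], m[3])
    if (at$position < 1L) stop("coding position must be >= 1 in '", s, "'", call. = FALSE)
    return(new_parsed_cdna(gene, at$position, at$offset, "substitution",
                           ref_base = m[4], alt_base = m[5]))
  }
  m <- regmatches(body, regexec(del_re, body))[[1]]
  if (length(m)) {
    a <- parse_pos(m[2], m[3])
    b <- if (is.na(m[4]) || m[4] == "") a else parse_pos(m[4], m[5])
    if (a$position < 1L) stop("coding position must be >= 1 in '", s, "'", call. = FALSE)
    # span order is lexicographic on (position, offset)
    if (b$position < a$position ||
        (b$position == a$position && b$offset < a$offset)) {
      stop("inverted deletion span in '", s, "'", call. = FALSE)
    }
    return(new_parsed_cdna(gene, a$position, a$offset, "deletion",
                           span_end_position = b$position, span_end_offset = b$offset))
  }
  stop("cannot parse HGVS cDNA description '", hgvs_string,
       "': unrecognized token '", body, "'", call. = FALSE)
}

new_parsed_cdna <- function(gene, position, intron_offset, edit_type,
                            ref_base = NA_character_, alt_base = NA_character_,
                            span_end_position = NA_integer_,
                            span_end_offset = NA_integer_) {
  structure(
    list(gene = gene, position = as.integer(position),
         intron_offset = as.integer(intron_offset), edit_type = edit_type,
         ref_base = ref_base, alt_base = alt_base,
         span_end_position = as.integer(span_end_position),
         span_end_offset = as.integer(span_end_offset)),
    class = "parsed_cdna"
  )
}

#' Render a parsed cDNA variant back to its HGVS string
#'
#' Inverse of [parse_cdna()]; \code{render_cdna(parse_cdna(x, g))} reproduces
#' the (whitespace-normalized) input.
#'
#' @param x A \code{"parsed_cdna"} object.
#' @return Character scalar.
#' @export
render_cdna <- function(x) {
  stopifnot(inherits(x, "parsed_cdna"))
  fmt_pos <- function(p, o) {
    paste0(p, if (o > 0L) paste0("+", o) else if (o < 0L) as.character(o) else "")
  }
  if (x$edit_type == "substitution") {
    paste0("c.", fmt_pos(x$position, x$intron_offset), x$ref_base, ">", x$alt_base)
  } else {
    a <- fmt_pos(x$position, x$intron_offset)
    b <- fmt_pos(x$span_end_position, x$span_end_offset)
    if (identical(a, b)) paste0("c.", a, "del") else paste0("c.", a, "_", b, "del")
  }
}

#' @export
print.parsed_cdna <- function(x, ...) {
  cat(sprintf("<parsed_cdna %s %s (%s)>\n", x$gene, render_cdna(x), x$edit_type))
  invisible(x)
}

#' Parse an HGVS protein change
#'
#' @param p_string String beginning with \code{"p."}, in three-letter code,
#'   e.g. \code{"p.Gly1164Cys"}.  Whitespace after \code{"p."} is tolerated.
#' @return Object of class \code{"protein_change"} with fields \code{ref_aa},
#'   \code{position}, \code{alt_aa}.
#' @examples
#' parse_protein("p.Gly624Asp")
#' @export
parse_protein <- function(p_string) {
  s <- gsub("[[:space:]]+", "", p_string)
  if (!startsWith(s, "p.")) {
    stop("HGVS protein description must begin with 'p.': '", p_string, "'", call. = FALSE)
  }
  m <- regmatches(s, regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", s))[[1]]
  if (!length(m)) stop("cannot parse protein change '", p_string, "'", call. = FALSE)
  aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
           "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
  for (code in c(m[2], m[4])) {
    if (!code %in% aa3) stop("unknown amino-acid code '", code, "' in '", p_string, "'",
                             call. = FALSE)
  }
  pos <- as.integer(m[3])
  if (pos < 1L) stop("protein position must be >= 1", call. = FALSE)
  structure(list(ref_aa = m[2], position = pos, alt_aa = m[4]),
            class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat(sprintf("<protein_change p.%s%d%s>\n", x$ref_aa, x$position, x$alt_aa))
  invisible(x)
}

#' Number of bases removed by a deletion
#'
#' Computes the deleted-base count for a deletion whose span lies within one
#' exon plus that exon's immediately flanking intronic bases (the common case
#' for amplicon panels; a span that would cross an entire intron is rejected
#' because its length cannot be derived from cDNA coordinates alone).
#'
#' The closed form is \code{(end_position - start_position + 1) + end_offset -
#' start_offset}: e.g. \code{c.1320_1369+2del} removes the 50 exonic bases
#' 1320..1369 plus the first 2 bases of the downstream intron = 52 bp.
#'
#' @param parsed A \code{"parsed_cdna"} deletion.
#' @return Integer number of deleted bases.
#' @export
deletion_length <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_cdna"))
  if (parsed$edit_type != "deletion") {
    stop("deletion_length is only defined for deletions", call. = FALSE)
  }
  o1 <- parsed$intron_offset; o2 <- parsed$span_end_offset
  p1 <- parsed$position; p2 <- parsed$span_end_position
  # a span from a downstream (+) flank to an upstream (-) flank, or with both
  # ends in the same-signed flank of *different* exon boundaries, would cross
  # a full intron; cDNA coordinates cannot measure that.
  if (o1 > 0L && (p2 > p1 || o2 < 0L)) {
    stop("unsupported deletion span: crosses a complete intron", call. = FALSE)
  }
  if (o2 < 0L && p1 < p2) {
    stop("unsupported deletion span: crosses a complete intron", call. = FALSE)
  }
  as.integer((p2 - p1 + 1L) + o2 - o1)
}
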