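#' Packaged reference fixture tables
#'
#' The package ships, under \code{inst/extdata}, the reference variant tables
#' of the Hungarian three-gene panel study it accompanies: 21 population
#' polymorphisms found in 66 unrelated non-AS/FBH controls (with minor
#' allele frequencies), 17 causative mutations identified across 14 families
#' and 3 isolated individuals, the case roster linking each of the 17 cases
#' to its variant(s), and the transcript exon boundaries self-documented by
#' the variant descriptions themselves.
#'
#' @name fixtures
NULL

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "alportdx")
  if (!nzchar(p)) stop("packaged fixture '", name, "' not found", call. = FALSE)
  p
}

.fixture_cache <- new.env(parent = emptyenv())

read_fixture_tsv <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- utils::read.delim(fixture_path(name),
                                                stringsAsFactors = FALSE,
                                                na.strings = "NA", quote = "")
  }
  .fixture_cache[[name]]
}

#' @describeIn fixtures The 21-row polymorphism table: gene, cdna, maf,
#'   protein, consequence_label, published_status, source, in_controls, note,
#'   cases.
#' @return data.frame.
#' @export
fixture_polymorphisms <- function() {
  tab <- read_fixture_tsv("polymorphism_table.tsv")
  tab$in_controls <- as.logical(tab$in_controls)
  tab$segregation <- NA_character_
  tab
}

#' @describeIn fixtures The 17-row mutation table: gene, cdna, protein,
#'   consequence_label, published_status, source, in_controls, segregation
#'   ("consistent" where family co-segregation was validated, NA for isolated
#'   individuals), cases.
#' @export
fixture_mutations <- function() {
  tab <- read_fixture_tsv("mutation_table.tsv")
  tab$in_controls <- as.logical(tab$in_controls)
  tab$maf <- NA_real_
  tab$note <- NA_character_
  tab
}

#' @describeIn fixtures The 17-case roster (14 families + 3 isolated
#'   individuals) with each case's assigned variant keys.
#' @export
fixture_roster <- function() {
  read_fixture_tsv("case_roster.tsv")
}

#' @describeIn fixtures Transcript models built from the packaged
#'   exon-boundary table; partial by design (only boundaries the variant
#'   descriptions document), sufficient for the packaged analysis.
#' @export
default_transcript_models <- function() {
  tab <- read_fixture_tsv("transcript_boundaries.tsv")
  out <- lapply(col4a_genes()$name, function(g) {
    d <- tab[tab$gene == g, , drop = FALSE]
    transcript_model(g,
                     exon_ends = d$position[d$boundary == "exon_end"],
                     exon_starts = d$position[d$boundary == "exon_start"])
  })
  stats::setNames(out, col4a_genes()$name)
}

#' @describeIn fixtures The full bundle: \code{variants} (merged 38-row
#'   table), \code{polymorphisms}, \code{mutations}, \code{roster},
#'   \code{transcripts} and \code{domains}.
#' @export
fixture_bundle <- function() {
  poly <- fixture_polymorphisms()
  mut <- fixture_mutations()
  shared <- c("gene", "cdna", "protein", "consequence_label", "maf",
              "published_status", "source", "in_controls", "segregation",
              "note", "cases")
  merged <- rbind(poly[, shared], mut[, shared])
  rownames(merged) <- NULL
  roster <- fixture_roster()
  mut_keys <- mapply(variant_key, mut$gene, mut$cdna, USE.NAMES = FALSE)
  for (keys in strsplit(roster$variant_keys, ";", fixed = TRUE)) {
    bad <- setdiff(keys, mut_keys)
    if (length(bad)) {
      stop("roster variant(s) not in mutation table: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  list(variants = merged, polymorphisms = poly, mutations = mut,
       roster = roster, transcripts = default_transcript_models(),
       domains = default_collagenous_domains())
}
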