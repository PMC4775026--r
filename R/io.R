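#' Read a variant table from TSV or minimally annotated VCF
#'
#' The TSV dialect is the primary input path: columns \code{gene},
#' \code{cdna} and optionally \code{protein} plus any annotation columns
#' accepted by [classify_cohort()].  The VCF dialect (VCFv4.2) is
#' reference-genome-free: each record must carry INFO subfields \code{GENE}
#' and \code{CDNA} (and optionally \code{PROTEIN}); CHROM/POS hold the gene
#' symbol and coding position for sorting only.  Sample GT fields are mapped
#' to allele counts, with haploid calls (male X) counted as 0 or 1.
#'
#' @param path Input file.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"vcf"}.
#' @return List with \code{variants} (data.frame; keyed by
#'   \code{variant_key}) and \code{genotypes} (data.frame individual_id,
#'   variant_key, allele_count; NULL for TSV input without genotype columns).
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
}

read_variant_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                           quote = "")
  for (col in c("gene", "cdna")) {
    if (!col %in% names(tab)) {
      stop("variant TSV must have a '", col, "' column", call. = FALSE)
    }
  }
  bad <- which(!tab$gene %in% col4a_genes()$name)
  if (length(bad)) {
    stop("unknown gene name(s) at line(s) ", paste(bad + 1L, collapse = ", "),
         ": ", paste(unique(tab$gene[bad]), collapse = ", "), call. = FALSE)
  }
  tab$variant_key <- mapply(variant_key, tab$gene, tab$cdna, USE.NAMES = FALSE)
  list(variants = tab, genotypes = NULL)
}

read_variant_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM")) {
    stop("malformed VCF: missing #CHROM header line", call. = FALSE)
  }
  header <- strsplit(sub("^#", "", body[1]), "\t", fixed = TRUE)[[1]]
  samples <- if (length(header) > 9L) header[-(1:9)] else character()
  records <- body[-1]
  records <- records[nzchar(records)]
  variants <- list(); genos <- list()
  for (i in seq_along(records)) {
    f <- strsplit(records[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stop("malformed VCF record at data line ", i, call. = FALSE)
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    info_map <- stats::setNames(
      vapply(kv, function(x) if (length(x) > 1L) x[2] else "", character(1)),
      vapply(kv, `[`, character(1), 1))
    info_get <- function(k) {
      if (k %in% names(info_map) && nzchar(info_map[[k]])) info_map[[k]] else
        NA_character_
    }
    gene <- info_get("GENE"); cdna <- info_get("CDNA")
    if (is.na(gene) || is.na(cdna)) {
      stop("VCF record at data line ", i, " lacks GENE=/CDNA= INFO subfields",
           call. = FALSE)
    }
    key <- variant_key(gene, cdna)
    variants[[i]] <- data.frame(
      gene = gene, cdna = gsub("[[:space:]]+", "", cdna),
      protein = info_get("PROTEIN"),
      variant_key = key, stringsAsFactors = FALSE)
    if (length(samples)) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gt_idx <- match("GT", fmt)
      if (is.na(gt_idx)) stop("VCF FORMAT lacks GT at data line ", i, call. = FALSE)
      for (s in seq_along(samples)) {
        gt <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]][gt_idx]
        alleles <- strsplit(gt, "[/|]")[[1]]
        if (any(alleles == ".")) next
        genos[[length(genos) + 1L]] <- data.frame(
          individual_id = samples[s], variant_key = key,
          allele_count = sum(alleles == "1"),
          hemizygous = length(alleles) == 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(variants = if (length(variants)) do.call(rbind, variants) else NULL,
       genotypes = if (length(genos)) do.call(rbind, genos) else NULL)
}

#' Write variants and genotypes as a minimal VCF
#'
#' Emits the reference-genome-free VCFv4.2 dialect read back by
#' [read_variant_table()]: CHROM carries the gene symbol, POS the cDNA coding
#' position, INFO carries \code{GENE}, \code{CDNA} and optionally
#' \code{PROTEIN}, and per-sample GT fields encode allele counts (haploid
#' \code{"0"}/\code{"1"} for male X genotypes).
#'
#' @param variants data.frame with \code{gene}, \code{cdna}, optional
#'   \code{protein}.
#' @param path Output path.
#' @param genotypes Optional data.frame (individual_id, variant_key,
#'   allele_count); sample columns are emitted in first-seen order.
#' @param sexes Optional named character vector (id -> "male"/"female") used
#'   to emit haploid GT for male X-linked genotypes.
#' @return Invisibly, \code{path}.
#' @export
write_variant_vcf <- function(variants, path, genotypes = NULL, sexes = NULL) {
  keys <- mapply(variant_key, variants$gene, variants$cdna, USE.NAMES = FALSE)
  prot <- if ("protein" %in% names(variants)) variants$protein else
    rep(NA_character_, nrow(variants))
  samples <- if (!is.null(genotypes)) unique(genotypes$individual_id) else character()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=alportdx",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Panel gene symbol">',
    '##INFO=<ID=CDNA,Number=1,Type=String,Description="HGVS cDNA description">',
    '##INFO=<ID=PROTEIN,Number=1,Type=String,Description="HGVS protein description">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    p <- parse_cdna(variants$cdna[i], variants$gene[i])
    ref <- if (p$edit_type == "substitution") p$ref_base else "N"
    alt <- if (p$edit_type == "substitution") p$alt_base else "<DEL>"
    info <- paste0("GENE=", variants$gene[i], ";CDNA=", render_cdna(p),
                   if (!is.na(prot[i]) && nzchar(prot[i]))
                     paste0(";PROTEIN=", gsub("[[:space:]]+", "", prot[i])) else "")
    gt <- if (length(samples)) {
      calls <- vapply(samples, function(s) {
        row <- genotypes[genotypes$individual_id == s &
                           genotypes$variant_key == keys[i], , drop = FALSE]
        ac <- if (nrow(row)) row$allele_count[1] else 0L
        haploid <- is_x_linked(variants$gene[i]) && !is.null(sexes) &&
          identical(unname(sexes[s]), "male")
        if (haploid) as.character(min(ac, 1L)) else
          c("0/0", "0/1", "1/1")[ac + 1L]
      }, character(1))
      paste(c("GT", calls), collapse = "\t")
    } else NULL
    paste(c(variants$gene[i], p$position, ".", ref, alt, ".", "PASS", info, gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a control-cohort frequency table
#'
#' @param path TSV with columns \code{variant_key} (or \code{gene} +
#'   \code{cdna}), \code{allele_count} and \code{allele_number} (e.g. 132
#'   control chromosomes for 66 diploid individuals).
#' @return data.frame with \code{variant_key}, \code{allele_count},
#'   \code{allele_number}, \code{maf} and \code{in_controls}.
#' @export
read_control_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!"variant_key" %in% names(tab)) {
    if (!all(c("gene", "cdna") %in% names(tab))) {
      stop("control table needs 'variant_key' or 'gene'+'cdna' columns", call. = FALSE)
    }
    tab$variant_key <- mapply(variant_key, tab$gene, tab$cdna, USE.NAMES = FALSE)
  }
  stopifnot(all(c("allele_count", "allele_number") %in% names(tab)))
  tab$maf <- tab$allele_count / tab$allele_number
  tab$in_controls <- tab$allele_count > 0L
  tab
}

#' Read target regions from BED
#'
#' BED is 0-based half-open; interval lengths are end minus start.
#'
#' @param path BED file (3+ columns; column 4, when present, names the
#'   region).
#' @return A [target_region_set()].
#' @export
read_bed_targets <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           sep = "\t", quote = "")
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  ids <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    sprintf("%s:%d-%d", tab[[1]], tab[[2]], tab[[3]])
  target_region_set(data.frame(region_id = ids,
                               length_bp = as.integer(tab[[3]] - tab[[2]]),
                               stringsAsFactors = FALSE))
}

#' Read a per-base depth track
#'
#' Accepts either the 3-column TSV dialect (region, offset, depth; one row
#' per base) or 4-column bedGraph (chrom, start, end, depth; runs expanded to
#' per-base values).
#'
#' @param path Input file.
#' @param format \code{"auto"} (bedGraph for .bedgraph/.bg extensions),
#'   \code{"tsv"} or \code{"bedgraph"}.
#' @return Integer vector of per-base depths.
#' @export
read_depth_track <- function(path, format = c("auto", "tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  }
  if (format == "bedgraph") {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             sep = "\t", quote = "")
    if (ncol(tab) < 4L) stop("bedGraph needs 4 columns", call. = FALSE)
    return(as.integer(rep(tab[[4]], times = tab[[3]] - tab[[2]])))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  depth_col <- intersect(c("depth", "coverage"), names(tab))
  if (!length(depth_col)) {
    if (ncol(tab) < 3L) stop("depth TSV needs columns region, offset, depth",
                             call. = FALSE)
    depth_col <- names(tab)[3]
  }
  as.integer(tab[[depth_col[1]]])
}

#' Write an analysis report
#'
#' Serializes variant classifications, family diagnoses and an optional QC
#' verdict with deterministic field order.  The JSON form round-trips through
#' [read_report()]; the TSV form writes the per-variant table only.
#'
#' @param classifications Output of [classify_cohort()].
#' @param diagnoses List of \code{"family_diagnosis"} objects (may be empty).
#' @param qc Output of [qc_verdict()], or NULL.
#' @param path Output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(classifications, diagnoses = list(), qc = NULL, path,
                         format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(classifications, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  diag_list <- lapply(diagnoses, function(d) {
    list(family_id = d$family_id, mode = d$mode,
         supporting_variants = as.list(d$supporting_variants),
         composite = d$composite, caveats = as.list(d$caveats))
  })
  payload <- list(
    tool = "alportdx",
    variants = classifications,
    diagnoses = diag_list,
    qc = if (is.null(qc)) NULL else list(pass = qc$pass, rules = qc$rules)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON report written by [write_report()].
#' @return List with \code{variants} (data.frame), \code{diagnoses} and
#'   \code{qc}.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
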