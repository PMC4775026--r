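#' Construct a pedigree
#'
#' A pedigree is a set of individuals with sex, affection status and parent
#' links, as in the standard 6-column PED format.  Individuals with unknown
#' affection are kept but ignored by segregation tests.
#'
#' @param family_id Family identifier.
#' @param members data.frame with columns \code{id}, \code{sex} ("male" /
#'   "female"), \code{affection} ("affected" / "unaffected" / "unknown"),
#'   \code{father_id}, \code{mother_id} (NA for founders).
#' @return Object of class \code{"pedigree"}.
#' @seealso [read_ped()], [validate_pedigree()]
#' @export
pedigree <- function(family_id, members) {
  required <- c("id", "sex", "affection", "father_id", "mother_id")
  if (!all(required %in% names(members))) {
    stop("members must have columns ", paste(required, collapse = ", "), call. = FALSE)
  }
  members <- as.data.frame(members, stringsAsFactors = FALSE)[, required]
  members$id <- as.character(members$id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  structure(list(family_id = as.character(family_id), members = members),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree %s: %d members, %d affected>\n", x$family_id,
              nrow(x$members), sum(x$members$affection == "affected")))
  invisible(x)
}

#' A genotype call for one individual at one variant
#'
#' @param individual_id Individual identifier (must exist in the pedigree the
#'   call is evaluated against).
#' @param variant_key Canonical key from [variant_key()].
#' @param allele_count Number of alternate alleles carried: 0, 1 or 2.
#' @return One-row data.frame; rbind calls together to form a genotype set.
#' @export
genotype_call <- function(individual_id, variant_key, allele_count) {
  allele_count <- as.integer(allele_count)
  if (!allele_count %in% 0:2) stop("allele_count must be 0, 1 or 2", call. = FALSE)
  data.frame(individual_id = as.character(individual_id),
             variant_key = variant_key,
             allele_count = allele_count,
             stringsAsFactors = FALSE)
}

#' Validate pedigree structure
#'
#' Checks the structural invariants of a pedigree and, optionally, sex-aware
#' genotype constraints: fathers must be male and mothers female; parent
#' references must resolve within the family; the parent graph must be
#' acyclic (no individual is its own ancestor); and no male may carry two
#' alleles of an X-linked (COL4A5) variant, since males are hemizygous.
#'
#' Violations are returned as data, not raised as errors, so that a loader can
#' report all problems in one pass.
#'
#' @param ped A [pedigree()].
#' @param genotypes Optional data.frame of genotype calls (columns
#'   \code{individual_id}, \code{variant_key}, \code{allele_count}).
#' @return data.frame with columns \code{rule}, \code{individual_id},
#'   \code{detail}; zero rows when every invariant holds.
#' @export
validate_pedigree <- function(ped, genotypes = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  m <- ped$members
  v <- list()
  add <- function(rule, id, detail) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, individual_id = id,
                                       detail = detail, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(m$id)) {
    for (id in unique(m$id[duplicated(m$id)])) add("duplicate_id", id, "individual id occurs more than once")
  }
  sex_of <- stats::setNames(m$sex, m$id)
  for (i in seq_len(nrow(m))) {
    for (side in c("father", "mother")) {
      pid <- m[[paste0(side, "_id")]][i]
      if (is.na(pid) || pid == "" || pid == "0") next
      if (!pid %in% m$id) {
        add("unresolved_parent", m$id[i], sprintf("%s '%s' not in family", side, pid))
      } else {
        want <- if (side == "father") "male" else "female"
        if (sex_of[[pid]] != want) {
          add("parent_sex", m$id[i], sprintf("%s '%s' is not %s", side, pid, want))
        }
      }
    }
  }
  # cycle check: walk ancestors from each individual
  parent_of <- function(id) {
    r <- m[m$id == id, , drop = FALSE]
    if (nrow(r) == 0L) return(character())
    p <- c(r$father_id[1], r$mother_id[1])
    p[!is.na(p) & p != "" & p != "0" & p %in% m$id]
  }
  for (id in m$id) {
    seen <- character(); frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier) { add("ancestry_cycle", id, "individual is its own ancestor"); break }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  if (!is.null(genotypes) && nrow(genotypes)) {
    for (i in seq_len(nrow(genotypes))) {
      g <- genotypes[i, ]
      gene <- sub(":.*$", "", g$variant_key)
      if (!g$individual_id %in% m$id) {
        add("genotype_orphan", g$individual_id, "genotyped individual not in pedigree")
        next
      }
      if (gene %in% col4a_genes()$name && is_x_linked(gene) &&
          sex_of[[g$individual_id]] == "male" && g$allele_count > 1L) {
        add("hemizygosity", g$individual_id,
            sprintf("male carries %d alleles of X-linked %s", g$allele_count, g$variant_key))
      }
    }
  }
  if (!length(v)) {
    return(data.frame(rule = character(), individual_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Read a PED pedigree file
#'
#' Reads the 6-column pre-MAKEPED dialect: family, individual, father, mother,
#' sex (1 = male, 2 = female), phenotype (1 = unaffected, 2 = affected,
#' 0 = unknown).  Founder parents are encoded as \code{"0"}.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return Named list of [pedigree()] objects, one per family id.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6L) stop("PED file must have at least 6 columns", call. = FALSE)
  names(raw)[1:6] <- c("family_id", "id", "father_id", "mother_id", "sex", "phenotype")
  if (!all(raw$sex %in% c("1", "2"))) {
    stop("PED sex column must be 1 (male) or 2 (female); unknown sex is not supported ",
         "because hemizygosity rules require it", call. = FALSE)
  }
  if (!all(raw$phenotype %in% c("0", "1", "2"))) {
    stop("PED phenotype column must be 0/1/2", call. = FALSE)
  }
  raw$sex <- c(`1` = "male", `2` = "female")[raw$sex]
  raw$affection <- c(`0` = "unknown", `1` = "unaffected", `2` = "affected")[raw$phenotype]
  raw$father_id[raw$father_id == "0"] <- NA_character_
  raw$mother_id[raw$mother_id == "0"] <- NA_character_
  out <- lapply(split(raw, raw$family_id), function(fam) {
    pedigree(fam$family_id[1], fam[, c("id", "sex", "affection", "father_id", "mother_id")])
  })
  out[unique(raw$family_id)]
}

#' Write pedigrees to a PED file
#'
#' Inverse of [read_ped()]; round-trips losslessly for supported fields.
#'
#' @param peds A [pedigree()] or list of pedigrees.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ped <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(p) {
    m <- p$members
    data.frame(
      family_id = p$family_id, id = m$id,
      father_id = ifelse(is.na(m$father_id), "0", m$father_id),
      mother_id = ifelse(is.na(m$mother_id), "0", m$mother_id),
      sex = ifelse(m$sex == "male", "1", "2"),
      phenotype = c(unknown = "0", unaffected = "1", affected = "2")[m$affection],
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
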