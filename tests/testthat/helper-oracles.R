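# Independent oracles shared by unit and acceptance tests.

# Brute-force deletion length: walk the written cDNA coordinates base by base
# from (p1, o1) to (p2, o2), counting steps.  Deliberately ignorant of the
# closed form used by deletion_length().
enumerate_deletion_bases <- function(p1, o1, p2, o2) {
  pos <- p1; off <- o1; n <- 1L
  while (!(pos == p2 && off == o2)) {
    if (off < 0L) {
      off <- off + 1L
    } else if (off == 0L && pos < p2) {
      pos <- pos + 1L
    } else {
      off <- off + 1L
    }
    n <- n + 1L
    if (n > 1e6L) stop("oracle runaway")
  }
  n
}

# Draw a random well-formed deletion span (same exon plus flanking bases).
random_deletion_span <- function() {
  shape <- sample(c("exonic", "left_flank", "right_flank", "both_flanks",
                    "same_flank"), 1L)
  p1 <- sample(50:500, 1L)
  switch(shape,
    exonic = {
      p2 <- p1 + sample(0:60, 1L)
      c(p1, 0L, p2, 0L)
    },
    left_flank = {
      p2 <- p1 + sample(0:60, 1L)
      c(p1, -sample(1:8, 1L), p2, 0L)
    },
    right_flank = {
      p2 <- p1 + sample(0:60, 1L)
      c(p1, 0L, p2, sample(1:8, 1L))
    },
    both_flanks = {
      p2 <- p1 + sample(1:60, 1L)
      c(p1, -sample(1:8, 1L), p2, sample(1:8, 1L))
    },
    same_flank = {
      # both ends in the same intronic flank of one boundary
      o <- sort(sample(1:8, 2L, replace = TRUE))
      if (stats::runif(1) < 0.5) c(p1, -o[2], p1, -o[1]) else c(p1, o[1], p1, o[2])
    })
}

# Per-member rule table for exclusive segregation, applied by direct
# enumeration of every member record (no shared code with the package path).
oracle_segregation <- function(members, gene, tolerant = FALSE) {
  # members: data.frame id, sex, affection, allele_count
  m <- members[members$affection != "unknown", , drop = FALSE]
  x_linked <- gene == "COL4A5"
  bad <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    carrier <- m$allele_count[i] > 0L
    if (m$affection[i] == "unaffected" && carrier) {
      bad[i] <- if (!x_linked) !tolerant else m$sex[i] == "male"
    }
  }
  affected <- m$affection == "affected"
  ok_presence <- !any(affected) || any(affected & m$allele_count > 0L)
  !any(bad) && ok_presence
}

# Pathogenicity rank used by monotonicity checks.
label_rank <- function(label) {
  c(POLYMORPHISM = 0L, VUS = 1L, PRESUMED_PATHOGENIC = 2L, PATHOGENIC = 3L)[[label]]
}

# Map the fixture tables' human-readable consequence labels to categories.
expected_category <- function(label) {
  switch(label,
    "missense" = "MISSENSE",
    "missense, splice acceptor" = "MISSENSE",
    "splice donor" = "SPLICE_DONOR",
    "splice acceptor" = "SPLICE_ACCEPTOR",
    "splice region" = "SPLICE_REGION_EXONIC",
    "presumed splice variant" = "SPLICE_REGION_INTRONIC",
    "deletion, splice donor" = "DELETION_WITH_SPLICE",
    stop("unmapped label ", label))
}

fixture_path_for_tests <- function(name) {
  system.file("extdata", name, package = "alportdx")
}

# Small well-formed trio used across pedigree tests.
make_trio <- function(affection = c("affected", "unaffected", "affected")) {
  pedigree("T1", data.frame(
    id = c("fa", "mo", "ch"),
    sex = c("male", "female", "male"),
    affection = affection,
    father_id = c(NA, NA, "fa"),
    mother_id = c(NA, NA, "mo"),
    stringsAsFactors = FALSE))
}

classified_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reproduce_reference_analysis()
    cache
  }
})
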