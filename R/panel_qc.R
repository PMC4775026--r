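#' Target region set for an amplicon panel
#'
#' @param regions data.frame with columns \code{region_id} and
#'   \code{length_bp} (positive integers).
#' @return Object of class \code{"target_region_set"} with the regions and
#'   their \code{total_bp}.
#' @export
target_region_set <- function(regions) {
  stopifnot(all(c("region_id", "length_bp") %in% names(regions)))
  if (any(regions$length_bp <= 0)) stop("region lengths must be positive", call. = FALSE)
  structure(list(regions = as.data.frame(regions), total_bp = sum(regions$length_bp)),
            class = "target_region_set")
}

#' Descriptive metadata of the reference three-gene amplicon panel
#'
#' Per-gene target sizes and amplicon counts of the panel design this package
#' accompanies.  These derive from a commercial design and are metadata only:
#' nothing recomputes them.
#'
#' @return List with \code{per_gene} (data.frame of gene, target_bp),
#'   \code{amplicons}, \code{pools} and \code{total_bp}.
#' @export
reference_panel_metadata <- function() {
  list(
    per_gene = data.frame(gene = c("COL4A3", "COL4A4", "COL4A5"),
                          target_bp = c(5013L, 5073L, 5383L),
                          stringsAsFactors = FALSE),
    amplicons = 197L,
    pools = c(99L, 98L),
    total_bp = 29400L
  )
}

#' Summarize a per-base depth track
#'
#' @param depths Integer vector of per-base depths (one value per target
#'   base); must be non-empty and non-negative.
#' @param thresholds Depth thresholds at which to report the covered
#'   fraction.
#' @return List with \code{n_bases}, \code{mean_depth} and
#'   \code{fraction_at_or_above}, a named numeric vector giving, for each
#'   threshold t, the fraction of bases with depth >= t (non-increasing in
#'   t).
#' @examples
#' coverage_summary(c(0, 50, 100, 200))
#' @export
coverage_summary <- function(depths, thresholds = c(25, 50, 100)) {
  if (length(depths) == 0L) stop("empty depth track", call. = FALSE)
  if (any(depths < 0)) stop("depths must be non-negative", call. = FALSE)
  frac <- vapply(thresholds, function(t) mean(depths >= t), numeric(1))
  names(frac) <- as.character(thresholds)
  list(n_bases = length(depths), mean_depth = mean(depths),
       fraction_at_or_above = frac)
}

#' Coverage QC thresholds
#'
#' Defaults follow standard amplicon-panel acceptance: strictly more than 90%
#' of target bases at 100x, strictly more than 95% at 50x, and a minimum mean
#' depth of 25x.
#'
#' @param min_fraction_100x,min_fraction_50x Covered-fraction thresholds
#'   (strict inequalities).
#' @param min_mean_depth Minimum mean depth (non-strict).
#' @return Named list.
#' @export
qc_thresholds <- function(min_fraction_100x = 0.90, min_fraction_50x = 0.95,
                          min_mean_depth = 25) {
  list(min_fraction_100x = min_fraction_100x, min_fraction_50x = min_fraction_50x,
       min_mean_depth = min_mean_depth)
}

#' Pass/fail verdict on a coverage summary
#'
#' @param summary Output of [coverage_summary()]; must include fractions at
#'   thresholds 50 and 100.
#' @param config A [qc_thresholds()].
#' @return List with \code{pass} (logical) and \code{rules}, a data.frame
#'   reporting each rule (observed, required, pass) separately.  The
#'   covered-fraction rules use strict inequality ("more than").
#' @export
qc_verdict <- function(summary, config = qc_thresholds()) {
  f100 <- summary$fraction_at_or_above[["100"]]
  f50 <- summary$fraction_at_or_above[["50"]]
  if (is.null(f100) || is.null(f50)) {
    stop("summary must include fractions at thresholds 50 and 100", call. = FALSE)
  }
  rules <- data.frame(
    rule = c("fraction_100x", "fraction_50x", "mean_depth"),
    observed = c(f100, f50, summary$mean_depth),
    required = c(config$min_fraction_100x, config$min_fraction_50x,
                 config$min_mean_depth),
    strict = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  rules$pass <- ifelse(rules$strict, rules$observed > rules$required,
                       rules$observed >= rules$required)
  list(pass = all(rules$pass), rules = rules)
}
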