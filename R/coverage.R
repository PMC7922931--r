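#' Per-locus coverage profile of recruited reads
#'
#' Coverage here means the number of recruited reads whose alignment starts
#' at a locus, tallied one increment per read, not per-base pileup depth.
#' The mean `M` and standard deviation `SD` are computed over the covered
#' loci only (the loci actually present in the dictionary `D`), because the
#' profile is built exclusively from recruited reads.
#'
#' @param hits Hits data frame for a single genome (all rows must share one
#'   `genome_id`).
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1) standard deviation.
#' @return An object of class `coverage_profile`: list with `genome_id`,
#'   `D` (named integer vector, names are 0-based loci), `M`, `SD`,
#'   `sd_type` and `n_hits`. An empty hit set yields an empty profile with
#'   `M = SD = 0`.
#' @export
compute_coverage <- function(hits, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.data.frame(hits), all(c("genome_id", "start") %in% names(hits)))
  gid <- unique(hits$genome_id)
  if (length(gid) > 1L) {
    stop("hits span several genomes (", paste(gid, collapse = ", "),
         "); profile one genome at a time")
  }
  if (nrow(hits) == 0L) {
    return(structure(list(genome_id = if (length(gid)) gid else NA_character_,
                          D = stats::setNames(integer(0), character(0)),
                          M = 0, SD = 0, sd_type = sd_type, n_hits = 0L),
                     class = "coverage_profile"))
  }
  tab <- table(hits$start)
  D <- stats::setNames(as.integer(tab), names(tab))
  M <- mean(D)
  SD <- if (sd_type == "population") {
    sqrt(mean((D - M)^2))
  } else {
    if (length(D) > 1L) stats::sd(D) else 0
  }
  structure(list(genome_id = gid, D = D, M = M, SD = SD,
                 sd_type = sd_type, n_hits = nrow(hits)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Coverage profile for", x$genome_id, "\n",
      " hits:", x$n_hits, " covered loci:", length(x$D),
      sprintf(" M: %.4g  SD (%s): %.4g\n", x$M, x$sd_type, x$SD))
  invisible(x)
}

#' Classify loci as qualified or unqualified
#'
#' A locus is unqualified when its read-start count exceeds
#' `M + sd_multiplier * SD`; counts equal to the threshold are qualified.
#' Such abnormally highly covered loci typically betray conserved repetitive
#' elements (rRNA operons, mobile elements) attracting reads from many taxa.
#'
#' @param profile A [compute_coverage()] profile.
#' @param sd_multiplier Number of standard deviations above the mean that
#'   defines the peak threshold (default 2).
#' @return Data frame with columns `locus`, `count` and `qualified`, plus a
#'   `threshold` attribute.
#' @export
locus_mask <- function(profile, sd_multiplier = 2) {
  stopifnot(inherits(profile, "coverage_profile"))
  threshold <- profile$M + sd_multiplier * profile$SD
  mask <- data.frame(locus = as.integer(names(profile$D)),
                     count = unname(profile$D),
                     qualified = unname(profile$D) <= threshold)
  attr(mask, "threshold") <- threshold
  mask
}

#' Remove recruited reads located at abnormally highly covered loci
#'
#' Single-pass peak filter: reads whose alignment-start locus has a count
#' strictly above `M + sd_multiplier * SD` are removed, all others are kept
#' in their original order. The pass is applied exactly once per genome;
#' re-running it on its own output recomputes `M` and `SD` on the reduced
#' profile and may remove further reads, which is deliberately not done by
#' the pipeline.
#'
#' @param hits Hits data frame for one genome.
#' @param profile Optional [compute_coverage()] profile computed from the
#'   same hit set; computed on the fly when omitted.
#' @param sd_multiplier Peak threshold multiplier (default 2).
#' @return The qualified hits, with attributes `n_removed`, `threshold` and
#'   `removed` (the removed rows).
#' @export
filter_recruited_reads <- function(hits, profile = NULL, sd_multiplier = 2) {
  if (is.null(profile)) profile <- compute_coverage(hits)
  stopifnot(inherits(profile, "coverage_profile"))
  if (nrow(hits) > 0L && !identical(unique(hits$genome_id), profile$genome_id)) {
    stop("profile genome (", profile$genome_id,
         ") does not match hits genome (",
         paste(unique(hits$genome_id), collapse = ", "), ")")
  }
  if (sum(profile$D) != nrow(hits)) {
    stop("profile was not computed from this hit set (",
         sum(profile$D), " profiled hits vs ", nrow(hits), " rows)")
  }
  threshold <- profile$M + sd_multiplier * profile$SD
  keep <- profile$D[as.character(hits$start)] <= threshold
  qualified <- hits[keep, , drop = FALSE]
  rownames(qualified) <- NULL
  removed <- hits[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  attr(qualified, "n_removed") <- nrow(removed)
  attr(qualified, "threshold") <- threshold
  attr(qualified, "removed") <- removed
  qualified
}
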