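#' Recruitment parameter set
#'
#' Bundles the tunables of the fragment recruiter. The identity threshold is
#' strict: a hit must have `matches / align_len` strictly greater than
#' `identity_threshold` (the conventional "> 97%" cutoff keeps only reads
#' from closely related genomes). `q` is the q-gram length of the candidate
#' filter; reads shorter than `min_align_len` are skipped and counted.
#'
#' @param identity_threshold Fraction in (0, 1]; default 0.97.
#' @param q q-gram length, between 4 and 31; default 11.
#' @param max_reads Subsample cap: only the first `max_reads` reads of a
#'   sample are recruited (default ten million).
#' @param min_align_len Minimum read length in bases (default 30); must be
#'   at least `q`.
#' @param strands `"both"` (default) searches the reverse complement of each
#'   read as well; `"forward"` does not. Coordinates are always reported on
#'   the forward strand of the genome.
#' @return An object of class `recruitment_params`.
#' @export
recruitment_params <- function(identity_threshold = 0.97, q = 11,
                               max_reads = 10000000, min_align_len = 30,
                               strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]")
  }
  q <- as.integer(q)
  if (is.na(q) || q < 4L || q > 31L) stop("q must be between 4 and 31")
  min_align_len <- as.integer(min_align_len)
  if (is.na(min_align_len) || min_align_len < q) {
    stop("min_align_len must be at least q (", q, ")")
  }
  max_reads <- as.numeric(max_reads)
  if (is.na(max_reads) || max_reads < 1) stop("max_reads must be positive")
  structure(list(identity_threshold = identity_threshold, q = q,
                 max_reads = max_reads, min_align_len = min_align_len,
                 strands = strands),
            class = "recruitment_params")
}

#' @export
print.recruitment_params <- function(x, ...) {
  cat("Recruitment parameters\n",
      "  identity threshold : > ", x$identity_threshold, "\n",
      "  q-gram length      : ", x$q, "\n",
      "  max reads          : ", format(x$max_reads, big.mark = ","), "\n",
      "  min alignment len  : ", x$min_align_len, "\n",
      "  strands            : ", x$strands, "\n", sep = "")
  invisible(x)
}

#' Positional q-gram index of a genome
#'
#' Maps every length-`q` substring of the genome (windows containing an `N`
#' are skipped) to the sorted list of its 0-based start offsets. This is the
#' lookup structure behind the candidate filter of [recruit_read()]; it is
#' exposed mainly for inspection and testing.
#'
#' @param genome A single sequence: character string, named length-1
#'   character vector, or a [Biostrings::DNAStringSet] of length 1.
#' @param q q-gram length (4..31).
#' @return Named list: q-gram string -> integer vector of 0-based offsets.
#' @examples
#' build_qgram_index(c(g = "ACGTACGT"), q = 4)[["ACGT"]]  # 0 4
#' @export
build_qgram_index <- function(genome, q = 11) {
  seqs <- as_single_sequence(genome)
  q <- as.integer(q)
  if (is.na(q) || q < 4L || q > 31L) stop("q must be between 4 and 31")
  if (nchar(seqs) < q) {
    stop("genome is shorter (", nchar(seqs), ") than q (", q, ")")
  }
  cpp_qgram_index(seqs, q)
}

#' Recruit one read onto one genome
#'
#' Candidate genome windows are those sharing at least
#' `n - q + 1 - k * q` position-consistent q-grams with the read, where `n`
#' is the read length and `k = floor((1 - identity_threshold) * n)` is the
#' largest mismatch count the threshold can tolerate (the q-gram lemma makes
#' this filter lossless). Each surviving full-length window is scored by
#' ungapped comparison; hits with identity strictly above the threshold are
#' returned, best identity first (ties: leftmost start, then forward
#' strand). With `strands = "both"` the reverse complement of the read is
#' searched too, with coordinates reported on the forward genome strand.
#'
#' @param read A single read: character string, or list/one-row data frame
#'   with `id` and `sequence`.
#' @param genome A single named sequence (see [build_qgram_index()]).
#' @param params A [recruitment_params()] object.
#' @return Hits data frame with columns `read_id`, `genome_id`, `start`
#'   (0-based), `end` (exclusive), `strand`, `matches`, `align_len`,
#'   `identity`. No candidate window means zero rows, not an error.
#' @export
recruit_read <- function(read, genome, params = recruitment_params()) {
  rd <- as_reads(read)
  if (nchar(rd$sequence[1L]) < params$min_align_len) {
    stop("read is shorter than min_align_len (", params$min_align_len, ")")
  }
  hits <- recruit_to_genome(rd, name_single_genome(genome), params,
                            best_per_read = FALSE)
  attr(hits, "skipped_short") <- NULL
  hits
}

#' Recruit a read set onto a panel of reference genomes
#'
#' Every read is compared independently against every genome, so one read
#' may be recruited to several genomes (recruitment abundances are
#' per-genome quantities). Within one genome only the best hit per read is
#' kept: highest identity, ties broken by smallest start, then forward
#' strand. Only the first `params$max_reads` reads are used; reads shorter
#' than `params$min_align_len` are skipped and counted in the
#' `skipped_short` attribute.
#'
#' @param reads Data frame of reads (`id`, `sequence`) as returned by
#'   [read_fastq()] or [generate_sample()].
#' @param genomes Named [Biostrings::DNAStringSet] or named character vector.
#' @param params A [recruitment_params()] object.
#' @return Named list (one element per genome) of hits data frames, with
#'   attributes `n_reads_used` and `skipped_short`.
#' @export
recruit_sample <- function(reads, genomes, params = recruitment_params()) {
  genomes <- as_genome_set(genomes)
  if (length(genomes) == 0L) stop("at least one reference genome is required")
  reads <- as_reads(reads)
  if (nrow(reads) > params$max_reads) {
    reads <- reads[seq_len(params$max_reads), , drop = FALSE]
  }
  if (nrow(reads) == 0L) warning("empty read stream: no reads to recruit")
  out <- vector("list", length(genomes))
  names(out) <- names(genomes)
  skipped <- 0L
  for (g in names(genomes)) {
    hits <- recruit_to_genome(reads, genomes[g], params, best_per_read = TRUE)
    skipped <- attr(hits, "skipped_short")
    attr(hits, "skipped_short") <- NULL
    out[[g]] <- hits
  }
  attr(out, "n_reads_used") <- nrow(reads)
  attr(out, "skipped_short") <- skipped
  out
}

#' Brute-force reference recruitment of one read
#'
#' Scores every full-length window of the genome (both strands unless
#' `strands = "forward"`) by direct ungapped comparison, with no q-gram
#' filter. This is the reference implementation used to validate
#' [recruit_read()]; it is exact but quadratic and only intended for small
#' instances.
#'
#' @inheritParams recruit_read
#' @return Hits data frame in the same format as [recruit_read()].
#' @export
recruit_read_naive <- function(read, genome, params = recruitment_params()) {
  rd <- as_reads(read)
  genome <- as_genome_set(name_single_genome(genome))
  stopifnot(length(genome) == 1L)
  res <- cpp_scan(as.character(genome[[1L]]), rd$sequence[1L],
                  params$identity_threshold, params$strands == "both")
  n <- length(res$start)
  data.frame(read_id = rep(rd$id[1L], n),
             genome_id = rep(names(genome), n),
             start = res$start, end = res$end, strand = as.character(res$strand),
             matches = res$matches, align_len = rep(res$align_len, n),
             identity = res$identity, stringsAsFactors = FALSE)
}

recruit_to_genome <- function(reads, genome, params, best_per_read) {
  genome <- as_genome_set(genome)
  stopifnot(length(genome) == 1L)
  res <- cpp_recruit(as.character(genome[[1L]]), reads$sequence, reads$id,
                     params$q, params$identity_threshold,
                     params$min_align_len, params$strands == "both",
                     best_per_read)
  hits <- data.frame(read_id = res$read_id,
                     genome_id = rep(names(genome), length(res$read_id)),
                     start = res$start, end = res$end, strand = res$strand,
                     matches = res$matches, align_len = res$align_len,
                     identity = res$identity, stringsAsFactors = FALSE)
  attr(hits, "skipped_short") <- res$skipped_short
  hits
}

name_single_genome <- function(genome) {
  if (is.character(genome) && is.null(names(genome))) {
    if (length(genome) != 1L) stop("expected exactly one genome sequence")
    return(stats::setNames(genome, "genome"))
  }
  genome
}

as_single_sequence <- function(genome) {
  g <- as_genome_set(name_single_genome(genome))
  if (length(g) != 1L) stop("expected exactly one genome sequence")
  as.character(g[[1L]])
}

as_reads <- function(read) {
  if (is.data.frame(read)) {
    stopifnot(all(c("id", "sequence") %in% names(read)))
    read$sequence <- toupper(read$sequence)
    return(read)
  }
  if (is.list(read)) {
    return(data.frame(id = read$id, sequence = toupper(read$sequence),
                      stringsAsFactors = FALSE))
  }
  if (is.character(read)) {
    id <- if (is.null(names(read))) paste0("read", seq_along(read)) else
      names(read)
    return(data.frame(id = id, sequence = toupper(unname(read)),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret object of class ", class(read)[1], " as reads")
}
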