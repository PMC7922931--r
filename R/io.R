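#' Read reference genomes from a FASTA file
#'
#' Sequences are uppercased on input; multi-line (wrapped) records are
#' concatenated and CRLF line endings are tolerated. Record names are split
#' at the first whitespace into an id and a free-text description.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A [Biostrings::DNAStringSet] named by record id, with a
#'   `description` metadata column. An empty file yields an empty set with a
#'   warning.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 toy genome", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(Biostrings::width(set) == 0L)) {
    bad <- which(Biostrings::width(set) == 0L)[1L]
    stop("malformed FASTA: empty record '", names(set)[bad], "' in ", path)
  }
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  set <- Biostrings::DNAStringSet(toupper(as.character(set)))
  names(set) <- ids
  S4Vectors::mcols(set)$description <- desc
  set
}

#' Write genomes to a FASTA file
#'
#' Inverse of [read_fasta()]: ids (and descriptions, when present) become
#' headers and sequences are written in 70-column wrapped lines.
#'
#' @param genomes A named [Biostrings::DNAStringSet] or named character
#'   vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  genomes <- as_genome_set(genomes)
  desc <- S4Vectors::mcols(genomes)$description
  out <- genomes
  if (!is.null(desc) && any(nzchar(desc))) {
    names(out) <- ifelse(nzchar(desc), paste(names(genomes), desc),
                         names(genomes))
  }
  Biostrings::writeXStringSet(out, filepath = path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file, keeping the first records only
#'
#' Reads four-line Sanger (Phred+33) FASTQ records in file order, stopping
#' after `max_reads` records. Subsampling a read set by taking the first
#' records of the file is the convention used throughout the recruitment
#' pipeline (the default cap is ten million reads). Qualities are carried
#' along but are not used by the recruiter.
#'
#' @param path Path to a FASTQ file (plain or gzip-compressed).
#' @param max_reads Maximum number of records to read (default `1e7`).
#' @return A data frame with columns `id`, `sequence` (uppercased) and
#'   `quality`.
#' @export
read_fastq <- function(path, max_reads = 10000000L) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  max_reads <- as.integer(max_reads)
  if (is.na(max_reads) || max_reads < 1L) {
    stop("max_reads must be a positive integer")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, n = 4L * max_reads, warn = FALSE)
  lines <- sub("\r$", "", lines)
  n_lines <- length(lines)
  if (n_lines == 0L) {
    warning("empty FASTQ file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n_lines %% 4L != 0L) {
    stop("malformed FASTQ: truncated record at end of ", path,
         " (", n_lines, " lines read, not a multiple of 4)")
  }
  idx <- seq(1L, n_lines, by = 4L)
  headers <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(headers, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ record ", bad_hdr[1L], " in ", path,
         ": header does not start with '@' (line ", idx[bad_hdr[1L]], ")")
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ record ", bad_plus[1L], " in ", path,
         ": separator line does not start with '+'")
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len)) {
    stop("malformed FASTQ record ", bad_len[1L], " in ", path,
         ": sequence and quality lengths differ")
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", headers)),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `sequence` and (optionally)
#'   `quality`; missing qualities are written as constant Phred 40 (`I`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  qual <- reads$quality
  if (is.null(qual)) {
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep("I", n), character(1))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence,
                             "+", qual)), con)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated table with columns `sample_id`, `environment` and
#' `total_reads` (the total read count of the sample, the denominator of the
#' per-billion normalization). Environments are restricted to soil, root and
#' rhizosphere, and each sample must map to exactly one environment.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three validated columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "environment", "total_reads")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  validate_sample_metadata(meta[required])
}

validate_sample_metadata <- function(meta) {
  envs <- c("soil", "root", "rhizosphere")
  bad <- setdiff(unique(meta$environment), envs)
  if (length(bad)) {
    stop("unknown environment(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(envs, collapse = ", "), ")")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id(s): ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  if (any(!is.finite(meta$total_reads)) || any(meta$total_reads <= 0)) {
    stop("total_reads must be positive for every sample")
  }
  meta
}

#' Write sample metadata to TSV
#' @param meta Data frame as returned by [read_sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(validate_sample_metadata(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write recruitment hits to TSV
#'
#' One row per hit with 0-based `start`, exclusive `end` and identity
#' rounded to four decimals, the on-disk interchange format between the
#' recruitment stages.
#'
#' @param hits A hits data frame (or named list of them, one per genome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- bind_hits(hits)
  hits$identity <- round(hits$identity, 4)
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read recruitment hits from TSV
#' @param path Path written by [write_hits()].
#' @return A hits data frame.
#' @export
read_hits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character",
                                   genome_id = "character",
                                   strand = "character"))
}

# coerce character vectors / DNAStringSet to a named DNAStringSet
as_genome_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (is.null(names(x))) stop("genomes must be named")
    return(x)
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("genomes must be named")
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  stop("cannot interpret object of class ", class(x)[1], " as genomes")
}

bind_hits <- function(hits_list) {
  do.call(rbind, c(hits_list, list(make.row.names = FALSE)))
}
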