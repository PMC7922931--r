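#' Simulation configuration
#'
#' Bundles the knobs of the seeded input generator. The defaults emulate a
#' small recruitment study: a handful of reference genomes diverged ~25%
#' from a common ancestor (far below the recruiter's >97% identity window,
#' so genomes are clearly distinguishable at read length 100), reads
#' carrying 2% substitution noise against the >97% identity threshold, a
#' conserved repeat element shared by all genomes (playing the role of an
#' rRNA-like repetitive region that attracts cross-taxon reads and creates
#' the coverage peaks the peak filter removes), a fraction of off-target
#' reads from an unrelated genome, and two samples in each of the soil,
#' root and rhizosphere environments.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including the seed.
#' @param n_genomes Number of reference genomes.
#' @param genome_length Genome length in bases.
#' @param pairwise_divergence Expected fraction of differing sites between
#'   two reference genomes.
#' @param n_reads Reads per sample.
#' @param read_length Read length in bases.
#' @param read_divergence Per-base substitution rate applied to sampled
#'   reads (sequencing error plus strain-level divergence).
#' @param repeat_length Length of the shared repeat element.
#' @param repeat_copies_per_genome Copies of the repeat planted per genome.
#' @param offtarget_fraction Fraction of reads drawn from an unrelated
#'   random genome.
#' @param environment_layout Named integer vector: samples per environment.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genomes = 5L,
                              genome_length = 10000L,
                              pairwise_divergence = 0.25,
                              n_reads = 5000L,
                              read_length = 100L,
                              read_divergence = 0.02,
                              repeat_length = 150L,
                              repeat_copies_per_genome = 3L,
                              offtarget_fraction = 0.1,
                              environment_layout = c(soil = 2L, root = 2L,
                                                     rhizosphere = 2L)) {
  fr <- c(pairwise_divergence = pairwise_divergence,
          read_divergence = read_divergence,
          offtarget_fraction = offtarget_fraction)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) stop(paste(bad, collapse = ", "), " must lie in [0, 1]")
  if (read_length > genome_length) {
    stop("read_length cannot exceed genome_length")
  }
  if (repeat_length * repeat_copies_per_genome > genome_length / 2) {
    stop("repeat copies would occupy more than half of each genome")
  }
  if (pairwise_divergence > 0.75) {
    stop("pairwise_divergence above 0.75 is not representable with a ",
         "uniform substitution model")
  }
  cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
              genome_length = as.integer(genome_length),
              pairwise_divergence = pairwise_divergence,
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              read_divergence = read_divergence,
              repeat_length = as.integer(repeat_length),
              repeat_copies_per_genome = as.integer(repeat_copies_per_genome),
              offtarget_fraction = offtarget_fraction,
              environment_layout = environment_layout)
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-genome substitution rate d such that two genomes independently
# mutated from one ancestor at rate d show the target pairwise divergence
# p = 2 d (1 - d) + (2/3) d^2 (both-mutated sites still differ w.p. 2/3)
divergence_rate <- function(p) {
  if (p == 0) return(0)
  (2 - sqrt(4 - 16 * p / 3)) / (8 / 3)
}

mutate_sequence <- function(codes, rate) {
  if (rate <= 0) return(codes)
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit)) {
    # shift by 1..3 modulo 4: always lands on a different base
    codes[hit] <- (codes[hit] + sample.int(3L, length(hit),
                                           replace = TRUE)) %% 4L
  }
  codes
}

codes_to_seq <- function(codes) paste(BASES[codes + 1L], collapse = "")
random_codes <- function(n) sample.int(4L, n, replace = TRUE) - 1L

# non-overlapping 0-based start positions for the repeat copies: draw the
# gap layout uniformly by sampling starts in the "compressed" genome with
# all copies removed, then re-expanding
place_repeats <- function(genome_length, repeat_length, copies) {
  if (copies == 0L) return(integer(0))
  slack <- genome_length - copies * repeat_length
  stopifnot(slack >= 0)
  compressed <- sort(sample.int(slack + 1L, copies, replace = FALSE) - 1L)
  compressed + (seq_len(copies) - 1L) * repeat_length
}

#' Generate reference genomes with a shared planted repeat
#'
#' Genomes are mutated independently from one random ancestor so that any
#' two of them sit at the configured expected pairwise divergence
#' (substitutions only; no indels, keeping ungapped alignment exact). One
#' shared repeat element is then written, unmutated and identical across
#' genomes, at random non-overlapping positions of every genome - the
#' conserved-repeat failure mode that the coverage peak filter targets.
#'
#' @param config A [simulation_config()].
#' @return List with `genomes` (named [Biostrings::DNAStringSet]) and
#'   `truth`: list with `divergence_rate`, `repeat_seq` and `repeats`
#'   (data frame `genome_id`, `start`, `end`, 0-based end-exclusive).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$genome_length
    d <- divergence_rate(config$pairwise_divergence)
    ancestor <- random_codes(L)
    repeat_seq <- codes_to_seq(random_codes(config$repeat_length))
    ids <- sprintf("genome_%02d", seq_len(config$n_genomes))
    seqs <- character(config$n_genomes)
    repeats <- vector("list", config$n_genomes)
    for (i in seq_len(config$n_genomes)) {
      codes <- mutate_sequence(ancestor, d)
      s <- codes_to_seq(codes)
      starts <- place_repeats(L, config$repeat_length,
                              config$repeat_copies_per_genome)
      for (st in starts) {
        substr(s, st + 1L, st + config$repeat_length) <- repeat_seq
      }
      seqs[i] <- s
      repeats[[i]] <- data.frame(genome_id = rep(ids[i], length(starts)),
                                 start = starts,
                                 end = starts + config$repeat_length,
                                 stringsAsFactors = FALSE)
    }
    genomes <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    list(genomes = genomes,
         truth = list(divergence_rate = d, repeat_seq = repeat_seq,
                      repeats = do.call(rbind, repeats)))
  })
}

#' Generate a metagenome read sample with per-read ground truth
#'
#' Reads are sampled uniformly from both strands of the source genome and
#' mutated by per-base substitution at `read_divergence`. A fraction of
#' off-target reads is drawn from an unrelated random genome generated
#' alongside the sample. Each read is labelled with its origin and, for
#' on-target reads, whether it lies entirely within a planted repeat copy.
#' Qualities are constant Phred 40 (`I`) - they are carried in the FASTQ
#' convention but unused by the recruiter.
#'
#' @param config A [simulation_config()].
#' @param genomes Reference genomes from [generate_references()].
#' @param source_genome_id Id of the genome the on-target reads come from.
#' @param truth Truth record of [generate_references()] (for repeat
#'   labelling); may be `NULL` when repeat labels are not needed.
#' @param sample_id Sample label used in read ids and metadata.
#' @param environment One of soil, root, rhizosphere.
#' @param seed Seed for this sample; defaults to the config seed (give each
#'   sample its own seed to generate several distinct samples).
#' @return List with `reads` (data frame `id`, `sequence`, `quality`),
#'   `meta` (one-row metadata data frame with `total_reads` = reads
#'   generated), `read_truth` (data frame `read_id`, `origin`, `start`,
#'   `end`, `strand`, `repeat_derived`) and `offtarget_genome`.
#' @export
generate_sample <- function(config, genomes, source_genome_id, truth = NULL,
                            sample_id = "S1", environment = "soil",
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  genomes <- as_genome_set(genomes)
  if (!source_genome_id %in% names(genomes)) {
    stop("source genome '", source_genome_id, "' not among the references")
  }
  with_seed(seed, {
    n <- config$n_reads
    rl <- config$read_length
    src <- as.character(genomes[[source_genome_id]])
    L <- nchar(src)
    off_genome <- codes_to_seq(random_codes(L))
    is_off <- stats::runif(n) < config$offtarget_fraction
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      tpl <- if (is_off[i]) off_genome else src
      w <- substr(tpl, starts[i] + 1L, starts[i] + rl)
      codes <- match(strsplit(w, "", fixed = TRUE)[[1]], BASES) - 1L
      codes <- mutate_sequence(codes, config$read_divergence)
      s <- codes_to_seq(codes)
      if (strands[i] == "-") s <- revcomp_chr(s)
      seqs[i] <- s
    }
    ids <- sprintf("%s_r%05d", sample_id, seq_len(n))
    repeat_derived <- rep(FALSE, n)
    if (!is.null(truth)) {
      reps <- truth$repeats[truth$repeats$genome_id == source_genome_id, ,
                            drop = FALSE]
      if (nrow(reps)) {
        for (j in seq_len(nrow(reps))) {
          inside <- !is_off & starts >= reps$start[j] &
            (starts + rl) <= reps$end[j]
          repeat_derived <- repeat_derived | inside
        }
      }
    }
    list(reads = data.frame(id = ids, sequence = seqs,
                            quality = strrep("I", rl),
                            stringsAsFactors = FALSE),
         meta = data.frame(sample_id = sample_id, environment = environment,
                           total_reads = n, stringsAsFactors = FALSE),
         read_truth = data.frame(read_id = ids,
                                 origin = ifelse(is_off, "offtarget",
                                                 "target"),
                                 start = starts, end = starts + rl,
                                 strand = strands,
                                 repeat_derived = repeat_derived,
                                 stringsAsFactors = FALSE),
         offtarget_genome = off_genome)
  })
}

#' Generate a full multi-environment simulated study
#'
#' Convenience wrapper: references plus one sample per slot of the
#' environment layout, cycling the source genome over the references so
#' different environments favour different genomes. Sample seeds are
#' derived as `config$seed + sample index`.
#'
#' @param config A [simulation_config()].
#' @return List with `genomes`, `truth`, `samples` (named list of
#'   [generate_sample()] results) and `metadata` (combined data frame).
#' @export
generate_study <- function(config) {
  refs <- generate_references(config)
  layout <- config$environment_layout
  envs <- rep(names(layout), layout)
  samples <- vector("list", length(envs))
  names(samples) <- sprintf("%s_%02d", envs, unlist(lapply(layout, seq_len)))
  for (i in seq_along(envs)) {
    src <- names(refs$genomes)[(i - 1L) %% length(refs$genomes) + 1L]
    samples[[i]] <- generate_sample(config, refs$genomes, src, refs$truth,
                                    sample_id = names(samples)[i],
                                    environment = envs[i],
                                    seed = config$seed + i)
  }
  metadata <- do.call(rbind, lapply(samples, `[[`, "meta"))
  rownames(metadata) <- NULL
  list(genomes = refs$genomes, truth = refs$truth, samples = samples,
       metadata = metadata)
}

#' Generate a compatibility matrix with a planted clique
#'
#' Symmetric strain-by-strain matrix with entries `+`, `-` or `nc`. The
#' planted members are pairwise `+`; every other pair is `nc` with
#' probability `nc_rate`, otherwise `+` with probability `edge_density`,
#' otherwise `-`. The truth record names the planted set so clique recovery
#' can be scored without re-deriving it.
#'
#' @param n_strains Number of strains.
#' @param planted_clique_size Size of the planted all-compatible set
#'   (0 plants nothing).
#' @param edge_density Probability that a non-planted pair is compatible.
#' @param nc_rate Probability that a non-planted pair is unclear.
#' @param seed Integer seed.
#' @return List with `compat` (character matrix, `+` diagonal) and
#'   `truth` (list with `planted`, the sorted planted strain names).
#' @export
generate_compatibility <- function(n_strains, planted_clique_size = 0L,
                                   edge_density = 0.3, nc_rate = 0,
                                   seed = 1L) {
  stopifnot(planted_clique_size <= n_strains,
            edge_density >= 0, edge_density <= 1,
            nc_rate >= 0, nc_rate <= 1)
  with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(n_strains))
    m <- empty_compat(ids)
    planted <- sort(sample(ids, planted_clique_size))
    for (i in seq_len(n_strains - 1L)) {
      for (j in seq((i + 1L), n_strains)) {
        a <- ids[i]; b <- ids[j]
        v <- if (a %in% planted && b %in% planted) {
          "+"
        } else if (stats::runif(1) < nc_rate) {
          "nc"
        } else if (stats::runif(1) < edge_density) {
          "+"
        } else {
          "-"
        }
        m[a, b] <- v
        m[b, a] <- v
      }
    }
    list(compat = m, truth = list(planted = planted))
  })
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
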