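#' Run the full recruitment pipeline on a set of samples
#'
#' Orchestrates recruit -> peak-filter -> count -> normalize for every
#' sample: reads are recruited to every reference genome, recruited reads
#' piled up at abnormally highly covered loci are removed (one pass per
#' genome), and the surviving counts are normalized per billion reads, per
#' sample and pooled per environment. All stage outputs and a JSON run
#' manifest with per-stage read counts are written below `out_dir`.
#'
#' @param refs Reference genomes: FASTA path or named
#'   [Biostrings::DNAStringSet].
#' @param samples Named list or vector, one element per sample: a FASTQ
#'   path or a reads data frame (`id`, `sequence`). Names are sample ids.
#' @param metadata Sample metadata data frame (or TSV path) with
#'   `sample_id`, `environment`, `total_reads` covering every sample.
#' @param params A [recruitment_params()] object.
#' @param out_dir Output directory, created if needed; `NULL` skips all
#'   file output.
#' @param sd_multiplier Peak threshold multiplier for the coverage filter.
#' @return List with `counts` (qualified genomes x samples matrix),
#'   `abundance` (per-sample [abundance_matrix()]), `by_environment`,
#'   `qualified` (hits by sample and genome) and `manifest`, invisibly.
#' @export
run_recruitment_pipeline <- function(refs, samples, metadata,
                                     params = recruitment_params(),
                                     out_dir = NULL, sd_multiplier = 2) {
  # fail on configuration problems before any compute
  if (is.character(refs) && length(refs) == 1L && !file.exists(refs)) {
    stop("reference FASTA not found: ", refs)
  }
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  metadata <- validate_sample_metadata(metadata)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be named by sample id")
  }
  missing_meta <- setdiff(names(samples), metadata$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  for (s in names(samples)) {
    if (is.character(samples[[s]]) && !file.exists(samples[[s]])) {
      stop("FASTQ for sample ", s, " not found: ", samples[[s]])
    }
  }
  genomes <- if (is.character(refs)) read_fasta(refs) else as_genome_set(refs)

  qualified <- list()
  sample_stats <- list()
  for (s in names(samples)) {
    reads <- if (is.character(samples[[s]])) {
      read_fastq(samples[[s]], max_reads = params$max_reads)
    } else {
      samples[[s]]
    }
    hits <- recruit_sample(reads, genomes, params)
    q <- lapply(hits, function(h) {
      filter_recruited_reads(h, sd_multiplier = sd_multiplier)
    })
    qualified[[s]] <- q
    sample_stats[[s]] <- list(
      n_input = nrow(reads),
      n_used = attr(hits, "n_reads_used"),
      skipped_short = attr(hits, "skipped_short"),
      recruited = vapply(hits, nrow, integer(1)),
      removed_by_peak_filter = vapply(q, function(x) {
        attr(x, "n_removed")
      }, integer(1)),
      qualified = vapply(q, nrow, integer(1)))
  }

  counts <- count_matrix(qualified)
  am <- abundance_matrix(counts, metadata)
  am_env <- aggregate_by_environment(am)
  manifest <- list(
    tool = "pgpmkit", version = as.character(utils::packageVersion("pgpmkit")),
    parameters = unclass(params), sd_multiplier = sd_multiplier,
    genomes = names(genomes), samples = sample_stats)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "qualified"), recursive = TRUE,
               showWarnings = FALSE)
    for (s in names(qualified)) {
      write_hits(qualified[[s]],
                 file.path(out_dir, "qualified", paste0(s, ".tsv")))
    }
    write_abundance(am, file.path(out_dir, "matrix_samples.tsv"))
    write_abundance(am_env, file.path(out_dir, "matrix_environments.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(counts = counts, abundance = am, by_environment = am_env,
                 qualified = qualified, manifest = manifest))
}

#' Run the consortium design and biostimulant pipeline
#'
#' Loads the packaged tables, validates the published consortia MC_A, MC_B
#' and MC_C pair by pair, enumerates candidate consortia as maximal
#' compatible cliques covering the required functions, and ranks the
#' bioactive compounds for every published consortium.
#'
#' @param fixture_dir Fixture directory (defaults to the packaged tables).
#' @param policy Compatibility policy for candidate enumeration.
#' @param required_functions Function tags candidates must jointly cover.
#'   The default is empty: coverage of the standard functions is always
#'   reported in the validation output, but it is not enforced as a hard
#'   candidate filter because the published designs themselves treat it as
#'   a design aim, not a constraint every consortium satisfies (requiring
#'   all of them would exclude every clique, since the sole IAA producer
#'   and the sole amylolytic strain are mutually incompatible).
#' @param size_range Candidate size range (default 5 or more members).
#' @param out_dir Optional output directory for JSON/CSV reports.
#' @return List with `tables`, `validations` (one report per published
#'   consortium), `candidates` and `biostimulant_rankings`, invisibly.
#' @export
run_consortium_pipeline <- function(fixture_dir = pgpm_fixtures(),
                                    policy = c("lenient", "strict"),
                                    required_functions = character(0),
                                    size_range = c(5, Inf),
                                    out_dir = NULL) {
  policy <- match.arg(policy)
  tables <- load_paper_tables(fixture_dir)
  validations <- lapply(names(tables$consortia), function(nm) {
    validate_consortium(nm, tables)
  })
  names(validations) <- names(tables$consortia)
  candidates <- enumerate_consortia(tables,
                                    required_functions = required_functions,
                                    size_range = size_range, policy = policy)
  rankings <- lapply(names(tables$consortia), function(nm) {
    rank_compounds(nm, tables)
  })
  names(rankings) <- names(tables$consortia)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(validations)) {
      v <- validations[[nm]]
      jsonlite::write_json(
        list(name = v$name, members = v$members, pairs = v$pairs,
             incompatible_pairs = v$incompatible_pairs,
             unclear_pairs = v$unclear_pairs,
             missing_pairs = v$missing_pairs,
             function_coverage = v$function_coverage,
             uncovered_functions = v$uncovered_functions,
             passes_strict = v$passes_strict,
             passes_lenient = v$passes_lenient),
        file.path(out_dir, paste0("validation_", nm, ".json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    cand_df <- data.frame(
      name = vapply(candidates, `[[`, character(1), "name"),
      size = vapply(candidates, function(x) length(x$members), integer(1)),
      members = vapply(candidates, function(x) {
        paste(x$members, collapse = "; ")
      }, character(1)))
    utils::write.csv(cand_df, file.path(out_dir, "candidates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(rankings,
                         file.path(out_dir, "biostimulant_rankings.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(tables = tables, validations = validations,
                 candidates = candidates, biostimulant_rankings = rankings))
}
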