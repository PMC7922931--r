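test_that("q-gram index maps substrings to all their offsets", {
  idx <- build_qgram_index(c(g = "ACGTACGT"), q = 4)
  expect_equal(idx[["ACGT"]], c(0L, 4L))
  expect_equal(idx[["CGTA"]], 1L)
  expect_length(build_qgram_index(c(g = strrep("N", 50)), q = 4), 0)
  expect_error(build_qgram_index(c(g = "ACG"), q = 4), "shorter")
})

test_that("q-gram index skips exactly the windows containing N", {
  set.seed(101)
  g <- strsplit(random_dna(1000), "", fixed = TRUE)[[1]]
  g[sample(1000, 20)] <- "N"
  genome <- paste(g, collapse = "")
  q <- 11
  idx <- build_qgram_index(c(g = genome), q = q)
  # direct window scan: a window is indexed iff it contains no N
  n_valid <- sum(vapply(0:(1000 - q), function(s) {
    !any(g[(s + 1):(s + q)] == "N")
  }, logical(1)))
  expect_equal(sum(lengths(idx)), n_valid)
})

test_that("an exact read is recruited at its template locus", {
  set.seed(7)
  genome <- c(ref = random_dna(2000))
  read <- substr(genome, 38, 137)  # 0-based offset 37, length 100
  hits <- recruit_read(c(r1 = read), genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 37L)
  expect_equal(hits$end, 137L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$align_len, hits$end - hits$start)
})

test_that("the >97% threshold is strict at the mismatch boundary", {
  set.seed(8)
  genome <- c(ref = random_dna(3000))
  template <- substr(genome, 501, 600)  # 100 bases at offset 500
  two_sub <- substitute_bases(template, c(10, 60))
  three_sub <- substitute_bases(template, c(10, 60, 90))
  h2 <- recruit_read(c(r = two_sub), genome)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$identity, 0.98)     # 2 mismatches: recruited
  expect_equal(h2$start, 500L)
  h3 <- recruit_read(c(r = three_sub), genome)
  expect_equal(nrow(h3), 0)           # 97/100 is not strictly above 0.97
})

test_that("reverse-complement reads map to forward-strand coordinates", {
  set.seed(9)
  genome <- c(ref = random_dna(1500))
  window <- substr(genome, 301, 400)
  hits <- recruit_read(c(r = revcomp(window)), genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 300L)
  expect_equal(hits$strand, "-")
  # forward-only search does not find it
  fwd <- recruit_read(c(r = revcomp(window)), genome,
                      recruitment_params(strands = "forward"))
  expect_equal(nrow(fwd), 0)
})

test_that("reads without shared q-grams yield an empty result, not an error", {
  set.seed(10)
  genome <- c(ref = random_dna(2000))
  alien <- random_dna(100)
  expect_equal(nrow(recruit_read(c(r = alien), genome)), 0)
})

test_that("a read matching two genomes is recruited to both", {
  set.seed(11)
  g <- random_dna(1000)
  genomes <- c(a = g, b = g)
  read <- data.frame(id = "r1", sequence = substr(g, 101, 200))
  hits <- recruit_sample(read, genomes)
  expect_equal(nrow(hits$a), 1)
  expect_equal(nrow(hits$b), 1)
})

test_that("only the first max_reads reads contribute hits", {
  set.seed(12)
  genome <- c(ref = random_dna(2000))
  reads <- data.frame(id = sprintf("r%03d", 1:500),
                      sequence = vapply(1:500, function(i) {
                        s <- sample(1900, 1)
                        substr(genome, s, s + 99)
                      }, character(1)))
  hits <- recruit_sample(reads, genome,
                         recruitment_params(max_reads = 100))
  expect_equal(attr(hits, "n_reads_used"), 100)
  expect_lte(nrow(hits$ref), 100)
  expect_true(all(hits$ref$read_id %in% reads$id[1:100]))
})

test_that("error-free reads from one reference are never cross-recruited", {
  cfg <- simulation_config(seed = 31, n_genomes = 2, genome_length = 8000,
                           pairwise_divergence = 0.25, n_reads = 1000,
                           read_length = 100, read_divergence = 0,
                           repeat_copies_per_genome = 0,
                           offtarget_fraction = 0)
  refs <- generate_references(cfg)
  smp <- generate_sample(cfg, refs$genomes, "genome_01", refs$truth)
  hits <- recruit_sample(smp$reads, refs$genomes)
  expect_equal(nrow(hits$genome_01), 1000)
  expect_true(all(hits$genome_01$identity == 1))
  expect_equal(nrow(hits$genome_02), 0)
})

test_that("short reads are skipped and counted", {
  genome <- c(ref = random_dna(500))
  reads <- data.frame(id = c("long", "short"),
                      sequence = c(substr(genome, 1, 60), "ACGTACGTACGT"))
  hits <- recruit_sample(reads, genome)
  expect_equal(attr(hits, "skipped_short"), 1L)
  expect_equal(hits$ref$read_id, "long")
  expect_error(recruit_read(c(r = "ACGTACGTACGT"), genome), "min_align_len")
})

test_that("empty read streams warn and recruit nothing", {
  genome <- c(ref = random_dna(500))
  empty <- data.frame(id = character(), sequence = character())
  expect_warning(hits <- recruit_sample(empty, genome), "empty read stream")
  expect_equal(nrow(hits$ref), 0)
})

test_that("indexed recruitment equals the brute-force scan on random instances", {
  set.seed(42)
  params <- recruitment_params()
  for (inst in 1:10) {
    genome <- c(g = random_dna(sample(800:2500, 1)))
    n <- sample(c(50, 80, 100, 150), 1)
    L <- nchar(genome)
    for (r in 1:15) {
      kind <- sample(c("derived", "derived_rc", "random"), 1,
                     prob = c(0.4, 0.3, 0.3))
      s <- sample(L - n + 1, 1)
      read <- substr(genome, s, s + n - 1)
      read <- substitute_bases(read, sample(n, sample(0:5, 1)))
      if (kind == "derived_rc") read <- revcomp(read)
      if (kind == "random") read <- random_dna(n)
      fast <- recruit_read(c(r = read), genome, params)
      slow <- recruit_read_naive(c(r = read), genome, params)
      expect_identical(hit_key(fast), hit_key(slow))
    }
  }
})

test_that("the q-gram candidate filter is lossless at the lemma bound", {
  set.seed(43)
  thr <- 0.97
  for (i in 1:10) {
    genome <- random_dna(1200)
    n <- 100
    k <- floor((1 - thr) * n)
    s <- sample(1100, 1)
    read <- substitute_bases(substr(genome, s, s + n - 1),
                             sample(n, sample(0:4, 1)))
    cand <- pgpmkit:::cpp_qgram_candidates(genome, read, 11L, thr)
    close_windows <- windows_within_k(genome, read, k)
    expect_true(all(close_windows %in% cand))
  }
})

test_that("raising the identity threshold never adds hits", {
  set.seed(44)
  genome <- c(g = random_dna(3000))
  for (i in 1:10) {
    s <- sample(2900, 1)
    read <- substitute_bases(substr(genome, s, s + 99),
                             sample(100, sample(0:4, 1)))
    loose <- recruit_read(c(r = read), genome,
                          recruitment_params(identity_threshold = 0.95))
    tight <- recruit_read(c(r = read), genome,
                          recruitment_params(identity_threshold = 0.98))
    expect_true(all(hit_key(tight) %in% hit_key(loose)))
  }
})

test_that("recruitment is deterministic for identical inputs", {
  set.seed(45)
  genome <- c(g = random_dna(1000))
  reads <- data.frame(id = sprintf("r%d", 1:30),
                      sequence = vapply(1:30, function(i) {
                        s <- sample(900, 1)
                        substitute_bases(substr(genome, s, s + 79),
                                         sample(80, 2))
                      }, character(1)))
  h1 <- recruit_sample(reads, genome)
  h2 <- recruit_sample(reads, genome)
  expect_identical(h1, h2)
})
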