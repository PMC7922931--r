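make_hits <- function(loci, genome_id = "g1") {
  n <- length(loci)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             genome_id = rep(genome_id, n),
             start = as.integer(loci), end = as.integer(loci) + 100L,
             strand = rep("+", n), matches = rep(100L, n),
             align_len = rep(100L, n), identity = rep(1, n),
             stringsAsFactors = FALSE)
}

test_that("coverage counts read starts per locus with moments over covered loci", {
  # 30 hits, 3 per locus over 10 loci
  hits <- make_hits(rep(seq(0, 900, by = 100), each = 3))
  prof <- compute_coverage(hits)
  expect_equal(length(prof$D), 10)
  expect_true(all(prof$D == 3))
  expect_equal(prof$M, 3)
  expect_equal(prof$SD, 0)

  prof2 <- compute_coverage(make_hits(c(5, 5, 9)))
  expect_equal(unname(prof2$D[c("5", "9")]), c(2L, 1L))
  expect_equal(prof2$M, 1.5)
  expect_equal(prof2$SD, 0.5)  # population SD of (2, 1)

  prof3 <- compute_coverage(make_hits(42))
  expect_equal(unname(prof3$D), 1L)
  expect_equal(prof3$M, 1)
  expect_equal(prof3$SD, 0)

  empty <- compute_coverage(make_hits(integer(0)))
  expect_equal(empty$M, 0)
  expect_equal(empty$SD, 0)
  expect_length(empty$D, 0)
})

test_that("profiling hits from mixed genomes is refused", {
  hits <- rbind(make_hits(1:3, "g1"), make_hits(1:3, "g2"))
  expect_error(compute_coverage(hits), "several genomes")
})

test_that("uniform coverage removes nothing (threshold degenerates to the mean)", {
  hits <- make_hits(rep(seq(0, 490, by = 10), each = 4))
  q <- filter_recruited_reads(hits)
  expect_equal(nrow(q), nrow(hits))
  expect_equal(attr(q, "n_removed"), 0L)
})

test_that("a 20-read peak over nine singleton loci is removed exactly", {
  hits <- make_hits(c(0:8, rep(500, 20)))
  prof <- compute_coverage(hits)
  expect_equal(prof$M, 2.9)
  expect_equal(prof$SD, sqrt((9 * (1 - 2.9)^2 + (20 - 2.9)^2) / 10))
  thr <- prof$M + 2 * prof$SD
  expect_lt(thr, 20)
  expect_gt(thr, 1)
  q <- filter_recruited_reads(hits, prof)
  expect_equal(nrow(q), 9)
  expect_equal(attr(q, "n_removed"), 20L)
  expect_true(all(q$start <= 8))
  # conservation and order preservation
  expect_equal(nrow(q) + nrow(attr(q, "removed")), nrow(hits))
  expect_identical(q$read_id, hits$read_id[hits$start <= 8])

  mask <- locus_mask(prof)
  expect_equal(sum(!mask$qualified), 1)
  expect_equal(mask$locus[!mask$qualified], 500)
})

test_that("counts exactly at the threshold are qualified", {
  # loci counts 1 and 3: M = 2, SD = 1, threshold = 4 >= both -> keep all;
  # construct counts 2 and 6: M = 4, SD = 2, threshold 8 >= 6 -> keep all
  hits <- make_hits(c(rep(0, 2), rep(10, 6)))
  q <- filter_recruited_reads(hits)
  expect_equal(attr(q, "n_removed"), 0L)
  # now an exact boundary: counts 1,1,4 -> M = 2, SD = sqrt(2), thr = 4.83
  hits2 <- make_hits(c(1, 2, rep(30, 4)))
  expect_equal(attr(filter_recruited_reads(hits2), "n_removed"), 0L)
})

test_that("the locus partition is invariant to scaling all counts", {
  base_loci <- c(0:8, rep(500, 20))   # nine singletons and one clear peak
  scaled_loci <- rep(base_loci, 3)    # every locus count times 3
  m1 <- locus_mask(compute_coverage(make_hits(base_loci)))
  m3 <- locus_mask(compute_coverage(make_hits(scaled_loci)))
  expect_equal(m1$qualified, m3$qualified)
  expect_false(all(m1$qualified))  # the partition is non-trivial
})

test_that("the filter is a deliberate single pass, not a fixed point", {
  # after removing the big peak, the recomputed threshold can drop below a
  # secondary peak: a second pass would remove more, and must not be run
  loci <- c(rep(0, 100), rep(50, 8), rep(seq(100, 1060, by = 10), each = 1))
  hits <- make_hits(loci)
  q1 <- filter_recruited_reads(hits)
  q2 <- filter_recruited_reads(q1[, ])
  expect_lt(nrow(q2), nrow(q1))  # not idempotent by construction
})

test_that("profile/hits mismatches are contract errors", {
  hits <- make_hits(1:10, "g1")
  prof_other <- compute_coverage(make_hits(1:10, "g2"))
  expect_error(filter_recruited_reads(hits, prof_other), "does not match")
  prof_stale <- compute_coverage(make_hits(1:5, "g1"))
  expect_error(filter_recruited_reads(hits, prof_stale), "not computed from")
})

test_that("planted conserved repeats are flushed out end to end", {
  cfg <- simulation_config(seed = 77, n_genomes = 1, genome_length = 20000,
                           n_reads = 4000, read_length = 50,
                           read_divergence = 0, repeat_length = 100,
                           repeat_copies_per_genome = 40,
                           offtarget_fraction = 0)
  refs <- generate_references(cfg)
  smp <- generate_sample(cfg, refs$genomes, "genome_01", refs$truth)
  hits <- recruit_sample(smp$reads, refs$genomes,
                         recruitment_params(min_align_len = 30))$genome_01
  prof <- compute_coverage(hits)
  q <- filter_recruited_reads(hits, prof)
  thr <- attr(q, "threshold")
  # every hit sitting at an over-covered locus is gone, the rest retained
  expect_true(all(prof$D[as.character(q$start)] <= thr))
  removed <- attr(q, "removed")
  expect_true(all(prof$D[as.character(removed$start)] > thr))
  expect_equal(nrow(q) + nrow(removed), nrow(hits))
  # the removed reads are dominated by repeat-derived reads: reads from any
  # of the 40 identical copies stack onto the leftmost copy's loci
  rep_reads <- smp$read_truth$read_id[smp$read_truth$repeat_derived]
  expect_gt(mean(removed$read_id %in% rep_reads), 0.9)
  expect_gt(length(rep_reads), 0)
})
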