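test_that("policy controls which assay verdicts become graph edges", {
  t <- paper_tables()
  strict <- build_compatibility_graph(t, policy = "strict")
  lenient <- build_compatibility_graph(t, policy = "lenient")

  edge <- function(g, a, b) {
    igraph::are_adjacent(g, a, b)
  }
  # incompatible pair: no edge under either policy
  expect_false(edge(strict, "Bacillus sp. BV84",
                    "Bacillus licheniformis PS141"))
  expect_false(edge(lenient, "Bacillus sp. BV84",
                    "Bacillus licheniformis PS141"))
  # compatible pair: edge under both
  expect_true(edge(strict, "Azotobacter chroococcum LS132",
                   "Komagataella pastoris PP59"))
  # unclear pair: lenient only
  expect_false(edge(strict, "Paraburkholderia tropica MDIIIAzo225",
                    "Trichoderma harzianum TH01"))
  expect_true(edge(lenient, "Paraburkholderia tropica MDIIIAzo225",
                   "Trichoderma harzianum TH01"))
  # the lenient graph is a supergraph of the strict graph
  es <- igraph::as_edgelist(strict)
  el <- igraph::as_edgelist(lenient)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(key(es) %in% key(el)))
})

test_that("published consortia validate as printed", {
  t <- paper_tables()

  a <- validate_consortium("MC_A", t)
  expect_equal(length(a$members), 6)
  expect_equal(nrow(a$pairs), choose(6, 2))
  expect_equal(nrow(a$incompatible_pairs), 0)
  expect_false(a$passes_strict)
  expect_true(a$passes_lenient)
  # strict failure is due to exactly one unclear pair
  expect_equal(nrow(a$unclear_pairs), 1)
  expect_setequal(unlist(a$unclear_pairs[1, ]),
                  c("Paraburkholderia tropica MDIIIAzo225",
                    "Trichoderma harzianum TH01"))

  b <- validate_consortium("MC_B", t)
  expect_equal(length(b$members), 5)
  expect_equal(nrow(b$incompatible_pairs), 0)
  expect_true(b$passes_strict)
  expect_true(b$passes_lenient)

  c3 <- validate_consortium("MC_C", t)
  expect_equal(length(c3$members), 5)
  expect_equal(nrow(c3$incompatible_pairs), 0)
  expect_true(c3$passes_strict)
})

test_that("an incompatible pair fails both policies", {
  t <- paper_tables()
  v <- validate_consortium(c("Bacillus sp. BV84",
                             "Bacillus licheniformis PS141"), t)
  expect_equal(nrow(v$incompatible_pairs), 1)
  expect_false(v$passes_strict)
  expect_false(v$passes_lenient)
})

test_that("function coverage reports covering members per required tag", {
  t <- paper_tables()
  b <- validate_consortium("MC_B", t)
  cov <- b$function_coverage
  expect_true("Azotobacter vinelandii DSM 2289" %in%
                cov$nitrogen_fixation)
  expect_true("Bacillus amyloliquefaciens LMG 9814" %in% cov$amylolytic)
  expect_true("Pseudomonas fluorescens DR54" %in% cov$biocontrol)
  expect_true("Pseudomonas fluorescens DR54" %in% cov$P_solubilization)
  # no IAA producer sits in MC_B: reported, not an error
  expect_true("IAA_production" %in% b$uncovered_functions)
})

test_that("unassayed pairs block strict passing only on request", {
  t <- paper_tables()
  both_fungi <- c("Trichoderma harzianum TH01",
                  "Trichoderma harzianum ATCC 48131",
                  "Komagataella pastoris PP59")
  v <- validate_consortium(both_fungi, t)
  expect_equal(nrow(v$missing_pairs), 1)
  expect_true(v$passes_strict)
  v2 <- validate_consortium(both_fungi, t, strict_missing = TRUE)
  expect_false(v2$passes_strict)
})

test_that("unresolvable members are named in the error", {
  t <- paper_tables()
  expect_error(validate_consortium(c("Bacillus sp. BV84", "Klingon X"), t),
               "no alias entry")
})

test_that("a complete compatibility graph yields one maximal clique", {
  m <- matrix("+", 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  out <- enumerate_consortia(m, required_functions = character(0),
                             size_range = c(2, 4))
  expect_length(out, 1)
  expect_equal(out[[1]]$members, paste0("S", 1:4))
})

test_that("planted cliques are recovered from noisy matrices", {
  sim <- generate_compatibility(12, planted_clique_size = 5,
                                edge_density = 0, nc_rate = 0, seed = 3)
  out <- enumerate_consortia(sim$compat, required_functions = character(0),
                             size_range = c(5, 12))
  expect_length(out, 1)
  expect_equal(out[[1]]$members, sim$truth$planted)

  # nc outside the clique carries no strict edge
  sim2 <- generate_compatibility(12, planted_clique_size = 5,
                                 edge_density = 0.5, nc_rate = 1, seed = 4)
  out2 <- enumerate_consortia(sim2$compat, required_functions = character(0),
                              size_range = c(5, 12), policy = "strict")
  expect_length(out2, 1)
  expect_equal(out2[[1]]$members, sim2$truth$planted)
})

test_that("enumeration equals exhaustive power-set search on small instances", {
  for (seed in 1:4) {
    sim <- generate_compatibility(sample(8:12, 1), planted_clique_size = 4,
                                  edge_density = 0.4, nc_rate = 0.15,
                                  seed = seed)
    for (policy in c("lenient", "strict")) {
      mine <- enumerate_consortia(sim$compat,
                                  required_functions = character(0),
                                  size_range = c(2, Inf), policy = policy)
      ref <- brute_force_consortia(sim$compat, policy = policy)
      expect_equal(lapply(mine, `[[`, "members"), ref,
                   ignore_attr = TRUE)
    }
  }
})

test_that("every enumerated consortium validates under its own policy", {
  sim <- generate_compatibility(14, planted_clique_size = 5,
                                edge_density = 0.35, nc_rate = 0.2, seed = 9)
  for (policy in c("lenient", "strict")) {
    out <- enumerate_consortia(sim$compat, required_functions = character(0),
                               size_range = c(2, Inf), policy = policy)
    for (cons in out) {
      v <- validate_consortium(cons$members, sim$compat,
                               required_functions = character(0))
      if (policy == "strict") expect_true(v$passes_strict)
      expect_true(v$passes_lenient)
    }
  }
})

test_that("functions nobody has make enumeration warn and return nothing", {
  t <- paper_tables()
  expect_warning(out <- enumerate_consortia(
    t, required_functions = "levitation"), "levitation")
  expect_length(out, 0)
})

test_that("candidate output order is by size then lexicographic members", {
  sim <- generate_compatibility(10, planted_clique_size = 4,
                                edge_density = 0.5, nc_rate = 0, seed = 11)
  out <- enumerate_consortia(sim$compat, required_functions = character(0),
                             size_range = c(2, Inf))
  sizes <- vapply(out, function(x) length(x$members), integer(1))
  expect_true(all(diff(sizes) <= 0))
  keys <- vapply(out, function(x) paste(x$members, collapse = "|"),
                 character(1))
  for (s in unique(sizes)) {
    expect_false(is.unsorted(keys[sizes == s]))
  }
})
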