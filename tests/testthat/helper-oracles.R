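# shared fixtures and independent reference computations used across tests

paper_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_paper_tables()
    cache
  }
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute the bases at 1-based positions `pos` with a different base
substitute_bases <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# windows of `genome` with at most k mismatches against `read`
# (forward strand, direct position-by-position comparison in R)
windows_within_k <- function(genome, read, k) {
  g <- strsplit(genome, "", fixed = TRUE)[[1]]
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(r)
  starts <- integer(0)
  for (s in 0:(length(g) - n)) {
    w <- g[(s + 1):(s + n)]
    mm <- sum(w != r | !(w %in% c("A", "C", "G", "T")))
    if (mm <= k) starts <- c(starts, s)
  }
  starts
}

# exhaustive power-set enumeration of maximal cliques (>= 2 vertices) of a
# compatibility matrix under a policy; independent of the igraph route
brute_force_consortia <- function(compat, policy = "lenient",
                                  size_range = c(2, Inf),
                                  functions = NULL,
                                  required = character(0)) {
  allowed <- if (policy == "strict") "+" else c("+", "nc")
  adj <- !is.na(compat) & matrix(compat %in% allowed, nrow(compat))
  diag(adj) <- FALSE
  n <- nrow(compat)
  stopifnot(n <= 15)
  nb <- vapply(seq_len(n), function(i) sum(2^(which(adj[i, ]) - 1)),
               numeric(1))
  bits <- 2^(0:(n - 1))
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bits) != 0)
    if (length(idx) < 2) next
    is_clique <- all(vapply(idx, function(i) {
      need <- mask - bits[i]
      bitwAnd(nb[i], need) == need
    }, logical(1)))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), idx)
    extendable <- any(vapply(outside, function(o) {
      bitwAnd(nb[o], mask) == mask
    }, logical(1)))
    if (extendable) next
    if (length(idx) < size_range[1] || length(idx) > size_range[2]) next
    members <- sort(rownames(compat)[idx])
    if (length(required) && !is.null(functions)) {
      if (!all(required %in% unique(unlist(functions[members])))) next
    }
    out[[length(out) + 1]] <- members
  }
  ord <- order(-lengths(out),
               vapply(out, paste, character(1), collapse = "|"))
  out[ord]
}

# canonical comparable form of a hits data frame
hit_key <- function(hits) {
  hits <- hits[order(-hits$identity, hits$start, hits$strand), ]
  paste(hits$start, hits$end, hits$strand, hits$matches, sep = ":")
}
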