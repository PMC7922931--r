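#' Normalize recruitment counts to a per-billion-read basis
#'
#' `N = R * 1e9 / T`: the recruited read count `R` is rescaled as if the
#' sample had a total of 1000 million reads, making samples of different
#' sequencing depth comparable.
#'
#' @param R Recruited (qualified) read count(s); non-negative, at most `T`.
#' @param T Total reads in the sample(s); positive. Recycled against `R`.
#' @return Normalized count(s) `N` as a double.
#' @examples
#' normalize_counts(1000, 1e9)  # 1000
#' normalize_counts(12, 1e7)    # 1200
#' @export
normalize_counts <- function(R, T) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive")
  if (any(!is.finite(R)) || any(R < 0)) stop("R must be non-negative")
  if (any(R > T)) stop("R cannot exceed T (more recruited reads than reads)")
  R * 1e9 / T
}

#' Tally qualified recruitment counts into a genomes x samples matrix
#'
#' @param hits_by_sample Named list (one element per sample) of named lists
#'   of per-genome qualified hits data frames, as produced by
#'   [recruit_sample()] followed by [filter_recruited_reads()].
#' @return Integer matrix of recruited read counts `R`, genomes as rows and
#'   samples as columns.
#' @export
count_matrix <- function(hits_by_sample) {
  stopifnot(is.list(hits_by_sample), length(hits_by_sample) > 0L)
  samples <- names(hits_by_sample)
  genomes <- unique(unlist(lapply(hits_by_sample, names)))
  R <- matrix(0L, nrow = length(genomes), ncol = length(samples),
              dimnames = list(genomes, samples))
  for (s in samples) {
    for (g in names(hits_by_sample[[s]])) {
      R[g, s] <- nrow(hits_by_sample[[s]][[g]])
    }
  }
  R
}

#' Normalized abundance matrix
#'
#' Wraps a genomes x samples count matrix together with the per-sample
#' totals and the derived per-billion normalized values.
#'
#' @param counts Matrix of recruited read counts (genomes x samples).
#' @param metadata Sample metadata data frame with `sample_id`,
#'   `environment`, `total_reads`; every column of `counts` must appear.
#' @return Object of class `abundance_matrix`: list with `values` (the
#'   normalized matrix `N`), `counts`, `totals`, `by` (`"sample"`) and
#'   `scaling` (`"none"`).
#' @export
abundance_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  metadata <- validate_sample_metadata(metadata)
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing)) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  totals <- stats::setNames(metadata$total_reads, metadata$sample_id)
  totals <- totals[colnames(counts)]
  N <- sweep(counts, 2L, 1e9 / totals, `*`)
  structure(list(values = N, counts = counts, totals = totals,
                 environment = stats::setNames(metadata$environment,
                                               metadata$sample_id)[colnames(counts)],
                 by = "sample", scaling = "none"),
            class = "abundance_matrix")
}

#' Pool samples into per-environment normalized abundances
#'
#' For each environment the recruited counts of its samples are pooled
#' before normalizing: `N[e, g] = sum(R[s, g]) * 1e9 / sum(T[s])` over the
#' samples `s` of environment `e` (a ratio of sums, not a mean of
#' per-sample ratios), i.e. counts are normalized to the total number of
#' sequence reads of each environment.
#'
#' @param am An [abundance_matrix()] built per sample (`scaling` must still
#'   be `"none"`).
#' @param metadata Optional metadata overriding the one captured in `am`.
#' @return An `abundance_matrix` with environments as columns
#'   (`by = "environment"`).
#' @export
aggregate_by_environment <- function(am, metadata = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$by != "sample") stop("abundance matrix is already aggregated")
  if (am$scaling != "none") stop("aggregate raw counts before scaling")
  env <- am$environment
  if (!is.null(metadata)) {
    metadata <- validate_sample_metadata(metadata)
    missing <- setdiff(colnames(am$counts), metadata$sample_id)
    if (length(missing)) {
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    }
    env <- stats::setNames(metadata$environment,
                           metadata$sample_id)[colnames(am$counts)]
  }
  envs <- unique(env)
  R <- sapply(envs, function(e) {
    rowSums(am$counts[, env == e, drop = FALSE])
  })
  R <- matrix(R, nrow = nrow(am$counts),
              dimnames = list(rownames(am$counts), envs))
  totals <- stats::setNames(
    vapply(envs, function(e) sum(am$totals[env == e]), numeric(1)), envs)
  N <- sweep(R, 2L, 1e9 / totals, `*`)
  structure(list(values = N, counts = R, totals = totals,
                 environment = stats::setNames(envs, envs),
                 by = "environment", scaling = "none"),
            class = "abundance_matrix")
}

#' Unit-variance scale the rows of an abundance matrix
#'
#' Autoscaling: each row is centred on its mean and divided by its
#' (population) standard deviation, so every genome contributes on the same
#' scale regardless of its absolute abundance. Constant rows have no
#' variance to scale by and are mapped to all zeros with a warning.
#'
#' @param am An [abundance_matrix()], or a plain numeric matrix with at
#'   least two columns.
#' @return Same type as the input, with `scaling = "row_autoscaled"` when an
#'   `abundance_matrix` was given.
#' @export
autoscale_rows <- function(am) {
  m <- if (inherits(am, "abundance_matrix")) am$values else as.matrix(am)
  if (ncol(m) < 2L) stop("autoscaling needs at least two columns")
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  flat <- sdev == 0
  if (any(flat)) {
    warning("constant row(s) mapped to zero: ",
            paste(rownames(m)[flat], collapse = ", "))
    sdev[flat] <- 1
  }
  scaled <- (m - mu) / sdev
  if (inherits(am, "abundance_matrix")) {
    am$values <- scaled
    am$scaling <- "row_autoscaled"
    am
  } else {
    scaled
  }
}

#' Cluster an abundance matrix for heatmap display
#'
#' Rows and columns are clustered independently by agglomerative
#' hierarchical clustering with average linkage (UPGMA) on Euclidean
#' distances. Ties in the minimal inter-cluster distance are broken by
#' merging the lexicographically smallest index pair, which makes the
#' result deterministic.
#'
#' @param am An [abundance_matrix()] or plain numeric matrix with at least
#'   two rows and two columns and no missing values.
#' @return List with `row_order`, `col_order` (label vectors in display
#'   order) and `row_tree`, `col_tree` (`hclust` objects).
#' @export
cluster_matrix <- function(am) {
  m <- if (inherits(am, "abundance_matrix")) am$values else as.matrix(am)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("clustering needs at least two rows and two columns")
  }
  if (any(!is.finite(m))) stop("matrix contains missing or infinite values")
  row_tree <- upgma(as.matrix(stats::dist(m)))
  col_tree <- upgma(as.matrix(stats::dist(t(m))))
  list(row_order = rownames(m)[row_tree$order],
       col_order = colnames(m)[col_tree$order],
       row_tree = row_tree, col_tree = col_tree)
}

#' Average-linkage (UPGMA) agglomeration with a fixed tie-break
#'
#' Naive O(n^3) agglomerative clustering: at each step the pair of clusters
#' at minimal average-linkage distance is merged; among equal minimal
#' distances the lexicographically smallest (i, j) index pair wins. Returns
#' a standard [stats::hclust] object (merge, height, order).
#'
#' @param d Symmetric numeric distance matrix with labels.
#' @return An object of class `hclust` with `method = "average"`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L, ncol(d) == n)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters are indexed by their hclust code: -i for singletons,
  # +k for the cluster created at merge k
  code <- -seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  dd <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    idx <- which(active)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        if (dd[i, j] < best_d) {  # strict: first minimal pair in (i, j) order
          best_d <- dd[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    # hclust convention: singletons (negative codes) first, by index
    pair <- c(code[i], code[j])
    if (all(pair < 0L)) pair <- -sort(-pair) else pair <- sort(pair)
    merge[step, ] <- pair
    height[step] <- best_d
    # average linkage update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      dd[i, others] <- (size[i] * dd[i, others] + size[j] * dd[j, others]) /
        (size[i] + size[j])
      dd[others, i] <- dd[i, others]
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- step
  }
  out <- structure(list(merge = merge, height = height,
                        order = hclust_leaf_order(merge),
                        labels = labels, method = "average",
                        dist.method = "euclidean",
                        call = match.call()),
                   class = "hclust")
  out
}

# depth-first leaf order of an hclust merge matrix (left branch first)
hclust_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix (", nrow(x$values), " genomes x ", ncol(x$values),
      " ", x$by, if (ncol(x$values) == 1) "" else "s",
      "; scaling: ", x$scaling, ")\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' Write an abundance matrix to TSV
#' @param am An [abundance_matrix()] or plain matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(am, path) {
  m <- if (inherits(am, "abundance_matrix")) am$values else as.matrix(am)
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Clustered heatmap of an abundance matrix
#'
#' Renders the matrix with rows and columns ordered by [cluster_matrix()].
#' Requires the pheatmap package; plots are presentation artifacts and no
#' analysis result depends on them.
#'
#' @param am An [abundance_matrix()] or plain numeric matrix.
#' @param filename Optional output file (png/pdf) forwarded to pheatmap.
#' @param ... Further arguments forwarded to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_abundance_heatmap <- function(am, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_abundance_heatmap requires the pheatmap package")
  }
  m <- if (inherits(am, "abundance_matrix")) am$values else as.matrix(am)
  cl <- cluster_matrix(m)
  p <- pheatmap::pheatmap(m, cluster_rows = cl$row_tree,
                          cluster_cols = cl$col_tree,
                          filename = filename, ...)
  invisible(p)
}
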