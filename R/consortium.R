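#' Default required functions for a consortium
#'
#' A designed consortium should carry, in at least one member each:
#' nitrogen fixation, phosphorus solubilization, biocontrol, amylolytic
#' activity, and auxin (IAA) production.
#'
#' @return Character vector of function tags.
#' @export
pgpm_required_functions <- function() {
  c("nitrogen_fixation", "P_solubilization", "biocontrol", "amylolytic",
    "IAA_production")
}

#' Build the strain compatibility graph
#'
#' Undirected graph with one vertex per strain and an edge for every pair
#' whose assay verdict permits coexistence under the chosen policy:
#' `"strict"` draws an edge only for `+` (compatible) pairs, `"lenient"`
#' also for `nc` (unclear) pairs. Pairs with no assay entry get no edge.
#'
#' @param compat Compatibility matrix or `pgpm_tables` object.
#' @param policy `"lenient"` (default) or `"strict"`.
#' @param strains Optional subset of strains (canonical names or aliases)
#'   to restrict the graph to.
#' @return An [igraph::graph] object.
#' @export
build_compatibility_graph <- function(compat,
                                      policy = c("lenient", "strict"),
                                      strains = NULL) {
  policy <- match.arg(policy)
  m <- as_compat_matrix(compat)
  if (!is.null(strains)) {
    al <- attr(m, "alias_map")
    if (!is.null(al)) strains <- canonical_strain(strains, al)
    missing <- setdiff(strains, rownames(m))
    if (length(missing)) {
      stop("strain(s) not in the compatibility matrix: ",
           paste(missing, collapse = ", "))
    }
    m <- m[strains, strains, drop = FALSE]
  }
  allowed <- if (policy == "strict") "+" else c("+", "nc")
  adj <- matrix(as.integer(!is.na(m) & m %in% allowed),
                nrow(m), ncol(m), dimnames = dimnames(m))
  diag(adj) <- 0L
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Assemble a consortium object
#'
#' @param name Consortium label.
#' @param members Character vector of at least two strain names.
#' @param policy Compatibility policy the consortium is meant to satisfy:
#'   `"lenient"` tolerates unclear (`nc`) pairs, `"strict"` does not.
#' @return Object of class `consortium`.
#' @export
consortium <- function(name, members, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  members <- unique(members)
  if (length(members) < 2L) stop("a consortium needs at least two members")
  structure(list(name = name, members = members, policy = policy),
            class = "consortium")
}

#' @export
print.consortium <- function(x, ...) {
  cat("Consortium", x$name, "(", x$policy, "policy,", length(x$members),
      "members )\n ", paste(x$members, collapse = "\n  "), "\n")
  invisible(x)
}

#' Validate a consortium against the compatibility assays
#'
#' Scores every unordered member pair, reports incompatible, unclear and
#' unassayed pairs, computes which members cover each required function,
#' and sets the two pass flags: strict (every pair `+`) and lenient (no
#' pair `-`). Unassayed ("missing") pairs block the strict flag only when
#' `strict_missing = TRUE`, since absence of an assay is not evidence of
#' antagonism.
#'
#' @param members A `consortium`, a consortium name from the packaged
#'   definitions (e.g. `"MC_A"`), or a character vector of strain names.
#' @param tables A `pgpm_tables` object (or compatibility matrix; function
#'   coverage then requires `functions`).
#' @param required_functions Function tags the consortium should cover.
#' @param functions Optional named list strain -> function tags, overriding
#'   the strain table.
#' @param strict_missing Should unassayed pairs block the strict pass flag?
#' @return Object of class `consortium_validation`: list with `name`,
#'   `members`, `pairs` (data frame `a`, `b`, `verdict`),
#'   `incompatible_pairs`, `unclear_pairs`, `missing_pairs`,
#'   `function_coverage` (named list of covering members),
#'   `uncovered_functions`, `passes_strict`, `passes_lenient`.
#' @export
validate_consortium <- function(members, tables,
                                required_functions = pgpm_required_functions(),
                                functions = NULL, strict_missing = FALSE) {
  name <- "consortium"
  if (inherits(members, "consortium")) {
    name <- members$name
    members <- members$members
  } else if (is.character(members) && length(members) == 1L &&
             inherits(tables, "pgpm_tables") &&
             members %in% names(tables$consortia)) {
    name <- members
    members <- tables$consortia[[members]]
  }
  m <- as_compat_matrix(tables)
  al <- attr(m, "alias_map")
  if (!is.null(al)) members <- canonical_strain(members, al)
  unresolvable <- setdiff(members, rownames(m))
  if (length(unresolvable)) {
    stop("unresolvable consortium member(s): ",
         paste(unresolvable, collapse = ", "))
  }
  if (length(members) < 2L) stop("a consortium needs at least two members")

  pair_idx <- utils::combn(sort(members), 2L)
  verdict <- apply(pair_idx, 2L, function(p) {
    v <- m[p[1L], p[2L]]
    if (is.na(v)) "missing" else v
  })
  pairs <- data.frame(a = pair_idx[1L, ], b = pair_idx[2L, ],
                      verdict = verdict, stringsAsFactors = FALSE)

  if (is.null(functions) && inherits(tables, "pgpm_tables")) {
    functions <- tables$strains$functions
  }
  coverage <- stats::setNames(vector("list", length(required_functions)),
                              required_functions)
  if (!is.null(functions) && length(required_functions)) {
    for (f in required_functions) {
      coverage[[f]] <- members[vapply(members, function(s) {
        f %in% functions[[s]]
      }, logical(1))]
    }
  }
  uncovered <- names(coverage)[lengths(coverage) == 0L]

  strict_block <- if (strict_missing) c("-", "nc", "missing") else c("-", "nc")
  structure(list(
    name = name, members = members, pairs = pairs,
    incompatible_pairs = pairs[pairs$verdict == "-", c("a", "b")],
    unclear_pairs = pairs[pairs$verdict == "nc", c("a", "b")],
    missing_pairs = pairs[pairs$verdict == "missing", c("a", "b")],
    function_coverage = coverage,
    uncovered_functions = uncovered,
    passes_strict = !any(verdict %in% strict_block),
    passes_lenient = !any(verdict == "-")
  ), class = "consortium_validation")
}

#' @export
print.consortium_validation <- function(x, ...) {
  cat("Validation of", x$name, "(", length(x$members), "members,",
      nrow(x$pairs), "pairs )\n")
  cat("  incompatible pairs:", nrow(x$incompatible_pairs), "\n")
  if (nrow(x$unclear_pairs)) {
    cat("  unclear pairs:",
        paste(paste(x$unclear_pairs$a, x$unclear_pairs$b, sep = " ~ "),
              collapse = "; "), "\n")
  }
  if (nrow(x$missing_pairs)) {
    cat("  unassayed pairs:", nrow(x$missing_pairs), "\n")
  }
  cat("  passes strict:", x$passes_strict,
      " passes lenient:", x$passes_lenient, "\n")
  covered <- names(x$function_coverage)[lengths(x$function_coverage) > 0L]
  if (length(covered)) cat("  functions covered:",
                           paste(covered, collapse = ", "), "\n")
  if (length(x$uncovered_functions)) {
    cat("  functions NOT covered:",
        paste(x$uncovered_functions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate candidate consortia as maximal compatible cliques
#'
#' Every inclusion-maximal clique of the compatibility graph (restricted to
#' selected strains when a strain table is available) is found by
#' Bron-Kerbosch search with pivoting, then filtered to the requested size
#' range and to cliques whose members jointly cover all required functions.
#' Only maximal cliques are returned; any compatible sub-consortium is a
#' subset of one of them. Output order is deterministic: decreasing size,
#' then lexicographic member list.
#'
#' @param tables A `pgpm_tables` object, or a compatibility matrix (then
#'   supply `functions` if function coverage should be enforced).
#' @param required_functions Function tags to cover; empty vector disables
#'   the coverage filter.
#' @param size_range Length-2 numeric, minimum (>= 2) and maximum size.
#' @param policy `"lenient"` or `"strict"` edge policy.
#' @param functions Optional named list strain -> function tags.
#' @param strains Optional strain subset; defaults to the selected strains
#'   of the strain table, or all strains of a bare matrix.
#' @return List of `consortium` objects (possibly empty), named
#'   `candidate_001`, ...
#' @export
enumerate_consortia <- function(tables,
                                required_functions = pgpm_required_functions(),
                                size_range = c(2, Inf),
                                policy = c("lenient", "strict"),
                                functions = NULL, strains = NULL) {
  policy <- match.arg(policy)
  stopifnot(length(size_range) == 2L, size_range[1L] >= 2)
  m <- as_compat_matrix(tables)
  if (is.null(functions) && inherits(tables, "pgpm_tables")) {
    functions <- tables$strains$functions
  }
  if (is.null(strains)) {
    strains <- if (inherits(tables, "pgpm_tables")) {
      tables$strains$name[tables$strains$selected]
    } else {
      rownames(m)
    }
  }
  if (length(required_functions) && !is.null(functions)) {
    pool <- unique(unlist(functions[strains]))
    orphan <- setdiff(required_functions, pool)
    if (length(orphan)) {
      warning("required function(s) possessed by no strain: ",
              paste(orphan, collapse = ", "))
      return(list())
    }
  }
  g <- build_compatibility_graph(m, policy = policy, strains = strains)
  cliques <- igraph::max_cliques(g, min = 2L)
  member_sets <- lapply(cliques, function(cl) sort(igraph::V(g)$name[cl]))
  keep <- vapply(member_sets, function(ms) {
    n <- length(ms)
    if (n < size_range[1L] || n > size_range[2L]) return(FALSE)
    if (length(required_functions) && !is.null(functions)) {
      covered <- unique(unlist(functions[ms]))
      if (!all(required_functions %in% covered)) return(FALSE)
    }
    TRUE
  }, logical(1))
  member_sets <- member_sets[keep]
  ord <- order(-lengths(member_sets),
               vapply(member_sets, paste, character(1), collapse = "|"))
  member_sets <- member_sets[ord]
  out <- lapply(seq_along(member_sets), function(i) {
    consortium(sprintf("candidate_%03d", i), member_sets[[i]], policy)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}
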