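#' Score a bioactive compound for a consortium
#'
#' The suitability of a compound is the fraction of the consortium's
#' members for which the compound showed a prebiotic (growth-supporting)
#' effect under starvation. Unclear responses score zero credit but stay in
#' the denominator, since an unclear assay is not evidence of support.
#' Members absent from the response table are reported and excluded from
#' the denominator.
#'
#' @param members A `consortium`, a packaged consortium name, or a
#'   character vector of strain names.
#' @param tables A `pgpm_tables` object (its `biostimulants` matrix is
#'   used), or such a matrix directly.
#' @param compound Compound id, one of the table's columns (BS1..BS4).
#' @return List with `compound`, `fraction` (positive members / members
#'   scored), `breakdown` (data frame `strain`, `response`) and
#'   `missing_members`.
#' @export
score_compound <- function(members, tables, compound) {
  bs <- as_bs_matrix(tables)
  members <- resolve_members(members, tables)
  if (length(members) == 0L) stop("empty consortium")
  if (!compound %in% colnames(bs)) {
    stop("unknown compound '", compound, "' (available: ",
         paste(colnames(bs), collapse = ", "), ")")
  }
  present <- members[members %in% rownames(bs)]
  missing <- setdiff(members, present)
  if (length(present) == 0L) {
    stop("no consortium member is present in the biostimulant table")
  }
  responses <- bs[present, compound]
  list(compound = compound,
       fraction = mean(responses == "positive"),
       breakdown = data.frame(strain = present, response = unname(responses),
                              stringsAsFactors = FALSE),
       missing_members = missing)
}

#' Rank bioactive compounds for a consortium
#'
#' Compounds are ordered by decreasing fraction of members with a positive
#' (prebiotic) response; ties are broken by fewer unclear responses, then
#' by compound id.
#'
#' @inheritParams score_compound
#' @return Data frame with one row per compound, in rank order: `compound`,
#'   `fraction`, `n_positive`, `n_none`, `n_unclear`, `n_scored`.
#' @export
rank_compounds <- function(members, tables) {
  bs <- as_bs_matrix(tables)
  scores <- lapply(colnames(bs), function(cmp) {
    s <- score_compound(members, tables, cmp)
    resp <- s$breakdown$response
    data.frame(compound = cmp, fraction = s$fraction,
               n_positive = sum(resp == "positive"),
               n_none = sum(resp == "none"),
               n_unclear = sum(resp == "unclear"),
               n_scored = length(resp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, scores)
  out <- out[order(-out$fraction, out$n_unclear, out$compound), ]
  rownames(out) <- NULL
  out
}

as_bs_matrix <- function(x) {
  if (inherits(x, "pgpm_tables")) return(x$biostimulants)
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class ", class(x)[1],
       " as a biostimulant table")
}

resolve_members <- function(members, tables) {
  if (inherits(members, "consortium")) members <- members$members
  if (inherits(tables, "pgpm_tables")) {
    if (is.character(members) && length(members) == 1L &&
        members %in% names(tables$consortia)) {
      members <- tables$consortia[[members]]
    }
    members <- canonical_strain(members, tables$aliases)
  }
  unique(members)
}
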