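#' Directory of the packaged strain and compatibility fixtures
#' @return Path to the installed `extdata` directory.
#' @export
pgpm_fixtures <- function() {
  system.file("extdata", package = "pgpmkit", mustWork = TRUE)
}

#' Load the packaged strain, compatibility, biostimulant and consortium tables
#'
#' Reads the machine-readable transcriptions of the published strain list,
#' the pairwise bacteria/yeast compatibility matrix (lower-triangular as
#' printed), the bacteria/yeast vs *Trichoderma harzianum* compatibility
#' table, the biostimulant response table (compounds BS1-BS4), and the
#' published consortium definitions MC_A, MC_B and MC_C.
#'
#' Strain names are canonicalized through an explicit alias map because the
#' source tables use inconsistent names (abbreviated genus, the
#' Pichia/Komagataella synonymy, occasional genus and strain-code
#' misprints); an unknown name with no alias entry is a load error. The
#' lower-triangular compatibility matrix is closed to a symmetric matrix;
#' conflicting symmetric entries are a load error. Self-pairs are not
#' assayed and are defined compatible by convention. Pairs never assayed
#' (the fungus-fungus pair) are `NA` ("missing").
#'
#' @param fixture_dir Directory holding the fixture CSVs; defaults to the
#'   packaged transcriptions in [pgpm_fixtures()].
#' @return Object of class `pgpm_tables`: list with
#'   \describe{
#'     \item{strains}{data frame: `name`, `kingdom`, `properties`,
#'       `selected`, `notes`, plus a `functions` list-column of normalized
#'       function tags.}
#'     \item{compat}{symmetric character matrix over all strains with
#'       entries `+`, `-`, `nc` or `NA`, alias map attached.}
#'     \item{biostimulants}{character matrix strains x BS1..BS4 with entries
#'       `positive`, `none`, `unclear`.}
#'     \item{consortia}{named list of canonical member name vectors.}
#'     \item{aliases}{named character vector alias -> canonical name.}
#'   }
#' @export
load_paper_tables <- function(fixture_dir = pgpm_fixtures()) {
  path <- function(f) {
    p <- file.path(fixture_dir, f)
    if (!file.exists(p)) stop("fixture not found: ", p)
    p
  }
  strains <- utils::read.csv(path("strains.csv"), stringsAsFactors = FALSE)
  strains$selected <- as.logical(strains$selected)
  aliases <- build_alias_map(strains)
  strains$functions <- lapply(seq_len(nrow(strains)), function(i) {
    sort(unique(c(map_properties(strains$properties[i]),
                  split_field(strains$extra_functions[i]))))
  })
  names(strains$functions) <- strains$name
  if (any(strains$selected &
          lengths(strains$functions) == 0L)) {
    stop("selected strain(s) with no function tags: ",
         paste(strains$name[strains$selected &
                              lengths(strains$functions) == 0L],
               collapse = ", "))
  }

  compat <- empty_compat(strains$name)
  compat <- fill_compat_square(compat,
                               utils::read.csv(path("compat_bacteria.csv"),
                                               check.names = FALSE,
                                               stringsAsFactors = FALSE),
                               aliases, "compat_bacteria.csv")
  compat <- fill_compat_long(compat,
                             utils::read.csv(path("compat_fungi.csv"),
                                             check.names = FALSE,
                                             stringsAsFactors = FALSE),
                             aliases, "compat_fungi.csv")
  attr(compat, "alias_map") <- aliases

  bs_raw <- utils::read.csv(path("biostimulants.csv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  bs_strains <- canonical_strain(bs_raw$strain, aliases)
  bs <- as.matrix(bs_raw[, -1, drop = FALSE])
  rownames(bs) <- bs_strains
  bad <- setdiff(unique(as.vector(bs)), c("+", "-", "nc"))
  if (length(bad)) {
    stop("biostimulants.csv has entries outside {+, -, nc}: ",
         paste(bad, collapse = ", "))
  }
  bs[] <- c("+" = "positive", "-" = "none", "nc" = "unclear")[bs]

  cons_raw <- utils::read.csv(path("consortia.csv"), stringsAsFactors = FALSE)
  consortia <- lapply(split(cons_raw$member, cons_raw$consortium),
                      canonical_strain, aliases = aliases)
  unresolved <- unlist(consortia)[!unlist(consortia) %in% strains$name]
  if (length(unresolved)) {
    stop("consortium member(s) not in the strain table: ",
         paste(unique(unresolved), collapse = ", "))
  }

  structure(list(strains = strains, compat = compat, biostimulants = bs,
                 consortia = consortia, aliases = aliases),
            class = "pgpm_tables")
}

#' @export
print.pgpm_tables <- function(x, ...) {
  cat("PGPM tables:", nrow(x$strains), "strains (",
      sum(x$strains$selected), "selected ),",
      sum(!is.na(x$compat[upper.tri(x$compat)])), "assayed pairs,",
      nrow(x$biostimulants), "biostimulant-tested strains,",
      length(x$consortia), "consortia (",
      paste(names(x$consortia), collapse = ", "), ")\n")
  invisible(x)
}

#' Canonicalize strain names through the alias map
#'
#' @param names Character vector of strain names as printed in a source
#'   table (canonical names pass through unchanged).
#' @param aliases Alias map (alias -> canonical), e.g.
#'   `load_paper_tables()$aliases` or the `alias_map` attribute of a
#'   compatibility matrix.
#' @return Canonical names; unknown names raise an error listing them.
#' @export
canonical_strain <- function(names, aliases) {
  key <- squeeze_ws(names)
  out <- aliases[key]
  unknown <- names[is.na(out)]
  if (length(unknown)) {
    stop("strain name(s) with no alias entry: ",
         paste(unique(unknown), collapse = "; "))
  }
  unname(out)
}

#' Look up the compatibility verdict for a strain pair
#'
#' Symmetric lookup: the order of the two names does not matter. Self-pairs
#' are compatible by convention; pairs never assayed return `"missing"`.
#'
#' @param compat Compatibility matrix (from [load_paper_tables()] or
#'   [generate_compatibility()]), or a `pgpm_tables` object.
#' @param a,b Strain names (aliases accepted when an alias map is attached).
#' @return One of `"+"`, `"-"`, `"nc"`, `"missing"`.
#' @export
compat_lookup <- function(compat, a, b) {
  m <- as_compat_matrix(compat)
  al <- attr(m, "alias_map")
  if (!is.null(al)) {
    a <- canonical_strain(a, al)
    b <- canonical_strain(b, al)
  }
  missing <- setdiff(c(a, b), rownames(m))
  if (length(missing)) {
    stop("strain(s) not in the compatibility matrix: ",
         paste(missing, collapse = ", "))
  }
  v <- m[a, b]
  if (is.na(v)) "missing" else v
}

as_compat_matrix <- function(x) {
  if (inherits(x, "pgpm_tables")) return(x$compat)
  if (is.list(x) && !is.null(x$compat)) return(x$compat)
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class ", class(x)[1],
       " as a compatibility matrix")
}

# ---- internal helpers -----------------------------------------------------

squeeze_ws <- function(x) gsub("\\s+", " ", trimws(x))

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

build_alias_map <- function(strains) {
  pairs <- lapply(seq_len(nrow(strains)), function(i) {
    al <- c(strains$name[i], split_field(strains$aliases[i]))
    stats::setNames(rep(strains$name[i], length(al)), squeeze_ws(al))
  })
  map <- do.call(c, pairs)
  dup <- names(map)[duplicated(names(map))]
  conflicting <- dup[vapply(dup, function(a) {
    length(unique(map[names(map) == a])) > 1L
  }, logical(1))]
  if (length(conflicting)) {
    stop("alias(es) mapping to several strains: ",
         paste(unique(conflicting), collapse = ", "))
  }
  map[!duplicated(names(map))]
}

# all-NA symmetric matrix with a compatible diagonal (self-compatibility
# is a convention, not an assay result)
empty_compat <- function(strain_names) {
  n <- length(strain_names)
  m <- matrix(NA_character_, n, n, dimnames = list(strain_names, strain_names))
  diag(m) <- "+"
  m
}

set_compat <- function(m, a, b, value, source) {
  if (!value %in% c("+", "-", "nc")) {
    stop(source, ": entry (", a, ", ", b, ") outside {+, -, nc}: '",
         value, "'")
  }
  existing <- m[a, b]
  if (!is.na(existing) && existing != value && a != b) {
    stop(source, ": conflicting symmetric entries for (", a, ", ", b, "): '",
         existing, "' vs '", value, "'")
  }
  m[a, b] <- value
  m[b, a] <- value
  m
}

# square (lower-triangular as printed) matrix CSV; symmetric closure applied
fill_compat_square <- function(m, df, aliases, source) {
  rows <- canonical_strain(df[[1]], aliases)
  cols <- canonical_strain(names(df)[-1], aliases)
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      v <- trimws(df[i, j + 1])
      if (is.na(v) || !nzchar(v)) next
      if (rows[i] == cols[j]) {
        stop(source, ": unexpected self-pair entry for ", rows[i])
      }
      m <- set_compat(m, rows[i], cols[j], v, source)
    }
  }
  m
}

# long-ish matrix: one row per strain, one column per fungal tester
fill_compat_long <- function(m, df, aliases, source) {
  rows <- canonical_strain(df[[1]], aliases)
  cols <- canonical_strain(names(df)[-1], aliases)
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      v <- trimws(df[i, j + 1])
      if (is.na(v) || !nzchar(v)) next
      m <- set_compat(m, rows[i], cols[j], v, source)
    }
  }
  m
}

# normalize free-text property descriptions into controlled function tags
map_properties <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  tags <- character(0)
  has <- function(p) grepl(p, text, ignore.case = TRUE)
  if (has("N-?fixation|nitrogen fix")) tags <- c(tags, "nitrogen_fixation")
  if (has("P-?solubili[sz]|phosph")) tags <- c(tags, "P_solubilization")
  if (has("biocontrol")) tags <- c(tags, "biocontrol")
  if (has("amylas|amylolytic|glucosidase")) tags <- c(tags, "amylolytic")
  if (has("IAA|indole acetic|auxin")) tags <- c(tags, "IAA_production")
  if (has("siderophore")) tags <- c(tags, "siderophore")
  if (has("phytase")) tags <- c(tags, "phytase")
  if (has("\\bPGP\\b")) tags <- c(tags, "PGP_generic")
  unique(tags)
}
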