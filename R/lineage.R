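#' Parse NCBI-style semicolon-delimited lineage strings
#'
#' Lineages are ordered rank paths from the root, printed the way NCBI
#' taxonomy dumps them, e.g. `"Eukaryota; stramenopiles; Oomycetes"`. The
#' canonical form used throughout the package joins labels with `"; "`.
#'
#' @param x Character vector of lineage strings.
#' @param sep Separator between rank labels; defaults to `";"`. Surrounding
#'   whitespace around labels is stripped.
#' @return Character vector of canonicalised lineage strings.
#' @examples
#' parse_lineage("Eukaryota;stramenopiles;  Oomycetes")
#' @export
parse_lineage <- function(x, sep = ";") {
  if (length(x) == 0) return(character())
  if (any(is.na(x) | !nzchar(trimws(x)))) {
    abort("lineage strings must be non-empty")
  }
  ranks <- lineage_ranks(x, sep = sep)
  bad <- vapply(ranks, function(r) any(!nzchar(r)), logical(1))
  if (any(bad)) {
    abort(paste0(
      "empty rank label in lineage(s): ",
      paste(utils::head(x[bad], 5), collapse = " | ")
    ))
  }
  vapply(ranks, paste, character(1), collapse = "; ")
}

#' Split lineages into rank label vectors
#'
#' @inheritParams parse_lineage
#' @return List of character vectors, one per input lineage. The empty
#'   string (the root) yields `character(0)`.
#' @export
lineage_ranks <- function(x, sep = ";") {
  out <- strsplit(as.character(x), sep, fixed = TRUE)
  lapply(out, function(r) {
    r <- trimws(r)
    r[nzchar(r) | seq_along(r) < length(r)] # keep internal empties for validation
  })
}

#' Lineage depth (number of rank labels)
#'
#' @inheritParams parse_lineage
#' @return Integer vector; the root lineage `""` has depth 0.
#' @export
lineage_depth <- function(x, sep = ";") {
  ifelse(
    !nzchar(trimws(as.character(x))), 0L,
    lengths(lineage_ranks(x, sep = sep))
  )
}

#' Ancestor test on lineages
#'
#' `is_ancestor(a, b)` is `TRUE` iff the rank path of `a` is a (proper or
#' equal) prefix of the rank path of `b`; every lineage is its own ancestor,
#' and the root (empty lineage) is an ancestor of everything.
#'
#' @param a,b Character vectors of lineage strings (recycled to a common
#'   length).
#' @param sep Rank separator.
#' @return Logical vector.
#' @examples
#' is_ancestor("Viruses", "Viruses; dsDNA viruses, no RNA stage; Phycodnaviridae")
#' @export
is_ancestor <- function(a, b, sep = ";") {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  ra <- lineage_ranks(a, sep = sep)
  rb <- lineage_ranks(b, sep = sep)
  ra[!nzchar(trimws(a))] <- list(character(0))
  rb[!nzchar(trimws(b))] <- list(character(0))
  mapply(function(x, y) {
    length(x) <= length(y) && (length(x) == 0 || all(x == y[seq_along(x)]))
  }, ra, rb, USE.NAMES = FALSE)
}

#' Last common ancestor of a set of lineages
#'
#' Returns the longest common rank-path prefix; disjoint domains reduce to
#' the root, returned as the empty string.
#'
#' @param lineages Non-empty character vector of lineage strings.
#' @param sep Rank separator.
#' @return Single canonical lineage string (possibly `""`, the root).
#' @examples
#' lca(c("Eukaryota; stramenopiles; Oomycetes",
#'       "Eukaryota; stramenopiles; Bicosoecida"))
#' @export
lca <- function(lineages, sep = ";") {
  if (length(lineages) == 0) abort("lca() needs at least one lineage")
  ranks <- lineage_ranks(parse_lineage(lineages, sep = sep))
  k <- min(lengths(ranks))
  if (k == 0) return("")
  ref <- ranks[[1]][seq_len(k)]
  for (r in ranks[-1]) {
    agree <- ref == r[seq_len(k)]
    if (!all(agree)) {
      k <- which(!agree)[1] - 1L
      if (k == 0) return("")
      ref <- ref[seq_len(k)]
    }
  }
  paste(ref, collapse = "; ")
}

#' All ancestor prefixes of a lineage up to a maximum depth
#'
#' @param x Single lineage string.
#' @param max_depth Deepest prefix to emit (`Inf` for all).
#' @param sep Rank separator.
#' @return Character vector of prefixes, shallowest first (root excluded).
#' @export
lineage_prefixes <- function(x, max_depth = Inf, sep = ";") {
  r <- lineage_ranks(x, sep = sep)[[1]]
  d <- min(length(r), max_depth)
  if (d == 0) return(character())
  vapply(seq_len(d), function(i) paste(r[seq_len(i)], collapse = "; "),
         character(1))
}

# first rank label ("domain" in the loose sense used here: Bacteria,
# Archaea, Eukaryota or Viruses)
lineage_domain <- function(x, sep = ";") {
  vapply(lineage_ranks(x, sep = sep), function(r) {
    if (length(r) == 0) NA_character_ else r[[1]]
  }, character(1))
}
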