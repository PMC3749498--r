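#' Remove 454-style artificial duplicate reads
#'
#' Pyrosequencing re-emits near-copies of template reads that share the
#' exact 5' start. Reads are clustered greedily: sorted by descending
#' length then lexical id, a read joins the first existing exemplar that
#' shares its first `prefix_len` nucleotides and has global alignment
#' identity at least `min_identity` (matches / alignment columns of a
#' global alignment of the shorter read against the exemplar prefix region
#' of the same length). Exemplars are kept; members are dropped. Reads
#' shorter than `prefix_len` are kept unconditionally. When `reads` spans
#' several samples each sample is deduplicated independently.
#'
#' @param reads Tibble with `read_id`, `sample_id`, `seq`.
#' @param prefix_len Number of identical starting nucleotides required
#'   (default 5).
#' @param min_identity Minimum overall nucleotide identity (default 0.97).
#' @return The input tibble (original row order) with added columns
#'   `exemplar_id` (the kept representative; equal to `read_id` for kept
#'   reads) and `is_exemplar`.
#' @export
remove_duplicates <- function(reads, prefix_len = 5L, min_identity = 0.97) {
  stopifnot(prefix_len >= 1, min_identity > 0, min_identity <= 1)
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    return(mutate(reads, exemplar_id = character(), is_exemplar = logical()))
  }
  parts <- split(seq_len(nrow(reads)), reads$sample_id)
  ex_id <- character(nrow(reads))
  for (idx in parts) {
    res <- dedup_one_sample(reads$read_id[idx], reads$seq[idx],
                            prefix_len, min_identity)
    ex_id[idx] <- res
  }
  mutate(reads, exemplar_id = ex_id, is_exemplar = ex_id == .data$read_id)
}

dedup_one_sample <- function(ids, seqs, prefix_len, min_identity) {
  ord <- order(-nchar(seqs), ids)
  exemplar <- setNames(rep(NA_character_, length(ids)), ids)
  # exemplars grouped by 5' prefix, in creation order
  buckets <- new.env(parent = emptyenv())
  short <- 0L
  for (i in ord) {
    s <- seqs[i]
    if (nchar(s) < prefix_len) {
      exemplar[i] <- ids[i]
      short <- short + 1L
      next
    }
    key <- substr(s, 1L, prefix_len)
    cand <- if (exists(key, envir = buckets)) get(key, envir = buckets) else integer()
    joined <- FALSE
    if (length(cand) > 0) {
      refs <- substr(seqs[cand], 1L, nchar(s))
      idents <- .nw_identity(s, refs)
      hit <- which(idents >= min_identity)
      if (length(hit) > 0) {
        exemplar[i] <- ids[cand[hit[1]]]
        joined <- TRUE
      }
    }
    if (!joined) {
      exemplar[i] <- ids[i]
      assign(key, c(cand, i), envir = buckets)
    }
  }
  if (short > 0) {
    inform(paste0(short, " read(s) shorter than the ", prefix_len,
                  "-nt prefix kept unconditionally"))
  }
  unname(exemplar)
}
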