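#' Extract stop-free peptides from all six reading frames
#'
#' Stands in for gene calling on short reads: every maximal stop-free
#' stretch of at least `min_len_aa` residues in each of the six frames is
#' emitted as one peptide (standard genetic code; `N`-containing codons
#' translate to `X`). Coordinates are 0-based half-open on the forward
#' strand regardless of frame.
#'
#' @param reads Tibble with `read_id`, `seq` (and optionally `sample_id`,
#'   carried through).
#' @param min_len_aa Minimum peptide length in residues (default 20).
#' @return Tibble with `peptide_id`, `read_id` (+ `sample_id` if present),
#'   `frame` (+1..+3, -1..-3), `start`, `end`, `seq`.
#' @export
six_frame_orfs <- function(reads, min_len_aa = 20L) {
  reads <- as_tibble(reads)
  empty <- tibble(
    peptide_id = character(), read_id = character(),
    frame = integer(), start = integer(), end = integer(), seq = character()
  )
  if ("sample_id" %in% names(reads)) {
    empty <- mutate(empty, sample_id = character(), .after = "read_id")
  }
  keep <- nchar(reads$seq) >= 3L
  if (!any(keep)) return(empty)
  reads <- reads[keep, , drop = FALSE]
  fwd <- Biostrings::DNAStringSet(reads$seq)
  rev <- Biostrings::reverseComplement(fwd)
  L <- nchar(reads$seq)

  out <- vector("list", 6L)
  k <- 0L
  for (f in 1:3) {
    for (strand in c(1L, -1L)) {
      k <- k + 1L
      src <- if (strand == 1L) fwd else rev
      w <- Biostrings::width(src) - (f - 1L)
      ok <- w >= 3L
      if (!any(ok)) next
      sub <- Biostrings::subseq(src[ok], start = f,
                                width = (w[ok] %/% 3L) * 3L)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "solve")
      ))
      m <- gregexpr("[^*]+", aa)
      ridx <- which(ok)
      lens <- lapply(m, function(x) attr(x, "match.length"))
      starts <- lapply(m, as.integer)
      nper <- vapply(starts, function(s) sum(s > 0), integer(1))
      if (sum(nper) == 0) next
      rid <- rep(ridx, nper)
      s_aa <- unlist(lapply(starts, function(s) s[s > 0]), use.names = FALSE)
      l_aa <- unlist(lapply(seq_along(starts), function(i) {
        sel <- starts[[i]] > 0
        lens[[i]][sel]
      }), use.names = FALSE)
      pass <- l_aa >= min_len_aa
      if (!any(pass)) next
      rid <- rid[pass]; s_aa <- s_aa[pass]; l_aa <- l_aa[pass]
      # nt coords in the translated strand
      nt_start <- (f - 1L) + 3L * (s_aa - 1L)
      nt_end <- nt_start + 3L * l_aa
      if (strand == -1L) {
        tmp <- L[rid] - nt_end
        nt_end <- L[rid] - nt_start
        nt_start <- tmp
      }
      pep <- substring(rep(aa, nper)[pass], s_aa, s_aa + l_aa - 1L)
      out[[k]] <- tibble(
        read_id = reads$read_id[rid],
        frame = strand * f,
        start = nt_start, end = nt_end, seq = pep
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res <- mutate(res,
    peptide_id = sprintf("%s|%+d|%d", .data$read_id, .data$frame, .data$start),
    .before = 1
  )
  if ("sample_id" %in% names(reads)) {
    res <- left_join(res,
                     select(reads, "read_id", "sample_id"), by = "read_id") |>
      dplyr::relocate("sample_id", .after = "read_id")
  }
  arrange(res, match(.data$read_id, reads$read_id), .data$frame, .data$start)
}
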