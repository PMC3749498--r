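#' Dual-search last-common-ancestor (2bLCA) read annotation
#'
#' Each read longer than `min_read_len` is annotated in four steps:
#' a first translated search (B1) against the reference database; reads
#' with no HSP at `b1_max_evalue` or better are `no_hit`. The subject
#' residues aligned in the best B1 HSP are then re-searched (B2,
#' protein vs protein) against the same database with an adaptive cutoff
#' equal to the best B1 E-value; the subjects of all B2 hits at that
#' cutoff or better form the close-homolog set H (the B2 query's own
#' source protein always qualifies via its self-hit and is retained).
#' The read's lineage is the last common ancestor of the lineages in H;
#' reads whose H spans more than one top-level domain (Bacteria, Archaea,
#' Eukaryota, Viruses) are `ambiguous`.
#'
#' @param reads Tibble with `read_id`, `seq` (and optionally `sample_id`).
#' @param db A [reference_db()] tibble.
#' @param b1_max_evalue B1 significance threshold (default 1e-5).
#' @param min_read_len Reads must be strictly longer than this many
#'   nucleotides to be annotated (default 100).
#' @param params [search_params()] for both searches; `max_evalue` of B1
#'   is taken from `b1_max_evalue`.
#' @param min_len_aa Minimum translated peptide length (default 20).
#' @return Tibble with `read_id` (+ `sample_id` if present), `status`
#'   (`assigned`, `ambiguous`, `no_hit`, `too_short`), `lineage` (`NA`
#'   unless assigned/ambiguous), `b1_best_evalue`, `support_size` and a
#'   list-column `support_ids` (the set H).
#' @export
assign_2blca <- function(reads, db, b1_max_evalue = 1e-5,
                         min_read_len = 100L, params = search_params(),
                         min_len_aa = 20L) {
  reads <- as_tibble(reads)
  params$max_evalue <- b1_max_evalue
  long <- nchar(reads$seq) > min_read_len
  b1 <- search_translated(reads[long, , drop = FALSE], db, params,
                          min_len_aa = min_len_aa)
  best <- b1 |>
    group_by(.data$query_id) |>
    arrange(.data$e_value, -.data$bit_score, .data$subject_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  lin <- setNames(db$lineage, db$protein_id)

  one <- function(read_id) {
    if (!read_id %in% best$query_id) {
      return(tibble(read_id = read_id, status = "no_hit",
                    lineage = NA_character_, b1_best_evalue = NA_real_,
                    support_size = 0L, support_ids = list(character())))
    }
    h <- best[best$query_id == read_id, ]
    p2 <- params
    p2$max_evalue <- h$e_value
    b2 <- search_protein(setNames(h$subject_alnseq, "b2q"), db, p2)
    H <- sort(union(b2$subject_id, h$subject_id))
    doms <- unique(lineage_domain(lin[H]))
    status <- if (length(doms) > 1) "ambiguous" else "assigned"
    tibble(read_id = read_id, status = status,
           lineage = lca(lin[H]), b1_best_evalue = h$e_value,
           support_size = length(H), support_ids = list(H))
  }

  res <- purrr::map_dfr(reads$read_id[long], one)
  if (any(!long)) {
    res <- bind_rows(res, tibble(
      read_id = reads$read_id[!long], status = "too_short",
      lineage = NA_character_, b1_best_evalue = NA_real_,
      support_size = 0L, support_ids = list(character())
    ))
  }
  res <- res[match(reads$read_id, res$read_id), ]
  if ("sample_id" %in% names(reads)) {
    res <- mutate(res, sample_id = reads$sample_id, .after = "read_id")
  }
  res
}

#' Default NCLDV family labels
#'
#' The seven distantly related families of nucleo-cytoplasmic large DNA
#' viruses, with both the Megaviridae label and its NCBI taxonomy
#' equivalent Mimiviridae accepted.
#' @return Character vector of family labels.
#' @export
ncldv_families <- function() {
  c("Megaviridae", "Mimiviridae", "Phycodnaviridae", "Marseilleviridae",
    "Iridoviridae", "Ascoviridae", "Asfarviridae", "Poxviridae")
}

#' Bin taxonomic assignments into NCLDV / cellular-domain bins
#'
#' A read is binned `NCLDV` iff its lineage starts at `Viruses` and
#' contains one of the NCLDV family labels; other viral reads fall outside
#' the four bins and get `NA` (reported via a message). Cellular domains
#' map directly; `ambiguous` and unannotated reads keep those labels.
#'
#' @param assignments Output of [assign_2blca()] (or any tibble with
#'   `status` and `lineage`).
#' @param families NCLDV family labels (default [ncldv_families()]).
#' @return The input with an added `bin` column (`NCLDV`, `Bacteria`,
#'   `Archaea`, `Eukaryota`, `ambiguous`, `no_hit`, or `NA`).
#' @export
classify_bin <- function(assignments, families = ncldv_families()) {
  a <- as_tibble(assignments)
  dom <- lineage_domain(ifelse(is.na(a$lineage), "", a$lineage))
  has_fam <- vapply(lineage_ranks(ifelse(is.na(a$lineage), "", a$lineage)),
                    function(r) any(r %in% families), logical(1))
  bin <- dplyr::case_when(
    a$status %in% c("no_hit", "too_short") ~ "no_hit",
    a$status == "ambiguous" ~ "ambiguous",
    dom == "Viruses" & has_fam ~ "NCLDV",
    dom %in% c("Bacteria", "Archaea", "Eukaryota") ~ dom,
    .default = NA_character_
  )
  n_other <- sum(is.na(bin) & a$status == "assigned")
  if (n_other > 0) {
    inform(paste0(n_other,
                  " assigned read(s) outside the NCLDV/cellular bins (",
                  "non-NCLDV viruses or root-level lineages)"))
  }
  mutate(a, bin = bin)
}
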