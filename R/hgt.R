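#' Best cellular homolog of each viral peptide
#'
#' First stage of the reciprocal-best-hit screen: each viral peptide is
#' searched against the cellular-only database; the best hit by E-value
#' (then bit score, then lexical subject id) at `max_evalue` or better is
#' retained.
#'
#' @param viral_peptides Tibble with `protein_id`/`peptide_id` and `seq`,
#'   or a named character vector.
#' @param cellular_db A [reference_db()] of cellular proteins only.
#' @param max_evalue Significance threshold (default 1e-5).
#' @param params [search_params()].
#' @return HSP tibble with at most one row per viral peptide.
#' @export
best_cellular_hit <- function(viral_peptides, cellular_db,
                              max_evalue = 1e-5,
                              params = search_params()) {
  if (any(cellular_db$source_group != "cellular")) {
    abort("cellular_db must contain only cellular proteins")
  }
  params$max_evalue <- max_evalue
  hits <- search_protein(viral_peptides, cellular_db, params)
  hits |>
    group_by(.data$query_id) |>
    arrange(.data$e_value, -.data$bit_score, .data$subject_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Taxonomically masked reciprocal check
#'
#' Searches a cellular protein against the combined cellular + viral
#' database, discards hits whose lineage shares its first
#' `exclusion_levels` labels with the query's own lineage (the query's
#' near relatives, including itself), and reports whether the best
#' surviving hit is viral. Ties between a viral and a cellular hit at
#' identical E-value resolve by bit score and reject on a residual tie.
#'
#' @param cellular_ids Ids of cellular proteins present in `combined_db`.
#' @param combined_db A [reference_db()] holding cellular and viral
#'   proteins.
#' @param exclusion_levels Number of leading lineage labels defining the
#'   masked taxonomic group (default 3; shallower lineages mask on their
#'   full depth).
#' @param params [search_params()] (its `max_evalue` gates the reciprocal
#'   search).
#' @return Tibble `protein_id`, `best_viral_id`, `best_e`, `reciprocal`
#'   (logical), `excluded_group`.
#' @export
reciprocal_check <- function(cellular_ids, combined_db,
                             exclusion_levels = 3L,
                             params = search_params()) {
  db_lin <- setNames(combined_db$lineage, combined_db$protein_id)
  db_grp <- setNames(combined_db$source_group, combined_db$protein_id)
  queries <- combined_db |> filter(.data$protein_id %in% cellular_ids)
  if (nrow(queries) < length(unique(cellular_ids))) {
    abort("some cellular ids are absent from combined_db")
  }
  group_of <- function(lin) {
    r <- lineage_ranks(lin)[[1]]
    paste(utils::head(r, exclusion_levels), collapse = "; ")
  }
  out <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    grp <- group_of(queries$lineage[q])
    hits <- search_protein(
      setNames(queries$seq[q], queries$protein_id[q]), combined_db, params
    )
    # mask the query's own taxonomic group (cellular relatives and self)
    hit_grp <- vapply(db_lin[hits$subject_id], group_of, character(1))
    hits <- hits[!(db_grp[hits$subject_id] == "cellular" & hit_grp == grp), ,
                 drop = FALSE]
    if (nrow(hits) == 0) {
      out[[q]] <- tibble(protein_id = queries$protein_id[q],
                         best_viral_id = NA_character_, best_e = NA_real_,
                         reciprocal = FALSE, excluded_group = grp)
      next
    }
    hits <- arrange(hits, .data$e_value, -.data$bit_score, .data$subject_id)
    top_e <- hits$e_value[1]
    top_b <- hits$bit_score[1]
    tied <- hits$e_value == top_e & hits$bit_score == top_b
    top_grps <- unique(db_grp[hits$subject_id[tied]])
    recip <- identical(top_grps, "viral")
    out[[q]] <- tibble(
      protein_id = queries$protein_id[q],
      best_viral_id = if (recip) hits$subject_id[1] else NA_character_,
      best_e = top_e, reciprocal = recip, excluded_group = grp
    )
  }
  bind_rows(out)
}

#' Screen a viral proteome for candidate virus-to-cell gene transfers
#'
#' Composition of [best_cellular_hit()] and [reciprocal_check()]: a
#' (viral peptide, cellular protein) pair is a candidate horizontal gene
#' transfer when the cellular protein is the peptide's best cellular
#' homolog and, with its own 3-level taxonomic group masked, its best
#' hit in the combined database is a viral peptide. Candidates are
#' deduplicated by pair. Phylogenetic confirmation is left to external
#' tree building.
#'
#' @param viral_db A [reference_db()] of viral peptides.
#' @param cellular_db A [reference_db()] of cellular proteins.
#' @param max_evalue Threshold for both searches (default 1e-5).
#' @param exclusion_levels Masked lineage depth (default 3).
#' @param params [search_params()].
#' @return Tibble of candidates: `viral_peptide_id`,
#'   `cellular_protein_id`, `e1`, `e2`, `cellular_lineage`,
#'   `excluded_group`.
#' @export
screen_hgt <- function(viral_db, cellular_db, max_evalue = 1e-5,
                       exclusion_levels = 3L, params = search_params()) {
  empty <- tibble(viral_peptide_id = character(),
                  cellular_protein_id = character(), e1 = numeric(),
                  e2 = numeric(), cellular_lineage = character(),
                  excluded_group = character())
  if (nrow(viral_db) == 0) return(empty)
  params$max_evalue <- max_evalue
  b1 <- best_cellular_hit(viral_db, cellular_db, max_evalue, params)
  if (nrow(b1) == 0) return(empty)
  combined <- reference_db(bind_rows(as_tibble(cellular_db),
                                     as_tibble(viral_db)))
  rc <- reciprocal_check(unique(b1$subject_id), combined,
                         exclusion_levels, params)
  cand <- b1 |>
    inner_join(rc, by = c("subject_id" = "protein_id")) |>
    filter(.data$reciprocal) |>
    left_join(select(as_tibble(cellular_db), "protein_id",
                     cellular_lineage = "lineage"),
              by = c("subject_id" = "protein_id"))
  cand |>
    transmute(viral_peptide_id = .data$query_id,
              cellular_protein_id = .data$subject_id,
              e1 = .data$e_value, e2 = .data$best_e,
              cellular_lineage = .data$cellular_lineage,
              excluded_group = .data$excluded_group) |>
    distinct(.data$viral_peptide_id, .data$cellular_protein_id,
             .keep_all = TRUE) |>
    arrange(.data$viral_peptide_id, .data$cellular_protein_id)
}
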