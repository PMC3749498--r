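#' Parameters for the local-alignment homology search
#'
#' The built-in engine computes Smith–Waterman local alignments with affine
#' gaps (a gap of length g costs `gap_open + g * gap_ext`) and converts raw
#' scores to bit scores and E-values with ungapped Karlin–Altschul
#' parameters for the chosen matrix: `E = K * m * n * exp(-lambda * S)`
#' with `m` the query length and `n` the database size in residues.
#' Absolute E-values only gate thresholds and define the adaptive 2bLCA
#' cutoff, so internal consistency is what matters; use
#' [load_tabular_hits()] for parity with an external engine.
#'
#' @param max_evalue Report hits with E-value at or below this (default 1e-5).
#' @param matrix Scoring matrix name (only `"BLOSUM62"` ships with the
#'   built-in engine).
#' @param gap_open,gap_ext Affine gap penalties (defaults 11, 1).
#' @param db_size_letters Effective database size in residues; defaults to
#'   the summed length of the database actually searched.
#' @param lambda,k Karlin–Altschul parameters (ungapped BLOSUM62 defaults
#'   0.3176 and 0.134).
#' @return A `search_params` list.
#' @export
search_params <- function(max_evalue = 1e-5, matrix = "BLOSUM62",
                          gap_open = 11, gap_ext = 1,
                          db_size_letters = NULL,
                          lambda = 0.3176, k = 0.134) {
  stopifnot(max_evalue > 0, gap_open >= 0, gap_ext >= 0, lambda > 0, k > 0)
  structure(
    list(max_evalue = max_evalue, matrix = matrix, gap_open = gap_open,
         gap_ext = gap_ext, db_size_letters = db_size_letters,
         lambda = lambda, k = k),
    class = "search_params"
  )
}

scoring_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

as_query_tbl <- function(query) {
  if (is.data.frame(query)) {
    idcol <- intersect(c("peptide_id", "protein_id", "query_id", "id"),
                       names(query))[1]
    if (is.na(idcol)) abort("query tibble needs an id column")
    tibble(query_id = query[[idcol]], seq = toupper(query$seq))
  } else {
    q <- toupper(as.character(query))
    ids <- names(query) %||% paste0("query", seq_along(q))
    if (is.null(names(query)) && length(q) == 1) ids <- "query"
    tibble(query_id = ids, seq = q)
  }
}

#' Protein vs protein local-alignment search
#'
#' Aligns each query against every database protein, keeping the single
#' best HSP per query–subject pair. Hits above `max_evalue` are dropped;
#' ties on E-value are broken by lexical subject id.
#'
#' @param query Amino-acid string(s): a character vector (optionally
#'   named), or a tibble with an id column and `seq`.
#' @param db A [reference_db()] tibble.
#' @param params A [search_params()] object.
#' @return Tibble of HSPs: `query_id`, `subject_id`, `bit_score`,
#'   `e_value`, `pct_identity` (fraction), `query_start`/`query_end` and
#'   `subject_start`/`subject_end` (0-based half-open, residue
#'   coordinates), `subject_alnseq` (subject residues inside the subject
#'   range), sorted by ascending E-value.
#' @export
search_protein <- function(query, db, params = search_params()) {
  qt <- as_query_tbl(query)
  if (any(!nzchar(qt$seq))) abort("empty query sequence")
  bad <- grepl("[^A-Z*]", qt$seq)
  if (any(bad)) abort(paste0("illegal residues in query: ",
                             paste(utils::head(qt$query_id[bad], 5),
                                   collapse = ", ")))
  empty <- hsp_tibble()
  if (nrow(db) == 0 || nrow(qt) == 0) return(empty)
  mat <- scoring_matrix(params$matrix)
  n_db <- params$db_size_letters %||% db_size_letters(db)
  subjects <- Biostrings::AAStringSet(setNames(db$seq, db$protein_id))
  res <- vector("list", nrow(qt))
  for (i in seq_len(nrow(qt))) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = subjects, subject = Biostrings::AAString(qt$seq[i]),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_ext
    )
    s <- Biostrings::score(pa)
    m <- nchar(qt$seq[i])
    ev <- params$k * m * n_db * exp(-params$lambda * s)
    keep <- which(s > 0 & ev <= params$max_evalue)
    if (length(keep) == 0) next
    pak <- pa[keep]
    patt <- Biostrings::pattern(pak)
    subj <- Biostrings::subject(pak)
    res[[i]] <- tibble(
      query_id = qt$query_id[i],
      subject_id = db$protein_id[keep],
      bit_score = (params$lambda * s[keep] - log(params$k)) / log(2),
      e_value = ev[keep],
      pct_identity = Biostrings::pid(pak, type = "PID1") / 100,
      query_start = Biostrings::start(subj) - 1L,
      query_end = Biostrings::end(subj),
      subject_start = Biostrings::start(patt) - 1L,
      subject_end = Biostrings::end(patt),
      subject_alnseq = gsub("-", "", as.character(patt), fixed = TRUE)
    )
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$e_value, .data$subject_id, .data$query_id)
}

hsp_tibble <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    bit_score = numeric(), e_value = numeric(), pct_identity = numeric(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer(),
    subject_alnseq = character()
  )
}

#' Translated (read vs protein) local-alignment search
#'
#' Equivalent to running [search_protein()] over the [six_frame_orfs()]
#' peptides of each read and mapping coordinates back to the forward
#' strand of the read; one best HSP is kept per read–subject pair.
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param db A [reference_db()] tibble.
#' @param params A [search_params()] object.
#' @param min_len_aa Minimum peptide length passed to [six_frame_orfs()].
#' @return HSP tibble as in [search_protein()] with `query_id` = read id,
#'   nucleotide `query_start`/`query_end` on the forward strand, and an
#'   extra `frame` column.
#' @export
search_translated <- function(reads, db, params = search_params(),
                              min_len_aa = 20L) {
  peps <- six_frame_orfs(reads, min_len_aa = min_len_aa)
  empty <- mutate(hsp_tibble(), frame = integer())
  if (nrow(peps) == 0) return(empty)
  hits <- search_protein(
    tibble(peptide_id = peps$peptide_id, seq = peps$seq), db, params
  )
  if (nrow(hits) == 0) return(empty)
  hits <- left_join(
    hits,
    select(peps, "peptide_id", "read_id", "frame",
           pep_start = "start", pep_end = "end"),
    by = c("query_id" = "peptide_id")
  ) |>
    mutate(
      nt_start = ifelse(.data$frame > 0,
                        .data$pep_start + 3L * .data$query_start,
                        .data$pep_end - 3L * .data$query_end),
      nt_end = ifelse(.data$frame > 0,
                      .data$pep_start + 3L * .data$query_end,
                      .data$pep_end - 3L * .data$query_start)
    ) |>
    mutate(query_id = .data$read_id,
           query_start = as.integer(.data$nt_start),
           query_end = as.integer(.data$nt_end)) |>
    select(-"read_id", -"pep_start", -"pep_end", -"nt_start", -"nt_end")
  hits |>
    group_by(.data$query_id, .data$subject_id) |>
    arrange(.data$e_value, -.data$bit_score, .data$frame,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$e_value, .data$subject_id, .data$query_id)
}

#' Load external search results in 12-column BLAST tabular format
#'
#' Adapter for results computed by an external engine (outfmt-6 dialect:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore, 1-based inclusive protein coordinates). The subject
#' aligned subsequence is reconstructed by slicing the database protein,
#' so every subject id must be present in `db`.
#'
#' @param path Path to the tabular file.
#' @param db A [reference_db()] tibble.
#' @return HSP tibble with the same contract as [search_protein()].
#' @export
load_tabular_hits <- function(path, db) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(x) == 0) return(hsp_tibble())
  missing <- setdiff(x$subject_id, db$protein_id)
  if (length(missing) > 0) {
    abort(paste0("subject ids absent from db: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  x <- left_join(x, select(db, "protein_id", subj_seq = "seq"),
                 by = c("subject_id" = "protein_id"))
  oob <- x$sstart < 1 | x$send > nchar(x$subj_seq) | x$sstart > x$send
  if (any(oob)) {
    abort(paste0("subject coordinates out of bounds for: ",
                 paste(utils::head(x$subject_id[oob], 10), collapse = ", ")))
  }
  tibble(
    query_id = x$query_id, subject_id = x$subject_id,
    bit_score = x$bitscore, e_value = x$evalue,
    pct_identity = x$pident / 100,
    query_start = as.integer(x$qstart - 1L), query_end = as.integer(x$qend),
    subject_start = as.integer(x$sstart - 1L),
    subject_end = as.integer(x$send),
    subject_alnseq = substring(x$subj_seq, x$sstart, x$send)
  ) |>
    arrange(.data$e_value, .data$subject_id, .data$query_id)
}
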