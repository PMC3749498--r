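#' Read metagenomic reads from a FASTA file
#'
#' Sequences are upper-cased and validated against the nucleotide alphabet
#' `A/C/G/T/N`. Record order is preserved and empty files yield an empty
#' tibble.
#'
#' @param path Path to a FASTA file.
#' @param sample_id Sample identifier attached to every read.
#' @return A tibble with columns `read_id`, `sample_id`, `seq`.
#' @export
read_read_fasta <- function(path, sample_id) {
  recs <- parse_fasta(path)
  seqs <- toupper(recs$seq)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0(
      "non-nucleotide characters in record(s): ",
      paste(utils::head(recs$id[bad], 5), collapse = ", ")
    ))
  }
  tibble(read_id = recs$id, sample_id = sample_id, seq = seqs)
}

# Minimal strict FASTA reader; hand-written (rather than Biostrings) so
# that malformed files fail with the offending line number.
parse_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) abort("line 1: expected FASTA header ('>')")
  blank <- !nzchar(trimws(lines))
  if (any(blank & !is_hdr)) {
    # blank lines inside records are tolerated only at record boundaries
    lines <- lines[!blank]
    is_hdr <- startsWith(lines, ">")
  }
  ids <- trimws(sub("^>", "", lines[is_hdr]))
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    abort(paste0("line ", which(is_hdr)[!nzchar(ids)][1], ": empty FASTA header"))
  }
  grp <- cumsum(is_hdr)
  seqlines <- split(lines[!is_hdr], grp[!is_hdr])
  seqs <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  seqs[names(seqlines)] <- vapply(seqlines, paste, character(1), collapse = "")
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("line ", which(is_hdr)[empty][1],
                 ": record '", ids[empty][1], "' has no sequence"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write reads or peptides to FASTA
#'
#' @param x A tibble with an id column (`read_id`, `peptide_id` or
#'   `protein_id`) and a `seq` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  idcol <- intersect(c("read_id", "peptide_id", "protein_id", "id"), names(x))[1]
  if (is.na(idcol)) abort("no id column found")
  set <- Biostrings::BStringSet(setNames(x$seq, x[[idcol]]))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load a lineage-annotated reference protein database
#'
#' The database is a protein FASTA plus a tab-separated lineage table with
#' columns `protein_id`, `lineage` and optionally `source_group`
#' (`"viral"`/`"cellular"`; inferred from the first lineage label when
#' absent). Every FASTA id must have a lineage row.
#'
#' @param fasta_path Protein FASTA.
#' @param lineage_tsv_path Lineage TSV.
#' @return A `ref_db` tibble with columns `protein_id`, `seq`, `lineage`,
#'   `source_group`.
#' @export
load_reference_db <- function(fasta_path, lineage_tsv_path) {
  recs <- parse_fasta(fasta_path)
  lin <- readr::read_tsv(lineage_tsv_path, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("protein_id", "lineage") %in% names(lin))) {
    abort("lineage TSV needs columns protein_id, lineage")
  }
  missing <- setdiff(recs$id, lin$protein_id)
  if (length(missing) > 0) {
    abort(paste0("proteins without lineage: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  tbl <- tibble(protein_id = recs$id, seq = toupper(recs$seq)) |>
    left_join(lin, by = "protein_id")
  reference_db(tbl)
}

#' Construct/validate a reference protein database from a tibble
#'
#' @param proteins Tibble with `protein_id`, `seq`, `lineage` and optionally
#'   `source_group`.
#' @return A validated `ref_db` tibble.
#' @export
reference_db <- function(proteins) {
  proteins <- as_tibble(proteins)
  req <- c("protein_id", "seq", "lineage")
  if (!all(req %in% names(proteins))) {
    abort(paste0("reference db needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(proteins$protein_id)) {
    abort(paste0(
      "duplicate protein ids: ",
      paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
            collapse = ", ")
    ))
  }
  if (any(!nzchar(proteins$seq))) abort("empty protein sequence")
  proteins$lineage <- parse_lineage(proteins$lineage)
  if (!"source_group" %in% names(proteins)) {
    proteins$source_group <-
      ifelse(lineage_domain(proteins$lineage) == "Viruses", "viral", "cellular")
  }
  structure(proteins, class = c("ref_db", class(proteins)))
}

#' @export
print.ref_db <- function(x, ...) {
  cat("<reference protein db: ", nrow(x), " proteins, ",
      sum(x$source_group == "viral"), " viral / ",
      sum(x$source_group == "cellular"), " cellular, ",
      db_size_letters(x), " residues>\n", sep = "")
  NextMethod()
}

db_size_letters <- function(db) sum(nchar(db$seq))

#' Read per-sample sequencing statistics
#'
#' Expects a TSV with at least `sample_id`, `total_bp`, `n_reads` and
#' `depth_zone` (`SRF`, `DCM` or `OMZ`).
#'
#' @param path TSV path.
#' @return Tibble of sample statistics.
#' @export
read_sample_stats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "total_bp", "n_reads", "depth_zone")
  if (!all(req %in% names(x))) {
    abort(paste0("sample stats TSV needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(x$total_bp < x$n_reads)) abort("total_bp must be >= n_reads")
  if (!all(x$depth_zone %in% c("SRF", "DCM", "OMZ"))) {
    abort("depth_zone must be one of SRF, DCM, OMZ")
  }
  as_tibble(x)
}

#' Read per-sample prokaryote cell counts
#'
#' TSV with `sample_id` and at least one of `fc_cells_per_ml`
#' (flow cytometry) and `microscopy_cells_per_ml`.
#'
#' @param path TSV path.
#' @return Tibble of cell counts.
#' @export
read_cell_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(x) ||
      !any(c("fc_cells_per_ml", "microscopy_cells_per_ml") %in% names(x))) {
    abort("cell counts TSV needs sample_id and a *_cells_per_ml column")
  }
  for (col in c("fc_cells_per_ml", "microscopy_cells_per_ml")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  as_tibble(x)
}

#' Per-sample sequencing summaries of the 17 Tara Oceans microbial
#' metagenomes
#'
#' The published quality-controlled totals (bp, reads, G+C, read and ORF
#' sizes) for the seventeen 0.2–1.6 µm size-fraction 454 pyrosequencing
#' samples, with depth zones (`SRF`/`DCM`/`OMZ`) taken from the `_S`/`_D`/
#' `_Z` sample-name suffixes. Shipped as a plain TSV under `extdata`.
#'
#' @return Tibble of 17 samples.
#' @export
tara_sample_stats <- function() {
  read_sample_stats(system.file("extdata", "tara_sample_stats.tsv",
                                package = "ncldvscope", mustWork = TRUE))
}
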