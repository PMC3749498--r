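#' Build the taxon-by-sample read-count matrix
#'
#' Rows are all taxonomy nodes of depth at most `depth` that receive at
#' least one read at-or-below them across all samples; the cell for
#' (taxon, sample) counts reads whose assigned lineage has the row's
#' lineage as ancestor-or-equal. The normalised view divides each cell by
#' the sample's total read count (ancestor rows double-count reads, so
#' column sums of the count matrix exceed the totals by design).
#'
#' @param assignments [assign_2blca()] output (needs `sample_id`,
#'   `status`, `lineage`); only `assigned`/`ambiguous` reads with a
#'   non-root lineage contribute.
#' @param sample_stats Tibble with `sample_id`, `n_reads` and
#'   `depth_zone`.
#' @param depth Deepest taxonomy level kept (default 5, counted from the
#'   root; nodes of smaller depth are also kept).
#' @return A `taxon_matrix` object.
#' @export
build_taxon_matrix <- function(assignments, sample_stats, depth = 5L) {
  a <- assignments |>
    filter(.data$status %in% c("assigned", "ambiguous"),
           !is.na(.data$lineage), nzchar(.data$lineage))
  samples <- tibble(
    sample_id = sample_stats$sample_id,
    total_reads = sample_stats$n_reads,
    depth_zone = sample_stats$depth_zone
  )
  if (nrow(a) == 0) {
    return(taxon_matrix(
      matrix(0L, 0, nrow(samples),
             dimnames = list(NULL, samples$sample_id)), samples))
  }
  pref <- lapply(a$lineage, lineage_prefixes, max_depth = depth)
  long <- tibble(
    sample_id = rep(a$sample_id, lengths(pref)),
    lineage = unlist(pref, use.names = FALSE)
  ) |>
    dplyr::count(.data$lineage, .data$sample_id)
  taxa <- sort(unique(long$lineage))
  counts <- matrix(0L, length(taxa), nrow(samples),
                   dimnames = list(taxa, samples$sample_id))
  counts[cbind(match(long$lineage, taxa),
               match(long$sample_id, samples$sample_id))] <- long$n
  taxon_matrix(counts, samples)
}

#' Construct a taxon-by-sample matrix from counts
#'
#' @param counts Integer matrix, taxa (lineage strings) x samples.
#' @param samples Tibble with `sample_id` and optionally `total_reads`
#'   (defaults to column sums) and `depth_zone` (defaults to `"SRF"`).
#' @return A `taxon_matrix` object: the count matrix plus sample and
#'   taxon metadata.
#' @export
taxon_matrix <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    abort("counts must have lineage rownames")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  if (is.null(samples)) {
    samples <- tibble(sample_id = colnames(counts) %||%
                        paste0("S", seq_len(ncol(counts))))
  }
  samples <- as_tibble(samples)
  if (!"total_reads" %in% names(samples)) {
    samples$total_reads <- colSums(counts)
  }
  if (!"depth_zone" %in% names(samples)) samples$depth_zone <- "SRF"
  colnames(counts) <- samples$sample_id
  structure(
    list(counts = counts, samples = samples,
         taxa = tibble(lineage = rownames(counts),
                       depth = lineage_depth(rownames(counts)))),
    class = "taxon_matrix"
  )
}

#' @export
print.taxon_matrix <- function(x, ...) {
  cat("<taxon_matrix: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples, ", sum(x$counts), " counted reads>\n", sep = "")
  invisible(x)
}

#' @export
dim.taxon_matrix <- function(x) dim(x$counts)

#' Normalised (relative-abundance) view of a taxon matrix
#'
#' Each column divided by the sample's total read count (fallback: the
#' column sum when totals are zero/unknown).
#'
#' @param tm A `taxon_matrix`.
#' @return Numeric matrix of per-sample relative read abundances.
#' @export
normalized_matrix <- function(tm) {
  tot <- tm$samples$total_reads
  tot[!is.finite(tot) | tot <= 0] <- colSums(tm$counts)[!is.finite(tot) | tot <= 0]
  tot[tot <= 0] <- 1
  sweep(tm$counts, 2, tot, "/")
}

#' Drop sparse taxa and keep the matrix normalisable
#'
#' Removes taxa with fewer than `min_total_reads` reads summed over all
#' samples (the threshold is strict: a row with exactly
#' `min_total_reads` reads is kept).
#'
#' @param tm A `taxon_matrix`.
#' @param min_total_reads Minimum row total (default 5).
#' @return Filtered `taxon_matrix`.
#' @export
filter_taxon_matrix <- function(tm, min_total_reads = 5L) {
  keep <- rowSums(tm$counts) >= min_total_reads
  taxon_matrix(tm$counts[keep, , drop = FALSE], tm$samples)
}

#' Read/write a taxon-by-sample matrix TSV
#'
#' First column `lineage`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @param sample_stats Optional sample stats supplying `total_reads` and
#'   `depth_zone` for the matrix columns.
#' @param tm A `taxon_matrix` (write).
#' @return A `taxon_matrix` (read); `path` invisibly (write).
#' @export
read_taxon_matrix <- function(path, sample_stats = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(x[, -1, drop = FALSE])
  rownames(counts) <- x[[1]]
  samples <- NULL
  if (!is.null(sample_stats)) {
    samples <- tibble(sample_id = colnames(counts)) |>
      left_join(
        select(sample_stats, "sample_id", total_reads = "n_reads",
               "depth_zone"),
        by = "sample_id"
      )
  }
  taxon_matrix(counts, samples)
}

#' @rdname read_taxon_matrix
#' @export
write_taxon_matrix <- function(tm, path) {
  readr::write_tsv(
    bind_cols(tibble(lineage = rownames(tm$counts)), as_tibble(tm$counts)),
    path
  )
  invisible(path)
}

#' @exportS3Method
tidy.taxon_matrix <- function(x, ...) {
  norm <- normalized_matrix(x)
  as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    setNames(c("lineage", "sample_id", "count")) |>
    mutate(rel_abundance = as.vector(norm)) |>
    as_tibble()
}

#' @exportS3Method
glance.taxon_matrix <- function(x, ...) {
  tibble(n_taxa = nrow(x$counts), n_samples = ncol(x$counts),
         total_counted = sum(x$counts),
         max_depth = max(c(0L, x$taxa$depth)))
}
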