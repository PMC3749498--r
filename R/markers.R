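#' Construct a set of single-copy marker-gene profiles
#'
#' A profile is an ungapped position-specific score matrix (log-odds bits
#' per alignment column) over the 20 amino acids, together with the length
#' `L` of the reference alignment it was derived from, a group label
#' (`ncldv` or `cellular`) and an optional family scope (e.g.
#' `Megaviridae`). Residues outside the 20-letter alphabet (`X` from
#' fuzzy codons) score 0 at every column.
#'
#' @param name Character vector of marker names (unique).
#' @param group `"ncldv"` or `"cellular"`, recycled.
#' @param pssm List of numeric matrices, one per marker, `L x 20` with
#'   column names the amino-acid one-letter codes.
#' @param family_scope Optional family label per marker (`NA` for
#'   group-wide markers).
#' @return A `marker_profiles` tibble with columns `name`, `group`,
#'   `family_scope`, `L` and list-column `pssm`.
#' @export
marker_profiles <- function(name, group, pssm, family_scope = NA_character_) {
  name <- unname(name)
  pssm <- unname(pssm)
  if (anyDuplicated(name)) abort("marker names must be unique")
  group <- rep_len(unname(group), length(name))
  family_scope <- rep_len(unname(family_scope), length(name))
  if (!all(group %in% c("ncldv", "cellular"))) {
    abort("group must be 'ncldv' or 'cellular'")
  }
  pssm <- lapply(pssm, function(m) {
    if (is.null(colnames(m)) || !setequal(colnames(m), aa_alphabet())) {
      abort("each pssm needs the 20 amino acids as column names")
    }
    m[, aa_alphabet(), drop = FALSE]
  })
  structure(
    tibble(name = name, group = group, family_scope = family_scope,
           L = vapply(pssm, nrow, integer(1)), pssm = pssm),
    class = c("marker_profiles", class(tibble())))
}

aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# expand an L x 20 pssm to the L x 27 layout the scanner expects
# (columns 'A'..'Z' plus a default column; non-standard letters score 0)
expand_pssm <- function(m) {
  out <- matrix(0, nrow = nrow(m), ncol = 27)
  out[, match(colnames(m), LETTERS)] <- m
  out
}

#' Write/read marker profiles as a plain score table
#'
#' Long TSV with columns `name`, `group`, `family_scope`, `pos` (1-based
#' alignment column), one score column per amino acid.
#'
#' @param profiles A [marker_profiles()] object.
#' @param path TSV path.
#' @return `path` (write) or a `marker_profiles` object (read).
#' @export
write_marker_profiles <- function(profiles, path) {
  rows <- purrr::pmap_dfr(profiles, function(name, group, family_scope, L, pssm) {
    bind_cols(tibble(name = name, group = group,
                     family_scope = family_scope, pos = seq_len(L)),
              as_tibble(pssm))
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_marker_profiles
#' @export
read_marker_profiles <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  parts <- split(x, factor(x$name, levels = unique(x$name)))
  marker_profiles(
    name = unname(vapply(parts, function(p) p$name[1], character(1))),
    group = unname(vapply(parts, function(p) p$group[1], character(1))),
    family_scope = unname(vapply(parts,
                                 function(p) as.character(p$family_scope[1]),
                                 character(1))),
    pssm = unname(lapply(parts, function(p) {
      m <- as.matrix(p[order(p$pos), aa_alphabet()])
      rownames(m) <- NULL
      m
    }))
  )
}

#' Scan peptides for marker-gene homologs
#'
#' Each peptide is scored against each profile with the best ungapped
#' window alignment (at least `min_overlap` aligned columns); the score S
#' in bits maps to `E = m * L * 2^-S` with `m` the peptide length. Hits at
#' `max_evalue` or better are reported once per (read, marker), keeping
#' the best E-value.
#'
#' @param peptides Output of [six_frame_orfs()] (needs `peptide_id`,
#'   `read_id`, `seq`; `sample_id` carried through if present).
#' @param profiles A [marker_profiles()] object.
#' @param max_evalue Scan threshold (default 1e-3).
#' @param min_overlap Minimum aligned columns (default 30).
#' @return Tibble with `read_id` (+`sample_id`), `marker_name`, `group`,
#'   `family_scope`, `score`, `e_value`.
#' @export
scan_markers <- function(peptides, profiles, max_evalue = 1e-3,
                         min_overlap = 30L) {
  peptides <- as_tibble(peptides)
  has_sample <- "sample_id" %in% names(peptides)
  empty <- tibble(read_id = character(), marker_name = character(),
                  group = character(), family_scope = character(),
                  score = numeric(), e_value = numeric())
  if (has_sample) empty <- mutate(empty, sample_id = character(),
                                  .after = "read_id")
  if (nrow(peptides) == 0) return(empty)
  if (any(grepl("[^A-Z]", peptides$seq))) {
    abort("peptides contain characters outside the amino-acid alphabet")
  }
  m <- nchar(peptides$seq)
  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    s <- .pssm_best_scores(peptides$seq, expand_pssm(profiles$pssm[[i]]),
                           as.integer(min_overlap))
    ev <- m * profiles$L[i] * 2^(-s)
    keep <- which(!is.na(s) & ev <= max_evalue)
    if (length(keep) == 0) next
    h <- tibble(
      read_id = peptides$read_id[keep],
      marker_name = profiles$name[i],
      group = profiles$group[i],
      family_scope = profiles$family_scope[i],
      score = s[keep], e_value = ev[keep]
    )
    if (has_sample) h <- mutate(h, sample_id = peptides$sample_id[keep],
                                .after = "read_id")
    out[[i]] <- h
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res |>
    group_by(.data$read_id, .data$marker_name) |>
    arrange(.data$e_value, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Attach a taxonomic bin to marker hits
#'
#' Marker-gene homologs are separated into NCLDV / Bacteria / Archaea /
#' Eukaryota bins by the 2bLCA annotation of their reads (`by = "2blca"`,
#' the reference route), or by the scanning profile's own group
#' (`by = "profile"`: `ncldv` profiles bin as `NCLDV`, `cellular`
#' profiles as `cellular`), which coincides with the 2bLCA route when the
#' marker set is group-pure.
#'
#' @param hits Output of [scan_markers()].
#' @param assignments [classify_bin()] output (required for `by="2blca"`).
#' @param by Binning route.
#' @return `hits` with an added `bin` column.
#' @export
bin_marker_hits <- function(hits, assignments = NULL,
                            by = c("2blca", "profile")) {
  by <- match.arg(by)
  if (by == "profile") {
    return(mutate(hits, bin = ifelse(.data$group == "ncldv",
                                     "NCLDV", "cellular")))
  }
  if (is.null(assignments) || !"bin" %in% names(assignments)) {
    abort("by='2blca' needs classify_bin() output in `assignments`")
  }
  left_join(hits, distinct(select(assignments, "read_id", "bin")),
            by = "read_id")
}

#' Per-sample marker-gene densities
#'
#' Density is the number of marker homolog hits per Mbp of metagenome:
#' `d = n_hits * 1e6 / total_bp`; the size-normalised variant divides by
#' the profile's reference alignment length `L`. Every (sample, marker)
#' combination is present in the output — markers with no hits get an
#' explicit zero row (`bin = NA`) so that group summaries include them.
#'
#' @param hits Binned marker hits ([bin_marker_hits()]).
#' @param sample_stats Tibble with `sample_id`, `total_bp`.
#' @param profiles A [marker_profiles()] object.
#' @return Tibble with `sample_id`, `marker_name`, `group`, `bin`,
#'   `n_hits`, `total_bp`, `density`, `norm_density`.
#' @export
marker_density <- function(hits, sample_stats, profiles) {
  if (any(sample_stats$total_bp <= 0)) abort("total_bp must be positive")
  if (!"bin" %in% names(hits)) abort("hits need a bin column; see bin_marker_hits()")
  obs <- hits |>
    filter(.data$sample_id %in% sample_stats$sample_id) |>
    dplyr::count(.data$sample_id, .data$marker_name, .data$bin,
                 name = "n_hits")
  grid <- tidyr::expand_grid(sample_id = sample_stats$sample_id,
                             marker_name = profiles$name) |>
    anti_join(distinct(obs, .data$sample_id, .data$marker_name),
              by = c("sample_id", "marker_name")) |>
    mutate(bin = NA_character_, n_hits = 0L)
  bind_rows(obs, grid) |>
    left_join(select(sample_stats, "sample_id", "total_bp"),
              by = "sample_id") |>
    left_join(select(profiles, marker_name = "name", "group", "L"),
              by = "marker_name") |>
    mutate(density = .data$n_hits * 1e6 / .data$total_bp,
           norm_density = .data$density / .data$L) |>
    select("sample_id", "marker_name", "group", "bin", "n_hits",
           "total_bp", "L", "density", "norm_density") |>
    arrange(.data$sample_id, .data$marker_name, .data$bin)
}

#' Summarise marker densities for a marker group
#'
#' Summary (mean or median) over the per-marker densities of one profile
#' group, with zero densities contributed by markers without hits. By
#' default per sample; `pooled = TRUE` first pools all samples into one
#' metagenome (summed hits over summed bp).
#'
#' @param densities Output of [marker_density()].
#' @param group Profile group (`"ncldv"` or `"cellular"`).
#' @param bins Restrict to hits binned into these bins (default: all
#'   binned hits). Zero rows always count as density 0.
#' @param mode `"mean"` or `"median"`.
#' @param normalised Use the alignment-length-normalised densities.
#' @param pooled Pool samples before summarising.
#' @return Tibble `sample_id`, `summary` (or one pooled row with
#'   `sample_id = "(pooled)"`).
#' @export
group_summary <- function(densities, group, bins = NULL,
                          mode = c("mean", "median"), normalised = FALSE,
                          pooled = FALSE) {
  mode <- match.arg(mode)
  d <- filter(densities, .data$group == !!group)
  if (nrow(d) == 0) abort(paste0("no markers in group '", group, "'"))
  if (!is.null(bins)) d <- filter(d, is.na(.data$bin) | .data$bin %in% bins)
  fn <- if (mode == "mean") mean else stats::median
  if (pooled) {
    bp_total <- sum(distinct(densities, .data$sample_id, .data$total_bp)$total_bp)
    per_marker <- d |>
      group_by(.data$marker_name, .data$L) |>
      summarise(n_hits = sum(.data$n_hits), .groups = "drop") |>
      mutate(density = .data$n_hits * 1e6 / bp_total,
             value = if (normalised) .data$density / .data$L else .data$density)
    return(tibble(sample_id = "(pooled)", summary = fn(per_marker$value)))
  }
  d |>
    group_by(.data$sample_id, .data$marker_name, .data$L) |>
    summarise(density = sum(.data$density),
              norm_density = sum(.data$norm_density), .groups = "drop") |>
    mutate(value = if (normalised) .data$norm_density else .data$density) |>
    group_by(.data$sample_id) |>
    summarise(summary = fn(.data$value), .groups = "drop")
}

#' Per-sample NCLDV : prokaryote marker-density ratio
#'
#' The relative genome abundance of NCLDVs: the average (or median)
#' density of the NCLDV markers binned `NCLDV`, divided by the average
#' density of the cellular markers binned as prokaryotes (`Bacteria` +
#' `Archaea`, or the coarse `cellular` bin from profile binning).
#'
#' @param densities Output of [marker_density()].
#' @param mode Summary across markers (default `"mean"`).
#' @param normalised Use alignment-length-normalised densities.
#' @param ncldv_bins,prok_bins Bin labels counted on each side.
#' @return Tibble `sample_id`, `ncldv_density`, `prok_density`, `r`.
#' @export
abundance_ratio <- function(densities, mode = "mean", normalised = FALSE,
                            ncldv_bins = "NCLDV",
                            prok_bins = c("Bacteria", "Archaea", "cellular")) {
  v <- group_summary(densities, "ncldv", bins = ncldv_bins, mode = mode,
                     normalised = normalised) |>
    rename(ncldv_density = "summary")
  p <- group_summary(densities, "cellular", bins = prok_bins, mode = mode,
                     normalised = normalised) |>
    rename(prok_density = "summary")
  inner_join(v, p, by = "sample_id") |>
    mutate(r = ifelse(.data$prok_density > 0,
                      .data$ncldv_density / .data$prok_density, NA_real_))
}

#' Rescale relative NCLDV abundance to genomes per ml
#'
#' `A = r * phi * C`: the NCLDV:prokaryote density ratio `r` times the
#' prokaryote cell concentration `C` (cells per ml) times the fraction
#' `phi` of prokaryotic cells assumed to pass the 1.6-µm pre-filter
#' (default 0.9). When both flow-cytometry and microscopy counts exist,
#' one estimate per count source is emitted rather than an average.
#'
#' @param ratios Tibble with `sample_id`, `r` (see [abundance_ratio()]).
#' @param cell_counts Tibble with `sample_id`, `fc_cells_per_ml` and/or
#'   `microscopy_cells_per_ml`.
#' @param passthrough Pre-filter pass-through fraction phi in (0, 1].
#' @return An `ncldv_abundance` tibble: `sample_id`, `r`, `count_source`,
#'   `cells_per_ml`, `passthrough`, `genomes_per_ml`.
#' @export
absolute_abundance <- function(ratios, cell_counts, passthrough = 0.9) {
  stopifnot(passthrough > 0, passthrough <= 1)
  cc <- tidyr::pivot_longer(
    cell_counts, dplyr::any_of(c("fc_cells_per_ml", "microscopy_cells_per_ml")),
    names_to = "count_source", values_to = "cells_per_ml"
  ) |>
    filter(!is.na(.data$cells_per_ml)) |>
    mutate(count_source = sub("_cells_per_ml$", "", .data$count_source))
  out <- inner_join(select(ratios, "sample_id", "r"), cc, by = "sample_id")
  if (nrow(out) == 0) abort("no cell counts available for these samples")
  out <- out |>
    mutate(passthrough = passthrough,
           genomes_per_ml = .data$r * passthrough * .data$cells_per_ml)
  structure(out, class = c("ncldv_abundance", class(out)))
}

#' Correlate two per-sample density vectors
#'
#' Used e.g. to check that the abundance of giant-virus MutS7/8
#' mismatch-repair homologs tracks the Megaviridae marker density across
#' samples. Pearson by default (Spearman available).
#'
#' @param x,y Numeric vectors over the same samples (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble `estimate`, `statistic`, `p_value`, `n`, `method`.
#' @export
correlate_densities <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance vector: correlation undefined")
    return(tibble(estimate = NA_real_, statistic = NA_real_,
                  p_value = NA_real_, n = length(x), method = method))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = length(x), method = method)
}
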