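#' Synthetic taxonomy, reference, community, read-set and matrix
#' generators
#'
#' Every input the pipeline consumes can be fabricated with known ground
#' truth: a rooted labelled taxonomy with the four top-level domains, a
#' lineage-annotated protein database with a mutation ladder between
#' related lineages, miniature genomes carrying single-copy marker genes,
#' size-fractionated read sets with planted artificial duplicates, and
#' compositional taxon-by-sample count matrices with planted coupled
#' taxon pairs. All generators are pure functions of (parameters, seed).
#'
#' @name synthetic-data
NULL

rand_id_syllable <- function(n) {
  con <- c("b", "d", "g", "k", "l", "m", "n", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    paste0(sample(con, 1), sample(vow, 1), sample(con, 1), sample(vow, 1))
  }, character(1))
}

#' Generate a rooted labelled taxonomy
#'
#' Four domains (Bacteria, Archaea, Eukaryota, Viruses) at level 1, then
#' `branching` children per node down to `depth` levels. Under Viruses
#' the first level-2 node is `"dsDNA viruses, no RNA stage"` and its
#' children are NCLDV family labels, so virus leaves carry realistic
#' NCLDV lineages. Labels carry a per-tree counter, so collisions are
#' impossible; the tree is deterministic for a seed.
#'
#' @param seed RNG seed.
#' @param depth Number of levels including the domain (default 5).
#' @param branching Children per internal node (default 3).
#' @return Tibble `lineage`, `depth`, `domain`, `is_leaf`.
#' @export
make_taxonomy <- function(seed, depth = 5L, branching = 3L) {
  stopifnot(depth >= 2, branching >= 1)
  with_seed(seed, {
    counter <- 0L
    new_label <- function() {
      counter <<- counter + 1L
      paste0(stringr::str_to_title(rand_id_syllable(1)),
             sprintf("%03d", counter))
    }
    rows <- list()
    grow <- function(prefix, level, fixed_children = NULL) {
      labels <- if (!is.null(fixed_children)) fixed_children
      else vapply(seq_len(branching), function(i) new_label(), character(1))
      for (lab in labels) {
        lin <- paste(c(prefix, lab), collapse = "; ")
        leaf <- level == depth
        rows[[length(rows) + 1L]] <<- tibble(
          lineage = lin, depth = level,
          domain = strsplit(lin, "; ", fixed = TRUE)[[1]][1],
          is_leaf = leaf
        )
        if (level < depth) grow(c(prefix, lab), level + 1L)
      }
    }
    for (dom in c("Bacteria", "Archaea", "Eukaryota", "Viruses")) {
      leaf1 <- depth == 1L
      rows[[length(rows) + 1L]] <- tibble(lineage = dom, depth = 1L,
                                          domain = dom, is_leaf = leaf1)
      if (depth >= 3 && dom == "Viruses") {
        # NCLDV families live under the dsDNA node; remaining level-2
        # nodes are phage-like synthetic clades
        l2 <- c("dsDNA viruses, no RNA stage",
                vapply(seq_len(max(0, branching - 1)),
                       function(i) new_label(), character(1)))
        for (k in seq_along(l2)) {
          lin2 <- paste(dom, l2[k], sep = "; ")
          leaf2 <- depth == 2L
          rows[[length(rows) + 1L]] <- tibble(lineage = lin2, depth = 2L,
                                              domain = dom,
                                              is_leaf = leaf2)
          kids <- if (k == 1) utils::head(ncldv_families()[-1], branching)
          else NULL
          grow(c(dom, l2[k]), 3L, fixed_children = kids)
        }
      } else if (depth >= 2) {
        grow(dom, 2L)
      }
    }
    bind_rows(rows)
  })
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
  }, character(1))
}

# substitute a fraction (or exact count) of residues/bases, never
# touching the first `protect_prefix` positions
mutate_seq <- function(seq, rate = NULL, n_sub = NULL, alphabet,
                       protect_prefix = 0L) {
  ch <- strsplit(seq, "")[[1]]
  idx_ok <- seq_along(ch)[seq_along(ch) > protect_prefix]
  k <- if (!is.null(n_sub)) min(n_sub, length(idx_ok))
  else stats::rbinom(1, length(idx_ok), rate)
  if (k > 0) {
    pos <- sample(idx_ok, k)
    ch[pos] <- vapply(ch[pos], function(c0) {
      sample(setdiff(alphabet, c0), 1)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Fabricate single-copy marker profiles with known consensus peptides
#'
#' Each marker gets a random consensus peptide of `profile_len` residues
#' and a log-odds score matrix that rewards the consensus residue
#' (emission probability 0.9 against a uniform background) and
#' penalises the rest. The consensus peptides are attached as the
#' `consensus` attribute and drive genome construction.
#'
#' @param n_ncldv,n_cellular Number of markers per group.
#' @param profile_len Reference alignment length L in residues.
#' @param seed RNG seed.
#' @param ncldv_family_scope Optional family labels recycled over the
#'   NCLDV markers.
#' @return A [marker_profiles()] object with a `consensus` attribute.
#' @export
make_marker_profiles <- function(n_ncldv = 4L, n_cellular = 4L,
                                 profile_len = 60L, seed = 1L,
                                 ncldv_family_scope = NA_character_) {
  with_seed(seed, {
    n <- n_ncldv + n_cellular
    names <- c(sprintf("ncldv_marker_%02d", seq_len(n_ncldv)),
               sprintf("cell_marker_%02d", seq_len(n_cellular)))
    group <- rep(c("ncldv", "cellular"), c(n_ncldv, n_cellular))
    fam <- c(rep_len(ncldv_family_scope, n_ncldv),
             rep(NA_character_, n_cellular))
    consensus <- setNames(random_aa(n, profile_len), names)
    match_s <- log2(0.9 / 0.05)
    mismatch_s <- log2((0.1 / 19) / 0.05)
    pssm <- lapply(consensus, function(cs) {
      ch <- strsplit(cs, "")[[1]]
      m <- matrix(mismatch_s, nrow = profile_len, ncol = 20,
                  dimnames = list(NULL, aa_alphabet()))
      m[cbind(seq_len(profile_len), match(ch, aa_alphabet()))] <- match_s
      m
    })
    out <- marker_profiles(names, group, pssm, fam)
    attr(out, "consensus") <- consensus
    out
  })
}

#' Fabricate a lineage-annotated reference protein database
#'
#' For every parent of leaves an ancestral protein set is drawn; each
#' leaf receives copies mutated at `leaf_divergence`, so sibling leaves
#' share about `1 - 2*leaf_divergence` identity and LCA behaviour is
#' exercised. When `profiles` are supplied, every applicable leaf also
#' receives one diverged copy of each marker consensus (NCLDV markers
#' for NCLDV-family leaves, cellular markers for cellular leaves) —
#' exactly once per leaf, mirroring single-copy genes.
#'
#' @param taxonomy Output of [make_taxonomy()].
#' @param n_proteins_per_leaf Non-marker proteins per leaf (default 2).
#' @param profiles Optional [make_marker_profiles()] output.
#' @param seed RNG seed.
#' @param protein_len Length of the non-marker proteins.
#' @param leaf_divergence Per-leaf substitution fraction (default 0.1).
#' @param marker_divergence Marker copy divergence (default 0.1).
#' @return List with `db` (a [reference_db()]) and `truth`
#'   (`protein_id`, `lineage`, `is_marker`, `marker_name`).
#' @export
make_reference_db <- function(taxonomy, n_proteins_per_leaf = 2L,
                              profiles = NULL, seed = 1L,
                              protein_len = 60L, leaf_divergence = 0.1,
                              marker_divergence = 0.1) {
  leaves <- filter(taxonomy, .data$is_leaf)
  with_seed(seed, {
    parent_of <- function(lin) {
      r <- lineage_ranks(lin)[[1]]
      paste(utils::head(r, -1), collapse = "; ")
    }
    parents <- vapply(leaves$lineage, parent_of, character(1))
    anc <- lapply(unique(parents), function(p) {
      random_aa(n_proteins_per_leaf, protein_len)
    })
    names(anc) <- unique(parents)
    rows <- list()
    pid <- 0L
    for (i in seq_len(nrow(leaves))) {
      lin <- leaves$lineage[i]
      for (j in seq_len(n_proteins_per_leaf)) {
        pid <- pid + 1L
        rows[[length(rows) + 1L]] <- tibble(
          protein_id = sprintf("P%05d", pid), lineage = lin,
          seq = mutate_seq(anc[[parents[i]]][j], rate = leaf_divergence,
                           alphabet = aa_alphabet()),
          is_marker = FALSE, marker_name = NA_character_
        )
      }
      if (!is.null(profiles)) {
        cons <- attr(profiles, "consensus")
        dom <- leaves$domain[i]
        is_ncldv_leaf <- dom == "Viruses" &&
          any(lineage_ranks(lin)[[1]] %in% ncldv_families())
        applicable <- if (is_ncldv_leaf) {
          profiles$name[profiles$group == "ncldv"]
        } else if (dom != "Viruses") {
          profiles$name[profiles$group == "cellular"]
        } else character()
        for (mk in applicable) {
          pid <- pid + 1L
          rows[[length(rows) + 1L]] <- tibble(
            protein_id = sprintf("P%05d", pid), lineage = lin,
            seq = mutate_seq(cons[[mk]], rate = marker_divergence,
                             alphabet = aa_alphabet()),
            is_marker = TRUE, marker_name = mk
          )
        }
      }
    }
    truth <- bind_rows(rows)
    list(db = reference_db(select(truth, "protein_id", "seq", "lineage")),
         truth = select(truth, -"seq"))
  })
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(peptide, codons = codon_table()) {
  ch <- strsplit(peptide, "")[[1]]
  paste(vapply(ch, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Assemble a miniature planktonic community with planted NCLDV fraction
#'
#' Draws prokaryote and NCLDV genomes from taxonomy leaves. Each genome
#' is random DNA of `genome_len` bp carrying exactly one diverged,
#' reverse-translated copy of each applicable marker consensus at evenly
#' spaced forward-strand positions (single-copy genes). Relative genome
#' abundances are lognormal within each compartment and scaled so the
#' summed NCLDV abundance is `ncldv_fraction` times the summed
#' prokaryote abundance — the planted NCLDV:prokaryote genome ratio.
#'
#' @param taxonomy Output of [make_taxonomy()].
#' @param profiles Output of [make_marker_profiles()].
#' @param ncldv_fraction Planted genome ratio (default 0.03).
#' @param n_prok,n_ncldv Genomes per compartment.
#' @param genome_len Genome length in bp (default 2000; compact desk-
#'   scale model genomes).
#' @param marker_divergence Substitution fraction applied to each marker
#'   consensus per genome (default 0.05).
#' @param cells_per_ml Planted prokaryote cell concentration.
#' @param seed RNG seed.
#' @return A `sim_community` list: `genomes` tibble (`genome_id`,
#'   `lineage`, `domain`, `seq`, `length`, `abundance`, `markers`
#'   list-column of marker coordinates), `ncldv_fraction`,
#'   `cells_per_ml`.
#' @export
sim_community <- function(taxonomy, profiles, ncldv_fraction = 0.03,
                          n_prok = 8L, n_ncldv = 3L, genome_len = 2000L,
                          marker_divergence = 0.05, cells_per_ml = 1e6,
                          seed = 1L) {
  stopifnot(ncldv_fraction >= 0)
  leaves <- filter(taxonomy, .data$is_leaf)
  ncldv_ok <- leaves$domain == "Viruses" &
    vapply(lineage_ranks(leaves$lineage),
           function(r) any(r %in% ncldv_families()), logical(1))
  prok_ok <- leaves$domain %in% c("Bacteria", "Archaea")
  if (sum(ncldv_ok) < n_ncldv || sum(prok_ok) < n_prok) {
    abort("taxonomy has too few NCLDV or prokaryote leaves")
  }
  with_seed(seed, {
    cons <- attr(profiles, "consensus")
    codons <- codon_table()
    pick_prok <- sample(which(prok_ok), n_prok)
    pick_ncldv <- sample(which(ncldv_ok), n_ncldv)
    build <- function(lin, dom, gid) {
      grp <- if (dom == "Viruses") "ncldv" else "cellular"
      mks <- profiles$name[profiles$group == grp]
      gene_nt <- 3L * profiles$L[match(mks, profiles$name)]
      stopifnot(sum(gene_nt) <= genome_len)
      base <- paste(sample(c("A", "C", "G", "T"), genome_len,
                           replace = TRUE), collapse = "")
      spacing <- genome_len %/% max(1L, length(mks))
      pos <- (seq_along(mks) - 1L) * spacing + 1L
      seq <- base
      coords <- tibble(marker = mks, start = pos - 1L,
                       end = pos - 1L + gene_nt)
      for (k in seq_along(mks)) {
        pep <- mutate_seq(cons[[mks[k]]], rate = marker_divergence,
                          alphabet = aa_alphabet())
        gene <- reverse_translate(pep, codons)
        substr(seq, pos[k], pos[k] + gene_nt[k] - 1L) <- gene
      }
      tibble(genome_id = gid, lineage = lin, domain = dom, seq = seq,
             length = genome_len, markers = list(coords))
    }
    genomes <- bind_rows(
      purrr::map2_dfr(leaves$lineage[pick_prok], seq_len(n_prok),
                      function(l, i) build(l, leaves$domain[match(l, leaves$lineage)],
                                           sprintf("prok%02d", i))),
      purrr::map2_dfr(leaves$lineage[pick_ncldv], seq_len(n_ncldv),
                      function(l, i) build(l, "Viruses",
                                           sprintf("ncldv%02d", i)))
    )
    ab_p <- stats::rlnorm(n_prok, 0, 0.5)
    ab_p <- ab_p / sum(ab_p)
    ab_v <- if (n_ncldv > 0) stats::rlnorm(n_ncldv, 0, 0.5) else numeric()
    ab_v <- if (length(ab_v)) ab_v / sum(ab_v) * ncldv_fraction else ab_v
    ab <- c(ab_p, ab_v)
    genomes$abundance <- ab / sum(ab)
    structure(list(genomes = genomes, ncldv_fraction = ncldv_fraction,
                   cells_per_ml = cells_per_ml),
              class = "sim_community")
  })
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a pyrosequencing sample from a community
#'
#' Reads are drawn from genomes proportionally to abundance times
#' length, from uniform start positions and random strands, with uniform
#' substitution errors. Artificial duplicates are injected at rate
#' `dup_rate`: a duplicate re-emits an earlier read with an identical 5'
#' start, at most 3% substitution divergence (never in the first five
#' bases) and an optionally truncated tail — the artefact the duplicate
#' filter is built to remove. Cell counts are drawn lognormally around
#' the community's planted concentration.
#'
#' @param community A [sim_community()] object.
#' @param n_reads Number of reads (default 50000).
#' @param read_len Read length in bp (default 350).
#' @param error_rate Per-base substitution rate (default 0).
#' @param dup_rate Artificial duplicate rate (default 0).
#' @param seed RNG seed.
#' @param sample_id Sample name.
#' @param depth_zone Zone label for the sample stats (default "SRF").
#' @return List: `reads` (tibble `read_id`, `sample_id`, `seq`), `truth`
#'   (provenance per read: `genome_id`, `start`, `end`, `strand`,
#'   `is_duplicate`, `dup_of`), `sample_stats`, `cell_counts`.
#' @export
simulate_sample <- function(community, n_reads = 50000L, read_len = 350L,
                            error_rate = 0, dup_rate = 0, seed = 1L,
                            sample_id = "sim1", depth_zone = "SRF") {
  g <- community$genomes
  with_seed(seed, {
    if (n_reads == 0) {
      reads <- tibble(read_id = character(), sample_id = character(),
                      seq = character())
      truth <- tibble(read_id = character(), genome_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), is_duplicate = logical(),
                      dup_of = character())
    } else {
      w <- g$abundance * g$length
      is_dup <- stats::runif(n_reads) < dup_rate
      is_dup[1] <- FALSE
      n_orig <- sum(!is_dup)
      gi <- sample.int(nrow(g), n_orig, replace = TRUE, prob = w)
      len <- pmin(read_len, g$length[gi])
      start <- vapply(seq_len(n_orig), function(k) {
        sample.int(g$length[gi[k]] - len[k] + 1L, 1L)
      }, integer(1))
      strand <- sample(c("+", "-"), n_orig, replace = TRUE)
      seqs <- substring(g$seq[gi], start, start + len - 1L)
      neg <- strand == "-"
      if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
      if (error_rate > 0) {
        nsub <- stats::rbinom(n_orig, nchar(seqs), error_rate)
        for (k in which(nsub > 0)) {
          seqs[k] <- mutate_seq(seqs[k], n_sub = nsub[k],
                                alphabet = c("A", "C", "G", "T"))
        }
      }
      ids <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
      orig_rows <- which(!is_dup)
      read_seq <- character(n_reads)
      read_seq[orig_rows] <- seqs
      src_row <- integer(n_reads)
      src_row[orig_rows] <- seq_len(n_orig)
      dup_of <- rep(NA_character_, n_reads)
      for (r in which(is_dup)) {
        donor <- sample(orig_rows[orig_rows < r], 1)
        s <- read_seq[donor]
        L <- nchar(s)
        keep <- L - sample.int(max(1L, floor(0.05 * L)), 1L) + 1L
        s <- substr(s, 1L, max(keep, 6L))
        k <- sample.int(floor(0.03 * nchar(s)) + 1L, 1L) - 1L
        read_seq[r] <- mutate_seq(s, n_sub = k,
                                  alphabet = c("A", "C", "G", "T"),
                                  protect_prefix = 5L)
        src_row[r] <- src_row[donor]
        dup_of[r] <- ids[donor]
      }
      reads <- tibble(read_id = ids, sample_id = sample_id, seq = read_seq)
      truth <- tibble(
        read_id = ids, genome_id = g$genome_id[gi[src_row]],
        start = start[src_row] - 1L, end = start[src_row] - 1L + len[src_row],
        strand = strand[src_row], is_duplicate = is_dup, dup_of = dup_of
      )
    }
    sample_stats <- tibble(
      sample_id = sample_id, total_bp = sum(nchar(reads$seq)),
      n_reads = nrow(reads), depth_zone = depth_zone
    )
    cell_counts <- tibble(
      sample_id = sample_id,
      fc_cells_per_ml = stats::rlnorm(1, log(community$cells_per_ml), 0.1),
      microscopy_cells_per_ml = stats::rlnorm(1, log(community$cells_per_ml),
                                              0.15)
    )
    list(reads = reads, truth = truth, sample_stats = sample_stats,
         cell_counts = cell_counts)
  })
}

#' Generate a compositional count matrix with planted coupled taxon
#' pairs
#'
#' Baseline counts are lognormal-Poisson (overdispersed) draws closed to
#' a fixed per-sample sequencing depth, which induces the compositional
#' bias the permutation-renormalization null is designed to handle.
#' Each planted pair shares a latent per-sample abundance factor scaled
#' by `effect` (log scale); `effect = 0` plants nothing. Pair members
#' are chosen from the middle of the abundance distribution: abundant
#' enough to survive the sparse-taxon filter, but not so dominant that
#' their shared swings move the compositional denominator and induce
#' closure correlations across the whole matrix. Taxa are distinct
#' depth-5 leaves, so no parent-child relations exist among rows.
#'
#' @param n_taxa,n_samples Matrix dimensions.
#' @param coupled_pairs Number of planted pairs.
#' @param effect Latent factor scale on the log-abundance (default 2,
#'   a strongly coupled pair: the shared factor carries ~94% of the
#'   log-abundance variance before compositional closure).
#' @param n_reads_per_sample Sequencing depth per sample.
#' @param noise_sd Independent lognormal noise sd (default 0.5).
#' @param n_omz Number of trailing samples labelled OMZ (default 0).
#' @param seed RNG seed.
#' @return List: `matrix` (a [taxon_matrix()]) and `truth` (tibble of
#'   planted `taxon_a`, `taxon_b`).
#' @export
make_coupled_matrix <- function(n_taxa = 100L, n_samples = 15L,
                                coupled_pairs = 5L, effect = 2,
                                n_reads_per_sample = 20000L,
                                noise_sd = 0.5, n_omz = 0L, seed = 1L) {
  stopifnot(n_samples >= 6, 2L * coupled_pairs <= n_taxa)
  with_seed(seed, {
    lin <- sprintf(
      "%s; Phy%03d; Cls%03d; Ord%03d; Fam%03d",
      sample(c("Bacteria", "Archaea", "Eukaryota", "Viruses"), n_taxa,
             replace = TRUE),
      seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa)
    )
    mu <- stats::rnorm(n_taxa, 0, 1)
    qs <- stats::quantile(mu, c(0.35, 0.75))
    eligible <- which(mu >= qs[1] & mu <= qs[2])
    members <- sample(eligible, 2L * coupled_pairs)
    pair_a <- members[seq_len(coupled_pairs)]
    pair_b <- members[coupled_pairs + seq_len(coupled_pairs)]
    loglam <- matrix(mu, n_taxa, n_samples) +
      matrix(stats::rnorm(n_taxa * n_samples, 0, noise_sd), n_taxa)
    if (effect > 0 && coupled_pairs > 0) {
      z <- matrix(stats::rnorm(coupled_pairs * n_samples), coupled_pairs)
      loglam[pair_a, ] <- loglam[pair_a, ] + effect * z
      loglam[pair_b, ] <- loglam[pair_b, ] + effect * z
    }
    lam <- exp(loglam)
    rel <- sweep(lam, 2, colSums(lam), "/")
    counts <- matrix(
      stats::rpois(n_taxa * n_samples, rel * n_reads_per_sample),
      n_taxa, n_samples,
      dimnames = list(lin, sprintf("S%02d", seq_len(n_samples)))
    )
    zones <- rep("SRF", n_samples)
    if (n_omz > 0) zones[n_samples - seq_len(n_omz) + 1L] <- "OMZ"
    tmx <- taxon_matrix(counts, tibble(sample_id = colnames(counts),
                                       total_reads = colSums(counts),
                                       depth_zone = zones))
    list(matrix = tmx,
         truth = tibble(taxon_a = pmin(lin[pair_a], lin[pair_b]),
                        taxon_b = pmax(lin[pair_a], lin[pair_b])))
  })
}

#' Plant virus-to-cell gene transfers in a synthetic protein universe
#'
#' Builds a viral proteome and a cellular database in which
#' `n_transfers` cellular proteins are recent near-verbatim copies of
#' viral peptides (the planted transfers), alongside decoy cellular
#' families that are homologous across different 3-level taxonomic
#' groups (their reciprocal best hits are cellular) and viral peptides
#' with no cellular homolog.
#'
#' @param seed RNG seed.
#' @param n_transfers Planted transfers (default 5).
#' @param n_decoy_families Cross-group homologous cellular families
#'   (default 10).
#' @param n_viral_only Viral peptides without cellular homologs.
#' @param protein_len Protein length (default 80).
#' @param transfer_divergence Divergence of the transferred copy
#'   (default 0.02).
#' @return List: `viral_db`, `cellular_db`, `truth` (tibble
#'   `viral_peptide_id`, `cellular_protein_id`).
#' @export
simulate_hgt <- function(seed = 1L, n_transfers = 5L,
                         n_decoy_families = 10L, n_viral_only = 5L,
                         protein_len = 80L, transfer_divergence = 0.02) {
  with_seed(seed, {
    cell_groups <- c("Bacteria; Proteobacteria; Gammaproteobacteria",
                     "Bacteria; Cyanobacteria; Chroococcales",
                     "Eukaryota; stramenopiles; Oomycetes",
                     "Eukaryota; stramenopiles; Bacillariophyta",
                     "Archaea; Euryarchaeota; Thermococci")
    viral_lineage <- "Viruses; dsDNA viruses, no RNA stage; Mimiviridae"
    vi <- 0L; ci <- 0L
    viral <- list(); cellular <- list()
    truth <- list()
    add_viral <- function(seq) {
      vi <<- vi + 1L
      id <- sprintf("VIR%03d", vi)
      viral[[vi]] <<- tibble(protein_id = id, seq = seq,
                             lineage = viral_lineage,
                             source_group = "viral")
      id
    }
    add_cell <- function(seq, grp) {
      ci <<- ci + 1L
      id <- sprintf("CEL%03d", ci)
      cellular[[ci]] <<- tibble(
        protein_id = id, seq = seq,
        lineage = paste0(grp, "; Gen", ci),
        source_group = "cellular"
      )
      id
    }
    for (t in seq_len(n_transfers)) {
      donor <- random_aa(1, protein_len)
      vid <- add_viral(donor)
      cid <- add_cell(
        mutate_seq(donor, rate = transfer_divergence,
                   alphabet = aa_alphabet()),
        cell_groups[(t - 1L) %% length(cell_groups) + 1L]
      )
      truth[[t]] <- tibble(viral_peptide_id = vid,
                           cellular_protein_id = cid)
    }
    for (d in seq_len(n_decoy_families)) {
      anc <- random_aa(1, protein_len)
      grps <- sample(cell_groups, 2)
      add_cell(mutate_seq(anc, rate = 0.05, alphabet = aa_alphabet()),
               grps[1])
      add_cell(mutate_seq(anc, rate = 0.05, alphabet = aa_alphabet()),
               grps[2])
      # a distant viral relative of the same family: close enough to
      # find the cellular copies, never closer than they are to each other
      add_viral(mutate_seq(anc, rate = 0.3, alphabet = aa_alphabet()))
    }
    for (v in seq_len(n_viral_only)) add_viral(random_aa(1, protein_len))
    list(viral_db = reference_db(bind_rows(viral)),
         cellular_db = reference_db(bind_rows(cellular)),
         truth = bind_rows(truth))
  })
}
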