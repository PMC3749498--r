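test_that("generators are pure functions of parameters and seed", {
  expect_identical(make_taxonomy(5, 4, 2), make_taxonomy(5, 4, 2))
  expect_false(identical(make_taxonomy(5, 4, 2)$lineage,
                         make_taxonomy(6, 4, 2)$lineage))
  pf <- make_marker_profiles(seed = 5)
  expect_identical(pf, make_marker_profiles(seed = 5))
  tx <- make_taxonomy(5, 4, 2)
  expect_identical(make_reference_db(tx, seed = 6),
                   make_reference_db(tx, seed = 6))
  cm <- sim_community(tx, pf, seed = 7)
  s1 <- simulate_sample(cm, n_reads = 500, seed = 8)
  s2 <- simulate_sample(cm, n_reads = 500, seed = 8)
  expect_identical(s1$reads, s2$reads)
  expect_identical(make_coupled_matrix(seed = 9)$matrix$counts,
                   make_coupled_matrix(seed = 9)$matrix$counts)
})

test_that("taxonomy shape follows depth and branching", {
  tx <- make_taxonomy(10, depth = 5, branching = 3)
  for (dom in c("Bacteria", "Archaea", "Eukaryota")) {
    expect_equal(sum(tx$is_leaf & tx$domain == dom), 3^4)
  }
  expect_equal(sum(tx$is_leaf & tx$domain == "Viruses"), 3^4)
  expect_false(any(duplicated(tx$lineage)))
  # NCLDV families sit under the dsDNA node
  fams <- tx$lineage[tx$depth == 3 & startsWith(
    tx$lineage, "Viruses; dsDNA viruses, no RNA stage")]
  expect_true(any(grepl("Mimiviridae|Phycodnaviridae", fams)))
})

test_that("the reference db carries markers once per leaf with full truth", {
  tx <- make_taxonomy(11, depth = 4, branching = 2)
  pf <- make_marker_profiles(n_ncldv = 2, n_cellular = 2, seed = 12)
  ref <- make_reference_db(tx, n_proteins_per_leaf = 1, profiles = pf,
                           seed = 13)
  expect_equal(nrow(ref$db), nrow(ref$truth))
  per_leaf <- dplyr::count(ref$truth[ref$truth$is_marker, ],
                           lineage, marker_name)
  expect_true(all(per_leaf$n == 1L))
  # sibling leaves share ~80% identity proteins by construction
  sib <- ref$truth[!ref$truth$is_marker, ]
  leaves <- dplyr::filter(tx, is_leaf)
  fam <- vapply(lineage_ranks(leaves$lineage),
                function(r) paste(r[-length(r)], collapse = "; "),
                character(1))
  pair <- leaves$lineage[fam == fam[1]][1:2]
  seqs <- ref$db$seq[match(
    sib$protein_id[match(pair, sib$lineage)], ref$db$protein_id)]
  ident <- ncldvscope:::.nw_identity(seqs[1], seqs[2])
  expect_gt(ident, 0.6)
  expect_lt(ident, 0.97)
})

test_that("communities respect the planted NCLDV fraction and single copies", {
  tx <- make_taxonomy(14, depth = 4, branching = 2)
  pf <- make_marker_profiles(seed = 15)
  cm <- sim_community(tx, pf, ncldv_fraction = 0.05, seed = 16)
  expect_equal(sum(cm$genomes$abundance), 1)
  ab_v <- sum(cm$genomes$abundance[cm$genomes$domain == "Viruses"])
  ab_p <- sum(cm$genomes$abundance[cm$genomes$domain != "Viruses"])
  expect_equal(ab_v / ab_p, 0.05, tolerance = 1e-12)
  # one copy of each applicable marker per genome, on the forward strand
  for (k in seq_len(nrow(cm$genomes))) {
    mk <- cm$genomes$markers[[k]]
    expect_false(any(duplicated(mk$marker)))
    grp <- if (cm$genomes$domain[k] == "Viruses") "ncldv" else "cellular"
    expect_setequal(mk$marker, pf$name[pf$group == grp])
  }
})

test_that("read sets carry exact provenance and duplicate flags", {
  tx <- make_taxonomy(17, depth = 4, branching = 2)
  pf <- make_marker_profiles(seed = 18)
  cm <- sim_community(tx, pf, seed = 19)
  s0 <- simulate_sample(cm, n_reads = 300, dup_rate = 0, seed = 20)
  expect_false(any(s0$truth$is_duplicate))
  expect_equal(nrow(s0$reads), 300L)
  expect_setequal(s0$truth$read_id, s0$reads$read_id)
  s <- simulate_sample(cm, n_reads = 300, dup_rate = 0.2, seed = 21)
  dups <- s$truth[s$truth$is_duplicate, ]
  expect_gt(nrow(dups), 30)
  # duplicates share the 5' start with their donor and stay >= 97% identical
  donor_seq <- s$reads$seq[match(dups$dup_of, s$reads$read_id)]
  dup_seq <- s$reads$seq[match(dups$read_id, s$reads$read_id)]
  expect_true(all(substr(donor_seq, 1, 5) == substr(dup_seq, 1, 5)))
  idents <- ncldvscope:::.nw_identity(dup_seq,
                                      substr(donor_seq, 1, nchar(dup_seq)))
  expect_true(all(idents >= 0.97))
  # empty request
  s_empty <- simulate_sample(cm, n_reads = 0, seed = 22)
  expect_equal(nrow(s_empty$reads), 0L)
})

test_that("coupled matrices plant detectable pairs and honour zones", {
  mm <- make_coupled_matrix(n_taxa = 30, n_samples = 12, coupled_pairs = 2,
                            n_omz = 2, seed = 23)
  expect_equal(dim(mm$matrix$counts), c(30L, 12L))
  expect_equal(sum(mm$matrix$samples$depth_zone == "OMZ"), 2L)
  expect_equal(nrow(mm$truth), 2L)
  expect_true(all(mm$truth$taxon_a %in% rownames(mm$matrix$counts)))
  # with a strong effect the planted pairs correlate strongly
  M <- normalized_matrix(mm$matrix)
  rho <- vapply(seq_len(2), function(k) {
    cor(M[mm$truth$taxon_a[k], ], M[mm$truth$taxon_b[k], ],
        method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0.5))
  # effect 0 plants nothing
  m0 <- make_coupled_matrix(n_taxa = 30, n_samples = 12, coupled_pairs = 0,
                            effect = 0, seed = 24)
  expect_equal(nrow(m0$truth), 0L)
})
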