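aa <- ncldvscope:::aa_alphabet()

db4 <- function() {
  # two congeneric eukaryote proteins (here identical-sequence orthologs,
  # so both are always at least as close to the B1 fragment as the read),
  # one bacterium, one NCLDV
  withr::with_seed(21, {
    euk <- random_protein(1, 60)
    reference_db(tibble::tibble(
      protein_id = c("euk1", "euk2", "bac1", "vir1"),
      seq = c(euk, euk, random_protein(1, 60), random_protein(1, 60)),
      lineage = c("Eukaryota; stramenopiles; Oomycetes; Phytophthora",
                  "Eukaryota; stramenopiles; Oomycetes; Pythium",
                  "Bacteria; Cyanobacteria",
                  "Viruses; dsDNA viruses, no RNA stage; Mimiviridae")
    ))
  })
}

back_translate_read <- function(protein, seed = 1, pad = 15) {
  withr::with_seed(seed, {
    paste0(random_dna(1, pad), ncldvscope:::reverse_translate(protein),
           random_dna(1, pad))
  })
}

test_that("an exact back-translation is assigned its source lineage", {
  db <- db4()[3, ]
  read <- tibble::tibble(read_id = "r1", seq = back_translate_read(db$seq[1]))
  a <- assign_2blca(read, db)
  expect_equal(a$status, "assigned")
  expect_equal(a$lineage, "Bacteria; Cyanobacteria")
  expect_equal(a$support_size, 1L)
  expect_equal(a$support_ids[[1]], "bac1")
})

test_that("congeneric support reduces to the common prefix", {
  db <- db4()
  read <- tibble::tibble(read_id = "r1",
                         seq = back_translate_read(db$seq[1], seed = 2))
  a <- assign_2blca(read, db)
  expect_equal(a$status, "assigned")
  expect_true(all(c("euk1", "euk2") %in% a$support_ids[[1]]))
  expect_equal(a$lineage, "Eukaryota; stramenopiles; Oomycetes")
})

test_that("length gate, no-hit and the B1-best-in-H invariant hold", {
  db <- db4()
  reads <- tibble::tibble(
    read_id = c("short", "junk", "hit"),
    seq = c(random_dna(1, 99),
            strrep("ACAC", 40),
            back_translate_read(db$seq[4], seed = 3))
  )
  a <- assign_2blca(reads, db)
  expect_equal(a$status[a$read_id == "short"], "too_short")
  expect_equal(a$status[a$read_id == "junk"], "no_hit")
  expect_equal(a$support_size[a$read_id == "junk"], 0L)
  expect_equal(a$status[a$read_id == "hit"], "assigned")
  # B1 best subject is always in H
  expect_true("vir1" %in% a$support_ids[[which(a$read_id == "hit")]])
})

test_that("a 101 bp boundary read is annotated, a 100 bp one is not", {
  db <- db4()[3, ]
  withr::with_seed(9, nt <- ncldvscope:::reverse_translate(db$seq[1]))
  reads <- tibble::tibble(read_id = c("len100", "len101"),
                          seq = c(substr(nt, 1, 100),
                                  substr(nt, 1, 101)))
  a <- assign_2blca(reads, db)
  expect_equal(a$status[a$read_id == "len100"], "too_short")
  expect_equal(a$status[a$read_id == "len101"], "assigned")
})

test_that("cross-domain support flags reads as ambiguous", {
  withr::with_seed(22, {
    shared <- random_protein(1, 60)
    db <- reference_db(tibble::tibble(
      protein_id = c("b", "v"),
      seq = c(shared, shared),
      lineage = c("Bacteria; Proteobacteria",
                  "Viruses; dsDNA viruses, no RNA stage; Mimiviridae")
    ))
  })
  read <- tibble::tibble(read_id = "r", seq = back_translate_read(db$seq[1],
                                                                  seed = 4))
  a <- assign_2blca(read, db)
  expect_equal(a$status, "ambiguous")
  expect_equal(a$lineage, "")
  expect_equal(a$support_size, 2L)
})

test_that("adding a homolog never sharpens an assignment", {
  db <- db4()
  read <- tibble::tibble(read_id = "r",
                         seq = back_translate_read(db$seq[1], seed = 5))
  before <- assign_2blca(read, db[c(1, 3, 4), ]) # euk1 alone
  after <- assign_2blca(read, db)                # euk2 added
  expect_equal(before$support_ids[[1]], "euk1")
  expect_true(is_ancestor(after$lineage, before$lineage))
})

test_that("assignments stay on the true branch under point mutations", {
  tx <- make_taxonomy(41, depth = 4, branching = 2)
  ref <- make_reference_db(tx, n_proteins_per_leaf = 1, seed = 42,
                           protein_len = 60)
  db <- ref$db
  withr::with_seed(43, {
    picks <- sample(nrow(db), 30, replace = TRUE)
    reads <- tibble::tibble(
      read_id = sprintf("r%02d", seq_along(picks)),
      seq = vapply(picks, function(i) {
        mut <- ncldvscope:::mutate_seq(db$seq[i], rate = 0.05, alphabet = aa)
        paste0(random_dna(1, 12), ncldvscope:::reverse_translate(mut),
               random_dna(1, 12))
      }, character(1))
    )
  })
  a <- assign_2blca(reads, db)
  assigned <- a$status == "assigned"
  expect_true(mean(assigned) > 0.8)
  onbranch <- mapply(function(lin, i) is_ancestor(lin, db$lineage[i]),
                     a$lineage[assigned], picks[assigned])
  expect_gte(mean(onbranch), 0.95)
})

test_that("bins follow the NCLDV family list and cellular domains", {
  a <- tibble::tibble(
    read_id = as.character(1:5),
    status = c("assigned", "assigned", "ambiguous", "no_hit", "assigned"),
    lineage = c("Viruses; dsDNA viruses, no RNA stage; Mimiviridae",
                "Bacteria; Cyanobacteria",
                "Viruses; dsDNA viruses, no RNA stage; Mimiviridae",
                NA, "Viruses; Caudovirales; Myoviridae")
  )
  expect_message(b <- classify_bin(a), "outside")
  expect_equal(b$bin, c("NCLDV", "Bacteria", "ambiguous", "no_hit", NA))
  # Megaviridae label is accepted as a family synonym
  b2 <- classify_bin(tibble::tibble(
    read_id = "x", status = "assigned",
    lineage = "Viruses; dsDNA viruses, no RNA stage; Megaviridae; Megavirus"
  ))
  expect_equal(b2$bin, "NCLDV")
})
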