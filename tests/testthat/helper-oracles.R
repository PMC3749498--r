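# Independent oracles: small, slow, literal re-implementations used to
# check the package's fast paths. They share only the declared contracts
# (scoring matrix, gap costs, E-value formula), never code.

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Gotoh local alignment (affine gaps, gap of length g costs open + g*ext)
# with full traceback. Returns score, matches, alignment length, and the
# 1-based aligned ranges in a (query) and b (subject).
oracle_sw <- function(a, b, mat = oracle_blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  ptrM <- matrix(0L, n + 1, m + 1) # 1 from M, 2 from Ix, 3 from Iy
  ptrX <- matrix(0L, n + 1, m + 1) # 1 open (from M), 2 extend
  ptrY <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      ptrX[i + 1, j + 1] <- if (M[i, j + 1] - open - ext >=
                                Ix[i, j + 1] - ext) 1L else 2L
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      ptrY[i + 1, j + 1] <- if (M[i + 1, j] - open - ext >=
                                Iy[i + 1, j] - ext) 1L else 2L
      s <- mat[A[i], B[j]]
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      k <- which.max(cand)
      val <- cand[k] + s
      if (val <= 0) {
        M[i + 1, j + 1] <- 0
        ptrM[i + 1, j + 1] <- 0L
      } else {
        M[i + 1, j + 1] <- val
        # a diagonal step from a zero M cell is a fresh alignment start
        ptrM[i + 1, j + 1] <- if (k == 1L && M[i, j] == 0) 0L else k
      }
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, matches = 0L, aln_len = 0L,
                q_range = c(0L, 0L), s_range = c(0L, 0L),
                s_aligned = ""))
  }
  # traceback: state is the matrix the current cell's value lives in;
  # ptrM == 0 marks the start of the local alignment
  i <- bi; j <- bj; state <- 1L
  matches <- 0L; cols <- 0L
  qi <- integer(); sj <- integer()
  repeat {
    if (state == 1L) {
      cols <- cols + 1L
      if (A[i] == B[j]) matches <- matches + 1L
      qi <- c(i, qi); sj <- c(j, sj)
      from <- ptrM[i + 1, j + 1]
      i <- i - 1L; j <- j - 1L
      if (from == 0L) break
      state <- from
    } else if (state == 2L) {
      cols <- cols + 1L
      qi <- c(i, qi)
      from <- ptrX[i + 1, j + 1]
      i <- i - 1L
      state <- if (from == 1L) 1L else 2L
    } else {
      cols <- cols + 1L
      sj <- c(j, sj)
      from <- ptrY[i + 1, j + 1]
      j <- j - 1L
      state <- if (from == 1L) 1L else 2L
    }
  }
  list(score = best, matches = matches, aln_len = cols,
       q_range = range(qi), s_range = range(sj),
       s_aligned = paste(B[sj[1]:sj[length(sj)]], collapse = ""))
}

oracle_evalue <- function(score, m, n, lambda = 0.3176, k = 0.134) {
  k * m * n * exp(-lambda * score)
}

# brute-force protein search: align query against every db protein,
# keep hits passing max_evalue, sort by E then subject id
oracle_search <- function(query, db, max_evalue = 1e-5,
                          db_letters = sum(nchar(db$seq))) {
  rows <- lapply(seq_len(nrow(db)), function(i) {
    al <- oracle_sw(query, db$seq[i])
    if (al$score <= 0) return(NULL)
    ev <- oracle_evalue(al$score, nchar(query), db_letters)
    if (ev > max_evalue) return(NULL)
    tibble::tibble(subject_id = db$protein_id[i], score = al$score,
                   e_value = ev, s_start = al$s_range[1],
                   s_end = al$s_range[2], s_aligned = al$s_aligned)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, e_value, subject_id)
}

# naive six-frame translation oracle (standard code, N -> X), maximal
# stop-free stretches of at least min_len residues
oracle_codon <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), names(gc))
})

oracle_translate_frame <- function(seq, offset) {
  s <- substr(seq, offset + 1, nchar(seq))
  ncod <- nchar(s) %/% 3
  if (ncod == 0) return("")
  out <- character(ncod)
  for (k in seq_len(ncod)) {
    codon <- substr(s, 3 * k - 2, 3 * k)
    out[k] <- if (grepl("N", codon)) {
      hits <- unique(oracle_codon[vapply(c("A", "C", "G", "T"),
        function(nt) gsub("N", nt, codon), character(1))])
      if (length(hits) == 1) hits else "X"
    } else oracle_codon[[codon]]
  }
  paste(out, collapse = "")
}

oracle_six_frame <- function(seq, min_len = 20) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  peps <- character()
  for (f in 0:2) {
    for (s in c(seq, rc)) {
      aa <- oracle_translate_frame(s, f)
      for (part in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        if (nchar(part) >= min_len) peps <- c(peps, part)
      }
    }
  }
  sort(peps)
}

# all-pairs duplicate clustering oracle: greedy over reads sorted by
# descending length then id, identity from Biostrings global alignment
oracle_dedup <- function(ids, seqs, prefix_len = 5, min_identity = 0.97) {
  ord <- order(-nchar(seqs), ids)
  exemplars <- integer()
  assign_to <- setNames(ids, ids)
  for (i in ord) {
    placed <- FALSE
    if (nchar(seqs[i]) >= prefix_len) {
      for (e in exemplars) {
        if (substr(seqs[i], 1, prefix_len) !=
            substr(seqs[e], 1, prefix_len)) next
        ref <- substr(seqs[e], 1, nchar(seqs[i]))
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(seqs[i]), Biostrings::DNAString(ref),
          type = "global",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1),
          gapOpening = 0, gapExtension = 2
        )
        ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
        if (ident >= min_identity) {
          assign_to[ids[i]] <- ids[e]
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) exemplars <- c(exemplars, i)
  }
  assign_to
}

# literal 2bLCA oracle built on oracle_search
oracle_2blca <- function(read, db, b1_max = 1e-5, min_len = 100,
                         min_len_aa = 20) {
  if (nchar(read) <= min_len) return(list(status = "too_short"))
  peps <- oracle_six_frame(read, min_len_aa)
  b1 <- dplyr::bind_rows(lapply(peps, function(p) {
    h <- oracle_search(p, db, b1_max)
    if (nrow(h) > 0) h$m <- nchar(p)
    h
  }))
  if (nrow(b1) == 0) return(list(status = "no_hit"))
  b1 <- dplyr::arrange(b1, e_value, subject_id)
  hstar <- b1[1, ]
  b2 <- oracle_search(hstar$s_aligned, db, max_evalue = hstar$e_value)
  H <- sort(unique(c(b2$subject_id, hstar$subject_id)))
  lins <- db$lineage[match(H, db$protein_id)]
  doms <- unique(vapply(strsplit(lins, ";"), function(x) trimws(x[1]),
                        character(1)))
  list(
    status = if (length(doms) > 1) "ambiguous" else "assigned",
    lineage = ncldvscope::lca(lins),
    H = H,
    b1_e = hstar$e_value
  )
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

random_protein <- function(n, len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

canonical_pairs <- function(d) {
  dplyr::mutate(d, a = pmin(.data$taxon_a, .data$taxon_b),
                b = pmax(.data$taxon_a, .data$taxon_b))
}
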