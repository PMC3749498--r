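toy_tm <- function(rows, samples = NULL) {
  counts <- do.call(rbind, rows)
  rownames(counts) <- names(rows)
  if (is.null(samples)) {
    # unit totals: the normalised view equals the input rows, so rank
    # properties can be asserted on the profiles as given
    samples <- tibble::tibble(sample_id = paste0("s", seq_len(ncol(counts))),
                              total_reads = 1)
  }
  taxon_matrix(counts, samples)
}

test_that("Spearman edges are rank-based with the asymptotic t p-value", {
  x <- 1:8
  tm <- toy_tm(list("Bacteria; A" = x, "Bacteria; B" = round(exp(x)),
                    "Bacteria; C" = rev(x)))
  e <- spearman_edges(tm)
  ab <- e[e$taxon_a == "Bacteria; A" & e$taxon_b == "Bacteria; B", ]
  expect_equal(ab$rho, 1)
  expect_equal(ab$p_value, 0)
  ac <- e[e$taxon_a == "Bacteria; A" & e$taxon_b == "Bacteria; C", ]
  expect_equal(ac$rho, -1)
  # p matches cor.test's asymptotic approximation on noisy data
  withr::with_seed(71, {
    y1 <- rnorm(12); y2 <- rnorm(12)
  })
  tm2 <- toy_tm(list("Bacteria; A" = abs(y1) * 100,
                     "Bacteria; B" = abs(y2) * 100))
  e2 <- spearman_edges(tm2)
  ct <- suppressWarnings(cor.test(rank(normalized_matrix(tm2)[1, ]),
                                  rank(normalized_matrix(tm2)[2, ])))
  expect_equal(e2$p_value, ct$p.value, tolerance = 1e-10)
  # constant rows are skipped with a message
  tm3 <- toy_tm(list("Bacteria; A" = rep(5, 8), "Bacteria; B" = x,
                     "Bacteria; C" = rev(x)),
                samples = tibble::tibble(sample_id = paste0("s", 1:8),
                                         total_reads = 100))
  expect_message(e3 <- spearman_edges(tm3), "constant")
  expect_equal(nrow(e3), 1L)
})

test_that("tail-area q-values behave at the limits and control FDR", {
  expect_equal(tail_area_qvalues(rep(1, 20)), rep(1, 20))
  expect_equal(tail_area_qvalues(numeric()), numeric())
  # one real signal among uniform noise gets a small q
  withr::with_seed(72, p <- c(1e-8, runif(999)))
  q <- tail_area_qvalues(p)
  expect_lt(q[1], 0.05)
  expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p
  # Monte-Carlo FDR: 10% strong alternatives among 5000 p-values
  withr::with_seed(73, {
    p0 <- runif(4500)
    p1 <- rbeta(500, 0.05, 1)
    pv <- c(p1, p0)
    truth <- rep(c(TRUE, FALSE), c(500, 4500))
  })
  qv <- tail_area_qvalues(pv)
  called <- qv < 0.05
  expect_gt(sum(called), 100)
  expect_lte(mean(!truth[called]), 0.08)
})

test_that("the symmetrised KL score matches its closed form", {
  expect_equal(kl_score(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0.2, 0.8, 0, 0); b <- c(0, 0, 0.5, 0.5)
  expect_equal(kl_score(a, b), kl_score(b, a))
  # direct evaluation of the formula with the documented pseudocount
  eps <- 1e-9
  p <- (a + eps) / sum(a + eps); q <- (b + eps) / sum(b + eps)
  want <- 0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
  expect_equal(kl_score(a, b), want)
  expect_gt(want, 0)
})

test_that("ReBoot is seed-reproducible and detects a perfect association", {
  withr::with_seed(74, {
    rows <- lapply(1:6, function(i) rpois(15, 60))
  })
  names(rows) <- sprintf("Bacteria; T%02d", 1:6)
  rows[["Bacteria; T02"]] <- rows[["Bacteria; T01"]] # duplicated profile
  tm <- toy_tm(rows)
  r1 <- reboot_edge(tm, "Bacteria; T01", "Bacteria; T02", "spearman",
                    n_perm = 200, n_boot = 200, seed = 75)
  r2 <- reboot_edge(tm, "Bacteria; T01", "Bacteria; T02", "spearman",
                    n_perm = 200, n_boot = 200, seed = 75)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.01)
  expect_equal(r1$score, 1)
  expect_true(r1$stable)
  r3 <- reboot_edge(tm, "Bacteria; T01", "Bacteria; T02", "spearman",
                    n_perm = 200, n_boot = 200, seed = 76)
  expect_false(identical(r3$p_value, r1$p_value))
})

test_that("degenerate constant rows give p = 1 with a message", {
  rows <- list("Bacteria; A" = rep(10, 8), "Bacteria; B" = rep(3, 8))
  tm <- toy_tm(rows, samples = tibble::tibble(sample_id = paste0("s", 1:8),
                                              total_reads = 50))
  expect_message(
    r <- reboot_edge(tm, "Bacteria; A", "Bacteria; B", "spearman",
                     n_perm = 50, n_boot = 50, seed = 1),
    "degenerate"
  )
  expect_equal(r$p_value, 1)
})

test_that("Brown's combination honours its limiting cases", {
  withr::with_seed(77, {
    p1 <- runif(300); p2 <- runif(300)
  })
  # independence limit: cov 0 reduces exactly to Fisher
  fisher <- pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
  expect_equal(combine_brown(p1, p2, cov_term = 0), fisher)
  expect_equal(combine_brown(1, 1, cov_term = 0), 1)
  # perfectly duplicated p-vectors: known cov 4 gives the single-test p
  expect_equal(combine_brown(p1, p1, cov_term = 4), p1, tolerance = 1e-12)
  # and the empirical covariance estimate lands close to that
  expect_equal(combine_brown(p1, p1), p1, tolerance = 0.05)
  expect_message(combine_brown(c(0, 0.5), c(0.1, 0.5)), "clipped")
})

test_that("method 2 excludes zones and parent-child pairs, reproducibly", {
  pm <- make_coupled_matrix(n_taxa = 20, n_samples = 12, coupled_pairs = 1,
                            n_omz = 2, seed = 78)
  tm <- pm$matrix
  # add an explicit parent-child pair of rows
  parent <- colSums(tm$counts[1:2, ])
  counts <- rbind(tm$counts, Bacteria = parent)
  tm2 <- taxon_matrix(counts, tm$samples)
  prm <- network_params(n_perm = 50, n_boot = 50, top_k = 30, seed = 79)
  net <- cooccurrence_method2(filter_taxon_matrix(tm2), prm)
  bad <- is_ancestor(net$taxon_a, net$taxon_b) |
    is_ancestor(net$taxon_b, net$taxon_a)
  expect_false(any(bad))
  net_again <- cooccurrence_method2(filter_taxon_matrix(tm2), prm)
  expect_identical(net, net_again)
  # OMZ exclusion: correlations are computed on 10 samples, so an
  # all-samples rho computed on 12 differs in general
  expect_true(all(c("rho2", "kl", "p2_rho", "p2_kl", "p_combined",
                    "q2", "method2_pass") %in% names(net)))
  tiny <- taxon_matrix(tm2$counts[, 1:2],
                       tm2$samples[1:2, ])
  expect_error(cooccurrence_method2(tiny, prm), "fewer than 3")
})

test_that("method-2 q-values keep the null discovery count near nominal", {
  # wide-candidate regime: every scored pair is evaluated, so BH over
  # the evaluated family is the usual correction
  nn <- make_coupled_matrix(n_taxa = 16, n_samples = 12, coupled_pairs = 0,
                            effect = 0, seed = 80)
  net <- cooccurrence_method2(filter_taxon_matrix(nn$matrix),
                              network_params(n_perm = 100, n_boot = 100,
                                             top_k = 1000, seed = 81))
  expect_lte(sum(net$method2_pass), ceiling(0.05 * nrow(net)) + 2)
})

test_that("method 1 flags pass |rho| and q thresholds jointly", {
  pm <- make_coupled_matrix(n_taxa = 25, n_samples = 14, coupled_pairs = 2,
                            seed = 82)
  net <- cooccurrence_method1(filter_taxon_matrix(pm$matrix))
  expect_true(all(abs(net$rho[net$method1_pass]) > 0.7))
  expect_true(all(net$q[net$method1_pass] < 0.05))
  expect_true(all(net$q >= net$p_value * 0 )) # q well-defined
  planted <- canonical_pairs(net) |>
    dplyr::inner_join(canonical_pairs(pm$truth), by = c("a", "b"))
  expect_gte(nrow(planted), 1L)
})

test_that("the full network object merges methods and supports broom verbs", {
  pm <- make_coupled_matrix(n_taxa = 15, n_samples = 12, coupled_pairs = 1,
                            seed = 83)
  net <- cooccurrence_network(pm$matrix, method = "both",
                              params = network_params(n_perm = 50,
                                                      n_boot = 50,
                                                      top_k = 20,
                                                      seed = 84))
  expect_s3_class(net, "cooccurrence_network")
  td <- tidy(net)
  expect_true(all(c("rho", "q", "method1_pass") %in% names(td)))
  g <- glance(net)
  expect_equal(g$n_samples, 12L)
  expect_s3_class(autoplot(net), "ggplot")
})
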