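#' Tuning parameters for the co-occurrence network
#'
#' Defaults follow the published analysis: taxa with fewer than 5 total
#' reads are dropped, taxonomy is cut at the fifth level from the root,
#' method 1 reports `|rho| > 0.7 & q < 0.05`, method 2 excludes the OMZ
#' samples, evaluates the 1000 top- and bottom-ranking edges per measure
#' with 1000 permutation-renormalization rounds and 1000 column
#' bootstraps, and reports `q' < 0.05`.
#'
#' @param min_total_reads,depth,rho_min,q_max,n_perm,n_boot,top_k,
#'   exclude_zones,seed See description.
#' @return A `network_params` list.
#' @export
network_params <- function(min_total_reads = 5L, depth = 5L, rho_min = 0.7,
                           q_max = 0.05, n_perm = 1000L, n_boot = 1000L,
                           top_k = 1000L, exclude_zones = "OMZ",
                           seed = NULL) {
  stopifnot(min_total_reads >= 0, depth >= 1, rho_min > 0, q_max > 0,
            n_perm >= 2, n_boot >= 2, top_k >= 1)
  structure(list(min_total_reads = min_total_reads, depth = depth,
                 rho_min = rho_min, q_max = q_max, n_perm = n_perm,
                 n_boot = n_boot, top_k = top_k,
                 exclude_zones = exclude_zones, seed = seed),
            class = "network_params")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Spearman correlation for every taxon pair
#'
#' Rank correlation (average ranks for ties) between the normalised
#' abundance profiles of every unordered taxon pair, with the asymptotic
#' two-sided t-approximation p-value (`t = rho * sqrt((n-2)/(1-rho^2))`,
#' `df = n - 2`; `rho = +/-1` gives `p = 0`). Constant rows are skipped
#' with a message.
#'
#' @param tm A [taxon_matrix()] (at least 3 samples).
#' @return Tibble `taxon_a`, `taxon_b`, `rho`, `p_value`.
#' @export
spearman_edges <- function(tm) {
  M <- normalized_matrix(tm)
  n <- ncol(M)
  if (n < 3) abort("need at least 3 samples")
  const <- apply(M, 1, function(x) max(x) == min(x))
  if (any(const)) {
    inform(paste0(sum(const), " constant taxon row(s) skipped"))
    M <- M[!const, , drop = FALSE]
  }
  if (nrow(M) < 2) {
    return(tibble(taxon_a = character(), taxon_b = character(),
                  rho = numeric(), p_value = numeric()))
  }
  R <- stats::cor(t(M), method = "spearman")
  idx <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[idx]
  a <- rownames(M)[idx[, 1]]
  b <- rownames(M)[idx[, 2]]
  tibble(
    # canonical orientation: taxon_a sorts before taxon_b
    taxon_a = pmin(a, b),
    taxon_b = pmax(a, b),
    rho = rho,
    p_value = spearman_p(rho, n)
  )
}

spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  exact1 <- abs(rho) >= 1 - 1e-12
  p[exact1] <- 0
  t <- rho[!exact1] * sqrt((n - 2) / (1 - rho[!exact1]^2))
  p[!exact1] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Tail-area false discovery rate (q-values)
#'
#' Estimates the null proportion eta0 from the flat right tail of the
#' p-value distribution and returns tail-area FDR values
#' `q(p) = eta0 * p * m / rank(p)`, made monotone and clipped to [0, 1].
#'
#' @param p Numeric vector of p-values.
#' @param eta0 Null proportion; estimated from the data when `NULL`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
tail_area_qvalues <- function(p, eta0 = NULL) {
  if (length(p) == 0) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  m <- length(p)
  if (is.null(eta0)) {
    # density of p above 1/2 is eta0 under a uniform null component
    eta0 <- min(1, sum(p > 0.5, na.rm = TRUE) / (0.5 * m))
    if (eta0 == 0) eta0 <- 1 / m
  }
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, eta0 * p[o] * m / rank(p, ties.method = "max")[o])
  q <- cummin(q)
  q[order(o)]
}

#' Symmetrised Kullback-Leibler score between two abundance profiles
#'
#' Rows are rescaled to probability vectors over samples with a
#' pseudocount, then scored with `0.5 * (KL(a||b) + KL(b||a))` (natural
#' log). 0 for identical profiles; low scores rank as co-presence, high
#' as exclusion.
#'
#' @param a,b Non-negative numeric vectors over the same samples.
#' @param eps Pseudocount (default 1e-9).
#' @return Non-negative scalar.
#' @export
kl_score <- function(a, b, eps = 1e-9) {
  unname(kl_rows(rbind(a), rbind(b), eps)[1])
}

# row-wise symmetrised KL for matrices of profiles
kl_rows <- function(A, B, eps = 1e-9) {
  P <- (A + eps) / rowSums(A + eps)
  Q <- (B + eps) / rowSums(B + eps)
  0.5 * (rowSums(P * log(P / Q)) + rowSums(Q * log(Q / P)))
}

# row-wise Spearman for two matrices of profiles (rows are replicates)
spearman_rows <- function(A, B) {
  RA <- t(apply(A, 1, rank))
  RB <- t(apply(B, 1, rank))
  RA <- RA - rowMeans(RA)
  RB <- RB - rowMeans(RB)
  den <- sqrt(rowSums(RA^2) * rowSums(RB^2))
  out <- rowSums(RA * RB) / den
  out[den == 0] <- NA_real_
  out
}

edge_measure <- function(A, B, measure, eps = 1e-9) {
  if (measure == "spearman") spearman_rows(A, B) else kl_rows(A, B, eps)
}

#' Permutation-renormalization (ReBoot) p-value for one edge
#'
#' The null distribution permutes the edge's two rows independently
#' across samples while the rest of the matrix is unchanged, then
#' restores the compositional bias by renormalising every column to its
#' original sum before recomputing the measure; the bootstrap resamples
#' matrix columns with replacement. The p-value is the two-sided normal
#' tail of the observed score's z-score against the permuted null
#' (continuous, so downstream combination and ranking are not floored
#' by the permutation count); the bootstrap distribution is reported as
#' a confidence interval and a stability flag (interval excludes the
#' null mean).
#'
#' @param tm A [taxon_matrix()].
#' @param taxon_a,taxon_b Row lineages of the edge.
#' @param measure `"spearman"` or `"kl"`.
#' @param n_perm,n_boot Replicate counts.
#' @param seed RNG seed (same seed, same p-value).
#' @param conf_level Bootstrap interval coverage (default 0.95).
#' @return One-row tibble: `taxon_a`, `taxon_b`, `measure`, `score`,
#'   `mean_null`, `sd_null`, `z`, `mean_boot`, `ci_lo`, `ci_hi`,
#'   `stable`, `p_value`.
#' @export
reboot_edge <- function(tm, taxon_a, taxon_b, measure = c("spearman", "kl"),
                        n_perm = 1000L, n_boot = 1000L, seed = NULL,
                        conf_level = 0.95) {
  measure <- match.arg(measure)
  edges <- tibble(taxon_a = taxon_a, taxon_b = taxon_b)
  with_seed(seed,
            reboot_edges(tm, edges, measure, n_perm, n_boot, conf_level))
}

reboot_edges <- function(tm, edges, measure, n_perm, n_boot,
                         conf_level = 0.95) {
  M <- normalized_matrix(tm)
  S <- ncol(M)
  m_col <- colSums(M)
  alpha <- (1 - conf_level) / 2
  out <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- match(edges$taxon_a[e], rownames(M))
    j <- match(edges$taxon_b[e], rownames(M))
    if (is.na(i) || is.na(j)) abort("edge taxa not found in matrix")
    ai <- M[i, ]; aj <- M[j, ]
    s_obs <- unname(edge_measure(rbind(ai), rbind(aj), measure))
    # --- permutation-renormalization null ---
    P1 <- t(matrix(ai[replicate(n_perm, sample.int(S))], nrow = S))
    P2 <- t(matrix(aj[replicate(n_perm, sample.int(S))], nrow = S))
    base <- rep(m_col - ai - aj, each = n_perm)
    newsum <- base + P1 + P2
    f <- rep(m_col, each = n_perm) / newsum
    # renormalised columns sum back to the original column sums
    stopifnot(max(abs(newsum * f - rep(m_col, each = n_perm))) < 1e-9)
    null <- edge_measure(P1 * f, P2 * f, measure)
    # --- column bootstrap ---
    idx <- matrix(sample.int(S, S * n_boot, replace = TRUE), nrow = n_boot)
    B1 <- matrix(ai[idx], nrow = n_boot)
    B2 <- matrix(aj[idx], nrow = n_boot)
    boot <- edge_measure(B1, B2, measure)
    null <- null[is.finite(null)]
    mean_null <- mean(null)
    sd_null <- sd(null)
    if (length(null) < 2 || sd_null == 0 || !is.finite(s_obs)) {
      inform(paste0("degenerate null for edge ", edges$taxon_a[e], " ~ ",
                    edges$taxon_b[e], "; p set to 1"))
      p <- 1
      z <- NA_real_
    } else {
      z <- (s_obs - mean_null) / sd_null
      p <- 2 * stats::pnorm(-abs(z))
    }
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    out[[e]] <- tibble(
      taxon_a = edges$taxon_a[e], taxon_b = edges$taxon_b[e],
      measure = measure, score = s_obs, mean_null = mean_null,
      sd_null = sd_null, z = z, mean_boot = mean(boot, na.rm = TRUE),
      ci_lo = ci[1], ci_hi = ci[2],
      stable = mean_null < ci[1] | mean_null > ci[2],
      p_value = p
    )
  }
  bind_rows(out)
}

#' Combine two dependent p-values (Brown's method)
#'
#' Fisher's statistic `Psi = -2 (ln p1 + ln p2)` referred to a scaled
#' chi-square whose variance absorbs the dependence between the two
#' tests: `E[Psi] = 4`, `Var[Psi] = 8 + 2 cov`, with `cov` the covariance
#' of the `-2 ln p` variables estimated empirically across the candidate
#' edge set (clamped to [0, 4]). With `cov = 0` this reduces exactly to
#' Fisher's combination; with perfectly duplicated p-value vectors it
#' returns the single-test p-value.
#'
#' @param p1,p2 P-value vectors in (0, 1]; zeros are clipped to the
#'   smallest positive double.
#' @param cov_term Covariance of the `-2 ln p` pair; estimated from the
#'   vectors when `NULL`.
#' @return Vector of combined p-values.
#' @export
combine_brown <- function(p1, p2, cov_term = NULL) {
  stopifnot(length(p1) == length(p2))
  if (length(p1) == 0) return(numeric())
  clip <- function(p) {
    if (any(p <= 0, na.rm = TRUE)) {
      inform("p-value(s) of 0 clipped to the smallest positive double")
    }
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  p1 <- clip(p1); p2 <- clip(p2)
  x1 <- -2 * log(p1); x2 <- -2 * log(p2)
  if (is.null(cov_term)) {
    cov_term <- if (length(p1) >= 3) stats::cov(x1, x2) else 0
  }
  cov_term <- min(max(cov_term, 0), 4)
  v <- 8 + 2 * cov_term
  c_scale <- v / 8       # Var / (2 E), E = 4
  f <- 32 / v            # 2 E^2 / Var
  stats::pchisq((x1 + x2) / c_scale, df = f, lower.tail = FALSE)
}

# all non-parent-child unordered pairs get both measures
method2_scores <- function(tm) {
  M <- normalized_matrix(tm)
  edges <- spearman_edges(tm)
  keep <- !is_ancestor(edges$taxon_a, edges$taxon_b) &
    !is_ancestor(edges$taxon_b, edges$taxon_a)
  edges <- edges[keep, , drop = FALSE]
  edges$kl <- vapply(seq_len(nrow(edges)), function(e) {
    kl_score(M[edges$taxon_a[e], ], M[edges$taxon_b[e], ])
  }, numeric(1))
  rename(edges, rho2 = "rho", p2_asym = "p_value")
}

#' Stringent co-occurrence analysis (method 2)
#'
#' Excludes the configured depth zones, scores all non-parent-child
#' taxon pairs with Spearman's rho and the symmetrised Kullback-Leibler
#' measure, evaluates the top- and bottom-ranking edges of each measure
#' with the permutation-renormalization null and column bootstrap,
#' combines the two measure p-values with Brown's method and corrects
#' with Benjamini-Hochberg q'-values.
#'
#' @param tm A filtered, normalisable [taxon_matrix()].
#' @param params A [network_params()] object.
#' @return Tibble of evaluated edges: `taxon_a`, `taxon_b`, `rho2`, `kl`,
#'   `p2_rho`, `p2_kl`, `stable_rho`, `stable_kl`, `p_combined`, `q2`,
#'   `method2_pass`.
#' @export
cooccurrence_method2 <- function(tm, params = network_params()) {
  keep <- !(tm$samples$depth_zone %in% params$exclude_zones)
  if (sum(keep) < 3) abort("fewer than 3 samples remain after zone exclusion")
  tm2 <- taxon_matrix(tm$counts[, keep, drop = FALSE],
                      tm$samples[keep, , drop = FALSE])
  scores <- method2_scores(tm2)
  if (nrow(scores) == 0) {
    return(tibble(taxon_a = character(), taxon_b = character(),
                  rho2 = numeric(), kl = numeric(), p2_rho = numeric(),
                  p2_kl = numeric(), stable_rho = logical(),
                  stable_kl = logical(), p_combined = numeric(),
                  q2 = numeric(), method2_pass = logical()))
  }
  k <- min(params$top_k, nrow(scores))
  pick <- function(o) unique(c(utils::head(o, k), utils::tail(o, k)))
  sel <- sort(unique(c(
    pick(order(-scores$rho2)),   # top = strongest co-presence by rho
    pick(order(scores$kl))       # top = smallest divergence by KL
  )))
  cand <- scores[sel, , drop = FALSE]
  edges <- select(cand, "taxon_a", "taxon_b")
  res <- with_seed(params$seed, {
    r_rho <- reboot_edges(tm2, edges, "spearman", params$n_perm,
                          params$n_boot)
    r_kl <- reboot_edges(tm2, edges, "kl", params$n_perm, params$n_boot)
    list(rho = r_rho, kl = r_kl)
  })
  cand$p2_rho <- res$rho$p_value
  cand$p2_kl <- res$kl$p_value
  cand$stable_rho <- res$rho$stable
  cand$stable_kl <- res$kl$stable
  cand$p_combined <- combine_brown(cand$p2_rho, cand$p2_kl)
  # BH over the evaluated candidate set (the top/bottom lists are the
  # family that is "further evaluated" and corrected)
  cand$q2 <- stats::p.adjust(cand$p_combined, method = "BH")
  cand$method2_pass <- cand$q2 < params$q_max
  select(cand, -"p2_asym") |>
    arrange(.data$q2, .data$taxon_a, .data$taxon_b)
}

#' All-samples Spearman co-occurrence analysis (method 1)
#'
#' Spearman correlations over all samples with asymptotic p-values and
#' tail-area FDR q-values; associations pass at `|rho| > rho_min` and
#' `q < q_max`. Parent-child pairs are not excluded by this method.
#'
#' @param tm A filtered, normalisable [taxon_matrix()].
#' @param params A [network_params()] object.
#' @return Tibble `taxon_a`, `taxon_b`, `rho`, `p_value`, `q`,
#'   `method1_pass`.
#' @export
cooccurrence_method1 <- function(tm, params = network_params()) {
  edges <- spearman_edges(tm)
  edges$q <- tail_area_qvalues(edges$p_value)
  edges$method1_pass <- abs(edges$rho) > params$rho_min &
    edges$q < params$q_max
  arrange(edges, .data$q, .data$taxon_a, .data$taxon_b)
}

#' Full two-method taxon co-occurrence network
#'
#' Runs [cooccurrence_method1()] and/or [cooccurrence_method2()] on a
#' taxon matrix (filtered with [filter_taxon_matrix()] first if
#' requested parameters say so) and merges the edge statistics.
#'
#' @param tm A [taxon_matrix()].
#' @param method `"both"`, `"1"` or `"2"`.
#' @param params A [network_params()] object.
#' @param filter Apply the `min_total_reads` row filter first
#'   (default TRUE).
#' @return A `cooccurrence_network` object with elements `edges`
#'   (merged tibble), `params`, `n_taxa`, `n_samples`.
#' @export
cooccurrence_network <- function(tm, method = c("both", "1", "2"),
                                 params = network_params(), filter = TRUE) {
  method <- match.arg(method)
  if (filter) tm <- filter_taxon_matrix(tm, params$min_total_reads)
  e1 <- if (method %in% c("both", "1")) cooccurrence_method1(tm, params)
  e2 <- if (method %in% c("both", "2")) cooccurrence_method2(tm, params)
  edges <- if (is.null(e1)) e2
  else if (is.null(e2)) e1
  else dplyr::full_join(e1, e2, by = c("taxon_a", "taxon_b"))
  structure(
    list(edges = edges, params = params,
         n_taxa = nrow(tm$counts), n_samples = ncol(tm$counts)),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network: ", x$n_taxa, " taxa, ", x$n_samples,
      " samples, ", nrow(x$edges), " edges>\n", sep = "")
  if ("method1_pass" %in% names(x$edges)) {
    cat("  method 1 associations: ",
        sum(x$edges$method1_pass, na.rm = TRUE), "\n", sep = "")
  }
  if ("method2_pass" %in% names(x$edges)) {
    cat("  method 2 associations: ",
        sum(x$edges$method2_pass, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method
tidy.cooccurrence_network <- function(x, ...) as_tibble(x$edges)

#' @exportS3Method
glance.cooccurrence_network <- function(x, ...) {
  tibble(
    n_taxa = x$n_taxa, n_samples = x$n_samples, n_edges = nrow(x$edges),
    n_method1 = if ("method1_pass" %in% names(x$edges))
      sum(x$edges$method1_pass, na.rm = TRUE) else NA_integer_,
    n_method2 = if ("method2_pass" %in% names(x$edges))
      sum(x$edges$method2_pass, na.rm = TRUE) else NA_integer_
  )
}
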