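#' Pseudocount fold change
#'
#' `(mean_A + eps) / (mean_B + eps)`. The pseudocount keeps fold changes
#' finite and symmetric in fully OFF states:
#' `fold_change(a, b) * fold_change(b, a) == 1`.
#'
#' @param mean_a,mean_b non-negative mean expression in normalized units.
#' @param eps pseudocount in the same units (default 0.5).
#' @return fold change(s) > 0.
#' @export
fold_change <- function(mean_a, mean_b, eps = 0.5) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be non-negative")
  (mean_a + eps) / (mean_b + eps)
}

#' Two-sided Fisher exact test for a window contrast
#'
#' Exact two-sided p for the 2x2 table `[[win_a, rest_a], [win_b,
#' rest_b]]`, where `rest` is the library size minus the window count
#' (replicates pooled within each group). The two-sided p is the sum of
#' probabilities of all hypergeometric tables whose probability does not
#' exceed that of the observed table (ties admitted at relative tolerance
#' 1e-12). Any zero margin gives p = 1 by convention.
#'
#' @param win_a,rest_a,win_b,rest_b non-negative integer counts
#'   (vectorised; recycled to common length).
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
fisher_window_test <- function(win_a, rest_a, win_b, rest_b) {
  n <- max(length(win_a), length(rest_a), length(win_b), length(rest_b))
  a <- rep_len(win_a, n); b <- rep_len(rest_a, n)
  c_ <- rep_len(win_b, n); d <- rep_len(rest_b, n)
  if (any(c(a, b, c_, d) < 0)) stop("counts must be non-negative")
  vapply(seq_len(n), function(i)
    fisher_p_one(a[i], b[i], c_[i], d[i]), numeric(1))
}

fisher_p_one <- function(a, b, c_, d, rel_tol = 1e-12) {
  m <- a + c_   # first-column margin
  nn <- b + d   # second-column margin
  k <- a + b    # first-row margin
  if (m == 0 || nn == 0 || k == 0 || (c_ + d) == 0) return(1)
  lo <- max(0, k - nn); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, nn, k)
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + rel_tol)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH: sort ascending, `q_i = min_{j >= i} p_j * n / j`, capped at
#' 1, returned in the input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same length/order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Replicate-aware negative-binomial gene test
#'
#' Counts are normalized to a common depth (`count / (size /
#' mean(sizes))`; the matrix-level caller supplies median-of-ratios size
#' factors) and group means are compared on the log scale by a Wald
#' statistic with negative-binomial variance `mu + phi * mu^2`. The
#' per-gene dispersion is the pooled method-of-moments estimate,
#' moderated toward a shared `phi_prior` with `prior_df` pseudo-degrees
#' of freedom (the across-gene common dispersion, supplied by
#' [diff_gene_table()]); the statistic is referred to a Student-t
#' distribution with `n_A + n_B - 2 + prior_df` df, so stronger
#' moderation moves the reference toward normal while an unmoderated
#' call keeps the heavy-tailed small-sample reference. As `phi -> 0`
#' the test tends to its Poisson-variance analogue.
#'
#' @param counts_a,counts_b integer replicate counts per group.
#' @param sizes_a,sizes_b library sizes or size factors per replicate
#'   (any common scale).
#' @param eps pseudocount on normalized means for the fold change and log
#'   ratio (default 0.5).
#' @param phi_floor dispersion floor (default 1e-8).
#' @param phi_prior optional shared dispersion to moderate toward; also
#'   the fallback when `n_A + n_B - 2 < 1` (single replicates).
#' @param prior_df weight of `phi_prior` in pseudo-df (default 20 when a
#'   prior is given).
#' @return list with `fc` (pseudocount fold change of normalized means,
#'   A over B), `log_fc`, `p` (two-sided), `phi`, `df`.
#' @seealso [diff_gene_table()] for the matrix-level interface with BH
#'   adjustment.
#' @export
nb_gene_test <- function(counts_a, counts_b, sizes_a, sizes_b,
                         eps = 0.5, phi_floor = 1e-8, phi_prior = NULL,
                         prior_df = if (is.null(phi_prior)) 0 else 20) {
  n_a <- length(counts_a); n_b <- length(counts_b)
  if (n_a == 0L || n_b == 0L) stop("empty replicate group")
  depth <- mean(c(sizes_a, sizes_b))
  ya <- counts_a / (sizes_a / depth)
  yb <- counts_b / (sizes_b / depth)
  mu_a <- mean(ya); mu_b <- mean(yb)
  df <- n_a + n_b - 2L
  if (df >= 1L) {
    s2 <- (sum((ya - mu_a)^2) + sum((yb - mu_b)^2)) / df
    mu <- mean(c(ya, yb))
    phi_g <- max((s2 - mu) / max(mu, eps)^2, 0)
  } else {
    if (is.null(phi_prior))
      stop("single replicates need a phi_prior (pooled dispersion)")
    phi_g <- phi_prior
  }
  if (prior_df > 0 && !is.null(phi_prior)) {
    phi <- (prior_df * phi_prior + df * phi_g) / (prior_df + df)
  } else phi <- phi_g
  phi <- max(phi, phi_floor)
  ref_df <- max(df, 1L) + prior_df
  w <- log(mu_a + eps) - log(mu_b + eps)
  v <- (1 / (mu_a + eps) + phi) / n_a + (1 / (mu_b + eps) + phi) / n_b
  tstat <- w / sqrt(v)
  p <- 2 * pt(-abs(tstat), df = ref_df)
  list(fc = (mu_a + eps) / (mu_b + eps), log_fc = w, p = p,
       phi = phi, df = ref_df)
}

#' Two-group differential table for a count matrix
#'
#' Runs [nb_gene_test()] per feature for the contrast `group_a` vs
#' `group_b` and BH-adjusts the p-values across features.
#'
#' Depth normalisation uses median-of-ratios size factors computed over
#' the whole matrix (all samples), which is robust to the composition
#' shifts that raw library-size scaling suffers when a large fraction of
#' features genuinely changes.
#'
#' @param counts features x samples count matrix (columns named by
#'   sample).
#' @param samples a [sample_table()].
#' @param group_a,group_b group labels of the contrast (fold change is A
#'   over B).
#' @param eps pseudocount, see [nb_gene_test()].
#' @return `data.frame`: feature_id, mean_a, mean_b (normalized counts),
#'   fc, p, padj.
#' @export
diff_gene_table <- function(counts, samples, group_a, group_b, eps = 0.5) {
  ids_a <- samples_in_group(samples, group_a)
  ids_b <- samples_in_group(samples, group_b)
  sf <- size_factors(counts[, samples$sample, drop = FALSE])
  names(sf) <- samples$sample
  sa <- sf[ids_a]
  sb <- sf[ids_b]
  ca <- counts[, ids_a, drop = FALSE]
  cb <- counts[, ids_b, drop = FALSE]
  # common dispersion across genes: mean of per-gene method-of-moments
  # estimates (clamped at zero), the moderation target
  depth <- mean(c(sa, sb))
  y <- cbind(sweep(ca, 2L, sa / depth, "/"), sweep(cb, 2L, sb / depth, "/"))
  ya <- y[, seq_along(ids_a), drop = FALSE]
  yb <- y[, length(ids_a) + seq_along(ids_b), drop = FALSE]
  df <- length(ids_a) + length(ids_b) - 2L
  mu <- rowMeans(y)
  phi_common <- if (df >= 1L) {
    s2 <- (rowSums((ya - rowMeans(ya))^2) +
             rowSums((yb - rowMeans(yb))^2)) / df
    ok <- mu > 0
    if (any(ok)) mean(pmax((s2[ok] - mu[ok]) / pmax(mu[ok], eps)^2, 0))
    else 0
  } else {
    # single replicates: treat the two samples as one pseudo-group
    s2 <- apply(y, 1L, var)
    ok <- mu > 0
    if (any(ok)) mean(pmax((s2[ok] - mu[ok]) / pmax(mu[ok], eps)^2, 0))
    else 0
  }
  res <- lapply(seq_len(nrow(counts)), function(i)
    nb_gene_test(ca[i, ], cb[i, ], sa, sb, eps = eps,
                 phi_prior = phi_common))
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(
    feature_id = rownames(counts),
    mean_a = rowMeans(sweep(ca, 2L, sa / mean(c(sa, sb)), "/")),
    mean_b = rowMeans(sweep(cb, 2L, sb / mean(c(sa, sb)), "/")),
    fc = vapply(res, `[[`, numeric(1), "fc"),
    p = p,
    padj = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-tailed two-group t test
#'
#' Pooled-variance Student's t by default (`var_equal = FALSE` gives
#' Welch). Degenerate zero-variance inputs follow the conventions: equal
#' means give p = 1, unequal means p = 0.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student's t (default `TRUE`).
#' @return list with `t`, `df`, `p`.
#' @export
two_group_t <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs >= 2 values")
  va <- var(values_a); vb <- var(values_b)
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(t = if (eq) 0 else sign(mean(values_a) - mean(values_b)) * Inf,
                df = length(values_a) + length(values_b) - 2L,
                p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `n.s.`.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "n.s."), right = FALSE) |> as.character()
}
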