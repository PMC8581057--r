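# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: hypergeometric probabilities via lchoose
# instead of dhyper, BH via the literal step-up formula, the t test via
# its closed form.

# Exhaustive two-sided Fisher p for one 2x2 table [[a, b], [c, d]]:
# enumerate every table with the observed margins, sum probabilities not
# exceeding the observed one.
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-12) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(lp)
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + rel_tol)]))
}

# Literal step-up BH: sort ascending, q_i = min_{j >= i} p_j * n / j,
# cap at 1, restore input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Closed-form pooled-variance two-sided t test.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}
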