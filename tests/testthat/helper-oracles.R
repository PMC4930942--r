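# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (enumeration, brute force, closed form) and share no
# code with the implementation they check.

# Brute-force BH step-up: q(i) = min_{j >= i} m * p(j) / j on sorted p.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i) min(pmin(1, m * ps[i:m] / (i:m))), 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric upper tail by direct summation of the pmf.
hyper_brute <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# Exact two-sided rank-sum p-value by full enumeration of all rank
# assignments (no ties assumed), using the same two-sided convention as
# wilcox.test: double the tail containing the observed Mann-Whitney U.
wilcox_brute <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

# Naive IUPAC scanner: expand the motif to all concrete words and
# substring-search each, on the plus strand and (unless palindromic) the
# reverse-complement words.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

expand_words <- function(iupac) {
  sets <- IUPAC_SETS[strsplit(toupper(iupac), "")[[1]]]
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1, paste0,
        collapse = "")
}

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

scan_naive <- function(sequence, iupac) {
  w <- nchar(iupac)
  n <- nchar(sequence)
  subs <- substring(sequence, 1:(n - w + 1), w:n)
  plus_words <- expand_words(iupac)
  minus_words <- unique(vapply(plus_words, revcomp_str, ""))
  starts_plus <- which(subs %in% plus_words)
  palindromic <- setequal(plus_words, minus_words)
  out <- data.frame(start = starts_plus,
                    strand = rep("+", length(starts_plus)))
  if (!palindromic) {
    starts_minus <- which(subs %in% minus_words)
    out <- rbind(out, data.frame(start = starts_minus,
                                 strand = rep("-", length(starts_minus))))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# Circular distance between phases in hours.
phase_error <- function(est, truth, period = 24) {
  d <- (est - truth) %% period
  pmin(d, period - d)
}

# Balanced accuracy of a classification against planted labels; the
# pipeline's "none" corresponds to the planted "null" class.
balanced_accuracy <- function(planted, called) {
  called <- ifelse(called == "none", "null", called)
  mean(vapply(unique(planted), function(cl) {
    mean(called[planted == cl] == cl)
  }, 1))
}
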