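# Independent oracles used across the suite. These deliberately take the
# naive route (enumeration, closed formulas) rather than the package's.

# all-windows sequon enumeration: every length-3 window N-[^P]-[ST]
naive_scan_positions <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3) return(integer())
  idx <- seq_len(n - 2)
  idx[ch[idx] == "N" & ch[idx + 1] != "P" & ch[idx + 2] %in% c("S", "T")]
}

# Benjamini-Hochberg step-up computed from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(1, min(m * sp[i:m] / seq(i, m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# two-sided Fisher exact p by full hypergeometric enumeration
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc
  n <- b + d
  k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by enumerating every labeling of the pooled values
mw_enum_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  r <- rank(z)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(z), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

random_protein <- function(n, alphabet = c(LETTERS[LETTERS %in% c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")], "X")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
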