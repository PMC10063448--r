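# Independent oracles used to verify the package implementations.

# Dynamic-programming edit distance, written independently of utils::adist.
lev_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A)
  lb <- length(B)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (A[i] != B[j]))
    }
  }
  d[la + 1, lb + 1]
}

# Gini coefficient by the literal pairwise mean-absolute-difference formula.
gini_pairwise_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all rank assignments
# (no ties assumed). Mirrors the two-sided convention 2 * min(P<=, P>=), <= 1.
rank_sum_enum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all sign vectors.
signed_rank_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Product-limit estimator computed by hand at event times.
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  s <- 1
  out <- numeric(0)
  times <- numeric(0)
  for (t in unique(time)) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    if (d > 0) {
      s <- s * (1 - d / at_risk)
      out <- c(out, s)
      times <- c(times, t)
    }
  }
  data.frame(time = times, estimate = out)
}
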