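# Independent oracles and small utilities shared by the tests.

# Full-matrix Levenshtein distance, vectorized over matrix rows. Written
# independently of the package's banded aligner: the left-to-right dependency
# is resolved with the running-minimum identity
#   D[i, j] = j + min(i, min_{k <= j}(t[k] - k))
# where t[k] = min(D[i-1, k-1] + cost, D[i-1, k] + 1).
lev_oracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(x); n <- length(y)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n
  for (i in seq_len(m)) {
    t <- pmin(prev[1:n] + (x[i] != y), prev[2:(n + 1L)] + 1L)
    cur <- seq_len(n) + pmin(i, cummin(t - seq_len(n)))
    prev <- c(i, cur)
  }
  prev[n + 1L]
}

# brute-force infix (free target ends) edit distance for tiny inputs
infix_oracle <- function(q, t) {
  n <- nchar(t)
  best <- Inf
  for (s in 0:n) for (e in s:n) {
    best <- min(best, lev_oracle(q, substr(t, s + 1L, e)))
  }
  best
}

# adjusted Rand index from the pair-counting formula
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# read set with per-base errors applied through the simulator's error model
errify <- function(seqs, error_rate) {
  vapply(seqs, function(s) {
    sdweaver:::cpp_mutate_read(s, error_rate, 0.6, 0.25, 0.15)$seq
  }, "", USE.NAMES = FALSE)
}
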