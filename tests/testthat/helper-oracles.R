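# Independent brute-force oracles, written as direct transcriptions of the
# metric and Tomek-link definitions; deliberately slow and loop-based so they
# share no code with the implementations they check.

oracle_ranks <- function(s) {
  ord <- order(-s, seq_along(s))
  r <- integer(length(s)); r[ord] <- seq_along(s); r
}

oracle_average_precision <- function(Y, S) {
  vals <- c()
  for (i in seq_len(nrow(Y))) {
    rel <- which(Y[i, ] == 1)
    if (length(rel) == 0) next
    r <- oracle_ranks(S[i, ])
    acc <- 0
    for (l in rel) {
      ahead <- 0
      for (l2 in rel) if (r[l2] <= r[l]) ahead <- ahead + 1
      acc <- acc + ahead / r[l]
    }
    vals <- c(vals, acc / length(rel))
  }
  mean(vals)
}

oracle_ranking_loss <- function(Y, S) {
  vals <- c()
  for (i in seq_len(nrow(Y))) {
    rel <- which(Y[i, ] == 1); irr <- which(Y[i, ] == 0)
    if (length(rel) == 0 || length(irr) == 0) next
    r <- oracle_ranks(S[i, ])
    bad <- 0
    for (a in rel) for (b in irr) if (r[a] > r[b]) bad <- bad + 1
    vals <- c(vals, bad / (length(rel) * length(irr)))
  }
  mean(vals)
}

oracle_hamming <- function(Y, Z) {
  tot <- 0
  for (i in seq_len(nrow(Y))) tot <- tot + sum(Y[i, ] != Z[i, ]) / ncol(Y)
  tot / nrow(Y)
}

oracle_micro_f1 <- function(Y, Z) {
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(Y))) for (l in seq_len(ncol(Y))) {
    if (Y[i, l] == 1 && Z[i, l] == 1) tp <- tp + 1
    if (Y[i, l] == 0 && Z[i, l] == 1) fp <- fp + 1
    if (Y[i, l] == 1 && Z[i, l] == 0) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

oracle_macro_auroc <- function(Y, S) {
  vals <- c()
  for (l in seq_len(ncol(Y))) {
    pos <- which(Y[, l] == 1); neg <- which(Y[, l] == 0)
    if (length(pos) == 0 || length(neg) == 0) next
    won <- 0
    for (p in pos) for (n in neg) {
      if (S[p, l] > S[n, l]) won <- won + 1
      else if (S[p, l] == S[n, l]) won <- won + 0.5
    }
    vals <- c(vals, won / (length(pos) * length(neg)))
  }
  mean(vals)
}

# O(n^2) Tomek-link enumeration: mutual nearest neighbours (ties by lowest
# index) of opposite class
oracle_tomek <- function(X, y) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- integer(n)
  for (i in seq_len(n)) nn[i] <- which(D[i, ] == min(D[i, ]))[1]
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && nn[i] == j && nn[j] == i && y[i] != y[j]) {
      out <- rbind(out, c(i, j))
    }
  }
  out
}
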