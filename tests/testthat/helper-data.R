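# Fixtures built in code: the worked six-label example rows and random
# multi-label datasets for property-style tests.

table1_labels <- function() {
  rows <- c("001011", "001110", "011100", "111001", "111110")
  do.call(rbind, lapply(strsplit(rows, ""), as.integer))
}

table1_mld <- function() {
  Y <- table1_labels()
  df <- tibble::as_tibble(Y, .name_repair = ~ paste0("label", 1:6))
  df$f1 <- as.numeric(1:5)
  mld(df, label_cols = paste0("label", 1:6))
}

# random mld with every label positive at least once
random_mld <- function(m, q, d = 2, p = 0.4) {
  repeat {
    Y <- matrix(rbinom(m * q, 1, p), m, q)
    if (all(colSums(Y) >= 1)) break
  }
  df <- tibble::as_tibble(Y, .name_repair = ~ paste0("l", seq_len(q)))
  X <- matrix(rnorm(m * d), m, d)
  df <- dplyr::bind_cols(tibble::as_tibble(X, .name_repair = ~ paste0("x", seq_len(d))), df)
  mld(df, label_cols = paste0("l", seq_len(q)))
}

expect_mld_equal <- function(a, b, tolerance = 0) {
  expect_equal(mld_features(a), mld_features(b), tolerance = tolerance)
  expect_equal(mld_labels(a), mld_labels(b))
  expect_identical(a$label_names, b$label_names)
  expect_identical(a$feature_names, b$feature_names)
}
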