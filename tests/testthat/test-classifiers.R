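blob_mld <- function(n = 120, q = 2, sep = 6) {
  # q well-separated label-wise blobs plus joint occurrences
  Y <- matrix(rbinom(n * q, 1, 0.5), n, q)
  Y[rowSums(Y) == 0, sample(q, 1)] <- 1L
  X <- Y %*% (diag(q) * sep) + matrix(rnorm(n * q, 0, 0.4), n, q)
  df <- dplyr::bind_cols(
    tibble::as_tibble(X, .name_repair = ~ paste0("x", seq_len(q))),
    tibble::as_tibble(Y, .name_repair = ~ paste0("l", seq_len(q))))
  mld(df, paste0("l", seq_len(q)))
}

test_that("binary relevance separates label-wise separable blobs", {
  set.seed(41)
  train <- blob_mld(150)
  test <- blob_mld(80)
  fit <- fit_br(train, base_learner("decision_tree"))
  pred <- predict(fit, test)
  expect_equal(dim(pred$scores), c(80L, 2L))
  expect_true(all(is.finite(pred$scores)))
  expect_true(all(pred$predicted %in% c(0L, 1L)))
  expect_lt(hamming_loss(mld_labels(test), pred$predicted), 0.05)
})

test_that("BR and CC coincide on a single label, and scores permute with labels", {
  set.seed(42)
  m <- blob_mld(80, q = 1)
  te <- blob_mld(40, q = 1)
  pb <- predict(fit_br(m, base_learner("decision_tree")), te)
  pc <- predict(fit_cc(m, base_learner("decision_tree")), te)
  expect_equal(pb$scores, pc$scores)
  expect_equal(pb$predicted, pc$predicted)

  set.seed(43)
  m3 <- blob_mld(120, q = 3)
  te3 <- blob_mld(50, q = 3)
  p1 <- predict(fit_br(m3, base_learner("decision_tree")), te3)
  perm <- c(3, 1, 2)
  mp <- mld(as_tibble(m3), label_cols = m3$label_names[perm])
  p2 <- predict(fit_br(mp, base_learner("decision_tree")), te3)
  expect_equal(unname(p2$scores), unname(p1$scores[, perm]))
})

test_that("a chained copy label follows its parent's prediction", {
  set.seed(44)
  n <- 120
  x <- rnorm(n)
  l1 <- as.integer(x + rnorm(n, 0, 0.3) > 0)
  df <- tibble::tibble(x1 = x, x2 = rnorm(n), l1 = l1, l2 = l1)
  m <- mld(df, c("l1", "l2"))
  fit <- fit_cc(m, base_learner("decision_tree"))
  te <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60))
  pred <- predict(fit, te)
  expect_equal(pred$predicted[, "l2"], pred$predicted[, "l1"])
})

test_that("label powerset lives in the closed world of observed labelsets", {
  set.seed(45)
  n <- 80
  Y <- cbind(rep(c(0L, 1L), each = n / 2), rep(c(0L, 1L), each = n / 2))
  X <- Y * 5 + matrix(rnorm(2 * n, 0, 0.3), n, 2)
  df <- dplyr::bind_cols(tibble::as_tibble(X, .name_repair = ~ c("x1", "x2")),
                         tibble::as_tibble(Y, .name_repair = ~ c("a", "b")))
  m <- mld(df, c("a", "b"))
  fit <- fit_lp(m, base_learner("decision_tree"))
  expect_equal(length(fit$components$classes), 2L)   # DC classes
  pred <- predict(fit, matrix(rnorm(100), 50, 2))
  keys <- apply(pred$predicted, 1, paste, collapse = "")
  expect_true(all(keys %in% c("00", "11")))

  # DC distinct combinations -> DC classes on the worked example rows
  fit5 <- fit_lp(table1_mld(), base_learner("decision_tree"))
  expect_equal(length(fit5$components$classes), 5L)
})

test_that("RAkEL with one full-size subset collapses to label powerset", {
  set.seed(46)
  m <- blob_mld(100, q = 3)
  te <- blob_mld(40, q = 3)
  lp <- predict(fit_lp(m, base_learner("decision_tree")), te)
  rk <- predict(fit_rakel(m, base_learner("decision_tree"),
                          labelset_size = 3, n_models = 1, seed = 1), te)
  expect_equal(rk$predicted, lp$predicted)
  expect_true(all(rk$scores %in% c(0, 1)))   # unanimous single member
  expect_error(fit_rakel(m, labelset_size = 4), "exceeds")
})

test_that("RAkEL defaults run on six labels and cover them", {
  set.seed(47)
  m <- generate_mld(frailty_like_preset(400, seed = 5))
  fit <- fit_rakel(m, base_learner("decision_tree"), seed = 2)
  expect_equal(length(fit$components$members), 12L)
  expect_true(all(lengths(lapply(fit$components$members, `[[`, "subset")) == 3L))
  pred <- predict(fit, m)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
})

test_that("CLR builds the pairwise-plus-calibration component count", {
  set.seed(48)
  m2 <- blob_mld(60, q = 2)
  fit2 <- fit_clr(m2, base_learner("decision_tree"))
  expect_equal(length(fit2$components$pairwise), 1L)
  expect_equal(length(fit2$components$calibration), 2L)

  m6 <- generate_mld(frailty_like_preset(300, seed = 6))
  fit6 <- suppressMessages(fit_clr(m6, base_learner("decision_tree")))
  expect_equal(length(fit6$components$pairwise), 15L)
  expect_equal(length(fit6$components$calibration), 6L)
  pred <- predict(fit6, m6)
  expect_true(all(is.finite(pred$scores)))
  expect_error(fit_clr(blob_mld(30, q = 1)), "two labels")
})

test_that("CLR ranks a dominant relevant label first", {
  set.seed(49)
  m <- blob_mld(150, q = 3)
  fit <- fit_clr(m, base_learner("decision_tree"))
  te <- blob_mld(60, q = 3)
  pred <- predict(fit, te)
  # instances with exactly one active, well-separated label
  solo <- which(rowSums(mld_labels(te)) == 1)
  top <- apply(pred$scores[solo, ], 1, which.max)
  truth <- apply(mld_labels(te)[solo, ], 1, which.max)
  expect_gt(mean(top == truth), 0.8)
})

test_that("MLkNN posteriors match a hand-built Bayes table at k = 1", {
  df <- tibble::tibble(x = c(0, 1, 10, 11),
                       l1 = c(1, 1, 0, 0), l2 = c(0, 0, 1, 1))
  m <- mld(df, c("l1", "l2"))
  fit <- fit_mlknn(m, k_neighbors = 1, smoothing = 1)
  # priors: (s + count) / (2s + m)
  expect_equal(unname(fit$components$prior1), c(3 / 6, 3 / 6))
  pred <- predict(fit, matrix(c(0, 11), ncol = 1))
  # l1, query x=0: neighbour is the training point x=0 itself (c=1);
  # LOO: both l1-positives see a positive, both negatives see a negative
  # lik1 = (1 + c(0,2))/(2 + 2); lik0 = (1 + c(2,0))/(2 + 2)
  p1 <- (1 / 2) * (3 / 4); p0 <- (1 / 2) * (1 / 4)
  expect_equal(unname(pred$scores[1, "l1"]), p1 / (p1 + p0))
  expect_equal(unname(pred$predicted[1, "l1"]), 1L)
  expect_equal(unname(pred$predicted[2, "l1"]), 0L)
  # unanimous neighbourhood at a training point predicts its label
  expect_equal(unname(pred$predicted[2, "l2"]), 1L)
  expect_equal(unname(pred$scores[2, "l2"]), p1 / (p1 + p0))
  expect_error(fit_mlknn(m, k_neighbors = 4), "smaller")
})

test_that("degenerate labels fall back to constant scorers", {
  df <- tibble::tibble(x = rnorm(20), a = 1, b = rep(c(0, 1), 10))
  m <- mld(df, c("a", "b"))
  expect_message(fit <- fit_br(m, base_learner("decision_tree")), "constant")
  pred <- predict(fit, m)
  expect_true(all(pred$scores[, "a"] == 1))
})

test_that("the experiment protocol is reproducible and shaped like a report", {
  set.seed(50)
  m <- generate_mld(frailty_like_preset(250, seed = 8))
  r1 <- suppressWarnings(run_experiment(m, resampler = "none",
                                        strategies = c("br", "lp"),
                                        base = base_learner("decision_tree"),
                                        folds = 2, seed = 7))
  r2 <- suppressWarnings(run_experiment(m, resampler = "none",
                                        strategies = c("br", "lp"),
                                        base = base_learner("decision_tree"),
                                        folds = 2, seed = 7))
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_equal(nrow(r1), 4L)            # 2 strategies x {cv, test}
  expect_named(r1, c("strategy", "split", "auroc", "ap", "f1", "hl", "rl"))
  gl <- glance(r1)
  expect_equal(nrow(gl), 2L)
  expect_named(gl, c("split", "sd_auroc", "sd_ap", "sd_f1", "sd_hl", "sd_rl"))
})

test_that("average ranks reproduce the published four-dataset comparison", {
  tbl <- average_rank(frailty_ap_benchmark())
  expect_equal(tbl$base, c(2, 5, 6, 3, 4, 1))
  expect_equal(tbl$tomek, c(3, 1, 5.5, 5.5, 4, 2))
  expect_equal(tbl$smote, c(2, 6, 3.5, 5, 1, 3.5))
  expect_equal(tbl$tlsmote, c(2.5, 6, 2.5, 4, 1, 5))
  expect_equal(tbl$average_rank, c(2.375, 4.5, 4.375, 4.375, 2.5, 2.875))
  # printed to two decimals: BR 2.38, CLR 2.5
  expect_equal(round(tbl$average_rank[tbl$model == "BR"], 2), 2.38)
  expect_equal(round(tbl$average_rank[tbl$model == "CLR"], 2), 2.5)
})

test_that("average ranks tie to the midpoint when all models coincide", {
  tbl <- average_rank(tibble::tibble(model = letters[1:4],
                                     d1 = rep(0.5, 4), d2 = rep(0.1, 4)))
  expect_equal(tbl$average_rank, rep(2.5, 4))
  expect_error(average_rank(tibble::tibble(model = character(0),
                                           d1 = numeric(0))), "empty")
  expect_error(average_rank(tibble::tibble(model = "a", d1 = NA_real_)),
               "missing")
})
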