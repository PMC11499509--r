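test_that("smote interpolation stays on the segment between its endpoints", {
  expect_equal(smote_interpolate(c(0, 0), c(1, 1), u = 0.5), c(0.5, 0.5))
  expect_equal(smote_interpolate(c(2, 3), c(2, 3), u = 0.99), c(2, 3))
  expect_error(smote_interpolate(c(1, 2), c(1, 2, 3)), "dimension")
  set.seed(10)
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(4)
    z <- smote_interpolate(a, b)
    expect_true(all(z >= pmin(a, b) - 1e-12 & z <= pmax(a, b) + 1e-12))
  }
})

test_that("tomek links match the hand-worked 1-D configuration", {
  x <- matrix(c(0, 0.9, 2, 3.5), ncol = 1)
  tl <- tomek_links(x, c(0, 1, 0, 0))
  expect_equal(tl$i, 1L)
  expect_equal(tl$j, 2L)
  expect_equal(tl$distance, 0.9)
  expect_equal(nrow(tomek_links(x, c(1, 1, 1, 1))), 0L)
  expect_equal(nrow(tomek_links(x[1, , drop = FALSE], 1)), 0L)
})

test_that("tomek links equal the O(n^2) enumeration oracle on random data", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(4:60, 1); d <- sample(1:5, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.5)
    got <- tomek_links(X, y)
    want <- oracle_tomek(X, y)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(cbind(got$i, got$j), want, ignore_attr = TRUE)
    }
  }
})

test_that("two well-separated clusters yield the boundary pair at most", {
  set.seed(12)
  a <- matrix(rnorm(20, 0, 0.05), 10, 2)
  b <- matrix(rnorm(20, 10, 0.05), 10, 2)
  X <- rbind(a, b)
  y <- rep(c(0, 1), each = 10)
  got <- tomek_links(X, y)
  want <- oracle_tomek(X, y)
  expect_equal(nrow(got), NROW(want))
})

balanced_two_label <- function() {
  # label A: 50 positives; label B: 10 pure-B instances
  set.seed(13)
  XA <- matrix(rnorm(100, 0), 50, 2)
  XB <- matrix(rnorm(20, 6), 10, 2)
  df <- tibble::tibble(x1 = c(XA[, 1], XB[, 1]), x2 = c(XA[, 2], XB[, 2]),
                       A = rep(c(1, 0), c(50, 10)),
                       B = rep(c(0, 1), c(50, 10)))
  mld(df, c("A", "B"))
}

test_that("ml_smote raises the rare label above the stopping ratio", {
  m <- balanced_two_label()
  prof <- imbalance_profile(m)
  set.seed(14)
  res <- ml_smote(m, k = 3)
  cnt <- label_counts(res$data)
  expect_gte(cnt["B"], 50 / prof$mean_ir)            # IRLbl(B) <= input MeanIR
  expect_equal(cnt["A"], c(A = 50L))                 # frequent label untouched
  # originals never modified, synthetic flagged
  n0 <- n_instances(m)
  expect_equal(mld_features(res$data)[1:n0, ], mld_features(m))
  expect_equal(mld_labels(res$data)[1:n0, ], mld_labels(m))
  expect_true(all(res$data$synthetic[-(1:n0)]))
  expect_equal(sum(res$synthetic_added), n_instances(res$data) - n0)
  # synthetic rows copy a seed's label vector and stay in the pool's hull
  synth <- mld_labels(res$data)[-(1:n0), , drop = FALSE]
  expect_true(all(synth[, "A"] == 0 & synth[, "B"] == 1))
  poolX <- mld_features(m)[mld_labels(m)[, "B"] == 1, , drop = FALSE]
  sx <- mld_features(res$data)[-(1:n0), , drop = FALSE]
  expect_true(all(sx[, 1] >= min(poolX[, 1]) - 1e-9 &
                    sx[, 1] <= max(poolX[, 1]) + 1e-9))
})

test_that("ml_smote leaves balanced data alone and warns on tiny pools", {
  ident <- mld(tibble::as_tibble(diag(3), .name_repair = ~ c("a", "b", "c")),
               label_cols = c("a", "b", "c"))
  res <- ml_smote(ident)
  expect_equal(n_instances(res$data), 3L)
  expect_equal(sum(res$synthetic_added), 0L)

  # rare label with a single pure seed cannot be interpolated
  df <- tibble::tibble(x = rnorm(12),
                       a = rep(1, 12),
                       b = c(1, rep(0, 11)))
  m <- mld(df, c("a", "b"))
  expect_warning(res <- ml_smote(m, k = 5), "cannot interpolate")
  expect_equal(n_instances(res$data), 12L)

  # pool of 3 clamps k = 5 to 2
  df <- tibble::tibble(x = rnorm(20), y = rnorm(20),
                       a = rep(c(1, 0), c(17, 3)),
                       b = rep(c(0, 1), c(17, 3)))
  m <- mld(df, c("a", "b"))
  expect_warning(ml_smote(m, k = 5), "clamped")
})

test_that("tomek cleaning removes a planted borderline pair and nothing else", {
  # two tight far-apart groups + one adjacent opposite-class pair in between
  df <- tibble::tibble(
    x = c(-100, -100.1, -100.2, 100, 100.1, 100.2, 0, 0.05),
    a = c(1, 1, 1, 1, 1, 1, 1, 0),
    b = c(0, 0, 1, 0, 0, 1, 0, 1))
  m <- mld(df, c("a", "b"))
  prof <- imbalance_profile(m)
  res <- ml_tomek_clean(m, prof)
  expect_equal(n_instances(res$data), 6L)
  expect_equal(sum(res$removed_by_tomek), 2L)
  expect_false(any(abs(mld_features(res$data)[, 1]) < 1))
  # survivors are a subset of the input
  expect_true(all(mld_features(res$data)[, 1] %in% df$x))
})

test_that("tomek cleaning never orphans a label", {
  # the only positive of b sits in a link under the a-view
  df <- tibble::tibble(x = c(0, 0.1, 50, 50.1, 50.2),
                       a = c(1, 0, 1, 1, 1),
                       b = c(0, 1, 0, 0, 0))
  m <- mld(df, c("a", "b"))
  res <- ml_tomek_clean(m)
  expect_gte(sum(mld_labels(res$data)[, "b"]), 1L)
  expect_gte(sum(mld_labels(res$data)[, "a"]), 1L)
})

test_that("well-separated classes survive cleaning unchanged", {
  set.seed(15)
  df <- tibble::tibble(x = c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01)),
                       a = rep(c(1, 0), each = 10),
                       b = rep(c(0, 1), each = 10))
  m <- mld(df, c("a", "b"))
  res <- ml_tomek_clean(m)
  expect_equal(n_instances(res$data), 20L)
  expect_equal(sum(res$removed_by_tomek), 0L)
})

test_that("the hybrid pipeline is deterministic and bookkeeps its counts", {
  m <- generate_mld(frailty_like_preset(700, seed = 16))
  r1 <- suppressWarnings(ml_tlsmote(m, k = 5, seed = 99))
  r2 <- suppressWarnings(ml_tlsmote(m, k = 5, seed = 99))
  expect_equal(mld_features(r1$data), mld_features(r2$data))
  expect_equal(mld_labels(r1$data), mld_labels(r2$data))
  rep <- r1$report
  expect_equal(n_instances(r1$data),
               n_instances(m) + sum(rep$synthetic_added) -
                 sum(rep$removed_by_tomek))
  expect_equal(rep$seed, 99)
  # cardinality stays within the active-label band
  card_out <- label_stats(r1$data)$cardinality
  expect_gte(card_out, 1)
  expect_lte(card_out, label_stats(m)$cardinality + 1)
})

test_that("the hybrid pipeline reduces imbalance across generator draws", {
  for (s in 1:5) {
    m <- generate_mld(frailty_like_preset(900, seed = 20 + s))
    r <- suppressWarnings(ml_tlsmote(m, k = 5, seed = s))
    expect_lt(r$report$after$mean_ir, r$report$before$mean_ir)
    expect_lt(r$report$after$cvir, r$report$before$cvir)
  }
})

test_that("balanced input and degenerate labels short-circuit the pipeline", {
  ident <- mld(tibble::as_tibble(diag(3), .name_repair = ~ c("a", "b", "c")),
               label_cols = c("a", "b", "c"))
  r <- ml_tlsmote(ident, seed = 1)
  expect_equal(n_instances(r$data), 3L)
  expect_equal(sum(r$report$synthetic_added), 0L)
  expect_equal(sum(r$report$removed_by_tomek), 0L)

  bad <- mld(tibble::tibble(x = 1:3, a = c(1, 1, 1), b = 0), c("a", "b"))
  expect_error(ml_tlsmote(bad), "refused")
})

test_that("resampling reports tidy into per-label before/after tables", {
  m <- generate_mld(frailty_like_preset(600, seed = 17))
  r <- suppressWarnings(ml_tlsmote(m, k = 5, seed = 2))
  td <- tidy(r)
  expect_equal(nrow(td), 6L)
  expect_named(td, c("label", "count_before", "irlbl_before",
                     "synthetic_added", "removed_by_tomek",
                     "count_after", "irlbl_after"))
  expect_equal(td$count_after, unname(label_counts(r$data)))
  expect_equal(td$count_before, unname(label_counts(m)))
  gl <- glance(r)
  expect_lte(gl$mean_ir_after, gl$mean_ir_before)
})
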