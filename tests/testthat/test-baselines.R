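test_that("univariate ANOVA-F selection favours separated features", {
  d <- tiny_two_class(n_per_class = 20, n_noise = 1, seed = 31)
  res <- ufs_select(d$X, d$y, 1)
  expect_identical(res$selected, "f1")

  X <- cbind(d$X, const = 5)
  scores <- anova_f_scores(X, d$y)
  expect_identical(unname(scores["const"]), 0)
  expect_identical(rev(rank_top_k(scores, ncol(X)))[1], "const")
})

test_that("ANOVA F matches aov on a small worked dataset", {
  X <- matrix(c(1.2, 0.8, 3.1, 2.9, 3.0,
                5.0, 4.0, 4.5, 6.0, 5.5), 5, 2,
              dimnames = list(NULL, c("g1", "g2")))
  y <- c("a", "a", "b", "b", "b")
  F <- anova_f_scores(X, y)
  for (j in 1:2) {
    oracle <- summary(stats::aov(X[, j] ~ factor(y)))[[1]]$`F value`[1]
    expect_equal(unname(F[j]), oracle, tolerance = 1e-10)
  }
})

test_that("RFE removes one feature per fit and counts N - k fits", {
  d <- tiny_two_class(n_per_class = 10, n_noise = 4, seed = 32)  # 5 features
  calls <- 0L
  fit_fun <- function(X, y, seed) {
    calls <<- calls + 1L
    stub_classifier(stats::setNames(seq_len(ncol(X)), colnames(X)))
  }
  res <- rfe_select(d$X, d$y, 2, fit_fun = fit_fun)
  expect_identical(res$fit_count, 3L)
  expect_identical(calls, 3L)
  expect_identical(length(res$selected), 2L)
  expect_identical(length(res$elimination_order), 3L)
})

test_that("RFE with a linear SVC eliminates a pure-noise feature first", {
  set.seed(33)
  n <- 40
  X <- cbind(f1 = c(rnorm(n / 2), rnorm(n / 2) + 8),
             f2 = c(rnorm(n / 2), rnorm(n / 2) + 8),
             f3 = rnorm(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- rep(c("A", "B"), each = n / 2)
  res <- rfe_select(X, y, 2, seed = 1)
  expect_identical(res$elimination_order[1], "f3")
  # single-fit coefficient oracle: the first removal is the smallest |w|
  std <- fit_standardization(X)
  m <- fit_classifier("svc_linear", apply_standardization(std, X), y, seed = 1)
  imp <- classifier_importance(m)
  expect_identical(names(which.min(imp)), "f3")
})

test_that("lasso excludes an independent noise feature and pads when sparse", {
  set.seed(34)
  n <- 60
  X <- cbind(f_signal = c(rnorm(n / 2), rnorm(n / 2) + 6),
             f_noise = rnorm(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- rep(c("A", "B"), each = n / 2)
  res <- penalized_select(X, y, 1, mode = "lasso", seed = 2)
  expect_identical(res$selected, "f_signal")
  expect_false(res$padded)

  # pure-noise labels: the CV-chosen penalty zeroes everything and the
  # selection is padded from zero-coefficient features in name order
  set.seed(35)
  Xn <- matrix(rnorm(40 * 3), 40, 3,
               dimnames = list(sprintf("s%02d", 1:40), c("a", "b", "c")))
  yn <- rep(c("A", "B"), 20)
  warns <- testthat::capture_warnings(
    res2 <- penalized_select(Xn, yn, 2, mode = "lasso", seed = 2))
  expect_true(any(grepl("padding|zero", warns)))
  expect_true(res2$padded)
  expect_identical(length(res2$selected), 2L)
})

test_that("duplicating every sample leaves the penalized selection unchanged", {
  set.seed(35)
  n <- 45
  X <- cbind(f1 = c(rnorm(15), rnorm(15) + 5, rnorm(15) - 5),
             f2 = c(rnorm(15), rnorm(15), rnorm(15) + 5),
             f3 = rnorm(n), f4 = rnorm(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- rep(c("A", "B", "C"), each = 15)
  sel1 <- penalized_select(X, y, 2, mode = "elastic_net", seed = 3)
  X2 <- rbind(X, X); rownames(X2) <- sprintf("s%02d", 1:(2 * n))
  sel2 <- penalized_select(X2, c(y, y), 2, mode = "elastic_net", seed = 3)
  expect_setequal(sel1$selected, sel2$selected)
})

test_that("EFS-CLA halves survivors with E = 50 and is seed-deterministic", {
  d <- tiny_two_class(n_per_class = 15, n_noise = 7, seed = 36)  # 8 features
  res <- efs_cla_select(d$X, d$y, 2, E = 50, calls_per_step = 3, seed = 4)
  expect_identical(res$survivor_counts, c(8L, 4L, 2L))
  expect_identical(length(res$selected), 2L)
  res2 <- efs_cla_select(d$X, d$y, 2, E = 50, calls_per_step = 3, seed = 4)
  expect_identical(res$selected, res2$selected)
})

test_that("EFS-CLA survivor counts follow the floor recurrence and trim to k", {
  d <- tiny_two_class(n_per_class = 15, n_noise = 29, seed = 37)  # 30 features
  k <- 5
  res <- efs_cla_select(d$X, d$y, k, E = 20, calls_per_step = 2, seed = 5)
  # independent floor recurrence, with the final step trimmed to exactly k
  oracle <- 30L
  repeat {
    nxt <- oracle[length(oracle)] - max(1L, as.integer(oracle[length(oracle)] * 0.2))
    oracle <- c(oracle, max(nxt, as.integer(k)))
    if (oracle[length(oracle)] <= k) break
  }
  expect_identical(res$survivor_counts, oracle)
  expect_identical(length(res$selected), as.integer(k))
})

test_that("random selection is uniform, seeded, and exhaustive at k = n", {
  features <- sprintf("m%02d", 1:20)
  expect_setequal(random_select(features, 20, seed = 1)$selected, features)
  expect_identical(random_select(features, 5, seed = 9)$selected,
                   random_select(features, 5, seed = 9)$selected)
  freq <- stats::setNames(numeric(20), features)
  for (s in 1:1000) {
    sel <- random_select(features, 5, seed = s)$selected
    freq[sel] <- freq[sel] + 1
  }
  p <- 5 / 20
  tol <- 3 * sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(freq / 1000 - p) <= tol))
})

test_that("signature overlap is the intersection size", {
  expect_identical(signature_overlap(letters[1:3], letters[1:3]), 3L)
  expect_identical(signature_overlap(letters[1:3], LETTERS[1:3]), 0L)
  expect_identical(signature_overlap(c("a", "b", "c"), c("b", "c", "d")), 2L)
})
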