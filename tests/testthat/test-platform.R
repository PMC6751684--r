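make_ref_instance <- function(seed = 5) {
  d <- generate_labeled_expression(synthetic_spec(
    n_samples = 120, n_classes = 3, class_proportions = c(0.4, 0.35, 0.25),
    n_features = 8, n_informative = 8, effect_size = 2, seed = seed))
  std <- fit_standardization(d$X)
  model <- fit_classifier("logistic_regression", apply_standardization(std, d$X),
                          d$labels$tumor_type, seed = seed)
  list(d = d, std = std, model = model)
}

test_that("mature-to-stem-loop aggregation copies the designated columns", {
  X <- expression_matrix(matrix(c(5, 7, 1, 2), 2, 2),
                         sample_ids = c("s1", "s2"),
                         feature_names = c("hsa-miR-10b", "hsa-miR-135a"))
  map <- data.frame(mature = c("hsa-miR-10b", "hsa-miR-135a", "hsa-miR-135a"),
                    stemloop = c("hsa-mir-10b", "hsa-mir-135a-1", "hsa-mir-135a-2"))
  out <- aggregate_mature_to_stemloop(X, map)
  expect_identical(colnames(out),
                   c("hsa-mir-10b", "hsa-mir-135a-1", "hsa-mir-135a-2"))
  expect_equal(unname(out[, "hsa-mir-10b"]), c(5, 7))
  # one mature sequence shared by two stem-loop loci: identical copies
  expect_identical(out[, "hsa-mir-135a-1"], out[, "hsa-mir-135a-2"],
                   ignore_attr = TRUE)
})

test_that("aggregation drops unmapped features and rejects empty overlap", {
  X <- expression_matrix(matrix(1:4, 2, 2), c("s1", "s2"),
                         c("hsa-miR-10b", "hsa-miR-unknown"))
  map <- data.frame(mature = "hsa-miR-10b", stemloop = "hsa-mir-10b")
  expect_message(out <- aggregate_mature_to_stemloop(X, map), "1 unmapped")
  expect_identical(colnames(out), "hsa-mir-10b")
  expect_error(aggregate_mature_to_stemloop(
    X, data.frame(mature = "zz", stemloop = "z")), "no overlap")
})

test_that("z-score unfolding follows X = (Z*sigma + mu) * a", {
  st <- structure(data.frame(feature = "m1", mean = 10, sd = 2),
                  class = c("reference_stats", "data.frame"))
  Z <- matrix(0, 1, 1, dimnames = list("s1", "m1"))
  expect_equal(as.numeric(zscore_to_reference(Z, st)), 10)
  Z[1] <- 1
  expect_equal(as.numeric(zscore_to_reference(Z, st, c(m1 = 3))), 36)
  # re-z-scoring with the same stats at a = 1 is the identity
  Zr <- matrix(rnorm(5), 5, 1, dimnames = list(paste0("s", 1:5), "m1"))
  X <- zscore_to_reference(Zr, st)
  expect_equal((X - 10) / 2, Zr, tolerance = 1e-12)
  # linearity: doubling a doubles X
  expect_equal(zscore_to_reference(Zr, st, c(m1 = 2)), 2 * X, tolerance = 1e-12)
  expect_error(zscore_to_reference(Zr, st, c(other = 1)), "misaligned")
})

test_that("the RMSE objective scores integer class-code disagreement", {
  lev <- c("a", "b", "c", "d", "e")
  fixed_model <- function(preds) structure(
    list(levels = lev, predict_fun = function(nd) preds),
    class = "mirsign_classifier")
  st <- structure(data.frame(feature = "m1", mean = 0, sd = 1),
                  class = c("reference_stats", "data.frame"))
  std <- fit_standardization(matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "m1")))
  Z <- matrix(0, 2, 1, dimnames = list(c("s1", "s2"), "m1"))

  expect_equal(rmse_objective(c(m1 = 1), Z, c("b", "c"),
                              fixed_model(c("b", "c")), st, std), 0)
  # predicted codes (1, 2) vs actual (1, 4): sqrt((0 + 4)/2)
  expect_equal(rmse_objective(c(m1 = 1), Z, c("b", "e"),
                              fixed_model(c("b", "c")), st, std), sqrt(2))
  expect_error(rmse_objective(c(m1 = 1), Z, c("b", "zz"),
                              fixed_model(c("b", "c")), st, std), "unseen")
})

test_that("the objective is invariant to sample order", {
  inst <- make_ref_instance(seed = 51)
  pt <- apply_platform_transform(inst$d$X, a_true = 1.3)
  y <- inst$d$labels$tumor_type
  o1 <- rmse_objective(rep(1, 8), pt$Z, y, inst$model, pt$stats, inst$std)
  perm <- sample(nrow(pt$Z))
  o2 <- rmse_objective(rep(1, 8), pt$Z[perm, ], y[perm], inst$model,
                       pt$stats, inst$std)
  expect_equal(o1, o2)
})

test_that("the simulated platform inverts exactly without noise", {
  inst <- make_ref_instance(seed = 52)
  pt <- apply_platform_transform(inst$d$X, a_true = 1, noise_sd = 0)
  back <- zscore_to_reference(pt$Z, pt$stats)
  expect_equal(back, inst$d$X, tolerance = 1e-8)
  pt2 <- apply_platform_transform(inst$d$X, a_true = 2, noise_sd = 0)
  back2 <- zscore_to_reference(pt2$Z, pt2$stats,
                               stats::setNames(rep(2, 8), colnames(inst$d$X)))
  expect_equal(back2, inst$d$X, tolerance = 1e-8)
})

test_that("platform round-trip error grows with the noise level", {
  inst <- make_ref_instance(seed = 53)
  errs <- vapply(c(0.1, 0.5, 1.5), function(ns) {
    e <- 0
    for (s in 1:3) {
      pt <- apply_platform_transform(inst$d$X, a_true = 1, noise_sd = ns, seed = s)
      e <- e + mean(abs(zscore_to_reference(pt$Z, pt$stats) - inst$d$X))
    }
    e / 3
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("scale fitting never worsens the objective and is seed-stable", {
  inst <- make_ref_instance(seed = 54)
  a_true <- seq(0.6, 1.8, length.out = 8)
  pt <- apply_platform_transform(inst$d$X, a_true = a_true, noise_sd = 0)
  fit <- fit_platform_scale(pt$Z, inst$d$labels$tumor_type, inst$model,
                            pt$stats, inst$std, budget = 400, seed = 9)
  expect_lte(fit$final_objective, fit$initial_objective)
  expect_lte(fit$evaluations, 400)
  fit2 <- fit_platform_scale(pt$Z, inst$d$labels$tumor_type, inst$model,
                             pt$stats, inst$std, budget = 400, seed = 9)
  expect_identical(fit$a, fit2$a)
  # self-map: external data drawn at a_true = 1 stays near 1
  pt1 <- apply_platform_transform(inst$d$X, a_true = 1, noise_sd = 0)
  fit1 <- fit_platform_scale(pt1$Z, inst$d$labels$tumor_type, inst$model,
                             pt1$stats, inst$std, budget = 400, seed = 9)
  expect_lte(fit1$final_objective, fit1$initial_objective)
  expect_lte(median(abs(fit1$a$a - 1)), 0.10)
})

test_that("platform tables round-trip through TSV", {
  map <- data.frame(mature = c("hsa-miR-10b", "hsa-miR-21"),
                    stemloop = c("hsa-mir-10b", "hsa-mir-21"))
  st <- structure(data.frame(feature = c("a", "b"), mean = c(1, 2),
                             sd = c(0.5, 1.5)),
                  class = c("reference_stats", "data.frame"))
  scale <- structure(list(a = data.frame(feature = c("a", "b"), a = c(1.2, 0.8)),
                          evaluations = 10L, initial_objective = 1,
                          final_objective = 0.5, seed = 1L),
                     class = "platform_scale")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_platform_tsv(map, path)
  expect_identical(read_mature_map_tsv(path), map)
  write_platform_tsv(st, path)
  expect_equal(as.data.frame(read_reference_stats_tsv(path)), as.data.frame(st))
  write_platform_tsv(scale, path)
  expect_equal(read_platform_scale_tsv(path)$a, scale$a)
})
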