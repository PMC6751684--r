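test_that("top-k tallies count list membership", {
  lists <- list(c("f1", "f2"), c("f2", "f3"), c("f2", "f1"))
  expect_equal(tally_top_k(lists, 2, c("f1", "f2", "f3")),
               c(f1 = 2L, f2 = 3L, f3 = 1L))
  expect_equal(tally_top_k(lists, 1, c("f1", "f2", "f3")),
               c(f1 = 1L, f2 = 2L, f3 = 0L))
  expect_error(tally_top_k(lists, 2, c("f1", "f2")), "unknown")
})

test_that("tallies agree with a brute-force oracle and conserve mass", {
  set.seed(11)
  for (i in 1:200) {
    p <- sample(2:10, 1)
    features <- sprintf("g%02d", seq_len(p))
    n_lists <- sample(1:8, 1)
    lists <- replicate(n_lists, sample(features), simplify = FALSE)
    k <- sample(1:p, 1)
    tally <- tally_top_k(lists, k, features)
    oracle <- vapply(features, function(f)
      sum(vapply(lists, function(l) f %in% l[seq_len(min(k, length(l)))],
                 logical(1))), integer(1))
    expect_equal(tally, oracle)
    expect_identical(sum(tally), as.integer(k * n_lists))
  }
})

test_that("consensus scores are the exact tally fraction", {
  tab <- consensus_scores(c(f = 73L), 100L)
  expect_identical(tab$s_f, 0.73)
  expect_identical(consensus_scores(c(f = 5L), 5L)$s_f, 1)
  expect_identical(consensus_scores(c(f = 0L), 5L)$s_f, 0)
  expect_error(consensus_scores(c(f = 6L), 5L), "N_t <= N_c")
})

test_that("signature selection orders by score with the stated tie rule", {
  tab <- consensus_scores(c(a = 9L, b = 5L, c = 5L, d = 1L), 10L)
  sig <- select_signature(tab, 2)
  expect_identical(sig$feature, c("a", "b"))
  full <- select_signature(tab, 4)
  expect_identical(full$feature, c("a", "b", "c", "d"))
  # property: s_f is monotone non-increasing along any signature
  set.seed(13)
  for (i in 1:50) {
    N_c <- sample(2:20, 1)
    tally <- stats::setNames(sample(0:N_c, 12, replace = TRUE),
                             sprintf("m%02d", 1:12))
    sig <- select_signature(consensus_scores(tally, N_c), sample(1:12, 1))
    expect_true(all(diff(sig$s_f) <= 0))
    expect_identical(sig$s_f, sort(tally, decreasing = TRUE)[seq_len(nrow(sig))] / N_c,
                     ignore_attr = TRUE)
  }
})

test_that("an ensemble of one instance reduces to ranking its importance vector", {
  d <- tiny_two_class(n_per_class = 15, n_noise = 4, seed = 21)
  cfg <- ensemble_config(classifier_families = "ridge", n_runs = 1,
                         n_folds = 3, top_k_tally = 3, signature_size = 3,
                         seed = 17)
  res <- run_ensemble_selection(d$X, d$y, cfg)
  expect_identical(res$report$N_c, 1L)
  # the signature is exactly the instance's top-k (ordering within the
  # signature falls back to the name tie rule because all scores are 1)
  expect_setequal(res$signature$feature, as.character(res$ranked_lists[[1]]))
  expect_true(all(res$signature$s_f == 1))
  # the separating feature is ranked first by the instance
  expect_identical(as.character(res$ranked_lists[[1]])[1], "f1")
})

test_that("feature tallies ignore features absent from every top-k list", {
  lists <- list(c("a", "b"), c("b", "a"))
  with_c <- select_signature(consensus_scores(tally_top_k(lists, 2, c("a", "b", "c")), 2L), 2)
  without_c <- select_signature(consensus_scores(tally_top_k(lists, 2, c("a", "b")), 2L), 2)
  expect_identical(with_c$feature, without_c$feature)
})

test_that("ensemble selection is deterministic given the seed", {
  d <- tiny_two_class(n_per_class = 15, n_noise = 4, seed = 22)
  cfg <- ensemble_config(classifier_families = c("ridge", "sgd_linear"),
                         n_runs = 2, n_folds = 3, top_k_tally = 3,
                         signature_size = 3, seed = 99)
  r1 <- run_ensemble_selection(d$X, d$y, cfg)
  r2 <- run_ensemble_selection(d$X, d$y, cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$signature, r2$signature)
  path1 <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_signature_tsv(r1$signature, path1)
  write_signature_tsv(r2$signature, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("a failing family is skipped with a warning and N_c decremented", {
  d <- tiny_two_class(n_per_class = 10, n_noise = 2, seed = 23)
  fitters <- list(ridge = function(X, y, params, seed) stop("no convergence"),
                  sgd_linear = stub_fitter)
  cfg <- ensemble_config(classifier_families = c("ridge", "sgd_linear"),
                         n_runs = 1, n_folds = 2, top_k_tally = 2,
                         signature_size = 2, seed = 1)
  expect_warning(res <- run_ensemble_selection(d$X, d$y, cfg, fitters = fitters),
                 "skipped")
  expect_identical(res$report$N_c, 1L)
  expect_identical(sum(res$report$instance_status$status == "ok"), 1L)
})

test_that("signature TSV round-trips with its N_c header", {
  tab <- consensus_scores(c(a = 3L, b = 1L), 4L)
  sig <- select_signature(tab, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, path)
  back <- read_signature_tsv(path)
  expect_identical(back$feature, sig$feature)
  expect_identical(attr(back, "N_c"), 4L)
})
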