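test_that("FG detection, exact model: subset-sum criterion", {
  fg <- find_first_generation_trees(wex_signal())
  expect_equal(fg_keys(fg), c("1;2,4", "3;5,6"))
  expect_equal(fg_keys(fg), fg_scan(wex_signal(), error_model("exact")))

  s <- aggregate_signal(c(1, 0.4), labels = c("d", "a"))
  expect_length(find_first_generation_trees(s), 0)
})

test_that("FG detection, bound model: additive allowance", {
  s <- wex_signal(eps = 0.02)
  fg <- find_first_generation_trees(s, error_model("bound"))
  # the full set must equal an independent exhaustive scan of all
  # (parent, subset) pairs under the same inclusive criterion
  expect_equal(fg_keys(fg), fg_scan(s, error_model("bound")))
  # and contain the nine reference trees (a tenth, (2;{3,5,6}), sits exactly
  # on the allowance boundary: |0.72 - 0.80| = 4 * 0.02)
  ref9 <- c("1;2,4", "1;2,5", "1;3,4,5", "1;3,4,5,6", "2;3,4",
            "2;4,5,6", "3;4,6", "3;5,6", "4;5")
  expect_true(all(ref9 %in% fg_keys(fg)))
  expect_true("2;3,5,6" %in% fg_keys(fg))
  expect_length(fg, 10)
})

test_that("FG detection is monotone in eps under the bound model", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(3:7, 1)
    s <- random_generic_signal(n)
    for (e in c(0.01, 0.03)) {
      small <- aggregate_signal(s$y, rep(e, n), s$labels)
      big <- aggregate_signal(s$y, rep(2 * e, n), s$labels)
      f1 <- fg_keys(find_first_generation_trees(small, error_model("bound")))
      f2 <- fg_keys(find_first_generation_trees(big, error_model("bound")))
      expect_true(all(f1 %in% f2))
    }
  }
})

test_that("FG detection refuses oversized signals", {
  y <- c(1, sort(stats::runif(26), decreasing = TRUE))
  s <- aggregate_signal(y, labels = c("dummy", sprintf("x%02d", 1:26)))
  expect_error(find_first_generation_trees(s), class = "decon_cap_error")
})

test_that("combine_partial_trees finds maximum compatible collections", {
  fg <- find_first_generation_trees(wex_signal())
  pt <- combine_partial_trees(fg)
  expect_length(pt, 1)
  expect_equal(pt[[1]]$h, 2L)
  expect_equal(fg_keys(pt[[1]]$fg), c("1;2,4", "3;5,6"))

  fgb <- find_first_generation_trees(wex_signal(0.02), error_model("bound"))
  ptb <- combine_partial_trees(fgb)
  expect_true(all(vapply(ptb, `[[`, integer(1), "h") == 2L))
  keys <- vapply(ptb, function(p) paste(fg_keys(p$fg), collapse = " "),
                 character(1))
  expect_true("1;2,4 3;5,6" %in% keys)
  expect_true("1;2,5 3;4,6" %in% keys)

  empty <- combine_partial_trees(list())
  expect_length(empty, 1)
  expect_equal(empty[[1]]$h, 0L)
})

test_that("enumeration grows partial trees into full trees", {
  pt <- combine_partial_trees(find_first_generation_trees(wex_signal()))[[1]]
  trees <- enumerate_solutions(wex_signal(), pt)
  expect_length(trees, 1)
  expect_equal(tree_key(trees[[1]]), tree_key(wex_parent))

  s <- aggregate_signal(c(1, 0.6, 0.4), labels = c("d", "a", "b"))
  t1 <- enumerate_solutions(s, list(fg = list(list(parent = 1L,
                                                   children = c(2L, 3L))),
                                    h = 1L))
  expect_length(t1, 1)
  expect_equal(tree_key(t1[[1]]), "0,1,1")

  # empty partial tree: the star would force x[1] = 0 at a non-FG clone
  t0 <- enumerate_solutions(s, list(fg = list(), h = 0L))
  expect_length(t0, 1)
  expect_equal(tree_key(t0[[1]]), "0,1,2")
  expect_equal(clone_frequencies(clone_tree(t0[[1]]), s), c(0.4, 0.2, 0.4))
})

test_that("enumeration honors ancestor and exclusivity constraints", {
  s <- aggregate_signal(c(1, 0.4, 0.3, 0.2),
                        labels = c("d", "a", "b", "c"))
  all_trees <- enumerate_solutions(s, list(fg = list(), h = 0L))
  anc <- enumerate_solutions(s, list(fg = list(), h = 0L),
                             constraint_set(ancestor = c(2, 4)))
  expect_true(length(anc) < length(all_trees))
  for (par in anc) {
    tree <- clone_tree(par)
    expect_true(2L %in% clone_ancestors(tree, 4L))
  }
  exc <- enumerate_solutions(s, list(fg = list(), h = 0L),
                             constraint_set(exclusive = c(2, 3)))
  for (par in exc) {
    tree <- clone_tree(par)
    expect_false(2L %in% clone_ancestors(tree, 3L))
    expect_false(3L %in% clone_ancestors(tree, 2L))
  }
  # impossible ancestor direction: descendant index below ancestor
  none <- enumerate_solutions(s, list(fg = list(), h = 0L),
                              constraint_set(ancestor = c(4, 2)))
  expect_length(none, 0)
})

test_that("fit_frequencies_nnls reproduces back-substitution and clamps", {
  fit <- fit_frequencies_nnls(wex_signal(), clone_tree(wex_parent),
                              unpopulated = c(1L, 3L))
  expect_equal(fit$x, wex_x, tolerance = 1e-9)
  expect_equal(fit$residual, 0, tolerance = 1e-9)

  y2 <- c(1, 0.73, 0.40, 0.28, 0.25, 0.15)
  s2 <- aggregate_signal(y2, eps = rep(0.02, 6), labels = wex_signal()$labels)
  fit2 <- fit_frequencies_nnls(s2, clone_tree(wex_parent),
                               unpopulated = c(1L, 3L))
  expect_true(all(fit2$x >= 0))
  expect_equal(fit2$x[c(1, 3)], c(0, 0))
  expect_lte(fit2$residual, 0.01 + 1e-9)

  s3 <- aggregate_signal(c(1, 1), labels = c("d", "a"))
  fit3 <- fit_frequencies_nnls(s3, clone_tree(c(NA, 1L)), unpopulated = 1L)
  expect_equal(fit3$x, c(0, 1))
})

test_that("deconvolve orchestrates the five steps", {
  r0 <- deconvolve(aggregate_signal(1, labels = "dummy"))
  expect_length(r0$solutions, 1)
  expect_equal(r0$solutions[[1]]$x, 1)
  expect_equal(r0$solutions[[1]]$populated, 1L)
  expect_equal(r0$solutions[[1]]$depth, 0L)

  r <- deconvolve(wex_signal())
  expect_length(r$solutions, 1)
  s <- r$solutions[[1]]
  expect_equal(tree_key(s$tree$parent), tree_key(wex_parent))
  expect_equal(s$x, wex_x, tolerance = 1e-9)
  expect_equal(s$populated, 4L)
  expect_equal(s$depth, 3L)

  rb <- deconvolve(wex_signal(0.02), error_model("bound"))
  expect_gt(length(rb$solutions), 1)
  expect_true(all(vapply(rb$solutions, `[[`, integer(1), "populated") == 4L))
  for (sol in rb$solutions) expect_true(all(sol$x >= 0))
})

test_that("deconvolve enforces the size cap with guidance", {
  y <- c(1, sort(stats::runif(26), decreasing = TRUE))
  s <- aggregate_signal(y, labels = c("dummy", sprintf("x%02d", 1:26)))
  expect_error(deconvolve(s), regexp = "cluster", class = "decon_cap_error")
})

test_that("solver solutions satisfy the structural invariants", {
  set.seed(77)
  for (r in 1:40) {
    n <- sample(2:8, 1)
    truth <- simulate_clone_tree(n, sample(seq_len(n), 1), max_attempts = 5000)
    res <- deconvolve(truth$signal)
    expect_lte(length(res$candidates), factorial(n - 1))
    for (sol in res$solutions) {
      expect_true(all(sol$x >= 0))
      expect_equal(sum(sol$x), 1, tolerance = 1e-9)
      expect_equal(sum(sol$x <= 1e-9), res$h_star)
    }
  }
})

test_that("noise-free planted solutions are always recovered when sparsest", {
  set.seed(88)
  for (r in 1:60) {
    n <- sample(3:9, 1)
    p <- sample(seq_len(max(1, ceiling(n / 2))), 1)
    truth <- tryCatch(simulate_clone_tree(n, p, max_attempts = 5000),
                      decon_input_error = function(e) NULL)
    if (is.null(truth)) next
    res <- deconvolve(truth$signal)
    # the truth's populated count is n - h*; its tree must appear among the
    # enumerated minimal-P candidates
    expect_equal(truth$p, res$p_min)
    expect_true(tree_key(truth$tree$parent) %in% sol_keys(res$candidates))
  }
})

test_that("rescoring hook reorders candidates", {
  s <- aggregate_signal(c(1, 0.6, 0.4), labels = c("d", "a", "b"))
  # prefer DEEP trees, against the default shallowness ranking
  r <- deconvolve(s, rescore = function(sol, sig) -sol$depth)
  expect_equal(r$solutions[[1]]$depth,
               max(vapply(r$candidates, `[[`, integer(1), "depth")))
})
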