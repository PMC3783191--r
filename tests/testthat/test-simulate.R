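test_that("simulate_clone_tree plants a valid sparse truth", {
  t1 <- simulate_clone_tree(1)
  expect_equal(t1$x, 1)
  expect_equal(t1$signal$y, 1)

  set.seed(5)
  t5 <- simulate_clone_tree(5, 5)
  expect_true(all(t5$x > 0))
  expect_equal(t5$p, 5L)

  set.seed(9)
  for (r in 1:30) {
    n <- sample(2:9, 1)
    p <- sample(seq_len(n), 1)
    tr <- tryCatch(simulate_clone_tree(n, p, max_attempts = 5000),
                   decon_input_error = function(e) NULL)
    if (is.null(tr)) next
    expect_equal(sum(tr$x), 1, tolerance = 1e-12)
    expect_equal(sum(tr$x > 0), p)
    # leaves are always populated
    leaves <- which(lengths(tr$tree$children) == 0L)
    expect_true(all(tr$x[leaves] > 0))
    # sorted-aggregate invariants hold after remapping
    expect_s3_class(tr$signal, "aggregate_signal")
    expect_equal(tr$y_clean,
                 aggregate_from_solution(genotype_matrix(tr$tree), tr$x))
    expect_false(is.unsorted(rev(tr$y_clean)))
  }

  expect_error(simulate_clone_tree(5, 0), class = "decon_input_error")
})

test_that("simulate_clone_tree is reproducible under a fixed seed", {
  set.seed(42)
  a <- simulate_clone_tree(6, 4)
  set.seed(42)
  b <- simulate_clone_tree(6, 4)
  expect_identical(a$tree$parent, b$tree$parent)
  expect_identical(a$x, b$x)
  expect_identical(a$signal$labels, b$signal$labels)
})

test_that("perturb_signal adds clipped uniform noise off the dummy", {
  y <- c(1, 0.6, 0.4)
  expect_equal(perturb_signal(y, 0)$y, y)
  expect_equal(perturb_signal(y, 0)$eps, c(0, 0, 0))

  set.seed(10)
  E <- 0.05
  shift <- replicate(10000, perturb_signal(y, E)$y[2] - y[2])
  expect_lt(abs(mean(shift)), 0.002)
  expect_true(all(abs(shift) <= E))

  set.seed(11)
  low <- replicate(200, perturb_signal(c(1, 0.01), E)$y[2])
  expect_true(all(low >= 0 & low <= 0.06))
  p <- perturb_signal(y, E)
  expect_equal(p$y[1], 1)
  expect_equal(p$eps, c(0, E, E))
})

test_that("mix_genotypes forward-simulates a bulk measurement", {
  G <- matrix(c(1, 0, 1, 1), nrow = 2,
              dimnames = list(c("a2", "a3"), c("S1", "S2")))
  mx <- mix_genotypes(G, weights = c(0.5, 0.3, 0.2))
  expect_equal(mx$signal$y, c(1, 0.8, 0.3))
  expect_equal(mx$signal$labels, c("dummy", "a2", "a3"))
  expect_equal(unname(mx$weights), c(0.5, 0.3, 0.2))

  # weights summing to 1 with no wildtype: populated x sums to 1
  G2 <- matrix(c(1, 0, 0, 1), nrow = 2,
               dimnames = list(c("a2", "a3"), c("S1", "S2")))
  mx2 <- mix_genotypes(G2, weights = c(0.6, 0.4), include_wildtype = FALSE)
  res2 <- deconvolve(mx2$signal)
  expect_equal(sum(res2$solutions[[1]]$x), 1, tolerance = 1e-9)
  expect_equal(res2$solutions[[1]]$x[1], 0)

  Gz <- cbind(G, S3 = c(0, 0))
  expect_error(mix_genotypes(Gz), class = "decon_input_error")
})

test_that("evaluate_run scores truth recovery", {
  # noise-free planted WEX-like runs: (TRUE, TRUE, TRUE) when unique
  set.seed(12)
  tr <- simulate_clone_tree(6, 4, max_attempts = 5000)
  inst <- noisy_instance(tr, 0)
  res <- deconvolve(inst$signal)
  ev <- evaluate_run(inst, res)
  expect_true(ev["sparsest"])
  if (length(res$solutions) == 1L) expect_true(ev["unique"])

  # star truth against the chain alternative on y = (1, .6, .4)
  star <- list(
    signal = aggregate_signal(c(1, 0.6, 0.4), labels = c("dummy", "a", "b")),
    truth_parent = c(NA, 1L, 1L), truth_x = c(0, 0.6, 0.4),
    truth_genotypes = list("a", "b"), truth_w = c(0.6, 0.4))
  resS <- deconvolve(star$signal)
  expect_equal(unname(evaluate_run(star, resS)), c(TRUE, TRUE, TRUE))

  # a maximally populated truth loses the sparsity race when an FG tree exists
  chain <- list(
    signal = star$signal,
    truth_parent = c(NA, 1L, 2L), truth_x = c(0.4, 0.2, 0.4),
    truth_genotypes = list(character(0), "a", c("a", "b")),
    truth_w = c(0.4, 0.2, 0.4))
  evC <- evaluate_run(chain, resS)
  expect_false(evC["sparsest"])
  expect_false(evC["in_solutions"])
})

test_that("recovery_check enforces genotypes and proportions", {
  G <- matrix(c(1, 0, 1, 1), nrow = 2,
              dimnames = list(c("a2", "a3"), c("S1", "S2")))
  mx <- mix_genotypes(G, weights = c(0.5, 0.3, 0.2))
  res <- deconvolve(mx$signal)
  expect_true(recovery_check(res, G, mx$weights, tol = 1e-9))

  # one missing subclone
  G3 <- cbind(G, S3 = c(0, 1))
  expect_false(recovery_check(res, G3, c(S1 = 0.5, S2 = 0.3, S3 = 0.1,
                                         wildtype = 0.1)))

  # threshold semantics: weights off by 0.02
  w_off <- mx$weights + c(0.02, -0.02, 0)
  expect_false(recovery_check(res, G, w_off, tol = 0.01))
  expect_true(recovery_check(res, G, w_off, tol = 0.05))
})

test_that("cooccurrence_fraction counts confirmed pairs", {
  s <- aggregate_signal(c(1, 0.6, 0.55, 0.4), labels = c("dummy", "a", "b", "c"))
  sol <- clone_solution(clone_tree(c(NA, 1L, 2L, 1L)),
                        x = c(0, 0.2, 0.55, 0.4), signal = s)
  expect_equal(cooccurrence_fraction(sol, list(c("a", "b"), "c")), 1.0)

  s2 <- aggregate_signal(c(1, 0.5, 0.5, 0.5), labels = c("dummy", "a", "b", "c"))
  solo <- clone_solution(clone_tree(c(NA, 1L, 2L, 3L)),
                         x = c(0.5, 0, 0, 0.5), signal = s2)
  expect_equal(cooccurrence_fraction(solo, list(c("a", "b"), c("b", "c"))),
               2 / 3)
  expect_warning(f0 <- cooccurrence_fraction(solo, list()), "empty")
  expect_equal(f0, 0)

  single <- clone_solution(clone_tree(c(NA, 1L)), x = c(0.5, 0.5),
                           signal = aggregate_signal(c(1, 0.5),
                                                     labels = c("dummy", "a")))
  out <- cooccurrence_fraction(single, list(c("a", "b")))
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("benchmark_grid is reproducible and degenerate at runs = 1", {
  g1 <- benchmark_grid(5, 2, 0, runs = 1, seed = 99)
  expect_true(all(unlist(g1[, 5:7]) %in% c(0, 100)))

  a <- benchmark_grid(c(4, 5), 2, c(0, 0.01), runs = 5, seed = 123)
  b <- benchmark_grid(c(4, 5), 2, c(0, 0.01), runs = 5, seed = 123)
  expect_identical(a, b)

  # noise-free sparse regime: always recovered; membership >= uniqueness
  g <- benchmark_grid(c(5, 6), 2, 0, runs = 20, seed = 7)
  expect_true(all(g$pct_in_solutions == 100))
  expect_true(all(g$pct_in_solutions >= g$pct_unique))
})
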