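test_that("expand_polyallelic emits the phasing hypotheses", {
  s1 <- multiallelic_site("101", "A", data.frame(allele = "G", freq = 0.3))
  red1 <- expand_polyallelic(list(s1))
  expect_length(red1, 1)
  expect_equal(red1[[1]]$events$label, "101:A>G")
  expect_equal(red1[[1]]$events$y, 0.3)
  expect_null(red1[[1]]$ancestor)
  expect_null(red1[[1]]$exclusive)

  s2 <- multiallelic_site("170", "A",
                          data.frame(allele = c("G", "C"), freq = c(0.3, 0.2)))
  red2 <- expand_polyallelic(list(s2))
  expect_length(red2, 3)
  hyp <- vapply(red2, `[[`, character(1), "hypothesis")
  gfirst <- red2[[which(hyp == "170:A>G>C")]]
  expect_equal(gfirst$events$y[match(c("170:A>G", "170:A>G>C"),
                                     gfirst$events$label)],
               c(0.5, 0.2))
  expect_equal(unname(gfirst$ancestor[1, ]), c("170:A>G", "170:A>G>C"))
  par <- red2[[which(hyp == "170:A>C|A>G")]]
  expect_equal(sort(par$events$y), c(0.2, 0.3))
  expect_equal(nrow(par$exclusive), 1)

  # two biallelic sites: 3 x 3 combinations
  s3 <- multiallelic_site("200", "T",
                          data.frame(allele = c("A", "G"), freq = c(0.1, 0.1)))
  expect_length(expand_polyallelic(list(s2, s3)), 9)

  # declared chain prunes to the matching serial hypothesis
  s4 <- multiallelic_site("170", "A",
                          data.frame(allele = c("G", "C"), freq = c(0.3, 0.2)),
                          known_chains = "A>G>C")
  expect_length(expand_polyallelic(list(s4)), 1)

  # hypothesis cap
  many <- lapply(1:7, function(i)
    multiallelic_site(paste0("p", i), "A",
                      data.frame(allele = c("G", "C"), freq = c(0.1, 0.1))))
  expect_error(expand_polyallelic(many), class = "decon_cap_error")
})

test_that("a three-allele site enumerates 13 chain arrangements", {
  s <- multiallelic_site("5", "A",
                         data.frame(allele = c("C", "G", "T"),
                                    freq = c(0.2, 0.15, 0.1)))
  expect_length(expand_polyallelic(list(s)), 13)
})

test_that("SHM-style serial chain: unique sparsest solution, conservation", {
  # planted truth: wildtype 0.55; S1 = {170 A>G, b1, b4} at 0.25;
  # S2 = S1's descendant {170 A>G>C, b2} at 0.20; phasing known from reads
  site <- multiallelic_site("170", "A",
                            data.frame(allele = c("G", "C"),
                                       freq = c(0.25, 0.20)),
                            known_chains = "A>G>C")
  bin <- data.frame(label = c("b1", "b4", "b2"), y = c(0.45, 0.25, 0.20))
  nb <- solve_nonbinary(list(site), bin)
  expect_length(nb$best, 1)
  expect_equal(nb$runs[[nb$best]]$hypothesis, "170:A>G>C")
  expect_length(nb$solutions, 1)
  sol <- nb$solutions[[1]]
  expect_equal(sol$populated, 3L)
  gt <- populated_genotypes(sol)
  keys <- sort(unname(vapply(gt, paste, character(1), collapse = "+")))
  expect_equal(keys, c("", "170:A>G+170:A>G>C+b1+b2", "170:A>G+b1+b4"))
  ww <- vapply(names(gt), function(j) sol$x[as.integer(j)], numeric(1))
  expect_equal(sort(unname(ww)), c(0.20, 0.25, 0.55), tolerance = 1e-9)

  # allele-frequency conservation: clones carrying the downstream event sum
  # to the C-allele frequency; G-event-only clones to the G-allele frequency
  iG <- match("170:A>G", sol$labels)
  iC <- match("170:A>G>C", sol$labels)
  expect_equal(sum(sol$x[sol$C[iC, ] == 1]), 0.20, tolerance = 1e-9)
  expect_equal(sum(sol$x[sol$C[iG, ] == 1 & sol$C[iC, ] == 0]), 0.25,
               tolerance = 1e-9)
})

test_that("parallel truth: the parallel hypothesis wins the ranking", {
  # truth: two sibling lineages S1 = {A>G, u1} (0.3), S2 = {A>C, v1} (0.25)
  site <- multiallelic_site("170", "A",
                            data.frame(allele = c("G", "C"),
                                       freq = c(0.3, 0.25)))
  bin <- data.frame(label = c("u1", "v1"), y = c(0.3, 0.25))
  nb <- solve_nonbinary(list(site), bin)
  expect_length(nb$best, 1)
  expect_equal(nb$runs[[nb$best]]$hypothesis, "170:A>C|A>G")
  # the winning solution keeps the two alleles on separate branches
  sol <- nb$solutions[[1]]
  iG <- match("170:A>G", sol$labels)
  iC <- match("170:A>C", sol$labels)
  expect_true(all(sol$C[iG, ] + sol$C[iC, ] <= 1))
})

test_that("without polyallelic sites the pipeline equals the binary path", {
  recs <- data.frame(label = c("a2", "a3"), y = c(0.6, 0.4))
  nb <- solve_nonbinary(list(), recs)
  direct <- deconvolve(build_signal(recs))
  expect_equal(sol_keys(nb$solutions), sol_keys(direct$solutions))
  expect_equal(nb$solutions[[1]]$x, direct$solutions[[1]]$x)
})

test_that("reduction count multiplies per-site hypothesis counts", {
  mono <- multiallelic_site("9", "C", data.frame(allele = "T", freq = 0.4))
  bi <- multiallelic_site("7", "G",
                          data.frame(allele = c("A", "T"), freq = c(0.2, 0.1)))
  expect_length(expand_polyallelic(list(mono)), 1)
  expect_length(expand_polyallelic(list(mono, bi)), 3)
  expect_length(expand_polyallelic(list(bi, bi)), 9)
})
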