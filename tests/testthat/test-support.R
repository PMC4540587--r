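test_that("placement candidates cover every attachment branch of the region", {
  backbone <- ape::read.tree(text = "(((A,B),(C,D)),M);")
  # whole backbone as region: 6 branches of the pruned 4-leaf tree + new root
  cands <- placement_candidates(backbone, "M")
  expect_length(cands, 7L)
  expect_true(all(vapply(cands, function(tr) setequal(tr$tip.label,
                                                      backbone$tip.label),
                         logical(1))))
  # single-branch region -> a single candidate
  one <- placement_candidates(backbone, "M", region = c("A"))
  expect_length(one, 1L)
  expect_identical(names(one), "sister_to:A")
  # region = one cherry: its two tip branches + the cherry branch
  cherry <- placement_candidates(backbone, "M", region = c("A", "B"))
  expect_length(cherry, 3L)
  expect_error(placement_candidates(backbone, "X"), "absent")
})

test_that("clean synapomorphies support exactly their generating placement", {
  backbone <- ape::read.tree(text = "(((A,B),(C,D)),M);")
  cands <- placement_candidates(backbone, "M")
  # markers built as synapomorphies of {M, C, D}: M sister to the (C,D) cherry
  target <- "sister_to:C+D"
  states <- do.call(rbind, replicate(5, c(A = "0", B = "0", C = "1", D = "1",
                                          M = "1"), simplify = FALSE))
  m <- pa_matrix(states)
  prof <- support_counts(m, cands)
  expect_identical(prof$n_support[prof$candidate == target], 5L)
  expect_identical(sum(prof$n_support), 5L)
  expect_identical(prof$candidate[1], target) # descending order
  # a marker with '?' in a discriminating taxon counts for no placement
  amb <- pa_matrix(rbind(c(A = "0", B = "0", C = "?", D = "1", M = "1")))
  expect_identical(sum(support_counts(amb, cands)$n_support), 0L)
  # support never exceeds the number of markers
  expect_lte(sum(prof$n_support), nrow(m))
})

test_that("the best placement recovers the generating tree on clean data", {
  gen <- ape::read.tree(text = "((((A,B),M),C),D);")
  m <- clade_markers(gen, copies = 3)
  backbone <- gen # candidates re-attach M everywhere, including its true branch
  cands <- placement_candidates(backbone, "M")
  prof <- support_counts(m, cands)
  expect_identical(prof$candidate[1], "sister_to:A+B")
})

test_that("hybridization flag formalises over-representation among alternatives", {
  # profile shaped like the mousebird analysis: strong best, near-symmetric rest
  mousebird_like <- c(best = 29, a1 = 11, a2 = 9, a3 = 7, a4 = 5, a5 = 4, a6 = 2)
  res <- hybridization_check(mousebird_like)
  expect_false(res$flag)
  expect_identical(res$method, "exact multinomial")
  expect_gt(res$p_value, 0.05)
  # gross asymmetry among the non-best candidates
  asym <- c(best = 50, a1 = 48, a2 = 1, a3 = 1, a4 = 1, a5 = 1)
  res2 <- hybridization_check(asym)
  expect_true(res2$flag)
  expect_lt(res2$p_value, 1e-6)
  # exact uniformity cannot be flagged
  flat <- c(best = 10, a1 = 2, a2 = 2, a3 = 2, a4 = 2, a5 = 2, a6 = 2)
  res3 <- hybridization_check(flat)
  expect_false(res3$flag)
  expect_equal(res3$p_value, 1)
  expect_error(hybridization_check(c(3, 4)), "at least 3")
  expect_error(hybridization_check(c(0, 0, 0)), "zero")
})

test_that("exact multinomial p-value matches direct enumeration on a tiny case", {
  # oracle: full outcome enumeration over 3 cells, n = 4
  obs <- c(3L, 1L, 0L)
  oracle <- local({
    outs <- expand.grid(a = 0:4, b = 0:4, c = 0:4)
    outs <- outs[rowSums(outs) == 4, ]
    pr <- apply(outs, 1, function(o) dmultinom(o, prob = rep(1 / 3, 3)))
    p_obs <- dmultinom(obs, prob = rep(1 / 3, 3))
    sum(pr[pr <= p_obs + 1e-12])
  })
  expect_equal(retroils:::exact_multinomial_p(obs), oracle, tolerance = 1e-10)
})

test_that("the symmetry test holds its nominal size under a uniform null", {
  set.seed(2026)
  n_rep <- 2000
  alpha <- 0.05
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    counts <- c(40, as.vector(stats::rmultinom(1, 300, rep(1 / 6, 6))))
    names(counts) <- c("best", paste0("a", 1:6))
    counts["best"] <- max(counts) + 1 # keep the best cell out of the test
    res <- hybridization_check(counts, alpha = alpha)
    if (res$flag) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  mc_se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lte(rate, alpha + 3 * mc_se)
})
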