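test_that("ILS duration counts independently sorting lineages minus one", {
  t5 <- t5_ladder()
  cf <- map_character(t5, c(A = "1", B = "1", C = "0", D = "0", E = "0"))
  expect_identical(ils_duration(cf), 0L)
  weak <- map_character(t5, c(A = "1", B = "0", C = "1", D = "0", E = "0"))
  expect_identical(ils_duration(weak), 2L) # three independently sorting lineages
  # a pattern sorting independently in 18 lineages persists across 17 events
  L18 <- caterpillar_tree(paste0("l", 1:18))
  # presence in the deepest lineage keeps the origin at the root, so all 18
  # lineages sort independently
  alt <- setNames(as.character(rep(c(0, 1), 9)), paste0("l", 1:18))
  m18 <- map_character(L18, alt)
  expect_identical(m18$fixations_to_1 + m18$fixations_to_0, 18L)
  expect_identical(ils_duration(m18), 17L)
  empty <- map_character(t5, c(A = "0", B = "0", C = "0", D = "0", E = "0"))
  expect_error(ils_duration(empty), "all-absent")
})

test_that("branch summary attributes markers to origin branches", {
  t5 <- t5_ladder()
  # 4 markers originating above MRCA(A,B): 3 clean, 1 ILS-affected
  ab_clean <- c(A = "1", B = "1", C = "0", D = "0", E = "0")
  states <- rbind(ab_clean, ab_clean, ab_clean,
                  c(A = "1", B = "0", C = "1", D = "0", E = "0"))
  colnames(states) <- names(ab_clean)
  m <- pa_matrix(states, marker_id = sprintf("b%d", 1:4))
  bs <- branch_summary(m, t5)
  mrca_ab <- ape::getMRCA(t5, c("A", "B"))
  mrca_abc <- ape::getMRCA(t5, c("A", "B", "C"))
  row_ab <- bs[bs$branch == mrca_ab, ]
  row_abc <- bs[bs$branch == mrca_abc, ]
  expect_identical(row_ab$conflict_free, 3L)
  expect_identical(row_abc$ils_2, 1L)
  expect_equal(row_abc$pct_ils, 100)
  # branches with no originating markers report NA, not 0
  expect_true(is.na(bs$pct_ils[bs$branch == 1])) # tip branch of A
  # conservation: totals over branches = informative markers
  expect_identical(sum(bs$total_markers), 4L)
  # a single origin branch carrying 4 markers of which one is ILS-affected
  states2 <- rbind(ab_clean, ab_clean, ab_clean,
                   c(A = "1", B = "0", C = "1", D = "?", E = "0"))
  colnames(states2) <- names(ab_clean)
  m2 <- pa_matrix(states2, marker_id = sprintf("c%d", 1:4))
  bs2 <- branch_summary(m2, t5)
  expect_true(all(bs2$pct_ils[!is.na(bs2$pct_ils)] >= 0 &
                    bs2$pct_ils[!is.na(bs2$pct_ils)] <= 100))
})

test_that("insertion rates need branch lengths in MY", {
  t5 <- t5_ladder()
  m <- clade_markers(t5, copies = 2)
  expect_error(branch_summary(m, t5, lengths_unit = "my"), "branch lengths")
  t5b <- ape::compute.brlen(t5, 2) # constant 2 MY branches
  bs <- branch_summary(m, t5b, lengths_unit = "my")
  got <- bs[bs$total_markers > 0, ]
  expect_equal(got$insertion_rate, got$total_markers / 2)
})

test_that("Spearman correlation matches closed cases and cor.test", {
  expect_equal(ils_correlate(1:4, c(8, 6, 4, 2))$rho, -1)
  expect_equal(ils_correlate(1:4, c(8, 6, 4, 2))$p, 0)
  expect_equal(ils_correlate(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_error(ils_correlate(1:4, rep(5, 4)), "constant")
  expect_error(ils_correlate(1:3, 3:1), "at least 4")
  set.seed(9)
  x <- rnorm(24); y <- 0.4 * x + rnorm(24) # n matches a two-dozen-internode table
  got <- ils_correlate(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  tref <- got$rho * sqrt((24 - 2) / (1 - got$rho^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tref), 22))
})

test_that("partition summaries split by chromosome and report unassigned", {
  t5 <- t5_ladder()
  states <- pa_states(clade_markers(t5, copies = 2))
  states[4, ] <- c("1", "0", "1", "0", "0") # one conflicted marker on chrZ
  meta <- tibble::tibble(chromosome = c("chr1", "chr2", "chrZ", "chrZ", "chr1", NA))
  m <- pa_matrix(states, marker_id = sprintf("p%d", 1:6), meta = meta)
  ps <- partition_summary(m, t5,
                          partitions = list(autosome = c("chr1", "chr2"), Z = "chrZ"))
  expect_setequal(ps$partition, c("autosome", "Z", "unassigned"))
  expect_equal(ps$pct_ils[ps$partition == "autosome"], 0)
  expect_equal(ps$pct_ils[ps$partition == "Z"], 50)
  expect_identical(ps$n_markers[ps$partition == "unassigned"], 1L)
  expect_identical(sum(ps$n_markers), 6L)
  # all conflict-free -> every partition at 0%
  m0 <- pa_matrix(pa_states(clade_markers(t5)),
                  marker_id = sprintf("q%d", 1:3),
                  meta = tibble::tibble(chromosome = c("chr1", "chrZ", "chr2")))
  ps0 <- partition_summary(m0, t5, partitions = function(ch) {
    if (ch == "chrZ") "Z" else "autosome"
  })
  expect_true(all(ps0$pct_ils == 0))
})

test_that("radiation spectra tally durations on the clade's internodes", {
  t8 <- caterpillar_tree(paste0("s", 1:8))
  clean <- pa_states(clade_markers(t8))
  confl <- matrix(c("1", "0", "1", "0", "0", "0", "0", "0"), 1,
                  dimnames = list("c1", paste0("s", 1:8)))
  m <- pa_matrix(rbind(clean, confl))
  spec <- radiation_spectrum(m, t8, radiations = list(shallow = paste0("s", 1:4),
                                                      all = paste0("s", 1:8)))
  shallow <- spec[spec$radiation == "shallow", ]
  expect_identical(unique(shallow$n_markers), 4L) # 3 nested clades + 1 conflict
  expect_equal(unique(shallow$pct_ils), 25)
  expect_identical(shallow$n[shallow$duration == 2], 1L)
  all_r <- spec[spec$radiation == "all", ]
  expect_identical(unique(all_r$n_markers), 7L)
})
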