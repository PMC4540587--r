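test_that("matrices round-trip through all three formats", {
  set.seed(101)
  for (rep in 1:4) {
    taxa <- paste0("sp", 1:sample(3:9, 1))
    m <- random_pa(sample(2:12, 1), taxa)
    for (fmt in c("csv", "phylip", "nexus")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_pa_matrix(m, path, fmt)
      m2 <- read_pa_matrix(path, fmt)
      expect_identical(unname(pa_states(m2)), unname(pa_states(m)),
                       info = fmt)
      expect_identical(pa_taxa(m2), pa_taxa(m), info = fmt)
    }
  }
})

test_that("csv round-trip preserves marker metadata", {
  states <- rbind(c("1", "1", "0"), c("1", "0", "?"))
  colnames(states) <- c("A", "B", "C")
  meta <- tibble::tibble(chromosome = c("chr1", "chrZ"),
                         start = c(100L, 5000L), end = c(600L, 5500L),
                         genic = c(TRUE, FALSE),
                         tsd_motif = c("ACGTA", "TTGCA"))
  m <- pa_matrix(states, marker_id = c("m1", "m2"), meta = meta)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pa_matrix(m, path, "csv")
  m2 <- read_pa_matrix(path, "csv")
  expect_identical(m2$chromosome, meta$chromosome)
  expect_identical(m2$start, meta$start)
  expect_identical(m2$genic, meta$genic)
  expect_identical(m2$tsd_motif, meta$tsd_motif)
  expect_identical(pa_states(m2), pa_states(m))
})

test_that("format errors are raised with context", {
  bad <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 3", "A 012", "B 010"), bad)
  expect_error(read_pa_matrix(bad, "phylip"), "non-binary symbol '2'")
  writeLines(c("3 3", "A 010", "B 010"), bad)
  expect_error(read_pa_matrix(bad, "phylip"), "declares 3 taxa")
  writeLines(c("2 3", "A 010", "A 011"), bad)
  expect_error(read_pa_matrix(bad, "phylip"), "duplicate taxon")
  writeLines(c("noheader", "A 010"), bad)
  expect_error(read_pa_matrix(bad, "phylip"), "header")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker_id,A,B", "m1,1,2"), csv)
  expect_error(read_pa_matrix(csv, "csv"), "invalid character state")
})

test_that("N and - are ingested as ? with a warning", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 3", "A 01N", "B 0-1"), f)
  expect_warning(m <- read_pa_matrix(f, "phylip"), "mapped to '\\?'")
  expect_identical(unname(pa_states(m)[, "A"]), c("0", "1", "?"))
  expect_identical(unname(pa_states(m)[, "B"]), c("0", "?", "1"))
})

test_that("NEXUS output declares the missing symbol", {
  m <- pa_matrix(rbind(c("1", "?", "0")), marker_id = "m1")
  path <- withr::local_tempfile(fileext = ".nex")
  write_pa_matrix(m, path, "nexus")
  expect_true(any(grepl("MISSING=\\?", toupper(readLines(path)))))
})

test_that("an empty matrix writes and reads as zero characters", {
  m <- pa_matrix(matrix(character(0), nrow = 0, ncol = 3,
                        dimnames = list(NULL, c("A", "B", "C"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pa_matrix(m, path, "csv")
  m2 <- read_pa_matrix(path, "csv")
  expect_identical(nrow(m2), 0L)
  expect_identical(pa_taxa(m2), c("A", "B", "C"))
})

test_that("newick trees round-trip and invalid trees are rejected", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):0.5,C:1.5);", path)
  tr <- read_species_tree(path)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$edge.length), c(0.5, 1, 1, 1.5))
  out <- withr::local_tempfile(fileext = ".nwk")
  write_species_tree(tr, out)
  tr2 <- read_species_tree(out)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))

  writeLines("((A,B),(A,C));", path)
  expect_error(read_species_tree(path), "duplicate leaf")
  writeLines("(A,B,C);", path)
  expect_error(read_species_tree(path), "unrooted")
  writeLines("((A,B,C);", path)
  expect_error(read_species_tree(path), "alformed|unexpected")
})

test_that("filter_informative removes exactly the prescribed marker classes", {
  taxa <- paste0("x", 1:12)
  states <- rbind(
    all1   = rep("1", 12),                          # plesiomorphic
    aut    = c("1", rep("0", 11)),                  # autapomorphic
    few    = c("1", "1", "0", rep("?", 9)),         # < 10 scored taxa
    none   = rep("0", 12),                          # no presence
    keep   = c("1", "1", rep("0", 10)),
    keep2  = c("1", "1", "1", "0", "0", rep("0", 7)))
  colnames(states) <- taxa
  m <- pa_matrix(states, marker_id = rownames(states))
  f <- filter_informative(m, min_taxa = 10)
  rep <- filter_report(f)
  expect_setequal(f$marker_id, c("keep", "keep2"))
  expect_identical(rep$reason[rep$marker_id == "all1"], "plesiomorphic")
  expect_identical(rep$reason[rep$marker_id == "aut"], "autapomorphic")
  expect_identical(rep$reason[rep$marker_id == "few"], "too_few_taxa")
  expect_identical(rep$reason[rep$marker_id == "none"], "no_presence")
  # report + retained = input
  expect_identical(nrow(rep) + nrow(f), nrow(m))
  # retained with min_taxa = 5: the pattern 1,1,0,0,0 example
  m2 <- pa_matrix(matrix(c("1", "1", "0", "0", "0"), 1,
                         dimnames = list("p", paste0("x", 1:5))))
  expect_identical(nrow(filter_informative(m2, min_taxa = 5)), 1L)
})

test_that("filter_informative is idempotent and order-insensitive", {
  set.seed(77)
  m <- random_pa(60, paste0("sp", 1:12), p_missing = 0.3)
  f1 <- filter_informative(m, min_taxa = 4)
  f2 <- filter_informative(f1, min_taxa = 4)
  expect_identical(f1$marker_id, f2$marker_id)
  expect_identical(nrow(filter_report(f2)), 0L)
  expect_identical(nrow(filter_report(f1)) + nrow(f1), nrow(m))
})
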