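test_that("edit distance matches the DP oracle on random pairs", {
  set.seed(101)
  for (i in 1:50) {
    a <- r_random_dna(sample(5:60, 1))
    b <- r_random_dna(sample(5:60, 1))
    expect_identical(edit_distance(a, b), r_edit_distance(a, b))
  }
})

test_that("anchored mapping recovers exact substrings", {
  set.seed(102)
  ref <- r_random_dna(3000)
  starts <- sample(0:(3000 - 300), 20)
  reads <- substring(ref, starts + 1, starts + 300)
  m <- map_reads(reads, ref, k = 15, band = 20)
  expect_true(all(m$mapped))
  expect_equal(m$start, starts)
  expect_equal(m$end, starts + 300L)
  expect_true(all(m$dist == 0L))
})

test_that("anchored mapping distance matches the oracle under indels", {
  set.seed(103)
  ref <- r_random_dna(1500)
  for (i in 1:10) {
    st <- sample(0:1200, 1)
    read <- substr(ref, st + 1, st + 250)
    # plant 2 substitutions and 1 deletion
    read <- r_substitute(read, 2)
    cut <- sample(10:240, 1)
    read <- paste0(substr(read, 1, cut - 1), substr(read, cut + 1, 250))
    m <- map_reads(read, ref, k = 15, band = 20)
    o <- r_semiglobal(read, ref)
    expect_true(m$mapped[1])
    expect_identical(m$dist[1], o$dist)
  }
})

test_that("overlap alignment reconstruction is consistent", {
  set.seed(104)
  ref <- r_random_dna(2000)
  query <- r_substitute(substr(ref, 301, 1700), 10)
  aln <- align_overlap(query, ref, k = 15, band = 60)
  expect_identical(gsub("-", "", aln$aligned_query), query)
  expect_identical(gsub("-", "", aln$aligned_ref), ref)
  expect_equal(nchar(aln$aligned_query), nchar(aln$aligned_ref))
  expect_identical(aln$dist, 10L)
  # lift maps query positions onto the reference
  lift <- aln$lift
  expect_equal(sum(!is.na(lift)), nchar(query))
  expect_true(all(diff(lift[!is.na(lift)]) >= 1))
})

test_that("reverse complement round-trips and matches the oracle", {
  set.seed(105)
  x <- vapply(1:10, function(i) r_random_dna(sample(10:50, 1)), "")
  expect_identical(unname(revcomp(x)), unname(r_revcomp(x)))
  expect_identical(as.character(revcomp(revcomp(x))), x)
})

test_that("simulated read errors follow the configured rates", {
  set.seed(106)
  tmpl <- r_random_dna(2000)
  reads <- allelepanel:::cpp_simulate_reads(rep(tmpl, 50), 0.05, 0.05, 0.05)
  d <- vapply(as.character(reads), function(r) {
    as.integer(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(r), Biostrings::DNAString(tmpl),
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(0, -1),
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)) * -1L
  }, 0L)
  expect_lt(abs(mean(d) - 0.15 * 2000), 0.15 * 0.15 * 2000)
})
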