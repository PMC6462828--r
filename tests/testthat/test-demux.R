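test_that("primer matching follows the edit-distance-below-two rule", {
  set.seed(201)
  seg <- r_random_dna(120)
  primer <- substr(seg, 41, 65)
  hit <- match_primer(seg, primer)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$edit_distance, 0L)
  expect_equal(hit$start, 40L)
  expect_equal(hit$end, 65L)
  # two substitutions exceed the default tolerance
  p2 <- r_substitute(primer, 2)
  while (r_edit_distance(p2, primer) < 2) p2 <- r_substitute(primer, 2)
  expect_equal(nrow(match_primer(seg, p2)), 0L)
  # one deletion: distance 1, position agrees with the DP oracle
  p1 <- paste0(substr(primer, 1, 11), substr(primer, 13, 25))
  hit1 <- match_primer(seg, p1)
  expect_equal(hit1$edit_distance, 1L)
  o <- r_semiglobal(p1, seg)
  expect_equal(o$dist, 1L)
  expect_equal(hit1$end, o$end)
  expect_error(match_primer(seg, ""), "empty")
})

test_that("primer matching equals the semi-global DP oracle", {
  set.seed(202)
  for (i in 1:60) {
    seg <- r_random_dna(sample(40:150, 1))
    primer <- r_random_dna(sample(8:25, 1))
    got <- allelepanel:::best_hit(primer, seg)
    o <- r_semiglobal(primer, seg)
    expect_identical(got$dist, o$dist)
  }
})

test_that("zero-error reads demultiplex perfectly and partition", {
  ds <- small_zero_dataset()
  dm <- demultiplex(ds$long$reads, ds$pool$primer_sets,
                    indexes = ds$long$indexes)
  expect_equal(nrow(dm$bins) + nrow(dm$unassigned), nrow(ds$long$reads))
  expect_false(any(duplicated(dm$bins$read_id)))
  expect_equal(nrow(dm$unassigned), 0L)
  j <- dplyr::inner_join(dm$bins, ds$long$truth, by = "read_id")
  expect_true(all(j$primer_set.x == j$primer_set.y))
  expect_true(all(j$sample.x == j$sample.y))
})

test_that("demultiplexing is idempotent under reverse complement", {
  ds <- small_zero_dataset()
  reads <- ds$long$reads[1:40, ]
  dm1 <- demultiplex(reads, ds$pool$primer_sets, indexes = ds$long$indexes)
  rc <- reads
  rc$sequence <- as.character(revcomp(rc$sequence))
  dm2 <- demultiplex(rc, ds$pool$primer_sets, indexes = ds$long$indexes)
  j <- dplyr::inner_join(dm1$bins, dm2$bins, by = "read_id")
  expect_equal(nrow(j), nrow(dm1$bins))
  expect_identical(j$primer_set.x, j$primer_set.y)
  expect_identical(j$sequence.x, j$sequence.y)  # orientation-normalized
  expect_true(all(j$orientation.x != j$orientation.y))
})

test_that("nested inner amplicons are assigned to the inner primer set", {
  ds <- small_zero_dataset()
  tr <- ds$long$truth
  nested_ids <- tr$read_id[tr$gene == "C" & tr$primer_set == "B"]
  expect_gt(length(nested_ids), 0)
  dm <- demultiplex(ds$long$reads[ds$long$reads$read_id %in% nested_ids, ],
                    ds$pool$primer_sets, indexes = ds$long$indexes)
  expect_true(all(dm$bins$primer_set == "B"))
})

test_that("gene classification follows the longest mapped fragment", {
  ds <- small_zero_dataset()
  db <- ds$db
  # a database allele classifies to its own gene with ~full-length fragment
  a <- db$info$allele[!db$info$cdna_only][1]
  cl <- classify_gene(db$sequences[[a]], db)
  expect_equal(cl$gene, db$info$gene[db$info$allele == a])
  expect_gt(cl$fragment_length, 0.9 * nchar(db$sequences[[a]]))
  # chimera: 60% gene A / 40% gene B -> gene A (longest fragment), checked
  # against exhaustive local alignment
  aa <- ds$pool$sequences[[ds$pool$info$allele[ds$pool$info$gene == "A"][1]]]
  bb <- ds$pool$sequences[[ds$pool$info$allele[ds$pool$info$gene == "B"][1]]]
  n <- 3000
  chim <- paste0(substr(aa, 1, 0.6 * n), substr(bb, 1, 0.4 * n))
  cl2 <- classify_gene(chim, db)
  expect_equal(cl2$gene, "A")
  # oracle: local alignment width against the best allele of each gene
  local_w <- function(subject) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(chim), Biostrings::DNAString(subject),
      type = "local")
    Biostrings::nchar(Biostrings::alignedPattern(pa))
  }
  wa <- max(vapply(db$sequences[db$info$allele[db$info$gene == "A"]],
                   local_w, 0))
  wb <- max(vapply(db$sequences[db$info$allele[db$info$gene == "B"]],
                   local_w, 0))
  expect_gt(wa, wb)
  # random sequence: unclassified
  set.seed(203)
  cl3 <- classify_gene(r_random_dna(2000), db)
  expect_true(is.na(cl3$gene))
})

test_that("contig primer containment is detected on both strands", {
  ds <- small_zero_dataset()
  ps <- ds$pool$primer_sets
  a <- ds$pool$info$allele[ds$pool$info$gene == "A"][1]
  full <- ds$pool$sequences[[a]]
  pa <- ps[ps$set == "A", ]
  expect_true(all(contains_primers(full, pa$forward, pa$reverse)))
  expect_true(all(contains_primers(as.character(revcomp(full)),
                                   pa$forward, pa$reverse)))
  truncated <- substr(full, 201, nchar(full))
  got <- contains_primers(truncated, pa$forward, pa$reverse)
  expect_false(got[["has_forward"]])
  expect_true(got[["has_reverse"]])
  # one edit in the forward primer still counts ("edit distance < 2")
  mut <- full
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  expect_true(contains_primers(mut, pa$forward, pa$reverse)[["has_forward"]])
})
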