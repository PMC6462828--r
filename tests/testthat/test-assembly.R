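test_that("a homozygous zero-error bin forms a single cluster", {
  set.seed(301)
  tmpl <- r_random_dna(2500)
  reads <- rep(tmpl, 12)
  cl <- cluster_bin(reads, assembly_params())
  expect_equal(length(cl), 1L)
  expect_equal(sort(cl[[1]]), 1:12)
})

test_that("heterozygous bins split by linked columns with high agreement", {
  set.seed(302)
  anc <- r_random_dna(3000)
  a1 <- r_substitute(anc, 15)
  a2 <- r_substitute(anc, 15)
  reads <- as.character(allelepanel:::cpp_simulate_reads(
    c(rep(a1, 30), rep(a2, 30)), 0.01, 0.06, 0.04))
  cl <- cluster_bin(reads, assembly_params())
  expect_equal(length(cl), 2L)
  truth <- rep(1:2, each = 30)
  agreement <- max(vapply(cl, function(v) {
    max(mean(truth[v] == 1), mean(truth[v] == 2))
  }, 0))
  expect_gte(agreement, 0.9)
})

test_that("single-difference heterozygotes stay assemblable", {
  set.seed(303)
  anc <- r_random_dna(2500)
  a2 <- anc
  substr(a2, 1200, 1200) <- if (substr(a2, 1200, 1200) == "G") "T" else "G"
  reads <- as.character(allelepanel:::cpp_simulate_reads(
    c(rep(anc, 25), rep(a2, 25)), 0.01, 0.06, 0.04))
  cl <- cluster_bin(reads, assembly_params())
  expect_lte(length(cl), 2L)
  for (v in cl) {
    p <- polish_consensus(reads[v], reads[attr(v, "seed")],
                          assembly_params())
    d <- min(edit_distance(p$sequence, anc), edit_distance(p$sequence, a2))
    expect_lte(d, 2L)
  }
})

test_that("consensus polishing converges to the template", {
  set.seed(304)
  tmpl <- r_random_dna(2000)
  # a single error-free read polishes to itself
  p1 <- polish_consensus(tmpl, tmpl, assembly_params())
  expect_identical(p1$sequence, tmpl)
  # identical reads: consensus equals the read, first round converges
  p2 <- polish_consensus(rep(tmpl, 10), tmpl, assembly_params())
  expect_identical(p2$sequence, tmpl)
  expect_true(p2$converged)
  # 30 indel-dominated reads: consensus within 2 edits of truth
  reads <- as.character(allelepanel:::cpp_simulate_reads(
    rep(tmpl, 30), 0.01, 0.06, 0.04))
  p3 <- polish_consensus(reads, reads[which.max(nchar(reads))],
                         assembly_params())
  d <- as.integer(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(p3$sequence), Biostrings::DNAString(tmpl),
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(0, -1),
    gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)) * -1L
  expect_lte(d, 2L)
})

test_that("contig fusing merges duplicates and drops weak artifacts", {
  set.seed(305)
  base <- r_random_dna(2400)
  near <- r_substitute(base, 3)   # a near-duplicate complete haplotype
  artifact <- r_substitute(base, 120)
  contigs <- tibble::tibble(
    sample = "S1", gene = "A",
    sequence = c(base, near, artifact),
    n_support = c(20L, 6L, 2L),
    full_length = c(TRUE, TRUE, TRUE))
  fused <- fuse_contigs(contigs, assembly_params())
  # complete near-duplicates are NOT distance-merged (they may be true
  # haplotypes one base apart); the weak artifact is discarded
  expect_equal(nrow(fused), 2L)
  expect_setequal(fused$sequence, c(base, near))
  expect_setequal(fused$n_support, c(20L, 6L))
  # identical contigs merge with summed support
  dup <- contigs[c(1, 1), ]
  dup$n_support <- c(5L, 7L)
  f2 <- fuse_contigs(dup, assembly_params())
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$n_support, 12L)
  # a contained truncated contig always merges into its full-length
  # container, even with more support
  inner <- substr(base, 301, 2100)
  cont <- tibble::tibble(
    sample = "S1", gene = "A",
    sequence = c(base, inner),
    n_support = c(10L, 40L),
    full_length = c(TRUE, FALSE))
  f3 <- fuse_contigs(cont, assembly_params())
  expect_equal(nrow(f3), 1L)
  expect_identical(f3$sequence, base)
  expect_equal(f3$n_support, 50L)
  # fusing conserves support counts
  expect_equal(sum(f3$n_support), sum(cont$n_support))
})

test_that("draft set deduplicates across samples and enforces contracts", {
  seqs <- c(r_random_dna(2200), r_random_dna(2200))
  contigs <- tibble::tibble(
    sample = c("S1", "S1", "S2", "S2"),
    gene = "A",
    sequence = c(seqs[1], seqs[2], seqs[1], seqs[1]),
    n_support = c(10L, 8L, 12L, 11L),
    full_length = TRUE)
  # S2 has the same sequence twice -> still two contigs, allowed (<= 2)
  draft <- build_draft_set(contigs)
  expect_equal(length(draft$sequences), 2L)
  shared <- draft$info$allele_id[draft$info$n_carriers == 2]
  expect_equal(length(shared), 1L)
  expect_identical(unname(draft$sequences[shared]), seqs[1])
  # more than two contigs for one sample/gene is a contract violation
  bad <- tibble::tibble(sample = "S1", gene = "A",
                        sequence = c(r_random_dna(100), r_random_dna(100),
                                     r_random_dna(100)),
                        n_support = 5L, full_length = TRUE)
  expect_error(build_draft_set(bad), "fuse_contigs")
})

test_that("zero-error assembly recovers the truth exactly", {
  ds <- small_zero_dataset()
  dm <- demultiplex(ds$long$reads, ds$pool$primer_sets,
                    indexes = ds$long$indexes)
  gs <- dplyr::select(dplyr::filter(ds$pool$targets, .data$full),
                      gene = "gene", set = "set")
  asm <- assemble_reads(dm$bins, ds$db, ds$pool$primer_sets, gs)
  truth_seqs <- unique(ds$pool$sequences[
    stats::na.omit(ds$truth$allele)])
  expect_setequal(unname(asm$draft$sequences), truth_seqs)
  expect_true(all(asm$draft$info$full_length))
  expect_true(all(asm$report$full_length))
})
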