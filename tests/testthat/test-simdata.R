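test_that("allele pool generation is deterministic and validated", {
  models <- gene_models()
  sizes <- c(A = 5, B = 5, C = 5, H = 5)
  p1 <- generate_allele_pool(models, sizes, 0.01, seed = 1)
  p2 <- generate_allele_pool(models, sizes, 0.01, seed = 1)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$info, p2$info)
  expect_error(generate_allele_pool(models, sizes, 0), "divergence_rate")
  # alleles of a gene pairwise distinct
  for (g in models$gene) {
    s <- p1$sequences[p1$info$allele[p1$info$gene == g]]
    expect_equal(length(unique(s)), length(s))
  }
  # frequencies sum to 1 per gene
  sums <- tapply(p1$info$frequency, p1$info$gene, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # names parse as GENE*gg:pp:ss:nn
  expect_true(all(grepl("^[ABCH]\\*\\d{2}:\\d{2}:\\d{2}:\\d{2}$",
                        p1$info$allele)))
})

test_that("pool divergence matches the configured rate", {
  models <- gene_models("A")
  pool <- generate_allele_pool(models, c(A = 20), 0.01, seed = 3)
  seqs <- pool$sequences
  L <- models$length[1]
  # brute-force alignment distance over all pairs (independent oracle)
  d <- Biostrings::stringDist(Biostrings::DNAStringSet(seqs),
                              method = "levenshtein")
  expected <- 2 * 0.01 * L
  expect_lt(abs(mean(d) - expected) / expected, 0.30)
})

test_that("exon annotations lift through indels", {
  models <- gene_models()
  pool <- generate_allele_pool(models, c(A = 8, B = 8, C = 8, H = 8),
                               0.01, seed = 4)
  # each allele's exons concatenate to a CDS of the canonical length
  for (a in pool$info$allele) {
    ex <- pool$annotations[pool$annotations$allele == a &
                             grepl("^exon", pool$annotations$region), ]
    cds <- sum(ex$end - ex$start)
    expect_equal(cds, 1098L)
  }
})

test_that("genotype drawing respects deletion frequency", {
  models <- gene_models()
  pool <- generate_allele_pool(models, c(A = 4, B = 4, C = 4, H = 4),
                               0.01, seed = 5)
  g1 <- draw_genotypes(pool, 20, deletion_freq = 1, seed = 1)
  expect_true(all(is.na(g1$allele[g1$gene == "H"])))
  expect_true(all(!is.na(g1$allele[g1$gene != "H"])))
  g0 <- draw_genotypes(pool, 20, deletion_freq = 0, seed = 1)
  expect_true(all(!is.na(g0$allele)))
  # copy-number-0 fraction ~ Binomial closed form at freq 0.3
  gg <- draw_genotypes(pool, 1000, deletion_freq = 0.3, seed = 2)
  cn0 <- tapply(is.na(gg$allele[gg$gene == "H"]),
                gg$sample[gg$gene == "H"], all)
  p <- mean(cn0)
  se <- sqrt(0.09 * 0.91 / 1000)
  expect_lt(abs(p - 0.09), 3 * se)
})

test_that("zero-error long reads are exact amplicon copies", {
  models <- gene_models(c("A", "B"))   # no nested geometry
  pool <- generate_allele_pool(models, c(A = 3, B = 3), 0.01, seed = 6)
  truth <- draw_genotypes(pool, 2, 0, seed = 1)
  cfg <- sim_config(n_samples = 2, long_mismatch = 0, long_insertion = 0,
                    long_deletion = 0, long_depth = 1)
  lr <- simulate_long_reads(pool, truth, cfg, seed = 2)
  idx <- setNames(lr$indexes$index, lr$indexes$sample)
  for (i in seq_len(nrow(lr$reads))) {
    tr <- lr$truth[lr$truth$read_id == lr$reads$read_id[i], ]
    adapter <- paste0(idx[tr$sample], "GGTAG")
    amp <- paste0(adapter, pool$sequences[[tr$allele]],
                  revcomp(adapter))
    expect_true(lr$reads$sequence[i] == amp ||
                  lr$reads$sequence[i] == as.character(revcomp(amp)))
  }
})

test_that("nested co-amplification enriches the inner interval ~4x", {
  ds <- small_zero_dataset()
  tr <- ds$long$truth
  cg <- tr[tr$gene == "C", ]
  inner <- sum(!cg$full)       # inner-only reads (B-set amplicons)
  outer <- sum(cg$full)        # full-length C amplicons
  # inner coverage = outer + nested; expected ratio (1 + multiplier)
  ratio <- (inner + outer) / outer
  expect_lt(abs(ratio - 4) / 4, 0.25)
})

test_that("short reads respect coverage, error and copy number", {
  models <- gene_models()
  pool <- generate_allele_pool(models, c(A = 3, B = 3, C = 3, H = 3),
                               0.01, seed = 7)
  truth <- draw_genotypes(pool, 3, deletion_freq = 1, seed = 3)
  cfg <- sim_config(n_samples = 3, short_error = 0, short_coverage = 30,
                    short_read_len = 150)
  sr <- simulate_short_reads(pool, truth, cfg, seed = 4)
  # no reads from the deleted locus
  expect_false(any(sr$truth$gene == "H"))
  # pair count per haplotype ~ cov * L / (2 * rl)
  cnt <- table(sr$truth$allele)
  for (a in names(cnt)) {
    L <- nchar(pool$sequences[[a]])
    carriers <- sum(!is.na(truth$allele) & truth$allele == a)
    expected <- carriers * 30 * L / 300
    expect_lt(abs(cnt[[a]] - expected) / expected, 0.2)
  }
  # zero error: every read is a substring of its haplotype (either strand)
  some <- sample(nrow(sr$reads), 50)
  for (i in some) {
    pid <- sub("/[12]$", "", sr$reads$read_id[i])
    al <- sr$truth$allele[sr$truth$pair_id == pid]
    hit <- grepl(sr$reads$sequence[i], pool$sequences[[al]], fixed = TRUE) ||
      grepl(as.character(revcomp(sr$reads$sequence[i])),
            pool$sequences[[al]], fixed = TRUE)
    expect_true(hit)
  }
})

test_that("datasets are byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 2, pool_sizes = c(A = 3, B = 3, C = 3, H = 3),
                    long_depth = 3)
  d1 <- simulate_dataset(cfg, seed = 9)
  d2 <- simulate_dataset(cfg, seed = 9)
  expect_identical(d1$long$reads, d2$long$reads)
  expect_identical(d1$short$reads, d2$short$reads)
  expect_identical(d1$db$sequences, d2$db$sequences)
  # truth maps complete: every read id exactly once
  expect_equal(sort(d1$long$reads$read_id), sort(d1$long$truth$read_id))
  expect_false(any(duplicated(d1$long$truth$read_id)))
})
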