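test_that("gene MSA satisfies the ungap invariant and width", {
  set.seed(401)
  anc <- r_random_dna(1200)
  seqs <- c(x1 = anc, x2 = r_substitute(anc, 10), x3 = r_substitute(anc, 12))
  msa <- build_gene_msa(seqs)
  expect_true(all(nchar(msa$rows) == msa$width))
  expect_identical(gsub("-", "", msa$rows[names(seqs)], fixed = TRUE),
                   seqs)
  # identical alleles -> no gap columns
  msa2 <- build_gene_msa(c(a = anc, b = anc))
  expect_false(grepl("-", paste(msa2$rows, collapse = "")))
})

test_that("a two-base deletion aligns as one two-column gap run", {
  set.seed(402)
  anc <- r_random_dna(1000)
  del <- paste0(substr(anc, 1, 499), substr(anc, 502, 1000))
  msa <- build_gene_msa(c(full = anc, short = del))
  v <- identify_variants(msa)
  expect_equal(length(unique(v$position)), 1L)
  vs <- v[v$allele_id == "short", ]
  expect_equal(vs$string, "")
  expect_equal(vs$col_end - vs$col_start, 2L)
})

test_that("built-in MSA scores at least as high as the star oracle", {
  set.seed(403)
  anc <- r_random_dna(600)
  seqs <- setNames(c(anc, replicate(5, r_substitute(anc, 8))),
                   paste0("a", 1:6))
  msa <- build_gene_msa(seqs)
  center <- names(seqs)[order(-nchar(seqs), names(seqs))][1]
  star <- r_star_msa(seqs, center)
  expect_gte(r_sop_score(msa$rows), r_sop_score(star))
})

test_that("variant identification matches per-column comparison", {
  # all-identical rows: no variants
  msa0 <- build_gene_msa(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(nrow(identify_variants(msa0)), 0L)
  # hand-built MSA with isolated differences
  rows <- c(a = "ACGTACGTAA", b = "ACCTACGTAA", c = "ACGTACTTAC")
  msa <- structure(list(rows = rows, width = 10L), class = "gene_msa")
  v <- identify_variants(msa)
  expect_equal(sort(unique(v$col_start)), c(2L, 6L, 9L))
  expect_equal(max(v$col_end - v$col_start), 1L)
})

test_that("an indel-overlap variant reports the figure's strings", {
  # one locus where one allele reads AGTT and the other GC-- in the MSA:
  # the substitutions plus the adjacent two-base deletion form one
  # maximal variant run with exactly those allele strings
  rows <- c(A1 = "CCATGAGTTGGTAC", A3 = "CCATGGC--GGTAC")
  msa <- structure(list(rows = rows, width = 14L), class = "gene_msa")
  v <- identify_variants(msa)
  expect_equal(length(unique(v$position)), 1L)
  expect_setequal(v$string, c("AGTT", "GC"))
  va3 <- v[v$allele_id == "A3", ]
  expect_equal(va3$col_end - va3$col_start, 4L)
  expect_equal(va3$ungapped_end - va3$ungapped_start, 2L)
})

test_that("support assessment classifies the figure's scenario", {
  set.seed(405)
  flank <- r_random_dna(300)
  flank2 <- r_random_dna(300)
  a1 <- paste0(flank, "AGTT", flank2)   # supported in its carrier
  a2 <- paste0(flank, "GCT", flank2)    # what the reads actually say
  a3 <- paste0(flank, "GC", flank2)     # draft consensus error
  set <- allele_set(
    sequences = c(A1 = a1, A2 = a2, A3 = a3),
    info = tibble::tibble(allele_id = c("A1", "A2", "A3"), gene = "A",
                          n_carriers = 1L, full_length = TRUE),
    carriers = tibble::tibble(allele_id = c("A1", "A2", "A3"),
                              sample = c("S1", "S2", "S1")))
  # S1 is heterozygous A1/A3 but its reads carry A1 and A2 haplotypes
  # (A3 is a consensus error of the A2 haplotype); S2 is homozygous A2
  mk_reads <- function(hap, n, sample) {
    starts <- floor(seq(0, nchar(hap) - 162, length.out = n))
    tibble::tibble(read_id = sprintf("%s_%03d", sample, seq_len(n)),
                   sample = sample,
                   sequence = substring(hap, starts + 1, starts + 162))
  }
  reads <- dplyr::bind_rows(
    mk_reads(a1, 60, "S1"), mk_reads(a2, 60, "S1"), mk_reads(a2, 80, "S2"))
  va <- variant_accuracy(set, reads)
  run <- va$assessments
  a1row <- run[run$allele_id == "A1" & run$sample == "S1", ]
  a3row <- run[run$allele_id == "A3" & run$sample == "S1", ]
  # the carrier's reads support every A1 observation, while A3's consensus
  # error is flagged unsupported with the reads' string as the alternative
  expect_true(all(a1row$status == "supported"))
  expect_true(any(a3row$status == "unsupported"))
  expect_false(any(a1row$status == "unsupported"))
  # correction merges A3 into A2
  ref <- refine_alleles(set, reads)
  expect_equal(length(ref$refined$sequences), 2L)
  merged <- ref$refined$info$allele_id[ref$refined$info$n_carriers == 2]
  expect_length(merged, 1L)
  expect_identical(unname(ref$refined$sequences[merged]), a2)
})

test_that("shallow pileups are unexamined", {
  set.seed(406)
  flank <- r_random_dna(200); flank2 <- r_random_dna(200)
  a1 <- paste0(flank, "A", flank2)
  a2 <- paste0(flank, "G", flank2)
  set <- allele_set(
    sequences = c(X1 = a1, X2 = a2),
    info = tibble::tibble(allele_id = c("X1", "X2"), gene = "A",
                          n_carriers = 1L, full_length = TRUE),
    carriers = tibble::tibble(allele_id = c("X1", "X2"),
                              sample = c("S1", "S2")))
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "q1", "q2", "q3", "q4", "q5", "q6"),
    sample = c(rep("S1", 3), rep("S2", 6)),
    sequence = c(rep(substr(a1, 150, 311), 3), rep(substr(a2, 150, 311), 6)))
  va <- variant_accuracy(set, reads, refine_params(min_depth = 5))
  s1 <- va$assessments[va$assessments$sample == "S1", ]
  s2 <- va$assessments[va$assessments$sample == "S2", ]
  expect_equal(s1$status, "unexamined")   # depth 3 < 5
  expect_equal(s2$status, "supported")
})

test_that("injected consensus errors are corrected back to truth", {
  ds <- small_zero_dataset()
  dm <- demultiplex(ds$long$reads, ds$pool$primer_sets,
                    indexes = ds$long$indexes)
  gs <- dplyr::select(dplyr::filter(ds$pool$targets, .data$full),
                      gene = "gene", set = "set")
  asm <- assemble_reads(dm$bins, ds$db, ds$pool$primer_sets, gs)
  draft <- asm$draft
  # inject single-base errors into some draft alleles
  set.seed(407)
  victims <- draft$info$allele_id[seq(1, length(draft$sequences), by = 3)]
  truth_of <- draft$sequences
  for (v in victims) {
    s <- draft$sequences[[v]]
    p <- sample(200:(nchar(s) - 200), 1)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, p, p))[1]
    draft$sequences[[v]] <- s
  }
  ref <- refine_alleles(draft, ds$short$reads)
  # at least 80% of the injected errors are removed (victim restored to
  # its pre-injection sequence)
  restored <- mean(unname(truth_of[victims]) %in%
                     unname(ref$refined$sequences))
  expect_gte(restored, 0.8)
  recovered <- mean(unname(truth_of) %in% unname(ref$refined$sequences))
  expect_gte(recovered, 0.8)
  acc <- ref$accuracy
  draft_acc <- acc$accuracy[acc$stage == "draft" & acc$gene == ".mean"]
  ref_acc <- acc$accuracy[acc$stage == "refined" & acc$gene == ".mean"]
  expect_gt(ref_acc, draft_acc)
  expect_lte(length(ref$refined$sequences), length(draft$sequences))
})
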