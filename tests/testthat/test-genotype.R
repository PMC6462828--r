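make_gene_pair <- function(len = 2000, ndiff = 20, seed = 1) {
  set.seed(seed)
  anc <- r_random_dna(len)
  list(anc = anc, a1 = r_substitute(anc, ndiff), a2 = r_substitute(anc, ndiff))
}

uniform_reads <- function(hap, n, rl = 162) {
  starts <- floor(seq(0, nchar(hap) - rl, length.out = n))
  substring(hap, starts + 1, starts + rl)
}

test_that("copy-number calls follow the depth ratio", {
  set.seed(501)
  gA <- r_random_dna(2000); gH <- r_random_dna(2000)
  refs <- c(A = gA, H = gH)
  mk <- function(copiesH) {
    c(uniform_reads(gA, 200), uniform_reads(gA, 200),
      if (copiesH > 0) unlist(lapply(seq_len(copiesH), function(i)
        uniform_reads(gH, 200))))
  }
  for (cn in 0:2) {
    call <- call_copy_number(mk(cn), refs, "H", "A")
    expect_equal(call$call, cn)
    expect_lt(abs(call$ratio - cn / 2), 0.15)
  }
})

test_that("zero-error genotyping is exact with positive margin", {
  gp <- make_gene_pair(seed = 502)
  cand <- c(x1 = gp$a1, x2 = gp$a2, x3 = r_substitute(gp$anc, 20))
  reads <- c(uniform_reads(gp$a1, 150), uniform_reads(gp$a2, 150))
  gt <- genotype_sample(reads, cand, 2L)
  expect_setequal(c(gt$allele1, gt$allele2), c("x1", "x2"))
  expect_gt(gt$margin, 0)
  # homozygous truth gives a homozygous call
  gt2 <- genotype_sample(uniform_reads(gp$a1, 200), cand, 2L)
  expect_equal(gt2$allele1, "x1")
  expect_equal(gt2$allele2, "x1")
  # copy number 0: empty call
  expect_equal(nrow(genotype_sample(reads, cand, 0L)), 0L)
  # copy number 1
  gt1 <- genotype_sample(uniform_reads(gp$a2, 100), cand, 1L)
  expect_equal(gt1$allele1, "x2")
  expect_true(is.na(gt1$allele2))
})

test_that("panel filtering keeps genotyped alleles and records alterations", {
  gp <- make_gene_pair(seed = 503)
  refined <- allele_set(
    sequences = c(R1 = gp$a1, R2 = gp$a2, R3 = r_substitute(gp$a1, 2)),
    info = tibble::tibble(allele_id = c("R1", "R2", "R3"), gene = "A",
                          n_carriers = c(2L, 1L, 1L), full_length = TRUE),
    carriers = tibble::tibble(allele_id = c("R1", "R1", "R2", "R3"),
                              sample = c("S1", "S2", "S1", "S2")))
  calls <- tibble::tibble(
    sample = c("S1", "S2"), gene = "A",
    allele1 = c("R1", "R1"), allele2 = c("R2", "R1"),
    loglik = 0, margin = 1, copy_number = 2L)
  sel <- filter_panel(refined, calls)
  expect_equal(length(sel$panel$sequences), 2L)
  dropped <- sel$selection[!sel$selection$kept, ]
  expect_equal(dropped$allele_id, "R3")
  expect_equal(dropped$reason, "never-genotyped")
  # R3's only carrier S2 was genotyped homozygous R1 -> alteration R1
  expect_equal(dropped$alteration, "R1")
  # panel ids renamed deterministically
  expect_true(all(grepl("^A_\\d{5}$", names(sel$panel$sequences))))
})

test_that("end-to-end genotyping concordance holds on noisy data", {
  ds <- small_noisy_dataset()
  run <- run_of(ds, "small_noisy_run")
  ev <- evaluate_run(run, ds)
  expect_gte(ev$genotype_concordance, 0.9)
  expect_equal(ev$copy_number_accuracy, 1)
  # calls respect copy number (deletable locus 0-2, others 2 alleles)
  calls <- run$calls
  h <- calls[calls$gene == "H", ]
  expect_true(all(h$copy_number %in% 0:2))
  expect_true(all(is.na(h$allele1[h$copy_number == 0])))
  nd <- calls[calls$gene != "H", ]
  expect_true(all(!is.na(nd$allele1) & !is.na(nd$allele2)))
  # panel never exceeds refined, refined never exceeds draft
  expect_lte(length(run$panel$sequences), length(run$refined$sequences))
  expect_lte(length(run$refined$sequences), length(run$draft$sequences))
})
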