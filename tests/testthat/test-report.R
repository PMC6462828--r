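test_that("allele names truncate by resolution", {
  n <- "B*07:02:01:03"
  expect_equal(truncate_allele_name(n, 4), "B*07:02")
  expect_equal(truncate_allele_name(n, 6), "B*07:02:01")
  expect_equal(truncate_allele_name(n, 8), "B*07:02:01:03")
})

test_that("closest database allele and novelty classes are assigned", {
  ds <- small_zero_dataset()
  db <- ds$db
  g <- "A"
  dba <- db$info$allele[db$info$gene == g & !db$info$cdna_only][1]
  full <- ds$pool$sequences[[dba]]   # panel allele = db allele + flanks
  panel <- allele_set(
    sequences = setNames(full, "A_00001"),
    info = tibble::tibble(allele_id = "A_00001", gene = g, n_carriers = 1L,
                          full_length = TRUE, refined_id = "A_r01"),
    carriers = tibble::tibble(allele_id = "A_00001", sample = "S1"))
  chr <- characterize_panel(panel, db)
  e <- chr$entries
  expect_equal(e$closest_db, dba)
  expect_equal(e$dist, 0L)
  expect_false(e$novel_8digit)
  expect_gte(e$upstream_ext, 0L)
  expect_gte(e$downstream_ext, 0L)
  expect_equal(e$length - e$db_length,
               e$upstream_ext + e$downstream_ext)
})

test_that("exonic substitutions drive 6/4-digit novelty and records", {
  ds <- small_zero_dataset()
  db <- ds$db
  dba <- db$info$allele[db$info$gene == "B" & !db$info$cdna_only][1]
  full <- ds$pool$sequences[[dba]]
  ex <- ds$pool$annotations[ds$pool$annotations$allele == dba &
                              ds$pool$annotations$region == "exon3", ]
  # nonsynonymous: force a first-codon-position change in exon 3
  pos <- ex$start + 4L
  mut <- full
  old <- substr(mut, pos + 1, pos + 1)
  substr(mut, pos + 1, pos + 1) <- if (old == "G") "C" else "G"
  panel <- allele_set(
    sequences = setNames(mut, "B_00001"),
    info = tibble::tibble(allele_id = "B_00001", gene = "B",
                          n_carriers = 1L, full_length = TRUE,
                          refined_id = "B_r01"),
    carriers = tibble::tibble(allele_id = "B_00001", sample = "S1"))
  chr <- characterize_panel(panel, db)
  e <- chr$entries
  expect_equal(e$closest_db, dba)
  expect_equal(e$exon_dist, 1L)
  expect_true(e$novel_8digit && e$novel_6digit)
  v <- chr$exon_variants
  expect_equal(nrow(v), 1L)
  expect_equal(v$exon, 3L)
  expect_equal(v$pos_in_exon, 5L)
  expect_equal(v$ref, old)
  # novelty chain always holds
  expect_true(all(!e$novel_4digit | e$novel_6digit))
  expect_true(all(!e$novel_6digit | e$novel_8digit))
})

test_that("synonymous third-position changes stay 6-digit novel only", {
  ds <- small_zero_dataset()
  db <- ds$db
  dba <- db$info$allele[db$info$gene == "C" & !db$info$cdna_only][1]
  full <- ds$pool$sequences[[dba]]
  ex2 <- ds$pool$annotations[ds$pool$annotations$allele == dba &
                               ds$pool$annotations$region == "exon2", ]
  # search a third-codon position in exon 2 whose substitution is silent
  exlens <- ds$pool$annotations[ds$pool$annotations$allele == dba &
                                  grepl("^exon",
                                        ds$pool$annotations$region), ]
  exlens <- exlens[order(exlens$start), ]
  cds_off <- cumsum(c(0, exlens$end - exlens$start))
  off2 <- cds_off[2]   # CDS offset of exon 2
  found <- FALSE
  # CDS position off2 + k must be the third base of a codon: the frame
  # within exon 2 is shifted by the exon 1 length (off2 mod 3)
  ks <- seq(6L - (off2 %% 3L), 90L, by = 3L)
  ks <- ks[ks >= 3L]
  for (k in ks) {
    gpos <- ex2$start + k - 1L   # 0-based genomic position of that base
    codon_start_g <- gpos - 2L
    codon <- substr(full, codon_start_g + 1, codon_start_g + 3)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      cod2 <- paste0(substr(codon, 1, 2), alt)
      if (as.character(Biostrings::translate(Biostrings::DNAString(cod2),
                                             no.init.codon = TRUE)) ==
          as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                             no.init.codon = TRUE))) {
        mut <- full
        substr(mut, gpos + 1, gpos + 1) <- alt
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  panel <- allele_set(
    sequences = setNames(mut, "C_00001"),
    info = tibble::tibble(allele_id = "C_00001", gene = "C",
                          n_carriers = 1L, full_length = TRUE,
                          refined_id = "C_r01"),
    carriers = tibble::tibble(allele_id = "C_00001", sample = "S1"))
  chr <- characterize_panel(panel, db)
  e <- chr$entries
  expect_true(e$novel_6digit)
  expect_false(e$novel_4digit)
  expect_equal(chr$exon_variants$aa_change, "Synonymous")
})

test_that("cDNA-only closest entries mark newly added introns", {
  ds <- small_zero_dataset()
  # database variant with a guaranteed cDNA-only fraction
  db <- make_reference_db(ds$pool, include_fraction = 0.8,
                          cdna_fraction = 0.5, seed = 21)
  cdna <- db$info$allele[db$info$cdna_only]
  expect_gt(length(cdna), 0)
  a <- cdna[1]
  g <- db$info$gene[db$info$allele == a]
  full <- ds$pool$sequences[[a]]
  panel <- allele_set(
    sequences = setNames(full, paste0(g, "_00001")),
    info = tibble::tibble(allele_id = paste0(g, "_00001"), gene = g,
                          n_carriers = 1L, full_length = TRUE,
                          refined_id = "r"),
    carriers = tibble::tibble(allele_id = paste0(g, "_00001"),
                              sample = "S1"))
  chr <- characterize_panel(panel, db)
  e <- chr$entries
  expect_equal(e$closest_db, a)   # exact exonic match beats genomic entries
  expect_true(e$adds_introns)
  expect_true(e$novel_8digit)
  expect_false(e$novel_6digit)
})

test_that("allele distribution counts slots and frequencies", {
  calls <- tibble::tibble(
    sample = paste0("S", 1:4), gene = "A",
    allele1 = c("a", "a", "b", "a"),
    allele2 = c("a", "b", "b", "b"),
    copy_number = 2L)
  d <- allele_distribution(calls)
  f <- d$frequencies
  expect_equal(f$frequency[f$allele == "a"], 0.5)
  expect_equal(f$frequency[f$allele == "b"], 0.5)
  # all samples homozygous for one allele
  calls2 <- dplyr::mutate(calls, allele1 = "z", allele2 = "z")
  f2 <- allele_distribution(calls2)$frequencies
  expect_equal(f2$frequency, 1)
  # untyped slots tracked separately
  calls3 <- calls
  calls3$allele2[1] <- NA
  d3 <- allele_distribution(calls3)
  expect_equal(d3$untyped$untyped_slots, 1L)
  expect_equal(sum(d3$frequencies$frequency), 1)
})

test_that("population coverage counts truncated-name matches monotonically", {
  entries <- tibble::tibble(
    gene = "A",
    closest_db = c("A*01:01:01:01", "A*02:01:01:01", "A*03:01:02:01"))
  pop <- tibble::tibble(
    gene = "A",
    allele = c("A*01:01:01:01", "A*01:01:01:02", "A*02:01:02:01",
               "A*04:01:01:01"))
  c4 <- population_coverage(pop, entries, 4L)
  expect_equal(c4$coverage, 0.75)   # A*04 uncovered
  c8 <- population_coverage(pop, entries, 8L)
  expect_equal(c8$coverage, 0.25)
  # monotone in resolution on random panels
  set.seed(601)
  for (i in 1:25) {
    nm <- sprintf("A*%02d:%02d:%02d:%02d",
                  sample(1:4, 12, TRUE), sample(1:3, 12, TRUE),
                  sample(1:2, 12, TRUE), sample(1:2, 12, TRUE))
    entries_i <- tibble::tibble(gene = "A", closest_db = unique(nm)[1:4])
    pop_i <- tibble::tibble(gene = "A", allele = sample(nm, 30, TRUE))
    cov <- vapply(c(4L, 6L, 8L), function(r) {
      population_coverage(pop_i, entries_i, r)$coverage
    }, 0)
    expect_true(cov[1] >= cov[2] && cov[2] >= cov[3])
  }
})

test_that("extension stats count variants in newly covered regions", {
  set.seed(602)
  core <- r_random_dna(800)
  up1 <- r_random_dna(120); up2 <- r_substitute(up1, 3)
  down <- r_random_dna(100)
  s1 <- paste0(up1, core, down); s2 <- paste0(up2, core, down)
  entries <- tibble::tibble(
    allele_id = c("X1", "X2"), gene = "A", closest_db = "A*01:01:01:01",
    length = nchar(s1), db_length = 800L,
    upstream_len = 120L, downstream_len = 100L,
    db_upstream_len = 0L, db_downstream_len = 0L,
    upstream_ext = 120L, downstream_ext = 100L,
    span_start = 120L, span_end = 920L)
  msa <- build_gene_msa(c(X1 = s1, X2 = s2))
  v <- identify_variants(msa)
  v$gene <- "A"
  st <- extension_and_variant_stats(entries, v)
  arow <- st[st$gene == "A", ]
  expect_equal(arow$novel_upstream, 3)
  expect_equal(arow$novel_downstream, 0)
  tot <- st[st$gene == "Total", ]
  expect_equal(tot$n_alleles, 2)
  expect_equal(tot$novel_upstream, 3)
})
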