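#' Derive a known-allele database from a pool
#'
#' Emulates an incomplete allele database: only a fraction of the pool is
#' cataloged, flanks are trimmed to short regulatory stubs (database
#' entries are shorter than the amplicons, so panel alleles extend them),
#' and a fraction of entries carry only the cDNA (concatenated exons), the
#' situation in which a panel allele newly contributes intron sequence.
#'
#' @param pool An [generate_allele_pool()] result.
#' @param include_fraction Fraction of pool alleles cataloged per gene.
#' @param cdna_fraction Fraction of cataloged entries kept as cDNA only.
#' @param keep_upstream,keep_downstream Regulatory stub lengths retained on
#'   genomic entries (bases).
#' @param seed Integer seed.
#' @return A `reference_db`: list with `sequences`, `info` (allele, gene,
#'   cdna_only), `annotations` (exon intervals in entry coordinates).
#' @export
make_reference_db <- function(pool, include_fraction = 0.7,
                              cdna_fraction = 0.15,
                              keep_upstream = 280L, keep_downstream = 250L,
                              seed = 1L) {
  set.seed(seed)
  seqs <- character(0); info <- list(); annots <- list()
  for (g in unique(pool$info$gene)) {
    al <- pool$info$allele[pool$info$gene == g]
    nkeep <- max(1L, ceiling(include_fraction * length(al)))
    keep <- sort(sample(seq_along(al), nkeep))
    cdna <- rep(FALSE, nkeep)
    if (nkeep > 1L && cdna_fraction > 0) {
      cdna[sample(seq_len(nkeep), floor(cdna_fraction * nkeep))] <- TRUE
    }
    for (i in seq_along(keep)) {
      a <- al[keep[i]]
      ex <- pool$annotations[pool$annotations$allele == a &
                               grepl("^exon", pool$annotations$region), ]
      ex <- ex[order(ex$start), ]
      full <- pool$sequences[[a]]
      if (cdna[i]) {
        seqs[[a]] <- paste(substring(full, ex$start + 1L, ex$end),
                           collapse = "")
        offs <- cumsum(c(0L, ex$end - ex$start))
        annots[[a]] <- tibble(allele = a,
                              start = offs[-length(offs)],
                              end = offs[-1L],
                              region = gsub("^exon", "exon", ex$region))
      } else {
        from <- max(0L, min(ex$start) - keep_upstream)
        to <- min(nchar(full), max(ex$end) + keep_downstream)
        seqs[[a]] <- substr(full, from + 1L, to)
        annots[[a]] <- tibble(allele = a, start = ex$start - from,
                              end = ex$end - from, region = ex$region)
      }
    }
    info[[g]] <- tibble(allele = al[keep], gene = g, cdna_only = cdna)
  }
  structure(list(sequences = seqs, info = bind_rows(info),
                 annotations = bind_rows(annots)),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", length(x$sequences), " entries (",
      sum(x$info$cdna_only), " cDNA-only)\n", sep = "")
  invisible(x)
}

#' Draw diploid truth genotypes from an allele pool
#'
#' Two haplotypes per sample and gene, sampled from the pool frequencies;
#' at deletable loci each haplotype is independently deleted with
#' probability `deletion_freq` (allele `NA`).
#'
#' @param pool Allele pool.
#' @param n_samples Number of diploid samples.
#' @param deletion_freq Haplotype deletion frequency at deletable loci.
#' @param seed Integer seed.
#' @return Tibble (`sample`, `gene`, `hap`, `allele`); `allele` is `NA`
#'   for deleted haplotypes.
#' @export
draw_genotypes <- function(pool, n_samples, deletion_freq = 0.3, seed = 1L) {
  stopifnot(deletion_freq >= 0, deletion_freq <= 1)
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  out <- list()
  for (gi in seq_len(nrow(pool$models))) {
    g <- pool$models$gene[gi]
    inf <- pool$info[pool$info$gene == g, ]
    al <- sample(inf$allele, 2L * n_samples, replace = TRUE,
                 prob = inf$frequency)
    if (pool$models$deletable[gi]) {
      al[runif(2L * n_samples) < deletion_freq] <- NA_character_
    }
    out[[g]] <- tibble(sample = rep(samples, each = 2L), gene = g,
                       hap = rep(1:2, n_samples), allele = al)
  }
  bind_rows(out)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: ~30x indel-dominated long-read
#' depth per amplicon, 162 bp paired short reads at ~16x per haplotype
#' (~32x diploid), nested co-amplification of the C-analog inner region by
#' the B primer set at 3x relative depth, and a deletable H-analog locus.
#'
#' @param n_samples Number of diploid samples.
#' @param pool_sizes Named vector, alleles per gene.
#' @param divergence_rate Pool divergence per base.
#' @param long_mismatch,long_insertion,long_deletion Long-read per-base
#'   error probabilities.
#' @param long_depth Long reads per amplicon per haplotype.
#' @param short_read_len,short_error,short_coverage,insert_mean,insert_sd
#'   Short-read geometry: read length (bp), per-base substitution rate,
#'   per-haplotype depth, insert size distribution.
#' @param deletion_freq Haplotype deletion frequency at deletable loci.
#' @param db_include_fraction,db_cdna_fraction Reference-database makeup.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 30L,
                       pool_sizes = c(A = 20L, B = 20L, C = 20L, H = 20L),
                       divergence_rate = 0.01,
                       long_mismatch = 0.01, long_insertion = 0.06,
                       long_deletion = 0.04, long_depth = 30L,
                       short_read_len = 162L, short_error = 0.001,
                       short_coverage = 16, insert_mean = 350, insert_sd = 50,
                       deletion_freq = 0.3,
                       db_include_fraction = 0.7, db_cdna_fraction = 0.15) {
  cfg <- list(n_samples = as.integer(n_samples), pool_sizes = pool_sizes,
              divergence_rate = divergence_rate,
              long_mismatch = long_mismatch, long_insertion = long_insertion,
              long_deletion = long_deletion, long_depth = as.integer(long_depth),
              short_read_len = as.integer(short_read_len),
              short_error = short_error, short_coverage = short_coverage,
              insert_mean = insert_mean, insert_sd = insert_sd,
              deletion_freq = deletion_freq,
              db_include_fraction = db_include_fraction,
              db_cdna_fraction = db_cdna_fraction)
  probs <- c(cfg$long_mismatch, cfg$long_insertion, cfg$long_deletion,
             cfg$short_error, cfg$deletion_freq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# random distinct sample barcodes, pairwise edit distance > 4 so the
# index matcher (max edit 2) cannot confuse them
make_indexes <- function(samples) {
  idx <- character(0)
  while (length(idx) < length(samples)) {
    cand <- random_dna(16L)
    if (all(vapply(idx, function(x) cpp_edit_distance(cand, x) > 4L,
                   logical(1)))) {
      idx <- c(idx, cand)
    }
  }
  tibble(sample = samples, index = idx)
}

# locate amplified interval of a primer set target on one allele
locate_amplicon <- function(seq, fwd_site, rev_site) {
  f <- as.integer(regexpr(fwd_site, seq, fixed = TRUE))
  r <- as.integer(regexpr(rev_site, seq, fixed = TRUE))
  if (f < 0L || r < 0L) return(NULL)
  c(start = f - 1L, end = r - 1L + nchar(rev_site))  # 0-based half-open
}

#' Simulate multiplexed long amplicon reads
#'
#' Each amplicon copy carries the sample's 16 bp index plus the 5 bp
#' universal linker ligated to both primer ends, then per-base errors
#' (mismatch, insertion, deletion) are applied and a random strand is
#' chosen. Nested co-amplification emits additional reads covering only the
#' inner interval at the configured depth multiplier -- the geometry that
#' truncates naive joint assembly of the outer gene.
#'
#' @param pool Allele pool (carries primer sets and targets).
#' @param truth Genotypes from [draw_genotypes()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `reads` tibble (`read_id`, `sample`, `sequence`),
#'   `truth` tibble (`read_id`, `sample`, `gene`, `allele`, `primer_set`,
#'   `full`), `indexes` tibble (`sample`, `index`).
#' @export
simulate_long_reads <- function(pool, truth, config, seed = 1L) {
  set.seed(seed)
  samples <- unique(truth$sample)
  indexes <- make_indexes(samples)
  sets <- pool$primer_sets
  site_of <- setNames(sets$forward, sets$set)
  rsite_of <- setNames(as.character(revcomp(sets$reverse)), sets$set)

  tmpl <- character(0)
  meta <- list()
  for (ti in seq_len(nrow(pool$targets))) {
    tg <- pool$targets[ti, ]
    fwd_site <- site_of[[tg$set]]
    rev_site <- rsite_of[[tg$set]]
    hap <- truth[truth$gene == tg$gene & !is.na(truth$allele), ]
    if (nrow(hap) == 0L) next
    ndup <- as.integer(round(config$long_depth * tg$multiplier))
    for (i in seq_len(nrow(hap))) {
      aseq <- pool$sequences[[hap$allele[i]]]
      iv <- locate_amplicon(aseq, fwd_site, rev_site)
      if (is.null(iv)) {
        stop(sprintf("primer set %s not found in allele %s",
                     tg$set, hap$allele[i]))
      }
      idx <- indexes$index[indexes$sample == hap$sample[i]]
      adapter <- paste0(idx, .UNIVERSAL)
      amp <- paste0(adapter, substr(aseq, iv["start"] + 1L, iv["end"]),
                    as.character(revcomp(adapter)))
      tmpl <- c(tmpl, rep(amp, ndup))
      meta[[length(meta) + 1L]] <- tibble(
        sample = hap$sample[i], gene = tg$gene, allele = hap$allele[i],
        primer_set = tg$set, full = tg$full, n = ndup)
    }
  }
  meta <- bind_rows(meta)
  tr <- meta[rep(seq_len(nrow(meta)), meta$n),
             c("sample", "gene", "allele", "primer_set", "full")]
  reads <- as.character(cpp_simulate_reads(
    tmpl, config$long_mismatch, config$long_insertion, config$long_deletion))
  flip <- runif(length(reads)) < 0.5
  reads[flip] <- as.character(revcomp(reads[flip]))
  tr$read_id <- sprintf("L%06d", seq_along(reads))
  list(reads = tibble(read_id = tr$read_id, sample = tr$sample,
                      sequence = reads),
       truth = tr[, c("read_id", "sample", "gene", "allele",
                      "primer_set", "full")],
       indexes = indexes)
}

#' Simulate paired short reads per sample
#'
#' Emulates locus-extracted WGS reads: fragments start uniformly across
#' (and beyond) each true haplotype, reads are clipped at the locus
#' boundary and kept when they overlap it by at least 50 bp, so coverage
#' stays uniform through the termini. Gaussian insert sizes, substitution
#' errors only, random strand per pair. Deleted haplotypes at a deletable
#' locus yield no reads.
#'
#' @inheritParams simulate_long_reads
#' @return List: `reads` tibble (`read_id`, `sample`, `mate`, `sequence`),
#'   `truth` tibble (`pair_id`, `sample`, `gene`, `allele`, `start`,
#'   `frag_len`).
#' @export
simulate_short_reads <- function(pool, truth, config, seed = 1L) {
  set.seed(seed)
  rl <- config$short_read_len
  minov <- 50L
  hap <- truth[!is.na(truth$allele), ]
  r1 <- character(0); r2 <- character(0)
  meta <- list()
  for (i in seq_len(nrow(hap))) {
    aseq <- pool$sequences[[hap$allele[i]]]
    L <- nchar(aseq)
    flen0 <- as.integer(round(config$insert_mean))
    W <- L + flen0 - 2L * minov
    npairs <- as.integer(round(config$short_coverage * W / (2 * rl)))
    flen <- pmax(rl, as.integer(round(
      rnorm(npairs, config$insert_mean, config$insert_sd))))
    start0 <- as.integer(floor(runif(npairs, -flen + minov, L - minov)))
    fs <- pmax(start0, 0L)
    fe <- pmin(start0 + flen, L)
    frag <- substring(aseq, fs + 1L, fe)
    r1 <- c(r1, substr(frag, 1L, rl))
    r2 <- c(r2, substr(as.character(revcomp(frag)), 1L, rl))
    meta[[i]] <- tibble(sample = hap$sample[i], gene = hap$gene[i],
                        allele = hap$allele[i], start = fs,
                        frag_len = fe - fs)
  }
  meta <- bind_rows(meta)
  npair <- nrow(meta)
  err <- as.character(cpp_simulate_reads(c(r1, r2), config$short_error, 0, 0))
  r1 <- err[seq_len(npair)]; r2 <- err[npair + seq_len(npair)]
  swap <- runif(npair) < 0.5
  tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
  meta$pair_id <- sprintf("P%07d", seq_len(npair))
  reads <- tibble(
    read_id = c(paste0(meta$pair_id, "/1"), paste0(meta$pair_id, "/2")),
    sample = rep(meta$sample, 2L),
    mate = rep(1:2, each = npair),
    sequence = c(r1, r2))
  list(reads = reads,
       truth = meta[, c("pair_id", "sample", "gene", "allele",
                        "start", "frag_len")])
}

#' Simulate a complete dataset
#'
#' Pool, reference database, truth genotypes, long amplicon reads and
#' paired short reads, all reproducible from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (sub-seeds are derived deterministically).
#' @param models Gene models (defaults to [gene_models()]).
#' @return A `sim_dataset` list: `pool`, `db`, `truth`, `long`, `short`,
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L,
                             models = gene_models()) {
  seed <- as.integer(seed) %% 500000000L
  pool <- generate_allele_pool(models, config$pool_sizes,
                               config$divergence_rate, seed = seed)
  db <- make_reference_db(pool, config$db_include_fraction,
                          config$db_cdna_fraction, seed = seed + 1L)
  truth <- draw_genotypes(pool, config$n_samples, config$deletion_freq,
                          seed = seed + 2L)
  long <- simulate_long_reads(pool, truth, config, seed = seed + 3L)
  short <- simulate_short_reads(pool, truth, config, seed = seed + 4L)
  structure(list(pool = pool, db = db, truth = truth, long = long,
                 short = short, config = config, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", length(unique(x$truth$sample)), " samples, ",
      length(x$pool$sequences), " pool alleles, ",
      nrow(x$long$reads), " long reads, ",
      nrow(x$short$reads), " short reads\n", sep = "")
  invisible(x)
}
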