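#' Genotyping parameters
#'
#' @param lambda Per-edit likelihood decay: a read's likelihood against an
#'   allele is `exp(-lambda * edit_distance)`.
#' @param top_k Candidates kept per gene after pre-pruning by total read
#'   score.
#' @param dist_cap_frac Edit distance assigned to a read with no alignment
#'   anchor against a candidate, as a fraction of read length.
#' @param map_k,map_band Anchored-alignment settings.
#' @param max_reads Reads scored per sample and gene (deterministic
#'   subset; ~400 x 162 bp saturates the discriminative positions of a
#'   4-5 kb gene).
#' @param het_penalty Log-likelihood penalty (in edit units) applied to
#'   heterozygous genotypes: an Occam prior so that a single error read
#'   coinciding with another allele's variant cannot flip a homozygote
#'   (true heterozygotes overwhelm it by hundreds of units).
#' @param cn_thresholds Depth-ratio thresholds `(low, high)`: ratio below
#'   `low` calls 0 copies, at or above `high` calls 2.
#' @param rounds Re-genotyping rounds over refined + database candidates
#'   (a fixed point is usually reached after 1).
#' @return A `genotype_params` list.
#' @export
genotype_params <- function(lambda = 1, top_k = 20L, dist_cap_frac = 0.25,
                            map_k = 15L, map_band = 20L, max_reads = 400L,
                            het_penalty = 3,
                            cn_thresholds = c(0.25, 0.75), rounds = 1L) {
  stopifnot(length(cn_thresholds) == 2L,
            cn_thresholds[1] < cn_thresholds[2])
  structure(list(lambda = lambda, top_k = as.integer(top_k),
                 dist_cap_frac = dist_cap_frac, map_k = as.integer(map_k),
                 map_band = as.integer(map_band),
                 max_reads = as.integer(max_reads),
                 het_penalty = het_penalty,
                 cn_thresholds = cn_thresholds, rounds = as.integer(rounds)),
            class = "genotype_params")
}

# assign short reads to genes by k-mer containment against one
# representative sequence per gene; reads are orientation-canonicalized
# (paired-end mates arrive on both strands)
classify_short_reads <- function(read_seqs, gene_refs, k = 15L,
                                 min_frac = 0.3) {
  rcs <- as.character(revcomp(read_seqs))
  contain <- function(seqs, ref) {
    as.numeric(cpp_kmer_containment(seqs, ref, as.integer(k)))
  }
  frf <- vapply(gene_refs, function(ref) contain(read_seqs, ref),
                numeric(length(read_seqs)))
  frr <- vapply(gene_refs, function(ref) contain(rcs, ref),
                numeric(length(read_seqs)))
  if (length(read_seqs) == 1L) {
    frf <- matrix(frf, nrow = 1L); frr <- matrix(frr, nrow = 1L)
  }
  fr <- pmax(frf, frr)
  best <- max.col(fr, ties.method = "first")
  sel <- cbind(seq_along(read_seqs), best)
  ok <- fr[sel] >= min_frac
  flip <- frr[sel] > frf[sel]
  tibble(gene = ifelse(ok, names(gene_refs)[best], NA_character_),
         sequence = ifelse(flip, rcs, read_seqs))
}

# canonicalize read orientation against one reference
orient_reads <- function(read_seqs, ref, k = 15L) {
  rcs <- as.character(revcomp(read_seqs))
  fwd <- as.numeric(cpp_kmer_containment(read_seqs, ref, as.integer(k)))
  rev <- as.numeric(cpp_kmer_containment(rcs, ref, as.integer(k)))
  ifelse(rev > fwd, rcs, read_seqs)
}

#' Copy-number call at a deletable locus from read depth
#'
#' Depth at the locus is normalized by the mean depth over non-deletable
#' normalizer loci; the ratio is thresholded into 0 / 1 / 2 copies
#' (diploid ratio ~1, hemizygous ~0.5, homozygous deletion ~0).
#'
#' @param read_seqs One sample's short-read sequences.
#' @param gene_refs Named list/vector of representative sequences, one per
#'   gene (full amplicon span).
#' @param locus Gene label of the deletable locus.
#' @param normalizers Gene labels used as depth normalizers.
#' @param params [genotype_params()].
#' @return Tibble (`locus`, `depth_locus`, `depth_norm`, `ratio`, `call`).
#' @export
call_copy_number <- function(read_seqs, gene_refs, locus, normalizers,
                             params = genotype_params()) {
  stopifnot(locus %in% names(gene_refs), all(normalizers %in% names(gene_refs)))
  cls <- classify_short_reads(read_seqs, gene_refs)
  depth <- vapply(names(gene_refs), function(g) {
    sum(nchar(read_seqs[!is.na(cls$gene) & cls$gene == g])) /
      nchar(gene_refs[[g]])
  }, 0)
  dn <- mean(depth[normalizers])
  if (dn <= 0) stop("normalizer depth is zero")
  ratio <- depth[[locus]] / dn
  call <- if (ratio < params$cn_thresholds[1]) 0L
  else if (ratio >= params$cn_thresholds[2]) 2L
  else 1L
  tibble(locus = locus, depth_locus = depth[[locus]], depth_norm = dn,
         ratio = ratio, call = call)
}

#' Genotype one sample at one gene by exhaustive diploid likelihood
#'
#' Every read is aligned to every candidate allele; a read's likelihood
#' under a genotype is `exp(-lambda * d)` with `d` the smaller of its edit
#' distances to the two alleles (capped for unalignable reads). All allele
#' multisets of size `copy_number` are scored exhaustively over the
#' `top_k` pre-pruned candidates; the maximum-likelihood genotype and its
#' margin over the runner-up are returned.
#'
#' @param read_seqs The sample's short reads assigned to this gene.
#' @param candidates Named character vector of candidate allele sequences
#'   (refined alleles plus database alleles).
#' @param copy_number 0, 1 or 2.
#' @param params [genotype_params()].
#' @return Tibble (`allele1`, `allele2`, `loglik`, `margin`); zero rows
#'   for copy number 0 or when there are no reads.
#' @export
genotype_sample <- function(read_seqs, candidates, copy_number = 2L,
                            params = genotype_params()) {
  empty <- tibble(allele1 = character(0), allele2 = character(0),
                  loglik = numeric(0), margin = numeric(0))
  if (copy_number == 0L || length(read_seqs) == 0L ||
      length(candidates) == 0L) {
    return(empty)
  }
  if (length(read_seqs) > params$max_reads) {
    read_seqs <- read_seqs[seq_len(params$max_reads)]
  }
  dm <- cpp_read_candidate_dist(read_seqs, unname(candidates),
                                params$map_k, params$map_band)
  cap <- ceiling(params$dist_cap_frac * nchar(read_seqs))
  dm[is.na(dm)] <- 10 * max(cap)
  dm <- pmin(dm, cap)  # cap recycles down columns, matching read rows
  score <- colSums(dm)
  keep <- order(score, names(candidates))[seq_len(min(params$top_k,
                                                      length(candidates)))]
  nm <- names(candidates)[keep]
  dmk <- dm[, keep, drop = FALSE]
  if (copy_number == 1L) {
    ll <- -params$lambda * colSums(dmk)
    ord <- order(-ll, nm)
    return(tibble(allele1 = nm[ord[1]], allele2 = NA_character_,
                  loglik = ll[ord[1]],
                  margin = if (length(ord) > 1L) ll[ord[1]] - ll[ord[2]]
                  else Inf))
  }
  nk <- length(nm)
  pairs <- which(upper.tri(matrix(0, nk, nk), diag = TRUE), arr.ind = TRUE)
  ll <- vapply(seq_len(nrow(pairs)), function(p) {
    -params$lambda * sum(pmin(dmk[, pairs[p, 1]], dmk[, pairs[p, 2]])) -
      params$lambda * params$het_penalty * (pairs[p, 1] != pairs[p, 2])
  }, 0)
  pn1 <- nm[pairs[, 1]]; pn2 <- nm[pairs[, 2]]
  # likelihood ties (e.g. (a,a) vs (a,x) when every read sits on a) are
  # broken toward the pair whose alleles individually explain the reads
  # best, then lexicographically
  sc <- colSums(dmk)
  pair_sc <- sc[pairs[, 1]] + sc[pairs[, 2]]
  ord <- order(-ll, pair_sc, pn1, pn2)
  best <- ord[1]
  tibble(allele1 = pn1[best], allele2 = pn2[best], loglik = ll[best],
         margin = if (length(ord) > 1L) ll[best] - ll[ord[2]] else Inf)
}

#' Genotype every sample at every gene
#'
#' Short reads are assigned to genes, copy number is called at deletable
#' loci, and each sample/gene is genotyped against the refined alleles of
#' that gene plus the database alleles.
#'
#' @param refined An `allele_set` (refined alleles).
#' @param db A `reference_db`.
#' @param short_reads Tibble (`read_id`, `sample`, `sequence`).
#' @param models Gene models (for deletable flags).
#' @param params [genotype_params()].
#' @return List: `calls` tibble (`sample`, `gene`, `allele1`, `allele2`,
#'   `loglik`, `margin`, `copy_number`), `copy_numbers` tibble.
#' @export
genotype_all <- function(refined, db, short_reads, models,
                         params = genotype_params()) {
  genes <- models$gene
  gene_refs <- lapply(setNames(genes, genes), function(g) {
    ids <- refined$info$allele_id[refined$info$gene == g]
    if (length(ids)) {
      ids <- ids[order(-nchar(refined$sequences[ids]), ids)]
      return(refined$sequences[[ids[1]]])
    }
    dbids <- db$info$allele[db$info$gene == g & !db$info$cdna_only]
    if (!length(dbids)) dbids <- db$info$allele[db$info$gene == g]
    db$sequences[[dbids[1]]]
  })
  deletable <- models$gene[models$deletable]
  normalizers <- models$gene[!models$deletable]

  samples <- unique(short_reads$sample)
  cn_list <- list(); call_list <- list()
  for (s in samples) {
    rs <- short_reads$sequence[short_reads$sample == s]
    cls <- classify_short_reads(rs, gene_refs)
    depth <- vapply(genes, function(g) {
      sum(nchar(rs[!is.na(cls$gene) & cls$gene == g])) /
        nchar(gene_refs[[g]])
    }, 0)
    dn <- mean(depth[normalizers])
    for (g in genes) {
      cnum <- 2L
      if (g %in% deletable) {
        ratio <- if (dn > 0) depth[[g]] / dn else 0
        cnum <- if (ratio < params$cn_thresholds[1]) 0L
        else if (ratio >= params$cn_thresholds[2]) 2L
        else 1L
        cn_list[[length(cn_list) + 1L]] <- tibble(
          sample = s, locus = g, depth_locus = depth[[g]],
          depth_norm = dn, ratio = ratio, call = cnum)
      }
      cand <- c(refined$sequences[refined$info$allele_id[
        refined$info$gene == g]],
        db$sequences[db$info$allele[db$info$gene == g]])
      g_reads <- cls$sequence[!is.na(cls$gene) & cls$gene == g]
      gt <- genotype_sample(g_reads, cand, cnum, params)
      call_list[[length(call_list) + 1L]] <- tibble(
        sample = s, gene = g,
        allele1 = if (nrow(gt)) gt$allele1 else NA_character_,
        allele2 = if (nrow(gt)) gt$allele2 else NA_character_,
        loglik = if (nrow(gt)) gt$loglik else NA_real_,
        margin = if (nrow(gt)) gt$margin else NA_real_,
        copy_number = cnum)
    }
  }
  list(calls = bind_rows(call_list), copy_numbers = bind_rows(cn_list))
}

#' Select the final panel from the refined set
#'
#' A refined allele is kept when it appears in at least one sample's best
#' genotype ("recursively genotyped"); alleles never selected are dropped.
#' When all carriers of a dropped allele were genotyped with one common
#' other allele, that allele is recorded as the alteration.
#'
#' @param refined An `allele_set`.
#' @param calls Genotype calls from [genotype_all()].
#' @return List: `panel` (`allele_set`, ids renamed `GENE_00001`-style
#'   ordered by carrier count), `selection` tibble (allele, kept, reason,
#'   alteration), `warnings` tibble of samples genotyped without any
#'   refined allele at a gene.
#' @export
filter_panel <- function(refined, calls) {
  used <- unique(stats::na.omit(c(calls$allele1, calls$allele2)))
  info <- refined$info
  kept <- info$allele_id %in% used
  alter <- rep(NA_character_, nrow(info))
  for (i in which(!kept)) {
    carr <- refined$carriers$sample[refined$carriers$allele_id ==
                                      info$allele_id[i]]
    cc <- calls[calls$sample %in% carr & calls$gene == info$gene[i], ]
    if (nrow(cc) == 0L) next
    common <- Reduce(intersect, lapply(seq_len(nrow(cc)), function(r) {
      unique(stats::na.omit(c(cc$allele1[r], cc$allele2[r])))
    }))
    if (length(common) == 1L) alter[i] <- common
  }
  selection <- tibble(allele_id = info$allele_id, gene = info$gene,
                      kept = kept,
                      reason = ifelse(kept, NA_character_,
                                      "never-genotyped"),
                      alteration = alter)
  # panel carriers follow the genotype calls ("altered" samples move to
  # the allele they were actually genotyped with)
  call_long <- bind_rows(
    calls |> transmute(sample = .data$sample, gene = .data$gene,
                       allele_id = .data$allele1),
    calls |> transmute(sample = .data$sample, gene = .data$gene,
                       allele_id = .data$allele2)) |>
    filter(!is.na(.data$allele_id)) |>
    distinct()
  new_carr <- call_long |>
    filter(.data$allele_id %in% info$allele_id) |>
    select("allele_id", "sample")
  n_carr <- new_carr |> count(.data$allele_id, name = "n_carriers")
  keep_info <- info[kept, , drop = FALSE] |>
    select(-"n_carriers") |>
    left_join(n_carr, by = "allele_id") |>
    arrange(.data$gene, -.data$n_carriers, .data$allele_id) |>
    group_by(.data$gene) |>
    mutate(panel_id = sprintf("%s_%05d", .data$gene, row_number())) |>
    ungroup()
  id_map <- setNames(keep_info$panel_id, keep_info$allele_id)
  panel <- allele_set(
    setNames(refined$sequences[keep_info$allele_id], keep_info$panel_id),
    keep_info |>
      transmute(allele_id = .data$panel_id, gene = .data$gene,
                n_carriers = .data$n_carriers,
                full_length = .data$full_length,
                refined_id = keep_info$allele_id),
    new_carr |>
      mutate(allele_id = id_map[.data$allele_id])
  )
  dbonly <- calls |>
    filter(!is.na(.data$allele1) |
             !is.na(.data$allele2)) |>
    filter(!(.data$allele1 %in% info$allele_id) &
             !(ifelse(is.na(.data$allele2), "", .data$allele2) %in%
                 info$allele_id))
  list(panel = panel, selection = selection,
       warnings = dbonly[, c("sample", "gene", "allele1", "allele2")])
}
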