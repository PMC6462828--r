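#' Gene models for a simulated multi-gene locus
#'
#' Builds the default four-gene locus emulating a class I HLA region:
#' three diploid coding genes (A, B, C) and a deletable pseudogene (H)
#' that is co-amplified by the A primer set. Each gene carries the class I
#' eight-exon structure (CDS 1098 bp) embedded between regulatory flanks;
#' the flank lengths follow the span the amplicons are designed to cover.
#'
#' @param genes Character vector of gene labels to include.
#' @return A tibble with one row per gene: `gene`, `length`,
#'   `upstream_len`, `downstream_len`, `deletable`, `amplified_by`, and a
#'   list-column `exons` of tibbles (`exon`, `start`, `end`; 0-based
#'   half-open absolute coordinates).
#' @export
gene_models <- function(genes = c("A", "B", "C", "H")) {
  defaults <- tibble(
    gene = c("A", "B", "C", "H"),
    length = c(5200L, 4100L, 4470L, 5160L),
    upstream_len = c(850L, 340L, 550L, 820L),
    downstream_len = c(1430L, 1080L, 1020L, 1440L),
    deletable = c(FALSE, FALSE, FALSE, TRUE),
    amplified_by = c("A", "B", "C", "A")
  )
  m <- defaults[defaults$gene %in% genes, , drop = FALSE]
  if (nrow(m) == 0L) stop("no known genes requested")
  m$exons <- lapply(seq_len(nrow(m)), function(i) {
    class1_exons(m$length[i], m$upstream_len[i], m$downstream_len[i])
  })
  validate_gene_models(m)
  m
}

# class I exon sizes; total CDS 1098 bp (divisible by 3)
.exon_sizes <- c(73L, 270L, 276L, 276L, 117L, 33L, 48L, 5L)
.intron_profile <- c(130, 240, 580, 100, 440, 115, 120)

class1_exons <- function(length, upstream_len, downstream_len) {
  span <- length - upstream_len - downstream_len
  intron_total <- span - sum(.exon_sizes)
  if (intron_total < 7L * 20L) stop("gene span too short for exon model")
  introns <- floor(.intron_profile / sum(.intron_profile) * intron_total)
  introns[length(introns)] <- intron_total - sum(introns[-length(introns)])
  starts <- upstream_len + cumsum(c(0L, .exon_sizes[-8] + introns))
  tibble(exon = 1:8, start = as.integer(starts),
         end = as.integer(starts + .exon_sizes))
}

validate_gene_models <- function(models) {
  stopifnot(all(models$length >= 2000L))
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    stopifnot(all(diff(ex$start) > 0), all(ex$end > ex$start),
              all(ex$start[-1] >= ex$end[-nrow(ex)]),
              all(ex$start >= models$upstream_len[i]),
              all(ex$end <= models$length[i] - models$downstream_len[i]))
  }
  invisible(models)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.PRIMER_LEN <- 25L
.NEST_OFFSET <- 310L
.UNIVERSAL <- "GGTAG"

#' Generate a pool of known alleles for each gene
#'
#' One random ancestral sequence per gene is mutated into `pool_sizes`
#' distinct alleles: substitutions at `divergence_rate` per base plus
#' occasional 1-4 bp indels restricted to non-exonic regions (so the
#' coding frame is preserved, as in expressed alleles). Primer annealing
#' sites -- the gene's own terminal sites, the nested inner sites planted in
#' the C-analog, and the A-set sites flanking the deletable H-analog -- are
#' masked from mutation, emulating primers designed on conserved regions.
#' Exon annotations are lifted through indels; allele frequencies are drawn
#' from a symmetric Dirichlet. Allele names follow `GENE*gg:pp:ss:nn`:
#' the first two fields index the protein (4-digit resolution), the third
#' synonymous exonic variation (6-digit), the fourth non-coding genomic
#' variation (8-digit).
#'
#' @param models Gene models from [gene_models()].
#' @param pool_sizes Named integer vector, alleles per gene.
#' @param divergence_rate Per-base substitution rate in (0, 0.05].
#' @param indel_rate Per-base indel rate (default `divergence_rate / 10`).
#' @param derived_fraction Fraction of alleles derived from an existing
#'   allele rather than the ancestor, creating 4/6/8-digit allele
#'   families.
#' @param syn_fraction Among derived alleles, the fraction that also carry
#'   synonymous exonic changes (a new 6-digit subtype); the rest differ in
#'   non-coding sequence only (a new 8-digit subtype).
#' @param seed Integer seed; fixed seed gives byte-identical pools.
#' @return An `allele_pool`: list with `sequences` (named character),
#'   `info` (allele, gene, frequency, protein/exon group ids),
#'   `annotations` (allele, start, end, region), `mutations` (truth
#'   records incl. synonymous status), `models`, `primer_sets`, `targets`
#'   (which primer set amplifies which gene at which depth multiplier).
#' @export
generate_allele_pool <- function(models, pool_sizes,
                                 divergence_rate = 0.01,
                                 indel_rate = divergence_rate / 10,
                                 derived_fraction = 0.4,
                                 syn_fraction = 0.35,
                                 seed = 1L) {
  if (divergence_rate <= 0 || divergence_rate > 0.05) {
    stop("divergence_rate must be in (0, 0.05]")
  }
  stopifnot(all(models$gene %in% names(pool_sizes)),
            all(pool_sizes[models$gene] >= 1L))
  set.seed(seed)

  anc <- setNames(vapply(models$length, random_dna, ""), models$gene)
  # terminal primer annealing sites per gene
  pl <- .PRIMER_LEN
  site_f <- substr(anc, 1L, pl)
  site_r <- substr(anc, nchar(anc) - pl + 1L, nchar(anc))
  # the deletable locus is amplified by its host set: copy host terminal sites
  for (g in models$gene[models$amplified_by != models$gene]) {
    host <- models$amplified_by[models$gene == g]
    substr(anc[g], 1L, pl) <- site_f[host]
    substr(anc[g], nchar(anc[g]) - pl + 1L, nchar(anc[g])) <- site_r[host]
  }
  masks <- lapply(setNames(models$gene, models$gene), function(g) {
    L <- nchar(anc[g])
    tibble(start = c(0L, L - pl), end = c(pl, L))
  })
  # nested geometry: the B set co-amplifies an inner interval of the C gene
  targets <- tibble(set = character(), gene = character(),
                    f_site = character(), multiplier = numeric(),
                    full = logical())
  own <- models$gene[models$amplified_by == models$gene]
  for (g in own) {
    targets <- bind_rows(targets, tibble(
      set = g, gene = g, f_site = "terminal", multiplier = 1, full = TRUE))
  }
  for (g in models$gene[models$amplified_by != models$gene]) {
    targets <- bind_rows(targets, tibble(
      set = models$amplified_by[models$gene == g], gene = g,
      f_site = "terminal", multiplier = 1, full = TRUE))
  }
  if (all(c("B", "C") %in% models$gene)) {
    LC <- nchar(anc["C"])
    substr(anc["C"], .NEST_OFFSET + 1L, .NEST_OFFSET + pl) <- site_f["B"]
    substr(anc["C"], LC - .NEST_OFFSET - pl + 1L, LC - .NEST_OFFSET) <-
      site_r["B"]
    masks$C <- bind_rows(masks$C, tibble(
      start = c(.NEST_OFFSET, LC - .NEST_OFFSET - pl),
      end = c(.NEST_OFFSET + pl, LC - .NEST_OFFSET)))
    targets <- bind_rows(targets, tibble(
      set = "B", gene = "C", f_site = "nested", multiplier = 3, full = FALSE))
  }
  primer_sets <- tibble(
    set = unname(own),
    forward = unname(site_f[own]),
    reverse = unname(as.character(revcomp(site_r[own])))
  )

  seqs <- character(0); info <- list(); annots <- list(); muts <- list()
  for (gi in seq_len(nrow(models))) {
    g <- models$gene[gi]
    npool <- pool_sizes[[g]]
    ex <- models$exons[[gi]]
    res <- mutate_pool(anc[[g]], npool, ex, masks[[g]],
                       divergence_rate, indel_rate,
                       derived_fraction, syn_fraction)
    names(res$seqs) <- paste0(g, "_tmp", seq_len(npool))
    freqs <- rgamma(npool, shape = 1)
    freqs <- freqs / sum(freqs)
    nm <- name_alleles(g, res$seqs, res$exon_tabs)
    names(res$seqs) <- nm
    seqs <- c(seqs, res$seqs)
    info[[g]] <- tibble(allele = nm, gene = g, frequency = freqs)
    annots[[g]] <- bind_rows(lapply(seq_len(npool), function(a) {
      et <- res$exon_tabs[[a]]
      L <- nchar(res$seqs[a])
      bind_rows(
        tibble(allele = nm[a], start = 0L, end = min(et$start),
               region = "upstream"),
        tibble(allele = nm[a], start = et$start, end = et$end,
               region = paste0("exon", et$exon)),
        tibble(allele = nm[a], start = max(et$end), end = L,
               region = "downstream"))
    }))
    m <- res$mutations
    m$allele <- nm[m$allele_idx]
    m$parent_allele <- ifelse(is.na(m$parent), NA_character_, nm[m$parent])
    muts[[g]] <- m[, c("allele", "pos", "type", "ref", "alt",
                       "region", "synonymous", "parent_allele")]
  }
  structure(list(
    sequences = seqs,
    info = bind_rows(info),
    annotations = bind_rows(annots),
    mutations = bind_rows(muts),
    models = models,
    primer_sets = primer_sets,
    targets = targets
  ), class = "allele_pool")
}

# mutate one ancestor into n distinct alleles; lifts exon coords through
# indels and records per-mutation region + synonymous status
mutate_pool <- function(ancestor, n, exons, mask, sub_rate, indel_rate,
                        derived_fraction = 0.4, syn_fraction = 0.35,
                        max_retry = 20L) {
  L <- nchar(ancestor)
  masked <- rep(FALSE, L)
  for (i in seq_len(nrow(mask))) masked[(mask$start[i] + 1L):mask$end[i]] <- TRUE
  exonic <- rep(FALSE, L)
  for (i in seq_len(nrow(exons))) exonic[(exons$start[i] + 1L):exons$end[i]] <- TRUE
  anc_chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  region_of <- function(pos0) {  # 0-based ancestor position
    hit <- which(exons$start <= pos0 & pos0 < exons$end)
    if (length(hit)) return(paste0("exon", exons$exon[hit[1]]))
    if (pos0 < min(exons$start)) return("upstream")
    if (pos0 >= max(exons$end)) return("downstream")
    paste0("intron", max(which(exons$end <= pos0)))
  }
  cds_pos <- cumsum(exonic)  # 1-based CDS index for exonic positions
  # indel events can span up to 5 following bases: precompute positions whose
  # 6-base window is clear of exons and masked primer sites
  bad <- cumsum(c(0L, as.integer(masked | exonic)))
  win_clear <- which((bad[7:(L + 1L)] - bad[1:(L - 5L)]) == 0L)
  win_clear <- win_clear[win_clear > 30L & win_clear < L - 30L]

  # conserved site strings, used to re-locate masks on derived parents
  mask_strs <- substring(ancestor, mask$start + 1L, mask$end)

  seqs <- character(n); exon_tabs <- vector("list", n); mrecs <- list()
  seen <- character(0)
  for (a in seq_len(n)) {
    ok <- FALSE
    # allele families: with probability derived_fraction an allele derives
    # from an already generated one by noncoding-only (or additionally
    # synonymous-exonic) substitutions, so several alleles share a protein
    # (4-digit family) or an exonic sequence (6-digit family)
    if (a > 1L && runif(1) < derived_fraction) {
      parent <- sample.int(a - 1L, 1L)
      mode <- if (runif(1) < syn_fraction) "synonymous" else "noncoding"
      for (try in seq_len(max_retry)) {
        ch <- derive_allele(seqs[parent], exon_tabs[[parent]], mask_strs,
                            sub_rate, mode)
        if (!(ch$seq %in% seen) && ch$seq != ancestor) {
          seqs[a] <- ch$seq
          exon_tabs[[a]] <- exon_tabs[[parent]]
          if (nrow(ch$rec)) {
            ch$rec$allele_idx <- a
            ch$rec$parent <- parent
            mrecs[[length(mrecs) + 1L]] <- ch$rec
          }
          seen <- c(seen, ch$seq)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to derive a distinct allele after retries")
      next
    }
    for (try in seq_len(max_retry)) {
      nsub <- rbinom(1L, L, sub_rate)
      sub_pos <- sample(which(!masked), min(nsub, sum(!masked)))
      nind <- rbinom(1L, L, indel_rate)
      ind_ok <- win_clear
      ind_pos <- if (nind > 0L) sample(ind_ok, min(nind, length(ind_ok))) else integer(0)

      chars <- anc_chars
      rec <- list()
      for (p in sub_pos) {
        old <- chars[p]
        newb <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        chars[p] <- newb
        syn <- NA
        reg <- region_of(p - 1L)
        if (exonic[p]) {
          ci <- cds_pos[p]
          cod0 <- (ci - 1L) %/% 3L
          in_cod <- (ci - 1L) %% 3L + 1L
          cod_idx <- which(exonic)[(cod0 * 3L + 1L):(cod0 * 3L + 3L)]
          old_cod <- anc_chars[cod_idx]
          new_cod <- old_cod; new_cod[in_cod] <- newb
          syn <- translate_codon(paste(old_cod, collapse = "")) ==
            translate_codon(paste(new_cod, collapse = ""))
        }
        rec[[length(rec) + 1L]] <- tibble(
          allele_idx = a, pos = p - 1L, type = "sub", ref = old, alt = newb,
          region = reg, synonymous = syn)
      }
      # indels, applied right-to-left so earlier positions stay valid
      ind_tab <- tibble(pos = integer(0), len = integer(0), ins = logical(0))
      if (length(ind_pos)) {
        lens <- sample(1:4, length(ind_pos), replace = TRUE)
        is_ins <- runif(length(ind_pos)) < 0.5
        ord <- order(ind_pos, decreasing = TRUE)
        out <- chars
        for (i in ord) {
          p <- ind_pos[i]
          if (is_ins[i]) {
            insseq <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
            out <- append(out, insseq, after = p)
            rec[[length(rec) + 1L]] <- tibble(
              allele_idx = a, pos = p - 1L, type = "ins", ref = "",
              alt = paste(insseq, collapse = ""),
              region = region_of(p - 1L), synonymous = NA)
          } else {
            dl <- min(lens[i], L - p - 30L)
            if (dl < 1L) next
            delseq <- paste(chars[(p + 1L):(p + dl)], collapse = "")
            out <- out[-((p + 1L):(p + dl))]
            rec[[length(rec) + 1L]] <- tibble(
              allele_idx = a, pos = p - 1L, type = "del", ref = delseq,
              alt = "", region = region_of(p - 1L), synonymous = NA)
          }
        }
        chars <- out
        ind_tab <- tibble(pos = ind_pos - 1L,
                          len = ifelse(is_ins, lens, -lens),
                          ins = is_ins)
      }
      s <- paste(chars, collapse = "")
      if (!(s %in% seen) && s != ancestor) {
        seqs[a] <- s
        exon_tabs[[a]] <- lift_exons(exons, ind_tab)
        if (length(rec)) {
          rr <- bind_rows(rec)
          rr$parent <- NA_integer_
          mrecs[[length(mrecs) + 1L]] <- rr
        }
        seen <- c(seen, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to generate a distinct allele after retries; ",
                  "increase divergence_rate or reduce pool size")
  }
  muts <- if (length(mrecs)) bind_rows(mrecs) else
    tibble(allele_idx = integer(0), pos = integer(0), type = character(0),
           ref = character(0), alt = character(0), region = character(0),
           synonymous = logical(0), parent = integer(0))
  list(seqs = seqs, exon_tabs = exon_tabs, mutations = muts)
}

# derive a child allele from a parent by noncoding substitutions (mode
# "noncoding") plus, for mode "synonymous", 1-3 silent exonic changes
derive_allele <- function(parent_seq, extab, mask_strs, sub_rate, mode,
                          max_tries = 100L) {
  Lp <- nchar(parent_seq)
  chars <- strsplit(parent_seq, "", fixed = TRUE)[[1]]
  exonicP <- rep(FALSE, Lp)
  for (i in seq_len(nrow(extab))) {
    exonicP[(extab$start[i] + 1L):extab$end[i]] <- TRUE
  }
  maskedP <- rep(FALSE, Lp)
  for (s in mask_strs) {
    p <- as.integer(regexpr(s, parent_seq, fixed = TRUE))
    if (p > 0L) maskedP[p:(p + nchar(s) - 1L)] <- TRUE
  }
  region_of <- function(pos0) {
    hit <- which(extab$start <= pos0 & pos0 < extab$end)
    if (length(hit)) return(paste0("exon", extab$exon[hit[1]]))
    if (pos0 < min(extab$start)) return("upstream")
    if (pos0 >= max(extab$end)) return("downstream")
    paste0("intron", max(which(extab$end <= pos0)))
  }
  cand <- which(!maskedP & !exonicP)
  cand <- cand[cand > 30L & cand < Lp - 30L]
  # subtypes within a family differ by a handful of variants
  nsub <- max(1L, rbinom(1L, length(cand), sub_rate / 4))
  pos <- sample(cand, min(nsub, length(cand)))
  rec <- list()
  for (p in pos) {
    old <- chars[p]
    newb <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    chars[p] <- newb
    rec[[length(rec) + 1L]] <- tibble(
      allele_idx = NA_integer_, pos = p - 1L, type = "sub", ref = old,
      alt = newb, region = region_of(p - 1L), synonymous = NA)
  }
  if (mode == "synonymous") {
    cds_idx <- which(exonicP)
    nsyn <- sample.int(3L, 1L)
    placed <- 0L
    for (tries in seq_len(max_tries)) {
      if (placed >= nsyn) break
      ci <- sample.int(length(cds_idx), 1L)
      cod0 <- (ci - 1L) %/% 3L
      cod_idx <- cds_idx[(cod0 * 3L + 1L):(cod0 * 3L + 3L)]
      if (any(is.na(cod_idx))) next
      in_cod <- (ci - 1L) %% 3L + 1L
      p <- cod_idx[in_cod]
      old <- chars[p]
      for (alt in sample(setdiff(c("A", "C", "G", "T"), old))) {
        new_cod <- chars[cod_idx]; new_cod[in_cod] <- alt
        if (translate_codon(paste(chars[cod_idx], collapse = "")) ==
            translate_codon(paste(new_cod, collapse = ""))) {
          chars[p] <- alt
          rec[[length(rec) + 1L]] <- tibble(
            allele_idx = NA_integer_, pos = p - 1L, type = "sub", ref = old,
            alt = alt, region = region_of(p - 1L), synonymous = TRUE)
          placed <- placed + 1L
          break
        }
      }
    }
  }
  list(seq = paste(chars, collapse = ""),
       rec = if (length(rec)) bind_rows(rec) else
         tibble(allele_idx = integer(0), pos = integer(0),
                type = character(0), ref = character(0), alt = character(0),
                region = character(0), synonymous = logical(0)))
}

# shift 0-based exon coordinates through signed indel events
lift_exons <- function(exons, ind_tab) {
  if (nrow(ind_tab) == 0L) return(exons)
  shift <- function(x) {
    x + vapply(x, function(p) sum(ind_tab$len[ind_tab$pos < p]), 0)
  }
  tibble(exon = exons$exon,
         start = as.integer(shift(exons$start)),
         end = as.integer(shift(exons$end)))
}

translate_codon <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

translate_cds <- function(seq) {
  if (nchar(seq) %% 3L != 0L) {
    stop("coding sequence length not divisible by 3")
  }
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE))
}

# GENE*gg:pp:ss:nn from protein / exon-nucleotide / genomic equivalence
name_alleles <- function(gene, seqs, exon_tabs) {
  n <- length(seqs)
  prot <- character(n); exnt <- character(n)
  for (a in seq_len(n)) {
    et <- exon_tabs[[a]]
    cds <- paste(substring(seqs[a], et$start + 1L, et$end), collapse = "")
    exnt[a] <- cds
    prot[a] <- translate_cds(cds)
  }
  pg <- match(prot, unique(prot))
  name <- character(n)
  for (p in unique(pg)) {
    ia <- which(pg == p)
    sg <- match(exnt[ia], unique(exnt[ia]))
    for (s in unique(sg)) {
      ib <- ia[sg == s]
      for (j in seq_along(ib)) {
        name[ib[j]] <- sprintf("%s*%02d:01:%02d:%02d", gene, p, s, j)
      }
    }
  }
  name
}

#' @export
print.allele_pool <- function(x, ...) {
  cat("<allele_pool> ", length(x$sequences), " alleles over ",
      nrow(x$models), " genes\n", sep = "")
  print(dplyr::count(x$info, .data$gene))
  invisible(x)
}
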