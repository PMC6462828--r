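#' Assembly parameters
#'
#' @param min_cluster_fraction Clusters smaller than this fraction of their
#'   amplicon group are dissolved into the major cluster.
#' @param min_support_reads Minimum reads supporting a surviving contig.
#' @param fuse_identity Pairwise identity (over the shorter contig's span)
#'   at or above which contigs of one sample/gene are merged. The default
#'   0.995 keeps true heterozygous pairs (~1% apart) separate while fusing
#'   error-bearing duplicates.
#' @param max_alleles_per_bin Alleles kept per sample and gene (1 or 2).
#' @param min_coverage_fraction Consensus columns at the contig ends with
#'   read coverage below this fraction of the cluster are trimmed; this is
#'   what truncates a consensus when nested inner reads dominate a
#'   non-separated pool.
#' @param het_min_fraction,het_link_jaccard Heterozygous-column calling:
#'   minimum minor-symbol fraction, and minimum Jaccard overlap of minor
#'   read sets for two columns to count as linked.
#' @param coarse_containment Minimum fraction of a read's k-mers shared
#'   with a group seed for coarse (per-amplicon) grouping.
#' @param map_band Band half-width for read-to-template alignment of
#'   long reads (anchored on an interpolated diagonal, so it only needs to
#'   absorb the random-walk part of the indel drift).
#' @param polish_max_reads Reads used for consensus polishing per cluster
#'   (a deterministic subset; support counts still reflect the full
#'   cluster).
#' @param max_rounds Maximum polishing rounds.
#' @return An `assembly_params` list.
#' @export
assembly_params <- function(min_cluster_fraction = 0.2,
                            min_support_reads = 3L,
                            fuse_identity = 0.995,
                            max_alleles_per_bin = 2L,
                            min_coverage_fraction = 0.3,
                            het_min_fraction = 0.25,
                            het_link_jaccard = 0.5,
                            coarse_containment = 0.02,
                            map_band = 60L,
                            polish_max_reads = 40L,
                            max_rounds = 5L) {
  stopifnot(min_cluster_fraction > 0, min_cluster_fraction <= 1,
            max_alleles_per_bin %in% 1:2)
  structure(as.list(environment()), class = "assembly_params")
}

# coarse per-amplicon grouping: greedy seeding from the longest read,
# membership by k-mer containment in the seed
coarse_groups <- function(seqs, params, k = 11L) {
  n <- length(seqs)
  group <- rep(NA_integer_, n)
  ord <- order(-nchar(seqs), seqs)
  g <- 0L
  for (i in ord) {
    if (!is.na(group[i])) next
    g <- g + 1L
    todo <- which(is.na(group))
    frac <- cpp_kmer_containment(seqs[todo], seqs[i], as.integer(k))
    group[todo[frac >= params$coarse_containment]] <- g
    group[i] <- g
  }
  group
}

#' Cluster the reads of one bin into haplotype groups
#'
#' Reads are first coarsely grouped into amplicon groups (different genes
#' co-amplified by the same primer set separate here), then each group is
#' split into at most two haplotype clusters: candidate heterozygous
#' columns are called where the minor symbol reaches `het_min_fraction`
#' with at least `min_support_reads` reads, and a split is made only when
#' two or more such columns are linked (their minor read sets overlap at
#' Jaccard >= `het_link_jaccard`), which protects homozygous bins from
#' error columns. Clusters below `min_cluster_fraction` of the group are
#' dissolved into the major cluster.
#'
#' @param sequences Character vector of binned read sequences
#'   (orientation-normalized).
#' @param params [assembly_params()].
#' @return A list of integer vectors (read indices per cluster), each with
#'   attribute `seed` (index of the group seed read).
#' @export
cluster_bin <- function(sequences, params = assembly_params()) {
  n <- length(sequences)
  if (n < params$min_support_reads) return(list())
  groups <- coarse_groups(sequences, params)
  clusters <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < params$min_support_reads) next
    seed <- idx[order(-nchar(sequences[idx]), sequences[idx])][1]
    split <- split_haplotypes(sequences[idx], sequences[seed], params)
    m <- attr(split, "map")
    for (cl in split) {
      v <- idx[cl]
      attr(v, "seed") <- seed
      if (!is.null(m)) {
        attr(v, "map") <- list(mapped = m$mapped[cl], start = m$start[cl],
                               end = m$end[cl], dist = m$dist[cl],
                               proj = m$proj[cl], ins = m$ins[cl])
      }
      clusters[[length(clusters) + 1L]] <- v
    }
  }
  clusters
}

split_haplotypes <- function(seqs, seed_seq, params) {
  n <- length(seqs)
  # noise-free groups collapse to at most two distinct read sequences:
  # split by exact identity (resolves haplotype pairs differing at a
  # single position, which the linked-column test cannot)
  uu <- unique(seqs)
  if (length(uu) == 1L) return(list(seq_len(n)))
  if (length(uu) == 2L) {
    i1 <- which(seqs == uu[1]); i2 <- which(seqs == uu[2])
    if (min(length(i1), length(i2)) >=
        max(params$min_support_reads, params$min_cluster_fraction * n)) {
      return(list(i1, i2))
    }
  }
  m <- cpp_map_reads(seqs, seed_seq, 11L, params$map_band, TRUE, TRUE)
  cnt <- cpp_column_counts(ifelse(m$mapped, m$start, -1L), m$proj,
                           nchar(seed_seq))
  cov <- colSums(cnt)
  # candidate heterozygous columns must look like substitutions: both the
  # top and the second symbol are bases. Columns dominated or seconded by
  # deletions are indel noise (e.g. every read deleting against a seed
  # read's insertion error) and must not seed a phase split.
  symbols <- c("A", "C", "G", "T", "-")
  o <- apply(cnt, 2, function(x) order(-x)[1:2])
  top_cnt <- cnt[cbind(o[1, ], seq_along(cov))]
  second_cnt <- cnt[cbind(o[2, ], seq_along(cov))]
  bases_ok <- o[1, ] <= 4L & o[2, ] <= 4L
  het <- which(bases_ok & cov >= params$min_support_reads &
                 second_cnt >= params$min_support_reads &
                 second_cnt / pmax(cov, 1L) >= params$het_min_fraction)
  if (length(het) >= 2L) {
    # cap the phasing columns at the strongest 40
    if (length(het) > 40L) {
      het <- het[order(-(second_cnt / cov)[het])][1:40]
      het <- sort(het)
    }
    ext <- cpp_extract_columns(ifelse(m$mapped, m$start, -1L), m$proj,
                               as.integer(het - 1L))
    minor_sym <- symbols[o[2, het]]
    minor_sets <- lapply(seq_along(het), function(ci) {
      which(!is.na(ext[, ci]) & ext[, ci] == minor_sym[ci])
    })
    jac <- function(a, b) {
      if (!length(a) || !length(b)) return(0)
      length(intersect(a, b)) / length(union(a, b))
    }
    nlink <- vapply(seq_along(het), function(i) {
      sum(vapply(seq_along(het), function(j) {
        i != j && jac(minor_sets[[i]], minor_sets[[j]]) >=
          params$het_link_jaccard
      }, logical(1)))
    }, 0L)
    if (any(nlink >= 1L)) {
      anchor <- which.max(nlink)
      phase <- c(anchor, which(vapply(seq_along(het), function(j) {
        j != anchor && jac(minor_sets[[anchor]], minor_sets[[j]]) >=
          params$het_link_jaccard
      }, logical(1))))
      score <- integer(n)
      for (ci in phase) {
        maj <- symbols[o[1, het[ci]]]; mnr <- minor_sym[ci]
        sc <- ifelse(is.na(ext[, ci]), 0L,
                     ifelse(ext[, ci] == mnr, 1L,
                            ifelse(ext[, ci] == maj, -1L, 0L)))
        score <- score + sc
      }
      cl_minor <- which(score > 0L)
      cl_major <- setdiff(seq_len(n), cl_minor)
      sizes <- c(length(cl_major), length(cl_minor))
      if (min(sizes) >= params$min_cluster_fraction * n &&
          min(sizes) >= params$min_support_reads) {
        return(structure(list(cl_major, cl_minor), map = m))
      }
    }
  }
  structure(list(seq_len(n)), map = m)
}

#' Polish a consensus from a read cluster
#'
#' Iterative consensus: reads are aligned to the current template, each
#' column takes the majority symbol (deletion included; ties keep the
#' template base), insertions carried by a majority of spanning reads are
#' added, and the template is replaced until a fixed point (at most
#' `max_rounds` rounds). Ends with coverage below
#' `min_coverage_fraction` of the cluster are trimmed.
#'
#' @param sequences Reads of one cluster.
#' @param seed_sequence Initial template (e.g. the longest read).
#' @param params [assembly_params()].
#' @param init_map Optional precomputed mapping of `sequences` onto
#'   `seed_sequence` (reused from clustering to save an alignment pass).
#' @return List: `sequence`, `rounds`, `converged`.
#' @export
polish_consensus <- function(sequences, seed_sequence,
                             params = assembly_params(), init_map = NULL) {
  stopifnot(length(sequences) >= 1L)
  if (length(sequences) > params$polish_max_reads) {
    # evenly spaced deterministic subset, so mixtures (e.g. full-length +
    # nested inner reads) keep their composition
    keep <- unique(round(seq(1, length(sequences),
                             length.out = params$polish_max_reads)))
    sequences <- sequences[keep]
    if (!is.null(init_map)) {
      init_map <- lapply(init_map, function(x) x[keep])
    }
  }
  template <- seed_sequence
  min_cov <- params$min_coverage_fraction * length(sequences)
  converged <- FALSE
  rounds <- 0L
  m <- NULL
  for (it in seq_len(params$max_rounds)) {
    rounds <- it
    m <- if (it == 1L && !is.null(init_map)) init_map else
      cpp_map_reads(sequences, template, 11L, params$map_band, TRUE, TRUE)
    st <- ifelse(m$mapped, m$start, -1L)
    en <- ifelse(m$mapped, m$end, -1L)
    cons <- cpp_consensus(st, en, m$proj, m$ins, template, min_cov)
    if (!nzchar(cons$seq)) return(list(sequence = "", rounds = rounds,
                                       converged = FALSE))
    if (cons$seq == template) {
      converged <- TRUE
      break
    }
    template <- cons$seq
    m <- NULL  # stale after template change
  }
  if (!converged && rounds == params$max_rounds) {
    warning("consensus did not converge after ", params$max_rounds,
            " rounds; returning last template")
  }
  if (length(sequences) >= params$min_support_reads) {
    template <- window_repolish(sequences, template, params, map = m)
  }
  list(sequence = template, rounds = rounds, converged = converged)
}

# Column-majority voting can reach a self-consistent but wrong fixed point
# in indel-dense windows (votes scatter over neighbouring columns and
# junctions), which per-column statistics cannot detect. Re-polish by
# tiling the template with windows (two offset phases) and replacing each
# window with the plurality raw read substring when it wins by a clear
# margin over the runner-up.
window_repolish <- function(sequences, template, params, width = 16L,
                            map = NULL) {
  m <- map
  for (phase in c(0L, width %/% 2L)) {
    n <- nchar(template)
    if (is.null(m)) {
      m <- cpp_map_reads(sequences, template, 11L, params$map_band,
                         TRUE, TRUE)
    }
    st <- ifelse(m$mapped, m$start, -1L)
    en <- ifelse(m$mapped, m$end, -1L)
    starts <- seq(phase, max(phase, n - 1L), by = width)
    repl <- list()
    for (us in starts) {
      ue <- min(us + width, n)
      if (ue <= us) next
      obs <- cpp_window_obs(st, en, m$proj, m$ins, us, ue, n)
      if (length(obs) < params$min_support_reads) next
      # center-string vote: few reads are error-free across a whole
      # window, so pick the candidate substring minimizing the total edit
      # distance to all covered read substrings; the template only loses
      # on a strict improvement (ties keep it)
      tpl <- substr(template, us + 1L, ue)
      cs <- cpp_center_string(obs, tpl)
      if (cs$best != tpl && cs$best_sum < cs$template_sum) {
        repl[[length(repl) + 1L]] <- list(us = us, ue = ue, new = cs$best)
      }
    }
    if (length(repl)) {
      for (r in rev(repl)) {
        template <- paste0(substr(template, 1L, r$us), r$new,
                           substr(template, r$ue + 1L, nchar(template)))
      }
      m <- NULL  # stale after replacements
    }
  }
  template
}

#' Fuse the contigs of one sample and gene
#'
#' Single-linkage grouping: identical contigs merge, and a contained
#' contig (markedly shorter, aligning within the longer at identity >=
#' `fuse_identity` over its own span) always merges into its container --
#' this is what removes truncated nested inner amplicons in favour of the
#' full-length consensus. Same-length near-duplicates are deliberately
#' NOT merged by distance: a pair of true haplotypes can differ by a
#' single base, indistinguishable from an error duplicate by distance
#' alone, so arbitration between them is left to the short-read
#' refinement (error-bearing duplicates become identical after correction
#' and merge there). Each group is fused into its preferred
#' representative (full-length first, then most support, longest,
#' lexicographic), supports are summed, and the top `max_alleles_per_bin`
#' groups with support >= `min_support_reads` survive.
#'
#' @param contigs Tibble with `sequence`, `n_support`, `full_length`.
#' @param params [assembly_params()].
#' @return Tibble of surviving contigs (same columns), possibly 0 rows.
#' @export
fuse_contigs <- function(contigs, params = assembly_params()) {
  n <- nrow(contigs)
  if (n == 0L) return(contigs)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (n > 1L) {
    # identical contigs always merge
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (contigs$sequence[i] == contigs$sequence[j]) {
          comp[find(j)] <- find(i)
        }
      }
    }
    # a truncated contig (missing its gene's primers) merges into its
    # single best container at identity >= fuse_identity over its own
    # span. Complete near-duplicates are deliberately NOT distance-merged
    # (two true haplotypes may differ by one base), and a truncation
    # joins only its closest container so it cannot bridge two sibling
    # haplotypes into one group.
    for (j in which(!contigs$full_length)) {
      cand <- which(nchar(contigs$sequence) >= nchar(contigs$sequence[j]) &
                      seq_len(n) != j)
      if (!length(cand)) next
      d <- vapply(cand, function(i) {
        cpp_semiglobal(contigs$sequence[j], contigs$sequence[i])$dist
      }, 0L)
      ident <- 1 - d / nchar(contigs$sequence[j])
      ok <- ident >= params$fuse_identity
      if (!any(ok)) next
      best <- cand[ok][order(d[ok], -nchar(contigs$sequence[cand[ok]]),
                             contigs$sequence[cand[ok]])][1]
      comp[find(j)] <- find(best)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  fused <- lapply(unique(comp), function(cmp) {
    mem <- contigs[comp == cmp, , drop = FALSE]
    rep_ord <- order(-mem$full_length, -mem$n_support,
                     -nchar(mem$sequence), mem$sequence)
    rep <- mem[rep_ord[1], , drop = FALSE]
    rep$n_support <- sum(mem$n_support)
    rep
  })
  fused <- bind_rows(fused)
  fused <- fused[fused$n_support >= params$min_support_reads, , drop = FALSE]
  fused <- fused[order(-fused$n_support, -nchar(fused$sequence),
                       fused$sequence), , drop = FALSE]
  head(fused, params$max_alleles_per_bin)
}

#' Assemble all bins into a draft allele set
#'
#' Runs clustering and polishing per (sample, primer set) bin, classifies
#' every contig to a gene against the known-allele database, flags
#' full-length contigs (both primers of the gene's designed set present),
#' fuses contigs per sample and gene, and deduplicates identical sequences
#' across samples into shared draft alleles.
#'
#' @param bins Demultiplexed reads (`bins` element of [demultiplex()]).
#' @param db Known-allele database for gene classification.
#' @param primer_sets Tibble (`set`, `forward`, `reverse`).
#' @param gene_set_map Tibble (`gene`, `set`): which designed set defines
#'   full length for each gene.
#' @param params [assembly_params()].
#' @param policy [primer_match_policy()] for the full-length check.
#' @return List: `draft` (an `allele_set`), `contigs` tibble (per
#'   sample/gene surviving contigs), `report` tibble (per-sample contig
#'   counts and full-length rates), `dropped` tibble.
#' @export
assemble_reads <- function(bins, db, primer_sets, gene_set_map,
                           params = assembly_params(),
                           policy = primer_match_policy()) {
  stopifnot(nrow(bins) > 0L)
  keys <- unique(bins[, c("sample", "primer_set")])
  raw <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- bins$sample == keys$sample[i] &
      bins$primer_set == keys$primer_set[i]
    seqs <- bins$sequence[sel]
    cl <- cluster_bin(seqs, params)
    for (cc in cl) {
      seed <- attr(cc, "seed")
      pol <- polish_consensus(seqs[cc], seqs[seed], params,
                              init_map = attr(cc, "map"))
      if (!nzchar(pol$sequence)) next
      raw[[length(raw) + 1L]] <- tibble(
        sample = keys$sample[i], primer_set = keys$primer_set[i],
        sequence = pol$sequence, n_support = length(cc))
    }
  }
  if (!length(raw)) stop("no contigs assembled")
  contigs <- bind_rows(raw)
  cls <- classify_gene(contigs$sequence, db)
  contigs$gene <- cls$gene
  contigs$closest <- cls$best_allele
  contigs <- contigs[!is.na(contigs$gene), , drop = FALSE]

  contigs$full_length <- vapply(seq_len(nrow(contigs)), function(i) {
    set <- gene_set_map$set[gene_set_map$gene == contigs$gene[i]]
    if (!length(set)) return(FALSE)
    ps <- primer_sets[primer_sets$set == set[1], ]
    all(contains_primers(contigs$sequence[i], ps$forward[1], ps$reverse[1],
                         policy))
  }, logical(1))

  fused <- list(); dropped <- list()
  keys2 <- unique(contigs[, c("sample", "gene")])
  for (i in seq_len(nrow(keys2))) {
    sel <- contigs$sample == keys2$sample[i] & contigs$gene == keys2$gene[i]
    fs <- fuse_contigs(contigs[sel, , drop = FALSE], params)
    fused[[i]] <- fs
    lost <- sum(contigs$n_support[sel]) - sum(fs$n_support)
    if (lost > 0L) {
      dropped[[length(dropped) + 1L]] <- tibble(
        sample = keys2$sample[i], gene = keys2$gene[i],
        reads_discarded = lost)
    }
  }
  fused <- bind_rows(fused)
  draft <- build_draft_set(fused)
  report <- fused |>
    group_by(.data$sample, .data$gene) |>
    summarise(n_contigs = dplyr::n(),
              full_length = all(.data$full_length), .groups = "drop")
  list(draft = draft, contigs = fused, report = report,
       dropped = bind_rows(dropped))
}

#' Build the draft allele set from surviving contigs
#'
#' Identical sequences across samples share one draft allele id; carriers
#' are recorded. Errors if any sample/gene still carries more than two
#' contigs (the fuse contract).
#'
#' @param contigs Tibble with `sample`, `gene`, `sequence`, `n_support`,
#'   `full_length`.
#' @return An `allele_set`: list with `sequences` (named), `info`
#'   (`allele_id`, `gene`, `n_carriers`, `full_length`), `carriers`
#'   (`allele_id`, `sample`).
#' @export
build_draft_set <- function(contigs) {
  bad <- contigs |>
    count(.data$sample, .data$gene) |>
    filter(.data$n > 2L)
  if (nrow(bad) > 0L) {
    stop("more than 2 contigs remain for ", bad$sample[1], "/", bad$gene[1],
         "; fuse_contigs contract violated")
  }
  uq <- contigs |>
    group_by(.data$gene, .data$sequence) |>
    summarise(n_carriers = dplyr::n_distinct(.data$sample),
              full_length = any(.data$full_length),
              carriers = list(unique(.data$sample)), .groups = "drop") |>
    arrange(.data$gene, -.data$n_carriers, .data$sequence)
  uq <- uq |>
    group_by(.data$gene) |>
    mutate(allele_id = sprintf("%s_d%02d", .data$gene, row_number())) |>
    ungroup()
  allele_set(
    sequences = setNames(uq$sequence, uq$allele_id),
    info = uq[, c("allele_id", "gene", "n_carriers", "full_length")],
    carriers = tidyr::unnest(uq[, c("allele_id", "carriers")],
                             "carriers") |>
      rename(sample = "carriers")
  )
}

#' Construct an allele set container
#'
#' @param sequences Named character vector.
#' @param info Tibble with at least `allele_id`, `gene`.
#' @param carriers Tibble (`allele_id`, `sample`).
#' @return An `allele_set` list.
#' @export
allele_set <- function(sequences, info, carriers) {
  structure(list(sequences = sequences, info = info, carriers = carriers),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set> ", length(x$sequences), " alleles\n", sep = "")
  print(dplyr::count(x$info, .data$gene))
  invisible(x)
}
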