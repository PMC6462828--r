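#' Refinement parameters
#'
#' @param min_depth Minimum weighted short-read depth for a variant
#'   observation to be examinable.
#' @param support_fraction Minimum agreeing fraction for "supported".
#' @param map_k,map_band Anchored-alignment settings for short-read
#'   mapping.
#' @param msa_band Band half-width for the pairwise steps of the built-in
#'   MSA.
#' @param max_dist_frac Reads whose best alignment to a candidate allele
#'   exceeds this edit fraction of their length are left out of pileups
#'   (screens out reads that merely share a primer annealing site).
#' @param engine MSA engine: `"builtin"` (center-star) or `"mafft"`
#'   (external, must be on PATH).
#' @return A `refine_params` list.
#' @export
refine_params <- function(min_depth = 5, support_fraction = 0.8,
                          map_k = 15L, map_band = 20L, msa_band = 150L,
                          max_dist_frac = 0.15,
                          engine = c("builtin", "mafft")) {
  engine <- match.arg(engine)
  structure(list(min_depth = min_depth, support_fraction = support_fraction,
                 map_k = as.integer(map_k), map_band = as.integer(map_band),
                 msa_band = as.integer(msa_band),
                 max_dist_frac = max_dist_frac, engine = engine),
            class = "refine_params")
}

#' Multiple sequence alignment of one gene's alleles
#'
#' Built-in engine: center-star alignment to the longest allele. Every
#' other allele is pairwise-aligned to the center (anchored banded edit
#' distance, free reference ends), and insertions relative to the center
#' are merged into shared gap columns. At the ~1% within-gene divergence
#' of allele panels this is effectively optimal and fully deterministic.
#' `engine = "mafft"` delegates to the external aligner instead.
#'
#' @param sequences Named character vector (>= 1 allele).
#' @param params [refine_params()].
#' @return A `gene_msa`: list with `rows` (named gapped sequences of equal
#'   width) and `width`. Ungapping any row reproduces its input sequence.
#' @export
build_gene_msa <- function(sequences, params = refine_params()) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  if (params$engine == "mafft") {
    rows <- mafft_msa(sequences)
    return(structure(list(rows = rows, width = nchar(rows[1])),
                     class = "gene_msa"))
  }
  if (length(sequences) == 1L) {
    return(structure(list(rows = sequences, width = nchar(sequences[1])),
                     class = "gene_msa"))
  }
  ord <- order(-nchar(sequences), names(sequences))
  center_name <- names(sequences)[ord[1]]
  center <- sequences[[center_name]]
  n <- nchar(center)
  others <- setdiff(names(sequences), center_name)

  # anchor size adapts to the shortest sequence so toy-sized inputs align
  k <- max(4L, min(15L, as.integer(min(nchar(sequences)) %/% 3L)))
  band <- max(params$msa_band,
              as.integer(max(abs(nchar(sequences) - n))) + 10L)
  m <- cpp_map_reads(unname(sequences[others]), center, k, band, TRUE, TRUE)
  if (!all(m$mapped)) {
    stop("MSA: allele(s) share no anchors with the center: ",
         paste(others[!m$mapped], collapse = ", "))
  }
  # per-position max insertion length across alleles
  G <- integer(n + 1L)
  ins_by <- vector("list", length(others))
  for (i in seq_along(others)) {
    ins <- m$ins[[i]]
    tab <- integer(n + 1L)
    if (length(ins$pos)) {
      for (q in seq_along(ins$pos)) {
        p <- ins$pos[q] + 1L
        tab[p] <- tab[p] + nchar(ins$seq[q])
      }
    }
    ins_by[[i]] <- ins
    G <- pmax(G, tab)
  }
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  # center row
  center_chars <- strsplit(center, "", fixed = TRUE)[[1]]
  rows_out <- setNames(vector("character", length(sequences)),
                       c(center_name, others))
  gapblock <- vapply(G, function(g) strrep("-", g), "")
  rows_out[center_name] <-
    paste0(paste0(gapblock[seq_len(n)], center_chars, collapse = ""),
           gapblock[n + 1L])
  for (i in seq_along(others)) {
    st <- m$start[i]; en <- m$end[i]
    proj <- strsplit(m$proj[i], "", fixed = TRUE)[[1]]
    ins <- ins_by[[i]]
    insmap <- character(n + 1L)
    if (length(ins$pos)) insmap[ins$pos + 1L] <- ins$seq
    piece <- character(n + 1L)
    for (p in seq_len(n + 1L)) {
      blk <- if (G[p] > 0L) pad(insmap[p], G[p]) else ""
      ch <- if (p <= n) {
        if (p - 1L >= st && p - 1L < en) proj[p - st] else "-"
      } else ""
      piece[p] <- paste0(blk, ch)
    }
    rows_out[others[i]] <- paste(piece, collapse = "")
  }
  msa <- structure(list(rows = rows_out, width = nchar(rows_out[1])),
                   class = "gene_msa")
  stopifnot(all(nchar(msa$rows) == msa$width))
  # ungap invariant
  ung <- gsub("-", "", msa$rows, fixed = TRUE)
  if (!identical(unname(ung[names(sequences)]), unname(sequences))) {
    stop("MSA ungap invariant violated")
  }
  msa
}

mafft_msa <- function(sequences) {
  if (Sys.which("mafft") == "") stop("mafft not found on PATH")
  tf <- tempfile(fileext = ".fa"); of <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tf, of)), add = TRUE)
  write_fasta(sequences, tf)
  system2("mafft", c("--auto", "--quiet", tf), stdout = of)
  rows <- toupper(read_fasta(of))
  rows[names(sequences)]
}

#' Identify variant positions in a gene MSA
#'
#' A variant is any maximal run of alignment columns at which at least two
#' alleles disagree (gaps count as symbols). Each allele's string over the
#' run is reported together with its ungapped footprint on that allele.
#'
#' @param msa A `gene_msa`.
#' @return Tibble (`position`, `col_start`, `col_end`, `allele_id`,
#'   `string`, `ungapped_start`, `ungapped_end`); columns and footprints
#'   are 0-based half-open, `string` is gap-free.
#' @export
identify_variants <- function(msa) {
  k <- length(msa$rows)
  empty <- tibble(position = integer(0), col_start = integer(0),
                  col_end = integer(0), allele_id = character(0),
                  string = character(0), ungapped_start = integer(0),
                  ungapped_end = integer(0))
  if (k < 2L) return(empty)
  mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  differs <- vapply(seq_len(ncol(mat)), function(j) {
    length(unique(mat[, j])) > 1L
  }, logical(1))
  if (!any(differs)) return(empty)
  r <- rle(differs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  nong <- apply(mat != "-", 1L, cumsum)  # width x k matrix of cumsums
  out <- vector("list", length(runs))
  for (q in seq_along(runs)) {
    c0 <- starts[runs[q]]; c1 <- ends[runs[q]]
    strs <- apply(mat[, c0:c1, drop = FALSE], 1L, paste, collapse = "")
    us <- if (c0 > 1L) nong[c0 - 1L, ] else rep(0L, k)
    ue <- nong[c1, ]
    out[[q]] <- tibble(position = q, col_start = c0 - 1L, col_end = c1,
                       allele_id = names(msa$rows),
                       string = gsub("-", "", strs, fixed = TRUE),
                       ungapped_start = as.integer(us),
                       ungapped_end = as.integer(ue))
  }
  bind_rows(out)
}

# map one sample's short reads onto its candidate alleles for one gene;
# returns per-allele mapping tables with tie-split weights
map_sample_reads <- function(read_seqs, alleles, params) {
  read_seqs <- orient_reads(read_seqs, alleles[[1]], params$map_k)
  maxd <- params$max_dist_frac * nchar(read_seqs)
  maps <- lapply(alleles, function(a) {
    m <- cpp_map_reads(read_seqs, a, params$map_k, params$map_band,
                       TRUE, TRUE)
    bad <- !m$mapped | m$dist > maxd
    m$dist[bad] <- NA_integer_
    m$mapped <- m$mapped & !bad
    m
  })
  dmat <- do.call(cbind, lapply(maps, function(m) m$dist))
  w <- matrix(0, nrow = length(read_seqs), ncol = length(alleles))
  if (length(alleles) == 1L) {
    w[!is.na(dmat[, 1]), 1] <- 1
  } else {
    dd <- dmat
    dd[is.na(dd)] <- .Machine$integer.max
    best <- apply(dd, 1L, min)
    anybest <- rowSums(!is.na(dmat)) > 0L
    for (j in seq_along(alleles)) {
      isbest <- anybest & dd[, j] == best
      nb <- rowSums(dd == best)
      w[isbest, j] <- 1 / nb[isbest]
    }
  }
  list(maps = maps, weights = w)
}

# assess all variant observations of one allele against one carrier's
# mapped reads; allele_len enables examining runs at the allele boundary
# (a terminal truncation shows up as read overhang insertions there)
assess_allele_carrier <- function(variants_a, map, weights, params,
                                  allele_len) {
  sel <- which(weights > 0 & map$mapped)
  if (!length(sel) || nrow(variants_a) == 0L) {
    return(variants_a |>
             mutate(status = "unexamined", depth = 0, agreeing = 0,
                    best_alternative = NA_character_, alt_agreeing = 0))
  }
  st <- map$start[sel]; en <- map$end[sel]
  proj <- map$proj[sel]; wts <- weights[sel]
  ins <- map$ins[sel]
  has_ins <- vapply(ins, function(x) length(x$pos) > 0L, logical(1))
  ins_tab <- NULL
  if (any(has_ins)) {
    ins_tab <- bind_rows(lapply(which(has_ins), function(i) {
      tibble(ri = i, pos = ins[[i]]$pos, seq = ins[[i]]$seq)
    }))
  }
  nv <- nrow(variants_a)
  status <- character(nv); depth <- numeric(nv); agreeing <- numeric(nv)
  alt <- rep(NA_character_, nv); alt_agreeing <- numeric(nv)
  for (v in seq_len(nv)) {
    us <- variants_a$ungapped_start[v]; ue <- variants_a$ungapped_end[v]
    left_ok <- if (us == 0L) st == 0L else st <= us - 1L
    right_ok <- if (ue >= allele_len) en >= allele_len else en >= ue + 1L
    covered <- which(left_ok & right_ok)
    d <- sum(wts[covered])
    depth[v] <- d
    if (d < params$min_depth) {
      status[v] <- "unexamined"
      next
    }
    if (ue > us) {
      obs <- gsub("-", "",
                  substr(proj[covered], us - st[covered] + 1L,
                         ue - st[covered]),
                  fixed = TRUE)
    } else {
      obs <- rep("", length(covered))
    }
    if (!is.null(ins_tab)) {
      lo <- if (ue > us) us else us
      hi <- if (ue > us) ue else us
      rel <- ins_tab[ins_tab$ri %in% covered & ins_tab$pos >= lo &
                       ins_tab$pos <= hi, , drop = FALSE]
      if (nrow(rel) > 0L) {
        for (i in unique(rel$ri)) {
          ci <- match(i, covered)
          obs[ci] <- splice_obs(proj[i], st[i], us, ue,
                                rel[rel$ri == i, , drop = FALSE])
        }
      }
    }
    own <- variants_a$string[v]
    ag <- sum(wts[covered][obs == own])
    agreeing[v] <- ag
    if (ag / d >= params$support_fraction) {
      status[v] <- "supported"
    } else {
      status[v] <- "unsupported"
      tab <- tapply(wts[covered], obs, sum)
      tab <- tab[order(-tab, names(tab))]
      alt[v] <- names(tab)[1]
      alt_agreeing[v] <- tab[[1]]
    }
  }
  variants_a |>
    mutate(status = status, depth = depth, agreeing = agreeing,
           best_alternative = alt, alt_agreeing = alt_agreeing)
}

# rebuild one read's observed string over [us, ue) with its insertions
splice_obs <- function(proj, st, us, ue, ins_rows) {
  ins_map <- setNames(ins_rows$seq, ins_rows$pos)
  out <- ""
  if (ue == us) {
    v <- ins_map[as.character(us)]
    return(if (is.na(v)) "" else unname(v))
  }
  for (j in us:(ue - 1L)) {
    key <- as.character(j)
    if (!is.na(ins_map[key])) out <- paste0(out, ins_map[key])
    ch <- substr(proj, j - st + 1L, j - st + 1L)
    if (ch != "-") out <- paste0(out, ch)
  }
  key <- as.character(ue)
  if (!is.na(ins_map[key])) out <- paste0(out, ins_map[key])
  out
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Assess variant support for an allele set against carriers' short reads
#'
#' For every gene the alleles are multiply aligned, variant positions are
#' identified, each carrier's short reads are mapped to the sample's
#' candidate alleles (ties split 0.5/0.5), and every (allele, carrier,
#' position) observation is classified supported / unsupported /
#' unexamined.
#'
#' @param set An `allele_set`.
#' @param short_reads Tibble (`read_id`, `sample`, `sequence`).
#' @param params [refine_params()].
#' @param candidates Optional tibble (`sample`, `gene`, `allele_id`)
#'   overriding the carrier table: which alleles each sample's reads
#'   compete over (e.g. the genotype calls after panel filtering). Ids not
#'   in the set are looked up in `extra_sequences` and serve as competing
#'   mapping targets only.
#' @param extra_sequences Named character vector of additional candidate
#'   sequences (e.g. database alleles).
#' @return List: `assessments` tibble, `variants` tibble, `msas` (per
#'   gene), `accuracy` tibble (per gene + unweighted mean row `.mean`).
#' @export
variant_accuracy <- function(set, short_reads, params = refine_params(),
                             candidates = NULL, extra_sequences = NULL) {
  genes <- unique(set$info$gene)
  seq_lookup <- c(set$sequences, extra_sequences)
  # pre-classify each sample's reads by gene (longest allele per gene as
  # the representative), so mapping only sees same-gene reads
  gene_refs <- lapply(setNames(genes, genes), function(g) {
    ids <- set$info$allele_id[set$info$gene == g]
    ids <- ids[order(-nchar(set$sequences[ids]), ids)]
    set$sequences[[ids[1]]]
  })
  reads_by <- list()
  for (s in unique(short_reads$sample)) {
    rs <- short_reads$sequence[short_reads$sample == s]
    if (!length(rs)) next
    cls <- classify_short_reads(rs, gene_refs)
    reads_by[[s]] <- split(cls$sequence[!is.na(cls$gene)],
                           cls$gene[!is.na(cls$gene)])
  }
  all_assess <- list(); all_var <- list(); msas <- list()
  for (g in genes) {
    ids <- set$info$allele_id[set$info$gene == g]
    msa <- build_gene_msa(set$sequences[ids], params)
    msas[[g]] <- msa
    v <- identify_variants(msa)
    all_var[[g]] <- if (nrow(v)) mutate(v, gene = g) else v
    if (nrow(v) == 0L) next
    if (is.null(candidates)) {
      carr <- set$carriers[set$carriers$allele_id %in% ids, , drop = FALSE]
    } else {
      carr <- candidates[candidates$gene == g, c("sample", "allele_id")]
      carr <- carr[carr$allele_id %in% names(seq_lookup), , drop = FALSE]
    }
    for (s in unique(carr$sample)) {
      cand <- unique(carr$allele_id[carr$sample == s])
      rs <- reads_by[[s]][[g]]
      if (is.null(rs) || !length(rs)) next
      mp <- map_sample_reads(rs, unname(seq_lookup[cand]), params)
      for (ai in seq_along(cand)) {
        if (!(cand[ai] %in% ids)) next  # competing target only
        va <- v[v$allele_id == cand[ai], , drop = FALSE]
        a <- assess_allele_carrier(va, mp$maps[[ai]], mp$weights[, ai],
                                   params,
                                   nchar(seq_lookup[[cand[ai]]]))
        a$sample <- s
        a$gene <- g
        all_assess[[length(all_assess) + 1L]] <- a
      }
    }
  }
  assessments <- bind_rows(all_assess)
  acc <- if (nrow(assessments) > 0L) {
    per_gene <- assessments |>
      filter(.data$status != "unexamined") |>
      group_by(.data$gene) |>
      summarise(examined = dplyr::n(),
                supported = sum(.data$status == "supported"),
                accuracy = .data$supported / .data$examined,
                .groups = "drop")
    bind_rows(per_gene,
              tibble(gene = ".mean", examined = sum(per_gene$examined),
                     supported = sum(per_gene$supported),
                     accuracy = mean(per_gene$accuracy)))
  } else {
    tibble(gene = ".mean", examined = 0L, supported = 0L, accuracy = NaN)
  }
  list(assessments = assessments, variants = bind_rows(all_var),
       msas = msas, accuracy = acc)
}

#' Correct unsupported variants and merge the refined set
#'
#' A position of an allele is corrected when it is unsupported in every
#' carrier with examinable depth, all carriers agree on the same
#' alternative, and the replacement strictly increases total read support.
#' Corrections are applied right-to-left in ungapped coordinates. Alleles
#' that become identical are merged (carriers united), support is
#' re-assessed on the refined set, and per-gene accuracy is required not
#' to decrease.
#'
#' @param draft An `allele_set` (draft alleles).
#' @param short_reads Tibble (`read_id`, `sample`, `sequence`).
#' @param params [refine_params()].
#' @return A `refinement`: list with `refined` (`allele_set`),
#'   `corrections` tibble, `accuracy` tibble (stage x gene), `draft_va`
#'   and `refined_va` (full [variant_accuracy()] results).
#' @export
refine_alleles <- function(draft, short_reads, params = refine_params()) {
  va <- variant_accuracy(draft, short_reads, params)
  corr <- plan_corrections(va$assessments, params$support_fraction)
  seqs <- draft$sequences
  if (nrow(corr) > 0L) {
    for (aid in unique(corr$allele_id)) {
      rows <- corr[corr$allele_id == aid, , drop = FALSE]
      rows <- rows[order(-rows$ungapped_start), , drop = FALSE]
      s <- seqs[[aid]]
      for (i in seq_len(nrow(rows))) {
        us <- rows$ungapped_start[i]; ue <- rows$ungapped_end[i]
        s <- paste0(substr(s, 1L, us), rows$new[i],
                    substr(s, ue + 1L, nchar(s)))
      }
      seqs[[aid]] <- s
    }
  }
  # merge identical corrected sequences
  tab <- tibble(allele_id = names(seqs), sequence = unname(seqs)) |>
    left_join(draft$info[, c("allele_id", "gene")], by = "allele_id")
  carriers <- draft$carriers |>
    left_join(tab, by = "allele_id")
  uq <- tab |>
    group_by(.data$gene, .data$sequence) |>
    summarise(from = list(.data$allele_id), .groups = "drop") |>
    arrange(.data$gene, .data$sequence)
  uq <- uq |>
    group_by(.data$gene) |>
    mutate(allele_id = sprintf("%s_r%02d", .data$gene, row_number())) |>
    ungroup()
  old2new <- setNames(rep(uq$allele_id, lengths(uq$from)),
                      unlist(uq$from))
  new_carr <- carriers |>
    mutate(allele_id = old2new[.data$allele_id]) |>
    distinct(.data$allele_id, .data$sample)
  full_len <- draft$info |>
    mutate(allele_id = old2new[.data$allele_id]) |>
    group_by(.data$allele_id) |>
    summarise(full_length = any(.data$full_length), .groups = "drop")
  info <- new_carr |>
    count(.data$allele_id, name = "n_carriers") |>
    left_join(uq[, c("allele_id", "gene")], by = "allele_id") |>
    left_join(full_len, by = "allele_id")
  refined <- allele_set(setNames(uq$sequence, uq$allele_id),
                        info[, c("allele_id", "gene", "n_carriers",
                                 "full_length")],
                        new_carr)
  if (length(refined$sequences) > length(draft$sequences)) {
    stop("refined set larger than draft set")
  }
  va2 <- variant_accuracy(refined, short_reads, params)
  a1 <- va$accuracy; a2 <- va2$accuracy
  cmp <- inner_join(a1[a1$gene != ".mean", c("gene", "accuracy")],
                    a2[a2$gene != ".mean", c("gene", "accuracy")],
                    by = "gene", suffix = c("_draft", "_refined"))
  if (any(cmp$accuracy_refined < cmp$accuracy_draft - 1e-12)) {
    stop("variant accuracy decreased after refinement (contract violation)")
  }
  accuracy <- bind_rows(mutate(a1, stage = "draft"),
                        mutate(a2, stage = "refined"))
  if (nrow(corr) > 0L) corr$allele_id_refined <- old2new[corr$allele_id]
  structure(list(refined = refined, corrections = corr,
                 accuracy = accuracy[, c("stage", "gene", "examined",
                                         "supported", "accuracy")],
                 draft_va = va, refined_va = va2),
            class = "refinement")
}

# Aggregate assessments over carriers and decide which positions to fix.
# A position is corrected only when every examinable carrier is
# unsupported, all agree on one alternative, and that alternative itself
# clears the support fraction in every carrier -- a true consensus error
# shows ~100% alternative reads, whereas an unassembled second haplotype
# shows a ~50/50 mixture that must not rewrite a correct allele.
plan_corrections <- function(assessments, support_fraction = 0.8) {
  empty <- tibble(allele_id = character(0), position = integer(0),
                  ungapped_start = integer(0), ungapped_end = integer(0),
                  old = character(0), new = character(0),
                  n_carriers = integer(0))
  if (nrow(assessments) == 0L) return(empty)
  agg <- assessments |>
    filter(.data$status != "unexamined") |>
    group_by(.data$allele_id, .data$position, .data$ungapped_start,
             .data$ungapped_end, .data$string) |>
    summarise(
      n_carriers = dplyr::n(),
      all_unsupported = all(.data$status == "unsupported"),
      one_alt = dplyr::n_distinct(.data$best_alternative) == 1L,
      alt_supported = all(.data$alt_agreeing >=
                            support_fraction * .data$depth),
      alt = .data$best_alternative[1],
      support_gain = {
        sel <- .data$status == "unsupported"
        sum(.data$depth[sel] - .data$agreeing[sel]) > sum(.data$agreeing)
      },
      .groups = "drop") |>
    filter(.data$all_unsupported, .data$one_alt, !is.na(.data$alt),
           .data$alt_supported, .data$support_gain)
  if (nrow(agg) == 0L) return(empty)
  agg |>
    transmute(allele_id = .data$allele_id, position = .data$position,
              ungapped_start = .data$ungapped_start,
              ungapped_end = .data$ungapped_end,
              old = .data$string, new = .data$alt,
              n_carriers = .data$n_carriers) |>
    filter(.data$old != .data$new)
}

#' @export
print.refinement <- function(x, ...) {
  cat("<refinement> ", length(x$refined$sequences), " refined alleles, ",
      nrow(x$corrections), " corrections\n", sep = "")
  print(x$accuracy)
  invisible(x)
}
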