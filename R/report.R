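#' Split an allele name into resolution fields
#'
#' Names follow `GENE*f1:f2:f3:f4`; the first two fields give 4-digit
#' (protein) resolution, the third 6-digit (synonymous exonic), the fourth
#' 8-digit (full genomic) resolution.
#'
#' @param name Allele names.
#' @param digits Resolution: 4, 6 or 8.
#' @return Truncated names.
#' @export
truncate_allele_name <- function(name, digits = 4L) {
  stopifnot(digits %in% c(4L, 6L, 8L))
  nf <- c(`4` = 2L, `6` = 3L, `8` = 4L)[[as.character(digits)]]
  vapply(strsplit(name, ":", fixed = TRUE), function(p) {
    paste(p[seq_len(min(nf, length(p)))], collapse = ":")
  }, "")
}

# exon table of a db entry, ordered, 0-based half-open entry coordinates
db_exons <- function(db, allele) {
  ex <- db$annotations[db$annotations$allele == allele, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  ex$exon <- seq_len(nrow(ex))
  ex
}

db_cds <- function(db, allele) {
  ex <- db_exons(db, allele)
  paste(substring(db$sequences[[allele]], ex$start + 1L, ex$end),
        collapse = "")
}

# project db exon intervals onto a panel allele through an overlap
# alignment (aln = align_overlap(db_seq, panel_seq))
project_exons <- function(aln, ex) {
  lift <- aln$lift
  n <- length(lift)
  lift_pos <- function(q) {  # q: 0-based db position -> 0-based panel pos
    i <- q + 1L
    while (i <= n && is.na(lift[i])) i <- i + 1L
    if (i > n) return(aln$end)
    lift[i]
  }
  tibble(exon = seq_len(nrow(ex)),
         start = vapply(ex$start, lift_pos, 0L),
         end = vapply(ex$end - 1L, function(q) lift_pos(q) + 1L, 0L),
         region = ex$region)
}

#' Closest database allele and novelty classification for a panel
#'
#' Each panel allele is compared by pairwise overlap alignment with every
#' same-gene database entry; the closest is the entry with the minimum
#' edit distance over its own span (cDNA-only entries are compared on the
#' projected exon concatenation), ties broken by fewer exonic edits, then
#' name. Differences are partitioned into exonic and non-coding, exon
#' haplotypes are translated to separate nonsynonymous from synonymous
#' changes, and the 8/6/4-digit novelty flags are set: any genomic
#' difference, any exonic difference, any nonsynonymous difference. A
#' cDNA-only closest entry marks the panel allele as newly contributing
#' intron sequence.
#'
#' @param panel An `allele_set` (final panel).
#' @param db A `reference_db`.
#' @return List: `entries` tibble (one row per panel allele: closest db
#'   allele, exon/noncoding edit distances, extension lengths, novelty
#'   flags, projected span), `exon_variants` tibble (per-variant records:
#'   exon, 1-based position in exon, ref > alt, amino-acid position and
#'   change or "Synonymous").
#' @export
characterize_panel <- function(panel, db) {
  entries <- list(); varrec <- list()
  for (i in seq_along(panel$sequences)) {
    pid <- names(panel$sequences)[i]
    pseq <- panel$sequences[[pid]]
    g <- panel$info$gene[panel$info$allele_id == pid]
    cand <- db$info[db$info$gene == g, , drop = FALSE]
    if (nrow(cand) == 0L) stop("empty database for gene ", g)
    genomic <- cand$allele[!cand$cdna_only]
    if (length(genomic) == 0L) stop("no genomic database entry for gene ", g)

    gm <- map_reads(unname(db$sequences[genomic]), pseq,
                    k = 15L, band = 150L)
    gdist <- setNames(gm$dist, genomic)
    best_g <- genomic[order(gdist, genomic)][1]
    aln_g <- align_overlap(db$sequences[[best_g]], pseq,
                           k = 15L, band = 150L)
    pex <- project_exons(aln_g, db_exons(db, best_g))
    pcds <- paste(substring(pseq, pex$start + 1L, pex$end), collapse = "")

    cdna <- cand$allele[cand$cdna_only]
    cdist <- if (length(cdna)) {
      vapply(cdna, function(a) cpp_edit_distance(pcds, db_cds(db, a)), 0L)
    } else integer(0)
    all_names <- c(genomic, cdna)
    all_dist <- c(gdist, cdist)
    dmin <- min(all_dist)
    tied <- all_names[all_dist == dmin]
    # exonic edit count per tied candidate
    exon_d <- vapply(tied, function(a) {
      if (a %in% cdna) return(as.integer(cpp_edit_distance(pcds, db_cds(db, a))))
      count_region_edits(db, a, pseq)$exon
    }, 0L)
    ord <- order(exon_d, tied)
    closest <- tied[ord[1]]
    is_cdna <- closest %in% cdna

    span_start <- aln_g$start
    span_end <- aln_g$end
    if (is_cdna) {
      exon_dist <- as.integer(cpp_edit_distance(pcds, db_cds(db, closest)))
      noncoding_dist <- NA_integer_
      dist <- exon_dist
      db_up <- 0L; db_down <- 0L
      vv <- exon_variant_records(pcds, db_cds(db, closest),
                                 db_exons(db, closest))
      # db coverage of the panel allele is exonic only
      span_start <- min(pex$start)
      span_end <- max(pex$end)
    } else {
      cre <- count_region_edits(db, closest, pseq)
      exon_dist <- cre$exon
      noncoding_dist <- cre$noncoding
      dist <- exon_dist + noncoding_dist
      dex <- db_exons(db, closest)
      db_up <- min(dex$start)
      db_down <- nchar(db$sequences[[closest]]) - max(dex$end)
      aln_c <- if (closest == best_g) aln_g else
        align_overlap(db$sequences[[closest]], pseq, k = 15L, band = 150L)
      span_start <- aln_c$start
      span_end <- aln_c$end
      pex_c <- project_exons(aln_c, dex)
      pcds_c <- paste(substring(pseq, pex_c$start + 1L, pex_c$end),
                      collapse = "")
      vv <- exon_variant_records(pcds_c, db_cds(db, closest), dex)
    }
    nonsyn <- nrow(vv) > 0L && any(vv$aa_change != "Synonymous")
    p_up <- min(pex$start)
    p_down <- nchar(pseq) - max(pex$end)
    entries[[i]] <- tibble(
      allele_id = pid, gene = g, closest_db = closest,
      cdna_only = is_cdna, dist = dist, exon_dist = exon_dist,
      noncoding_dist = noncoding_dist,
      length = nchar(pseq), db_length = nchar(db$sequences[[closest]]),
      upstream_len = p_up, downstream_len = p_down,
      db_upstream_len = if (is_cdna) 0L else db_up,
      db_downstream_len = if (is_cdna) 0L else db_down,
      upstream_ext = p_up - (if (is_cdna) 0L else db_up),
      downstream_ext = p_down - (if (is_cdna) 0L else db_down),
      span_start = span_start,
      span_end = span_end,
      novel_8digit = dist > 0L || is_cdna,
      adds_introns = is_cdna,
      novel_6digit = exon_dist > 0L,
      novel_4digit = nonsyn
    )
    if (nrow(vv) > 0L) {
      vv$allele_id <- pid
      vv$gene <- g
      vv$closest_db <- closest
      varrec[[length(varrec) + 1L]] <- vv
    }
  }
  entries <- bind_rows(entries)
  stopifnot(all(!entries$novel_4digit | entries$novel_6digit),
            all(!entries$novel_6digit | entries$novel_8digit))
  ev <- if (length(varrec)) bind_rows(varrec) else
    tibble(exon = integer(0), pos_in_exon = integer(0), ref = character(0),
           alt = character(0), aa_pos = integer(0), aa_change = character(0),
           allele_id = character(0), gene = character(0),
           closest_db = character(0))
  list(entries = entries,
       exon_variants = ev[, c("allele_id", "gene", "closest_db", "exon",
                              "pos_in_exon", "ref", "alt", "aa_pos",
                              "aa_change")])
}

# count aligned-column edits of a panel allele vs one genomic db entry,
# split into exonic vs non-coding (within the db span)
count_region_edits <- function(db, db_allele, pseq) {
  aln <- align_overlap(db$sequences[[db_allele]], pseq, k = 15L, band = 150L)
  aq <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  ar <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  nz <- which(aq != "-")
  span <- seq(min(nz), max(nz))   # columns within the db entry's span
  qpos <- cumsum(aq != "-")       # db bases consumed up to each column
  ex <- db_exons(db, db_allele)
  exonic_pos <- rep(FALSE, max(qpos))
  for (j in seq_len(nrow(ex))) {
    exonic_pos[(ex$start[j] + 1L):ex$end[j]] <- TRUE
  }
  diff <- aq[span] != ar[span]
  # a column where the db has a gap belongs to the region of the preceding base
  is_exonic <- exonic_pos[pmax(qpos[span], 1L)]
  list(exon = as.integer(sum(diff & is_exonic)),
       noncoding = as.integer(sum(diff & !is_exonic)))
}

# per-variant records comparing the panel CDS with the db CDS;
# positions are 1-based within the exon, amino acids 1-based in the
# protein; multi-base substitution runs are one record
exon_variant_records <- function(pcds, dcds, ex) {
  empty <- tibble(exon = integer(0), pos_in_exon = integer(0),
                  ref = character(0), alt = character(0),
                  aa_pos = integer(0), aa_change = character(0))
  if (pcds == dcds) return(empty)
  if (nchar(pcds) == nchar(dcds)) {
    a <- strsplit(dcds, "", fixed = TRUE)[[1]]
    b <- strsplit(pcds, "", fixed = TRUE)[[1]]
  } else {
    aln <- align_overlap(pcds, dcds, k = 9L, band = 50L)
    a <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
    b <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  }
  if (nchar(dcds) %% 3L != 0L) {
    stop("database coding sequence length not divisible by 3")
  }
  prot_d <- translate_cds(dcds)
  prot_p <- if (nchar(pcds) %% 3L == 0L) translate_cds(pcds) else NA
  exlen <- ex$end - ex$start
  exoff <- cumsum(c(0L, exlen))  # CDS offset of each exon
  d <- which(a != b)
  if (!length(d)) return(empty)
  runs <- split(d, cumsum(c(1L, diff(d) != 1L)))
  dpos <- cumsum(a != "-")  # db CDS coordinate per column
  out <- lapply(runs, function(cols) {
    q0 <- dpos[cols[1]]            # 1-based db CDS pos of run start
    if (q0 < 1L) q0 <- 1L
    k <- max(which(exoff < q0))    # exon index
    refs <- paste(a[cols][a[cols] != "-"], collapse = "")
    alts <- paste(b[cols][b[cols] != "-"], collapse = "")
    aa_pos <- (q0 - 1L) %/% 3L + 1L
    aa_change <- "Synonymous"
    if (!is.na(prot_p) && nchar(prot_p) == nchar(prot_d)) {
      aa_last <- (dpos[cols[length(cols)]] - 1L) %/% 3L + 1L
      aa_last <- min(aa_last, nchar(prot_d))
      chg <- which(strsplit(prot_d, "")[[1]][aa_pos:aa_last] !=
                     strsplit(prot_p, "")[[1]][aa_pos:aa_last])
      if (length(chg)) {
        ap <- aa_pos + chg[1] - 1L
        aa_change <- paste0(substr(prot_d, ap, ap), " > ",
                            substr(prot_p, ap, ap))
        aa_pos <- ap
      }
    } else if (is.na(prot_p)) {
      aa_change <- "Frameshift"
    }
    tibble(exon = ex$exon[k],
           pos_in_exon = as.integer(unname(q0 - exoff[k])),
           ref = refs, alt = alts, aa_pos = as.integer(unname(aa_pos)),
           aa_change = unname(aa_change))
  })
  bind_rows(out)
}

#' Sequence-extension and novel-variant summary (per gene)
#'
#' Mean full length, mean closest-database length, mean regulatory region
#' lengths, and counts of variant positions among the panel alleles that
#' fall in regions not covered by any database entry (the newly
#' contributed regulatory sequence), with a totals row.
#'
#' @param entries `entries` from [characterize_panel()].
#' @param panel_variants Variant table of the panel alleles (from
#'   [variant_accuracy()] on the panel, or [identify_variants()]).
#' @return Tibble, one row per gene plus a `Total` row.
#' @export
extension_and_variant_stats <- function(entries, panel_variants) {
  span <- entries[, c("allele_id", "span_start", "span_end")]
  nv <- panel_variants |>
    left_join(span, by = "allele_id") |>
    group_by(.data$gene, .data$position) |>
    summarise(
      upstream_novel = all(pmax(.data$ungapped_end - 1L,
                                .data$ungapped_start) < .data$span_start),
      downstream_novel = all(.data$ungapped_start >= .data$span_end),
      .groups = "drop") |>
    group_by(.data$gene) |>
    summarise(novel_upstream = sum(.data$upstream_novel),
              novel_downstream = sum(.data$downstream_novel),
              .groups = "drop")
  per_gene <- entries |>
    group_by(.data$gene) |>
    summarise(n_alleles = dplyr::n(),
              mean_length = mean(.data$length),
              mean_db_length = mean(.data$db_length),
              mean_upstream = mean(.data$upstream_len),
              mean_db_upstream = mean(.data$db_upstream_len),
              mean_downstream = mean(.data$downstream_len),
              mean_db_downstream = mean(.data$db_downstream_len),
              .groups = "drop") |>
    left_join(nv, by = "gene") |>
    mutate(novel_upstream = tidyr::replace_na(.data$novel_upstream, 0L),
           novel_downstream = tidyr::replace_na(.data$novel_downstream, 0L))
  bind_rows(per_gene,
            tibble(gene = "Total",
                   n_alleles = sum(per_gene$n_alleles),
                   mean_length = NA, mean_db_length = NA,
                   mean_upstream = NA, mean_db_upstream = NA,
                   mean_downstream = NA, mean_db_downstream = NA,
                   novel_upstream = sum(per_gene$novel_upstream),
                   novel_downstream = sum(per_gene$novel_downstream)))
}

#' Allele distribution over genotype calls
#'
#' Counts allele occurrences over the typed chromosomes of each gene
#' (copy-number adjusted at deletable loci; untyped slots tracked
#' separately).
#'
#' @param calls Genotype calls (`sample`, `gene`, `allele1`, `allele2`,
#'   `copy_number`).
#' @return List: `frequencies` tibble (`gene`, `allele`, `count`,
#'   `frequency`), `untyped` tibble (`gene`, `untyped_slots`,
#'   `total_slots`).
#' @export
allele_distribution <- function(calls) {
  long <- bind_rows(
    calls |> transmute(gene = .data$gene, allele = .data$allele1,
                       slot = pmin(.data$copy_number, 1L)),
    calls |> transmute(gene = .data$gene, allele = .data$allele2,
                       slot = ifelse(.data$copy_number == 2L, 1L, 0L))
  ) |> filter(.data$slot > 0L)
  untyped <- long |>
    group_by(.data$gene) |>
    summarise(untyped_slots = sum(is.na(.data$allele)),
              total_slots = dplyr::n(), .groups = "drop")
  freqs <- long |>
    filter(!is.na(.data$allele)) |>
    count(.data$gene, .data$allele, name = "count") |>
    group_by(.data$gene) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup() |>
    arrange(.data$gene, -.data$count, .data$allele)
  list(frequencies = freqs, untyped = untyped)
}

#' Total frequency of novel alleles per gene and resolution
#'
#' @param distribution Result of [allele_distribution()] over calls whose
#'   allele ids are refined ids (mapped to panel entries via
#'   `panel$info$refined_id`).
#' @param panel Panel `allele_set` (with `refined_id` in info).
#' @param entries `entries` from [characterize_panel()].
#' @return Tibble (`gene`, `resolution`, `novel_frequency`).
#' @export
novel_frequency_totals <- function(distribution, panel, entries) {
  map <- setNames(panel$info$allele_id, panel$info$refined_id)
  fl <- distribution$frequencies |>
    mutate(panel_id = map[.data$allele]) |>
    left_join(entries |>
                select("allele_id", "novel_8digit", "novel_6digit",
                       "novel_4digit"),
              by = c(panel_id = "allele_id"))
  bind_rows(lapply(c(8L, 6L, 4L), function(res) {
    flag <- paste0("novel_", res, "digit")
    fl |>
      group_by(.data$gene) |>
      summarise(resolution = res,
                novel_frequency = sum(.data$frequency[
                  !is.na(.data[[flag]]) & .data[[flag]]]),
                .groups = "drop")
  }))
}

#' Coverage of a population's allele calls by the panel
#'
#' An allele call is covered when its name truncated to the resolution
#' matches the truncation of any panel allele's assigned (closest
#' database) name. Coverage is the covered fraction of typed calls.
#'
#' @param population_calls Tibble (`gene`, `allele`) of population allele
#'   calls (database names; `NA` = untyped).
#' @param entries Panel entries from [characterize_panel()].
#' @param resolution 4, 6 or 8.
#' @return Tibble (`gene`, `resolution`, `covered`, `total`, `coverage`).
#' @export
population_coverage <- function(population_calls, entries,
                                resolution = 4L) {
  typed <- population_calls |> filter(!is.na(.data$allele))
  out <- lapply(unique(typed$gene), function(g) {
    pnames <- truncate_allele_name(
      entries$closest_db[entries$gene == g], resolution)
    calls <- truncate_allele_name(typed$allele[typed$gene == g], resolution)
    tibble(gene = g, resolution = resolution,
           covered = sum(calls %in% pnames), total = length(calls),
           coverage = mean(calls %in% pnames))
  })
  bind_rows(out)
}
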