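#' Primer match policy
#'
#' Controls primer and index matching during demultiplexing. The defaults
#' implement the "edit distance < 2" rule for primers: a primer is
#' considered present if its best semi-global occurrence (primer fully
#' aligned, free ends on the read segment) has at most `max_edit = 1`
#' edits. Sample indexes (16 bp barcodes) are matched with up to
#' `index_max_edit = 2` edits within the leftmost `index_window` bases.
#'
#' @param max_edit Maximum edit distance for a primer hit in a polished
#'   contig (the "edit distance < 2" rule).
#' @param read_max_edit Maximum edit distance for a primer hit in a raw
#'   long read during demultiplexing. Raw reads carry indel-dominated
#'   errors (~10% per base), so a 25 bp primer accumulates ~2-3 edits on
#'   average; the default tolerates that while staying far below the
#'   ~19 edits separating unrelated primers.
#' @param search_window Bases searched from each read end for primers.
#' @param index_max_edit Maximum edit distance for an index hit.
#' @param index_window Bases searched from the 5' end for the index.
#' @return A `primer_match_policy` list.
#' @export
primer_match_policy <- function(max_edit = 1L, read_max_edit = 7L,
                                search_window = 100L,
                                index_max_edit = 2L, index_window = 30L) {
  stopifnot(max_edit >= 0L, read_max_edit >= 0L, search_window >= 1L)
  structure(list(max_edit = as.integer(max_edit),
                 read_max_edit = as.integer(read_max_edit),
                 search_window = as.integer(search_window),
                 index_max_edit = as.integer(index_max_edit),
                 index_window = as.integer(index_window)),
            class = "primer_match_policy")
}

#' Best occurrence of a primer in a read segment
#'
#' Semi-global alignment: the primer is fully consumed, both ends of the
#' segment are free, so terminal truncations of the primer count as edits.
#' Returns the leftmost minimum-distance occurrence, or a zero-row tibble
#' when the minimum exceeds `policy$max_edit`.
#'
#' @param segment Read segment (character scalar).
#' @param primer Primer sequence (character scalar).
#' @param policy A [primer_match_policy()].
#' @return Tibble with 0 or 1 rows: `start`, `end` (0-based half-open on
#'   the segment) and `edit_distance`.
#' @export
match_primer <- function(segment, primer, policy = primer_match_policy()) {
  if (!nzchar(primer)) stop("empty primer")
  if (nchar(segment) < nchar(primer)) {
    stop("segment shorter than primer")
  }
  h <- cpp_semiglobal(primer, segment)
  if (h$dist > policy$max_edit) {
    return(tibble(start = integer(0), end = integer(0),
                  edit_distance = integer(0)))
  }
  tibble(start = h$start, end = h$end, edit_distance = h$dist)
}

# best hit distance of `pattern` within `segment` (no threshold), internal
best_hit <- function(pattern, segment) {
  h <- cpp_semiglobal(pattern, segment)
  list(dist = h$dist, start = h$start, end = h$end)
}

#' Separate long reads by primer set (and sample index)
#'
#' A read is assigned to a primer set only when the set's forward primer
#' hits the 5' window AND its reverse primer (as reverse complement) hits
#' the 3' window in the same orientation; this two-primer requirement is
#' what protects nested co-amplified reads from being pooled with the
#' outer gene before assembly. Ties across sets are broken by total edit
#' distance, then by longer total primer length; remaining ties are
#' unassigned ("ambiguous"). Assigned reads are orientation-normalized and
#' trimmed to the span between (and including) the primers, removing the
#' index + universal adapter.
#'
#' @param reads Tibble with `read_id`, `sequence`, and `sample` (unless
#'   `indexes` is given).
#' @param primer_sets Tibble (`set`, `forward`, `reverse`).
#' @param policy A [primer_match_policy()].
#' @param indexes Optional tibble (`sample`, `index`); when given, the
#'   sample is recovered from the 16 bp barcode instead of trusted from
#'   the input.
#' @return List: `bins` tibble (`read_id`, `sample`, `primer_set`,
#'   `orientation`, `sequence`), `unassigned` tibble (`read_id`,
#'   `reason`).
#' @export
demultiplex <- function(reads, primer_sets, policy = primer_match_policy(),
                        indexes = NULL) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (is.null(indexes)) stopifnot("sample" %in% names(reads))
  # mutual distinguishability of the sets at the allowed edit distance
  if (nrow(primer_sets) > 1L) {
    for (i in seq_len(nrow(primer_sets) - 1L)) {
      for (j in (i + 1L):nrow(primer_sets)) {
        dmin <- min(cpp_edit_distance(primer_sets$forward[i],
                                      primer_sets$forward[j]),
                    cpp_edit_distance(primer_sets$reverse[i],
                                      primer_sets$reverse[j]))
        if (dmin <= 2L * policy$max_edit) {
          warning("primer sets ", primer_sets$set[i], " and ",
                  primer_sets$set[j],
                  " are not distinguishable at max_edit = ",
                  policy$max_edit)
        }
      }
    }
  }
  nsets <- nrow(primer_sets)
  fw <- primer_sets$forward
  rv_rc <- as.character(revcomp(primer_sets$reverse))
  plen_f <- nchar(fw); plen_r <- nchar(primer_sets$reverse)
  W <- policy$search_window + 21L   # adapter = 16 bp index + 5 bp universal

  n <- nrow(reads)
  out_set <- character(n); out_orient <- character(n)
  out_seq <- character(n); out_sample <- character(n)
  reason <- character(n)

  seq_fwd <- reads$sequence
  seq_rc <- as.character(revcomp(seq_fwd))

  for (r in seq_len(n)) {
    best <- NULL
    fail <- "no-5prime"
    for (orient in c("forward", "reverse")) {
      s <- if (orient == "forward") seq_fwd[r] else seq_rc[r]
      L <- nchar(s)
      w5 <- substr(s, 1L, min(L, W))
      w3 <- substr(s, max(1L, L - W + 1L), L)
      off3 <- max(1L, L - W + 1L) - 1L
      for (k in seq_len(nsets)) {
        hf <- best_hit(fw[k], w5)
        if (hf$dist > policy$read_max_edit) next
        fail <- if (fail == "no-5prime") "no-3prime" else fail
        hr <- best_hit(rv_rc[k], w3)
        if (hr$dist > policy$read_max_edit) next
        cand <- list(set = primer_sets$set[k],
                     orient = orient,
                     total = hf$dist + hr$dist,
                     plen = plen_f[k] + plen_r[k],
                     from = hf$start,
                     to = off3 + hr$end)
        if (is.null(best)) {
          best <- cand
        } else if (cand$total < best$total ||
                   (cand$total == best$total && cand$plen > best$plen)) {
          best <- cand
        } else if (cand$total == best$total && cand$plen == best$plen &&
                   cand$set != best$set) {
          best$ambiguous <- TRUE
        }
      }
      if (!is.null(best)) break  # same-orientation assignment found
    }
    if (is.null(best)) {
      reason[r] <- fail
      next
    }
    if (isTRUE(best$ambiguous)) {
      reason[r] <- "ambiguous"
      next
    }
    s <- if (best$orient == "forward") seq_fwd[r] else seq_rc[r]
    out_set[r] <- best$set
    out_orient[r] <- best$orient
    out_seq[r] <- substr(s, best$from + 1L, best$to)
    if (!is.null(indexes)) {
      w_idx <- substr(s, 1L, policy$index_window)
      dists <- vapply(indexes$index,
                      function(ix) cpp_semiglobal(ix, w_idx)$dist, 0L)
      if (min(dists) <= policy$index_max_edit &&
          sum(dists == min(dists)) == 1L) {
        out_sample[r] <- indexes$sample[which.min(dists)]
      } else {
        out_set[r] <- ""
        reason[r] <- "no-index"
      }
    } else {
      out_sample[r] <- reads$sample[r]
    }
  }

  assigned <- nzchar(out_set)
  list(
    bins = tibble(read_id = reads$read_id[assigned],
                  sample = out_sample[assigned],
                  primer_set = out_set[assigned],
                  orientation = ifelse(out_orient[assigned] == "forward",
                                       "forward", "reverse-complemented"),
                  sequence = out_seq[assigned]),
    unassigned = tibble(read_id = reads$read_id[!assigned],
                        reason = reason[!assigned])
  )
}

#' Classify contigs to genes by longest mapped fragment
#'
#' Each contig is compared against every database allele; the gene of the
#' allele achieving the longest contiguously mapped fragment wins (ties:
#' higher identity, then lexicographic allele name). The fragment measure
#' is the longest run of shared k-mers (gaps up to `max_gap` bridged),
#' a linear-time stand-in for exhaustive local alignment that agrees with
#' it at these divergences.
#'
#' @param contigs Character vector of contig sequences.
#' @param db A `reference_db` or `allele_pool` (uses `sequences`/`info`).
#' @param min_fragment Minimum fragment length; below it a contig is
#'   unclassified (`NA`).
#' @param k,max_gap K-mer size and bridgeable gap for the fragment runs.
#' @return Tibble (`contig`, `gene`, `best_allele`, `fragment_length`).
#' @export
classify_gene <- function(contigs, db, min_fragment = 200L,
                          k = 15L, max_gap = 60L) {
  if (length(db$sequences) == 0L) stop("empty allele database")
  al_names <- names(db$sequences)
  genes <- db$info$gene[match(al_names, db$info$allele)]
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    cov <- cpp_kmer_cover(contigs[i], unname(db$sequences),
                          as.integer(k), as.integer(max_gap))
    frag <- cov$longest_run
    ident <- ifelse(cov$total > 0, cov$matched / cov$total, 0)
    ord <- order(-frag, -ident, al_names)
    b <- ord[1]
    if (frag[b] < min_fragment) {
      out[[i]] <- tibble(contig = i, gene = NA_character_,
                         best_allele = NA_character_,
                         fragment_length = as.integer(frag[b]))
    } else {
      out[[i]] <- tibble(contig = i, gene = genes[b],
                         best_allele = al_names[b],
                         fragment_length = as.integer(frag[b]))
    }
  }
  bind_rows(out)
}

#' Which primers of a set does a contig contain?
#'
#' A contig contains a primer when the primer (on either strand) occurs
#' with edit distance at most `policy$max_edit`.
#'
#' @param contig Character scalar.
#' @param forward,reverse Primer sequences of one set.
#' @param policy A [primer_match_policy()].
#' @return Named logical vector `c(has_forward, has_reverse)`.
#' @export
contains_primers <- function(contig, forward, reverse,
                             policy = primer_match_policy()) {
  rc <- as.character(revcomp(contig))
  hasp <- function(p) {
    min(cpp_semiglobal(p, contig)$dist, cpp_semiglobal(p, rc)$dist) <=
      policy$max_edit
  }
  c(has_forward = hasp(forward), has_reverse = hasp(reverse))
}
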