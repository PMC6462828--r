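#' Alignment utilities
#'
#' Thin wrappers around the compiled alignment kernels. All user-facing
#' coordinates are 0-based half-open unless stated otherwise.
#'
#' @name align-utils
NULL

#' Levenshtein edit distance between two sequences
#'
#' @param a,b Character scalars (DNA strings).
#' @return Integer edit distance.
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  cpp_edit_distance(a, b)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  cpp_revcomp(x)
}

#' Map reads onto a reference by anchored banded alignment
#'
#' Each read is aligned globally; the reference ends are free (overlap
#' alignment). Exact k-mer anchors locate the diagonal; the dynamic program
#' is restricted to a band around it, so the cost is linear in read length.
#'
#' @param reads Character vector of read sequences.
#' @param ref Reference sequence (character scalar).
#' @param k Anchor k-mer size. Small k (11) tolerates high error rates;
#'   larger k (15) is faster for low-error short reads.
#' @param band Half-width of the alignment band.
#' @param keep_proj Keep per-read projections onto reference coordinates
#'   (`-` marks a deletion in the read).
#' @param keep_ins Keep read insertions relative to the reference as
#'   per-read `(pos, seq)` records (`pos` is the reference junction the
#'   insertion precedes).
#' @return A tibble with columns `read` (index), `mapped`, `start`, `end`,
#'   `dist`, and optionally list/character columns `proj` and `ins`.
#' @export
map_reads <- function(reads, ref, k = 15L, band = 30L,
                      keep_proj = FALSE, keep_ins = FALSE) {
  res <- cpp_map_reads(reads, ref, as.integer(k), as.integer(band),
                       keep_proj, keep_ins)
  out <- tibble(
    read = seq_along(reads),
    mapped = res$mapped,
    start = ifelse(res$mapped, res$start, NA_integer_),
    end = ifelse(res$mapped, res$end, NA_integer_),
    dist = ifelse(res$mapped, res$dist, NA_integer_)
  )
  if (keep_proj) out$proj <- res$proj
  if (keep_ins) out$ins <- res$ins
  out
}

#' Overlap-align a query against a reference
#'
#' Global on the query, free end gaps on the reference: the natural model
#' for comparing a database allele (shorter) against a panel allele that
#' extends it on both flanks, and for pairwise steps of the built-in MSA.
#'
#' @param query,ref Character scalars.
#' @param k Anchor k-mer size.
#' @param band Band half-width.
#' @return A list with `dist` (edits over the query span), `start`/`end`
#'   (query footprint on the reference, 0-based half-open), the gapped
#'   `aligned_query` / `aligned_ref` strings covering the whole reference,
#'   and `lift`, an integer vector mapping each query position (1-based)
#'   to its 0-based reference position (NA for inserted query bases).
#' @export
align_overlap <- function(query, ref, k = 15L, band = 100L) {
  m <- map_reads(query, ref, k = k, band = band,
                 keep_proj = TRUE, keep_ins = TRUE)
  if (!m$mapped[1]) {
    stop("align_overlap: no k-mer anchors between query and reference")
  }
  start <- m$start[1]; end <- m$end[1]
  proj <- strsplit(m$proj[1], "", fixed = TRUE)[[1]]
  ins <- m$ins[[1]]
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(refc)
  qlen <- nchar(query)
  ins_at <- integer(n + 1L)            # total inserted length before ref pos p
  ins_seq_at <- character(n + 1L)
  if (length(ins$pos)) {
    for (i in seq_along(ins$pos)) {
      p <- ins$pos[i] + 1L
      ins_at[p] <- ins_at[p] + nchar(ins$seq[i])
      ins_seq_at[p] <- paste0(ins_seq_at[p], ins$seq[i])
    }
  }
  aq <- character(0); ar <- character(0)
  lift <- rep(NA_integer_, qlen)
  qi <- 0L
  pieces_q <- vector("list", n + 1L)
  pieces_r <- vector("list", n + 1L)
  for (j in seq_len(n + 1L)) {
    g <- ins_at[j]
    qpart <- ""
    rpart <- ""
    if (g > 0L) {
      qpart <- ins_seq_at[j]
      rpart <- strrep("-", g)
      qi <- qi + g
    }
    if (j <= n) {
      if (j - 1L >= start && j - 1L < end) {
        ch <- proj[j - start]
        if (ch == "-") {
          qpart <- paste0(qpart, "-")
        } else {
          qi <- qi + 1L
          lift[qi] <- j - 1L
          qpart <- paste0(qpart, ch)
        }
      } else {
        qpart <- paste0(qpart, "-")
      }
      rpart <- paste0(rpart, refc[j])
    }
    pieces_q[[j]] <- qpart
    pieces_r[[j]] <- rpart
  }
  list(
    dist = m$dist[1], start = start, end = end,
    aligned_query = paste(unlist(pieces_q), collapse = ""),
    aligned_ref = paste(unlist(pieces_r), collapse = ""),
    lift = lift
  )
}
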