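# Independent oracles: plain dynamic-programming implementations used to
# verify the package's alignment kernels, plus small sequence utilities.
# These share no code with the package's compiled paths.

# full-matrix Levenshtein distance (row-vectorized)
r_edit_distance <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]),
                        prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# exhaustive semi-global alignment: pattern fully aligned, free text ends;
# returns the minimum distance and the leftmost optimal end column
r_semiglobal <- function(pattern, text) {
  P <- strsplit(pattern, "", fixed = TRUE)[[1]]
  TT <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(P); m <- length(TT)
  prev <- rep(0L, m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (P[i] != TT[j]),
                        prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  dist <- min(prev)
  list(dist = as.integer(dist), end = which(prev == dist)[1] - 1L)
}

r_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), ""))
}

r_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence with n substitutions at distinct positions
r_substitute <- function(s, n) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# sum-of-pairs score of an MSA (match = 1, mismatch/gap-vs-base = 0,
# gap-gap = 0)
r_sop_score <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  k <- nrow(mat)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- s + sum(mat[i, ] == mat[j, ] & mat[i, ] != "-")
    }
  }
  s
}

# star MSA oracle built from Biostrings pairwise alignments to a center
r_star_msa <- function(sequences, center_name) {
  center <- sequences[[center_name]]
  others <- setdiff(names(sequences), center_name)
  n <- nchar(center)
  ins_len <- integer(n + 1)
  alns <- list()
  for (o in others) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sequences[[o]]), Biostrings::DNAString(center),
      type = "global", gapOpening = 0, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    alns[[o]] <- list(p = ap, s = as_)
    # insertion length before each center position
    cpos <- 1L; run <- 0L
    for (k in seq_along(as_)) {
      if (as_[k] == "-") run <- run + 1L
      else {
        ins_len[cpos] <- max(ins_len[cpos], run)
        run <- 0L; cpos <- cpos + 1L
      }
    }
    ins_len[n + 1] <- max(ins_len[n + 1], run)
  }
  pad <- function(x, w) c(x, rep("-", w - length(x)))
  out <- setNames(vector("list", length(sequences)), names(sequences))
  cc <- strsplit(center, "")[[1]]
  row_c <- character(0)
  for (p in seq_len(n)) row_c <- c(row_c, rep("-", ins_len[p]), cc[p])
  row_c <- c(row_c, rep("-", ins_len[n + 1]))
  out[[center_name]] <- paste(row_c, collapse = "")
  for (o in others) {
    ap <- alns[[o]]$p; as_ <- alns[[o]]$s
    row <- character(0); buf <- character(0); cpos <- 1L
    for (k in seq_along(as_)) {
      if (as_[k] == "-") buf <- c(buf, ap[k])
      else {
        row <- c(row, pad(buf, ins_len[cpos]), ap[k])
        buf <- character(0); cpos <- cpos + 1L
      }
    }
    row <- c(row, pad(buf, ins_len[n + 1]))
    out[[o]] <- paste(row, collapse = "")
  }
  unlist(out)
}
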