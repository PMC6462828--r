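#' Read and write sequence sets
#'
#' FASTA/FASTQ handling goes through Biostrings; annotations use BED
#' (0-based half-open), tables are TSV.
#'
#' @param sequences Named character vector.
#' @param path File path.
#' @return `read_fasta` returns a named character vector; writers return
#'   the path invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname write_fasta
#' @param qualities Optional quality strings (defaults to flat Q30).
#' @export
write_fastq <- function(sequences, path, qualities = NULL) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(qualities)) {
    qualities <- vapply(nchar(sequences), function(n) strrep("?", n), "")
  }
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub(" .*", "", names(x)))
}

#' Write annotations as BED
#'
#' Columns: allele (chrom), start, end, region name.
#'
#' @param annotations Tibble (`allele`, `start`, `end`, `region`).
#' @param path Output path.
#' @export
write_bed <- function(annotations, path) {
  write.table(annotations[, c("allele", "start", "end", "region")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE,
                  col.names = c("allele", "start", "end", "region"))
  as_tibble(x)
}

#' Read a primer sheet
#'
#' TSV with columns `set`, `role` (F/R), `sequence`; returns the wide
#' (`set`, `forward`, `reverse`) form used by [demultiplex()].
#'
#' @param path TSV path.
#' @return Tibble (`set`, `forward`, `reverse`).
#' @export
read_primer_sheet <- function(path) {
  x <- as_tibble(read.delim(path))
  stopifnot(all(c("set", "role", "sequence") %in% names(x)))
  x |>
    tidyr::pivot_wider(id_cols = "set", names_from = "role",
                       values_from = "sequence") |>
    rename(forward = "F", reverse = "R")
}

#' Write a simulated dataset to a directory
#'
#' Emits the allele pool FASTA + BED, the reference database FASTA + BED,
#' truth genotype and read-truth TSVs, per-sample long-read FASTQ and
#' paired short-read FASTQs, plus the primer and index sheets.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created).
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$pool$sequences, file.path(dir, "pool.fasta"))
  write_bed(dataset$pool$annotations, file.path(dir, "pool.bed"))
  write_fasta(dataset$db$sequences, file.path(dir, "db.fasta"))
  write_bed(dataset$db$annotations, file.path(dir, "db.bed"))
  write.table(dataset$truth, file.path(dir, "truth_genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$long$truth, file.path(dir, "long_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$long$indexes, file.path(dir, "indexes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- dataset$pool$primer_sets
  sheet <- bind_rows(
    tibble(set = ps$set, role = "F", sequence = ps$forward),
    tibble(set = ps$set, role = "R", sequence = ps$reverse))
  write.table(sheet, file.path(dir, "primers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fastq(setNames(dataset$long$reads$sequence,
                       dataset$long$reads$read_id),
              file.path(dir, "long_reads.fastq"))
  for (m in 1:2) {
    sel <- dataset$short$reads$mate == m
    write_fastq(setNames(dataset$short$reads$sequence[sel],
                         dataset$short$reads$read_id[sel]),
                file.path(dir, sprintf("short_R%d.fastq", m)))
  }
  write.table(dataset$short$reads[, c("read_id", "sample")],
              file.path(dir, "short_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$db$info, file.path(dir, "db_info.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gs <- dataset$pool$targets
  write.table(gs[gs$full, c("gene", "set")], file.path(dir, "gene_sets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write pipeline outputs to a directory
#'
#' Panel FASTA (headers `panel_id|closest_db`), genotype TSV, selection
#' and accuracy reports (JSON), panel entry and exon-variant TSVs.
#'
#' @param run A `panel_run`.
#' @param dir Output directory (created).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0(run$entries$allele_id, "|", run$entries$closest_db)
  write_fasta(setNames(run$panel$sequences[run$entries$allele_id], hdr),
              file.path(dir, "panel.fasta"))
  write.table(run$calls, file.path(dir, "genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$entries, file.path(dir, "panel_entries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$exon_variants, file.path(dir, "exon_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = run$accuracy, selection = run$selection,
         extension_stats = run$extension_stats,
         corrections = run$refinement$corrections),
    file.path(dir, "reports.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
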