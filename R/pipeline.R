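#' Run the full panel-construction pipeline
#'
#' Demultiplexes long reads by primer set and sample, assembles and fuses
#' per-bin consensus contigs into the draft allele set, refines draft
#' alleles against each carrier's short reads, genotypes every sample by
#' exhaustive diploid likelihood over refined + database alleles (with
#' copy-number calls at deletable loci), filters the panel to recursively
#' genotyped alleles, and characterizes the panel against the database.
#'
#' @param long_reads Tibble (`read_id`, `sample`, `sequence`) of long
#'   amplicon reads (`sample` may be omitted when `indexes` is given).
#' @param short_reads Tibble (`read_id`, `sample`, `sequence`).
#' @param db Known-allele database (`reference_db`).
#' @param primer_sets Tibble (`set`, `forward`, `reverse`).
#' @param gene_set_map Tibble (`gene`, `set`) defining the designed set of
#'   each gene.
#' @param models Gene models (deletable flags); defaults to
#'   [gene_models()].
#' @param indexes Optional (`sample`, `index`) barcode sheet.
#' @param policy,asm,ref,gt Stage parameter objects.
#' @param separate_primers Set `FALSE` to bypass primer separation (all of
#'   a sample's reads pooled into one bin) -- the failure mode the pipeline
#'   exists to fix; exposed for regression testing.
#' @return A `panel_run` list with every stage's outputs.
#' @export
run_pipeline <- function(long_reads, short_reads, db, primer_sets,
                         gene_set_map, models = gene_models(),
                         indexes = NULL,
                         policy = primer_match_policy(),
                         asm = assembly_params(),
                         ref = refine_params(),
                         gt = genotype_params(),
                         separate_primers = TRUE) {
  dm <- demultiplex(long_reads, primer_sets, policy, indexes)
  bins <- dm$bins
  if (!separate_primers) {
    bins$primer_set <- "pooled"
  }
  asmres <- assemble_reads(bins, db, primer_sets, gene_set_map, asm, policy)
  refres <- refine_alleles(asmres$draft, short_reads, ref)
  gtres <- genotype_all(refres$refined, db, short_reads, models, gt)
  sel <- filter_panel(refres$refined, gtres$calls)
  # panel accuracy: reads compete over each sample's full genotype call
  # (panel alleles plus database alleles), matching the filtering model
  id_map <- setNames(sel$panel$info$allele_id, sel$panel$info$refined_id)
  cand <- bind_rows(
    gtres$calls |> transmute(sample = .data$sample, gene = .data$gene,
                             allele_id = .data$allele1),
    gtres$calls |> transmute(sample = .data$sample, gene = .data$gene,
                             allele_id = .data$allele2)) |>
    filter(!is.na(.data$allele_id)) |>
    mutate(allele_id = ifelse(.data$allele_id %in% names(id_map),
                              id_map[.data$allele_id], .data$allele_id)) |>
    distinct()
  panel_va <- variant_accuracy(sel$panel, short_reads, ref,
                               candidates = cand,
                               extra_sequences = db$sequences)
  chr <- characterize_panel(sel$panel, db)
  dist <- allele_distribution(gtres$calls)
  accuracy <- bind_rows(
    refres$accuracy,
    mutate(panel_va$accuracy, stage = "panel")[, c("stage", "gene",
                                                   "examined", "supported",
                                                   "accuracy")])
  ext <- extension_and_variant_stats(chr$entries, panel_va$variants)
  structure(list(
    demux = dm, contigs = asmres$contigs, assembly_report = asmres$report,
    draft = asmres$draft, refinement = refres, refined = refres$refined,
    copy_numbers = gtres$copy_numbers, calls = gtres$calls,
    selection = sel$selection, panel = sel$panel,
    panel_va = panel_va, entries = chr$entries,
    exon_variants = chr$exon_variants, extension_stats = ext,
    distribution = dist, accuracy = accuracy
  ), class = "panel_run")
}

#' Run the pipeline on a simulated dataset
#'
#' Convenience wrapper wiring a [simulate_dataset()] result into
#' [run_pipeline()] (primer sheet, barcode sheet and gene/set map come
#' from the simulation's pool).
#'
#' @param dataset A `sim_dataset`.
#' @param ... Passed to [run_pipeline()].
#' @return A `panel_run`.
#' @export
run_simulated <- function(dataset, ...) {
  gs <- dataset$pool$targets |>
    filter(.data$full) |>
    select(gene = "gene", set = "set")
  run_pipeline(dataset$long$reads, dataset$short$reads, dataset$db,
               dataset$pool$primer_sets, gs, models = dataset$pool$models,
               indexes = dataset$long$indexes, ...)
}

#' @export
print.panel_run <- function(x, ...) {
  cat("<panel_run>\n")
  cat("  draft alleles:   ", length(x$draft$sequences), "\n", sep = "")
  cat("  refined alleles: ", length(x$refined$sequences), "\n", sep = "")
  cat("  panel alleles:   ", length(x$panel$sequences), "\n", sep = "")
  acc <- x$accuracy[x$accuracy$gene == ".mean", ]
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-8s mean variant accuracy: %.1f%% (%d examined)\n",
                acc$stage[i], 100 * acc$accuracy[i], acc$examined[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into the panel entry table
#'
#' @param x A `panel_run`.
#' @param ... Unused.
#' @return Tibble of panel entries (closest database allele, distances,
#'   extensions, novelty flags).
#' @export
tidy.panel_run <- function(x, ...) {
  x$entries
}

#' One-row summary of a pipeline run
#'
#' @param x A `panel_run`.
#' @param ... Unused.
#' @return One-row tibble with allele counts, mean variant accuracies per
#'   stage, correction count and genotyping rate.
#' @export
glance.panel_run <- function(x, ...) {
  acc <- x$accuracy[x$accuracy$gene == ".mean", ]
  ac <- setNames(acc$accuracy, acc$stage)
  typed <- mean(!is.na(x$calls$allele1) | x$calls$copy_number == 0L)
  tibble(
    n_draft = length(x$draft$sequences),
    n_refined = length(x$refined$sequences),
    n_panel = length(x$panel$sequences),
    accuracy_draft = unname(ac["draft"]),
    accuracy_refined = unname(ac["refined"]),
    accuracy_panel = unname(ac["panel"]),
    n_corrections = nrow(x$refinement$corrections),
    typed_rate = typed
  )
}

#' Compare a pipeline run against simulation truth
#'
#' @param run A `panel_run`.
#' @param dataset The `sim_dataset` the run was computed from.
#' @return One-row tibble: fraction of carried truth alleles recovered
#'   exactly in the panel, fraction of panel alleles exactly matching a
#'   truth allele, genotype concordance (sample/gene calls whose allele
#'   sequences equal the truth pair), and copy-number accuracy at
#'   deletable loci.
#' @export
evaluate_run <- function(run, dataset) {
  truth_carried <- unique(stats::na.omit(dataset$truth$allele))
  truth_seqs <- dataset$pool$sequences[truth_carried]
  panel_seqs <- run$panel$sequences
  recovered <- mean(truth_seqs %in% panel_seqs)
  exact <- mean(panel_seqs %in% truth_seqs)

  # genotype concordance on allele sequences
  cand_seq <- c(run$refined$sequences, dataset$db$sequences)
  tr <- dataset$truth |>
    group_by(.data$sample, .data$gene) |>
    summarise(truth_key = paste(sort(stats::na.omit(.data$allele)),
                                collapse = "|"), .groups = "drop")
  pool_by_seq <- setNames(names(dataset$pool$sequences),
                          unname(dataset$pool$sequences))
  call_key <- vapply(seq_len(nrow(run$calls)), function(i) {
    al <- stats::na.omit(c(run$calls$allele1[i], run$calls$allele2[i]))
    nm <- vapply(al, function(a) {
      s <- cand_seq[[a]]
      hit <- pool_by_seq[s]
      if (is.na(hit)) a else unname(hit)
    }, "")
    paste(sort(nm), collapse = "|")
  }, "")
  cc <- run$calls |>
    mutate(call_key = call_key) |>
    left_join(tr, by = c("sample", "gene"))
  concordance <- mean(cc$call_key == cc$truth_key)

  cn_acc <- NA_real_
  if (nrow(run$copy_numbers) > 0L) {
    cn_truth <- dataset$truth |>
      filter(.data$gene %in% run$copy_numbers$locus) |>
      group_by(.data$sample, locus = .data$gene) |>
      summarise(cn = sum(!is.na(.data$allele)), .groups = "drop")
    cmp <- inner_join(run$copy_numbers, cn_truth, by = c("sample", "locus"))
    cn_acc <- mean(cmp$call == cmp$cn)
  }
  tibble(truth_recovery = recovered, panel_exact = exact,
         genotype_concordance = concordance, copy_number_accuracy = cn_acc)
}
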