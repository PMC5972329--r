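# End-to-end orchestration: germline -> subgroups -> mutation calling ->
# summaries -> mutability -> motifs -> windows, bundled into one report
# object with deterministic TSV output.

#' Run the full SHM characterization pipeline
#'
#' Stages run in order: germline inference (unless a reference is
#' supplied), allelic-subgroup splitting, per-subgroup mutation calling
#' (summed afterwards), per-individual and pooled summaries, mono/di/tri
#' mutability tables, motif scan/overlap/density and the per-window
#' profile.
#'
#' @param clones Clone tibble (e.g. from [read_clone_fasta()]).
#' @param reference Optional `shm_germline`; inferred from the pool when
#'   NULL.
#' @param rmap Optional `shm_region_map`.
#' @param allele_threshold Allelic-position threshold for
#'   [infer_germline()].
#' @param window Window size in bp for [window_profile()].
#' @param masked_spans Optional primer-span mask tibble (`start`, `end`).
#' @param motif_classes Motif classes to scan.
#' @param seed Seed recorded in the metadata (the analysis itself is
#'   deterministic).
#' @return List of class `shm_report`: `germline`, `subgroups`, `records`,
#'   `summary`, `mutability` (list mono/di/tri), `motif_hits`,
#'   `motif_summary`, `windows`, `metadata`.
#' @export
run_shm_pipeline <- function(clones, reference = NULL, rmap = NULL,
                             allele_threshold = 0.3, window = 20,
                             masked_spans = NULL,
                             motif_classes = c("AID_RGYW", "AID_WRCY",
                                               "WA", "TW"),
                             seed = 1L) {
  check_clone_tbl(clones)
  germ <- if (is.null(reference)) {
    infer_germline(clones, allele_threshold = allele_threshold,
                   frame_offset = if (!is.null(rmap)) rmap$frame_offset else 0L)
  } else reference
  split <- split_subgroups(clones, germ)
  resolved <- split$clones[!is.na(split$clones$subgroup), , drop = FALSE]
  if (nrow(resolved) == 0) {
    stop_shm("no clone resolved to an allelic subgroup; the pool is too ",
             "heterogeneous for consensus germline inference (restrict to ",
             "one V/J gene or supply `reference`)")
  }

  rec_list <- list()
  surveyed <- list()
  for (sg in unique(resolved$subgroup)) {
    sub_clones <- resolved[resolved$subgroup == sg, , drop = FALSE]
    ref_seq <- split$references$sequence[split$references$subgroup == sg]
    sub_germ <- germline_reference(ref_seq, frame_offset = germ$frame_offset)
    r <- call_mutations(sub_clones, sub_germ, rmap = rmap,
                        masked_spans = masked_spans)
    surveyed[[sg]] <- attr(r, "surveyed")
    rec_list[[sg]] <- r
  }
  records <- dplyr::bind_rows(rec_list)
  surveyed <- dplyr::bind_rows(surveyed)
  clone_meta <- dplyr::left_join(
    resolved[, c("clone_id", "individual_id")], surveyed, by = "clone_id")

  per_ind <- unname(split(clone_meta, clone_meta$individual_id))
  rows <- c(
    purrr::map(per_ind, function(m) {
      strip_cls(summarize_mutations(
        records[records$clone_id %in% m$clone_id, , drop = FALSE],
        n_bp = sum(m$n_bp), n_clones = nrow(m), label = m$individual_id[1]))
    }),
    list(strip_cls(summarize_mutations(
      records, n_bp = sum(clone_meta$n_bp),
      n_clones = nrow(clone_meta), label = "Total")))
  )
  summary <- dplyr::bind_rows(rows)
  class(summary) <- c("shm_summary", class(summary))

  mut_tables <- list(
    mono = mutability_table(records, germ$sequence, 1, masked_spans),
    di = mutability_table(records, germ$sequence, 2, masked_spans),
    tri = mutability_table(records, germ$sequence, 3, masked_spans)
  )
  hits <- scan_motifs(germ$sequence, motif_classes)
  motif_summary <- dplyr::left_join(
    motif_density(germ$sequence, motif_classes, masked_spans),
    motif_overlap(records, hits), by = "motif_class")
  records <- annotate_motif_flags(records, hits)
  windows <- window_profile(records, n_clones = nrow(resolved),
                            ref_length = nchar(germ$sequence),
                            window = window, masked_spans = masked_spans)
  structure(list(
    germline = germ, subgroups = split, records = records,
    summary = summary, mutability = mut_tables,
    motif_hits = hits, motif_summary = motif_summary, windows = windows,
    metadata = list(
      n_clones = nrow(clones), n_unresolved = sum(is.na(split$clones$subgroup)),
      allele_threshold = allele_threshold, window = window,
      motif_classes = motif_classes, seed = seed
    )
  ), class = "shm_report")
}

#' @export
print.shm_report <- function(x, ...) {
  cat("<shm_report>", x$metadata$n_clones, "clones,",
      nrow(x$records), "mutation events\n")
  print(x$summary)
  invisible(x)
}

#' Write an analysis report bundle to disk
#'
#' Emits summary.tsv, mutations.tsv, mutability_mono/di/tri.tsv,
#' motif_summary.tsv, windows.tsv, motifs.bed and run_metadata.txt.
#' Output is byte-identical across reruns on identical inputs. Ratio and
#' frequency columns in summary.tsv are also given as printed columns
#' truncated to two decimals.
#'
#' @param report `shm_report` from [run_shm_pipeline()].
#' @param out_dir Output directory.
#' @return Files written, invisibly.
#' @export
write_shm_bundle <- function(report, out_dir) {
  summary_tbl <- dplyr::mutate(
    tibble::as_tibble(report$summary),
    freq_per_kb_printed = printed_value(.data$freq_per_kb, 2),
    rs_ratio_printed = printed_value(.data$rs_ratio, 2)
  )
  write_tables(
    list(
      summary = summary_tbl,
      mutations = tibble::as_tibble(report$records),
      mutability_mono = tibble::as_tibble(report$mutability$mono),
      mutability_di = tibble::as_tibble(report$mutability$di),
      mutability_tri = tibble::as_tibble(report$mutability$tri),
      motif_summary = report$motif_summary,
      windows = report$windows,
      motifs_bed = motif_hits_to_bed(report$motif_hits)
    ),
    out_dir, metadata = report$metadata
  )
}
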