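#' Run the full genome-to-marker pipeline on one sequence set
#'
#' Convenience wrapper chaining the stages: SSR scan, compound merging,
#' classification summary, primer design, redundancy filtering, physical
#' mapping back to the source sequences, and (optionally) association
#' screens of the unique markers. Per-stage counts are reported.
#'
#' @param seqs input sequence set ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param config an [ssr_config()].
#' @param dataset_tag dataset label for the summaries.
#' @param te_proteins optional TE protein library for the association
#'   screen (skipped when `NULL`).
#' @param mature_mirnas optional mature-miRNA set (skipped when
#'   `NULL`).
#' @param annotations optional named character vector of functional
#'   annotations keyed by marker id.
#' @param verbose print per-stage counts to stderr.
#' @return list: `loci`, `summary` (`ssr_summary`), `density`,
#'   `markers` (evaluated marker table), `dedup_report`, `stage_counts`.
#' @export
run_ssr_pipeline <- function(seqs, config = ssr_config(),
                             dataset_tag = "other",
                             te_proteins = NULL, mature_mirnas = NULL,
                             annotations = NULL, verbose = FALSE) {
  log_stage <- function(...) if (verbose) message(sprintf(...))
  loci <- scan_ssrs(seqs, config)
  loci <- merge_compound(loci)
  log_stage("scan: %d loci (%d compound)", nrow(loci),
            sum(loci$is_compound))
  summary <- tabulate_dataset(loci, dataset_tag)
  density <- summarize_density(loci, seqs, dataset_tag)
  markers <- design_markers(loci, seqs, config)
  n_designed <- sum(markers$status == "designed")
  log_stage("design: %d/%d designed", n_designed, nrow(markers))
  dd <- deduplicate_primers(markers)
  markers <- dd$markers
  log_stage("dedup: %d kept (%s%%)", dd$report$kept,
            dd$report$retention_pct)
  markers <- physical_map(markers, seqs, config)
  log_stage("map: %d unique", sum(markers$map_status == "unique"))
  markers$te_associated <- NA
  markers$te_family <- NA_character_
  markers$mirna_associated <- NA
  sv <- as_seqs(seqs)
  if (!is.null(te_proteins) || !is.null(mature_mirnas)) {
    for (i in which(markers$status == "designed")) {
      fl <- extract_flanks(markers[i, ], sv[[markers$seq_id[i]]],
                           config$flank_length)
      if (!is.null(te_proteins)) {
        hit <- te_association(fl, te_proteins, config$te_min_identity,
                              config$te_max_evalue)
        markers$te_associated[i] <- nrow(hit) > 0
        if (nrow(hit)) markers$te_family[i] <- hit$te_family
      }
      if (!is.null(mature_mirnas)) {
        mh <- mirna_association(fl, mature_mirnas,
                                config$mirna_max_mismatches)
        markers$mirna_associated[i] <- nrow(mh) > 0
      }
    }
  }
  markers$function_category <- if (!is.null(annotations))
    categorize_annotation(annotations[markers$marker_id]) else
      NA_character_
  markers$transferability_count <- NA_integer_
  markers$polymorphism <- NA_character_
  stage_counts <- data.frame(
    stage = c("loci", "compound", "designed", "non_redundant",
              "unique_mapped"),
    count = c(nrow(loci), sum(loci$is_compound), n_designed,
              dd$report$kept, sum(markers$map_status == "unique"))
  )
  list(loci = loci, summary = summary, density = density,
       markers = markers, dedup_report = dd$report,
       stage_counts = stage_counts)
}
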