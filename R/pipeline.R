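#' Pipeline configuration
#'
#' @param min_orf_len Strict lower bound on ORF peptide length (aa).
#' @param sources List of `evidence_source` objects; `NULL` uses the two
#'   built-in offline sources (homeodomain profile + reference k-mer).
#' @param keep_longest Keep-longest policy for zero-evidence transcripts.
#' @param dedup_mode `"exact"` or `"containment"`.
#' @param catalog A `motif_catalog`.
#' @param profile An `hd_profile`.
#' @param threshold_bits Scan threshold; `NULL` uses the profile default.
#' @param params Classifier parameters, see [classifier_params()].
#' @param seed Seed recorded in report headers (the pipeline itself is
#'   deterministic for fixed inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_orf_len = 50L, sources = NULL,
                            keep_longest = FALSE,
                            dedup_mode = c("exact", "containment"),
                            catalog = default_catalog(),
                            profile = default_profile(),
                            threshold_bits = NULL,
                            params = classifier_params(), seed = 1L) {
  dedup_mode <- match.arg(dedup_mode)
  if (is.null(threshold_bits)) threshold_bits <- attr(profile, "threshold_bits")
  if (is.null(sources)) {
    sources <- list(
      profile_evidence_source(profile, threshold_bits),
      kmer_evidence_source())
  }
  structure(list(min_orf_len = as.integer(min_orf_len), sources = sources,
                 keep_longest = keep_longest, dedup_mode = dedup_mode,
                 catalog = catalog, profile = profile,
                 threshold_bits = threshold_bits, params = params,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the homeobox mining pipeline end-to-end
#'
#' transcripts -> six-frame ORF candidates -> evidence vote -> one
#' selected CDS per transcript -> exact-identity deduplication ->
#' homeodomain scan -> paralog-group classification, with a per-stage
#' count summary. Deterministic for fixed inputs and configuration.
#'
#' @param transcripts Sequence record data frame (nt).
#' @param config A `pipeline_config`.
#' @return List with `candidates`, `evidence`, `selected`, `clusters`,
#'   `nonredundant`, `hd_hits`, `classified`, `label_counts`, `summary`
#'   and `config`.
#' @export
run_pipeline <- function(transcripts, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "enumerate_orfs"
  res <- tryCatch({
    candidates <- enumerate_orfs_set(transcripts, config$min_orf_len)
    stage <- "collect_evidence"
    evidence <- collect_evidence(candidates, config$sources)
    stage <- "select_cds"
    selected <- select_cds(candidates, evidence, config$keep_longest)
    stage <- "dedup"
    proteins <- data.frame(id = selected$transcript_id,
                           peptide = selected$peptide,
                           stringsAsFactors = FALSE)
    cl <- cluster_exact(proteins, config$dedup_mode)
    nonredundant <- cl$representatives
    stage <- "homeodomain_scan"
    hd_hits <- do.call(rbind, lapply(seq_len(nrow(nonredundant)), function(i) {
      h <- suppressWarnings(scan_homeodomains(
        nonredundant$peptide[i], config$profile,
        threshold_bits = config$threshold_bits,
        protein_id = nonredundant$id[i]))
      if (nrow(h)) h[1L, , drop = FALSE] else NULL
    }))
    if (is.null(hd_hits)) {
      hd_hits <- data.frame(protein_id = character(), hd_start = integer(),
                            score = numeric(), stringsAsFactors = FALSE)
    }
    stage <- "classify"
    classified <- if (nrow(nonredundant)) {
      classify_set(nonredundant, config$profile, config$catalog, config$params)
    } else {
      data.frame(protein_id = character(), status = character(),
                 label = character(), candidates = character(),
                 score = numeric(), hd_start = integer(), hd_score = numeric(),
                 matched_features = character(), stringsAsFactors = FALSE)
    }
    list(candidates = candidates, evidence = evidence, selected = selected,
         clusters = cl$clusters, nonredundant = nonredundant,
         hd_hits = hd_hits, classified = classified)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  assigned <- res$classified[res$classified$status == "assigned", , drop = FALSE]
  labels <- catalog_labels(config$catalog)
  label_counts <- vapply(labels, function(l) sum(assigned$label == l),
                         integer(1))
  counts <- c(transcripts = nrow(transcripts),
              candidate_orfs = nrow(res$candidates),
              selected_cds = nrow(res$selected),
              nonredundant_proteins = nrow(res$nonredundant),
              homeodomain_hits = nrow(res$hd_hits),
              classified = sum(res$classified$status == "assigned"),
              ambiguous = sum(res$classified$status == "AMBIGUOUS"),
              unclassified = sum(res$classified$status == "UNCLASSIFIED"))
  c(res, list(label_counts = label_counts,
              summary = stage_summary(counts), config = config))
}

#' Render per-stage counts as a summary table
#'
#' @param counts Named integer vector of per-stage counts, pipeline
#'   order.
#' @return Data frame with `stage`, `count`, `percent_of_previous`
#'   (100 for the first row; per-stage ratios, not constrained to sum).
#' @export
stage_summary <- function(counts) {
  n <- length(counts)
  prev <- c(NA, utils::head(unname(counts), -1L))
  pct <- ifelse(is.na(prev), 100,
                ifelse(prev > 0, 100 * unname(counts) / prev, 0))
  data.frame(stage = names(counts), count = unname(counts),
             percent_of_previous = round(pct, 1), stringsAsFactors = FALSE)
}

#' Score pipeline output against a generator truth table
#'
#' Traces every planted (non-decoy) truth row through selection,
#' deduplication and classification, and reports whether the planted
#' label was recovered.
#'
#' @param result Output of [run_pipeline()].
#' @param truth Truth table from [generate_transcriptome()].
#' @return Data frame: `transcript_id`, `planted_group`, `selected`,
#'   `representative`, `status`, `label`, `recovered`.
#' @export
evaluate_against_truth <- function(result, truth) {
  planted <- truth[truth$planted_group != "DECOY", , drop = FALSE]
  rep_of <- stats::setNames(result$clusters$representative_id,
                            result$clusters$member_id)
  cls <- result$classified
  rows <- lapply(seq_len(nrow(planted)), function(i) {
    tid <- planted$transcript_id[i]
    sel <- tid %in% result$selected$transcript_id
    rep_id <- if (sel) unname(rep_of[tid]) else NA_character_
    r <- if (!is.na(rep_id)) cls[cls$protein_id == rep_id, , drop = FALSE]
         else cls[0, , drop = FALSE]
    status <- if (nrow(r)) r$status else "not_selected"
    label <- if (nrow(r)) r$label else ""
    data.frame(transcript_id = tid, planted_group = planted$planted_group[i],
               selected = sel, representative = ifelse(is.na(rep_id), "", rep_id),
               status = status, label = label,
               recovered = status == "assigned" &
                 label == planted$planted_group[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the standard pipeline report files
#'
#' Emits `selected_cds.faa`, `nonredundant.faa`, `hd_hits.tsv`,
#' `classified.tsv` and `summary.tsv` (plus `truth_eval.tsv` when a
#' truth table is supplied) under `out_dir`. Report coordinates are
#' 1-based inclusive; the configured seed is recorded in the summary.
#'
#' @param result Output of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param truth Optional truth table.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, out_dir, truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sel <- result$selected
  write_fasta(seq_records(
    sel$transcript_id,
    sprintf("frame=%+d nt=%d-%d evidence=%d", sel$frame, sel$nt_start + 1L,
            sel$nt_end, sel$evidence_count),
    sel$peptide), file.path(out_dir, "selected_cds.faa"))
  write_fasta(seq_records(result$nonredundant$id, "",
                          result$nonredundant$peptide),
              file.path(out_dir, "nonredundant.faa"))
  hd <- result$hd_hits
  hd$start_1based <- hd$hd_start + 1L
  write_tsv_report(hd[, c("protein_id", "start_1based", "score")],
                   file.path(out_dir, "hd_hits.tsv"))
  write_tsv_report(result$classified, file.path(out_dir, "classified.tsv"))
  sm <- result$summary
  sm$seed <- result$config$seed
  write_tsv_report(sm, file.path(out_dir, "summary.tsv"))
  if (!is.null(truth)) {
    write_tsv_report(evaluate_against_truth(result, truth),
                     file.path(out_dir, "truth_eval.tsv"))
  }
  invisible(out_dir)
}
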