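.FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Enumerate open reading frames in all six frames
#'
#' Finds every maximal ATG-to-stop ORF (standard genetic code) whose
#' translated length exceeds `min_len_exclusive` amino acids. Within a
#' frame, only the longest ORF per stop codon is emitted (the first ATG
#' after the previous stop; nested ATGs are not re-emitted). A stop codon
#' is required: open-ended ORFs at transcript edges are not reported.
#' Codons containing N translate to X; stop detection is unaffected.
#'
#' @param transcript Nucleotide string over ACGTN.
#' @param min_len_exclusive Strict lower bound on peptide length (a
#'   peptide of exactly this length is rejected); default 50.
#' @param id Transcript identifier carried into the output.
#' @return Data frame with columns `transcript_id`, `orf_index`, `frame`
#'   (+1..+3 forward, -1..-3 on the reverse complement), `nt_start`,
#'   `nt_end` (0-based half-open on the forward strand, stop codon
#'   included), `peptide` (no stop), `aa_length`. Ordered by frame
#'   (+1, +2, +3, -1, -2, -3) then `nt_start`.
#' @export
enumerate_orfs <- function(transcript, min_len_exclusive = 50L,
                           id = "transcript") {
  transcript <- toupper(transcript)
  L <- nchar(transcript)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) transcript else revcomp(transcript)
    for (offset in 0:2) {
      aa <- translate_nt(s, offset = offset)
      if (!nchar(aa)) next
      chars <- strsplit(aa, "")[[1L]]
      stops <- which(chars == "*")
      seg_start <- 1L  # 1-based aa index where the current segment begins
      for (st in stops) {
        if (st > seg_start) {
          ms <- which(chars[seg_start:(st - 1L)] == "M")
          if (length(ms)) {
            m <- seg_start + ms[1L] - 1L
            aa_len <- st - m
            if (aa_len > min_len_exclusive) {
              nt_s <- offset + 3L * (m - 1L)     # 0-based on this strand
              nt_e <- offset + 3L * st           # includes stop codon
              if (strand == 1L) {
                fs <- nt_s; fe <- nt_e
              } else {
                fs <- L - nt_e; fe <- L - nt_s
              }
              out[[length(out) + 1L]] <- data.frame(
                transcript_id = id,
                frame = strand * (offset + 1L),
                nt_start = fs, nt_end = fe,
                peptide = paste(chars[m:(st - 1L)], collapse = ""),
                aa_length = aa_len, stringsAsFactors = FALSE)
            }
          }
        }
        seg_start <- st + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), orf_index = integer(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), peptide = character(),
                      aa_length = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(match(df$frame, .FRAME_ORDER), df$nt_start), , drop = FALSE]
  df <- cbind(df[, "transcript_id", drop = FALSE],
              orf_index = seq_len(nrow(df)),
              df[, setdiff(names(df), "transcript_id"), drop = FALSE])
  rownames(df) <- NULL
  df
}

#' Enumerate ORFs across a set of transcripts
#'
#' @param transcripts Sequence record data frame (see [read_fasta()]).
#' @param min_len_exclusive As in [enumerate_orfs()].
#' @return Row-bound candidate table with a `candidate_id` column
#'   (`<transcript_id>|orf<k>`).
#' @export
enumerate_orfs_set <- function(transcripts, min_len_exclusive = 50L) {
  parts <- lapply(seq_len(nrow(transcripts)), function(i) {
    enumerate_orfs(transcripts$residues[i], min_len_exclusive,
                   id = transcripts$id[i])
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || nrow(df) == 0L) {
    df <- enumerate_orfs("", min_len_exclusive)
  }
  .with_candidate_id(df)
}

.with_candidate_id <- function(df) {
  df$candidate_id <- if (nrow(df)) {
    paste0(df$transcript_id, "|orf", df$orf_index)
  } else {
    character(0)
  }
  df
}

# ---- evidence sources -------------------------------------------------

new_evidence_source <- function(name, fn) {
  structure(list(name = name, fn = fn), class = "evidence_source")
}

#' Homeodomain-profile evidence source
#'
#' Positive for a candidate iff its peptide has a profile scan hit at or
#' above the threshold.
#'
#' @param profile A `hd_profile` (default: the packaged consensus profile).
#' @param threshold_bits Scan threshold; `NULL` uses the calibrated
#'   default of the profile.
#' @return An `evidence_source`.
#' @export
profile_evidence_source <- function(profile = default_profile(),
                                    threshold_bits = NULL) {
  if (is.null(threshold_bits)) {
    threshold_bits <- attr(profile, "threshold_bits")
    if (is.null(threshold_bits)) {
      threshold_bits <- default_scan_threshold(profile)
    }
  }
  new_evidence_source("hd_profile", function(peptide, candidate_id) {
    hits <- suppressWarnings(
      scan_homeodomains(peptide, profile, threshold_bits = threshold_bits))
    nrow(hits) > 0L
  })
}

#' Reference-peptide k-mer evidence source
#'
#' Positive iff the candidate peptide shares at least `cutoff` distinct
#' k-mers with the reference peptide set (default: the packaged
#' homeodomain consensus set).
#'
#' @param reference Character vector of reference peptides.
#' @param k K-mer size.
#' @param cutoff Minimum shared distinct k-mer count.
#' @return An `evidence_source`.
#' @export
kmer_evidence_source <- function(reference = hd_consensus_set(), k = 5L,
                                 cutoff = 10L) {
  ref_kmers <- unique(unlist(lapply(reference, .peptide_kmers, k = k)))
  new_evidence_source("ref_kmer", function(peptide, candidate_id) {
    q <- .peptide_kmers(peptide, k)
    sum(q %in% ref_kmers) >= cutoff
  })
}

.peptide_kmers <- function(peptide, k) {
  n <- nchar(peptide)
  if (n < k) return(character(0))
  unique(substring(peptide, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' External hit-table evidence source
#'
#' Reads similarity-search output (TSV with columns `query_id`,
#' `source_name`, `subject_id`, `e_value`, `bit_score`; `query_id` is the
#' candidate id `<transcript>|orf<k>`). Positive iff any row for the
#' candidate has `e_value` at or below the cutoff (default 1e-06).
#'
#' @param hits Data frame or path to a TSV.
#' @param e_max E-value cutoff.
#' @param name Source name used in the evidence table.
#' @param candidate_ids Known candidate ids; rows referencing other ids
#'   are ignored with a warning.
#' @return An `evidence_source`.
#' @export
tsv_evidence_source <- function(hits, e_max = 1e-6, name = "external",
                                candidate_ids = NULL) {
  if (is.character(hits)) hits <- read_tsv_report(hits)
  needed <- c("query_id", "e_value")
  if (!all(needed %in% names(hits))) {
    stop("hit table must have columns query_id and e_value")
  }
  if (any(hits$e_value < 0)) stop("negative e_value in hit table")
  if (!is.null(candidate_ids)) {
    unknown <- setdiff(unique(hits$query_id), candidate_ids)
    if (length(unknown)) {
      warning("ignoring hit rows for unknown candidate id(s): ",
              paste(utils::head(unknown, 3L), collapse = ", "))
      hits <- hits[hits$query_id %in% candidate_ids, , drop = FALSE]
    }
  }
  positive <- unique(hits$query_id[hits$e_value <= e_max])
  new_evidence_source(name, function(peptide, candidate_id) {
    candidate_id %in% positive
  })
}

#' Collect evidence votes for ORF candidates
#'
#' Runs every source on every candidate and tallies the number of
#' positive sources per candidate.
#'
#' @param candidates Candidate table from [enumerate_orfs_set()].
#' @param sources List of `evidence_source` objects (possibly empty).
#' @return The candidate key columns plus one logical column per source
#'   and `evidence_count`.
#' @export
collect_evidence <- function(candidates, sources = list()) {
  if (!"candidate_id" %in% names(candidates)) {
    candidates <- .with_candidate_id(candidates)
  }
  ev <- candidates[, c("transcript_id", "orf_index", "candidate_id"),
                   drop = FALSE]
  for (src in sources) {
    stopifnot(inherits(src, "evidence_source"))
    ev[[src$name]] <- vapply(seq_len(nrow(candidates)), function(i) {
      isTRUE(src$fn(candidates$peptide[i], candidates$candidate_id[i]))
    }, logical(1))
  }
  src_cols <- setdiff(names(ev), c("transcript_id", "orf_index", "candidate_id"))
  ev$evidence_count <- if (length(src_cols)) {
    as.integer(rowSums(as.matrix(ev[, src_cols, drop = FALSE])))
  } else {
    integer(nrow(ev)) # no sources configured: all zero
  }
  ev
}

#' Select the unique CDS per transcript by evidence vote
#'
#' Per transcript the winner is the candidate with the highest evidence
#' count; ties are broken by longer peptide, then 5'-most `nt_start`,
#' then frame order +1, +2, +3, -1, -2, -3. Transcripts whose best count
#' is zero yield nothing unless `keep_longest` is set, in which case the
#' longest ORF is selected and flagged.
#'
#' @param candidates Candidate table from [enumerate_orfs_set()].
#' @param evidence Evidence table from [collect_evidence()] covering all
#'   candidates.
#' @param keep_longest Keep-longest policy for zero-evidence transcripts.
#' @return One row per selected transcript: candidate columns plus
#'   `evidence_count` and `zero_evidence`.
#' @export
select_cds <- function(candidates, evidence, keep_longest = FALSE) {
  if (!"candidate_id" %in% names(candidates)) {
    candidates <- .with_candidate_id(candidates)
  }
  if (!all(candidates$candidate_id %in% evidence$candidate_id)) {
    stop("evidence table does not cover all candidates")
  }
  m <- merge(candidates,
             evidence[, c("candidate_id", "evidence_count")],
             by = "candidate_id", sort = FALSE)
  picks <- lapply(split(m, m$transcript_id), function(d) {
    best <- max(d$evidence_count)
    if (best == 0L && !keep_longest) return(NULL)
    pool <- if (best > 0L) d[d$evidence_count == best, , drop = FALSE] else d
    ord <- order(-pool$aa_length, pool$nt_start,
                 match(pool$frame, .FRAME_ORDER))
    w <- pool[ord[1L], , drop = FALSE]
    w$zero_evidence <- best == 0L
    w
  })
  picks <- do.call(rbind, picks)
  if (is.null(picks)) {
    picks <- cbind(candidates[0, , drop = FALSE],
                   evidence_count = integer(), zero_evidence = logical())
  }
  rownames(picks) <- NULL
  picks[order(picks$transcript_id), , drop = FALSE]
}
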