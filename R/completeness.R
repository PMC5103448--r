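#' Local alignment of a marker against a protein
#'
#' Smith-Waterman via [Biostrings::pairwiseAlignment()] with a standard
#' amino-acid substitution matrix (default BLOSUM62) and a linear gap
#' penalty. Coverage is the fraction of marker residues spanned by the
#' local alignment; identity is matches over alignment columns (gap
#' columns included).
#'
#' @param marker,protein Non-empty peptide strings.
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"PAM70"`, ...) as shipped with Biostrings.
#' @param gap_penalty Per-residue gap cost (linear), default 8.
#' @return List with `score`, `marker_coverage`, `identity`.
#' @export
align_marker <- function(marker, protein, matrix = "BLOSUM62",
                         gap_penalty = 8) {
  if (!nzchar(marker) || !nzchar(protein)) stop("empty sequence")
  sm <- .substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(marker), Biostrings::AAString(protein),
    type = "local", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = gap_penalty)
  p <- Biostrings::pattern(aln)
  covered <- Biostrings::end(p) - Biostrings::start(p) + 1L
  cols <- nchar(as.character(p))
  list(score = Biostrings::score(aln),
       marker_coverage = covered / nchar(marker),
       identity = Biostrings::nmatch(aln) / cols)
}

.substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Assess marker recovery in a protein set
#'
#' A simplified single-copy ortholog completeness metric: each marker is
#' locally aligned against every protein; a protein is a qualifying full
#' hit when `marker_coverage >= cov_complete` and
#' `identity >= id_min`. A marker is `complete` with exactly one such
#' protein, `duplicated` with more than one, `fragmented` when its best
#' qualifying hit (identity passed) covers at least `cov_fragment` but
#' less than `cov_complete`, else `missing`. The completeness percentage
#' counts complete markers only.
#'
#' @param markers Sequence records (or data frame with `id`, `peptide`).
#' @param proteome Sequence records; may have zero rows.
#' @param cov_complete,cov_fragment Coverage thresholds,
#'   `0 < cov_fragment < cov_complete <= 1`.
#' @param id_min Minimum identity for a hit to qualify.
#' @param matrix,gap_penalty Passed to [align_marker()].
#' @return A `marker_recovery_report`: list with `status` (data frame:
#'   `marker_id`, `status`, `best_protein`, `coverage`, `identity`),
#'   `counts` (named: complete, duplicated, fragmented, missing) and
#'   `completeness_pct`.
#' @export
assess_completeness <- function(markers, proteome, cov_complete = 0.9,
                                cov_fragment = 0.3, id_min = 0.4,
                                matrix = "BLOSUM62", gap_penalty = 8) {
  markers <- .as_peptides(markers)
  proteome <- .as_peptides(proteome)
  if (nrow(markers) == 0L) stop("empty marker set")
  stopifnot(0 < cov_fragment, cov_fragment < cov_complete, cov_complete <= 1)
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    mk <- markers$peptide[i]
    best <- NULL
    n_full <- 0L
    if (nrow(proteome) > 0L) {
      for (j in seq_len(nrow(proteome))) {
        a <- align_marker(mk, proteome$peptide[j], matrix, gap_penalty)
        if (a$identity < id_min) next
        if (a$marker_coverage >= cov_complete) n_full <- n_full + 1L
        if (is.null(best) || a$score > best$score) {
          best <- c(a, list(id = proteome$id[j]))
        }
      }
    }
    status <- if (n_full > 1L) "duplicated"
      else if (n_full == 1L) "complete"
      else if (!is.null(best) && best$marker_coverage >= cov_fragment)
        "fragmented"
      else "missing"
    data.frame(marker_id = markers$id[i], status = status,
               best_protein = if (is.null(best)) "" else best$id,
               coverage = if (is.null(best)) 0 else best$marker_coverage,
               identity = if (is.null(best)) 0 else best$identity,
               stringsAsFactors = FALSE)
  })
  status <- do.call(rbind, rows)
  counts <- vapply(c("complete", "duplicated", "fragmented", "missing"),
                   function(s) sum(status$status == s), integer(1))
  structure(list(status = status, counts = counts,
                 completeness_pct = 100 * counts[["complete"]] / nrow(markers)),
            class = "marker_recovery_report")
}

.as_peptides <- function(d) {
  if ("residues" %in% names(d) && !("peptide" %in% names(d))) {
    d$peptide <- d$residues
  }
  stopifnot(all(c("id", "peptide") %in% names(d)))
  d
}

#' @export
print.marker_recovery_report <- function(x, ...) {
  cat("marker_recovery_report: C:", x$counts[["complete"]],
      " D:", x$counts[["duplicated"]], " F:", x$counts[["fragmented"]],
      " M:", x$counts[["missing"]],
      sprintf("  completeness %.1f%%\n", x$completeness_pct))
  invisible(x)
}
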