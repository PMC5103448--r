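# package-level cache for the default profile and its calibrated threshold
.pkg_cache <- new.env(parent = emptyenv())

#' Build a 60-column homeodomain scoring profile
#'
#' Position-specific log-odds scores in bits from an alignment of
#' homeodomains: `score(col, aa) = log2(((count + pc) / (N_col + 20 pc))
#' / q_aa)` with Laplace pseudocount `pc` and background frequency
#' `q_aa`. A sequence with a gap in a column is excluded from that
#' column's counts (per-column denominator). Columns gapped in every
#' sequence are removed; the result must be exactly 60 columns wide.
#'
#' @param aligned Character vector of aligned sequences (gaps `-`), or a
#'   sequence record data frame.
#' @param pseudocount Laplace pseudocount (default 1).
#' @param background Named numeric vector of background frequencies over
#'   the 20 residues; default uniform (0.05).
#' @return An `hd_profile` object (20 x 60 score matrix in bits).
#' @export
build_profile <- function(aligned, pseudocount = 1,
                          background = NULL) {
  if (is.data.frame(aligned)) aligned <- aligned$residues
  if (!length(aligned)) stop("empty alignment")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), .AA20)
  }
  stopifnot(all(.AA20 %in% names(background)))
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  if (!all(apply(mat, 1, length) == ncol(mat))) stop("ragged alignment")
  all_gap <- apply(mat, 2, function(col) all(col == "-"))
  mat <- mat[, !all_gap, drop = FALSE]
  if (ncol(mat) != 60L) {
    stop("homeodomain alignment must be 60 columns wide after gap-column ",
         "removal; got ", ncol(mat))
  }
  scores <- matrix(0, nrow = 20L, ncol = 60L,
                   dimnames = list(.AA20, NULL))
  for (j in seq_len(60L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    n_j <- length(col)
    counts <- table(factor(col, levels = .AA20))
    p <- (as.numeric(counts) + pseudocount) / (n_j + 20 * pseudocount)
    scores[, j] <- log2(p / background[.AA20])
  }
  structure(list(scores = scores, pseudocount = pseudocount,
                 background = background[.AA20], n_sequences = nrow(mat)),
            class = "hd_profile")
}

#' @export
print.hd_profile <- function(x, ...) {
  cat("hd_profile: 60 columns, trained on", x$n_sequences,
      "sequences, pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Scan a protein for homeodomain windows
#'
#' Slides the 60-column profile over the peptide; every window scoring at
#' or above the threshold is reported, best-first (ties by start).
#' Residues outside the 20-letter alphabet (X) contribute 0 bits.
#'
#' @param protein Amino-acid string.
#' @param profile An `hd_profile`.
#' @param threshold_bits Minimum window score in bits.
#' @param protein_id Identifier carried into the output.
#' @return Data frame with `protein_id`, `hd_start` (0-based window
#'   offset), `score` (bits). Proteins shorter than 60 residues give an
#'   empty result with a warning.
#' @export
scan_homeodomains <- function(protein, profile, threshold_bits,
                              protein_id = "protein") {
  stopifnot(inherits(profile, "hd_profile"))
  empty <- data.frame(protein_id = character(), hd_start = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  n <- nchar(protein)
  if (n < 60L) {
    warning("protein '", protein_id, "' shorter than 60 residues; no scan")
    return(empty)
  }
  scores <- window_scores(protein, profile)
  hit <- which(scores >= threshold_bits)
  if (!length(hit)) return(empty)
  df <- data.frame(protein_id = protein_id, hd_start = hit - 1L,
                   score = scores[hit], stringsAsFactors = FALSE)
  df[order(-df$score, df$hd_start), , drop = FALSE]
}

#' Per-window profile scores for a peptide
#'
#' @param protein Amino-acid string (length >= 60).
#' @param profile An `hd_profile`.
#' @return Numeric vector of window scores, one per 0-based offset.
#' @export
window_scores <- function(protein, profile) {
  chars <- strsplit(toupper(protein), "")[[1L]]
  idx <- match(chars, .AA20)              # NA for X etc. -> 0 bits
  nw <- length(chars) - 59L
  if (nw < 1L) return(numeric(0))
  total <- numeric(nw)
  for (k in seq_len(60L)) {
    s <- profile$scores[idx[seq_len(nw) + k - 1L], k]
    s[is.na(s)] <- 0
    total <- total + s
  }
  unname(total)
}

#' Calibrated default scan threshold
#'
#' The 99.9th percentile of the best window score over `n` random
#' peptides of length `len` at a fixed seed: at this threshold at least
#' 99 percent of unrelated peptides of that length produce no hit.
#'
#' @param profile An `hd_profile`.
#' @param n Number of null peptides (default 1000).
#' @param len Null peptide length (default 200).
#' @param seed Calibration seed (fixed default for reproducibility).
#' @param probs Percentile of the null maxima (default 0.999).
#' @return Threshold in bits.
#' @export
default_scan_threshold <- function(profile, n = 1000L, len = 200L,
                                   seed = 4242L, probs = 0.999) {
  maxima <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      max(window_scores(.random_aa(len), profile))
    }, numeric(1))
  })
  unname(stats::quantile(maxima, probs = probs, type = 7))
}

#' The packaged default homeodomain profile
#'
#' Built from the shipped synthetic consensus alignment; memoized
#' together with its calibrated threshold.
#'
#' @return An `hd_profile` with attribute `"threshold_bits"`.
#' @export
default_profile <- function() {
  if (is.null(.pkg_cache$profile)) {
    prof <- build_profile(unname(hd_consensus_set()))
    attr(prof, "threshold_bits") <- default_scan_threshold(prof)
    .pkg_cache$profile <- prof
  }
  .pkg_cache$profile
}
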