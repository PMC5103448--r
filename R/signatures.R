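#' Call per-column diagnostic signature residues from a labeled alignment
#'
#' A column is diagnostic for a label with residue `a` iff the
#' gap-excluded frequency of `a` within the label is at least `tau_in`
#' and the frequency of `a` within every other label is at most
#' `tau_out`. Columns with more than 50 percent gaps in a label, or
#' fewer than 2 ungapped residues for it, are uncallable for that label.
#'
#' @param sequences Aligned sequences (character vector or sequence
#'   records; gaps `-`), all the same width.
#' @param labels Label per sequence (same order/length).
#' @param tau_in In-group frequency threshold, `0.5 < tau_in <= 1`.
#' @param tau_out Out-group frequency ceiling, `0 <= tau_out < 0.5`.
#' @return Data frame of calls: `column` (1-based alignment column),
#'   `label`, `residue`, `freq_in`, `max_freq_out`.
#' @export
column_signatures <- function(sequences, labels, tau_in = 0.9,
                              tau_out = 0.1) {
  if (is.data.frame(sequences)) sequences <- sequences$residues
  stopifnot(length(sequences) == length(labels))
  if (!(tau_in > 0.5 && tau_in <= 1)) stop("tau_in must lie in (0.5, 1]")
  if (!(tau_out >= 0 && tau_out < 0.5)) stop("tau_out must lie in [0, 0.5)")
  if (length(unique(labels)) < 2L) stop("need at least 2 labels")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  if (length(unique(nchar(sequences))) != 1L) stop("ragged alignment")
  ncol_aln <- ncol(mat)
  labs <- unique(labels)
  calls <- list()
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    for (g in labs) {
      in_res <- col[labels == g]
      in_ungapped <- in_res[in_res != "-"]
      if (length(in_ungapped) < 2L) next                    # uncallable
      if (mean(in_res == "-") > 0.5) next                   # gap-majority
      tab <- table(in_ungapped)
      a <- names(tab)[which.max(tab)]
      if (a == "X") next
      f_in <- tab[[a]] / length(in_ungapped)
      if (f_in < tau_in) next
      f_out <- vapply(setdiff(labs, g), function(h) {
        out_res <- col[labels == h]
        out_ungapped <- out_res[out_res != "-"]
        sum(out_ungapped == a) / max(1L, length(out_ungapped))
      }, numeric(1))
      if (all(f_out <= tau_out)) {
        calls[[length(calls) + 1L]] <- data.frame(
          column = j, label = g, residue = a, freq_in = f_in,
          max_freq_out = if (length(f_out)) max(f_out) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(column = integer(), label = character(),
                      residue = character(), freq_in = numeric(),
                      max_freq_out = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, calls)
  df[order(df$label, df$column), , drop = FALSE]
}

#' Merge adjacent signature calls into motif features
#'
#' Maximal runs of adjacent diagnostic columns for the same label merge
#' into one exact-pattern feature; singleton calls become length-1
#' features. Positions are reported in the alignment's coordinate frame,
#' which equals the canonical homeodomain frame 1-60 when the alignment
#' is homeodomain-anchored.
#'
#' @param calls Data frame from [column_signatures()].
#' @return Data frame of features: `label`, `start`, `end` (1-based
#'   inclusive columns), `pattern`.
#' @export
merge_motifs <- function(calls) {
  empty <- data.frame(label = character(), start = integer(),
                      end = integer(), pattern = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  out <- list()
  for (g in unique(calls$label)) {
    d <- calls[calls$label == g, , drop = FALSE]
    d <- d[order(d$column), , drop = FALSE]
    run_id <- cumsum(c(1L, diff(d$column) != 1L))
    for (r in split(d, run_id)) {
      out[[length(out) + 1L]] <- data.frame(
        label = g, start = min(r$column), end = max(r$column),
        pattern = paste(r$residue, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$label, df$start), , drop = FALSE]
}

#' Discover diagnostic features from a labeled alignment
#'
#' Runs [column_signatures()] and [merge_motifs()] and additionally
#' renders the merged motifs as catalog-format `HD_POS` feature
#' descriptors (weight 1), so that discovered signatures can fill the
#' default catalog's placeholder slots.
#'
#' @inheritParams column_signatures
#' @param scope Scope tag attached to emitted features.
#' @return List with `calls`, `motifs` (data frames) and `features`
#'   (list of validated catalog feature descriptors, usable in a
#'   `motif_catalog` group).
#' @export
discover_signatures <- function(sequences, labels, tau_in = 0.9,
                                tau_out = 0.1, scope = "lophotrochozoan") {
  calls <- column_signatures(sequences, labels, tau_in, tau_out)
  motifs <- merge_motifs(calls)
  features <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- motifs[i, ]
    .validate_feature(list(
      id = sprintf("%s_disc_%d_%d", tolower(m$label), m$start, m$end),
      region = "HD_POS", positions = as.list(m$start:m$end),
      pattern = m$pattern, weight = 1.0, scope = scope),
      group = m$label)
  })
  names(features) <- vapply(features, `[[`, character(1), "id")
  list(calls = calls, motifs = motifs, features = features)
}
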