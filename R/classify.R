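#' Classifier parameters
#'
#' @param min_score Minimum winning score for an assignment (> 0).
#' @param min_margin Minimum lead over the runner-up group's score.
#' @param threshold_bits Homeodomain scan threshold; `NULL` uses the
#'   profile's calibrated default.
#' @param n_window Width (aa) of the N-flank search window upstream of
#'   homeodomain position 1.
#' @param c_window Width (aa) of the C-flank search window downstream of
#'   position 60.
#' @return List of parameters.
#' @export
classifier_params <- function(min_score = 1, min_margin = 0,
                              threshold_bits = NULL,
                              n_window = 60L, c_window = 30L) {
  stopifnot(min_score > 0, min_margin >= 0)
  list(min_score = min_score, min_margin = min_margin,
       threshold_bits = threshold_bits,
       n_window = as.integer(n_window), c_window = as.integer(c_window))
}

# HD position (1-60) -> 0-based aa offset
.hd_to_aa <- function(hd_start, pos) hd_start + pos - 1L

#' Match one diagnostic feature against a peptide
#'
#' `HD_POS` features test residues at the mapped homeodomain positions
#' (exact pattern or residue-set predicate). `C_FLANK`/`N_FLANK`
#' features with an `offset` test at that exact flank offset; windowed
#' flank features slide the pattern over the window and report the first
#' (leftmost) match. `X` never matches. A feature whose span extends
#' past the peptide is a no-match, not an error.
#'
#' @param peptide Amino-acid string.
#' @param hd_start 0-based homeodomain offset (from the scan).
#' @param feature A catalog feature descriptor.
#' @param params See [classifier_params()].
#' @return `NULL` on no-match, else a list with `feature_id`, `start_aa`,
#'   `end_aa` (0-based half-open) and `residues`.
#' @export
match_feature <- function(peptide, hd_start, feature,
                          params = classifier_params()) {
  if (feature$placeholder) return(NULL)
  chars <- strsplit(peptide, "")[[1L]]
  n <- length(chars)
  at <- function(i) if (i >= 1L && i <= n) chars[i] else NA_character_

  if (feature$region == "HD_POS") {
    idx <- .hd_to_aa(hd_start, feature$positions) + 1L  # 1-based
    res <- vapply(idx, at, character(1))
    if (anyNA(res)) return(NULL)
    if (!is.null(feature$predicate)) {
      pfun <- .PREDICATES[[feature$predicate]]
      fl <- at(min(idx) - 1L)
      fr <- at(max(idx) + 1L)
      if (!isTRUE(pfun(res, fl, fr))) return(NULL)
    } else {
      if (any(res == "X")) return(NULL)
      if (paste(res, collapse = "") != feature$pattern) return(NULL)
    }
    return(list(feature_id = feature$id, start_aa = min(idx) - 1L,
                end_aa = max(idx), residues = paste(res, collapse = "")))
  }

  pat <- feature$pattern
  L <- nchar(pat)
  if (feature$region == "N_FLANK") {
    if (!is.null(feature$offset)) {
      starts <- hd_start + feature$offset + 1L       # 1-based first residue
      starts <- starts[starts >= 1L & (starts + L - 1L) <= hd_start]
    } else {
      win_lo <- max(1L, hd_start - params$n_window + 1L)
      win_hi <- hd_start                             # last residue before HD
      starts <- if (win_hi - L + 1L >= win_lo) win_lo:(win_hi - L + 1L)
                else integer(0)
    }
  } else {  # C_FLANK
    flank0 <- hd_start + 60L                         # 0-based first flank pos
    if (!is.null(feature$offset)) {
      starts <- flank0 + feature$offset              # 1-based: flank0+off-1+1
      starts <- starts[(starts + L - 1L) <= n]
    } else {
      win_lo <- flank0 + 1L
      win_hi <- min(n, flank0 + params$c_window)
      starts <- if (win_hi - L + 1L >= win_lo) win_lo:(win_hi - L + 1L)
                else integer(0)
    }
  }
  for (s in starts) {
    sub <- substr(peptide, s, s + L - 1L)
    if (!grepl("X", sub, fixed = TRUE) && sub == pat) {
      return(list(feature_id = feature$id, start_aa = s - 1L,
                  end_aa = s - 1L + L, residues = sub))
    }
  }
  NULL
}

#' Classify a homeodomain-bearing peptide into a paralog group
#'
#' Locates the homeodomain with the profile scan (best hit), then scores
#' every catalog group as the summed weight of its matched
#' non-placeholder features (a missing required feature zeroes the
#' group). The winner is the argmax provided it reaches `min_score` and
#' leads the runner-up by `min_margin`; exact score ties are broken in
#' favour of the group with the larger fraction of its scoring features
#' matched, and remaining ties (or sub-threshold scores) yield
#' `AMBIGUOUS` with the tied candidate set. A peptide without a
#' homeodomain hit, or matching no feature at all, is `UNCLASSIFIED`.
#'
#' @param peptide Amino-acid string.
#' @param profile An `hd_profile` (default: packaged profile).
#' @param catalog A `motif_catalog` (default: packaged catalog).
#' @param params See [classifier_params()].
#' @param protein_id Identifier carried into the result.
#' @return A `classification_result` list: `protein_id`, `status`
#'   (`assigned` / `AMBIGUOUS` / `UNCLASSIFIED`), `label` (NA unless
#'   assigned), `candidates`, `scores` (named numeric), `matched`
#'   (data frame of matched features with 0-based coordinates),
#'   `hd_start`, `hd_score`, and `unassignable_groups` (labels with no
#'   scoring feature, e.g. all-placeholder groups).
#' @export
classify <- function(peptide, profile = default_profile(),
                     catalog = default_catalog(),
                     params = classifier_params(),
                     protein_id = "protein") {
  thr <- params$threshold_bits
  if (is.null(thr)) thr <- attr(profile, "threshold_bits")
  if (is.null(thr)) thr <- default_scan_threshold(profile)
  labels <- catalog_labels(catalog)
  unassignable <- labels[vapply(labels, function(g)
    length(scoring_features(catalog, g)) == 0L, logical(1))]
  base <- list(protein_id = protein_id, status = "UNCLASSIFIED",
               label = NA_character_, candidates = character(0),
               scores = stats::setNames(numeric(length(labels)), labels),
               matched = data.frame(group = character(),
                                    feature_id = character(),
                                    start_aa = integer(), end_aa = integer(),
                                    residues = character(),
                                    stringsAsFactors = FALSE),
               hd_start = NA_integer_, hd_score = NA_real_,
               unassignable_groups = unassignable)
  class(base) <- "classification_result"
  hits <- suppressWarnings(
    scan_homeodomains(peptide, profile, threshold_bits = thr,
                      protein_id = protein_id))
  if (nrow(hits) == 0L) return(base)
  hd_start <- hits$hd_start[1L]
  base$hd_start <- hd_start
  base$hd_score <- hits$score[1L]

  scores <- stats::setNames(numeric(length(labels)), labels)
  frac <- stats::setNames(numeric(length(labels)), labels)
  matched_rows <- list()
  for (g in labels) {
    feats <- scoring_features(catalog, g)
    if (!length(feats)) next
    s <- 0; nm <- 0L; required_missing <- FALSE
    for (f in feats) {
      m <- match_feature(peptide, hd_start, f, params)
      if (is.null(m)) {
        if (f$required) required_missing <- TRUE
      } else {
        s <- s + f$weight
        nm <- nm + 1L
        matched_rows[[length(matched_rows) + 1L]] <- data.frame(
          group = g, feature_id = m$feature_id, start_aa = m$start_aa,
          end_aa = m$end_aa, residues = m$residues, stringsAsFactors = FALSE)
      }
    }
    scores[g] <- if (required_missing) 0 else s
    frac[g] <- nm / length(feats)
  }
  base$scores <- scores
  if (length(matched_rows)) base$matched <- do.call(rbind, matched_rows)
  best <- max(scores)
  if (best <= 0) return(base)  # nothing matched -> UNCLASSIFIED
  top <- labels[scores == best]
  runner_up <- if (length(top) > 1L) best else max(scores[scores < best], 0)
  if (best < params$min_score || (best - runner_up) < params$min_margin) {
    base$status <- "AMBIGUOUS"
    base$candidates <- top
    return(base)
  }
  if (length(top) > 1L) {
    # tie-break: the group whose scoring feature set is most fully matched
    tf <- frac[top]
    top <- top[tf == max(tf)]
  }
  if (length(top) == 1L) {
    base$status <- "assigned"
    base$label <- top
    base$candidates <- top
  } else {
    base$status <- "AMBIGUOUS"
    base$candidates <- top
  }
  base
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result:", x$protein_id, "->", x$status)
  if (x$status == "assigned") cat(" [", x$label, "]", sep = "")
  if (x$status == "AMBIGUOUS") {
    cat(" {", paste(x$candidates, collapse = ", "), "}", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Classify a set of proteins
#'
#' @param proteins Data frame with `id` and `peptide` (or `residues`).
#' @inheritParams classify
#' @return Data frame: `protein_id`, `status`, `label`, `candidates`
#'   (comma-joined), `score`, `hd_start`, `hd_score`,
#'   `matched_features` (comma-joined feature ids).
#' @export
classify_set <- function(proteins, profile = default_profile(),
                         catalog = default_catalog(),
                         params = classifier_params()) {
  if ("residues" %in% names(proteins) && !("peptide" %in% names(proteins))) {
    proteins$peptide <- proteins$residues
  }
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    r <- classify(proteins$peptide[i], profile, catalog, params,
                  protein_id = proteins$id[i])
    own <- r$matched[r$matched$group %in% r$label, , drop = FALSE]
    data.frame(protein_id = r$protein_id, status = r$status,
               label = ifelse(is.na(r$label), "", r$label),
               candidates = paste(r$candidates, collapse = ","),
               score = if (all(r$scores == 0)) 0 else max(r$scores),
               hd_start = r$hd_start, hd_score = r$hd_score,
               matched_features = paste(own$feature_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
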