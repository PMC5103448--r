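#' Pairwise identity between two peptides
#'
#' Identity is the number of matches (identities) on the optimal global
#' alignment divided by the number of alignment columns, gap columns
#' included. The alignment scores match 1, mismatch 0, and each gap
#' column a unit penalty (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()]).
#'
#' @param a,b Non-empty peptide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  letters <- unique(c(.AA20, "X", strsplit(paste0(a, b), "")[[1L]]))
  sm <- diag(1, length(letters))
  dimnames(sm) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  structure(Biostrings::nmatch(aln) / cols,
            matches = Biostrings::nmatch(aln), columns = cols,
            score = Biostrings::score(aln))
}

#' Cluster proteins at 100 percent identity
#'
#' `exact` mode merges string-equal peptides. `containment` mode
#' additionally merges a peptide that is a contiguous substring of a
#' longer member (identity 1.0 over its aligned columns). The
#' representative of a cluster is its longest member, ties broken by
#' lexicographically smallest id.
#'
#' @param proteins Data frame with columns `id` and `peptide` (or
#'   sequence records with `residues`).
#' @param mode `"exact"` (default) or `"containment"`.
#' @return List with `clusters` (data frame: `representative_id`,
#'   `member_id`) and `representatives` (the input rows of the
#'   representatives).
#' @export
cluster_exact <- function(proteins, mode = c("exact", "containment")) {
  mode <- match.arg(mode)
  if ("residues" %in% names(proteins) && !("peptide" %in% names(proteins))) {
    proteins$peptide <- proteins$residues
  }
  stopifnot(all(c("id", "peptide") %in% names(proteins)))
  n <- nrow(proteins)
  if (n == 0L) {
    return(list(clusters = data.frame(representative_id = character(),
                                      member_id = character(),
                                      stringsAsFactors = FALSE),
                representatives = proteins))
  }
  # union-find over input rows
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  # exact merges via hashing on the peptide string
  groups <- split(seq_len(n), proteins$peptide)
  for (g in groups) if (length(g) > 1L) for (j in g[-1L]) union_(g[1L], j)
  if (mode == "containment") {
    reps <- vapply(groups, `[[`, integer(1), 1L)
    peps <- proteins$peptide[reps]
    ord <- order(nchar(peps))
    for (ii in seq_along(ord)) {
      for (jj in seq_along(ord)) {
        if (ii == jj) next
        short <- ord[ii]; long <- ord[jj]
        if (nchar(peps[short]) < nchar(peps[long]) &&
            grepl(peps[short], peps[long], fixed = TRUE)) {
          union_(reps[short], reps[long])
          break
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  members <- split(seq_len(n), root)
  rows <- lapply(members, function(idx) {
    lens <- nchar(proteins$peptide[idx])
    ids <- proteins$id[idx]
    rep_id <- ids[order(-lens, ids)][1L]
    data.frame(representative_id = rep_id, member_id = ids,
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows)
  clusters <- clusters[order(clusters$representative_id,
                             clusters$member_id), , drop = FALSE]
  rownames(clusters) <- NULL
  reps <- proteins[proteins$id %in% unique(clusters$representative_id), ,
                   drop = FALSE]
  rownames(reps) <- NULL
  list(clusters = clusters, representatives = reps)
}
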