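# Independent oracles and small fixture builders used across the suite.
# The oracles are deliberately brute-force and share no code with the
# implementation paths they check.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_nt <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
random_aa <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# -- six-frame ORF oracle ------------------------------------------------
# Tests every (frame, ATG, first-stop) triple directly on codon strings,
# then keeps the longest ORF per (frame, stop).
oracle_codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  a <- gc[codon]
  ifelse(is.na(a), "X", unname(a))
}

oracle_orfs <- function(nt, min_len = 50L) {
  L <- nchar(nt)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  hits <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) nt else rc
    for (off in 0:2) {
      n_cod <- (nchar(s) - off) %/% 3L
      if (n_cod < 1L) next
      pos <- off + 1L + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(s, pos, pos + 2L)
      aas <- oracle_codon_aa(codons)
      atg <- which(codons == "ATG")
      stop_idx <- which(aas == "*")
      for (m in atg) {
        st <- stop_idx[stop_idx > m]
        if (!length(st)) next
        st <- st[1L]
        len <- st - m
        if (len <= min_len) next
        nt_s <- off + 3L * (m - 1L)
        nt_e <- off + 3L * st
        if (strand == -1L) { tmp <- nt_s; nt_s <- L - nt_e; nt_e <- L - tmp }
        hits[[length(hits) + 1L]] <- data.frame(
          frame = strand * (off + 1L), nt_start = nt_s, nt_end = nt_e,
          peptide = paste(aas[m:(st - 1L)], collapse = ""),
          aa_length = len, stop_key = paste(strand, off, st),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer(), peptide = character(),
                      aa_length = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  # longest ORF per stop within a frame
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$stop_key), function(idx) {
    idx[which.max(df$aa_length[idx])]
  }))
  df <- df[keep, c("frame", "nt_start", "nt_end", "peptide", "aa_length")]
  df[order(match(df$frame, c(1, 2, 3, -1, -2, -3)), df$nt_start), ]
}

# -- global alignment oracle (match 1 / mismatch 0 / unit gap) -----------
oracle_global_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -(0:n); D[1, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- max(D[i, j] + (x[i] == y[j]),
                           D[i, j + 1] - 1, D[i + 1, j] - 1)
  }
  D[n + 1, m + 1]
}

# -- Smith-Waterman oracle (substitution matrix, linear gap) -------------
oracle_local_score <- function(a, b, sm, gap = 8) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    H[i + 1, j + 1] <- max(0, H[i, j] + sm[x[i], y[j]],
                           H[i, j + 1] - gap, H[i + 1, j] - gap)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# -- per-column signature oracle -----------------------------------------
oracle_signatures <- function(seqs, labels, tau_in, tau_out) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  labs <- unique(labels)
  out <- list()
  for (j in seq_len(ncol(mat))) for (g in labs) {
    v <- mat[labels == g, j]
    u <- v[v != "-"]
    if (length(u) < 2 || mean(v == "-") > 0.5) next
    for (a in setdiff(unique(u), "X")) {
      if (sum(u == a) / length(u) < tau_in) next
      ok <- TRUE
      for (h in setdiff(labs, g)) {
        w <- mat[labels == h, j]; w <- w[w != "-"]
        if (sum(w == a) / max(1, length(w)) > tau_out) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <- data.frame(
        column = j, label = g, residue = a, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(column = integer(), label = character(),
                                      residue = character()))
  df <- do.call(rbind, out)
  df[order(df$label, df$column), ]
}

# -- misc fixtures -------------------------------------------------------
default_mix <- function(n_each = 1L) {
  stats::setNames(rep(n_each, 14L), catalog_labels(default_catalog()))
}

# labels whose printed (non-placeholder) features separate them from every
# other group in the default catalog
SEPARABLE_LABELS <- c("Hox1", "Hox2", "Hox3", "Hox4", "Hox5", "Gsx")

# embed a peptide in a forward-strand transcript with an in-frame stop
# guard before the ATG, using seeded random UTRs
embed_cds <- function(peptide, seed = 1, utr = 60L) {
  rt <- reverse_translate(peptide, seed = seed)
  withr::with_seed(seed + 1L, {
    u5 <- random_nt(utr); u3 <- random_nt(utr)
  })
  substr(u5, utr - 2L, utr) <- "TAA"
  list(transcript = paste0(u5, rt$cds, u3),
       cds_start = utr, cds_end = utr + nchar(rt$cds))
}
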