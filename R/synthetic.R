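.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")
.random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# deterministic per-item sub-seed, kept inside 32-bit range
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Describe a synthetic transcriptome
#'
#' Collects the knobs of the generator: how many transcripts of which
#' paralog group to plant, and the rates of the assembly artifacts the
#' pipeline must tolerate (decoy transcripts without a true CDS, exact
#' peptide duplicates, homeodomain substitution noise, homopolymer-style
#' single-nucleotide frameshifts).
#'
#' @param group_mix Named integer vector, catalog label -> planted count.
#' @param decoy_rate,duplicate_rate,hd_mut_rate,frameshift_rate Rates in
#'   `[0, 1]`. Decoy and duplicate rates are fractions of the total
#'   transcript count; `hd_mut_rate` is the per-position substitution rate
#'   inside the homeodomain (catalog-diagnostic positions are never
#'   mutated); `frameshift_rate` is the per-transcript probability of
#'   carrying 1-3 single-nucleotide indels in its CDS.
#' @param utr_len_range Length range (nt) for each UTR, default 30-150.
#' @param n_transcripts Total transcripts; defaults to
#'   `round(sum(group_mix) / (1 - decoy_rate - duplicate_rate))` so that
#'   the planted counts are honoured exactly when both rates are 0.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, catalog).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(group_mix, decoy_rate = 0, duplicate_rate = 0,
                           hd_mut_rate = 0, frameshift_rate = 0,
                           utr_len_range = c(30L, 150L),
                           n_transcripts = NULL, seed = 1L) {
  rates <- c(decoy_rate, duplicate_rate, hd_mut_rate, frameshift_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (length(group_mix) && (is.null(names(group_mix)) || any(!nzchar(names(group_mix))))) {
    stop("group_mix must be a named vector (label -> count)")
  }
  if (any(group_mix < 0)) stop("group_mix counts must be non-negative")
  if (is.null(n_transcripts)) {
    if (decoy_rate + duplicate_rate >= 1) {
      stop("give n_transcripts explicitly when decoy_rate + duplicate_rate >= 1")
    }
    n_transcripts <- round(sum(group_mix) / (1 - decoy_rate - duplicate_rate))
  }
  structure(list(group_mix = group_mix, decoy_rate = decoy_rate,
                 duplicate_rate = duplicate_rate, hd_mut_rate = hd_mut_rate,
                 frameshift_rate = frameshift_rate,
                 utr_len_range = as.integer(utr_len_range),
                 n_transcripts = as.integer(n_transcripts),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# HD positions that must never be mutated for a group: every position a
# catalog feature of that group touches (placeholders included: the
# consensus carries their planted residues), plus the bracketing
# positions of flanked_by_basic predicates.
.protected_positions <- function(catalog, group) {
  g <- catalog$groups[[group]]
  pos <- integer()
  for (f in g$features) {
    if (f$region != "HD_POS") next
    pos <- c(pos, f$positions)
    if (!is.null(f$predicate) && f$predicate == "flanked_by_basic") {
      pos <- c(pos, f$positions - 1L, f$positions + 1L)
    }
  }
  sort(unique(pos[pos >= 1L & pos <= 60L]))
}

#' Generate one synthetic homeobox protein for a paralog group
#'
#' The peptide is `M` + random N-flank + the group's consensus
#' homeodomain (per-position substitution at `spec$hd_mut_rate`, never at
#' catalog-diagnostic positions) + random C-flank, with every
#' non-placeholder catalog feature of the group inserted at its declared
#' region/offset (windowed flank motifs at a random in-window position).
#'
#' @param group Catalog label.
#' @param catalog A `motif_catalog`.
#' @param spec A `generator_spec`.
#' @param seed Integer seed (byte-identical output for identical inputs).
#' @return List with `peptide`, `hd_start_aa` (0-based), and
#'   `planted_features` (data frame: feature id, 0-based aa start).
#' @export
generate_protein <- function(group, catalog, spec, seed) {
  g <- catalog$groups[[group]]
  if (is.null(g)) stop("unknown catalog group: ", group)
  consensus <- hd_consensus_set()[[group]]
  if (is.null(consensus)) stop("no consensus homeodomain for group ", group)
  feats <- scoring_features(catalog, group)
  # conflicting exact-offset features (same region, overlapping span)
  anchored <- Filter(function(f) f$region != "HD_POS" && !is.null(f$offset), feats)
  if (length(anchored) > 1L) {
    spans <- lapply(anchored, function(f) f$offset + seq_len(nchar(f$pattern)) - 1L)
    for (i in seq_along(spans)) for (j in seq_len(i - 1L)) {
      if (length(intersect(spans[[i]], spans[[j]]))) {
        stop("group '", group, "': conflicting exact-offset features '",
             anchored[[i]]$id, "' and '", anchored[[j]]$id, "'")
      }
    }
  }
  withr::with_seed(seed, {
    n_len <- sample(15:40, 1L)
    c_len <- sample(12:30, 1L)
    n_flank <- strsplit(paste0("M", .random_aa(n_len - 1L)), "")[[1L]]
    c_flank <- strsplit(.random_aa(c_len), "")[[1L]]
    hd <- strsplit(consensus, "")[[1L]]
    protected <- .protected_positions(catalog, group)
    if (spec$hd_mut_rate > 0) {
      mutable <- setdiff(seq_len(60L), protected)
      hit <- mutable[stats::runif(length(mutable)) < spec$hd_mut_rate]
      for (p in hit) hd[p] <- sample(setdiff(.AA20, hd[p]), 1L)
    }
    planted <- list()
    for (f in feats) {
      if (f$region == "HD_POS") next  # carried by the consensus itself
      pat <- strsplit(f$pattern, "")[[1L]]
      L <- length(pat)
      if (f$region == "N_FLANK") {
        if (!is.null(f$offset)) {
          # offset is the (negative) position of the pattern's first residue
          start <- n_len + f$offset + 1L
        } else {
          # keep position 1 (the initial M) untouched
          start <- sample(2:(n_len - L + 1L), 1L)
        }
        n_flank[start:(start + L - 1L)] <- pat
        planted[[f$id]] <- start - 1L
      } else {
        if (!is.null(f$offset)) {
          start <- f$offset
        } else {
          start <- sample(seq_len(min(30L, c_len) - L + 1L), 1L)
        }
        c_flank[start:(start + L - 1L)] <- pat
        planted[[f$id]] <- n_len + 60L + start - 1L
      }
    }
    peptide <- paste(c(n_flank, hd, c_flank), collapse = "")
    list(peptide = peptide, hd_start_aa = n_len,
         planted_features = data.frame(
           feature_id = names(planted),
           aa_start = if (length(planted)) unlist(planted, use.names = FALSE)
                      else integer(),
           stringsAsFactors = FALSE))
  })
}

#' Reverse-translate a peptide into a coding sequence
#'
#' Standard genetic code; codon choice uniform among synonyms, seeded.
#' The CDS begins with ATG (an `M` is prepended, and reported, when the
#' peptide does not start with one) and ends with a single stop codon.
#'
#' @param peptide Amino-acid string over the 20 standard residues.
#' @param seed Integer seed.
#' @return List with `cds` (nt string) and `m_prepended` (logical).
#' @export
reverse_translate <- function(peptide, seed) {
  aa <- strsplit(peptide, "")[[1L]]
  if (!length(aa)) stop("empty peptide")
  if (any(!(aa %in% .AA20))) {
    stop("peptide contains a residue outside the 20-letter alphabet")
  }
  m_prepended <- aa[1L] != "M"
  if (m_prepended) aa <- c("M", aa)
  syn <- .codons_by_aa()
  withr::with_seed(seed, {
    codons <- vapply(aa, function(a) {
      cs <- syn[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    stop_codon <- sample(.STOP_CODONS, 1L)
  })
  list(cds = paste(c(codons, stop_codon), collapse = ""),
       m_prepended = m_prepended)
}

# translation used by truth-table checks: slice [cds_start, cds_end) of the
# forward strand, reverse-complemented first for negative frames
truth_translate <- function(transcript, cds_start, cds_end, frame) {
  slice <- substr(transcript, cds_start + 1L, cds_end)
  if (frame < 0) slice <- revcomp(slice)
  sub("\\*$", "", translate_nt(slice))
}

#' Generate a synthetic transcriptome with a truth table
#'
#' Each non-decoy transcript is 5' UTR + CDS + 3' UTR on a uniformly
#' chosen strand; an in-frame stop is placed at the end of the 5' UTR so
#' the planted ORF is the maximal one in its frame. Decoys are random
#' nucleotide sequences rejection-sampled to contain no ATG-initiated ORF
#' longer than 50 aa. Duplicates are exact copies of an already-emitted
#' translated CDS peptide under a new transcript id (new codons, new
#' UTRs). Frameshifted transcripts carry recorded single-nt indels in
#' their CDS.
#'
#' @param spec A `generator_spec`.
#' @param catalog A `motif_catalog`.
#' @return List with `transcripts` (sequence record data frame) and
#'   `truth` (data frame: transcript_id, planted_group, cds_start,
#'   cds_end, frame, hd_start_aa, duplicate_of, frameshift_positions,
#'   peptide). Coordinates are 0-based half-open on the forward strand of
#'   the emitted transcript; `frameshift_positions` are 0-based within
#'   the CDS.
#' @export
generate_transcriptome <- function(spec, catalog) {
  stopifnot(inherits(spec, "generator_spec"), inherits(catalog, "motif_catalog"))
  unknown <- setdiff(names(spec$group_mix), catalog_labels(catalog))
  if (length(unknown)) stop("group_mix references unknown label: ", unknown[1L])

  n_total <- spec$n_transcripts
  n_decoy <- round(spec$decoy_rate * n_total)
  n_dup <- round(spec$duplicate_rate * n_total)
  n_plant <- max(0L, n_total - n_decoy - n_dup)
  mix <- spec$group_mix[spec$group_mix > 0]
  plant_labels <- rep(names(mix), times = mix)
  if (n_plant > 0 && !length(plant_labels)) {
    stop("group_mix is empty but planted transcripts were requested")
  }
  if (length(plant_labels)) {
    plant_labels <- rep_len(plant_labels, n_plant)
  } else {
    plant_labels <- character(0)
  }
  if (n_dup > 0 && n_plant == 0) {
    stop("duplicates requested but no planted transcripts to copy")
  }

  transcripts <- vector("list", n_total)
  truth <- vector("list", n_total)
  planted_peps <- character(0)   # id -> peptide
  planted_grp <- character(0)
  planted_hd <- integer(0)

  emit_cds_transcript <- function(i, id, group, peptide, hd_start_aa,
                                  duplicate_of) {
    s <- .sub_seed(spec$seed, 100000L + i)
    rt <- reverse_translate(peptide, seed = .sub_seed(spec$seed, 200000L + i))
    cds <- rt$cds
    withr::with_seed(s, {
      u5 <- sample(spec$utr_len_range[1L]:spec$utr_len_range[2L], 1L)
      u3 <- sample(spec$utr_len_range[1L]:spec$utr_len_range[2L], 1L)
      utr5 <- .random_nt(u5)
      utr3 <- .random_nt(u3)
      # in-frame stop guard so the planted ATG starts the maximal ORF
      if (u5 >= 3L) substr(utr5, u5 - 2L, u5) <- sample(.STOP_CODONS, 1L)
      fs_positions <- integer(0)
      if (spec$frameshift_rate > 0 && stats::runif(1L) < spec$frameshift_rate) {
        n_fs <- sample(1:3, 1L)
        fs_positions <- sort(sample(seq_len(nchar(cds) - 6L), n_fs)) + 2L
        for (p in rev(fs_positions)) {
          if (stats::runif(1L) < 0.5) {  # insertion
            cds <- paste0(substr(cds, 1L, p),
                          sample(c("A", "C", "G", "T"), 1L),
                          substr(cds, p + 1L, nchar(cds)))
          } else {                       # deletion
            cds <- paste0(substr(cds, 1L, p), substr(cds, p + 2L, nchar(cds)))
          }
        }
      }
      fwd <- paste0(utr5, cds, utr3)
      minus <- stats::runif(1L) < 0.5
    })
    L <- nchar(fwd)
    if (minus) {
      transcript <- revcomp(fwd)
      cds_start <- L - (u5 + nchar(cds))
      cds_end <- L - u5
      frame <- -((cds_start %% 3L) + 1L)
    } else {
      transcript <- fwd
      cds_start <- u5
      cds_end <- u5 + nchar(cds)
      frame <- (cds_start %% 3L) + 1L
    }
    transcripts[[i]] <<- c(id = id, residues = transcript)
    truth[[i]] <<- data.frame(
      transcript_id = id, planted_group = group,
      cds_start = cds_start, cds_end = cds_end, frame = frame,
      hd_start_aa = hd_start_aa,
      duplicate_of = duplicate_of,
      frameshift_positions = paste(fs_positions, collapse = ","),
      peptide = peptide, stringsAsFactors = FALSE)
  }

  i <- 0L
  for (k in seq_along(plant_labels)) {
    i <- i + 1L
    group <- plant_labels[k]
    id <- sprintf("tr%04d", i)
    prot <- generate_protein(group, catalog, spec,
                             seed = .sub_seed(spec$seed, i))
    emit_cds_transcript(i, id, group, prot$peptide, prot$hd_start_aa, "")
    planted_peps[id] <- prot$peptide
    planted_grp[id] <- group
    planted_hd[id] <- prot$hd_start_aa
  }
  for (k in seq_len(n_dup)) {
    i <- i + 1L
    id <- sprintf("tr%04d", i)
    src <- withr::with_seed(.sub_seed(spec$seed, 300000L + i),
                            sample(names(planted_peps), 1L))
    emit_cds_transcript(i, id, planted_grp[[src]], planted_peps[[src]],
                        planted_hd[[src]], src)
  }
  for (k in seq_len(n_decoy)) {
    i <- i + 1L
    id <- sprintf("tr%04d", i)
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      decoy <- withr::with_seed(
        .sub_seed(spec$seed, 400000L + 1000L * i + attempt), {
          .random_nt(sample(300:800, 1L))
        })
      if (nrow(enumerate_orfs(decoy, min_len_exclusive = 50L)) == 0L) break
      if (attempt > 200L) stop("decoy rejection sampling failed")
    }
    transcripts[[i]] <- c(id = id, residues = decoy)
    truth[[i]] <- data.frame(
      transcript_id = id, planted_group = "DECOY",
      cds_start = NA_integer_, cds_end = NA_integer_, frame = NA_integer_,
      hd_start_aa = NA_integer_, duplicate_of = "",
      frameshift_positions = "", peptide = "", stringsAsFactors = FALSE)
  }

  tr <- do.call(rbind, lapply(transcripts, function(x) {
    seq_records(x[["id"]], "synthetic transcript", x[["residues"]])
  }))
  list(transcripts = tr, truth = do.call(rbind, truth))
}

#' Generate a labeled homeodomain alignment
#'
#' Emits `n_per_group` aligned 60-column copies of each group's consensus
#' homeodomain, mutated per position at `mut_rate` outside
#' catalog-diagnostic positions, together with a label per sequence.
#' Input shape for [discover_signatures()].
#'
#' @param catalog A `motif_catalog`.
#' @param n_per_group Copies per label (>= 2 for columns to be callable).
#' @param mut_rate Per-position substitution rate outside diagnostic
#'   positions.
#' @param seed Integer seed.
#' @return List with `sequences` (sequence records, aligned, width 60)
#'   and `labels` (data frame: id, label).
#' @export
generate_labeled_msa <- function(catalog, n_per_group = 3L, mut_rate = 0,
                                 seed = 1L) {
  cons <- hd_consensus_set()
  labs <- catalog_labels(catalog)
  rows <- list()
  lab_rows <- list()
  for (g in labs) {
    protected <- .protected_positions(catalog, g)
    for (j in seq_len(n_per_group)) {
      s <- strsplit(cons[[g]], "")[[1L]]
      if (mut_rate > 0) {
        s <- withr::with_seed(
          .sub_seed(seed, 1000L * match(g, labs) + j), {
            mutable <- setdiff(seq_len(60L), protected)
            hit <- mutable[stats::runif(length(mutable)) < mut_rate]
            for (p in hit) s[p] <- sample(setdiff(.AA20, s[p]), 1L)
            s
          })
      }
      id <- sprintf("%s_%02d", g, j)
      rows[[id]] <- paste(s, collapse = "")
      lab_rows[[id]] <- g
    }
  }
  list(sequences = seq_records(names(rows), "", unlist(rows, use.names = FALSE)),
       labels = data.frame(id = names(lab_rows),
                           label = unlist(lab_rows, use.names = FALSE),
                           stringsAsFactors = FALSE))
}
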