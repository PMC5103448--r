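# Alphabet policy: nt files admit ACGTN; aa files admit the 20 standard
# residues plus X (unknown) and a single terminal '*'.
.NT_LETTERS <- c("A", "C", "G", "T", "N")
.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a FASTA file into a sequence record data frame
#'
#' Wraps [Biostrings::readBStringSet()] and enforces the package-wide
#' sequence contract: identifiers unique within a file, residues uppercased,
#' and every residue drawn from the declared alphabet (`"nt"`: ACGTN;
#' `"aa"`: the 20 standard amino acids plus `X`, with `*` permitted only as
#' a terminal stop).
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @return A data frame with columns `id`, `description`, `residues`,
#'   one row per record in file order. An empty file yields a zero-row
#'   data frame with a warning.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_records(character(), character(), character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  recs <- seq_records(ids, desc, residues)
  validate_seq_records(recs, alphabet, context = path)
  recs
}

#' Construct a sequence record data frame
#'
#' The in-memory carrier for sequences throughout the package: one row
#' per record with `id`, `description` and `residues`.
#'
#' @param id Character vector of identifiers.
#' @param description Character vector of free-text descriptions.
#' @param residues Character vector of sequences.
#' @return Data frame with the three columns, recycled to equal length.
#' @export
seq_records <- function(id, description, residues) {
  data.frame(id = as.character(id),
             description = as.character(description),
             residues = as.character(residues),
             stringsAsFactors = FALSE)
}

validate_seq_records <- function(records, alphabet, context = "records") {
  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1L]
    stop("duplicate sequence id '", dup, "' in ", context)
  }
  if (any(!nzchar(records$residues))) {
    stop("empty sequence for id '",
         records$id[!nzchar(records$residues)][1L], "' in ", context)
  }
  allowed <- if (alphabet == "nt") .NT_LETTERS else c(.AA_LETTERS, "X")
  for (i in seq_len(nrow(records))) {
    s <- records$residues[i]
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (alphabet == "aa" && length(chars) > 1L &&
        chars[length(chars)] == "*") {
      chars <- chars[-length(chars)]
    }
    bad <- which(!(chars %in% allowed))
    if (length(bad)) {
      stop("invalid ", alphabet, " residue '", chars[bad[1L]],
           "' at position ", bad[1L], " in sequence '", records$id[i],
           "' (", context, ")")
    }
  }
  invisible(records)
}

#' Write sequence records to FASTA
#'
#' Byte-deterministic for fixed input; sequence lines wrapped at `width`.
#'
#' @param records Data frame as returned by [read_fasta()] (columns `id`,
#'   `description`, `residues`).
#' @param path Output path.
#' @param width Line width for sequence wrapping (>= 1).
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(width >= 1L)
  if (nrow(records) == 0L) {
    warning("writing empty FASTA file: ", path)
    file.create(path)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i])) {
      paste(records$id[i], records$description[i])
    } else {
      records$id[i]
    }
    s <- records$residues[i]
    starts <- seq.int(1L, nchar(s), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", header), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Write a data frame as a TSV report
#'
#' All tabular outputs of the package go through this writer: tab-separated,
#' header row, fixed column order, no quoting, no row names.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
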