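.FEATURE_KEYS <- c("id", "region", "positions", "pattern", "predicate",
                   "offset", "weight", "required", "scope", "note")
.GROUP_KEYS <- c("name", "class", "features")
.REGIONS <- c("HD_POS", "N_FLANK", "C_FLANK")
.SCOPES <- c("bilaterian", "lophotrochozoan", "molluscan")
.BASIC_RESIDUES <- c("K", "R", "H")

# Residue-set predicates available to HD_POS features.  X never satisfies
# any predicate (unknown residues cannot carry diagnostic evidence).
.PREDICATES <- list(
  # every listed position holds a non-basic residue (not K/R/H)
  non_basic = function(res, flank_left, flank_right) {
    all(res != "X") && !any(res %in% .BASIC_RESIDUES)
  },
  # the listed position is bracketed by basic residues on both sides
  flanked_by_basic = function(res, flank_left, flank_right) {
    all(res != "X") &&
      !is.na(flank_left) && flank_left %in% .BASIC_RESIDUES &&
      !is.na(flank_right) && flank_right %in% .BASIC_RESIDUES
  }
)

#' Read a diagnostic-motif catalog from structured text (YAML)
#'
#' A catalog declares, per paralog-group label, the diagnostic residues
#' and motifs used for classification, anchored to homeodomain
#' coordinates (positions 1-60; C-flank offsets +1, +2, ...; N-flank
#' offsets -1, -2, ...). Unknown keys, unknown region types and
#' out-of-range homeodomain positions are rejected.
#'
#' @param path Path to a catalog file.
#' @return A `motif_catalog` object.
#' @seealso [default_catalog()]
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups)) stop("catalog has no 'groups' section")
  extra <- setdiff(names(raw), "groups")
  if (length(extra)) stop("unknown catalog key(s): ", paste(extra, collapse = ", "))
  groups <- lapply(raw$groups, .validate_group)
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(names(groups))) {
    stop("duplicate group name: ", names(groups)[duplicated(names(groups))][1L])
  }
  structure(list(groups = groups), class = "motif_catalog")
}

.validate_group <- function(g) {
  extra <- setdiff(names(g), .GROUP_KEYS)
  if (length(extra)) stop("unknown group key(s): ", paste(extra, collapse = ", "))
  if (is.null(g$name) || !nzchar(g$name)) stop("group without a name")
  if (is.null(g$class) || !(g$class %in% c("hox", "parahox"))) {
    stop("group '", g$name, "': class must be 'hox' or 'parahox'")
  }
  g$features <- lapply(g$features, .validate_feature, group = g$name)
  g
}

.validate_feature <- function(f, group) {
  extra <- setdiff(names(f), .FEATURE_KEYS)
  if (length(extra)) {
    stop("feature in group '", group, "': unknown key(s): ",
         paste(extra, collapse = ", "))
  }
  if (is.null(f$id)) stop("feature in group '", group, "' without an id")
  if (is.null(f$region) || !(f$region %in% .REGIONS)) {
    stop("feature '", f$id, "': unknown region type '", f$region, "'")
  }
  f$weight <- if (is.null(f$weight)) 1.0 else as.numeric(f$weight)
  if (f$weight < 0) stop("feature '", f$id, "': negative weight")
  f$required <- isTRUE(f$required)
  if (!is.null(f$scope) && !(f$scope %in% .SCOPES)) {
    stop("feature '", f$id, "': unknown scope '", f$scope, "'")
  }
  f$pattern <- if (is.null(f$pattern)) "" else toupper(f$pattern)
  has_pattern <- nzchar(f$pattern)
  has_predicate <- !is.null(f$predicate)
  if (has_predicate && !(f$predicate %in% names(.PREDICATES))) {
    stop("feature '", f$id, "': unknown predicate '", f$predicate, "'")
  }
  if (has_pattern && has_predicate) {
    stop("feature '", f$id, "': give a pattern or a predicate, not both")
  }
  f$positions <- as.integer(unlist(f$positions))
  if (f$region == "HD_POS") {
    if (length(f$positions)) {
      if (any(f$positions < 1L | f$positions > 60L)) {
        stop("feature '", f$id, "': HD_POS positions must lie in 1-60")
      }
      if (is.unsorted(f$positions, strictly = TRUE)) {
        stop("feature '", f$id, "': positions must be strictly increasing")
      }
      if (has_pattern && nchar(f$pattern) != length(f$positions)) {
        stop("feature '", f$id, "': pattern length differs from positions")
      }
    } else if (has_pattern || has_predicate) {
      stop("feature '", f$id, "': HD_POS feature needs positions")
    }
  } else {
    if (length(f$positions)) {
      stop("feature '", f$id, "': flank features use 'offset', not positions")
    }
    if (!is.null(f$offset)) f$offset <- as.integer(f$offset)
    if (has_predicate) {
      stop("feature '", f$id, "': predicates are only supported at HD_POS")
    }
  }
  f$placeholder <- !has_pattern && !has_predicate
  if (f$placeholder && f$weight != 0) {
    stop("feature '", f$id, "': placeholder (no pattern/predicate) must have weight 0")
  }
  # canonical key order so catalogs round-trip identically
  f[intersect(c(.FEATURE_KEYS, "placeholder"), names(f))]
}

#' The packaged default Hox/ParaHox catalog
#'
#' Contains the 11 Hox labels (Hox1-Hox5, Lox5, Antp, Lox4, Lox2, Post2,
#' Post1) and 3 ParaHox labels (Gsx, Xlox, Cdx) of the ancestral
#' lophotrochozoan toolkit, with the printed diagnostic features (the
#' hexapeptide YPWM for Hox4/Hox5, LPNTK for Hox4, the molluscan HIAKNM
#' immediately after the homeodomain for Hox5, non-basic residues at
#' homeodomain positions 2-3 for Hox1, the flanked-by-basic position 4
#' for Hox2/Hox3, the lophotrochozoan AL at 36-37 for Hox3, and LRTCD in
#' the Gsx C-terminal arm) plus inert placeholder slots for features the
#' literature localizes without printing residues.
#'
#' @return A `motif_catalog`.
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "hox_parahox_catalog.yaml",
                           package = "hoxminer", mustWork = TRUE))
}

#' Labels of a catalog
#'
#' @param catalog A `motif_catalog`.
#' @param class Optional filter, `"hox"` or `"parahox"`.
#' @return Character vector of group labels, catalog order.
#' @export
catalog_labels <- function(catalog, class = NULL) {
  stopifnot(inherits(catalog, "motif_catalog"))
  labs <- names(catalog$groups)
  if (!is.null(class)) {
    keep <- vapply(catalog$groups, function(g) g$class == class, logical(1))
    labs <- labs[keep]
  }
  labs
}

#' Scoring (non-placeholder) features of a group
#'
#' @param catalog A `motif_catalog`.
#' @param group Group label.
#' @return List of feature descriptors with positive weight and a filled
#'   pattern or predicate.
#' @export
scoring_features <- function(catalog, group) {
  g <- catalog$groups[[group]]
  if (is.null(g)) stop("unknown catalog group: ", group)
  Filter(function(f) !f$placeholder && f$weight > 0, g$features)
}

#' @export
print.motif_catalog <- function(x, ...) {
  nfeat <- sum(vapply(x$groups, function(g) length(g$features), integer(1)))
  nscore <- sum(vapply(names(x$groups),
                       function(g) length(scoring_features(x, g)), integer(1)))
  cat("motif_catalog: ", length(catalog_labels(x, "hox")), " hox + ",
      length(catalog_labels(x, "parahox")), " parahox labels, ",
      nfeat, " features (", nscore, " scoring)\n", sep = "")
  invisible(x)
}

#' Write a catalog back to structured text
#'
#' Emits the same YAML layout [read_catalog()] accepts, so discovered
#' features can be merged and re-loaded.
#'
#' @param catalog A `motif_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "motif_catalog"))
  groups <- lapply(unname(catalog$groups), function(g) {
    g$features <- lapply(g$features, function(f) {
      f$placeholder <- NULL
      if (!length(f$positions)) f$positions <- NULL
      if (!is.null(f$positions)) f$positions <- as.list(f$positions)
      if (!f$required) f$required <- NULL
      f
    })
    g
  })
  yaml::write_yaml(list(groups = groups), path)
  invisible(path)
}

#' The packaged synthetic homeodomain consensus set
#'
#' One fixed 60-residue consensus per catalog label: a shared
#' homeodomain-like backbone, distinct between groups only at
#' catalog-diagnostic positions. Used to train the default scan profile,
#' as the reference set of the k-mer evidence source, and by the
#' synthetic-transcriptome generator.
#'
#' @return Named character vector, one 60-mer per label.
#' @export
hd_consensus_set <- function() {
  recs <- read_fasta(system.file("extdata", "hd_consensus_synthetic.faa",
                                 package = "hoxminer", mustWork = TRUE),
                     alphabet = "aa")
  stats::setNames(recs$residues, recs$id)
}
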