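# Phosphopattern algebra for the seven phosphorylatable Ser/Thr residues of
# the bovine rhodopsin C-terminus. Patterns are 7-bit occupancy vectors in
# fixed sequence order; this order is used by every design matrix and report.

#' Canonical phosphorylation sites of the rhodopsin C-terminus
#'
#' The seven phosphorylatable serines/threonines of the bovine rhodopsin
#' C-terminal tail, in sequence order. All phosphopattern bit vectors,
#' design matrices and coefficient reports in this package use this order.
#'
#' @return Character vector of the seven site names.
#' @examples
#' phospho_sites()
#' @export
phospho_sites <- function() {
  c("S334", "T335", "T336", "S338", "T340", "T342", "S343")
}

#' The invariant peptide backbone sequence
#'
#' Amino-acid sequence shared by every peptide in the combinatorial panel
#' (rhodopsin C-terminus with an N-terminal Cys for fluorescent labeling);
#' panel members differ only in which Ser/Thr carry a phosphate.
#'
#' @return A single string.
#' @export
panel_sequence <- function() "CDDEASTTVSKTETSQVAPA"

#' Construct a phosphopattern
#'
#' A phosphopattern is the unit of barcode identity: a 7-bit occupancy
#' indicator over the canonical sites (see [phospho_sites()]).
#'
#' @param bits Integer/logical vector of length 7 (0/1), in site order.
#' @param label Optional peptide name (e.g. `"7P"`, `"3Pf"`, `"0P"`).
#'   The conventional labels `"0P"` and `"7P"` are checked against the bits.
#' @return An object of class `phospho_pattern`: a named integer vector of
#'   length 7 with a `label` attribute.
#' @examples
#' phospho_pattern(c(0, 0, 0, 0, 1, 1, 1), label = "3Pf")
#' @export
phospho_pattern <- function(bits, label = NULL) {
  bits <- as.integer(bits)
  if (length(bits) != 7L || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be 7 binary values (one per site)", call. = FALSE)
  }
  names(bits) <- phospho_sites()
  if (!is.null(label)) {
    label <- as.character(label)
    if (identical(label, "0P") && sum(bits) != 0L) {
      stop("label \"0P\" requires an all-zero pattern", call. = FALSE)
    }
    if (identical(label, "7P") && sum(bits) != 7L) {
      stop("label \"7P\" requires an all-one pattern", call. = FALSE)
    }
    attr(bits, "label") <- label
  }
  class(bits) <- "phospho_pattern"
  bits
}

#' @export
print.phospho_pattern <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<phospho_pattern",
      if (!is.null(lab)) paste0("\"", lab, "\""), pattern_bitstring(x),
      paste0("{", paste(decode_pattern(x), collapse = ","), "}"), ">\n")
  invisible(x)
}

#' Encode a set of phosphorylated sites as a pattern
#'
#' @param sites Character vector of site names drawn from [phospho_sites()]
#'   (duplicates allowed, ignored). May be empty.
#' @param label Optional peptide label, passed to [phospho_pattern()].
#' @return A `phospho_pattern` with 1-bits exactly at `sites`.
#' @examples
#' encode_pattern(c("T340", "T342", "S343"), label = "3Pf")
#' @export
encode_pattern <- function(sites = character(), label = NULL) {
  sites <- unique(as.character(sites))
  canon <- phospho_sites()
  bad <- setdiff(sites, canon)
  if (length(bad)) {
    stop("unknown phosphosite name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  phospho_pattern(as.integer(canon %in% sites), label = label)
}

#' Decode a pattern back to its phosphorylated site names
#'
#' Inverse of [encode_pattern()]: `encode_pattern(decode_pattern(p))`
#' reproduces `p` for every pattern.
#'
#' @param pattern A `phospho_pattern` or a 7-element 0/1 vector.
#' @return Character vector of site names with occupancy 1.
#' @export
decode_pattern <- function(pattern) {
  bits <- as_pattern_bits(pattern)
  phospho_sites()[bits == 1L]
}

#' Number of phosphorylated sites in a pattern
#'
#' @inheritParams decode_pattern
#' @return Integer count of 1-bits.
#' @export
phospho_count <- function(pattern) {
  sum(as_pattern_bits(pattern))
}

#' Serialize a pattern as a 7-character bitstring
#'
#' Bitstrings (e.g. `"0000111"` for peptide 3Pf) are the on-disk pattern
#' representation in every file this package reads or writes.
#'
#' @inheritParams decode_pattern
#' @return A single string of 7 characters `"0"`/`"1"`.
#' @seealso [parse_bitstring()]
#' @export
pattern_bitstring <- function(pattern) {
  paste(as_pattern_bits(pattern), collapse = "")
}

#' Parse a 7-character bitstring into a pattern
#'
#' @param x A string of exactly 7 characters, each `"0"` or `"1"`.
#' @param label Optional peptide label.
#' @return A `phospho_pattern`.
#' @export
parse_bitstring <- function(x, label = NULL) {
  x <- as.character(x)
  if (length(x) != 1L || is.na(x) || !grepl("^[01]{7}$", x)) {
    stop("bitstring must be 7 characters of 0/1, got: ",
         deparse(x), call. = FALSE)
  }
  phospho_pattern(as.integer(strsplit(x, "")[[1]]), label = label)
}

# Coerce pattern-like input to a bare integer bit vector of length 7
# (or length n for generic patterns from enumerate_patterns()).
as_pattern_bits <- function(pattern) {
  if (inherits(pattern, "phospho_pattern")) {
    return(unclass(pattern))
  }
  if (is.character(pattern) && length(pattern) == 1L) {
    return(unclass(parse_bitstring(pattern)))
  }
  bits <- as.integer(pattern)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("cannot interpret input as a phosphopattern", call. = FALSE)
  }
  bits
}

#' Enumerate all phosphopatterns up to a maximal phosphorylation level
#'
#' Generates every subset of `n_sites` sites with 0 to `max_phospho`
#' phosphates, exactly once, in a deterministic order: ascending phosphate
#' count, then lexicographic on the bitstring. The non-phosphorylated
#' control is included, so `enumerate_patterns(7, 3)` yields the 64-member
#' mono- to tri-phosphorylated array panel (1 + 7 + 21 + 35).
#'
#' @param n_sites Number of sites (7 for the rhodopsin C-terminus; other
#'   values are supported for generic combinatorics).
#' @param max_phospho Maximal number of phosphorylated sites, between 0 and
#'   `n_sites`.
#' @return A data.frame with columns `bitstring` (length-`n_sites` 0/1
#'   string) and `n_phospho`; when `n_sites == 7` the rows are valid inputs
#'   to [parse_bitstring()].
#' @examples
#' nrow(enumerate_patterns(7, 3)) # 64
#' @export
enumerate_patterns <- function(n_sites, max_phospho) {
  n_sites <- as.integer(n_sites)
  max_phospho <- as.integer(max_phospho)
  if (is.na(n_sites) || n_sites < 0L || is.na(max_phospho) || max_phospho < 0L) {
    stop("`n_sites` and `max_phospho` must be nonnegative", call. = FALSE)
  }
  if (max_phospho > n_sites) {
    stop("`max_phospho` must not exceed `n_sites`", call. = FALSE)
  }
  rows <- lapply(0:max_phospho, function(k) {
    if (k == 0L) {
      return(paste(rep("0", n_sites), collapse = ""))
    }
    idx <- utils::combn(n_sites, k, simplify = FALSE)
    bs <- vapply(idx, function(i) {
      b <- rep("0", n_sites)
      b[i] <- "1"
      paste(b, collapse = "")
    }, character(1))
    sort(bs)
  })
  bitstring <- unlist(rows)
  data.frame(
    bitstring = bitstring,
    n_phospho = vapply(strsplit(bitstring, ""),
                       function(b) sum(b == "1"), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Construct a peptide panel
#'
#' A panel is an ordered collection of labelled phosphopatterns sharing the
#' invariant backbone sequence.
#'
#' @param labels Character vector of unique peptide labels.
#' @param bitstrings Character vector of 7-character bitstrings, same length.
#' @param sequence Backbone sequence; defaults to [panel_sequence()].
#' @return A data.frame of class `peptide_panel` with columns `label`,
#'   `bitstring`, `n_phospho` and a `sequence` attribute.
#' @export
peptide_panel <- function(labels, bitstrings, sequence = panel_sequence()) {
  labels <- as.character(labels)
  bitstrings <- as.character(bitstrings)
  if (length(labels) != length(bitstrings)) {
    stop("`labels` and `bitstrings` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("panel labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  pats <- Map(parse_bitstring, bitstrings, labels)
  panel <- data.frame(
    label = labels,
    bitstring = bitstrings,
    n_phospho = vapply(pats, phospho_count, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(panel) <- NULL
  attr(panel, "sequence") <- sequence
  class(panel) <- c("peptide_panel", "data.frame")
  panel
}

#' The full combinatorial array panel (mono- to tri-phosphorylated)
#'
#' The 64-peptide design probed on the peptide microarray: the
#' non-phosphorylated control plus every mono-, di- and tri-phosphorylated
#' pattern over the seven sites. Labels are `"p" + bitstring`, except the
#' all-zero control which keeps its conventional name `"0P"`.
#'
#' @return A `peptide_panel` with 64 rows.
#' @export
combinatorial_panel <- function() {
  pats <- enumerate_patterns(7, 3)
  labels <- paste0("p", pats$bitstring)
  labels[pats$n_phospho == 0L] <- "0P"
  peptide_panel(labels, pats$bitstring)
}

#' The packaged named-peptide panel (synthetic reconstruction)
#'
#' The named peptides used in the binding, proteolysis and NMR assays
#' (0P, 3Pa--3Pk, 4P, 5P, 6P, 7P). Compositions of 0P, 7P, 3Pf and the
#' constraints on 3Pa--3Pd, 3Pg, 3Pi, 4P, 5P and 6P are fixed by the assay
#' narrative; the remaining site assignments are a synthetic reconstruction
#' consistent with those constraints (the original graphical table is not
#' machine-readable). Rows whose composition is narrative-fixed carry
#' `source = "text"`, reconstructed rows carry `source = "synthetic"`.
#'
#' @return A `peptide_panel` with an extra `source` column.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel_synthetic.csv",
                      package = "phosphobarcode", mustWork = TRUE)
  read_panel(path)
}

#' Read a peptide panel from CSV
#'
#' Expected columns: `label`, `bitstring`; extra columns are carried along.
#'
#' @param path Path to a CSV file.
#' @return A `peptide_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("label", "bitstring") %in% names(df))) {
    stop("panel file must have columns `label` and `bitstring`",
         call. = FALSE)
  }
  panel <- peptide_panel(df$label, df$bitstring)
  extra <- setdiff(names(df), c("label", "bitstring"))
  for (col in extra) panel[[col]] <- df[[col]]
  panel
}

#' Write a peptide panel to CSV
#'
#' @param panel A `peptide_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# 0/1 design matrix (rows = peptides, cols = the 7 sites) for a panel.
panel_bits <- function(panel) {
  m <- t(vapply(strsplit(panel$bitstring, ""),
                function(b) as.integer(b == "1"), integer(7)))
  colnames(m) <- phospho_sites()
  rownames(m) <- panel$label
  m
}
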