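# Rule-based phosphosite motif classifier: the functional site roles
# (key / inhibitory / secondary / modulator) and the pure-pattern
# predictors for arrestin-1 binding, C-tail release and ternary complex
# formation, plus cross-assay concordance reporting and a declarative
# boolean motif scanner.

#' Functional roles of the seven phosphosites
#'
#' The fixed role map: T340 and S343 are the key sites required for tight
#' arrestin-1 binding and activation; T342 is the inhibitory site that
#' abrogates binding at low total phosphorylation; T335 and S338 are
#' secondary sites that partially rescue recruitment when one key site is
#' missing; S334 and T336 are modulator sites tuning global conformation.
#' T335 and S338 also belong to the broader modulator region; their
#' primary role here is `secondary` and the dual membership is recorded in
#' the `modulator_region` column.
#'
#' @return Data.frame with columns `site`, `role`, `modulator_region`.
#' @export
assign_roles <- function() {
  data.frame(
    site = phospho_sites(),
    role = c("modulator", "secondary", "modulator", "secondary",
             "key", "inhibitory", "key"),
    modulator_region = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# bit helpers over a pattern-like input
pattern_has <- function(pattern, site) {
  bits <- as_pattern_bits(pattern)
  bits[match(site, phospho_sites())] == 1L
}

#' Predict arrestin-1 binding class from a phosphopattern
#'
#' `tight` iff both key sites (T340, S343) are phosphorylated and the
#' inhibitory site T342 is not engaged at low total phosphorylation:
#' T342 abrogates binding only when at most three sites are
#' phosphorylated; in more highly phosphorylated peptides (4P, 6P, 7P)
#' the upstream phosphates anchor the register and T342 is neutral.
#'
#' @param pattern A `phospho_pattern`, bitstring, or 7-element 0/1 vector.
#' @return `"tight"` or `"weak"`.
#' @examples
#' predict_arr1_binding("1111111") # 7P -> tight
#' predict_arr1_binding("0000111") # 3Pf -> weak (inhibitory T342)
#' @export
predict_arr1_binding <- function(pattern) {
  bits <- as_pattern_bits(pattern)
  keys <- pattern_has(bits, "T340") && pattern_has(bits, "S343")
  inhibited <- pattern_has(bits, "T342") && sum(bits) <= 3L
  if (keys && !inhibited) "tight" else "weak"
}

#' Predict arrestin-1 C-tail release from a phosphopattern
#'
#' C-tail displacement (the limited-proteolysis hallmark of activation)
#' follows the same predicate as tight binding: every peptide that binds
#' tightly releases the C-tail, and no weak binder does.
#'
#' @inheritParams predict_arr1_binding
#' @return `"yes"` or `"no"`.
#' @export
predict_ctail_release <- function(pattern) {
  if (predict_arr1_binding(pattern) == "tight") "yes" else "no"
}

#' Predict ternary complex formation from a phosphopattern
#'
#' `robust` for tight binders; `moderate` for patterns with exactly one
#' key site but both secondary sites (T335 and S338) phosphorylated, which
#' partially rescue recruitment; `low` otherwise.
#'
#' @inheritParams predict_arr1_binding
#' @return `"robust"`, `"moderate"` or `"low"`.
#' @export
predict_ternary <- function(pattern) {
  bits <- as_pattern_bits(pattern)
  if (predict_arr1_binding(bits) == "tight") return("robust")
  n_keys <- pattern_has(bits, "T340") + pattern_has(bits, "S343")
  if (n_keys == 1L && pattern_has(bits, "T335") &&
      pattern_has(bits, "S338")) "moderate" else "low"
}

#' Predict arrestin-2 binding class (isoform-specific exceptions)
#'
#' Arrestin-2's spontaneously displaced C-tail lets it bind some peptides
#' arrestin-1 rejects. The rule claimed here is deliberately narrow:
#' tight if both key sites are set, or for the two documented exceptions
#' (a 5P-like pattern with T340 but not S343 and >= 5 phosphates, and the
#' 3Pf pattern exactly). No general arrestin-2 code is asserted.
#'
#' @inheritParams predict_arr1_binding
#' @return `"tight"` or `"weak"`.
#' @export
predict_arr2_binding <- function(pattern) {
  bits <- as_pattern_bits(pattern)
  keys <- pattern_has(bits, "T340") && pattern_has(bits, "S343")
  like_5p <- pattern_has(bits, "T340") && !pattern_has(bits, "S343") &&
    sum(bits) >= 5L
  like_3pf <- identical(unname(bits), c(0L, 0L, 0L, 0L, 1L, 1L, 1L))
  if (keys || like_5p || like_3pf) "tight" else "weak"
}

#' Annotate a panel with rule-based predictions
#'
#' @param panel A `peptide_panel`.
#' @return The panel with columns `predicted_arr1_binding`,
#'   `predicted_ctail_release`, `predicted_ternary`.
#' @export
annotate_panel <- function(panel) {
  panel$predicted_arr1_binding <-
    vapply(panel$bitstring, predict_arr1_binding, character(1),
           USE.NAMES = FALSE)
  panel$predicted_ctail_release <-
    vapply(panel$bitstring, predict_ctail_release, character(1),
           USE.NAMES = FALSE)
  panel$predicted_ternary <-
    vapply(panel$bitstring, predict_ternary, character(1),
           USE.NAMES = FALSE)
  panel
}

#' Cross-assay concordance report
#'
#' One row per panel peptide: pattern, rule-based predictions, measured
#' outcomes when supplied, and agreement flags, with per-assay accuracy
#' summaries. Measured labels absent from the panel are reported as
#' orphans, not errors.
#'
#' @param panel A `peptide_panel`.
#' @param measured Optional data.frame keyed by `label` with any of:
#'   `Kd` (numeric, uM; `NA` for not-determinable), `censored` (logical;
#'   Kd above the assay bound), `ctail` (`"yes"`/`"no"`), `ternary`
#'   (`"robust"`/`"moderate"`/`"low"`).
#' @param bound Kd bound separating tight from weak binders (exclusive;
#'   default 250 uM).
#' @return A data.frame of class `concordance_table` with attributes
#'   `accuracy` (named vector per assay) and `orphans` (unmatched
#'   measured labels).
#' @export
concordance_table <- function(panel, measured = NULL, bound = 250) {
  out <- as.data.frame(annotate_panel(panel))
  attr(out, "orphans") <- character(0)
  acc <- c(binding = NA_real_, ctail = NA_real_, ternary = NA_real_)
  if (!is.null(measured)) {
    if (!"label" %in% names(measured)) {
      stop("`measured` must have a `label` column", call. = FALSE)
    }
    attr(out, "orphans") <- setdiff(measured$label, panel$label)
    idx <- match(out$label, measured$label)
    if (all(c("Kd", "censored") %in% names(measured)) ||
        "Kd" %in% names(measured)) {
      kd <- measured$Kd[idx]
      cens <- if ("censored" %in% names(measured)) {
        measured$censored[idx]
      } else !is.finite(kd)
      cens <- cens | !is.finite(kd)
      out$measured_binding <- ifelse(is.na(idx), NA_character_,
                                     ifelse(!cens & kd < bound,
                                            "tight", "weak"))
      out$binding_agrees <- out$measured_binding == out$predicted_arr1_binding
      acc["binding"] <- mean(out$binding_agrees, na.rm = TRUE)
    }
    if ("ctail" %in% names(measured)) {
      out$measured_ctail <- measured$ctail[idx]
      out$ctail_agrees <- out$measured_ctail == out$predicted_ctail_release
      acc["ctail"] <- mean(out$ctail_agrees, na.rm = TRUE)
    }
    if ("ternary" %in% names(measured)) {
      out$measured_ternary <- measured$ternary[idx]
      out$ternary_agrees <- out$measured_ternary == out$predicted_ternary
      acc["ternary"] <- mean(out$ternary_agrees, na.rm = TRUE)
    }
  }
  attr(out, "accuracy") <- acc
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' Write a concordance table to TSV
#'
#' @param tab A `concordance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- declarative motif scanner --------------------------------------------

# Tokenize a boolean motif expression over site states. Tokens: site
# names, AND/&, OR/|, NOT/!, parentheses. Returns tokens with their
# character positions for error reporting.
motif_tokenize <- function(spec) {
  pat <- "\\(|\\)|&{1,2}|\\|{1,2}|!|[A-Za-z_][A-Za-z0-9_]*"
  m <- gregexpr(pat, spec)[[1]]
  if (m[1] == -1) stop("empty motif spec", call. = FALSE)
  tokens <- regmatches(spec, gregexpr(pat, spec))[[1]]
  # anything outside matched tokens other than whitespace is an error
  covered <- rep(FALSE, nchar(spec))
  for (i in seq_along(m)) {
    covered[seq(m[i], m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
  }
  chars <- strsplit(spec, "")[[1]]
  stray <- which(!covered & !grepl("[[:space:]]", chars))
  if (length(stray)) {
    stop("malformed motif spec at position ", stray[1], ": unexpected `",
         chars[stray[1]], "`", call. = FALSE)
  }
  up <- toupper(tokens)
  type <- ifelse(tokens == "(", "lparen",
          ifelse(tokens == ")", "rparen",
          ifelse(up == "AND" | grepl("^&+$", tokens), "and",
          ifelse(up == "OR" | grepl("^\\|+$", tokens), "or",
          ifelse(up == "NOT" | tokens == "!", "not", "site")))))
  data.frame(token = tokens, type = type, pos = as.integer(m),
             stringsAsFactors = FALSE)
}

# Recursive-descent parser; grammar:
#   expr   := term (OR term)*
#   term   := factor (AND factor)*
#   factor := NOT factor | "(" expr ")" | site
# Returns a predicate closure over a named logical site-state vector.
motif_parse <- function(tokens, valid_sites) {
  i <- 0L
  peek <- function() if (i < nrow(tokens)) tokens[i + 1L, ] else NULL
  advance <- function() {
    i <<- i + 1L
    tokens[i, ]
  }
  fail <- function(tok, what) {
    pos <- if (is.null(tok)) "end of input" else
      paste0("position ", tok$pos, " (`", tok$token, "`)")
    stop("malformed motif spec at ", pos, ": expected ", what,
         call. = FALSE)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "a site name, NOT or `(`")
    if (tok$type == "not") {
      advance()
      inner <- parse_factor()
      return(function(state) !inner(state))
    }
    if (tok$type == "lparen") {
      advance()
      inner <- parse_expr()
      close <- peek()
      if (is.null(close) || close$type != "rparen") fail(close, "`)`")
      advance()
      return(inner)
    }
    if (tok$type == "site") {
      advance()
      site <- tok$token
      if (!site %in% valid_sites) {
        stop("malformed motif spec at position ", tok$pos,
             ": unknown site `", site, "`", call. = FALSE)
      }
      return(function(state) unname(state[site]))
    }
    fail(tok, "a site name, NOT or `(`")
  }
  parse_term <- function() {
    left <- parse_factor()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "and") return(left)
      advance()
      right <- parse_factor()
      left <- local({
        l <- left
        r <- right
        function(state) l(state) && r(state)
      })
    }
  }
  parse_expr <- function() {
    left <- parse_term()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "or") return(left)
      advance()
      right <- parse_term()
      left <- local({
        l <- left
        r <- right
        function(state) l(state) || r(state)
      })
    }
  }
  root <- parse_expr()
  leftover <- peek()
  if (!is.null(leftover)) fail(leftover, "end of input")
  root
}

#' Scan patterns against a declarative motif
#'
#' Evaluates a boolean expression over site phosphorylation states, e.g.
#' `"T340 AND S343 AND NOT T342"`. Operators: `AND`/`&`, `OR`/`|`,
#' `NOT`/`!`, parentheses; site names are the canonical
#' [phospho_sites()]. Spacing-style motifs (sites a fixed distance apart)
#' are expressed by expanding the admissible placements as an `OR` of
#' concrete site conjunctions. Malformed specs are rejected with the
#' character position of the error.
#'
#' @param pattern A single pattern (any form accepted by
#'   [encode_pattern()]'s relatives) or a `peptide_panel` for batch mode.
#' @param motif_spec The boolean expression as a string.
#' @return A logical match flag; for a panel, a named logical vector (one
#'   flag per peptide).
#' @examples
#' motif_scan("1111111", "T340 AND S343")            # TRUE
#' motif_scan("0000111", "T340 & S343 & !T342")      # FALSE (3Pf)
#' @export
motif_scan <- function(pattern, motif_spec) {
  tokens <- motif_tokenize(motif_spec)
  pred <- motif_parse(tokens, phospho_sites())
  eval_one <- function(p) {
    bits <- as_pattern_bits(p)
    state <- stats::setNames(bits == 1L, phospho_sites())
    isTRUE(pred(state))
  }
  if (inherits(pattern, "peptide_panel")) {
    stats::setNames(vapply(pattern$bitstring, eval_one, logical(1),
                           USE.NAMES = FALSE), pattern$label)
  } else {
    eval_one(pattern)
  }
}
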