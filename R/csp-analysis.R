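# Chemical shift perturbation (CSP) analysis of amide 1H/15N titration
# series: weighted combined shifts per residue, trajectory tracking across
# peptide:protein ratios, magnitude classification and line-broadening
# flags.

#' CSP analysis configuration
#'
#' @param n_weight Scaling factor applied to the 15N shift difference
#'   before combining with 1H (default 0.2, the conventional weight for
#'   the narrower proton dispersion).
#' @param class_edges Four strictly ascending ppm thresholds separating
#'   the magnitude classes nonsignificant / minor / moderate / large /
#'   very_large. `NULL` (default) means: derive them as the 20/40/60/80th
#'   percentiles of the nonzero combined shifts of the dataset under
#'   analysis (see [analyze_csp()]).
#' @param broadening_ratio A residue is flagged line-broadened when its
#'   endpoint intensity falls below this fraction of its reference
#'   intensity (default 0.3), after median-normalizing each spectrum.
#' @return A list of class `csp_config`.
#' @export
csp_config <- function(n_weight = 0.2, class_edges = NULL,
                       broadening_ratio = 0.3) {
  if (n_weight <= 0 || n_weight > 1) {
    stop("`n_weight` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(class_edges)) {
    class_edges <- as.numeric(class_edges)
    if (length(class_edges) != 4 || any(diff(class_edges) <= 0)) {
      stop("`class_edges` must be four strictly ascending thresholds",
           call. = FALSE)
    }
  }
  if (broadening_ratio <= 0 || broadening_ratio >= 1) {
    stop("`broadening_ratio` must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_weight = n_weight, class_edges = class_edges,
                 broadening_ratio = broadening_ratio),
            class = "csp_config")
}

#' The CSP magnitude classes
#'
#' @return Character vector of class labels, ascending magnitude, with
#'   `"broadened"` as the overriding terminal category.
#' @export
csp_classes <- function() {
  c("nonsignificant", "minor", "moderate", "large", "very_large",
    "broadened")
}

#' Weighted combined chemical shift perturbation
#'
#' `ddelta = sqrt((w * (dN_bound - dN_free))^2 + (dH_bound - dH_free)^2)`
#' with nitrogen weight `w` (default 0.2). Symmetric in which spectrum is
#' called free vs bound.
#'
#' @param free,bound Peak positions for the same residue: lists or one-row
#'   data.frames with fields `residue`, `dH`, `dN`.
#' @param cfg A [csp_config()].
#' @return Combined shift perturbation in ppm (>= 0).
#' @examples
#' cfg <- csp_config()
#' compute_csp(list(residue = "E39", dH = 8.0, dN = 120),
#'             list(residue = "E39", dH = 8.0, dN = 121), cfg) # 0.2
#' @export
compute_csp <- function(free, bound, cfg = csp_config()) {
  if (!identical(as.character(free$residue), as.character(bound$residue))) {
    stop("residue mismatch: ", free$residue, " vs ", bound$residue,
         call. = FALSE)
  }
  combined_shift(bound$dH - free$dH, bound$dN - free$dN, cfg$n_weight)
}

combined_shift <- function(dH, dN, n_weight = 0.2) {
  sqrt((n_weight * dN)^2 + dH^2)
}

#' Track one residue's peak across the titration
#'
#' Computes the combined shift of every titration point against the
#' free-protein reference (ratio 0), takes `final_delta` at the largest
#' ratio, and evaluates line broadening before classification: a residue
#' is broadened when its endpoint peak is missing or its endpoint
#' intensity drops below `broadening_ratio` of the reference intensity.
#'
#' @param peaks Data.frame for a single residue with columns `residue`,
#'   `ratio`, `dH`, `dN`, `intensity` (one row per titration point,
#'   reference ratio 0 required).
#' @param cfg A [csp_config()].
#' @param endpoint_ratio The ratio that counts as the titration endpoint;
#'   defaults to the largest ratio present in `peaks`. Supply the
#'   dataset-wide endpoint so a residue whose endpoint peak vanished is
#'   recognized as broadened.
#' @return A list of class `csp_record`: `residue`, `ratios`, `delta`
#'   (ppm per ratio), `final_delta`, `broadened`, `csp_class` (`NA` until
#'   [classify_csp()]).
#' @export
track_trajectory <- function(peaks, cfg = csp_config(),
                             endpoint_ratio = max(peaks$ratio)) {
  residue <- unique(as.character(peaks$residue))
  if (length(residue) != 1) {
    stop("`peaks` must describe a single residue", call. = FALSE)
  }
  peaks <- peaks[order(peaks$ratio), , drop = FALSE]
  if (!0 %in% peaks$ratio) {
    stop("missing free-protein reference (ratio 0) for residue ", residue,
         call. = FALSE)
  }
  ref <- peaks[peaks$ratio == 0, , drop = FALSE][1, ]
  delta <- combined_shift(peaks$dH - ref$dH, peaks$dN - ref$dN,
                          cfg$n_weight)
  names(delta) <- peaks$ratio
  has_endpoint <- endpoint_ratio %in% peaks$ratio
  if (has_endpoint) {
    end <- peaks[peaks$ratio == endpoint_ratio, , drop = FALSE][1, ]
    broadened <- is.finite(end$intensity) && is.finite(ref$intensity) &&
      ref$intensity > 0 &&
      end$intensity < cfg$broadening_ratio * ref$intensity
    final_delta <- combined_shift(end$dH - ref$dH, end$dN - ref$dN,
                                  cfg$n_weight)
  } else {
    # endpoint peak collapsed below detection: broadened by definition
    broadened <- TRUE
    final_delta <- max(delta)
  }
  structure(list(residue = residue, ratios = peaks$ratio, delta = delta,
                 final_delta = final_delta, broadened = broadened,
                 csp_class = NA_character_),
            class = "csp_record")
}

#' Classify a CSP record by magnitude
#'
#' Bins `final_delta` by the four configured edges into nonsignificant /
#' minor / moderate / large / very_large; a broadened record is always
#' classed `"broadened"` regardless of shift.
#'
#' @param record A `csp_record` from [track_trajectory()].
#' @param cfg A [csp_config()] whose `class_edges` are set (fixed ppm
#'   values, or dataset-derived ones from [csp_default_edges()]).
#' @return The record with `csp_class` filled in.
#' @export
classify_csp <- function(record, cfg) {
  if (is.null(cfg$class_edges)) {
    stop("`cfg$class_edges` must be set before classification; ",
         "use csp_default_edges() or fixed ppm values", call. = FALSE)
  }
  record$csp_class <- if (record$broadened) "broadened" else {
    csp_classes()[findInterval(record$final_delta, cfg$class_edges) + 1L]
  }
  record
}

#' Dataset-derived magnitude class edges
#'
#' The default binning when no fixed ppm thresholds are configured: the
#' 20/40/60/80th percentiles of the nonzero final combined shifts of
#' non-broadened residues.
#'
#' @param final_deltas Numeric vector of final combined shifts (ppm).
#' @return Four ascending edges.
#' @export
csp_default_edges <- function(final_deltas) {
  nz <- final_deltas[is.finite(final_deltas) & final_deltas > 0]
  if (length(nz) < 5) {
    stop("too few nonzero shifts (", length(nz),
         ") to derive percentile edges; supply fixed `class_edges`",
         call. = FALSE)
  }
  edges <- unname(stats::quantile(nz, c(0.2, 0.4, 0.6, 0.8)))
  if (any(diff(edges) <= 0)) {
    stop("degenerate shift distribution; supply fixed `class_edges`",
         call. = FALSE)
  }
  edges
}

#' Analyze a full CSP titration dataset
#'
#' Median-normalizes intensities within each spectrum (titration point),
#' tracks every residue against the ratio-0 reference, derives class edges
#' from the data unless fixed ones are configured, and classifies each
#' residue. Unassigned peaks (residue id beginning with `"unass"`) are
#' tracked but excluded from classification and from the edge estimate.
#'
#' @param peaks A `peak_series` data.frame (columns `residue`, `ratio`,
#'   `dH`, `dN`, `intensity`), e.g. from [gen_csp_dataset()] or
#'   [read_peak_lists()].
#' @param cfg A [csp_config()].
#' @return A data.frame of class `csp_table`: one row per residue with
#'   `residue`, one `delta_<ratio>` column per nonzero ratio,
#'   `final_delta`, `broadened`, `csp_class`; plus attributes
#'   `class_edges` and `endpoint_ratio`.
#' @export
analyze_csp <- function(peaks, cfg = csp_config()) {
  need <- c("residue", "ratio", "dH", "dN", "intensity")
  if (!all(need %in% names(peaks))) {
    stop("`peaks` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # dilution / receiver-gain differences between spectra are removed by
  # median normalization per titration point
  med <- tapply(peaks$intensity, peaks$ratio, stats::median)
  peaks$intensity <- peaks$intensity / med[as.character(peaks$ratio)]
  endpoint_ratio <- max(peaks$ratio)
  records <- lapply(split(peaks, peaks$residue), track_trajectory,
                    cfg = cfg, endpoint_ratio = endpoint_ratio)
  unassigned <- grepl("^unass", vapply(records, `[[`, character(1),
                                       "residue"), ignore.case = TRUE)
  if (is.null(cfg$class_edges)) {
    fd <- vapply(records, `[[`, numeric(1), "final_delta")
    br <- vapply(records, `[[`, logical(1), "broadened")
    cfg$class_edges <- csp_default_edges(fd[!br & !unassigned])
  }
  records <- lapply(records, classify_csp, cfg = cfg)
  ratios <- sort(unique(peaks$ratio))
  ratios <- ratios[ratios > 0]
  rows <- lapply(records, function(rec) {
    d <- stats::setNames(rep(NA_real_, length(ratios)),
                         paste0("delta_", ratios))
    present <- intersect(as.character(ratios), names(rec$delta))
    d[paste0("delta_", present)] <- rec$delta[present]
    cbind(data.frame(residue = rec$residue, stringsAsFactors = FALSE),
          as.data.frame(as.list(d), check.names = FALSE),
          data.frame(final_delta = rec$final_delta,
                     broadened = rec$broadened,
                     csp_class = rec$csp_class,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out$csp_class[unassigned] <- NA_character_
  rownames(out) <- NULL
  attr(out, "class_edges") <- cfg$class_edges
  attr(out, "endpoint_ratio") <- endpoint_ratio
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Protein occupancy at each titration ratio
#'
#' Delegates to the exact depletion-corrected equilibrium
#' ([occupancy_exact()]) with peptide total = ratio x protein
#' concentration. At the standard endpoint (ratio 10, 100 uM protein) a
#' 250 uM Kd gives ~79% occupancy and a 100 uM Kd ~90%.
#'
#' @param Kd Dissociation constant (uM).
#' @param protein_conc Protein concentration (uM, default 100).
#' @param ratios Peptide:protein ratios (default 0, 1, 4, 10).
#' @return Data.frame with `ratio`, `peptide_uM`, `occupancy`.
#' @export
saturation_report <- function(Kd, protein_conc = 100,
                              ratios = c(0, 1, 4, 10)) {
  data.frame(ratio = ratios,
             peptide_uM = ratios * protein_conc,
             occupancy = occupancy_exact(Pt = protein_conc,
                                         Lt = ratios * protein_conc,
                                         Kd = Kd))
}

#' Read a Sparky-style amide peak list
#'
#' Whitespace-delimited lines of `assignment  w1(15N ppm)  w2(1H ppm)
#' height`; a header line containing "Assignment" and blank/comment lines
#' are skipped. The residue id is the assignment up to the first atom
#' separator (e.g. `"E39N-H"` -> `"E39"`).
#'
#' @param path Path to the peak list.
#' @param ratio Peptide:protein ratio of this spectrum.
#' @return Data.frame with `residue`, `ratio`, `dH`, `dN`, `intensity`.
#' @export
read_sparky <- function(path, ratio) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!grepl("Assignment", lines, ignore.case = TRUE)]
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) < 4)
  if (length(bad)) {
    stop("malformed peak-list line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  }
  assignment <- vapply(fields, `[[`, character(1), 1)
  data.frame(
    residue = sub("^([A-Za-z]*[0-9]+|unass[0-9]*).*$", "\\1", assignment),
    ratio = ratio,
    dN = as.numeric(vapply(fields, `[[`, character(1), 2)),
    dH = as.numeric(vapply(fields, `[[`, character(1), 3)),
    intensity = as.numeric(vapply(fields, `[[`, character(1), 4)),
    stringsAsFactors = FALSE)
}

#' Read one peak table per titration ratio
#'
#' @param paths Named character vector: names are ratios, values are file
#'   paths. Files ending `.csv` are read as CSV (columns `residue`, `dH`,
#'   `dN`, `intensity`); anything else as a Sparky-style list.
#' @return A `peak_series` data.frame spanning all ratios.
#' @export
read_peak_lists <- function(paths) {
  ratios <- as.numeric(names(paths))
  if (anyNA(ratios)) {
    stop("`paths` must be named by their peptide:protein ratios",
         call. = FALSE)
  }
  rows <- Map(function(path, ratio) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("residue", "dH", "dN", "intensity")
      if (!all(need %in% names(df))) {
        stop("CSV peak list must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
      }
      df$ratio <- ratio
      df[, c("residue", "ratio", "dH", "dN", "intensity")]
    } else {
      read_sparky(path, ratio)
    }
  }, paths, ratios)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_series", "data.frame")
  out
}

#' Write a peak table as a Sparky-style list
#'
#' @param peaks Data.frame with `residue`, `dH`, `dN`, `intensity` (one
#'   titration point).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparky <- function(peaks, path) {
  lines <- c(sprintf("%12s %9s %9s %12s", "Assignment", "w1", "w2",
                     "Height"),
             sprintf("%12s %9.3f %9.3f %12.4g",
                     paste0(peaks$residue, "N-H"),
                     peaks$dN, peaks$dH, peaks$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Write a CSP result table to TSV
#'
#' @param csp A `csp_table` from [analyze_csp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csp_tsv <- function(csp, path) {
  utils::write.table(as.data.frame(csp), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a residue-to-class map for structure coloring
#'
#' Plain two-column text (`residue  class`), keyed by residue number,
#' suitable for driving molecular-graphics coloring scripts. Unclassified
#' (unassigned) residues are omitted.
#'
#' @inheritParams write_csp_tsv
#' @return `path`, invisibly.
#' @export
write_class_map <- function(csp, path) {
  keep <- !is.na(csp$csp_class)
  writeLines(paste(csp$residue[keep], csp$csp_class[keep]), path)
  invisible(path)
}
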