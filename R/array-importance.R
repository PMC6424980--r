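# Per-site importance from the combinatorial peptide array: an additive
# linear model in the seven occupancy bits, fitted by exhaustive all-subset
# OLS (2^7 = 128 models) and ranked by AIC. Exhaustive enumeration
# dominates any stepwise path, so "bidirectional stepwise" is subsumed.

#' Average replicate spot intensities per pattern
#'
#' One response value per peptide: the arithmetic mean of its replicate
#' intensities (replicates are duplicate spots across independently
#' synthesized arrays).
#'
#' @param spots An `array_spots` data.frame (columns `label`, `bitstring`,
#'   `rep1..repN`; see [gen_array()] / [read_array_spots()]).
#' @return A data.frame of class `array_responses` with columns `label`,
#'   `bitstring`, `intensity`.
#' @export
average_replicates <- function(spots) {
  if (is.null(spots) || nrow(spots) == 0) {
    stop("`spots` must contain at least one peptide", call. = FALSE)
  }
  rep_cols <- grep("^rep[0-9]+$", names(spots), value = TRUE)
  if (!length(rep_cols)) stop("no replicate columns (`rep1..repN`) found",
                              call. = FALSE)
  reps <- as.matrix(spots[, rep_cols, drop = FALSE])
  if (any(!is.finite(reps)) || any(reps < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  out <- data.frame(label = spots$label, bitstring = spots$bitstring,
                    intensity = rowMeans(reps), stringsAsFactors = FALSE)
  class(out) <- c("array_responses", "data.frame")
  out
}

#' Gaussian profile-likelihood AIC for an OLS fit
#'
#' `AIC = n * ln(rss / n) + 2 * p`, with `p` the number of mean
#' parameters (included sites plus the always-present intercept). The
#' constant contribution of the profiled-out variance parameter is omitted,
#' which leaves all model rankings unchanged. Lower is better. An exactly
#' zero `rss` is floored at machine epsilon so noise-free fits stay finite.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n_obs Number of observations.
#' @param n_params Number of mean parameters, `|support| + 1`.
#' @return The AIC value.
#' @examples
#' aic_gauss(rss = 10, n_obs = 10, n_params = 4) # log term vanishes -> 8
#' @export
aic_gauss <- function(rss, n_obs, n_params) {
  if (rss < 0) stop("`rss` must be >= 0", call. = FALSE)
  if (n_obs <= n_params) {
    stop("model not overdetermined: n_obs = ", n_obs,
         " <= n_params = ", n_params, call. = FALSE)
  }
  rss <- max(rss, .Machine$double.eps)
  n_obs * log(rss / n_obs) + 2 * n_params
}

# Responses -> design pieces shared by the subset fitters.
response_design <- function(responses) {
  y <- responses$intensity
  bits <- t(vapply(strsplit(responses$bitstring, ""),
                   function(b) as.integer(b == "1"), integer(7)))
  colnames(bits) <- phospho_sites()
  list(y = y, bits = bits)
}

#' Fit the additive model on one subset of sites
#'
#' Ordinary least squares of mean spot intensity on the occupancy bits of
#' the chosen sites, with the intercept (non-specific binding) always
#' included.
#'
#' @param responses An `array_responses` table (see [average_replicates()]).
#' @param support Character vector of site names to include (possibly
#'   empty), drawn from [phospho_sites()].
#' @return A list of class `subset_model` with elements `support`,
#'   `coefficients` (named, one per included site), `intercept`, `rss`,
#'   `n_obs` and `aic`.
#' @export
fit_subset <- function(responses, support = character()) {
  support <- as.character(support)
  bad <- setdiff(support, phospho_sites())
  if (length(bad)) stop("unknown site(s) in support: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  d <- response_design(responses)
  fit_subset_impl(d$y, d$bits, support)
}

fit_subset_impl <- function(y, bits, support) {
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, bits[, support, drop = FALSE])
  p <- ncol(X)
  if (n <= p) {
    stop("too few patterns (", n, ") for a ", p, "-parameter model",
         call. = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, p)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  # floor rss so that exact interpolation (noise-free data) keeps the
  # log-likelihood finite without perturbing any real comparison
  rss_f <- max(rss, .Machine$double.eps * max(tss, 1))
  structure(list(
    support = support,
    coefficients = if (length(support)) beta[support] else
      stats::setNames(numeric(0), character(0)),
    intercept = unname(beta["(Intercept)"]),
    rss = rss,
    n_obs = n,
    aic = aic_gauss(rss_f, n, p)
  ), class = "subset_model")
}

#' @export
print.subset_model <- function(x, ...) {
  cat("<subset_model {", paste(x$support, collapse = ","),
      "} aic =", signif(x$aic, 6), " rss =", signif(x$rss, 4), ">\n")
  invisible(x)
}

# Support set -> 7-bit string in canonical site order.
support_bitstring <- function(support) {
  paste(as.integer(phospho_sites() %in% support), collapse = "")
}

#' Fit every subset of the seven sites
#'
#' Exhaustive all-subset OLS: one model per subset of the 7 sites
#' (128 models), each with intercept, scored by [aic_gauss()]. Models are
#' returned in deterministic enumeration order (ascending support size,
#' lexicographic bitstring within size); use [rank_models()] or
#' [importance_matrix()] for the AIC ordering.
#'
#' @param responses An `array_responses` table with at least 9 distinct
#'   patterns, so the full 8-parameter model is overdetermined.
#' @return A list of class `subset_models` containing 128 `subset_model`
#'   objects, named by support bitstring.
#' @export
fit_all_subsets <- function(responses) {
  if (length(unique(responses$bitstring)) < 9) {
    stop("need >= 9 distinct patterns to fit all 7-site subsets",
         call. = FALSE)
  }
  d <- response_design(responses)
  sites <- phospho_sites()
  supports <- unlist(lapply(0:7, function(k) {
    if (k == 0L) return(list(character()))
    sets <- utils::combn(sites, k, simplify = FALSE)
    sets[order(vapply(sets, support_bitstring, character(1)))]
  }), recursive = FALSE)
  models <- lapply(supports, function(s) fit_subset_impl(d$y, d$bits, s))
  names(models) <- vapply(supports, support_bitstring, character(1))
  class(models) <- "subset_models"
  models
}

#' Order subset models by AIC
#'
#' Ascending AIC; ties broken by smaller support, then lexicographic
#' support bitstring.
#'
#' @param models A `subset_models` list.
#' @return The models, reordered.
#' @export
rank_models <- function(models) {
  aic <- vapply(models, `[[`, numeric(1), "aic")
  size <- vapply(models, function(m) length(m$support), integer(1))
  bs <- vapply(models, function(m) support_bitstring(m$support), character(1))
  out <- models[order(aic, size, bs)]
  class(out) <- "subset_models"
  out
}

#' Coefficient-importance matrix of the top AIC models
#'
#' The per-site importance display: rows are the `k` best models by AIC
#' (best first), columns the seven sites plus the intercept. An entry is
#' the fitted coefficient, exactly zero when the site is excluded from
#' that model.
#'
#' @param models A `subset_models` list (all 128 fits).
#' @param k Number of top models to keep (default 20).
#' @return A list of class `importance_matrix` with elements `matrix`
#'   (k x 8 numeric, rownames = support bitstrings) and `models` (the
#'   top-k `subset_model`s, AIC order).
#' @export
importance_matrix <- function(models, k = 20) {
  if (k > length(models)) {
    stop("`k` (", k, ") exceeds the number of models (", length(models), ")",
         call. = FALSE)
  }
  top <- rank_models(models)[seq_len(k)]
  sites <- phospho_sites()
  m <- matrix(0, nrow = k, ncol = length(sites) + 1L,
              dimnames = list(
                vapply(top, function(x) support_bitstring(x$support),
                       character(1)),
                c(sites, "intercept")))
  for (i in seq_len(k)) {
    m[i, top[[i]]$support] <- top[[i]]$coefficients
    m[i, "intercept"] <- top[[i]]$intercept
  }
  structure(list(matrix = m, models = top), class = "importance_matrix")
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat("<importance_matrix: top", nrow(x$matrix), "models by AIC>\n")
  print(signif(x$matrix, 4))
  invisible(x)
}

#' Akaike-weighted aggregate site importance
#'
#' Model-averaged coefficient per site over all supplied models: weights
#' proportional to `exp(-dAIC / 2)`, with a site's coefficient taken as 0
#' in models that exclude it. Used as the scalar ranking statistic for
#' threshold-robustness reports.
#'
#' @param models A `subset_models` list.
#' @return Named numeric vector (one value per site), descending order
#'   preserved by [threshold_robustness()].
#' @export
aggregate_importance <- function(models) {
  aic <- vapply(models, `[[`, numeric(1), "aic")
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)
  sites <- phospho_sites()
  coefs <- vapply(models, function(m) {
    v <- stats::setNames(numeric(length(sites)), sites)
    v[m$support] <- m$coefficients
    v
  }, numeric(length(sites)))
  drop(coefs %*% w)
}

#' Robustness of the site ranking to low-signal filtering
#'
#' Repeats the all-subset analysis after excluding peptides whose mean
#' intensity falls below each threshold, and reports the per-threshold
#' site ranking by [aggregate_importance()]. Thresholds leaving fewer than
#' 9 distinct patterns are reported infeasible rather than failing.
#'
#' @param spots An `array_spots` table.
#' @param thresholds Ascending numeric intensity cutoffs (a threshold of 0
#'   reproduces the unfiltered analysis).
#' @return A list of class `threshold_robustness`, one element per
#'   threshold: `threshold`, `feasible`, `n_patterns`, `importance`
#'   (named vector) and `ranking` (site names, most important first);
#'   infeasible thresholds carry `feasible = FALSE` and NULL results.
#' @export
threshold_robustness <- function(spots, thresholds) {
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds)) {
    stop("`thresholds` must be sorted ascending", call. = FALSE)
  }
  responses <- average_replicates(spots)
  out <- lapply(thresholds, function(th) {
    keep <- responses[responses$intensity >= th, , drop = FALSE]
    if (length(unique(keep$bitstring)) < 9) {
      return(list(threshold = th, feasible = FALSE,
                  n_patterns = nrow(keep), importance = NULL,
                  ranking = NULL))
    }
    models <- fit_all_subsets(keep)
    imp <- aggregate_importance(models)
    list(threshold = th, feasible = TRUE, n_patterns = nrow(keep),
         importance = imp,
         ranking = names(sort(imp, decreasing = TRUE)))
  })
  class(out) <- "threshold_robustness"
  out
}

#' Write the full model table to TSV
#'
#' One row per subset: support bitstring, aic, rss, intercept and the
#' seven per-site coefficients (0 where excluded).
#'
#' @param models A `subset_models` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_tsv <- function(models, path) {
  sites <- phospho_sites()
  rows <- lapply(models, function(m) {
    v <- stats::setNames(numeric(length(sites)), sites)
    v[m$support] <- m$coefficients
    cbind(data.frame(support = support_bitstring(m$support),
                     aic = m$aic, rss = m$rss, intercept = m$intercept,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an importance matrix to TSV
#'
#' @param im An `importance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance_matrix <- function(im, path) {
  df <- data.frame(support = rownames(im$matrix),
                   aic = vapply(im$models, `[[`, numeric(1), "aic"),
                   im$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
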