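# 1:1 binding analysis: hyperbolic anisotropy-titration fits (tracer
# depletion neglected; tracer is 20 nM, orders of magnitude below any Kd
# here) and the exact quadratic equilibrium with ligand depletion (needed
# at NMR concentrations, where protein is 100 uM and depletion is not
# negligible).

#' Construct a titration curve
#'
#' @param protein_conc Protein concentrations in uM; should include a
#'   zero-protein (buffer-only) control. Sorted ascending on construction.
#' @param anisotropy Anisotropy reading per concentration (dimensionless).
#' @param tracer_conc Labeled-peptide concentration in nM (default 20).
#' @param label Optional peptide label.
#' @return A data.frame of class `titration_curve` with columns `conc_uM`
#'   and `anisotropy`, plus `tracer_nM` and `label` attributes.
#' @export
titration_curve <- function(protein_conc, anisotropy, tracer_conc = 20,
                            label = NULL) {
  protein_conc <- as.numeric(protein_conc)
  anisotropy <- as.numeric(anisotropy)
  if (length(protein_conc) != length(anisotropy)) {
    stop("`protein_conc` and `anisotropy` must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(protein_conc)) || any(protein_conc < 0)) {
    stop("protein concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(anisotropy))) {
    stop("anisotropy readings must be finite", call. = FALSE)
  }
  ord <- order(protein_conc)
  curve <- data.frame(conc_uM = protein_conc[ord],
                      anisotropy = anisotropy[ord])
  attr(curve, "tracer_nM") <- tracer_conc
  attr(curve, "label") <- label
  class(curve) <- c("titration_curve", "data.frame")
  curve
}

#' Fit an anisotropy titration to the 1:1 binding model
#'
#' Fits `r = R0 + dR * P / (Kd + P)` by nonlinear least squares, where `r`
#' is the anisotropy reading, `R0` the free-tracer anisotropy, `dR` the
#' amplitude (complex minus free tracer) and `P` the protein concentration.
#' Depletion of the ~20 nM tracer is deliberately neglected, as is standard
#' when tracer << Kd. Degenerate (flat) curves and fits with nonpositive
#' Kd are returned as censored rather than as errors.
#'
#' @param curve A [titration_curve()] (or data.frame with `conc_uM` and
#'   `anisotropy` columns) with at least 5 points spanning >= one decade of
#'   nonzero concentration.
#' @param censor_bound Kd (uM) above which a fit is reported as censored;
#'   see [censor_weak()]. Default 250.
#' @return An object of class `binding_fit`: a list with elements `R0`,
#'   `dR`, `Kd`, `Kd_se`, `censored`, `rss`, `max_conc`, `label` and
#'   `convergence` (message from the optimizer, if any).
#' @examples
#' truth <- titration_ground_truth(Kd = 50, noise_sd = 0)
#' fit <- fit_binding(gen_titration(truth, seed = 1))
#' fit$Kd
#' @export
fit_binding <- function(curve, censor_bound = 250) {
  if (!all(c("conc_uM", "anisotropy") %in% names(curve))) {
    stop("`curve` needs columns `conc_uM` and `anisotropy`", call. = FALSE)
  }
  P <- curve$conc_uM
  r <- curve$anisotropy
  if (any(!is.finite(r))) stop("anisotropy readings must be finite", call. = FALSE)
  pos <- P[P > 0]
  if (length(P) < 5 || length(pos) < 2 || max(pos) / min(pos) < 10) {
    stop("need >= 5 points spanning at least one decade of concentration",
         call. = FALSE)
  }
  label <- attr(curve, "label")
  out <- list(R0 = NA_real_, dR = NA_real_, Kd = NA_real_, Kd_se = NA_real_,
              censored = FALSE, rss = NA_real_, max_conc = max(P),
              label = label, convergence = NULL)
  class(out) <- "binding_fit"

  # flat curve: dR and Kd jointly unidentifiable
  if (diff(range(r)) <= 1e-12 * max(1, abs(mean(r)))) {
    out$R0 <- mean(r)
    out$dR <- 0
    out$censored <- TRUE
    out$rss <- sum((r - mean(r))^2)
    out$convergence <- "flat curve; Kd unidentifiable"
    return(out)
  }

  # starting values: R0 from the zero/lowest point, dR from the span,
  # Kd from the concentration nearest half-rise
  r0_start <- r[which.min(P)]
  dr_start <- r[which.max(P)] - r0_start
  if (abs(dr_start) < 1e-12) dr_start <- diff(range(r))
  half <- r0_start + dr_start / 2
  kd_start <- pos[which.min(abs(r[P > 0] - half))]
  if (!is.finite(kd_start) || kd_start <= 0) kd_start <- stats::median(pos)

  df <- data.frame(P = P, r = r)
  fit <- tryCatch(
    stats::nls(r ~ R0 + dR * P / (Kd + P), data = df,
               start = list(R0 = r0_start, dR = dr_start, Kd = kd_start),
               control = stats::nls.control(maxiter = 200, tol = 1e-8,
                                             scaleOffset = 1,
                                             warnOnly = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back on a bounded algorithm, more forgiving of poor starts
    fit <- tryCatch(
      stats::nls(r ~ R0 + dR * P / (Kd + P), data = df,
                 start = list(R0 = r0_start, dR = dr_start, Kd = kd_start),
                 algorithm = "port",
                 lower = c(R0 = -Inf, dR = -Inf, Kd = 1e-9),
                 control = stats::nls.control(maxiter = 200, tol = 1e-8,
                                             scaleOffset = 1,
                                             warnOnly = TRUE)),
      error = function(e) e)
  }
  if (inherits(fit, "error")) {
    stop("binding fit did not converge (start: R0=", signif(r0_start, 4),
         ", dR=", signif(dr_start, 4), ", Kd=", signif(kd_start, 4), "): ",
         conditionMessage(fit), call. = FALSE)
  }

  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  out$R0 <- unname(est["R0"])
  out$dR <- unname(est["dR"])
  out$Kd <- unname(est["Kd"])
  out$Kd_se <- unname(se["Kd"])
  out$rss <- sum(stats::residuals(fit)^2)
  out$convergence <- fit$convInfo$stopMessage
  if (!is.finite(out$Kd) || out$Kd <= 0) {
    out$censored <- TRUE
    out$Kd <- NA_real_
    out$Kd_se <- NA_real_
  }
  censor_weak(out, bound = censor_bound)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit", if (!is.null(x$label)) paste0("\"", x$label, "\""), ">\n")
  if (x$censored) {
    cat("  Kd: >", format(attr(x, "censor_bound") %||% 250), "uM (censored)\n")
  } else {
    cat(sprintf("  Kd: %.4g uM (se %.3g)\n", x$Kd, x$Kd_se))
  }
  cat(sprintf("  R0: %.4g  dR: %.4g  rss: %.3g\n", x$R0, x$dR, x$rss))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Censor weak binders
#'
#' Marks a fit censored when its Kd lies at or above the assay's reliable
#' bound (default 250 uM; the boundary itself is excluded from the binder
#' class), when the Kd estimate is undefined, or when the standard error
#' overlaps the bound and the titration never reached half-saturation
#' (top tested concentration below the fitted Kd). Censored fits are
#' reported as ">bound" in tables.
#'
#' @param fit A `binding_fit`.
#' @param bound Censoring bound in uM (default 250).
#' @return The fit with its `censored` flag set accordingly and a
#'   `censor_bound` attribute recorded.
#' @export
censor_weak <- function(fit, bound = 250) {
  stopifnot(inherits(fit, "binding_fit"))
  attr(fit, "censor_bound") <- bound
  if (fit$censored) return(fit)
  if (!is.finite(fit$Kd) || fit$Kd >= bound) {
    fit$censored <- TRUE
    return(fit)
  }
  if (is.finite(fit$Kd_se) && fit$Kd + fit$Kd_se > bound &&
      is.finite(fit$max_conc) && fit$max_conc < fit$Kd) {
    fit$censored <- TRUE
  }
  fit
}

#' Exact 1:1 equilibrium occupancy with ligand depletion
#'
#' Fraction of protein in complex at total protein `Pt`, total ligand `Lt`
#' and dissociation constant `Kd`, from the physical root of the binding
#' quadratic:
#' `PL = ((Pt + Lt + Kd) - sqrt((Pt + Lt + Kd)^2 - 4 Pt Lt)) / 2`.
#' Unlike the hyperbolic approximation used for tracer titrations, this is
#' exact at comparable protein and ligand concentrations (e.g. NMR samples
#' at 100 uM protein).
#'
#' All arguments are vectorized and recycled. Limits are handled
#' analytically: `Lt = 0` gives 0; `Kd = 0` gives `min(1, Lt / Pt)`;
#' `Pt = 0` gives the infinite-dilution occupancy `Lt / (Kd + Lt)`.
#'
#' @param Pt Total protein concentration (uM), >= 0.
#' @param Lt Total ligand (peptide) concentration (uM), >= 0.
#' @param Kd Dissociation constant (uM), >= 0.
#' @return Fraction of protein bound, in `[0, min(1, Lt/Pt)]`.
#' @examples
#' occupancy_exact(Pt = 100, Lt = 1000, Kd = 250) # ~0.787
#' @export
occupancy_exact <- function(Pt, Lt, Kd) {
  n <- max(length(Pt), length(Lt), length(Kd))
  Pt <- rep_len(as.numeric(Pt), n)
  Lt <- rep_len(as.numeric(Lt), n)
  Kd <- rep_len(as.numeric(Kd), n)
  if (any(Pt < 0 | Lt < 0 | Kd < 0, na.rm = TRUE)) {
    stop("`Pt`, `Lt` and `Kd` must be nonnegative", call. = FALSE)
  }
  f <- numeric(n)
  zeroL <- Lt == 0
  zeroP <- !zeroL & Pt == 0
  zeroK <- !zeroL & !zeroP & Kd == 0
  gen <- !(zeroL | zeroP | zeroK)
  f[zeroL] <- 0
  f[zeroP] <- Lt[zeroP] / (Kd[zeroP] + Lt[zeroP])
  f[zeroK] <- pmin(1, Lt[zeroK] / Pt[zeroK])
  if (any(gen)) {
    S <- Pt[gen] + Lt[gen] + Kd[gen]
    disc <- S^2 - 4 * Pt[gen] * Lt[gen]
    PL <- (S - sqrt(pmax(disc, 0))) / 2
    f[gen] <- pmin(pmax(PL / Pt[gen], 0), 1)
  }
  f
}

#' Kd that yields a target protein occupancy
#'
#' Closed-form inverse of [occupancy_exact()] in Kd:
#' `Kd = (Lt - f * Pt) * (1 - f) / f` for target fraction `f`. The target
#' must be feasible, i.e. strictly between 0 and `min(1, Lt/Pt)`;
#' `f = 0` returns `Inf` (no binding at any finite affinity deficit).
#'
#' @param target_fraction Desired fraction of protein bound.
#' @param Pt Total protein (uM).
#' @param Lt Total ligand (uM).
#' @return Kd in uM.
#' @examples
#' kd_for_occupancy(0.787, Pt = 100, Lt = 1000) # ~250
#' @export
kd_for_occupancy <- function(target_fraction, Pt, Lt) {
  f <- as.numeric(target_fraction)
  n <- max(length(f), length(Pt), length(Lt))
  f <- rep_len(f, n); Pt <- rep_len(as.numeric(Pt), n)
  Lt <- rep_len(as.numeric(Lt), n)
  out <- numeric(n)
  zero <- f == 0
  out[zero] <- Inf
  ok <- !zero
  if (any(f[ok] < 0 | f[ok] >= pmin(1, Lt[ok] / Pt[ok]))) {
    stop("`target_fraction` must lie in [0, min(1, Lt/Pt))", call. = FALSE)
  }
  out[ok] <- (Lt[ok] - f[ok] * Pt[ok]) * (1 - f[ok]) / f[ok]
  out
}

#' Read a titration CSV
#'
#' Expected columns: `conc_uM`, `anisotropy`.
#'
#' @param path CSV path.
#' @param tracer_conc Tracer concentration in nM (metadata; default 20).
#' @param label Optional peptide label.
#' @return A [titration_curve()].
#' @export
read_titration <- function(path, tracer_conc = 20, label = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("conc_uM", "anisotropy") %in% names(df))) {
    stop("titration file must have columns `conc_uM` and `anisotropy`",
         call. = FALSE)
  }
  titration_curve(df$conc_uM, df$anisotropy, tracer_conc = tracer_conc,
                  label = label)
}

#' Write a titration curve to CSV
#'
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("conc_uM", "anisotropy")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate binding fits
#'
#' @param fits A list of `binding_fit` objects.
#' @param bound Censoring bound used for the `Kd_report` column.
#' @return A data.frame with columns `label`, `R0`, `dR`, `Kd`, `Kd_se`,
#'   `censored` and `Kd_report` (numeric Kd, or `">bound"` when censored).
#' @export
binding_fit_table <- function(fits, bound = 250) {
  stopifnot(length(fits) > 0)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(
      label = f$label %||% names(fits)[i] %||% as.character(i),
      R0 = f$R0, dR = f$dR, Kd = f$Kd, Kd_se = f$Kd_se,
      censored = f$censored,
      Kd_report = if (f$censored) paste0(">", format(bound))
                  else format(signif(f$Kd, 4)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a binding-fit table to TSV
#'
#' @inheritParams binding_fit_table
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_fits <- function(fits, path, bound = 250) {
  utils::write.table(binding_fit_table(fits, bound = bound), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
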