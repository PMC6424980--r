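# Synthetic datasets with known ground truth for every assay stage, so the
# simulate -> fit loop is closed and testable without wet-lab data. Each
# generator takes an explicit seed and restores the caller's RNG state.

# Evaluate `code` under `seed` without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic peptide-array experiment
#'
#' The additive forward model behind the array regression: each spot's mean
#' intensity is `intercept + sum(bits * theta)`, with independent Gaussian
#' replicate noise clipped at zero. Default `theta` encodes the qualitative
#' structure the assay reports: largest contributions from the two key
#' sites (T340, S343), intermediate from the secondary sites (T335, S338),
#' small from the remaining sites; the intercept is the non-specific
#' binding component.
#'
#' @param theta Named numeric vector of per-site contributions
#'   (fluorescence units), in [phospho_sites()] order.
#' @param intercept Baseline (non-specific) intensity.
#' @param noise_sd Replicate noise standard deviation (same units).
#' @param replicates Replicates per peptide (default 4: duplicate spots on
#'   two independently synthesized arrays).
#' @return A list of class `array_ground_truth`.
#' @export
array_ground_truth <- function(theta = c(S334 = 50, T335 = 400, T336 = 50,
                                         S338 = 400, T340 = 900, T342 = 60,
                                         S343 = 800),
                               intercept = 500, noise_sd = 100,
                               replicates = 4) {
  theta <- as.numeric(theta)[seq_len(7)]
  if (length(theta) != 7 || anyNA(theta)) {
    stop("`theta` must supply 7 per-site contributions", call. = FALSE)
  }
  names(theta) <- phospho_sites()
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  structure(list(theta = theta, intercept = intercept,
                 noise_sd = noise_sd, replicates = replicates),
            class = "array_ground_truth")
}

#' Simulate peptide-array spot intensities
#'
#' @param truth An [array_ground_truth()].
#' @param panel A `peptide_panel`; defaults to the 64-peptide
#'   [combinatorial_panel()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A data.frame of class `array_spots` with columns `label`,
#'   `bitstring` and `rep1..repN`, plus a `truth` attribute.
#' @export
gen_array <- function(truth, panel = combinatorial_panel(), seed) {
  stopifnot(inherits(truth, "array_ground_truth"))
  if (nrow(panel) == 0) stop("`panel` must be nonempty", call. = FALSE)
  bits <- panel_bits(panel)
  mu <- truth$intercept + drop(bits %*% truth$theta)
  reps <- with_seed(seed, {
    m <- matrix(stats::rnorm(nrow(panel) * truth$replicates,
                             mean = rep(mu, truth$replicates),
                             sd = truth$noise_sd),
                nrow = nrow(panel))
    pmax(m, 0) # fluorescence cannot be negative
  })
  colnames(reps) <- paste0("rep", seq_len(truth$replicates))
  spots <- cbind(data.frame(label = panel$label, bitstring = panel$bitstring,
                            stringsAsFactors = FALSE),
                 as.data.frame(reps))
  attr(spots, "truth") <- truth
  class(spots) <- c("array_spots", "data.frame")
  spots
}

#' Ground truth for a synthetic anisotropy titration
#'
#' Forward model of the 1:1 tracer titration: an 11-step geometric protein
#' dilution plus a buffer-only control, readings
#' `r = R0 + dR * P / (Kd + P)` with additive Gaussian noise. The 2-fold
#' dilution factor is a convention (the assay describes an 11-step series
#' without stating the factor).
#'
#' @param Kd Dissociation constant in uM.
#' @param R0 Free-tracer anisotropy.
#' @param dR Anisotropy amplitude of the complex minus free tracer.
#' @param tracer_conc Tracer concentration in nM (metadata; default 20).
#' @param n_steps Number of nonzero dilution steps (default 11).
#' @param top_conc Highest protein concentration in uM.
#' @param dilution_factor Ratio between consecutive steps (> 1).
#' @param noise_sd Anisotropy noise standard deviation.
#' @return A list of class `titration_ground_truth`.
#' @export
titration_ground_truth <- function(Kd = 50, R0 = 0.05, dR = 0.10,
                                   tracer_conc = 20, n_steps = 11,
                                   top_conc = 500, dilution_factor = 2,
                                   noise_sd = 0.002) {
  if (Kd <= 0) stop("`Kd` must be > 0", call. = FALSE)
  if (n_steps < 3) stop("`n_steps` must be >= 3", call. = FALSE)
  if (dilution_factor <= 1) stop("`dilution_factor` must be > 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(Kd = Kd, R0 = R0, dR = dR, tracer_conc = tracer_conc,
                 n_steps = as.integer(n_steps), top_conc = top_conc,
                 dilution_factor = dilution_factor, noise_sd = noise_sd),
            class = "titration_ground_truth")
}

#' Simulate an anisotropy titration curve
#'
#' @param truth A [titration_ground_truth()].
#' @param seed Integer seed.
#' @return A [titration_curve()] with a `truth` attribute.
#' @export
gen_titration <- function(truth, seed) {
  stopifnot(inherits(truth, "titration_ground_truth"))
  P <- c(0, truth$top_conc / truth$dilution_factor^(seq_len(truth$n_steps) - 1))
  r <- truth$R0 + truth$dR * P / (truth$Kd + P)
  r <- r + with_seed(seed, stats::rnorm(length(P), sd = truth$noise_sd))
  curve <- titration_curve(P, r, tracer_conc = truth$tracer_conc)
  attr(curve, "truth") <- truth
  curve
}

#' Ground truth for a synthetic NMR titration (fast exchange)
#'
#' Emulates an amide TROSY titration of a 100 uM protein against peptide at
#' stoichiometric ratios 0/1/4/10. For each perturbed residue the observed
#' shift at a ratio is the population-weighted average
#' `free + occupancy * dmax` with occupancy from the exact 1:1
#' equilibrium ([occupancy_exact()]); a subset of residues instead loses
#' intensity with saturation (line broadening, intermediate exchange).
#' Defaults reflect the assay scale: ~160 assigned amides (~40% of the
#' protein), micromolar Kd, sub-ppm proton shift changes.
#'
#' @param n_residues Number of observed residues.
#' @param perturbed_fraction Fraction with a nonzero bound-state shift.
#' @param dmax_H,dmax_N Maximal bound-state shift change (ppm) on 1H / 15N;
#'   per-residue maxima are drawn uniformly up to these values.
#' @param Kd Peptide-protein dissociation constant (uM).
#' @param protein_conc Protein concentration (uM, constant; default 100).
#' @param ratios Peptide:protein ratios measured (default 0, 1, 4, 10).
#' @param broadened_fraction Fraction of perturbed residues flagged as
#'   intensity-lost instead of shifted.
#' @param shift_noise_sd Ppm noise on observed positions (default 0, so
#'   trajectories are exactly monotone in ratio).
#' @return A list of class `csp_ground_truth`.
#' @export
csp_ground_truth <- function(n_residues = 160, perturbed_fraction = 0.3,
                             dmax_H = 0.12, dmax_N = 0.6, Kd = 50,
                             protein_conc = 100, ratios = c(0, 1, 4, 10),
                             broadened_fraction = 0.08,
                             shift_noise_sd = 0) {
  if (perturbed_fraction < 0 || perturbed_fraction > 1 ||
      broadened_fraction < 0 || broadened_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (protein_conc <= 0) stop("`protein_conc` must be > 0", call. = FALSE)
  if (!0 %in% ratios) stop("`ratios` must include the free-protein point 0",
                           call. = FALSE)
  structure(list(n_residues = as.integer(n_residues),
                 perturbed_fraction = perturbed_fraction,
                 dmax_H = dmax_H, dmax_N = dmax_N, Kd = Kd,
                 protein_conc = protein_conc, ratios = sort(ratios),
                 broadened_fraction = broadened_fraction,
                 shift_noise_sd = shift_noise_sd),
            class = "csp_ground_truth")
}

#' Simulate fast-exchange NMR titration peak tables
#'
#' @param truth A [csp_ground_truth()].
#' @param seed Integer seed.
#' @return A data.frame of class `peak_series` with columns `residue`,
#'   `ratio`, `dH`, `dN`, `intensity`, plus a `truth` attribute holding
#'   per-residue `dmax_H`, `dmax_N`, `perturbed` and `broadened` vectors
#'   and the occupancy at each ratio.
#' @export
gen_csp_dataset <- function(truth, seed) {
  stopifnot(inherits(truth, "csp_ground_truth"))
  n <- truth$n_residues
  occ <- occupancy_exact(Pt = truth$protein_conc,
                         Lt = truth$ratios * truth$protein_conc,
                         Kd = truth$Kd)
  sim <- with_seed(seed, {
    residue <- sprintf("R%03d", seq_len(n))
    free_H <- stats::runif(n, 6.5, 9.5)
    free_N <- stats::runif(n, 104, 132)
    perturbed <- stats::runif(n) < truth$perturbed_fraction
    broadened <- perturbed & (stats::runif(n) < truth$broadened_fraction /
                                max(truth$perturbed_fraction, 1e-12))
    # broadened residues lose intensity with saturation; shifted residues
    # move in fast exchange instead
    dH_max <- ifelse(perturbed & !broadened,
                     stats::runif(n, 0.2, 1) * truth$dmax_H *
                       sign(stats::runif(n) - 0.5), 0)
    dN_max <- ifelse(perturbed & !broadened,
                     stats::runif(n, 0.2, 1) * truth$dmax_N *
                       sign(stats::runif(n) - 0.5), 0)
    base_int <- stats::runif(n, 0.5, 1.5)
    rows <- lapply(seq_along(truth$ratios), function(k) {
      f <- occ[k]
      data.frame(
        residue = residue,
        ratio = truth$ratios[k],
        dH = free_H + f * dH_max +
          stats::rnorm(n, sd = truth$shift_noise_sd),
        dN = free_N + f * dN_max +
          stats::rnorm(n, sd = truth$shift_noise_sd),
        intensity = base_int * ifelse(broadened, pmax(0.02, 1 - f), 1),
        stringsAsFactors = FALSE)
    })
    list(df = do.call(rbind, rows),
         truth_per_residue = data.frame(
           residue = residue, perturbed = perturbed, broadened = broadened,
           dmax_H = dH_max, dmax_N = dN_max, stringsAsFactors = FALSE))
  })
  out <- sim$df
  rownames(out) <- NULL
  attr(out, "truth") <- c(truth,
                          list(per_residue = sim$truth_per_residue,
                               occupancy = occ))
  class(out) <- c("peak_series", "data.frame")
  out
}

#' Read a peptide-array spot table
#'
#' Expected columns: `label`, `bitstring`, `rep1..repN`.
#'
#' @param path CSV path.
#' @return An `array_spots` data.frame.
#' @export
read_array_spots <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character",
                                       bitstring = "character"))
  need <- c("label", "bitstring")
  if (!all(need %in% names(df)) ||
      !length(grep("^rep[0-9]+$", names(df)))) {
    stop("array file must have columns `label`, `bitstring`, `rep1..repN`",
         call. = FALSE)
  }
  class(df) <- c("array_spots", "data.frame")
  df
}

#' Write a peptide-array spot table
#'
#' @param spots An `array_spots` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_array_spots <- function(spots, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
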