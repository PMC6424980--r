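# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: OLS via explicit normal equations, occupancy
# via a numeric root-finder, counts via factorials.

# Closed-form subset count: sum_{i=0..k} C(n, i), from factorials only.
count_subsets_oracle <- function(n, k) {
  sum(vapply(0:k, function(i) {
    factorial(n) / (factorial(i) * factorial(n - i))
  }, numeric(1)))
}

# OLS through the normal equations (no qr, no lm).
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta), rss = sum(res^2))
}

# Fraction of protein bound, via uniroot on the mass-balance equation
# (Pt - PL)(Lt - PL) = Kd * PL, polished with Newton steps to ~1e-14.
occupancy_oracle <- function(Pt, Lt, Kd) {
  if (Lt == 0) return(0)
  f <- function(PL) (Pt - PL) * (Lt - PL) - Kd * PL
  upper <- min(Pt, Lt)
  PL <- uniroot(f, c(0, upper), tol = 1e-14)$root
  for (i in 1:3) {
    g <- -(Lt - PL) - (Pt - PL) - Kd
    step <- f(PL) / g
    PL2 <- PL - step
    if (is.finite(PL2) && PL2 >= 0 && PL2 <= upper) PL <- PL2
  }
  PL / Pt
}

# A random response table over a random sub-panel of the 64-peptide array,
# for brute-force comparisons. Returns an `array_responses`-shaped df.
random_responses <- function(n_patterns = 64, seed = 1) {
  set.seed(seed)
  panel <- combinatorial_panel()
  idx <- sort(sample(nrow(panel), n_patterns))
  out <- data.frame(label = panel$label[idx],
                    bitstring = panel$bitstring[idx],
                    intensity = runif(n_patterns, 0, 1000),
                    stringsAsFactors = FALSE)
  class(out) <- c("array_responses", "data.frame")
  out
}

# Design matrix (intercept + chosen site bits) for a responses table.
design_for <- function(responses, support) {
  bits <- t(vapply(strsplit(responses$bitstring, ""),
                   function(b) as.integer(b == "1"), integer(7)))
  colnames(bits) <- phospho_sites()
  cbind(1, bits[, support, drop = FALSE])
}

# All supports of the 7 sites, smallest first (for brute-force scans).
all_supports <- function() {
  sites <- phospho_sites()
  unlist(lapply(0:7, function(k) {
    if (k == 0) list(character()) else combn(sites, k, simplify = FALSE)
  }), recursive = FALSE)
}

# Frozen measured outcomes for the peptides whose assay results the study
# narrative states explicitly: arrestin-1 binding class, C-tail release
# and ternary-complex level. Kd numbers are placeholders on the correct
# side of the 250 uM bound; censored rows have no determinable Kd.
text_constrained_measurements <- function() {
  data.frame(
    label   = c("7P", "0P", "3Pf", "5P", "3Pa", "3Pb", "3Pc", "3Pd",
                "3Pg", "3Pi"),
    Kd      = c(50, NA, NA, NA, 50, 50, 50, 50, NA, NA),
    censored = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE),
    ctail   = c("yes", "no", "no", "no", "yes", "yes", "yes", "yes",
                "no", "no"),
    ternary = c("robust", "low", "low", "moderate", "robust", "robust",
                "robust", "robust", "moderate", "moderate"),
    stringsAsFactors = FALSE)
}
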