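cfg0 <- csp_config()

peak <- function(res, dH, dN, intensity = 1, ratio = 0) {
  data.frame(residue = res, ratio = ratio, dH = dH, dN = dN,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("compute_csp reproduces hand-evaluated combined shifts", {
  free <- peak("E39", dH = 8.00, dN = 120.0)
  expect_equal(compute_csp(free, peak("E39", 8.10, 120.0), cfg0), 0.1)
  expect_equal(compute_csp(free, peak("E39", 8.00, 121.0), cfg0), 0.2)
  # sqrt((0.2*0.2)^2 + 0.03^2) = sqrt(0.04^2 + 0.03^2) = 0.05
  expect_equal(compute_csp(free, peak("E39", 8.03, 120.2), cfg0), 0.05)
  expect_error(compute_csp(free, peak("L172", 8.0, 120.0), cfg0),
               "residue mismatch")
})

test_that("combined shift is symmetric, homogeneous and zero iff unchanged", {
  set.seed(31)
  for (i in 1:50) {
    a <- peak("X1", runif(1, 6, 10), runif(1, 104, 132))
    b <- peak("X1", runif(1, 6, 10), runif(1, 104, 132))
    d1 <- compute_csp(a, b, cfg0)
    expect_equal(d1, compute_csp(b, a, cfg0))         # free/bound swap
    s <- runif(1, 0.1, 5)                              # joint scaling
    scaled <- peak("X1", a$dH + s * (b$dH - a$dH),
                   a$dN + s * (b$dN - a$dN))
    expect_equal(compute_csp(a, scaled, cfg0), s * d1, tolerance = 1e-12)
    expect_gt(d1, 0)
  }
  same <- peak("X1", 8.1, 118.3)
  expect_equal(compute_csp(same, same, cfg0), 0)
})

test_that("track_trajectory computes deltas against the ratio-0 reference", {
  # identical peaks at all ratios: zero shift, not broadened
  pk <- do.call(rbind, lapply(c(0, 1, 4, 10), function(r)
    peak("E39", 8.0, 120.0, ratio = r)))
  rec <- track_trajectory(pk, cfg0)
  expect_equal(rec$final_delta, 0)
  expect_false(rec$broadened)

  # fast-exchange forward model: final_delta = occupancy * dmax (1H-only)
  occ <- occupancy_exact(100, c(0, 100, 400, 1000) , 250)
  pk2 <- do.call(rbind, Map(function(r, f)
    peak("L172", 8.0 + f * 0.1, 120.0, ratio = r),
    c(0, 1, 4, 10), occ))
  rec2 <- track_trajectory(pk2, cfg0)
  expect_equal(rec2$final_delta, occ[4] * 0.1, tolerance = 1e-12)
  expect_equal(rec2$final_delta, 0.0787, tolerance = 1e-3)
  expect_equal(unname(rec2$delta), occ * 0.1, tolerance = 1e-12)

  # missing reference is an error
  expect_error(track_trajectory(pk2[-1, ], cfg0), "reference")
})

test_that("broadening is flagged from endpoint intensity or a lost peak", {
  pk <- do.call(rbind, Map(function(r, int)
    peak("G389", 8.0, 120.0, intensity = int, ratio = r),
    c(0, 1, 4, 10), c(1, 0.8, 0.5, 0.1)))
  rec <- track_trajectory(pk, cfg0) # 0.1 < 0.3 * 1
  expect_true(rec$broadened)
  expect_equal(classify_csp(rec, csp_config(class_edges = 1:4))$csp_class,
               "broadened")

  # endpoint peak vanished entirely: broadened by definition
  rec2 <- track_trajectory(pk[pk$ratio < 10, ], cfg0, endpoint_ratio = 10)
  expect_true(rec2$broadened)

  # intensity above threshold: not broadened
  pk$intensity <- c(1, 1, 0.9, 0.8)
  expect_false(track_trajectory(pk, cfg0)$broadened)
})

test_that("classify_csp bins by the configured edges", {
  cfg <- csp_config(class_edges = c(0.02, 0.05, 0.1, 0.2))
  mk <- function(d) structure(list(residue = "X", final_delta = d,
                                   broadened = FALSE,
                                   csp_class = NA_character_),
                              class = "csp_record")
  got <- vapply(c(0, 0.03, 0.07, 0.15, 0.5), function(d)
    classify_csp(mk(d), cfg)$csp_class, character(1))
  expect_equal(got, c("nonsignificant", "minor", "moderate", "large",
                      "very_large"))
  expect_error(classify_csp(mk(0.1), csp_config()), "class_edges")
  expect_error(csp_config(class_edges = c(3, 2, 1, 0)), "ascending")
})

test_that("analyze_csp recovers the generator's broadening and occupancy", {
  truth <- csp_ground_truth(n_residues = 120, Kd = 250, protein_conc = 100,
                            perturbed_fraction = 0.4,
                            broadened_fraction = 0.1)
  peaks <- gen_csp_dataset(truth, seed = 17)
  planted <- attr(peaks, "truth")$per_residue
  res <- analyze_csp(peaks, cfg0)
  res <- res[match(planted$residue, res$residue), ]

  # broadened flags recovered exactly
  expect_equal(res$broadened, planted$broadened)
  expect_true(all(res$csp_class[planted$broadened] == "broadened"))
  # unperturbed residues land in nonsignificant
  quiet <- !planted$perturbed
  expect_true(all(res$csp_class[quiet] == "nonsignificant"))
  # fast exchange: final_delta / dmax equals the endpoint occupancy
  occ_end <- occupancy_exact(100, 1000, 250)
  shifted <- planted$perturbed & !planted$broadened
  dmax <- sqrt((0.2 * planted$dmax_N[shifted])^2 + planted$dmax_H[shifted]^2)
  expect_equal(res$final_delta[shifted] / dmax,
               rep(occ_end, sum(shifted)), tolerance = 1e-9)
})

test_that("unassigned peaks are tracked but not classified", {
  truth <- csp_ground_truth(n_residues = 40, perturbed_fraction = 0.5,
                            broadened_fraction = 0)
  peaks <- gen_csp_dataset(truth, seed = 23)
  peaks$residue[peaks$residue == "R001"] <- "unass1"
  res <- analyze_csp(peaks, cfg0)
  expect_true(is.na(res$csp_class[res$residue == "unass1"]))
  expect_false(anyNA(res$csp_class[res$residue != "unass1"]))
  expect_true(is.finite(res$final_delta[res$residue == "unass1"]))
})

test_that("saturation_report reproduces the printed occupancy regimes", {
  # weakest binder (Kd at the 250 uM detection bound): ~79% at 10:1
  rep250 <- saturation_report(Kd = 250, protein_conc = 100)
  expect_equal(rep250$occupancy[rep250$ratio == 0], 0)
  expect_equal(round(rep250$occupancy[rep250$ratio == 10], 3), 0.787)
  # tight binders (Kd below ~115 uM): inside the 88-93% band at 10:1,
  # checked against the independent root-finder oracle
  rep100 <- saturation_report(Kd = 100, protein_conc = 100)
  occ100 <- rep100$occupancy[rep100$ratio == 10]
  expect_equal(occ100, occupancy_oracle(100, 1000, 100), tolerance = 1e-10)
  expect_true(occ100 >= 0.88)
  for (kd in c(40, 80, 115)) {
    occ <- saturation_report(kd)$occupancy[4]
    expect_true(occ >= 0.88)
  }
})

test_that("csp tables and class maps export to disk", {
  peaks <- gen_csp_dataset(csp_ground_truth(n_residues = 30), seed = 29)
  res <- analyze_csp(peaks, cfg0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_csp_tsv(res, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 30)
  expect_true(all(c("residue", "final_delta", "csp_class") %in% names(back)))

  f2 <- withr::local_tempfile(fileext = ".txt")
  write_class_map(res, f2)
  lines <- readLines(f2)
  expect_equal(length(lines), sum(!is.na(res$csp_class)))
  expect_match(lines[1], "^R[0-9]+ [a-z_]+$")
})
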