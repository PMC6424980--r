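test_that("average_replicates takes the arithmetic mean per pattern", {
  spots <- data.frame(label = c("a", "b"), bitstring = c("0000000", "1111111"),
                      rep1 = c(1, 0), rep2 = c(1, 2), rep3 = c(1, 1),
                      rep4 = c(1, 1), stringsAsFactors = FALSE)
  out <- average_replicates(spots)
  expect_equal(out$intensity, c(1, 1))
  expect_error(average_replicates(spots[0, ]), "at least one")

  # mean of noise-free replicates equals the forward-model value
  truth <- array_ground_truth(theta = c(10, 0, 0, 0, 5, 0, 3),
                              intercept = 100, noise_sd = 0)
  rs <- average_replicates(gen_array(truth, seed = 1))
  expect_equal(rs$intensity[rs$bitstring == "1000101"], 100 + 10 + 5 + 3)
})

test_that("fit_subset reproduces planted coefficients exactly at sigma=0", {
  truth <- array_ground_truth(theta = c(0, 0, 0, 0, 5, 0, 3), intercept = 2,
                              noise_sd = 0)
  rs <- average_replicates(gen_array(truth, seed = 1))
  m <- fit_subset(rs, c("T340", "S343"))
  expect_equal(unname(m$coefficients), c(5, 3))
  expect_equal(m$intercept, 2)
  expect_equal(m$rss, 0, tolerance = 1e-18)

  # intercept-only model: grand mean, rss = TSS
  m0 <- fit_subset(rs, character())
  expect_equal(m0$intercept, mean(rs$intensity))
  expect_equal(m0$rss, sum((rs$intensity - mean(rs$intensity))^2))

  expect_error(fit_subset(rs, "T999"), "unknown site")
})

test_that("fit_subset agrees with the normal-equations oracle", {
  rs <- random_responses(n_patterns = 30, seed = 3)
  for (support in list(character(), "T340", c("T335", "S338", "S343"),
                       phospho_sites())) {
    m <- fit_subset(rs, support)
    o <- ols_oracle(design_for(rs, support), rs$intensity)
    expect_equal(unname(c(m$intercept, m$coefficients)), unname(o$beta),
                 tolerance = 1e-9)
    expect_equal(m$rss, o$rss, tolerance = 1e-9)
  }
})

test_that("fit_subset rejects rank-deficient designs naming the culprits", {
  # duplicate the same pattern rows so one site's bit is constant zero
  rs <- random_responses(n_patterns = 12, seed = 4)
  rs$bitstring <- rep("1000000", nrow(rs)) # S334 constant 1, rest 0
  expect_error(fit_subset(rs, c("S334", "T335")), "collinear")
})

test_that("aic_gauss implements n*ln(rss/n) + 2p", {
  # rss = n so the log term vanishes: AIC = 2 * (|support| + 1)
  expect_equal(aic_gauss(rss = 10, n_obs = 10, n_params = 4), 8)
  expect_equal(aic_gauss(rss = 10, n_obs = 10, n_params = 1), 2)
  expect_error(aic_gauss(10, n_obs = 4, n_params = 4), "overdetermined")
  expect_error(aic_gauss(-1, 10, 2), ">= 0")

  # adding a parameter only pays off if rss shrinks by factor < exp(-2/n):
  # algebraic consequence, property-checked over random rss values
  set.seed(1)
  for (i in 1:50) {
    n <- sample(10:64, 1)
    p <- sample(1:6, 1)
    rss <- runif(1, 1, 100)
    shrink <- runif(1, exp(-2 / n), 1) # too little improvement
    expect_gt(aic_gauss(rss * shrink, n, p + 1), aic_gauss(rss, n, p))
    shrink2 <- runif(1, 0.01, exp(-2 / n) * 0.999) # enough improvement
    expect_lt(aic_gauss(rss * shrink2, n, p + 1), aic_gauss(rss, n, p))
  }
})

test_that("fit_all_subsets enumerates all 128 models once", {
  rs <- random_responses(n_patterns = 20, seed = 5)
  models <- fit_all_subsets(rs)
  expect_length(models, 128)
  expect_false(anyDuplicated(names(models)) > 0)
  expect_error(fit_all_subsets(rs[1:8, ]), ">= 9 distinct")
})

test_that("exhaustive search equals the brute-force oracle", {
  for (seed in 1:5) {
    rs <- random_responses(n_patterns = sample(15:64, 1), seed = seed)
    models <- fit_all_subsets(rs)
    # oracle: refit every subset independently and score it
    oracle_aic <- vapply(all_supports(), function(s) {
      o <- ols_oracle(design_for(rs, s), rs$intensity)
      n <- nrow(rs)
      rss <- max(o$rss, .Machine$double.eps *
                   max(sum((rs$intensity - mean(rs$intensity))^2), 1))
      n * log(rss / n) + 2 * (length(s) + 1)
    }, numeric(1))
    pkg_aic <- vapply(models, `[[`, numeric(1), "aic")
    # same subsets, same scores (order-independent comparison)
    key <- vapply(all_supports(), function(s) {
      paste(as.integer(phospho_sites() %in% s), collapse = "")
    }, character(1))
    expect_equal(unname(pkg_aic[key]), unname(oracle_aic), tolerance = 1e-9)
    # and the best model is the brute-force argmin
    best <- rank_models(models)[[1]]
    expect_equal(best$aic, min(oracle_aic), tolerance = 1e-9)
  }
})

test_that("nested subsets have monotone rss", {
  rs <- random_responses(n_patterns = 40, seed = 8)
  models <- fit_all_subsets(rs)
  rss <- vapply(models, `[[`, numeric(1), "rss")
  supp <- lapply(models, `[[`, "support")
  set.seed(8)
  for (i in sample(length(models), 40)) {
    for (j in sample(length(models), 10)) {
      if (all(supp[[j]] %in% supp[[i]]) && length(supp[[j]]) < length(supp[[i]])) {
        expect_lte(rss[i], rss[j] + 1e-9)
      }
    }
  }
})

test_that("the AIC-best support equals the true support at sigma=0", {
  sites <- phospho_sites()
  set.seed(123)
  for (rep in 1:50) {
    k <- sample(1:5, 1)
    support <- sort(sample(sites, k))
    theta <- setNames(numeric(7), sites)
    theta[support] <- runif(k, 50, 500) # all true effects > 0
    truth <- array_ground_truth(theta = theta,
                                intercept = runif(1, 0, 300), noise_sd = 0)
    rs <- average_replicates(gen_array(truth, seed = rep))
    best <- rank_models(fit_all_subsets(rs))[[1]]
    expect_identical(sort(best$support), support)
  }
})

test_that("coefficient recovery error shrinks as noise shrinks", {
  sites <- phospho_sites()
  theta <- setNames(c(50, 400, 50, 400, 900, 60, 800), sites)
  err_at <- function(sd) {
    errs <- vapply(1:5, function(s) {
      truth <- array_ground_truth(theta = theta, intercept = 500,
                                  noise_sd = sd)
      rs <- average_replicates(gen_array(truth, seed = s))
      fit <- fit_subset(rs, sites)
      mean(abs(fit$coefficients[sites] - theta))
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(200), err_at(20), err_at(2))
  expect_true(all(diff(e) < 0))
  expect_lt(e[3], 1)
})

test_that("importance_matrix reports top-k coefficients with zeros", {
  truth <- array_ground_truth(noise_sd = 50)
  rs <- average_replicates(gen_array(truth, seed = 2))
  models <- fit_all_subsets(rs)
  im <- importance_matrix(models, k = 20)
  expect_equal(dim(im$matrix), c(20, 8))
  aics <- vapply(im$models, `[[`, numeric(1), "aic")
  expect_true(!is.unsorted(aics))
  # excluded sites are exactly zero
  for (i in 1:20) {
    excl <- setdiff(phospho_sites(), im$models[[i]]$support)
    expect_true(all(im$matrix[i, excl] == 0))
  }
  # k = 1: the single best model's coefficients
  im1 <- importance_matrix(models, k = 1)
  best <- rank_models(models)[[1]]
  expect_equal(unname(im1$matrix[1, best$support]),
               unname(best$coefficients))
  expect_error(importance_matrix(models, k = 500), "exceeds")
})

test_that("dominant sites occupy the top-20 models at small noise", {
  # two dominant sites: present in >= 90% of the top-20 model supports
  sites <- phospho_sites()
  theta <- setNames(c(0, 0, 0, 0, 900, 0, 800), sites)
  hits <- vapply(1:5, function(s) {
    truth <- array_ground_truth(theta = theta, intercept = 200,
                                noise_sd = 20)
    rs <- average_replicates(gen_array(truth, seed = s))
    im <- importance_matrix(fit_all_subsets(rs), k = 20)
    mean(im$matrix[, "T340"] != 0 & im$matrix[, "S343"] != 0)
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})

test_that("threshold_robustness filters, refits and stays stable", {
  truth <- array_ground_truth(noise_sd = 50)
  spots <- gen_array(truth, seed = 31)
  rs <- average_replicates(spots)

  tr <- threshold_robustness(spots, thresholds = c(0, 600, 1e6))
  expect_error(threshold_robustness(spots, c(100, 0)), "ascending")

  # threshold 0 reproduces the unfiltered analysis
  unfiltered <- aggregate_importance(fit_all_subsets(rs))
  expect_equal(tr[[1]]$importance, unfiltered)
  expect_true(tr[[1]]$feasible)
  # absurd threshold is infeasible, not fatal
  expect_false(tr[[3]]$feasible)
  expect_null(tr[[3]]$ranking)
  # the two dominant sites stay on top across feasible thresholds
  for (el in tr[c(1, 2)]) {
    expect_true(el$feasible && el$n_patterns >= 30)
    expect_setequal(el$ranking[1:2], c("T340", "S343"))
  }
})

test_that("model and importance tables export to TSV", {
  rs <- random_responses(30, seed = 10)
  models <- fit_all_subsets(rs)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_models_tsv(models, f1)
  tab <- read.delim(f1, colClasses = c(support = "character"))
  expect_equal(nrow(tab), 128)
  expect_true(all(c("support", "aic", "rss", "intercept", "T340") %in%
                    names(tab)))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_importance_matrix(importance_matrix(models, 20), f2)
  tab2 <- read.delim(f2, check.names = FALSE,
                     colClasses = c(support = "character"))
  expect_equal(dim(tab2), c(20, 10)) # support + aic + 7 sites + intercept
})
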