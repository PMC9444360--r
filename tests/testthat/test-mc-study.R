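test_that("study design validates inputs and round-trips through YAML", {
  d <- study_design(reps = 100, sample_sizes = c(20, 40), seed = 9)
  expect_s3_class(d, "lomax_study_design")
  expect_error(study_design(reps = 0), "positive integer")
  expect_error(study_design(cases = list(I = c(scale = -1, shape = 2))),
               "positive")
  expect_error(study_design(a_values = c(0.5, -1)), "positive")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_design(d, path)
  d2 <- read_study_design(path)
  expect_equal(d2, d)
})

test_that("a single-replicate cell equals the hand-recomputed estimates", {
  d <- study_design(reps = 1, sample_sizes = 20,
                    cases = list(II = c(scale = 2, shape = 2)), seed = 33)
  tab <- run_study(d)

  # regenerate the one sample from the cell's derived seed, then apply the
  # public per-sample estimators
  set.seed(lomaxshape:::cell_seed(33L, 1L, 20L))
  u <- runif(20)
  x <- 2 * ((1 - u)^(-1 / 2) - 1)
  s <- lomax_suffstat(x, 2)
  cell <- function(est) tab$mse[tab$estimator == est]

  expect_equal(cell("mle"), (est_mle(s) - 2)^2)
  expect_equal(cell("umvue"), (est_umvue(s) - 2)^2)
  expect_equal(cell("ols"), (est_ols(x, 2, "median_rank") - 2)^2)
  expect_equal(cell("ridge"), (est_ridge(x, 2, "median_rank", 0.75) - 2)^2)
  expect_equal(cell("median"), (est_median(x, 2) - 2)^2)
  expect_equal(cell("gamma_self"),
               (est_bayes(s, lomax_prior("gamma"), "self") - 2)^2)
  expect_equal(cell("chisq_llf_a1"),
               (est_bayes(s, lomax_prior("chi_square"), "linex", 1) - 2)^2)
  expect_equal(cell("ilevy_cllf_a1.5"),
               (est_bayes(s, lomax_prior("inverted_levy"), "clinex", 1.5) - 2)^2)
  expect_equal(cell("ej_llf_a0.5"),
               (est_bayes(s, lomax_prior("extended_jeffreys"), "linex", 0.5) - 2)^2)
})

test_that("identical seed and design give bitwise-identical results", {
  d <- study_design(reps = 50, sample_sizes = c(20, 40), seed = 4)
  expect_identical(run_study(d)$mse, run_study(d)$mse)
})

test_that("study columns obey the structural identities", {
  d <- study_design(reps = 400, sample_sizes = c(20, 60, 100), seed = 2)
  tab <- run_study(d)
  for (cs in unique(tab$case)) for (n in unique(tab$n)) {
    sub <- tab[tab$case == cs & tab$n == n, ]
    # extended Jeffreys at c = 0.5 under SELF is the MLE
    expect_identical(sub$mse[sub$estimator == "mle"],
                     sub$mse[sub$estimator == "ej_self"])
    expect_lte(sub$mse[sub$estimator == "umvue"],
               sub$mse[sub$estimator == "mle"])
  }
  # MSE shrinks with n (one MC-noise violation allowed per column)
  for (cs in unique(tab$case)) for (e in unique(tab$estimator)) {
    col <- tab[tab$case == cs & tab$estimator == e, ]
    col <- col[order(col$n), ]
    expect_lte(sum(diff(col$mse) > 0), 1)
  }
  # MSE grows with the true shape at fixed n and estimator
  for (e in c("mle", "umvue", "gamma_self")) {
    col <- tab[tab$n == 20 & tab$estimator == e, ]
    col <- col[order(col$shape), ]
    expect_true(all(diff(col$mse) > 0))
  }
})

test_that("an estimator failing on a replicate aborts with a diagnostic", {
  d <- study_design(cases = list(I = c(scale = 2, shape = 2.5)),
                    sample_sizes = 2, reps = 20, a_values = 25, seed = 1)
  expect_error(run_study(d), "composite-LINEX.*replicate")
})

test_that("table writer emits the full per-prior layout and refuses gaps", {
  d <- study_design(reps = 25, sample_sizes = c(20, 40), seed = 6)
  tab <- run_study(d)
  dir <- withr::local_tempdir()
  paths <- write_mse_tables(tab, dir)
  expect_length(paths, 6)

  cl <- read.csv(file.path(dir, "mse_classical.csv"), check.names = FALSE)
  expect_identical(names(cl), c("case", "n", "MLE", "OLS", "Rid", "UMVUE", "Med"))
  expect_equal(cl$UMVUE[cl$case == "I" & cl$n == 20],
               tab$mse[tab$case == "I" & tab$n == 20 & tab$estimator == "umvue"])

  for (fam in c("extended_jeffreys", "chi_square", "inverted_levy", "gamma")) {
    w <- read.csv(file.path(dir, paste0("mse_", fam, ".csv")), check.names = FALSE)
    expect_identical(names(w),
                     c("case", "n", "SELF", "LLF a=0.5", "LLF a=1", "LLF a=1.5",
                       "CLLF a=0.5", "CLLF a=1", "CLLF a=1.5"))
  }
  gm <- read.csv(file.path(dir, "mse_gamma.csv"), check.names = FALSE)
  expect_equal(gm[["CLLF a=1.5"]][gm$case == "II" & gm$n == 40],
               tab$mse[tab$case == "II" & tab$n == 40 &
                       tab$estimator == "gamma_cllf_a1.5"])
  expect_true(file.exists(file.path(dir, "mse_report.md")))

  broken <- tab[tab$estimator != "ols", ]
  attr(broken, "design") <- attr(tab, "design")
  class(broken) <- class(tab)
  expect_error(write_mse_tables(broken, dir), "incomplete")
})
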