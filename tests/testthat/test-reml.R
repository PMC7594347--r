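small_dataset <- function(seed = 1, n_t = 2, n_c = 2, per_cg = 3) {
  ped <- random_pedigree(n = 28, n_founders = 6, seed = seed)
  r <- tiny_records(ped, n_t = n_t, n_c = n_c, per_cg = per_cg, seed = seed)
  study_dataset(r, ped)
}

test_that("MME block layout matches the design", {
  ped <- new_pedigree(c("A1", "A2"), c(NA, NA), c(NA, NA))
  r <- data.frame(animal = c("A1", "A2"), breed = "ANGUS", trait = "LMA",
                  value = c(80, 85), technician = "T1", cg = "C1", lab = "1",
                  age_days = 400L)
  mme <- assemble_mme(study_dataset(r, ped),
                      vc = variance_components(1, 1, 1, 1))
  expect_equal(nrow(mme$C), 1 + 1 + 1 + 2)
  expect_equal(length(mme$layout$a), 2)
})

test_that("sparse REML likelihood equals the dense oracle up to log|A|", {
  for (seed in 1:4) {
    ds <- small_dataset(seed = seed)
    A <- build_A(ds$pedigree)
    Ainv <- build_A_inverse(ds$pedigree, include_inbreeding = TRUE)
    ldetA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
    for (vc in list(variance_components(50, 120, 20, 35),
                    variance_components(5, 8, 60, 12))) {
      dense <- dense_neg2_loglik(ds$records, ds$pedigree, A, vc)
      sparse <- reml_neg2_loglik(vc, ds, Ainv)
      expect_equal(sparse + ldetA, dense, tolerance = 1e-6)
    }
  }
})

test_that("MME solutions equal dense GLS/BLUP and EBVs match", {
  ds <- small_dataset(seed = 7)
  A <- build_A(ds$pedigree)
  Ainv <- build_A_inverse(ds$pedigree, include_inbreeding = TRUE)
  vc <- variance_components(40, 90, 25, 30)
  mme <- assemble_mme(ds, Ainv, vc)
  sol <- as.numeric(Matrix::solve(mme$C, mme$rhs))
  oracle <- dense_blup(ds$records, ds$pedigree, A, vc)
  expect_equal(sol[mme$layout$mu], oracle$mu, tolerance = 1e-8)
  expect_equal(sol[mme$layout$t], oracle$t, tolerance = 1e-8)
  expect_equal(sol[mme$layout$c], oracle$c, tolerance = 1e-8)
  expect_equal(sol[mme$layout$a], oracle$a, tolerance = 1e-8)
  ebv <- solve_ebv(ds, Ainv, vc)
  expect_equal(ebv$ebv, oracle$a, tolerance = 1e-8)
})

test_that("huge technician/CG variances approach fixed-effect solutions", {
  ds <- small_dataset(seed = 3, n_t = 2, n_c = 3)
  Ainv <- build_A_inverse(ds$pedigree)
  vc <- variance_components(1e8, 1e8, 1e-8, 30)
  mme <- assemble_mme(ds, Ainv, vc)
  sol <- as.numeric(Matrix::solve(mme$C, mme$rhs))
  l <- mme$layout
  r <- ds$records
  fitted_mme <- sol[l$mu] + sol[l$t][match(r$technician, l$technicians)] +
    sol[l$c][match(r$cg, l$cgs)] +
    sol[l$a][match(r$animal, l$animals)]
  fitted_lm <- stats::fitted(stats::lm(value ~ technician + cg, data = r))
  expect_equal(fitted_mme, unname(fitted_lm), tolerance = 1e-4)
})

test_that("likelihood obeys the exact scale transformation", {
  ds <- small_dataset(seed = 5)
  Ainv <- build_A_inverse(ds$pedigree)
  vc <- variance_components(40, 90, 25, 30)
  base <- reml_neg2_loglik(vc, ds, Ainv)
  k <- 2.5
  ds2 <- ds
  ds2$records$value <- k * ds$records$value
  scaled <- reml_neg2_loglik(k^2 * vc, ds2, Ainv)
  n <- nrow(ds$records)
  expect_equal(scaled - base, (n - 1) * log(k^2), tolerance = 1e-8)
})

test_that("likelihood is invariant to record order and id relabeling", {
  ds <- small_dataset(seed = 2)
  Ainv <- build_A_inverse(ds$pedigree)
  vc <- variance_components(40, 90, 25, 30)
  base <- reml_neg2_loglik(vc, ds, Ainv)
  perm <- sample(nrow(ds$records))
  ds_perm <- study_dataset(ds$records[perm, , drop = FALSE], ds$pedigree)
  expect_equal(reml_neg2_loglik(vc, ds_perm, Ainv), base, tolerance = 1e-9)
  relab <- ds$records
  relab$technician <- paste0("ZZ_", relab$technician)
  relab$cg <- chartr("TC", "qz", relab$cg)
  ds_relab <- study_dataset(relab, ds$pedigree)
  expect_equal(reml_neg2_loglik(vc, ds_relab, Ainv), base, tolerance = 1e-9)
})

test_that("REML estimates agree with lme4 on a pedigree-free three-way design", {
  skip_if_not_installed("lme4")
  set.seed(21)
  n_t <- 4; n_c <- 3; n_an <- 30; n_obs <- 180
  an_ids <- sprintf("A%02d", 1:n_an)
  r <- data.frame(
    animal = sample(an_ids, n_obs, replace = TRUE),
    breed = "ANGUS", trait = "LMA",
    technician = sample(paste0("T", 1:n_t), n_obs, replace = TRUE),
    age_days = 400L, stringsAsFactors = FALSE)
  r$cg <- paste0(r$technician, "C", sample(1:n_c, n_obs, replace = TRUE))
  r$lab <- "1"
  t_eff <- stats::rnorm(n_t, 0, 3)
  c_eff <- stats::setNames(stats::rnorm(n_t * n_c, 0, 4),
                           as.vector(outer(paste0("T", 1:n_t),
                                           paste0("C", 1:n_c), paste0)))
  a_eff <- stats::setNames(stats::rnorm(n_an, 0, 2.5), an_ids)
  r$value <- 80 + t_eff[as.integer(factor(r$technician))] + c_eff[r$cg] +
    a_eff[r$animal] + stats::rnorm(n_obs, 0, 3)
  ped <- new_pedigree(an_ids, rep(NA, n_an), rep(NA, n_an))  # A = I
  ds <- study_dataset(r, ped)
  fit <- fit_univariate(ds, options = reml_options(n_restarts = 1))
  lmm <- lme4::lmer(value ~ (1 | technician) + (1 | cg) + (1 | animal),
                    data = r, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(lmm))
  ref <- stats::setNames(vcs$vcov, vcs$grp)
  expect_equal(fit$vc[["sigma2_t"]], ref[["technician"]], tolerance = 0.02)
  expect_equal(fit$vc[["sigma2_c"]], ref[["cg"]], tolerance = 0.02)
  expect_equal(fit$vc[["sigma2_a"]], ref[["animal"]], tolerance = 0.02)
  expect_equal(fit$vc[["sigma2_e"]], ref[["Residual"]], tolerance = 0.02)
  expect_equal(fit$mu_hat, unname(lme4::fixef(lmm)[1]), tolerance = 1e-3)
})

test_that("restarts from perturbed components converge to one optimum", {
  cfg <- sim_config_angus_lab1(seed = 31, technicians_per_lab = 5,
                               cgs_per_technician = 4, animals_per_cg = 6)
  ds <- simulate_dataset(cfg)
  Ainv <- build_A_inverse(ds$pedigree)
  fit <- fit_univariate(ds, Ainv,
                        options = reml_options(tol = 1e-13, n_restarts = 2,
                                               restart_factors = c(0.5, 2)))
  expect_true(fit$converged)
  expect_lt(fit$restart_spread, 1e-6)
})

test_that("a zero technician variance is recovered at the boundary", {
  cfg <- sim_config_angus_lab1(seed = 8, technicians_per_lab = 15,
                               cgs_per_technician = 6, animals_per_cg = 6,
                               sigma2_t = 1e-12)
  ds <- simulate_dataset(cfg)
  fit <- fit_univariate(ds, options = reml_options(n_restarts = 0))
  vp <- sum(fit$vc)
  expect_lt(fit$vc[["sigma2_t"]] / vp, 0.05)
})

test_that("EBV accuracies respond to progeny information", {
  # two founder sires: one with 12 recorded progeny, one with a single one
  n_prog <- 13
  ids <- c("SBIG", "SONE", sprintf("P%02d", 1:n_prog))
  p1 <- c(NA, NA, rep("SBIG", 12), "SONE")
  ped <- new_pedigree(ids, p1, rep(NA_character_, length(ids)))
  set.seed(12)
  r <- data.frame(animal = sprintf("P%02d", 1:n_prog), breed = "ANGUS",
                  trait = "LMA", value = stats::rnorm(n_prog, 80, 8),
                  technician = "T1",
                  cg = rep(c("C1", "C2"), length.out = n_prog), lab = "1",
                  age_days = 400L)
  ds <- study_dataset(r, ped)
  ebv <- solve_ebv(ds, vc = variance_components(1, 1, 20, 30))
  acc <- stats::setNames(ebv$accuracy, ebv$animal)
  expect_gt(acc[["SBIG"]], acc[["SONE"]])
  # an unconnected founder has nothing to borrow: EBV 0, accuracy 0
  ped2 <- new_pedigree(c(ids, "LONER"), c(p1, NA), rep(NA, length(ids) + 1))
  ebv2 <- solve_ebv(study_dataset(r, ped2), vc = variance_components(1, 1, 20, 30))
  loner <- ebv2[ebv2$animal == "LONER", ]
  expect_equal(loner$ebv, 0, tolerance = 1e-10)
  expect_equal(loner$accuracy, 0, tolerance = 1e-6)
})

test_that("component covariance yields finite delta-method SEs", {
  cfg <- sim_config_angus_lab1(seed = 19, technicians_per_lab = 5,
                               cgs_per_technician = 4, animals_per_cg = 6)
  ds <- simulate_dataset(cfg)
  fit <- fit_univariate(ds, options = reml_options(n_restarts = 1))
  ps <- partition_summary(fit)
  expect_equal(sum(ps$percents), 100, tolerance = 1e-8)
  expect_true(all(is.finite(ps$percent_se)))
  expect_true(all(ps$percent_se > 0))
  expect_true(ps$h2 >= 0 && ps$h2 <= 1)
  expect_true(is.finite(ps$h2_se) && ps$h2_se > 0)
  # within-CG heritability exceeds the additive share of total variance
  expect_gte(ps$h2, ps$percents[["sigma2_a"]] / 100)
})
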