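test_that("heritability and percentage partitions reproduce published cells", {
  # Angus LMA lab 1 and Angus IMF lab 2 from the published component tables
  expect_equal(round(heritability(16.87, 35.06), 2), 0.32)
  expect_equal(round(heritability(0.52, 0.26), 2), 0.67)
  expect_equal(heritability(0, 1), 0)
  expect_error(heritability(0, 0), "zero")

  pct <- variance_percentages(variance_components(53.98, 124.13, 16.87, 35.06))
  expect_equal(unname(round(pct)), c(23, 54, 7, 15))
  pct2 <- variance_percentages(variance_components(1.15, 1.58, 1.43, 1.59))
  expect_equal(unname(round(pct2)), c(20, 27, 25, 28))
  expect_equal(unname(variance_percentages(variance_components(1, 1, 1, 1))),
               rep(25, 4))
  expect_equal(sum(pct), 100)
})

test_that("range-over-mean dispersion matches published laboratory spreads", {
  expect_equal(round(dispersion_range_over_mean(c(16.87, 16.65, 17.41)), 1),
               4.5)   # Angus LMA additive variance across labs
  expect_equal(round(dispersion_range_over_mean(c(0.27, 0.13, 0.32)), 1),
               79.2)  # Hereford IMF residual variance across labs
  expect_equal(dispersion_range_over_mean(c(3, 3, 3)), 0)
  expect_error(dispersion_range_over_mean(5), "two")
  expect_error(dispersion_range_over_mean(c(-2, 2)), "positive")
})

test_that("CG-mean correction yields technician-grouped residuals", {
  r <- data.frame(value = c(4, 6, 5, 5, 9, 1, 7),
                  cg = c("a", "a", "b", "b", "c", "c", "d"),
                  technician = c("t1", "t1", "t1", "t1", "t2", "t2", "t2"))
  rw <- residuals_within_technician(r)
  expect_equal(rw$groups$t1, c(-1, 1, 0, 0))
  expect_equal(rw$groups$t2, c(4, -4))
  expect_equal(rw$n_singleton_dropped, 1)  # the singleton CG "d"
  expect_equal(sum(lengths(rw$groups)), 6)

  const <- data.frame(value = rep(5, 4), cg = c("a", "a", "b", "b"),
                      technician = "t1")
  expect_true(all(unlist(residuals_within_technician(const)$groups) == 0))
})

test_that("Bartlett statistic agrees with the hand-computed formula", {
  set.seed(11)
  groups <- list(g1 = rnorm(5), g2 = rnorm(5, sd = 2), g3 = rnorm(7, sd = 0.5))
  out <- bartlett_homogeneity(groups)
  # textbook Bartlett with Box correction, computed from first principles
  ni <- lengths(groups)
  si2 <- vapply(groups, var, numeric(1))
  N <- sum(ni); k <- length(groups)
  sp2 <- sum((ni - 1) * si2) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ni - 1) * log(si2))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(out$statistic, stat, tolerance = 1e-12)
  expect_equal(out$df, k - 1)
  expect_equal(out$p_value, pchisq(stat, k - 1, lower.tail = FALSE))

  same <- list(a = c(1, 2, 3), b = c(4, 5, 6))  # identical sample variances
  out2 <- bartlett_homogeneity(same)
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$p_value, 1)

  degen <- list(a = c(1, 1, 1), b = c(1, 2, 3))
  out3 <- bartlett_homogeneity(degen)
  expect_true(out3$zero_variance_group)
  expect_equal(out3$p_value, 0)
  expect_error(bartlett_homogeneity(list(a = 1:3)), "two groups")
})

test_that("genetic-correlation SE reduces to the classical form and obeys monotonicity", {
  # at unit accuracies: sqrt((1 - 2 rg^2 + rg^4)/(N-1)) = (1 - rg^2)/sqrt(N-1)
  for (rg in c(0, 0.3, 0.7, 0.95)) for (N in c(10, 100)) {
    expect_equal(se_genetic_correlation(rg, 1, 1, N),
                 (1 - rg^2) / sqrt(N - 1), tolerance = 1e-12)
  }
  expect_equal(se_genetic_correlation(1, 1, 1, 50), 0)
  expect_equal(se_genetic_correlation(0, 0.8, 0.8, 401),
               sqrt((1 / 0.4096) / 400), tolerance = 1e-12)
  # decreasing in N and in each accuracy for fixed rg in [0, 1)
  rg <- 0.6
  se_n <- vapply(c(10, 50, 200, 1000),
                 function(N) se_genetic_correlation(rg, 0.7, 0.7, N),
                 numeric(1))
  expect_true(all(diff(se_n) < 0))
  se_acc <- vapply(c(0.3, 0.5, 0.7, 0.9, 1),
                   function(a) se_genetic_correlation(rg, a, 0.8, 100),
                   numeric(1))
  expect_true(all(diff(se_acc) < 0))
  expect_error(se_genetic_correlation(0.9, 1, 1, 1), "two common sires")
  expect_error(se_genetic_correlation(0.9, 0, 1, 10), "accuracies")
})

test_that("z-test against 1 flags the published starred and unstarred cells", {
  unstarred <- rg_z_test(0.94, 0.04)  # Angus LMA labs 1-2
  expect_equal(unstarred$z, -1.5)
  expect_false(unstarred$reject)
  starred <- rg_z_test(0.78, 0.06)    # Simmental LMA labs 1-2
  expect_equal(starred$z, -3.6667, tolerance = 1e-4)
  expect_true(starred$reject)
  expect_equal(rg_z_test(1, 0.05)$z, 0)
  degen <- rg_z_test(0.9, 0)
  expect_true(degen$reject)
  expect_true(degen$infinite_z)
  expect_false(rg_z_test(1, 0)$reject)
})

test_that("Spearman EBV correlation uses average-rank ties on common sires", {
  x <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5)
  expect_equal(spearman_ebv_correlation(x, x)$rho, 1)
  expect_equal(spearman_ebv_correlation(
    x, stats::setNames(rev(unname(x)) * 2, names(x)))$rho, -1)
  # hand example with one tie: rank-then-Pearson oracle
  y <- c(s1 = 10, s2 = 10, s3 = 30, s4 = 25, s5 = 50, s9 = 1)
  sp <- spearman_ebv_correlation(x, y)
  expect_equal(sp$n_common, 5)
  common <- paste0("s", 1:5)
  expect_equal(sp$rho, stats::cor(rank(x[common]), rank(y[common])))
  expect_error(spearman_ebv_correlation(x[1:2], y), "three common")
})

test_that("genetic correlation arithmetic and scale invariance", {
  G0 <- diag(3)
  expect_equal(genetic_correlation(G0, 1, 2), 0)
  G <- matrix(c(4, 5.4, 5.4, 9), 2, 2)
  expect_equal(genetic_correlation(G, 1, 2), 0.9)
  k <- 3.7
  Gk <- G
  Gk[1, 1] <- k^2 * G[1, 1]
  Gk[1, 2] <- Gk[2, 1] <- k * G[1, 2]
  expect_equal(genetic_correlation(Gk, 1, 2), genetic_correlation(G, 1, 2))
  expect_error(genetic_correlation(matrix(0, 2, 2), 1, 2), "positive")
})
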