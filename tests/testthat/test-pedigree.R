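test_that("pedigree construction orders parents first and rejects bad input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "C,A,B", "A,0,0", "B,0,0"), tmp)
  ped <- read_pedigree(tmp)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_gt(match("C", ped$animal), max(match(c("A", "B"), ped$animal)))

  writeLines(c("animal,sire,dam", "A,B,0", "B,A,0"), tmp)
  expect_error(read_pedigree(tmp), "cycle")
  writeLines(c("animal,sire,dam", "A,0,0", "A,0,0"), tmp)
  expect_error(read_pedigree(tmp), "duplicate")

  # ancestors referenced without their own rows become founders
  ped2 <- new_pedigree("X", "S", "D")
  expect_equal(sort(ped2$animal), c("D", "S", "X"))
  expect_true(all(is.na(ped2$parent1[ped2$animal != "X"])))
})

test_that("pedigree CSV round-trips a simulated three-generation fixture", {
  cfg <- sim_config_angus_lab1(seed = 5, technicians_per_lab = 2,
                               cgs_per_technician = 2, animals_per_cg = 3,
                               generations = 3)
  ped <- simulate_pedigree(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, tmp)
  again <- read_pedigree(tmp)
  expect_equal(as.data.frame(again), as.data.frame(ped), ignore_attr = TRUE)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(again, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("inbreeding coefficients match textbook cases", {
  expect_equal(unname(inbreeding_coefficients(
    new_pedigree(c("A", "B"), c(NA, NA), c(NA, NA)))), c(0, 0))
  # offspring of full sibs
  full_sib <- new_pedigree(c("X", "Y", "K"), c("S", "S", "X"),
                           c("D", "D", "Y"))
  expect_equal(inbreeding_coefficients(full_sib)[["K"]], 0.25)
  # offspring of a parent-offspring mating
  po <- new_pedigree(c("X", "K"), c("S", "S"), c("D", "X"))
  expect_equal(inbreeding_coefficients(po)[["K"]], 0.25)
  # sire-mgs mode: inbreeding not tracked
  mgs <- new_pedigree(c("X", "K"), c("S", "S"), c("G", "X"),
                      mode = "sire_mgs")
  expect_equal(unname(inbreeding_coefficients(mgs)), rep(0, nrow(mgs)))
})

test_that("dense A reproduces defining relationships in both modes", {
  expect_equal(build_A(new_pedigree(c("A", "B"), c(NA, NA), c(NA, NA))),
               diag(2), ignore_attr = TRUE)
  po <- build_A(new_pedigree("X", "S", NA))
  expect_equal(po["X", "S"], 0.5)
  sibs <- new_pedigree(c("F", "H"), c("S", "S"), c("D", "D2"))
  A <- build_A(sibs)
  expect_equal(A["F", "H"], 0.25)  # half sibs (dams differ)
  fs <- build_A(new_pedigree(c("F", "H"), c("S", "S"), c("D", "D")))
  expect_equal(fs["F", "H"], 0.5)  # full sibs
  Am <- build_A(new_pedigree("X", "S", "G", mode = "sire_mgs"))
  expect_equal(Am["X", "S"], 0.5)
  expect_equal(Am["X", "G"], 0.25)
  expect_equal(diag(Am), rep(1, 3), ignore_attr = TRUE)
})

test_that("Henderson trio inverse matches hand-derived entries", {
  trio <- new_pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  Ai <- as.matrix(build_A_inverse(trio))
  expect_equal(diag(Ai), c(1.5, 1.5, 2.0), ignore_attr = TRUE)
  expect_equal(Ai["A", "C"], -1)
  expect_equal(Ai["B", "C"], -1)
  expect_equal(Ai["A", "B"], 0.5)
  expect_equal(as.matrix(build_A_inverse(
    new_pedigree(c("A", "B"), c(NA, NA), c(NA, NA)))), diag(2),
    ignore_attr = TRUE)
})

test_that("A times its Henderson inverse is the identity on random pedigrees", {
  for (seed in 1:6) {
    ped <- random_pedigree(n = sample(8:30, 1), n_founders = 4, seed = seed)
    A <- build_A(ped)
    expect_gt(min(eigen(A, only.values = TRUE)$values), 0)
    # default inverse assumes non-inbred parents: it inverts the implied
    # gene-flow covariance with fixed Mendelian-sampling variances
    Ai0 <- as.matrix(build_A_inverse(ped, include_inbreeding = FALSE))
    A0 <- build_A_implied(ped)
    expect_lt(max(abs(A0 %*% Ai0 - diag(nrow(A0)))), 1e-9)
    # with inbreeding the sparse inverse matches the dense inverse of A
    Ai1 <- as.matrix(build_A_inverse(ped, include_inbreeding = TRUE))
    expect_lt(max(abs(Ai1 - solve(A))), 1e-9)
  }
})

test_that("sire-mgs Henderson inverse matches dense inversion", {
  set.seed(9)
  n <- 20
  ids <- sprintf("M%02d", 1:n)
  p1 <- p2 <- rep(NA_character_, n)
  for (i in 6:n) {
    p1[i] <- ids[sample.int(i - 1, 1)]
    if (stats::runif(1) > 0.3) {
      cand <- setdiff(ids[seq_len(i - 1)], p1[i])
      p2[i] <- sample(cand, 1)
    }
  }
  ped <- new_pedigree(ids, p1, p2, mode = "sire_mgs")
  A <- build_A_implied(ped)
  Ai <- as.matrix(build_A_inverse(ped))
  expect_lt(max(abs(A %*% Ai - diag(n))), 1e-9)
  # on pedigrees whose sires and maternal grandsires are unrelated the
  # display matrix (unit diagonal) agrees with the implied covariance
  flat <- new_pedigree(c(sprintf("X%02d", 1:6)),
                       c(NA, NA, NA, NA, "X01", "X02"),
                       c(NA, NA, NA, NA, "X03", "X04"), mode = "sire_mgs")
  expect_equal(build_A(flat), build_A_implied(flat), tolerance = 1e-12)
})

test_that("sparse inverse export writes 0-based lower-triangle triplets", {
  trio <- new_pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  Ai <- build_A_inverse(trio)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_A_inverse(Ai, tmp)
  trip <- utils::read.table(tmp, col.names = c("i", "j", "value"))
  expect_true(all(trip$i >= trip$j))
  expect_true(all(trip$i >= 0 & trip$j >= 0))
  dense <- matrix(0, 3, 3)
  dense[cbind(trip$i + 1, trip$j + 1)] <- trip$value
  dense[upper.tri(dense)] <- t(dense)[upper.tri(dense)]
  expect_equal(dense, as.matrix(Ai), ignore_attr = TRUE)
})
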