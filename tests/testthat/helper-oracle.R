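# Dense oracles and small random generators shared across tests.

# random acyclic pedigree: first `n_founders` animals are founders, later
# animals draw parents uniformly among earlier ones (or unknown)
random_pedigree <- function(n, n_founders = 5, p_unknown = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n))
  p1 <- p2 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    if (stats::runif(1) > p_unknown) p1[i] <- ids[sample.int(i - 1, 1)]
    if (stats::runif(1) > p_unknown) p2[i] <- ids[sample.int(i - 1, 1)]
    if (!is.na(p1[i]) && identical(p1[i], p2[i])) p2[i] <- NA_character_
  }
  new_pedigree(ids, p1, p2)
}

# dense design matrices for a univariate record set
dense_design <- function(records, ped) {
  n <- nrow(records)
  tech <- factor(records$technician)
  cg <- factor(records$cg)
  an <- factor(records$animal, levels = ped$animal)
  Zt <- matrix(0, n, nlevels(tech)); Zt[cbind(1:n, as.integer(tech))] <- 1
  Zc <- matrix(0, n, nlevels(cg)); Zc[cbind(1:n, as.integer(cg))] <- 1
  Za <- matrix(0, n, nrow(ped)); Za[cbind(1:n, as.integer(an))] <- 1
  list(X = matrix(1, n, 1), Zt = Zt, Zc = Zc, Za = Za, y = records$value)
}

# -2 restricted log-likelihood from the dense covariance, full constant
# except the 2*pi term
dense_neg2_loglik <- function(records, ped, A, vc) {
  d <- dense_design(records, ped)
  V <- vc[["sigma2_t"]] * tcrossprod(d$Zt) +
    vc[["sigma2_c"]] * tcrossprod(d$Zc) +
    vc[["sigma2_a"]] * d$Za %*% A %*% t(d$Za) +
    vc[["sigma2_e"]] * diag(nrow(d$X))
  Vi <- solve(V)
  XVX <- t(d$X) %*% Vi %*% d$X
  P <- Vi - Vi %*% d$X %*% solve(XVX) %*% t(d$X) %*% Vi
  as.numeric(determinant(V, logarithm = TRUE)$modulus +
               determinant(XVX, logarithm = TRUE)$modulus +
               t(d$y) %*% P %*% d$y)
}

# GLS fixed effect and BLUP random effects from the dense covariance
dense_blup <- function(records, ped, A, vc) {
  d <- dense_design(records, ped)
  V <- vc[["sigma2_t"]] * tcrossprod(d$Zt) +
    vc[["sigma2_c"]] * tcrossprod(d$Zc) +
    vc[["sigma2_a"]] * d$Za %*% A %*% t(d$Za) +
    vc[["sigma2_e"]] * diag(nrow(d$X))
  Vi <- solve(V)
  XVX <- t(d$X) %*% Vi %*% d$X
  beta <- solve(XVX, t(d$X) %*% Vi %*% d$y)
  resid <- d$y - d$X %*% beta
  list(mu = as.numeric(beta),
       t = as.numeric(vc[["sigma2_t"]] * t(d$Zt) %*% Vi %*% resid),
       c = as.numeric(vc[["sigma2_c"]] * t(d$Zc) %*% Vi %*% resid),
       a = as.numeric(vc[["sigma2_a"]] * A %*% t(d$Za) %*% Vi %*% resid))
}

# small single-lab record set with genuinely nested structure over a random
# pedigree; n records over n_t technicians x n_c CGs each
tiny_records <- function(ped, n_t = 2, n_c = 2, per_cg = 3, seed = 1,
                         lab = "1") {
  set.seed(seed)
  rows <- list()
  recorded <- utils::tail(ped$animal, n_t * n_c * per_cg)
  k <- 0
  for (te in seq_len(n_t)) for (cg in seq_len(n_c)) for (j in seq_len(per_cg)) {
    k <- k + 1
    rows[[k]] <- data.frame(
      animal = recorded[k], breed = "ANGUS", trait = "LMA",
      value = stats::rnorm(1, 78, 8),
      technician = paste0("T", te),
      cg = paste0("T", te, "C", cg), lab = lab,
      age_days = 400L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Covariance structure T D T' that the Henderson sparse inverse inverts
# exactly when inbreeding is ignored: the gene-flow recurrence with fixed
# Mendelian-sampling variances. Its diagonal exceeds 1 when an animal's
# parents are related, unlike the unit-diagonal display convention.
build_A_implied <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$animal
  p1 <- unname(idx[ped$parent1]); p2 <- unname(idx[ped$parent2])
  mgs <- attr(ped, "mode") == "sire_mgs"
  w <- if (mgs) c(0.5, 0.25) else c(0.5, 0.5)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    par <- c(p1[i], p2[i])
    known <- !is.na(par)
    d <- if (mgs) {
      if (all(known)) 11 / 16 else if (known[1]) 3 / 4
      else if (known[2]) 15 / 16 else 1
    } else {
      c(1, 0.75, 0.5)[sum(known) + 1]
    }
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      for (u in which(known)) row <- row + w[u] * A[j, par[u]]
      A[j, i] <- A[i, j] <- row
    }
    quad <- 0
    for (u in which(known)) for (v in which(known))
      quad <- quad + w[u] * w[v] * A[par[u], par[v]]
    A[i, i] <- quad + d
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}
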