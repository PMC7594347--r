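#' @title Trivariate laboratory-as-trait model
#' @description The same ultrasound trait interpreted by each of the three
#'   image-interpretation laboratories is treated as a distinct trait. The
#'   genetic covariance across the three lab-traits is \eqn{A \otimes G_0}
#'   with \eqn{G_0} the 3x3 genetic covariance; technician, contemporary-group
#'   and residual (co)variances are diagonal across labs because no
#'   technician, contemporary group or record spans two laboratories.
#' @name multitrait
NULL

# ---- internal: stacked model context ---------------------------------------
tri_context <- function(records, ped, Ainv) {
  labs <- sort(unique(as.character(records$lab)))
  k <- length(labs)
  lab <- factor(as.character(records$lab), levels = labs)
  tech <- factor(records$technician)
  cg <- factor(records$cg)
  an <- factor(records$animal, levels = ped$animal)
  if (anyNA(an)) stop("recorded animal(s) missing from pedigree")
  n <- nrow(records); n_t <- nlevels(tech); n_c <- nlevels(cg)
  n_a <- nrow(ped)
  # each technician/CG must sit in exactly one lab
  tech_lab <- tapply(as.integer(lab), tech, function(x) unique(x))
  cg_lab <- tapply(as.integer(lab), cg, function(x) unique(x))
  if (any(lengths(tech_lab) > 1) || any(lengths(cg_lab) > 1))
    stop("technician or contemporary group spans more than one laboratory")
  tech_lab <- vapply(tech_lab, identity, integer(1))
  cg_lab <- vapply(cg_lab, identity, integer(1))
  X <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(lab), x = 1,
                            dims = c(n, k))
  Zt <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(tech), x = 1,
                             dims = c(n, n_t))
  Zc <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cg), x = 1,
                             dims = c(n, n_c))
  # lab-major animal block: record in lab l loads breeding value (l, animal)
  Za <- Matrix::sparseMatrix(
    i = seq_len(n), j = (as.integer(lab) - 1L) * n_a + as.integer(an),
    x = 1, dims = c(n, k * n_a))
  W <- cbind(X, Zt, Zc, Za)
  y <- records$value
  rows <- split(seq_len(n), lab)
  Ml <- lapply(rows, function(r)
    Matrix::forceSymmetric(Matrix::crossprod(W[r, , drop = FALSE])))
  Wtyl <- lapply(rows, function(r)
    as.numeric(Matrix::crossprod(W[r, , drop = FALSE], y[r])))
  layout <- list(mu = seq_len(k), t = k + seq_len(n_t),
                 c = k + n_t + seq_len(n_c),
                 a = k + n_t + n_c + seq_len(k * n_a),
                 n = n, k = k, n_t = n_t, n_c = n_c, n_a = n_a,
                 labs = labs, technicians = levels(tech), cgs = levels(cg),
                 animals = ped$animal, tech_lab = tech_lab, cg_lab = cg_lab,
                 n_per_lab = lengths(rows),
                 n_t_per_lab = tabulate(tech_lab, k),
                 n_c_per_lab = tabulate(cg_lab, k))
  ctx <- list(Ml = Ml, Wtyl = Wtyl,
              ytyl = vapply(rows, function(r) sum(y[r]^2), numeric(1)),
              Ainv = Ainv, layout = layout,
              cache = new.env(parent = emptyenv()),
              var_y = stats::var(y))
  ctx$acc <- tri_accumulator(ctx)
  ctx
}

# multiplier classes: e per lab (1..k), t per lab (k+1..2k), c per lab
# (2k+1..3k), then the k(k+1)/2 upper-triangle cells of G0^{-1}
tri_accumulator <- function(ctx) {
  l <- ctx$layout
  k <- l$k
  n <- k + l$n_t + l$n_c + k * l$n_a
  ii <- list(); jj <- list(); bb <- list(); cc <- list()
  add <- function(i, j, base, cls) {
    m <- length(ii) + 1
    ii[[m]] <<- i; jj[[m]] <<- j; bb[[m]] <<- base
    cc[[m]] <<- if (length(cls) == 1L) rep.int(cls, length(i)) else cls
  }
  for (lb in seq_len(k)) {
    tr <- sparse_triplets(ctx$Ml[[lb]])
    add(tr$i, tr$j, tr$x, lb)
  }
  add(k + seq_len(l$n_t), k + seq_len(l$n_t), rep(1, l$n_t), k + l$tech_lab)
  add(k + l$n_t + seq_len(l$n_c), k + l$n_t + seq_len(l$n_c),
      rep(1, l$n_c), 2 * k + l$cg_lab)
  a0 <- k + l$n_t + l$n_c
  up <- sparse_triplets(ctx$Ainv)                  # one triangle
  full <- sparse_triplets(ctx$Ainv, general = TRUE)  # both triangles
  g_cls <- 3 * k
  g_index <- matrix(0L, k, k)
  for (lb in seq_len(k)) for (m in lb:k) {
    g_cls <- g_cls + 1L
    g_index[lb, m] <- g_index[m, lb] <- g_cls
    if (lb == m) {
      add(a0 + (lb - 1L) * l$n_a + up$i, a0 + (lb - 1L) * l$n_a + up$j,
          up$x, g_cls)
    } else {
      add(a0 + (lb - 1L) * l$n_a + full$i, a0 + (m - 1L) * l$n_a + full$j,
          full$x, g_cls)
    }
  }
  acc <- sym_accumulator(unlist(ii), unlist(jj), unlist(bb),
                         unlist(cc), n)
  acc$g_index <- g_index
  acc
}

tri_coefmat <- function(ctx, s2t, s2c, s2e, G0inv) {
  k <- ctx$layout$k
  gvals <- numeric(0)
  for (lb in seq_len(k)) for (m in lb:k)
    gvals <- c(gvals, G0inv[lb, m])
  acc_matrix(ctx$acc, c(1 / s2e, 1 / s2t, 1 / s2c, gvals))
}

tri_neg2_loglik_ctx <- function(ctx, s2t, s2c, s2e, G0) {
  l <- ctx$layout
  G0inv <- tryCatch(solve(G0), error = function(e) NULL)
  if (is.null(G0inv)) return(Inf)
  ldetG0 <- determinant(G0, logarithm = TRUE)
  if (ldetG0$sign <= 0) return(Inf)
  C <- tri_coefmat(ctx, s2t, s2c, s2e, G0inv)
  Ch <- tryCatch(chol_factor(ctx, C), error = function(e) NULL)
  if (is.null(Ch)) return(Inf)
  ldetC <- as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                          sqrt = FALSE)$modulus)
  rhs <- Reduce(`+`, Map(`/`, ctx$Wtyl, as.list(s2e)))
  sol <- as.numeric(Matrix::solve(Ch, rhs, system = "A"))
  yPy <- sum(ctx$ytyl / s2e) - sum(sol * rhs)
  sum(l$n_per_lab * log(s2e)) + sum(l$n_t_per_lab * log(s2t)) +
    sum(l$n_c_per_lab * log(s2c)) + l$n_a * as.numeric(ldetG0$modulus) +
    ldetC + yPy
}

# theta: log s2t (k), log s2c (k), log s2e (k), then the lower-triangular
# factor of G0 column-wise with log-diagonal (PSD by construction)
tri_unpack <- function(theta, k) {
  s2t <- exp(theta[seq_len(k)])
  s2c <- exp(theta[k + seq_len(k)])
  s2e <- exp(theta[2 * k + seq_len(k)])
  L <- matrix(0, k, k)
  pos <- 3 * k
  for (j in seq_len(k)) for (i in j:k) {
    pos <- pos + 1
    L[i, j] <- if (i == j) exp(theta[pos]) else theta[pos]
  }
  list(s2t = s2t, s2c = s2c, s2e = s2e, G0 = L %*% t(L))
}

tri_pack <- function(s2t, s2c, s2e, G0) {
  k <- length(s2t)
  L <- t(chol(G0))
  lp <- numeric(0)
  for (j in seq_len(k)) for (i in j:k)
    lp <- c(lp, if (i == j) log(L[i, j]) else L[i, j])
  c(log(s2t), log(s2c), log(s2e), lp)
}

#' Pairs of laboratories without genetic links
#'
#' The cross-lab genetic covariance is identified only through pedigree ties
#' (chiefly sires with recorded progeny under both labs). Returns the lab
#' pairs whose recorded animals share no parent, for which
#' \eqn{\sigma_{a(i,j)}} is structurally unidentifiable.
#'
#' @param ds a \code{study_dataset} for one trait across labs.
#' @return Data frame with columns \code{lab_i}, \code{lab_j},
#'   \code{n_shared_parents}.
#' @export
lab_pair_links <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  r <- ds$records
  ped <- ds$pedigree
  par <- stats::setNames(
    lapply(split(r$animal, as.character(r$lab)), function(an) {
      rows <- ped[match(unique(an), ped$animal), ]
      unique(stats::na.omit(c(rows$parent1, rows$parent2)))
    }), sort(unique(as.character(r$lab))))
  labs <- names(par)
  out <- data.frame(lab_i = character(0), lab_j = character(0),
                    n_shared_parents = integer(0))
  for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j)
    out[nrow(out) + 1, ] <- list(labs[i], labs[j],
                                 length(intersect(par[[i]], par[[j]])))
  out
}

#' Fit the trivariate laboratory-as-trait model by derivative-free REML
#'
#' Maximises the restricted likelihood of the stacked three-lab model over
#' the per-lab technician, contemporary-group and residual variances and the
#' full 3x3 genetic covariance \eqn{G_0}, parameterised by its Cholesky
#' factor so the estimate is positive semidefinite by construction. One fixed
#' mean is fitted per lab-trait. The same simplex convergence rule as
#' \code{\link{fit_univariate}} applies (variance of \eqn{-2\log L} across
#' vertices below \code{options$tol}).
#'
#' @param ds a \code{study_dataset} with records of one trait spread over the
#'   laboratories (records disjoint across labs).
#' @param Ainv sparse inverse relationship matrix (\code{NULL} to build it).
#' @param start either a list of \code{uni_fit} objects (one per lab, in lab
#'   order) whose components seed the per-lab variances and the \eqn{G_0}
#'   diagonal, or \code{NULL} for a crude equal-partition start.
#' @param start_rg genetic correlation used to seed the off-diagonals of
#'   \eqn{G_0} (default 0.5).
#' @param options see \code{\link{reml_options}}; trivariate fits default to
#'   a single confirmation restart.
#' @return Object of class \code{tri_fit}: \code{labs}, \code{components}
#'   (data frame of per-lab \code{sigma2_t}, \code{sigma2_c},
#'   \code{sigma2_e}), \code{G0}, \code{rg} (correlation matrix),
#'   \code{mu_hat}, \code{neg2_logL}, \code{converged},
#'   \code{unidentifiable_pairs}, and the internal context for EBV
#'   extraction.
#' @export
fit_trivariate <- function(ds, Ainv = NULL, start = NULL, start_rg = 0.5,
                           options = reml_options(n_restarts = 1)) {
  stopifnot(inherits(ds, "study_dataset"))
  if (is.null(Ainv)) Ainv <- build_A_inverse(ds$pedigree)
  ctx <- tri_context(ds$records, ds$pedigree, Ainv)
  k <- ctx$layout$k
  links <- lab_pair_links(ds)
  weak <- links[links$n_shared_parents == 0, , drop = FALSE]
  if (nrow(weak))
    warning("no genetic links between lab pair(s): ",
            paste(weak$lab_i, weak$lab_j, sep = "-", collapse = ", "),
            "; the corresponding genetic covariance is unidentifiable",
            call. = FALSE)
  vp <- ctx$var_y
  if (is.null(start)) {
    s2t <- rep(0.2 * vp, k); s2c <- rep(0.3 * vp, k)
    s2a <- rep(0.2 * vp, k); s2e <- rep(0.3 * vp, k)
  } else {
    stopifnot(length(start) == k)
    vcs <- vapply(start, function(f)
      if (inherits(f, "uni_fit")) f$vc else f, numeric(4))
    s2t <- vcs["sigma2_t", ]; s2c <- vcs["sigma2_c", ]
    s2a <- vcs["sigma2_a", ]; s2e <- vcs["sigma2_e", ]
  }
  G0 <- diag(s2a, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    G0[i, j] <- start_rg * sqrt(s2a[i] * s2a[j])
  floor_v <- options$floor_frac * vp
  obj <- function(theta) {
    p <- tri_unpack(theta, k)
    tri_neg2_loglik_ctx(ctx, pmax(p$s2t, floor_v), pmax(p$s2c, floor_v),
                        pmax(p$s2e, floor_v), p$G0)
  }
  run <- nelder_mead(obj, tri_pack(s2t, s2c, s2e, G0), tol = options$tol,
                     max_eval = options$max_eval, step = options$step)
  restarts <- numeric(0)
  best <- run
  for (f in utils::head(options$restart_factors, options$n_restarts)) {
    r <- nelder_mead(obj, best$x + log(f) / 2, tol = options$tol,
                     max_eval = options$max_eval, step = options$step)
    restarts <- c(restarts, r$f)
    if (r$f < best$f) best <- r
  }
  p <- tri_unpack(best$x, k)
  rg <- stats::cov2cor(p$G0)
  dimnames(rg) <- dimnames(p$G0) <- list(ctx$layout$labs, ctx$layout$labs)
  comp <- data.frame(lab = ctx$layout$labs, sigma2_t = pmax(p$s2t, floor_v),
                     sigma2_c = pmax(p$s2c, floor_v), sigma2_a = diag(p$G0),
                     sigma2_e = pmax(p$s2e, floor_v))
  sol <- tri_solution(ctx, comp, p$G0)
  fit <- list(labs = ctx$layout$labs, components = comp, G0 = p$G0, rg = rg,
              mu_hat = stats::setNames(sol$effects[ctx$layout$mu],
                                       ctx$layout$labs),
              neg2_logL = best$f,
              converged = run$converged && best$converged,
              n_eval = run$n_eval,
              restart_neg2_logL = restarts,
              restart_spread = if (length(restarts))
                max(abs(restarts - best$f)) else NA_real_,
              unidentifiable_pairs = weak, ctx = ctx, options = options)
  class(fit) <- "tri_fit"
  fit
}

tri_solution <- function(ctx, comp, G0) {
  C <- tri_coefmat(ctx, comp$sigma2_t, comp$sigma2_c, comp$sigma2_e,
                   solve(G0))
  Ch <- chol_factor(ctx, C)
  rhs <- Reduce(`+`, Map(`/`, ctx$Wtyl, as.list(comp$sigma2_e)))
  list(effects = as.numeric(Matrix::solve(Ch, rhs, system = "A")),
       Ch = Ch, C = C)
}

#' @export
print.tri_fit <- function(x, ...) {
  cat("Trivariate lab-as-trait REML fit\n")
  cat(sprintf("  -2 log L: %.6f (converged: %s)\n", x$neg2_logL, x$converged))
  cat("  genetic correlations between labs:\n")
  print(round(x$rg, 3))
  invisible(x)
}

#' Per-lab EBVs from a trivariate fit
#'
#' Extracts, for every pedigree animal and every lab-trait, the estimated
#' breeding value, prediction-error variance and accuracy
#' \eqn{\sqrt{1 - PEV/\sigma_{a,lab}^2}} from the stacked mixed-model
#' equations at the fitted components.
#'
#' @param fit a \code{tri_fit}.
#' @return Data frame with columns \code{animal}, \code{lab}, \code{ebv},
#'   \code{pev}, \code{accuracy}.
#' @export
solve_ebv_trivariate <- function(fit) {
  stopifnot(inherits(fit, "tri_fit"))
  ctx <- fit$ctx
  l <- ctx$layout
  sol <- tri_solution(ctx, fit$components, fit$G0)
  idx <- l$a
  pev <- cinv_diag(sol$Ch, idx, nrow(sol$C))
  out <- data.frame(
    animal = rep(l$animals, times = l$k),
    lab = rep(l$labs, each = l$n_a),
    ebv = sol$effects[idx], pev = pev)
  s2a <- stats::setNames(diag(fit$G0), l$labs)
  out$accuracy <- sqrt(pmax(0, pmin(1, 1 - out$pev / s2a[out$lab])))
  out
}

#' Genetic correlation from a genetic covariance matrix
#'
#' @param G0 symmetric genetic covariance matrix.
#' @param i,j trait (lab) indices.
#' @return \eqn{r_g = \sigma_{a(i,j)} / \sqrt{\sigma_{ai}^2 \sigma_{aj}^2}}.
#' @export
genetic_correlation <- function(G0, i, j) {
  if (G0[i, i] <= 0 || G0[j, j] <= 0)
    stop("genetic variances must be positive to form a correlation")
  G0[i, j] / sqrt(G0[i, i] * G0[j, j])
}

#' z-test of a genetic correlation against 1
#'
#' Two-sided test of \eqn{H_0: r_g = 1} at the 5\% level, the criterion used
#' to star between-laboratory correlations: \eqn{z = (r_g - 1)/SE}, rejected
#' when \eqn{|z| > 1.959964}.
#'
#' @param rg estimated genetic correlation.
#' @param se its standard error (nonnegative).
#' @return List with \code{z}, \code{reject} (logical), and
#'   \code{infinite_z} flag for the degenerate \code{se = 0} case.
#' @export
rg_z_test <- function(rg, se) {
  if (se < 0) stop("se must be nonnegative")
  crit <- 1.959964
  if (se == 0) {
    if (rg == 1) return(list(z = 0, reject = FALSE, infinite_z = FALSE))
    return(list(z = -Inf * sign(1 - rg), reject = TRUE, infinite_z = TRUE))
  }
  z <- (rg - 1) / se
  list(z = z, reject = abs(z) > crit, infinite_z = FALSE)
}
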