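#' Variance components of the univariate animal model
#'
#' The single-trait model is \eqn{y = \mu + t + c + a + e} with technician
#' \eqn{t \sim N(0, I\sigma_t^2)}, contemporary group within technician
#' \eqn{c \sim N(0, I\sigma_c^2)}, additive genetic effect
#' \eqn{a \sim N(0, A\sigma_a^2)} and residual \eqn{e \sim N(0, I\sigma_e^2)}.
#'
#' @param sigma2_t technician variance (trait units squared).
#' @param sigma2_c contemporary-group-within-technician variance.
#' @param sigma2_a additive genetic variance.
#' @param sigma2_e residual variance (must be positive).
#' @return Named numeric vector of the four components.
#' @export
variance_components <- function(sigma2_t, sigma2_c, sigma2_a, sigma2_e) {
  vc <- c(sigma2_t = sigma2_t, sigma2_c = sigma2_c,
          sigma2_a = sigma2_a, sigma2_e = sigma2_e)
  if (any(vc < 0)) stop("variance components must be nonnegative")
  if (sigma2_e <= 0) stop("residual variance must be positive")
  vc
}

#' Options controlling the derivative-free REML fit
#'
#' @param tol convergence threshold: the fit stops when the sample variance of
#'   \eqn{-2\log L} across the simplex vertices falls below this value.
#' @param max_eval cap on likelihood evaluations per simplex run.
#' @param n_restarts additional simplex runs from perturbed starts used to
#'   confirm convergence to a common optimum.
#' @param step initial simplex step on the log-variance scale.
#' @param floor_frac lower bound for any variance component, as a fraction of
#'   the phenotypic variance (components are optimised on the log scale and
#'   cannot reach zero exactly).
#' @param restart_factors multiplicative perturbations applied to the
#'   converged components to seed the restarts.
#' @return List of options.
#' @export
reml_options <- function(tol = 1e-10, max_eval = 5000, n_restarts = 2,
                         step = 0.4, floor_frac = 1e-8,
                         restart_factors = c(0.5, 2)) {
  list(tol = tol, max_eval = max_eval, n_restarts = n_restarts, step = step,
       floor_frac = floor_frac, restart_factors = restart_factors)
}

# ---- internal: model context ------------------------------------------------
# Precomputes sparse design cross-products for one trait-by-lab record set so
# that each likelihood evaluation only re-weights and refactorises.

uni_context <- function(records, ped, Ainv) {
  stopifnot(nrow(records) > 0)
  y <- records$value
  n <- length(y)
  tech <- factor(records$technician)
  cg <- factor(records$cg)
  an <- factor(records$animal, levels = ped$animal)
  if (anyNA(an)) stop("recorded animal(s) missing from pedigree")
  n_t <- nlevels(tech); n_c <- nlevels(cg); n_a <- nrow(ped)
  Zt <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(tech),
                             x = 1, dims = c(n, n_t))
  Zc <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cg),
                             x = 1, dims = c(n, n_c))
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(an),
                             x = 1, dims = c(n, n_a))
  X <- Matrix::Matrix(1, n, 1, sparse = TRUE)
  W <- cbind(X, Zt, Zc, Za)
  layout <- list(
    mu = 1L, t = 1L + seq_len(n_t), c = 1L + n_t + seq_len(n_c),
    a = 1L + n_t + n_c + seq_len(n_a),
    n = n, n_t = n_t, n_c = n_c, n_a = n_a,
    technicians = levels(tech), cgs = levels(cg), animals = ped$animal)
  env <- new.env(parent = emptyenv())  # symbolic-factorisation cache
  ctx <- list(M = Matrix::forceSymmetric(Matrix::crossprod(W)),
              Wty = as.numeric(Matrix::crossprod(W, y)), yty = sum(y * y),
              Ainv = Ainv, layout = layout, cache = env,
              var_y = stats::var(y))
  ctx$acc <- uni_accumulator(ctx)
  ctx
}

# multiplier classes: 1 = 1/sigma2_e (cross-products), 2 = 1/sigma2_t,
# 3 = 1/sigma2_c, 4 = 1/sigma2_a (A-inverse ridge)
uni_accumulator <- function(ctx) {
  l <- ctx$layout
  n <- 1L + l$n_t + l$n_c + l$n_a
  m <- sparse_triplets(ctx$M)
  a <- sparse_triplets(ctx$Ainv)
  a0 <- 1L + l$n_t + l$n_c
  sym_accumulator(
    i = c(m$i, 1L + seq_len(l$n_t), 1L + l$n_t + seq_len(l$n_c), a0 + a$i),
    j = c(m$j, 1L + seq_len(l$n_t), 1L + l$n_t + seq_len(l$n_c), a0 + a$j),
    base = c(m$x, rep(1, l$n_t + l$n_c), a$x),
    class_id = c(rep(1L, length(m$x)), rep(2L, l$n_t), rep(3L, l$n_c),
                 rep(4L, length(a$x))),
    n = n)
}

uni_coefmat <- function(ctx, vc) {
  acc_matrix(ctx$acc, 1 / c(vc[["sigma2_e"]], vc[["sigma2_t"]],
                            vc[["sigma2_c"]], vc[["sigma2_a"]]))
}

chol_factor <- function(ctx, C) {
  C <- methods::as(Matrix::forceSymmetric(C), "CsparseMatrix")
  if (is.null(ctx$cache$Ch)) {
    ctx$cache$Ch <- Matrix::Cholesky(C, LDL = FALSE, super = TRUE,
                                     perm = TRUE)
    ctx$cache$Ch
  } else {
    tryCatch(Matrix::update(ctx$cache$Ch, C),
             error = function(e) Matrix::Cholesky(C, LDL = FALSE,
                                                  super = TRUE, perm = TRUE))
  }
}

floor_vc <- function(vc, ctx, floor_frac) {
  pmax(vc, floor_frac * ctx$var_y)
}

# ---- mixed-model equations --------------------------------------------------

#' Assemble Henderson's mixed-model equations
#'
#' Coefficient matrix and right-hand side for the univariate animal model at
#' given variance components: a single intercept plus random technician,
#' contemporary-group and animal blocks, the last carrying the ridge
#' \eqn{A^{-1}\sigma_e^2/\sigma_a^2}. Animals without records still occupy
#' equations through \eqn{A^{-1}}. The system is scaled by
#' \eqn{1/\sigma_e^2}, so the inverse coefficient matrix is directly the
#' prediction-error covariance.
#'
#' @param ds a \code{study_dataset} restricted to one trait and lab (or any
#'   record set sharing one residual variance).
#' @param Ainv sparse inverse relationship matrix over \code{ds$pedigree};
#'   \code{NULL} builds it from the pedigree.
#' @param vc variance components (see \code{\link{variance_components}});
#'   zero components are floored at a small fraction of the phenotypic
#'   variance rather than dropped.
#' @return List with \code{C} (sparse symmetric coefficient matrix),
#'   \code{rhs}, and \code{layout} (index vectors for the \code{mu}, \code{t},
#'   \code{c}, \code{a} blocks plus id labels).
#' @export
assemble_mme <- function(ds, Ainv = NULL, vc) {
  stopifnot(inherits(ds, "study_dataset"))
  if (is.null(Ainv)) Ainv <- build_A_inverse(ds$pedigree)
  ctx <- uni_context(ds$records, ds$pedigree, Ainv)
  vc <- floor_vc(vc, ctx, reml_options()$floor_frac)
  list(C = uni_coefmat(ctx, vc), rhs = ctx$Wty / vc[["sigma2_e"]],
       layout = ctx$layout)
}

# core evaluation shared by the exported wrapper and the optimiser
neg2_loglik_ctx <- function(vc, ctx) {
  l <- ctx$layout
  C <- uni_coefmat(ctx, vc)
  Ch <- tryCatch(chol_factor(ctx, C), error = function(e) NULL)
  if (is.null(Ch)) return(Inf)
  ldet <- as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                         sqrt = FALSE)$modulus)
  rhs <- ctx$Wty / vc[["sigma2_e"]]
  sol <- as.numeric(Matrix::solve(Ch, rhs, system = "A"))
  yPy <- ctx$yty / vc[["sigma2_e"]] - sum(sol * rhs * vc[["sigma2_e"]]) /
    vc[["sigma2_e"]]
  l$n * log(vc[["sigma2_e"]]) + l$n_t * log(vc[["sigma2_t"]]) +
    l$n_c * log(vc[["sigma2_c"]]) + l$n_a * log(vc[["sigma2_a"]]) +
    ldet + yPy
}

#' Restricted log-likelihood of the univariate animal model
#'
#' Returns \eqn{-2\log L_R} up to an additive constant that does not depend on
#' the variance components (the constant absorbs \eqn{\log|A|} and the
#' \eqn{2\pi} term). Evaluated through a sparse symmetric factorisation of the
#' mixed-model equations, using the identity
#' \eqn{\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|}.
#'
#' @param vc variance components, all strictly positive.
#' @param ds a \code{study_dataset} for one trait and lab.
#' @param Ainv sparse inverse relationship matrix (\code{NULL} to build it).
#' @return \eqn{-2\log L_R} as a scalar; \code{Inf} if the system is not
#'   positive definite.
#' @export
reml_neg2_loglik <- function(vc, ds, Ainv = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  if (any(vc <= 0)) stop("variance components must be strictly positive")
  if (is.null(Ainv)) Ainv <- build_A_inverse(ds$pedigree)
  ctx <- uni_context(ds$records, ds$pedigree, Ainv)
  neg2_loglik_ctx(vc, ctx)
}

# ---- Nelder-Mead simplex ----------------------------------------------------
# Direct-search minimiser with the derivative-free REML stopping rule: stop
# when the sample variance of the objective across the simplex vertices drops
# below `tol`.
nelder_mead <- function(fn, x0, tol = 1e-10, max_eval = 5000, step = 0.4) {
  d <- length(x0)
  simplex <- matrix(rep(x0, d + 1), nrow = d + 1, byrow = TRUE)
  for (i in seq_len(d)) simplex[i + 1, i] <- simplex[i + 1, i] + step
  fv <- apply(simplex, 1, fn)
  n_eval <- d + 1
  converged <- FALSE
  while (n_eval < max_eval) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    if (stats::var(fv) < tol) { converged <- TRUE; break }
    centroid <- colMeans(simplex[seq_len(d), , drop = FALSE])
    xr <- centroid + (centroid - simplex[d + 1, ])
    fr <- fn(xr); n_eval <- n_eval + 1
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[d + 1, ])
      fe <- fn(xe); n_eval <- n_eval + 1
      if (fe < fr) { simplex[d + 1, ] <- xe; fv[d + 1] <- fe }
      else { simplex[d + 1, ] <- xr; fv[d + 1] <- fr }
    } else if (fr < fv[d]) {
      simplex[d + 1, ] <- xr; fv[d + 1] <- fr
    } else {
      xc <- if (fr < fv[d + 1]) centroid + 0.5 * (xr - centroid)
            else centroid + 0.5 * (simplex[d + 1, ] - centroid)
      fc <- fn(xc); n_eval <- n_eval + 1
      if (fc < min(fr, fv[d + 1])) {
        simplex[d + 1, ] <- xc; fv[d + 1] <- fc
      } else {  # shrink toward the best vertex
        for (i in 2:(d + 1))
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
        fv[2:(d + 1)] <- apply(simplex[2:(d + 1), , drop = FALSE], 1, fn)
        n_eval <- n_eval + d
      }
    }
  }
  best <- which.min(fv)
  list(x = simplex[best, ], f = fv[best], n_eval = n_eval,
       converged = converged)
}

# ---- univariate fit ---------------------------------------------------------

#' Fit the univariate animal model by derivative-free REML
#'
#' Minimises \eqn{-2\log L_R} over the four variance components with a
#' Nelder--Mead simplex on the log-variance scale (positivity enforced by
#' construction). Convergence is declared when the variance of
#' \eqn{-2\log L} across the simplex vertices falls below \code{options$tol}
#' (default \code{1e-10}). After the first run, additional simplex runs are
#' started from the converged components scaled by
#' \code{options$restart_factors}; agreement of their minima guards against
#' local optima.
#'
#' @param ds a \code{study_dataset} holding the records of one trait and lab.
#' @param Ainv sparse inverse relationship matrix (\code{NULL} to build it
#'   from \code{ds$pedigree}).
#' @param start starting variance components; \code{NULL} partitions the
#'   phenotypic variance as 20/30/20/30\% across t/c/a/e.
#' @param options see \code{\link{reml_options}}.
#' @return Object of class \code{uni_fit}: \code{vc} (estimates),
#'   \code{neg2_logL}, \code{mu_hat}, \code{converged},
#'   \code{n_eval}, \code{restart_neg2_logL} (minima of the restart runs),
#'   \code{restart_spread} (max absolute difference of the minima),
#'   \code{flat_likelihood} flag, and the internal context for downstream EBV
#'   extraction.
#' @export
fit_univariate <- function(ds, Ainv = NULL, start = NULL,
                           options = reml_options()) {
  stopifnot(inherits(ds, "study_dataset"))
  if (is.null(Ainv)) Ainv <- build_A_inverse(ds$pedigree)
  ctx <- uni_context(ds$records, ds$pedigree, Ainv)
  vp <- ctx$var_y
  if (is.null(start))
    start <- variance_components(0.2 * vp, 0.3 * vp, 0.2 * vp, 0.3 * vp)
  floor_v <- options$floor_frac * vp
  obj <- function(logv) {
    vc <- stats::setNames(pmax(exp(logv), floor_v),
                          c("sigma2_t", "sigma2_c", "sigma2_a", "sigma2_e"))
    neg2_loglik_ctx(vc, ctx)
  }
  run <- nelder_mead(obj, log(pmax(start, floor_v)), tol = options$tol,
                     max_eval = options$max_eval, step = options$step)
  restarts <- numeric(0)
  best <- run
  for (f in utils::head(options$restart_factors, options$n_restarts)) {
    r <- nelder_mead(obj, best$x + log(f), tol = options$tol,
                     max_eval = options$max_eval, step = options$step)
    restarts <- c(restarts, r$f)
    if (r$f < best$f) best <- r
  }
  vc <- stats::setNames(pmax(exp(best$x), floor_v),
                        c("sigma2_t", "sigma2_c", "sigma2_a", "sigma2_e"))
  # flat likelihood: a unit-scale move in log(sigma2_a) barely changes -2logL
  probe <- obj(best$x + c(0, 0, 0.5, 0))
  flat <- is.finite(probe) && abs(probe - best$f) < 1e-6
  sol <- mme_solution(ctx, vc)
  fit <- list(vc = vc, neg2_logL = best$f,
              mu_hat = sol$effects[ctx$layout$mu],
              converged = run$converged && best$converged,
              n_eval = run$n_eval,
              restart_neg2_logL = restarts,
              restart_spread = if (length(restarts))
                max(abs(restarts - best$f)) else NA_real_,
              flat_likelihood = flat,
              ctx = ctx, options = options)
  class(fit) <- "uni_fit"
  if (flat)
    warning("flat likelihood in sigma2_a: additive and residual variance ",
            "may be identified only in sum", call. = FALSE)
  fit
}

#' @export
print.uni_fit <- function(x, ...) {
  cat("Univariate animal-model REML fit\n")
  cat(sprintf("  -2 log L: %.6f (converged: %s)\n", x$neg2_logL, x$converged))
  print(round(x$vc, 4))
  pct <- variance_percentages(x$vc)
  cat("  percent of phenotypic variance:",
      paste(sprintf("%s=%d", c("t", "c", "a", "e"), round(pct)),
            collapse = " "), "\n")
  invisible(x)
}

# solve the MME once at fixed components
mme_solution <- function(ctx, vc) {
  C <- uni_coefmat(ctx, vc)
  Ch <- chol_factor(ctx, C)
  rhs <- ctx$Wty / vc[["sigma2_e"]]
  list(effects = as.numeric(Matrix::solve(Ch, rhs, system = "A")),
       Ch = Ch, C = C)
}

# diagonal of C^{-1} over selected indices, by blocked column solves
cinv_diag <- function(Ch, idx, ntot, chunk = 512L) {
  out <- numeric(length(idx))
  for (s in seq(1, length(idx), by = chunk)) {
    cols <- idx[s:min(s + chunk - 1L, length(idx))]
    E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(ntot, length(cols)))
    S <- Matrix::solve(Ch, E, system = "A")
    out[s:(s + length(cols) - 1L)] <-
      S[cbind(cols, seq_along(cols))]
  }
  out
}

#' Estimated breeding values, prediction-error variances and accuracies
#'
#' Solves the mixed-model equations at the supplied variance components and
#' extracts the animal block: EBV, PEV (diagonal of the inverse coefficient
#' matrix over the animal equations) and accuracy
#' \eqn{r_i = \sqrt{1 - PEV_i/\sigma_a^2}}. Animals with no records and no
#' recorded relatives get EBV 0 and accuracy 0.
#'
#' @param ds a \code{study_dataset} for one trait and lab, or a fitted
#'   \code{uni_fit} (in which case \code{Ainv} and \code{vc} are taken from
#'   the fit).
#' @param Ainv sparse inverse relationship matrix.
#' @param vc variance components at which to solve.
#' @return Data frame with columns \code{animal}, \code{ebv}, \code{pev},
#'   \code{accuracy}.
#' @export
solve_ebv <- function(ds, Ainv = NULL, vc = NULL) {
  if (inherits(ds, "uni_fit")) {
    ctx <- ds$ctx
    vc <- ds$vc
  } else {
    stopifnot(inherits(ds, "study_dataset"), !is.null(vc))
    if (is.null(Ainv)) Ainv <- build_A_inverse(ds$pedigree)
    ctx <- uni_context(ds$records, ds$pedigree, Ainv)
  }
  l <- ctx$layout
  if (vc[["sigma2_a"]] <= 0)
    return(data.frame(animal = l$animals, ebv = 0, pev = 0, accuracy = 0))
  sol <- mme_solution(ctx, vc)
  ebv <- sol$effects[l$a]
  pev <- cinv_diag(sol$Ch, l$a, nrow(sol$C))
  acc <- sqrt(pmax(0, pmin(1, 1 - pev / vc[["sigma2_a"]])))
  data.frame(animal = l$animals, ebv = ebv, pev = pev, accuracy = acc)
}

# ---- asymptotic covariance of the estimates ---------------------------------

#' Asymptotic covariance of REML variance-component estimates
#'
#' Inverse of half the central-difference Hessian of \eqn{-2\log L_R} at the
#' estimates (the observed-information approximation). Used by
#' \code{\link{partition_summary}} to delta-method standard errors onto
#' percentages and heritability.
#'
#' @param fit a \code{uni_fit}.
#' @param rel_h relative step for the central differences.
#' @return 4x4 covariance matrix of
#'   \eqn{(\sigma_t^2, \sigma_c^2, \sigma_a^2, \sigma_e^2)}.
#' @export
vc_covariance <- function(fit, rel_h = 1e-3) {
  stopifnot(inherits(fit, "uni_fit"))
  ctx <- fit$ctx
  th <- fit$vc
  f <- function(v) neg2_loglik_ctx(stats::setNames(
    v, c("sigma2_t", "sigma2_c", "sigma2_a", "sigma2_e")), ctx)
  h <- pmax(rel_h * th, 1e-10)
  H <- matrix(0, 4, 4)
  f0 <- f(th)
  for (i in 1:4) for (j in i:4) {
    ei <- ej <- numeric(4); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <- if (i == j) {
      (f(th + ei) - 2 * f0 + f(th - ei)) / h[i]^2
    } else {
      (f(th + ei + ej) - f(th + ei - ej) - f(th - ei + ej) +
         f(th - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  V <- tryCatch(solve(H / 2), error = function(e)
    matrix(NA_real_, 4, 4))
  dimnames(V) <- list(names(th), names(th))
  V
}
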