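#' Within-contemporary-group heritability
#'
#' \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)}. Technician and
#' contemporary-group variances are excluded from the denominator: only one
#' technician scans a contemporary group, so neither contributes to variation
#' among animals measured together.
#'
#' @param sigma2_a additive genetic variance (>= 0).
#' @param sigma2_e residual variance.
#' @return Heritability in [0, 1].
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  if (sigma2_a < 0 || sigma2_e < 0) stop("variances must be nonnegative")
  if (sigma2_a + sigma2_e == 0)
    stop("additive and residual variance are both zero")
  sigma2_a / (sigma2_a + sigma2_e)
}

#' Percentage of phenotypic variance per component
#'
#' Each component as a percentage of the phenotypic variance
#' \eqn{\sigma_t^2 + \sigma_c^2 + \sigma_a^2 + \sigma_e^2}. Display rounding
#' to integer percent is the caller's choice; the unrounded values sum to 100.
#'
#' @param vc named variance components (\code{\link{variance_components}}).
#' @return Named numeric vector of four percentages.
#' @export
variance_percentages <- function(vc) {
  tot <- sum(vc)
  if (tot <= 0) stop("all variance components are zero")
  100 * vc / tot
}

#' Partition summary with delta-method standard errors
#'
#' Bundles the fitted components, their percentages of phenotypic variance,
#' delta-method standard errors of the percentages, and the
#' within-contemporary-group heritability with its standard error.
#'
#' @param fit a \code{uni_fit}.
#' @param vcov covariance matrix of the component estimates; default
#'   \code{\link{vc_covariance}(fit)}.
#' @return List of class \code{partition_summary}: \code{vc},
#'   \code{percents}, \code{percent_se}, \code{h2}, \code{h2_se}.
#' @export
partition_summary <- function(fit, vcov = NULL) {
  stopifnot(inherits(fit, "uni_fit"))
  if (is.null(vcov)) vcov <- vc_covariance(fit)
  vc <- fit$vc
  tot <- sum(vc)
  pct <- variance_percentages(vc)
  # gradient of p_x = 100 s_x / sum(s): d p_x / d s_y = 100 (d_xy tot - s_x)/tot^2
  pse <- vapply(seq_along(vc), function(x) {
    g <- -100 * vc[x] / tot^2
    g <- rep(g, length(vc))
    g[x] <- 100 * (tot - vc[x]) / tot^2
    v <- as.numeric(t(g) %*% vcov %*% g)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }, numeric(1))
  names(pse) <- names(vc)
  h2 <- heritability(vc[["sigma2_a"]], vc[["sigma2_e"]])
  den <- vc[["sigma2_a"]] + vc[["sigma2_e"]]
  gh <- c(0, 0, vc[["sigma2_e"]] / den^2, -vc[["sigma2_a"]] / den^2)
  vh <- as.numeric(t(gh) %*% vcov %*% gh)
  structure(list(vc = vc, percents = pct, percent_se = pse, h2 = h2,
                 h2_se = if (is.finite(vh) && vh >= 0) sqrt(vh) else NA_real_),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  df <- data.frame(component = names(x$vc), estimate = round(x$vc, 4),
                   percent = round(x$percents),
                   percent_se = round(x$percent_se, 1))
  rownames(df) <- NULL
  print(df)
  cat(sprintf("h2 = %.2f +/- %.2f\n", x$h2, x$h2_se))
  invisible(x)
}

#' Range-over-mean dispersion of estimates across laboratories
#'
#' \eqn{100 (\max - \min)/\mathrm{mean}}, the statistic used to express how
#' much a variance component differs among the three laboratories.
#'
#' @param values numeric vector of at least two values with positive mean.
#' @return Dispersion in percent.
#' @export
dispersion_range_over_mean <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  100 * (max(values) - min(values)) / m
}

#' Residuals within technicians after contemporary-group correction
#'
#' Centers each record on its contemporary-group mean and groups the
#' deviations by technician, the preparation for Bartlett's homogeneity test.
#' Records in singleton contemporary groups carry no within-group deviation
#' and are dropped (their count is reported).
#'
#' @param records data frame with \code{value}, \code{cg}, \code{technician}.
#' @return List with \code{groups} (named list of residual vectors, one per
#'   technician) and \code{n_singleton_dropped}.
#' @export
residuals_within_technician <- function(records) {
  cg_n <- table(records$cg)
  singleton <- records$cg %in% names(cg_n)[cg_n < 2]
  kept <- records[!singleton, , drop = FALSE]
  res <- kept$value - stats::ave(kept$value, kept$cg)
  list(groups = split(res, kept$technician),
       n_singleton_dropped = sum(singleton))
}

#' Bartlett's test of homogeneity of variance
#'
#' Classical Bartlett chi-square statistic with the Box correction factor,
#' applied to grouped residuals (typically the output of
#' \code{\link{residuals_within_technician}}). A group with zero variance
#' makes the statistic infinite; this is flagged and reported with p = 0.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{zero_variance_group} flag.
#' @export
bartlett_homogeneity <- function(groups) {
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2)
    stop("need at least two groups with at least two observations")
  vars <- vapply(groups, stats::var, numeric(1))
  if (any(vars == 0))
    return(list(statistic = Inf, df = length(groups) - 1L, p_value = 0,
                zero_variance_group = TRUE))
  bt <- stats::bartlett.test(groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p_value = bt$p.value, zero_variance_group = FALSE)
}

#' Standard error of a between-laboratory genetic correlation
#'
#' Approximation driven by the average accuracies of the sire EBVs under the
#' two laboratories and the number of common sires:
#' \deqn{SE(r_g) = \sqrt{\frac{1/(r_{ik}^2 r_{jk}^2) +
#'   (1 + 0.5 r_{ik}^4 + 0.5 r_{jk}^4 - 2 r_{ik}^2 - 2 r_{jk}^2) r_g^2 +
#'   r_g^4}{N - 1}}}
#' At unit accuracies this reduces to the classical
#' \eqn{(1 - r_g^2)/\sqrt{N - 1}}.
#'
#' @param rg estimated genetic correlation.
#' @param r_ik average sire-EBV accuracy under lab i, in (0, 1].
#' @param r_jk average sire-EBV accuracy under lab j, in (0, 1].
#' @param N number of sires with progeny records under both labs (>= 2).
#' @return Standard error of \code{rg}.
#' @export
se_genetic_correlation <- function(rg, r_ik, r_jk, N) {
  if (N < 2) stop("need at least two common sires")
  if (r_ik <= 0 || r_ik > 1 || r_jk <= 0 || r_jk > 1)
    stop("accuracies must lie in (0, 1]")
  num <- 1 / (r_ik^2 * r_jk^2) +
    (1 + 0.5 * r_ik^4 + 0.5 * r_jk^4 - 2 * r_ik^2 - 2 * r_jk^2) * rg^2 +
    rg^4
  sqrt(num / (N - 1))
}

#' Spearman rank correlation of sire EBVs between two laboratories
#'
#' Rank correlation (average-rank ties) over the sires evaluated under both
#' laboratories, measuring re-ranking of sires when a different laboratory
#' interprets the images.
#'
#' @param ebv_i named numeric vector, sire EBVs under lab i.
#' @param ebv_j named numeric vector, sire EBVs under lab j.
#' @return List with \code{rho} and \code{n_common}.
#' @export
spearman_ebv_correlation <- function(ebv_i, ebv_j) {
  common <- intersect(names(ebv_i), names(ebv_j))
  if (length(common) < 3) stop("need at least three common sires")
  list(rho = stats::cor(ebv_i[common], ebv_j[common], method = "spearman"),
       n_common = length(common))
}

#' Sires with recorded progeny under each laboratory
#'
#' Identifies, for every pair of laboratories, the sires having at least one
#' recorded progeny under both. These are the sires over which EBV accuracies
#' are averaged for \code{\link{se_genetic_correlation}} and over which
#' \code{\link{spearman_ebv_correlation}} is computed.
#'
#' @param ds a \code{study_dataset} for one trait.
#' @return Named list (\code{"i-j"} per lab pair) of sire id vectors.
#' @export
common_sires <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  r <- ds$records
  ped <- ds$pedigree
  sire_of <- stats::setNames(ped$parent1, ped$animal)
  by_lab <- lapply(split(r$animal, as.character(r$lab)), function(an)
    unique(stats::na.omit(unname(sire_of[unique(an)]))))
  labs <- sort(names(by_lab))
  out <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j)
    out[[paste(labs[i], labs[j], sep = "-")]] <-
      intersect(by_lab[[labs[i]]], by_lab[[labs[j]]])
  out
}
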