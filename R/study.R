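#' Run the full variance-partitioning study on one breed
#'
#' Reproduces the study design end to end on a validated dataset: the
#' breed-specific scan-age filter, structural validation, one univariate
#' animal-model REML fit per trait-by-laboratory cell, one trivariate
#' lab-as-trait fit per trait, and the downstream diagnostics (heritability
#' and percentage partitions with standard errors, range/mean dispersion of
#' components across laboratories, Bartlett's test of residual homogeneity
#' across technicians, between-laboratory genetic correlations with
#' standard errors and z-tests, Spearman rank correlations of common-sire
#' EBVs).
#'
#' @param ds a \code{\link{study_dataset}}, or a records data frame (then
#'   \code{pedigree} must be supplied).
#' @param pedigree pedigree to pair with a bare records data frame.
#' @param breed breed to analyse; default the single breed present.
#' @param strict if \code{TRUE}, structural violations or non-converged fits
#'   raise an error instead of a flag.
#' @param options REML options shared by all fits
#'   (\code{\link{reml_options}}).
#' @param seed integer stored in the run metadata (the fits themselves are
#'   deterministic given the data).
#' @param out_dir if non-\code{NULL}, \code{\link{write_study_report}} is
#'   called on the result.
#' @return Object of class \code{study_report}; see the vignette for the
#'   layout.
#' @export
run_study <- function(ds, pedigree = NULL, breed = NULL, strict = FALSE,
                      options = reml_options(), seed = 1L, out_dir = NULL) {
  if (!inherits(ds, "study_dataset")) ds <- study_dataset(ds, pedigree)
  records <- ds$records
  if (is.null(breed)) {
    breed <- unique(records$breed)
    if (length(breed) != 1)
      stop("multiple breeds present; analyse one breed at a time")
  }
  records <- records[records$breed == toupper(breed), , drop = FALSE]
  filt <- filter_age_window(records)
  records <- filt$kept
  ds <- study_dataset(records, ds$pedigree)
  violations <- validate_structure(ds)
  if (strict && nrow(violations))
    stop("structural validation failed: ", nrow(violations), " violation(s)")
  Ainv <- build_A_inverse(ds$pedigree)

  traits <- sort(unique(records$trait))
  uni_rows <- list()
  uni_fits <- list()
  tri_fits <- list()
  rg_rows <- list()
  bartlett_rows <- list()
  disp_rows <- list()
  for (tr in traits) {
    rtr <- records[records$trait == tr, , drop = FALSE]
    labs <- sort(unique(as.character(rtr$lab)))
    fits <- list()
    for (lb in labs) {
      dsl <- study_dataset(rtr[rtr$lab == lb, , drop = FALSE], ds$pedigree)
      fit <- fit_univariate(dsl, Ainv, options = options)
      if (strict && !fit$converged)
        stop("univariate fit did not converge: ", tr, " lab ", lb)
      ps <- partition_summary(fit)
      fits[[lb]] <- fit
      uni_rows[[paste(tr, lb)]] <- data.frame(
        trait = tr, lab = lb,
        sigma2_t = fit$vc[["sigma2_t"]], sigma2_c = fit$vc[["sigma2_c"]],
        sigma2_a = fit$vc[["sigma2_a"]], sigma2_e = fit$vc[["sigma2_e"]],
        pct_t = ps$percents[["sigma2_t"]], pct_c = ps$percents[["sigma2_c"]],
        pct_a = ps$percents[["sigma2_a"]], pct_e = ps$percents[["sigma2_e"]],
        pct_t_se = ps$percent_se[["sigma2_t"]],
        pct_c_se = ps$percent_se[["sigma2_c"]],
        pct_a_se = ps$percent_se[["sigma2_a"]],
        pct_e_se = ps$percent_se[["sigma2_e"]],
        h2 = ps$h2, h2_se = ps$h2_se, neg2_logL = fit$neg2_logL,
        converged = fit$converged, restart_spread = fit$restart_spread,
        stringsAsFactors = FALSE)
    }
    uni_fits[[tr]] <- fits
    sa <- vapply(fits, function(f) f$vc[["sigma2_a"]], numeric(1))
    se2 <- vapply(fits, function(f) f$vc[["sigma2_e"]], numeric(1))
    if (length(labs) >= 2)
      disp_rows[[tr]] <- data.frame(
        trait = tr,
        dispersion_sigma2_a = dispersion_range_over_mean(sa),
        dispersion_sigma2_e = dispersion_range_over_mean(se2),
        stringsAsFactors = FALSE)
    bt <- tryCatch({
      rw <- residuals_within_technician(rtr)
      c(bartlett_homogeneity(rw$groups),
        list(n_singleton_dropped = rw$n_singleton_dropped))
    }, error = function(e) NULL)
    if (!is.null(bt))
      bartlett_rows[[tr]] <- data.frame(
        trait = tr, statistic = bt$statistic, df = bt$df,
        p_value = bt$p_value, zero_variance_group = bt$zero_variance_group,
        stringsAsFactors = FALSE)
    if (length(labs) >= 2) {
      dst <- study_dataset(rtr, ds$pedigree)
      tfit <- fit_trivariate(dst, Ainv, start = fits, options = options)
      if (strict && !tfit$converged)
        stop("multi-lab fit did not converge: ", tr)
      tri_fits[[tr]] <- tfit
      cs <- common_sires(dst)
      ebv_by_lab <- lapply(fits, function(f) {
        e <- solve_ebv(f)
        stats::setNames(e$ebv, e$animal)
      })
      acc_by_lab <- lapply(fits, function(f) {
        e <- solve_ebv(f)
        stats::setNames(e$accuracy, e$animal)
      })
      for (pair in names(cs)) {
        li <- strsplit(pair, "-")[[1]][1]
        lj <- strsplit(pair, "-")[[1]][2]
        sires <- cs[[pair]]
        i <- match(li, tfit$labs); j <- match(lj, tfit$labs)
        rg <- genetic_correlation(tfit$G0, i, j)
        row <- data.frame(trait = tr, lab_i = li, lab_j = lj, rg = rg,
                          se = NA_real_, z = NA_real_, rejected = NA,
                          spearman = NA_real_, n_sires = length(sires),
                          stringsAsFactors = FALSE)
        if (length(sires) >= 3) {
          rik <- mean(acc_by_lab[[li]][sires])
          rjk <- mean(acc_by_lab[[lj]][sires])
          if (rik > 0 && rjk > 0) {
            row$se <- se_genetic_correlation(rg, rik, rjk, length(sires))
            zt <- rg_z_test(rg, row$se)
            row$z <- zt$z
            row$rejected <- zt$reject
          }
          sp <- spearman_ebv_correlation(ebv_by_lab[[li]][sires],
                                         ebv_by_lab[[lj]][sires])
          row$spearman <- sp$rho
        }
        rg_rows[[paste(tr, pair)]] <- row
      }
    }
  }
  bind <- function(rows) if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else NULL
  report <- structure(list(
    breed = toupper(breed),
    summary = summarize_dataset(ds),
    n_dropped_age = filt$dropped,
    violations = violations,
    univariate = bind(uni_rows),
    dispersion = bind(disp_rows),
    bartlett = bind(bartlett_rows),
    correlations = bind(rg_rows),
    uni_fits = uni_fits, tri_fits = tri_fits,
    meta = list(seed = seed, options = options,
                strict = strict)), class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report for %s: %d records after age filter\n",
              x$breed, sum(x$summary$n_records)))
  if (nrow(x$violations))
    cat(sprintf("  %d structural violation(s)\n", nrow(x$violations)))
  if (!is.null(x$univariate)) {
    cat("\nUnivariate variance components (per trait and lab):\n")
    cols <- c("trait", "lab", "sigma2_a", "sigma2_t", "sigma2_c", "sigma2_e",
              "h2", "converged")
    df <- x$univariate[cols]
    df[3:7] <- lapply(df[3:7], round, 3)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$correlations)) {
    cat("\nBetween-lab genetic correlations:\n")
    df <- x$correlations
    df$rg <- round(df$rg, 2)
    df$se <- round(df$se, 2)
    df$spearman <- round(df$spearman, 2)
    print(df[c("trait", "lab_i", "lab_j", "rg", "se", "rejected",
               "spearman", "n_sires")], row.names = FALSE)
  }
  if (!is.null(x$bartlett)) {
    cat("\nBartlett homogeneity of residuals across technicians:\n")
    print(x$bartlett, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report to files
#'
#' Emits \code{report.md} (a human-readable digest), one CSV per result
#' table under \code{tables/}, and per-fit JSON (components, likelihood and
#' convergence metadata) under \code{fits/}.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  for (d in file.path(dir, c("", "tables", "fits")))
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  for (nm in c("summary", "univariate", "dispersion", "bartlett",
               "correlations", "violations")) {
    tab <- report[[nm]]
    if (!is.null(tab) && nrow(tab))
      utils::write.csv(tab, file.path(dir, "tables", paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  for (tr in names(report$uni_fits)) for (lb in names(report$uni_fits[[tr]])) {
    f <- report$uni_fits[[tr]][[lb]]
    jsonlite::write_json(
      list(trait = tr, lab = lb, vc = as.list(f$vc),
           neg2_logL = f$neg2_logL, converged = f$converged,
           restart_neg2_logL = f$restart_neg2_logL,
           restart_spread = f$restart_spread),
      file.path(dir, "fits", sprintf("uni_%s_lab%s.json", tr, lb)),
      auto_unbox = TRUE, digits = NA)
  }
  for (tr in names(report$tri_fits)) {
    f <- report$tri_fits[[tr]]
    jsonlite::write_json(
      list(trait = tr, labs = f$labs,
           components = f$components, G0 = as.data.frame(f$G0),
           rg = as.data.frame(f$rg), neg2_logL = f$neg2_logL,
           converged = f$converged,
           restart_neg2_logL = f$restart_neg2_logL),
      file.path(dir, "fits", sprintf("tri_%s.json", tr)),
      auto_unbox = TRUE, digits = NA)
  }
  md <- file.path(dir, "report.md")
  con <- file(md, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(dir)
}
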