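#' Published variance components for ultrasound carcass traits
#'
#' The estimated technician, contemporary-group-within-technician, additive
#' genetic and residual variances for each breed (Angus, Hereford,
#' Simmental), trait (LMA in cm^2, SFD in mm, IMF in percent) and
#' image-interpretation laboratory, as published for the 2015--2017 U.S.
#' breed-association data, together with the printed integer percentages of
#' phenotypic variance. These serve as reference inputs for the derived
#' statistics (heritability, percentage partitions, range/mean dispersion)
#' and as realistic true parameters for the synthetic-data generator.
#'
#' @return Data frame with columns \code{breed}, \code{trait}, \code{lab},
#'   \code{sigma2_a}, \code{sigma2_t}, \code{sigma2_c}, \code{sigma2_e} and
#'   the printed percentages \code{pct_a}, \code{pct_t}, \code{pct_c},
#'   \code{pct_e}.
#' @export
published_variance_components <- function() {
  df <- utils::read.csv(text = 'breed,trait,lab,sigma2_a,pct_a,sigma2_t,pct_t,sigma2_c,pct_c,sigma2_e,pct_e
Angus,LMA,1,16.87,7,53.98,23,124.13,54,35.06,15
Angus,LMA,2,16.65,6,42.58,16,162.95,61,45.10,17
Angus,LMA,3,17.41,9,13.40,7,129.10,68,29.28,15
Hereford,LMA,1,18.85,9,34.24,17,120.75,59,30.50,15
Hereford,LMA,2,20.45,8,15.57,6,169.03,70,35.97,15
Hereford,LMA,3,14.75,8,8.14,4,143.16,74,28.11,14
Simmental,LMA,1,27.31,13,57.21,26,93.89,43,38.60,18
Simmental,LMA,2,33.35,13,60.64,23,126.81,49,40.31,15
Simmental,LMA,3,30.57,12,49.98,20,133.84,55,30.67,13
Angus,SFD,1,0.98,13,1.48,19,3.58,47,1.64,21
Angus,SFD,2,0.87,11,0.92,12,4.26,54,1.79,23
Angus,SFD,3,1.08,15,1.44,19,3.46,47,1.42,19
Hereford,SFD,1,0.86,13,0.64,10,3.18,47,2.04,30
Hereford,SFD,2,0.80,13,0.33,5,3.27,52,1.93,31
Hereford,SFD,3,0.74,10,1.68,23,3.16,43,1.75,24
Simmental,SFD,1,1.43,25,1.15,20,1.58,28,1.59,28
Simmental,SFD,2,0.92,22,0.70,16,1.35,31,1.32,31
Simmental,SFD,3,0.93,17,1.24,23,2.17,39,1.15,21
Angus,IMF,1,0.34,20,0.43,25,0.56,33,0.37,22
Angus,IMF,2,0.52,30,0.21,12,0.73,43,0.26,15
Angus,IMF,3,0.51,22,0.33,15,1.03,45,0.41,18
Hereford,IMF,1,0.16,16,0.21,22,0.37,34,0.27,28
Hereford,IMF,2,0.15,26,0.07,12,0.23,39,0.13,23
Hereford,IMF,3,0.24,17,0.20,14,0.69,48,0.32,22
Simmental,IMF,1,0.28,27,0.27,27,0.26,25,0.23,22
Simmental,IMF,2,0.17,26,0.10,16,0.22,34,0.16,25
Simmental,IMF,3,0.31,24,0.18,14,0.55,42,0.26,20')
  df$lab <- as.integer(df$lab)
  df
}

#' Published within-contemporary-group heritabilities
#'
#' The printed heritability estimates (\eqn{\sigma_a^2/(\sigma_a^2 +
#' \sigma_e^2)}) per breed, laboratory and trait, with standard errors.
#' Note that a minority of cells are not exactly reproducible from the
#' two-decimal published variance components (see the package vignette).
#'
#' @return Data frame with columns \code{breed}, \code{lab}, \code{trait},
#'   \code{h2}, \code{se}.
#' @export
published_heritabilities <- function() {
  utils::read.csv(text = 'breed,lab,trait,h2,se
Angus,1,LMA,0.32,0.02
Angus,2,LMA,0.27,0.03
Angus,3,LMA,0.38,0.03
Hereford,1,LMA,0.35,0.02
Hereford,2,LMA,0.35,0.03
Hereford,3,LMA,0.34,0.03
Simmental,1,LMA,0.41,0.02
Simmental,2,LMA,0.45,0.05
Simmental,3,LMA,0.50,0.03
Angus,1,SFD,0.37,0.02
Angus,2,SFD,0.33,0.03
Angus,3,SFD,0.43,0.03
Hereford,1,SFD,0.26,0.02
Hereford,2,SFD,0.25,0.03
Hereford,3,SFD,0.29,0.03
Simmental,1,SFD,0.47,0.02
Simmental,2,SFD,0.41,0.05
Simmental,3,SFD,0.45,0.03
Angus,1,IMF,0.48,0.02
Angus,2,IMF,0.67,0.04
Angus,3,IMF,0.55,0.04
Hereford,1,IMF,0.34,0.02
Hereford,2,IMF,0.49,0.03
Hereford,3,IMF,0.42,0.03
Simmental,1,IMF,0.55,0.02
Simmental,2,IMF,0.52,0.05
Simmental,3,IMF,0.54,0.03')
}

#' Published between-laboratory genetic correlations
#'
#' The printed genetic correlations between pairs of image-interpretation
#' laboratories with their standard errors and the flag of the z-test
#' against 1 at the 5\% level, plus the Spearman rank correlations of sire
#' EBVs and the number of common sires.
#'
#' @return Data frame with columns \code{breed}, \code{trait}, \code{lab_i},
#'   \code{lab_j}, \code{rg}, \code{se}, \code{rejected}, \code{spearman},
#'   \code{n_sires}.
#' @export
published_lab_correlations <- function() {
  df <- utils::read.csv(text = 'breed,trait,lab_i,lab_j,rg,se,rejected,spearman,n_sires
Angus,LMA,1,2,0.94,0.04,FALSE,0.99,417
Angus,LMA,1,3,0.96,0.04,FALSE,0.99,501
Angus,LMA,2,3,0.94,0.04,FALSE,0.99,327
Hereford,LMA,1,2,0.92,0.06,FALSE,0.95,245
Hereford,LMA,1,3,0.98,0.06,FALSE,1.00,199
Hereford,LMA,2,3,0.88,0.06,FALSE,0.96,251
Simmental,LMA,1,2,0.78,0.06,TRUE,0.88,341
Simmental,LMA,1,3,0.85,0.05,FALSE,0.94,510
Simmental,LMA,2,3,0.80,0.06,TRUE,0.93,320
Angus,SFD,1,2,0.93,0.04,FALSE,0.99,418
Angus,SFD,1,3,0.92,0.04,TRUE,0.98,501
Angus,SFD,2,3,0.92,0.04,TRUE,0.98,327
Hereford,SFD,1,2,0.70,0.11,TRUE,0.82,232
Hereford,SFD,1,3,0.58,0.14,TRUE,0.77,185
Hereford,SFD,2,3,0.26,0.14,TRUE,0.49,238
Simmental,SFD,1,2,0.82,0.05,TRUE,0.95,341
Simmental,SFD,1,3,0.94,0.04,FALSE,0.99,510
Simmental,SFD,2,3,0.79,0.06,TRUE,0.93,341
Angus,IMF,1,2,0.95,0.03,FALSE,0.99,418
Angus,IMF,1,3,0.94,0.03,TRUE,0.99,501
Angus,IMF,2,3,0.89,0.03,TRUE,0.97,327
Hereford,IMF,1,2,0.89,0.06,TRUE,0.97,245
Hereford,IMF,1,3,0.87,0.07,TRUE,0.97,200
Hereford,IMF,2,3,0.80,0.06,TRUE,0.93,251
Simmental,IMF,1,2,0.79,0.05,TRUE,0.94,341
Simmental,IMF,1,3,0.88,0.04,TRUE,0.97,320
Simmental,IMF,2,3,0.87,0.05,TRUE,0.96,510')
  df$rejected <- as.logical(df$rejected)
  df
}
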