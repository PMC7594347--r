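#' Configuration of a synthetic ultrasound study
#'
#' Describes a study with the nested structure the variance models assume:
#' laboratories, technicians reporting to exactly one laboratory,
#' contemporary groups scanned by exactly one technician, and recorded
#' animals from paternal half-sib (or full-sib) families whose sires may have
#' progeny under several laboratories.
#'
#' The default parameters emulate the Angus LMA lab-1 cell of the study this
#' package reproduces: technician variance 53.98, contemporary-group variance
#' 124.13, additive genetic variance 16.87, residual variance 35.06
#' (cm^4) around a mean of 78.2 cm^2, with scan ages uniform inside the
#' breed's 320--460 d acceptance window.
#'
#' @param n_labs number of laboratories (1 for univariate designs, 3 for the
#'   lab-as-trait model).
#' @param technicians_per_lab,cgs_per_technician,animals_per_cg structure
#'   sizes.
#' @param n_sires number of founder sires; default one sire per ~10 recorded
#'   animals, giving paternal half-sib families.
#' @param n_dams number of founder dams; default one dam per recorded animal.
#' @param sire_sharing fraction of sires whose progeny may appear under any
#'   laboratory (genetic links identifying cross-lab genetic covariances).
#' @param sigma2_t,sigma2_c,sigma2_e true variances, scalars or per-lab
#'   vectors.
#' @param sigma2_a true additive genetic variance (scalar); ignored when
#'   \code{G0} is given.
#' @param G0 true genetic covariance across lab-traits (\code{n_labs} square,
#'   positive semidefinite); \code{NULL} for a single shared genetic trait.
#' @param mu phenotypic mean, scalar or per-lab vector.
#' @param breed one of ANGUS, HEREFORD, SIMMENTAL (sets the scan-age window).
#' @param trait trait code (LMA, SFD, IMF).
#' @param generations 2 (founders + recorded) or 3 (dams themselves have
#'   recorded parents, giving three-generation pedigrees).
#' @param cg_size_dispersion \code{NULL} for fixed contemporary-group sizes;
#'   otherwise the negative-binomial \code{size} parameter used to draw
#'   skewed group sizes with mean \code{animals_per_cg} (minimum 1).
#' @param seed integer seed; the generator is deterministic given the
#'   configuration.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_labs = 3, technicians_per_lab = 10,
                       cgs_per_technician = 8, animals_per_cg = 10,
                       n_sires = NULL, n_dams = NULL, sire_sharing = 1,
                       sigma2_t = 53.98, sigma2_c = 124.13,
                       sigma2_a = 16.87, G0 = NULL, sigma2_e = 35.06,
                       mu = 78.2, breed = "ANGUS", trait = "LMA",
                       generations = 2, cg_size_dispersion = NULL,
                       seed = 1) {
  n_rec <- n_labs * technicians_per_lab * cgs_per_technician * animals_per_cg
  if (is.null(n_sires)) n_sires <- max(2L, round(n_rec / 10))
  if (is.null(n_dams)) n_dams <- n_rec
  stopifnot(n_labs >= 1, technicians_per_lab >= 1, cgs_per_technician >= 1,
            animals_per_cg >= 1, n_sires >= 1, n_dams >= 1,
            sire_sharing >= 0, sire_sharing <= 1, generations %in% c(2, 3))
  breed <- toupper(breed)
  if (!breed %in% names(breed_age_windows())) stop("unknown breed: ", breed)
  expand <- function(x) if (length(x) == 1) rep(x, n_labs) else x
  cfg <- list(n_labs = n_labs, technicians_per_lab = technicians_per_lab,
              cgs_per_technician = cgs_per_technician,
              animals_per_cg = animals_per_cg, n_sires = n_sires,
              n_dams = n_dams, sire_sharing = sire_sharing,
              sigma2_t = expand(sigma2_t), sigma2_c = expand(sigma2_c),
              sigma2_a = sigma2_a, G0 = G0, sigma2_e = expand(sigma2_e),
              mu = expand(mu), breed = breed, trait = toupper(trait),
              generations = generations,
              cg_size_dispersion = cg_size_dispersion, seed = as.integer(seed))
  if (!is.null(G0)) {
    stopifnot(nrow(G0) == n_labs, isSymmetric(unname(G0)),
              min(eigen(G0, only.values = TRUE)$values) > -1e-8)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' The default single-laboratory scenario
#'
#' Convenience wrapper for the univariate Angus LMA lab-1 scenario at the
#' package's testing scale: one laboratory, 10 technicians of 8 contemporary
#' groups of 10 animals, paternal half-sib families.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
sim_config_angus_lab1 <- function(seed = 1, ...) {
  sim_config(n_labs = 1, seed = seed, ...)
}

# independent RNG substream per component so changing one configuration
# field perturbs only the draws of that component
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.numeric(seed) * 10007 + h * 97) %% 2147483629
}

# deterministic study design: one row per recorded animal with its lab,
# technician, contemporary group, sire and dam
sim_design <- function(cfg) {
  set.seed(substream(cfg$seed, "design"))
  sires <- sprintf("S%04d", seq_len(cfg$n_sires))
  n_shared <- round(cfg$sire_sharing * cfg$n_sires)
  shared <- sires[seq_len(n_shared)]
  rest <- setdiff(sires, shared)
  lab_specific <- if (length(rest))
    split(rest, rep_len(seq_len(cfg$n_labs), length(rest)))
  else rep(list(character(0)), cfg$n_labs)
  # dams belong to a single herd and therefore to a single laboratory;
  # only sires create genetic links across laboratories
  dam_pool <- split(sprintf("D%04d", seq_len(cfg$n_dams)),
                    rep_len(seq_len(cfg$n_labs), cfg$n_dams))
  rows <- list()
  aid <- 0L
  for (l in seq_len(cfg$n_labs)) {
    pool <- c(shared, lab_specific[[min(l, length(lab_specific))]])
    dams_l <- dam_pool[[l]]
    for (te in seq_len(cfg$technicians_per_lab)) {
      tech_id <- sprintf("L%dT%02d", l, te)
      for (cg in seq_len(cfg$cgs_per_technician)) {
        cg_id <- sprintf("%sC%02d", tech_id, cg)
        n_in_cg <- if (is.null(cfg$cg_size_dispersion)) cfg$animals_per_cg
        else max(1L, stats::rnbinom(1, size = cfg$cg_size_dispersion,
                                    mu = cfg$animals_per_cg))
        for (k in seq_len(n_in_cg)) {
          aid <- aid + 1L
          rows[[aid]] <- data.frame(
            animal = sprintf("A%05d", aid), lab = as.character(l),
            technician = tech_id, cg = cg_id,
            sire = sample(pool, 1),
            dam = dams_l[sample.int(length(dams_l), 1)],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a pedigree with the study's family structure
#'
#' Founder sires and dams are unrelated; the recorded generation arises from
#' random sire-by-dam matings, giving paternal half-sib families.
#' \code{sire_sharing} controls how many sires have progeny under more than
#' one laboratory. With \code{generations = 3}, dams are themselves offspring
#' of a disjoint founder generation, yielding three-generation pedigrees
#' (and, by construction, no inbreeding).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A \code{\link{new_pedigree}} in sire-dam mode.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  des <- sim_design(cfg)
  dams <- sort(unique(des$dam))
  if (cfg$generations >= 3) {
    set.seed(substream(cfg$seed, "granddesign"))
    n_gs <- max(2L, ceiling(length(dams) / 10))
    dam_rows <- data.frame(
      animal = dams,
      parent1 = sprintf("GS%04d", sample.int(n_gs, length(dams),
                                             replace = TRUE)),
      parent2 = sprintf("GD%04d", seq_along(dams)),
      stringsAsFactors = FALSE)
  } else {
    dam_rows <- data.frame(animal = dams, parent1 = NA_character_,
                           parent2 = NA_character_, stringsAsFactors = FALSE)
  }
  new_pedigree(c(dam_rows$animal, des$animal),
               c(dam_rows$parent1, des$sire),
               c(dam_rows$parent2, des$dam))
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw from \eqn{N(0, \sigma_a^2)} (or \eqn{N(0, G_0)} for
#' correlated lab-traits); non-founders are the parent average plus a
#' Mendelian-sampling deviation with variance 1/2, 3/4 or 1 times the
#' genetic (co)variance for two, one or zero known parents (non-inbred
#' parents assumed, which the generator guarantees).
#'
#' @param ped a topologically ordered \code{pedigree}.
#' @param genetic_params scalar \eqn{\sigma_a^2} or a PSD matrix \eqn{G_0}.
#' @param seed integer seed.
#' @return Named vector (scalar case) or matrix with one row per animal.
#' @export
simulate_breeding_values <- function(ped, genetic_params, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(as.integer(seed %% 2147483629))
  n <- nrow(ped)
  pi <- ped_indices(ped)
  G <- if (is.matrix(genetic_params)) genetic_params
       else matrix(genetic_params, 1, 1)
  k <- nrow(G)
  Lg <- if (all(G == 0)) matrix(0, k, k) else t(chol(G + 1e-12 * diag(k)))
  bv <- matrix(0, n, k)
  for (i in seq_len(n)) {
    s <- pi$p1[i]; d <- pi$p2[i]
    known <- sum(!is.na(c(s, d)))
    pa <- numeric(k)
    if (!is.na(s)) pa <- pa + 0.5 * bv[s, ]
    if (!is.na(d)) pa <- pa + 0.5 * bv[d, ]
    mvar <- c(1, 0.75, 0.5)[known + 1]
    bv[i, ] <- pa + sqrt(mvar) * as.numeric(Lg %*% stats::rnorm(k))
  }
  rownames(bv) <- ped$animal
  if (k == 1) stats::setNames(bv[, 1], ped$animal) else bv
}

#' Simulate a complete study dataset
#'
#' Draws technician, contemporary-group, genetic and residual effects at the
#' configured true variances and assembles phenotypes
#' \eqn{y = \mu_{lab} + t + c + a + e}, with scan ages uniform inside the
#' breed's acceptance window. The output satisfies every structural
#' invariant checked by \code{\link{validate_structure}} and is byte-stable
#' under a fixed configuration.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A \code{\link{study_dataset}}.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  des <- sim_design(cfg)
  ped <- simulate_pedigree(cfg)
  gp <- if (is.null(cfg$G0)) cfg$sigma2_a else cfg$G0
  bv <- simulate_breeding_values(ped, gp, substream(cfg$seed, "bv"))
  set.seed(substream(cfg$seed, "effects"))
  lab <- as.integer(des$lab)
  techs <- unique(des$technician)
  cgs <- unique(des$cg)
  tech_lab <- lab[match(techs, des$technician)]
  cg_lab <- lab[match(cgs, des$cg)]
  t_eff <- stats::setNames(stats::rnorm(length(techs),
                                        sd = sqrt(cfg$sigma2_t[tech_lab])),
                           techs)
  c_eff <- stats::setNames(stats::rnorm(length(cgs),
                                        sd = sqrt(cfg$sigma2_c[cg_lab])),
                           cgs)
  e <- stats::rnorm(nrow(des), sd = sqrt(cfg$sigma2_e[lab]))
  a <- if (is.matrix(bv))
    bv[cbind(match(des$animal, rownames(bv)), lab)]
  else bv[des$animal]
  set.seed(substream(cfg$seed, "ages"))
  win <- breed_age_windows()[[cfg$breed]]
  ages <- sample(seq(win[1], win[2]), nrow(des), replace = TRUE)
  records <- data.frame(
    animal = des$animal, breed = cfg$breed, trait = cfg$trait,
    value = cfg$mu[lab] + t_eff[des$technician] + c_eff[des$cg] + a + e,
    technician = des$technician, cg = des$cg, lab = des$lab,
    age_days = ages, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  suppressWarnings(study_dataset(records, ped))
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Emits \code{records.csv}, \code{pedigree.csv}, \code{config.yaml} and
#' \code{truth.json} (the true simulation parameters, for recovery tests)
#' into a directory.
#'
#' @param ds a \code{study_dataset}.
#' @param dir output directory (created if absent).
#' @param cfg the \code{sim_config} that generated \code{ds} (stored as the
#'   configuration and truth files); optional.
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(ds, dir, cfg = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_records(ds$records, file.path(dir, "records.csv"))
  write_pedigree(ds$pedigree, file.path(dir, "pedigree.csv"))
  if (!is.null(cfg)) {
    plain <- unclass(cfg)
    plain$G0 <- if (is.null(cfg$G0)) NULL else as.numeric(cfg$G0)
    yaml::write_yaml(plain, file.path(dir, "config.yaml"))
    truth <- list(sigma2_t = cfg$sigma2_t, sigma2_c = cfg$sigma2_c,
                  sigma2_a = cfg$sigma2_a, sigma2_e = cfg$sigma2_e,
                  G0 = if (is.null(cfg$G0)) NULL else as.numeric(cfg$G0),
                  mu = cfg$mu, seed = cfg$seed)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a fixture directory back into a study dataset
#'
#' @param dir directory written by \code{\link{write_fixture}}.
#' @return List with \code{dataset} (a \code{study_dataset}) and, when
#'   present, \code{config} and \code{truth}.
#' @examples
#' fx <- read_fixture(system.file("extdata", "synthetic_angus_lma",
#'                                package = "ultravar"))
#' fx$dataset
#' @export
read_fixture <- function(dir) {
  ds <- study_dataset(read_records(file.path(dir, "records.csv")),
                      read_pedigree(file.path(dir, "pedigree.csv")))
  out <- list(dataset = ds)
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) out$config <- yaml::read_yaml(cfg_path)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) out$truth <- jsonlite::read_json(
    truth_path, simplifyVector = TRUE)
  out
}
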