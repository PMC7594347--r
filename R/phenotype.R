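#' @title Ultrasound phenotype records and study datasets
#' @description Record-level containers and structural checks for the nested
#'   study design: contemporary groups (CG) scanned by exactly one technician,
#'   technicians reporting to exactly one image-interpretation laboratory,
#'   and every recorded animal present in the pedigree.
#' @name phenotype
NULL

#' Recognised ultrasound carcass traits and their units
#' @return Named character vector mapping trait code to unit.
#' @export
trait_units <- function() {
  c(LMA = "cm2", SFD = "mm", IMF = "%")
}

# Scan-age windows (days, closed intervals) used by the breed associations.
breed_age_windows <- function() {
  list(ANGUS = c(320L, 460L), SIMMENTAL = c(270L, 500L),
       HEREFORD = c(301L, 530L))
}

# Plausibility bounds per trait: observed data extremes padded ~20%.
# Violations warn rather than error: association data are taken as provided.
trait_bounds <- function() {
  list(LMA = c(20, 160), SFD = c(0.2, 28), IMF = c(0.25, 15))
}

#' Read ultrasound records from CSV
#'
#' Expects the header
#' \code{animal,breed,trait,value,technician,cg,lab,age_days}. Values outside
#' the per-trait plausibility bounds raise a warning (not an error).
#'
#' @param path CSV file path.
#' @return Data frame of records with typed columns.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("animal", "breed", "trait", "value", "technician", "cg",
              "lab", "age_days")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("records file missing column(s): ", paste(missing, collapse = ", "))
  df$value <- as.numeric(df$value)
  df$age_days <- as.integer(df$age_days)
  df$breed <- toupper(df$breed)
  df$trait <- toupper(df$trait)
  validate_records(df)
  df[needed]
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  bad_trait <- setdiff(unique(records$trait), names(trait_units()))
  if (length(bad_trait))
    stop("unknown trait code(s): ", paste(bad_trait, collapse = ", "))
  if (nrow(records) && any(records$age_days <= 0, na.rm = TRUE))
    stop("age_days must be positive")
  bounds <- trait_bounds()
  for (tr in unique(records$trait)) {
    v <- records$value[records$trait == tr]
    b <- bounds[[tr]]
    n_out <- sum(v < b[1] | v > b[2], na.rm = TRUE)
    if (n_out > 0)
      warning(sprintf("%d %s value(s) outside plausibility bounds [%g, %g]",
                      n_out, tr, b[1], b[2]), call. = FALSE)
  }
  invisible(records)
}

#' Bundle records and pedigree into a study dataset
#'
#' @param records data frame as returned by \code{\link{read_records}}.
#' @param pedigree a \code{\link{new_pedigree}} object covering all recorded
#'   animals.
#' @return An object of class \code{study_dataset} (list with elements
#'   \code{records}, \code{pedigree}).
#' @export
study_dataset <- function(records, pedigree) {
  validate_records(records)
  stopifnot(inherits(pedigree, "pedigree"))
  structure(list(records = records, pedigree = pedigree),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Study dataset: %d records (%d animals, %d technicians, %d CGs, %d labs), pedigree of %d\n",
    nrow(x$records), length(unique(x$records$animal)),
    length(unique(x$records$technician)), length(unique(x$records$cg)),
    length(unique(x$records$lab)), nrow(x$pedigree)))
  invisible(x)
}

#' Validate the nesting structure of a study dataset
#'
#' Checks the three structural invariants the variance models rely on: each
#' contemporary group scanned by exactly one technician, each technician
#' reporting to exactly one laboratory, and every recorded animal present in
#' the pedigree. Repeated animal-by-trait observations are also flagged (the
#' models carry no permanent-environment effect).
#'
#' @param ds a \code{study_dataset}.
#' @return Data frame of violations with columns \code{type}, \code{id},
#'   \code{detail}; zero rows iff the dataset is structurally valid.
#' @export
validate_structure <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  r <- ds$records
  out <- data.frame(type = character(0), id = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  add <- function(type, id, detail) {
    out[nrow(out) + 1, ] <<- list(type, id, detail)
  }
  by_cg <- tapply(r$technician, r$cg, function(x) unique(x))
  for (cg in names(by_cg))
    if (length(by_cg[[cg]]) > 1)
      add("cg_multiple_technicians", cg,
          paste(sort(by_cg[[cg]]), collapse = ","))
  by_tech <- tapply(r$lab, r$technician, function(x) unique(x))
  for (te in names(by_tech))
    if (length(by_tech[[te]]) > 1)
      add("technician_multiple_labs", te,
          paste(sort(by_tech[[te]]), collapse = ","))
  absent <- setdiff(unique(r$animal), ds$pedigree$animal)
  for (an in absent) add("animal_not_in_pedigree", an, "")
  dup <- r[duplicated(r[c("animal", "trait")]), c("animal", "trait")]
  for (k in seq_len(nrow(dup)))
    add("repeated_measure", dup$animal[k], dup$trait[k])
  out
}

#' Apply the breed-specific scan-age window
#'
#' Keeps records whose age at scanning lies inside the closed interval the
#' breed association accepts for genetic evaluation: 320--460 d (Angus),
#' 270--500 d (Simmental), 301--530 d (Hereford).
#'
#' @param records data frame of records.
#' @param breed breed to filter; \code{NULL} (default) uses each record's own
#'   \code{breed} column.
#' @return List with \code{kept} (records inside the window) and
#'   \code{dropped} (count removed).
#' @export
filter_age_window <- function(records, breed = NULL) {
  windows <- breed_age_windows()
  b <- if (is.null(breed)) toupper(records$breed) else
    rep(toupper(breed), nrow(records))
  bad <- setdiff(unique(b), names(windows))
  if (length(bad)) stop("unknown breed(s): ", paste(bad, collapse = ", "))
  if (!nrow(records)) return(list(kept = records, dropped = 0L))
  lo <- vapply(windows, `[`, numeric(1), 1)[b]
  hi <- vapply(windows, `[`, numeric(1), 2)[b]
  keep <- records$age_days >= lo & records$age_days <= hi
  list(kept = records[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Summarise a study dataset by breed, trait and laboratory
#'
#' One row per breed-by-trait-by-lab cell: record count, number of
#' technicians, number of contemporary groups, mean, SD, minimum and maximum
#' of the phenotype. Cells with a single record report \code{sd = 0} and are
#' flagged \code{zero_variance}.
#'
#' @param ds a \code{study_dataset} (or a bare records data frame).
#' @return Data frame of summaries.
#' @export
summarize_dataset <- function(ds) {
  r <- if (inherits(ds, "study_dataset")) ds$records else ds
  if (!nrow(r)) stop("no records to summarise")
  key <- interaction(r$breed, r$trait, r$lab, drop = TRUE)
  rows <- lapply(split(r, key), function(g) {
    data.frame(breed = g$breed[1], trait = g$trait[1], lab = g$lab[1],
               n_records = nrow(g),
               n_technicians = length(unique(g$technician)),
               n_cgs = length(unique(g$cg)),
               mean = mean(g$value),
               sd = if (nrow(g) > 1) stats::sd(g$value) else 0,
               min = min(g$value), max = max(g$value),
               zero_variance = nrow(g) < 2 || stats::var(g$value) == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$breed, out$trait, out$lab), ]
}

#' Write ultrasound records to CSV
#'
#' @param records data frame of records.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("animal", "breed", "trait", "value", "technician", "cg",
            "lab", "age_days")
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
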