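#' Construct a pedigree
#'
#' Builds a topologically ordered pedigree from parallel vectors of animal and
#' parent identifiers. Two parent conventions are supported: \code{"sire_dam"}
#' (parent1 = sire, parent2 = dam) and \code{"sire_mgs"} (parent1 = sire,
#' parent2 = maternal grandsire), the latter being the form used when dams are
#' untracked and relationships flow through the maternal grandsire with weight
#' 1/4 instead of 1/2.
#'
#' Identifiers are opaque strings; \code{"0"}, \code{""} and \code{NA} denote
#' an unknown parent. Animals that appear only as parents are inserted as
#' founders, so three-generation pedigrees may list ancestors without their own
#' rows. Duplicate animal rows and parentage cycles are rejected.
#'
#' @param animal character vector of animal ids.
#' @param parent1 character vector, sire ids.
#' @param parent2 character vector, dam ids (or maternal-grandsire ids in
#'   \code{"sire_mgs"} mode).
#' @param mode \code{"sire_dam"} or \code{"sire_mgs"}.
#' @return An object of class \code{pedigree}: a data frame with columns
#'   \code{animal}, \code{parent1}, \code{parent2} (\code{NA} = unknown) in
#'   topological order (every parent precedes its offspring), with attributes
#'   \code{mode} and \code{founder} (logical, inserted-founder flag).
#' @examples
#' ped <- new_pedigree(c("C"), c("A"), c("B"))
#' ped$animal  # A, B auto-inserted as founders ahead of C
#' @export
new_pedigree <- function(animal, parent1, parent2,
                         mode = c("sire_dam", "sire_mgs")) {
  mode <- match.arg(mode)
  animal <- as.character(animal)
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  parent1 <- clean(parent1)
  parent2 <- clean(parent2)
  if (length(parent1) != length(animal) || length(parent2) != length(animal))
    stop("animal, parent1 and parent2 must have equal length")
  if (anyNA(animal) || any(animal == "" | animal == "0"))
    stop("animal ids must be non-missing and distinct from the unknown code")
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (any(!is.na(parent1) & parent1 == animal) ||
      any(!is.na(parent2) & parent2 == animal))
    stop("animal listed as its own parent")

  # auto-insert parents that lack their own rows as founders
  extra <- setdiff(stats::na.omit(c(parent1, parent2)), animal)
  inserted <- c(rep(FALSE, length(animal)), rep(TRUE, length(extra)))
  animal <- c(animal, extra)
  parent1 <- c(parent1, rep(NA_character_, length(extra)))
  parent2 <- c(parent2, rep(NA_character_, length(extra)))

  ord <- toposort_pedigree(animal, parent1, parent2)
  ped <- data.frame(animal = animal[ord], parent1 = parent1[ord],
                    parent2 = parent2[ord], stringsAsFactors = FALSE)
  structure(ped, mode = mode, founder = inserted[ord],
            class = c("pedigree", "data.frame"))
}

# Kahn's algorithm over the parent -> offspring DAG; errors naming a cycle
# member if the pedigree is not acyclic.
toposort_pedigree <- function(animal, parent1, parent2) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  p1 <- idx[parent1]
  p2 <- idx[parent2]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(p1[i], p2[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    member <- animal[setdiff(seq_len(n), out)][1]
    stop("pedigree contains a cycle involving animal '", member, "'")
  }
  out
}

#' Read a pedigree from CSV
#'
#' Expects a header \code{animal,sire,dam} (or \code{animal,sire,mgs});
#' \code{"0"} or an empty field denotes an unknown parent. The mode defaults to
#' the header actually present.
#'
#' @param path CSV file path.
#' @param mode parent convention; \code{NULL} (default) infers it from the
#'   header (\code{mgs} column implies \code{"sire_mgs"}).
#' @return A \code{\link{new_pedigree}} object.
#' @export
read_pedigree <- function(path, mode = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"animal" %in% names(df) || ncol(df) < 3)
    stop("pedigree file must have columns animal,sire,dam (or animal,sire,mgs)")
  inferred <- if ("mgs" %in% names(df)) "sire_mgs" else "sire_dam"
  if (is.null(mode)) mode <- inferred
  second <- if ("dam" %in% names(df)) df$dam else df$mgs
  new_pedigree(df$animal, df$sire, second, mode = mode)
}

#' Write a pedigree to CSV
#'
#' Inverse of \code{\link{read_pedigree}}: unknown parents are written as
#' \code{"0"}, and the second parent column is named \code{dam} or \code{mgs}
#' according to the pedigree mode.
#'
#' @param ped a \code{pedigree}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  df <- data.frame(animal = ped$animal,
                   sire = ifelse(is.na(ped$parent1), "0", ped$parent1),
                   second = ifelse(is.na(ped$parent2), "0", ped$parent2),
                   stringsAsFactors = FALSE)
  names(df)[3] <- if (attr(ped, "mode") == "sire_mgs") "mgs" else "dam"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree (%s mode): %d animals, %d founders\n",
              attr(x, "mode"), nrow(x),
              sum(is.na(x$parent1) & is.na(x$parent2))))
  invisible(x)
}

# internal: 0-based-free integer indices of parents in topological order
ped_indices <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  list(p1 = unname(idx[ped$parent1]), p2 = unname(idx[ped$parent2]), idx = idx)
}

#' Inbreeding coefficients
#'
#' Computes Wright's inbreeding coefficient \eqn{F_i = a(s_i, d_i)/2}, half the
#' additive relationship between the parents, by the recursive kinship
#' (coancestry) method with memoisation. In sire--maternal-grandsire mode the
#' maternal line is untracked, so all coefficients are returned as zero.
#'
#' @param ped a \code{pedigree}.
#' @return Named numeric vector of F, one entry per animal, in pedigree order.
#' @examples
#' ped <- new_pedigree(c("X", "Y", "K"), c("S", "S", "X"), c("D", "D", "Y"))
#' inbreeding_coefficients(ped)[["K"]]  # offspring of full sibs: 0.25
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  F <- numeric(n)
  names(F) <- ped$animal
  if (attr(ped, "mode") == "sire_mgs" || n == 0) return(F)
  pi <- ped_indices(ped)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  # kinship phi(i,j); phi(i,i) = (1 + F_i)/2 with F_i = phi(s_i, d_i)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    if (!is.null(v <- cache[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(pi$p1[i], pi$p2[i]))
    } else {
      # j later in topological order, so recurse through j's parents
      0.5 * (phi(i, pi$p1[j]) + phi(i, pi$p2[j]))
    }
    cache[[key]] <- v
    v
  }
  for (i in seq_len(n)) F[i] <- phi(pi$p1[i], pi$p2[i])
  F
}

#' Dense numerator relationship matrix A
#'
#' Tabular recurrence over the topologically ordered pedigree. In
#' \code{sire_dam} mode: \eqn{a_{ij} = (a_{j,s(i)} + a_{j,d(i)})/2} for
#' \eqn{j < i} and \eqn{a_{ii} = 1 + a_{s(i),d(i)}/2}. In \code{sire_mgs}
#' mode: \eqn{a_{ij} = a_{j,s(i)}/2 + a_{j,mgs(i)}/4} with \eqn{a_{ii} = 1}
#' (non-inbred convention). Intended for testing-scale pedigrees; use
#' \code{\link{build_A_inverse}} for model fitting.
#'
#' @param ped a \code{pedigree}.
#' @return Dense symmetric matrix with animal ids as dimnames; diagonal
#'   \eqn{1 + F_i}.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pi <- ped_indices(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  mgs <- attr(ped, "mode") == "sire_mgs"
  w <- if (mgs) c(0.5, 0.25) else c(0.5, 0.5)
  for (i in seq_len(n)) {
    s <- pi$p1[i]; d <- pi$p2[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (!is.na(s)) row <- row + w[1] * A[j, s]
      if (!is.na(d)) row <- row + w[2] * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- if (mgs) 1 else {
      1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules: for each animal \eqn{i} with Mendelian-sampling variance
#' \eqn{d_i}, add \eqn{\alpha_i = 1/d_i} at \eqn{(i,i)},
#' \eqn{-\alpha_i k_p} at \eqn{(i,p)} and \eqn{\alpha_i k_p k_q} at
#' \eqn{(p,q)} over the known parents, with weights \eqn{k = 1/2} for sire and
#' dam, or \eqn{(1/2, 1/4)} for sire and maternal grandsire.
#'
#' Mendelian-sampling variances: \code{sire_dam} without inbreeding uses
#' 1/2, 3/4, 1 for both/one/no parents known; with
#' \code{include_inbreeding = TRUE} the both-parent case becomes
#' \eqn{1/2 - (F_s + F_d)/4} and the one-parent case \eqn{3/4 - F_p/4}.
#' \code{sire_mgs} uses 11/16, 3/4, 15/16, 1 for (sire+mgs)/(sire)/(mgs)/
#' (neither) known and ignores inbreeding (maternal line untracked).
#'
#' @param ped a \code{pedigree}.
#' @param include_inbreeding adjust \eqn{d_i} for parental inbreeding
#'   (default \code{FALSE}).
#' @return Sparse symmetric matrix (\code{Matrix::dsCMatrix}) with animal ids
#'   as dimnames.
#' @export
build_A_inverse <- function(ped, include_inbreeding = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pi <- ped_indices(ped)
  mgs <- attr(ped, "mode") == "sire_mgs"
  Fc <- if (include_inbreeding && !mgs) inbreeding_coefficients(ped) else numeric(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, v) {
    ii[[length(ii) + 1]] <<- i; jj[[length(jj) + 1]] <<- j
    xx[[length(xx) + 1]] <<- v
  }
  for (i in seq_len(n)) {
    par <- c(pi$p1[i], pi$p2[i])
    w <- if (mgs) c(0.5, 0.25) else c(0.5, 0.5)
    known <- !is.na(par)
    d <- if (mgs) {
      if (all(known)) 11 / 16
      else if (known[1]) 3 / 4
      else if (known[2]) 15 / 16
      else 1
    } else {
      if (all(known)) 0.5 - 0.25 * (Fc[par[1]] + Fc[par[2]])
      else if (any(known)) 0.75 - 0.25 * Fc[par[known]]
      else 1
    }
    a <- 1 / d
    push(i, i, a)
    kp <- par[known]; kw <- w[known]
    for (u in seq_along(kp)) {
      push(i, kp[u], -a * kw[u])
      push(kp[u], i, -a * kw[u])
      for (v in seq_along(kp)) push(kp[u], kp[v], a * kw[u] * kw[v])
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
}

#' Export a sparse A-inverse as coordinate triplets
#'
#' Writes the lower triangle as a three-column text file \code{i j value} with
#' 0-based indices, one nonzero per line.
#'
#' @param Ainv sparse symmetric matrix from \code{\link{build_A_inverse}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_A_inverse <- function(Ainv, path) {
  tri <- methods::as(Matrix::tril(Ainv), "TsparseMatrix")
  df <- data.frame(i = tri@i, j = tri@j, value = tri@x)
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
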