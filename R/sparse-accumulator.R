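# Fixed-pattern symmetric sparse accumulator.
#
# REML likelihood evaluations refactorise the same coefficient matrix pattern
# thousands of times with different variance multipliers. Building that
# matrix by sparse addition each time dominates the cost, so the pattern is
# assembled once: every component entry (design cross-products, ridge
# diagonals, relationship-inverse blocks) is mapped to its slot in the
# template's @x vector together with a base value and a multiplier class.
# An evaluation is then one vectorised rowsum.

sym_accumulator <- function(i, j, base, class_id, n) {
  stopifnot(length(i) == length(j), length(i) == length(base),
            length(i) == length(class_id))
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  template <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                                   symmetric = TRUE)
  tT <- methods::as(template, "TsparseMatrix")
  key_t <- as.numeric(tT@j) * n + as.numeric(tT@i)
  key_c <- (as.numeric(j) - 1) * n + (as.numeric(i) - 1)
  pos <- match(key_c, key_t)
  if (anyNA(pos)) stop("internal error: accumulator pattern mismatch")
  # slot-by-class scatter matrix: assembly becomes one sparse mat-vec
  S <- Matrix::sparseMatrix(i = pos, j = as.integer(class_id), x = base,
                            dims = c(length(tT@x), max(class_id)))
  list(template = template, S = S)
}

acc_matrix <- function(acc, mult) {
  C <- acc$template
  C@x <- as.numeric(acc$S %*% mult)
  C
}

# triplets (1-based) of a sparse matrix, keeping only stored entries
sparse_triplets <- function(M, general = FALSE) {
  if (general) M <- methods::as(M, "generalMatrix")
  T <- methods::as(M, "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L, x = T@x)
}
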