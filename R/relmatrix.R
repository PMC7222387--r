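#' Relationship matrix container
#'
#' Light wrapper pairing a (dense or sparse) symmetric matrix with the
#' animal identifiers its rows refer to, the kind of matrix it is, and --
#' for combined pedigree-genomic kinds -- the positions of the genotyped
#' animals.
#'
#' @param values symmetric numeric matrix (base matrix or `Matrix` sparse).
#' @param ids character vector of animal identifiers, one per row.
#' @param kind one of `"A"`, `"G"`, `"H"`, `"A_inv"`, `"H_inv"`, `"G_inv"`,
#'   `"A22"`, `"A22_inv"`.
#' @param genotyped_index integer positions of genotyped animals within
#'   `ids` (for `H` kinds), or `NULL`.
#' @return An object of class `relmat`.
#' @export
relmat <- function(values, ids,
                   kind = c("A", "G", "H", "A_inv", "H_inv", "G_inv",
                            "A22", "A22_inv"),
                   genotyped_index = NULL) {
  kind <- match.arg(kind)
  stopifnot(nrow(values) == length(ids), ncol(values) == length(ids))
  structure(list(values = values, ids = as.character(ids), kind = kind,
                 genotyped_index = genotyped_index),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat %s> %d x %d (%s)\n", x$kind, length(x$ids),
              length(x$ids),
              if (is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.relmat <- function(x) dim(x$values)

#' @export
as.matrix.relmat <- function(x, ...) as.matrix(x$values)

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Computes the dense additive relationship matrix A by the tabular
#' recursion: for animal `i` with parents `s`, `d`,
#' `a_ij = 0.5 (a_js + a_jd)` for earlier animals `j`, and
#' `a_ii = 1 + 0.5 a_sd`; unknown-parent terms contribute 0. Diagonals are
#' therefore `1 + F_i`.
#'
#' @param ped a [pedigree()] object.
#' @return A [relmat()] of kind `"A"`.
#' @export
compute_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  A <- tabular_A(ifelse(is.na(ped$sire_idx), -1L, ped$sire_idx - 1L),
                 ifelse(is.na(ped$dam_idx), -1L, ped$dam_idx - 1L))
  dimnames(A) <- list(ped$id, ped$id)
  relmat(A, ped$id, "A")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules with
#' inbreeding: each animal contributes `alpha_i = 1/d_i` (the reciprocal of
#' its Mendelian-sampling variance, from the Meuwissen-Luo recursion on
#' parental inbreeding) to the diagonal, `-alpha_i/2` to animal-parent
#' cells and `alpha_i/4` to parent-parent cells. The dense A is never
#' formed.
#'
#' @param ped a [pedigree()] object.
#' @return A [relmat()] of kind `"A_inv"` holding a sparse symmetric matrix.
#' @export
compute_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  alpha <- 1 / ped$D
  s <- ped$sire_idx; d <- ped$dam_idx
  i0 <- seq_len(n)

  ii <- i0; jj <- i0; xx <- alpha                    # (i,i)
  hs <- !is.na(s); hd <- !is.na(d)
  ii <- c(ii, i0[hs], s[hs]); jj <- c(jj, s[hs], i0[hs])
  xx <- c(xx, -alpha[hs] / 2, -alpha[hs] / 2)        # (i,s), (s,i)
  ii <- c(ii, i0[hd], d[hd]); jj <- c(jj, d[hd], i0[hd])
  xx <- c(xx, -alpha[hd] / 2, -alpha[hd] / 2)        # (i,d), (d,i)
  ii <- c(ii, s[hs], d[hd]); jj <- c(jj, s[hs], d[hd])
  xx <- c(xx, alpha[hs] / 4, alpha[hd] / 4)          # (s,s), (d,d)
  both <- hs & hd
  ii <- c(ii, s[both], d[both]); jj <- c(jj, d[both], s[both])
  xx <- c(xx, alpha[both] / 4, alpha[both] / 4)      # (s,d), (d,s)

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  relmat(Ainv, ped$id, "A_inv")
}

#' Extract pedigree-relationship blocks for genotyped/ungenotyped subsets
#'
#' Partitions A into the ungenotyped (subscript 1) and genotyped
#' (subscript 2) blocks used by the combined-matrix formulas. `A22_inv` is
#' the inverse of the extracted `A22` block, not the genotyped block of
#' A-inverse.
#'
#' @param A a [relmat()] of kind `"A"`.
#' @param genotyped_ids identifiers of the genotyped animals (subset of
#'   `A$ids`).
#' @return A list with dense matrices `A11`, `A12`, `A22`, `A22_inv` and
#'   the integer index vectors `idx1` (ungenotyped) and `idx2` (genotyped).
#' @export
extract_blocks <- function(A, genotyped_ids) {
  stopifnot(inherits(A, "relmat"), A$kind == "A")
  idx2 <- match(as.character(genotyped_ids), A$ids)
  if (anyNA(idx2)) {
    stop("genotyped ids not in pedigree: ",
         paste(genotyped_ids[is.na(idx2)], collapse = ", "))
  }
  idx1 <- setdiff(seq_along(A$ids), idx2)
  Av <- A$values
  A11 <- Av[idx1, idx1, drop = FALSE]
  A12 <- Av[idx1, idx2, drop = FALSE]
  A22 <- Av[idx2, idx2, drop = FALSE]
  A22_inv <- if (length(idx2) > 0) chol_inv(A22) else A22
  list(A11 = A11, A12 = A12, A22 = A22, A22_inv = A22_inv,
       idx1 = idx1, idx2 = idx2)
}

# symmetric positive-definite inverse via Cholesky, with a clear error
chol_inv <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) stop(what, " is singular or not positive definite")
  chol2inv(ch)
}

#' Export a relationship matrix to text files
#'
#' Sparse matrices are written in MatrixMarket coordinate format, dense
#' matrices as tab-delimited text; in both cases a sidecar `<path>.ids`
#' file lists the animal identifiers, one per row.
#'
#' @param x a [relmat()].
#' @param path output path (the id sidecar gets `.ids` appended).
#' @return `path`, invisibly.
#' @export
write_relmat <- function(x, path) {
  stopifnot(inherits(x, "relmat"))
  if (is(x$values, "sparseMatrix")) {
    Matrix::writeMM(as(as(x$values, "generalMatrix"), "TsparseMatrix"), path)
  } else {
    utils::write.table(as.matrix(x$values), path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  writeLines(x$ids, paste0(path, ".ids"))
  invisible(path)
}
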