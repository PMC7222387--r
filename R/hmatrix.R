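#' Combined pedigree-genomic relationship matrix H
#'
#' Assembles the single-step matrix joining pedigree and genomic
#' information. With subscript 1 for ungenotyped and 2 for genotyped
#' animals, the ungenotyped block is
#' `A11 - A12 A22^-1 A21 + A12 A22^-1 G A22^-1 A21`, the cross block is
#' `A12 A22^-1 G`, and the genotyped block is `G` itself. The result is
#' returned in ungenotyped-first order with a permutation back to the
#' pedigree order.
#'
#' @param A a [relmat()] of kind `"A"` covering all animals.
#' @param G a [relmat()] of kind `"G"`; `G$ids` defines the genotyped set
#'   and must be a subset of `A$ids`. Pass `blend_weight > 0` to blend
#'   towards `A22` first.
#' @param blend_weight weight of `A22` in the blended genomic matrix
#'   (see [blend_G()]); default 0.05, 0 disables blending.
#' @return A [relmat()] of kind `"H"` with attributes `perm` (such that
#'   `values[perm, perm]` restores pedigree order) and `blend_weight`.
#' @export
compute_H <- function(A, G, blend_weight = 0.05) {
  stopifnot(inherits(A, "relmat"), A$kind == "A",
            inherits(G, "relmat"), G$kind == "G")
  if (length(G$ids) == 0) {
    out <- relmat(A$values, A$ids, "H", genotyped_index = integer(0))
    attr(out, "perm") <- seq_along(A$ids)
    attr(out, "blend_weight") <- blend_weight
    return(out)
  }
  bl <- extract_blocks(A, G$ids)
  Gb <- blend_G(G, bl$A22, blend_weight)$values
  A22i <- tryCatch(bl$A22_inv, error = function(e)
    stop("A22 block is singular; check the pedigree of genotyped animals"))
  P <- bl$A12 %*% A22i                       # n1 x n2 projector
  n1 <- length(bl$idx1); n2 <- length(bl$idx2)
  H <- matrix(0, n1 + n2, n1 + n2)
  up <- seq_len(n1); gn <- n1 + seq_len(n2)
  if (n1 > 0) {
    H[up, up] <- bl$A11 - P %*% t(bl$A12) + P %*% Gb %*% t(P)
    H[up, gn] <- P %*% Gb
    H[gn, up] <- t(H[up, gn])
  }
  H[gn, gn] <- Gb
  H <- (H + t(H)) / 2
  ids <- c(A$ids[bl$idx1], A$ids[bl$idx2])
  dimnames(H) <- list(ids, ids)
  out <- relmat(H, ids, "H", genotyped_index = gn)
  attr(out, "perm") <- match(A$ids, ids)
  attr(out, "blend_weight") <- blend_weight
  out
}

#' Sparse inverse of the combined matrix H
#'
#' Computes `H^-1` as the sparse pedigree inverse `A^-1` plus the
#' genotyped-block correction `G^-1 - A22^-1` scattered into the genotyped
#' rows and columns; the dense H is never formed. The result is in the
#' original pedigree order.
#'
#' @param ped a [pedigree()] object.
#' @param G a [relmat()] of kind `"G"` for the genotyped subset of the
#'   pedigree.
#' @param A optional precomputed [relmat()] of kind `"A"` (only the `A22`
#'   block is used); computed from `ped` when omitted.
#' @param blend_weight weight of `A22` blended into G before inversion
#'   (default 0.05). With `blend_weight = 0` a singular G is an error.
#' @return A [relmat()] of kind `"H_inv"` (sparse) with attribute
#'   `blend_weight`.
#' @export
compute_H_inverse <- function(ped, G, A = NULL, blend_weight = 0.05) {
  stopifnot(inherits(ped, "pedigree"), inherits(G, "relmat"), G$kind == "G")
  Ainv <- compute_A_inverse(ped)
  if (length(G$ids) == 0) {
    out <- relmat(Ainv$values, ped$id, "H_inv", genotyped_index = integer(0))
    attr(out, "blend_weight") <- blend_weight
    return(out)
  }
  if (is.null(A)) A <- compute_A(ped)
  bl <- extract_blocks(A, G$ids)
  Gb <- blend_G(G, bl$A22, blend_weight)$values
  Gi <- tryCatch(chol_inv(Gb, "G"), error = function(e) {
    if (blend_weight == 0)
      stop("G is singular; consider blending (blend_weight > 0)")
    stop(e)
  })
  corr <- Gi - bl$A22_inv
  n <- nrow(ped)
  idx2 <- bl$idx2
  Hinv <- as(Ainv$values, "CsparseMatrix") +
    Matrix::sparseMatrix(i = rep(idx2, times = length(idx2)),
                         j = rep(idx2, each = length(idx2)),
                         x = as.vector(corr), dims = c(n, n))
  dimnames(Hinv) <- list(ped$id, ped$id)
  out <- relmat(Hinv, ped$id, "H_inv", genotyped_index = idx2)
  attr(out, "blend_weight") <- blend_weight
  out
}
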