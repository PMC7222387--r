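#' Genotype panel container
#'
#' Holds an animal-by-SNP matrix of additive codes 0/1/2 (count of the
#' counted allele) with `NA` for missing calls.
#'
#' @param codes numeric matrix, animals in rows, SNPs in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param animal_ids,snp_ids identifier vectors for rows and columns.
#' @return An object of class `genotype_panel` with elements `codes`,
#'   `animal_ids`, `snp_ids` and `allele_freq` (frequency of the counted
#'   allele, recomputed from non-missing codes).
#' @export
genotype_panel <- function(codes, animal_ids = rownames(codes),
                           snp_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  ok <- is.na(codes) | codes == 0 | codes == 1 | codes == 2
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(animal_ids)) animal_ids <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  dimnames(codes) <- list(animal_ids, snp_ids)
  structure(list(codes = codes,
                 animal_ids = as.character(animal_ids),
                 snp_ids = as.character(snp_ids),
                 allele_freq = colMeans(codes, na.rm = TRUE) / 2),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d animals x %d SNPs, %.2f%% missing\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: given the allele counts, the probability of each
#' possible heterozygote count under HWE is computed by enumeration, and
#' the p-value is the sum of probabilities not exceeding that of the
#' observed table. Monomorphic SNPs return `p = 1` by convention.
#'
#' @param nAA,nAB,nBB genotype counts.
#' @return p-value in `[0, 1]`.
#' @examples
#' hwe_test(25, 50, 25)  # 1
#' hwe_test(50, 0, 50)   # << 1e-6
#' @export
hwe_test <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n <= 0) stop("empty genotype table")
  nA <- 2 * nAA + nAB
  if (nA == 0 || nA == 2 * n) return(1.0)
  pr <- hwe_het_distribution(n, nA)
  obs <- pr[as.character(nAB)]
  if (is.na(obs)) stop("heterozygote count has wrong parity for allele count")
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Conditional distribution of the heterozygote count given n genotypes and
# nA copies of allele A, under HWE. Computed on the log scale from the
# closed-form count probability; names give the heterozygote counts.
hwe_het_distribution <- function(n, nA) {
  nB <- 2 * n - nA
  r <- min(nA, nB)
  het <- seq(r %% 2, r, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((nB - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  names(p) <- het
  p
}

#' Apply genotype quality control
#'
#' Filters are applied sequentially in a fixed order: animal call rate,
#' SNP call rate, minor allele frequency (monomorphic SNPs counted
#' separately), and the exact Hardy-Weinberg test. Counts removed at each
#' stage are recorded; allele frequencies are recomputed on the retained
#' data.
#'
#' @param panel a [genotype_panel()].
#' @param animal_call_rate,snp_call_rate minimum call rates (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha significance level of the exact HWE test
#'   (default `1e-6`).
#' @param snp_whitelist optional character vector of SNP ids to retain
#'   (applied before all other filters), e.g. the intersection of several
#'   chip versions.
#' @return A list with the filtered `panel` and a `report` of class
#'   `qc_report`.
#' @export
qc_genotypes <- function(panel, animal_call_rate = 0.90, snp_call_rate = 0.90,
                         maf_min = 0.01, hwe_alpha = 1e-6,
                         snp_whitelist = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  codes <- panel$codes
  n_animals_in <- nrow(codes); n_snps_in <- ncol(codes)
  if (n_animals_in == 0 || n_snps_in == 0) stop("empty genotype panel")

  removed <- c(whitelist = 0L, call_rate = 0L, monomorphic = 0L,
               maf = 0L, hwe = 0L)
  if (!is.null(snp_whitelist)) {
    keep_w <- colnames(codes) %in% snp_whitelist
    removed["whitelist"] <- sum(!keep_w)
    codes <- codes[, keep_w, drop = FALSE]
  }

  a_cr <- rowMeans(!is.na(codes))
  keep_a <- a_cr >= animal_call_rate
  codes <- codes[keep_a, , drop = FALSE]

  s_cr <- colMeans(!is.na(codes))
  drop_cr <- s_cr < snp_call_rate
  removed["call_rate"] <- sum(drop_cr)
  codes <- codes[, !drop_cr, drop = FALSE]

  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_mono <- maf == 0 | is.nan(maf)
  removed["monomorphic"] <- sum(drop_mono)
  codes <- codes[, !drop_mono, drop = FALSE]
  maf <- maf[!drop_mono]

  drop_maf <- maf < maf_min
  removed["maf"] <- sum(drop_maf)
  codes <- codes[, !drop_maf, drop = FALSE]

  hwe_p <- apply(codes, 2, function(g) {
    hwe_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 2, na.rm = TRUE))
  })
  drop_hwe <- hwe_p < hwe_alpha
  removed["hwe"] <- sum(drop_hwe)
  codes <- codes[, !drop_hwe, drop = FALSE]

  report <- structure(list(n_animals_in = n_animals_in,
                           n_animals_out = nrow(codes),
                           n_snps_in = n_snps_in,
                           n_snps_out = ncol(codes),
                           removed_by = removed,
                           thresholds = c(animal_call_rate = animal_call_rate,
                                          snp_call_rate = snp_call_rate,
                                          maf_min = maf_min,
                                          hwe_alpha = hwe_alpha)),
                      class = "qc_report")
  if (ncol(codes) == 0) {
    e <- simpleError("all SNPs removed by quality control")
    e$report <- report
    stop(e)
  }
  list(panel = genotype_panel(codes), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  animals: %d -> %d\n", x$n_animals_in, x$n_animals_out))
  cat(sprintf("  SNPs:    %d -> %d\n", x$n_snps_in, x$n_snps_out))
  for (k in names(x$removed_by))
    cat(sprintf("    removed by %-11s %d\n", paste0(k, ":"), x$removed_by[[k]]))
  cat("  thresholds:",
      paste(names(x$thresholds), signif(x$thresholds, 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a QC report as plain text key-value pairs
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(paste0("n_animals_in\t", report$n_animals_in),
             paste0("n_animals_out\t", report$n_animals_out),
             paste0("n_snps_in\t", report$n_snps_in),
             paste0("n_snps_out\t", report$n_snps_out),
             paste0("removed_", names(report$removed_by), "\t",
                    report$removed_by),
             paste0("threshold_", names(report$thresholds), "\t",
                    report$thresholds))
  writeLines(lines, path)
  invisible(path)
}

#' VanRaden genomic relationship matrix
#'
#' Centers the additive codes by twice the allele frequency
#' (`M_ij = codes_ij - 2 p_j`) and computes
#' `G = M M' / (2 sum_j p_j (1 - p_j))`. Missing codes are mean-imputed to
#' `2 p_j` (they contribute 0 after centering).
#'
#' @param panel a quality-controlled [genotype_panel()].
#' @param freq allele frequencies: `"observed"` (default, recomputed from
#'   the panel) or a numeric vector of per-SNP frequencies of the counted
#'   allele.
#' @return A [relmat()] of kind `"G"`.
#' @export
compute_G <- function(panel, freq = "observed") {
  stopifnot(inherits(panel, "genotype_panel"))
  codes <- panel$codes
  p <- if (identical(freq, "observed")) {
    colMeans(codes, na.rm = TRUE) / 2
  } else {
    stopifnot(is.numeric(freq), length(freq) == ncol(codes))
    freq
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: sum p(1-p) is zero")
  M <- sweep(codes, 2, 2 * p)
  M[is.na(M)] <- 0                        # mean imputation after centering
  G <- tcrossprod(M) / denom
  relmat(G, panel$animal_ids, "G")
}

#' Blend a genomic matrix with the pedigree block
#'
#' `G* = (1 - w) G + w A22` guarantees invertibility of the genomic matrix
#' before it enters the combined-matrix inverse. `w = 0` disables blending.
#'
#' @param G a [relmat()] of kind `"G"`.
#' @param A22 dense pedigree relationship block of the same animals.
#' @param weight blending weight in `[0, 1]`, default 0.05.
#' @return A [relmat()] of kind `"G"` with attribute `blend_weight`.
#' @export
blend_G <- function(G, A22, weight = 0.05) {
  stopifnot(inherits(G, "relmat"), G$kind == "G",
            weight >= 0, weight <= 1,
            all(dim(A22) == dim(G$values)))
  out <- relmat((1 - weight) * G$values + weight * as.matrix(A22), G$ids, "G")
  attr(out, "blend_weight") <- weight
  out
}
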