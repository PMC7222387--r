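#' Read PLINK RAW (additive dosage) genotypes
#'
#' Reads the whitespace-delimited output of `plink --recode A`: columns
#' FID IID PAT MAT SEX PHENOTYPE followed by one 0/1/2 dosage per SNP
#' (header gives SNP names, typically with an `_allele` suffix, which is
#' stripped). `NA` marks missing calls.
#'
#' @param path path to the `.raw` file.
#' @return A [genotype_panel()].
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 7) stop("PLINK RAW file has no genotype columns")
  ids <- as.character(df[["IID"]])
  codes <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(codes) <- "double"
  snp <- sub("_[ACGT0-9]+$", "", colnames(codes))
  genotype_panel(codes, ids, snp)
}

#' Read PLINK PED/MAP genotypes
#'
#' Reads allele-pair genotypes from a PED file with its MAP sidecar.
#' `0` codes a missing allele. Additive codes count copies of the minor
#' allele at each SNP (ties broken toward the alphabetically later
#' allele), so homozygotes for the major allele are coded 0.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return A [genotype_panel()].
#' @export
read_plink_pedmap <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  snp_ids <- as.character(map[[2]])
  raw <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- length(snp_ids)
  if (ncol(raw) != 6 + 2 * m)
    stop("PED file has ", ncol(raw) - 6,
         " allele columns but MAP lists ", m, " SNPs")
  ids <- raw[[2]]
  codes <- matrix(NA_real_, nrow(raw), m)
  for (j in seq_len(m)) {
    a1 <- raw[[6 + 2 * j - 1]]
    a2 <- raw[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) == 0) next
    counts <- table(factor(c(a1[!miss], a2[!miss]), levels = alleles))
    minor <- names(counts)[order(counts, names(counts))][1]
    if (length(alleles) == 1) minor <- alleles  # monomorphic: count it
    codes[!miss, j] <- (a1[!miss] == minor) + (a2[!miss] == minor)
  }
  genotype_panel(codes, ids, snp_ids)
}

#' Read a delimited dosage matrix
#'
#' Expects a header row of SNP identifiers, a first column of animal
#' identifiers, and 0/1/2 dosages (`NA` for missing).
#'
#' @param path path to the file (comma or tab delimited, autodetected).
#' @return A [genotype_panel()].
#' @export
read_dosage_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  codes <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(codes) <- "double"
  genotype_panel(codes, as.character(df[[1]]), colnames(df)[-1])
}

#' Write a genotype panel as a delimited dosage matrix
#' @param panel a [genotype_panel()].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(panel, path) {
  df <- data.frame(animal = panel$animal_ids, panel$codes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pedigree file
#' @param ped a [pedigree()] object.
#' @param path output path (tab-delimited; unknown parents written as `0`).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- data.frame(animal = ped$id,
                   sire = ifelse(is.na(ped$sire), "0", ped$sire),
                   dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype file into a trait dataset
#'
#' Reads a delimited file with columns `animal`, one trait value column,
#' fixed-effect columns and a `flock` column, and builds a
#' [trait_data()] object.
#'
#' @param path path to the file (comma or tab delimited, autodetected).
#' @param trait name of the trait value column.
#' @param fixed names of the fixed-effect columns (default
#'   `c("year", "appraiser", "dam_age", "sex", "strain")`, intersected with
#'   the columns present).
#' @param flock name of the flock column, or `NULL` for no flock effect.
#' @param kind `"linear"` or `"threshold"`.
#' @param n_categories number of ordinal categories (threshold only).
#' @return A [trait_data()] object.
#' @export
read_phenotypes <- function(path, trait,
                            fixed = c("year", "appraiser", "dam_age",
                                      "sex", "strain"),
                            flock = "flock", kind = "linear",
                            n_categories = NULL) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- intersect(fixed, names(df))
  if (!trait %in% names(df)) stop("trait column not found: ", trait)
  trait_data(animal = as.character(df$animal), y = df[[trait]],
             fixed_effects = df[fixed],
             flock = if (!is.null(flock) && flock %in% names(df))
               as.character(df[[flock]]) else NULL,
             kind = kind, n_categories = n_categories)
}

#' Write a trait dataset as a delimited phenotype file
#' @param data a [trait_data()] object.
#' @param path output path (tab-delimited).
#' @param trait name for the trait value column.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(data, path, trait = "value") {
  df <- data.frame(animal = data$animal, stats::setNames(list(data$y), trait),
                   data$fixed_effects, check.names = FALSE)
  if (!is.null(data$flock)) df$flock <- data$flock
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
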