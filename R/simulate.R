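#' Simulation scenario configuration
#'
#' Describes a synthetic population with the structure the evaluation
#' pipeline assumes: a multi-generation pedigree under polygynous random
#' mating, a genotyped subset drawn from the youngest cohorts, independent
#' biallelic SNPs gene-dropped through the pedigree, and phenotypes
#' generated as `y = Xb + Z1 h + Z2 a + e`.
#'
#' The defaults emulate a fine-wool sheep recording scheme at desk scale:
#' 3,000 animals across 4 discrete post-founder generations of 600 (600
#' founders), 1,000 genotyped animals concentrated in the last two
#' generations, and 2,000 SNPs with founder allele frequencies uniform on
#' (0.01, 0.5).
#'
#' @param n_founders founders in generation 0.
#' @param n_generations number of discrete offspring generations.
#' @param n_offspring offspring born per generation.
#' @param sire_fraction fraction of previous-generation males used as
#'   sires (polygyny; dams are sampled with replacement from all females).
#' @param n_snps number of independent biallelic SNPs.
#' @param founder_maf_range founder allele-frequency range (uniform draw).
#' @param genotype_missing_rate per-call missing rate of the SNP assay.
#' @param n_genotyped number of genotyped animals, sampled from the last
#'   two generations (overrides `genotyped_fraction` when not `NULL`).
#' @param genotyped_fraction alternatively, the fraction of all animals
#'   genotyped.
#' @param trait a list describing the trait: `kind` ("linear" or
#'   "threshold"), variance components `sigma_a2`, `sigma_h2`, `sigma_e2`,
#'   `n_flocks`, `fixed_levels` (named integer vector of class counts),
#'   `n_categories` and optional `thresholds` for ordinal traits (default:
#'   equal-mass cuts), and `bv_method` ("pedigree" Mendelian-sampling
#'   recursion or "snp" effects through the genotypes).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 600, n_generations = 4,
                       n_offspring = 600, sire_fraction = 0.05,
                       n_snps = 2000, founder_maf_range = c(0.01, 0.5),
                       genotype_missing_rate = 0.01,
                       n_genotyped = 1000, genotyped_fraction = NULL,
                       trait = list(), seed = 1L) {
  trait <- utils::modifyList(
    list(kind = "linear", sigma_a2 = 0.3, sigma_h2 = 0.2, sigma_e2 = 0.5,
         n_flocks = 156,
         fixed_levels = c(year = 8, appraiser = 6, dam_age = 4, sex = 2,
                          strain = 4),
         n_categories = 5, thresholds = NULL, bv_method = "pedigree"),
    trait)
  stopifnot(n_founders >= 2, trait$sigma_a2 > 0, trait$sigma_h2 > 0,
            trait$sigma_e2 > 0)
  if (!is.null(trait$thresholds) &&
      any(diff(trait$thresholds) <= 0))
    stop("ordinal thresholds must be strictly increasing")
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 n_offspring = n_offspring, sire_fraction = sire_fraction,
                 n_snps = n_snps, founder_maf_range = founder_maf_range,
                 genotype_missing_rate = genotype_missing_rate,
                 n_genotyped = n_genotyped,
                 genotyped_fraction = genotyped_fraction,
                 trait = trait, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations with random polygynous mating: each generation a
#' small pool of sires (a configurable fraction of the previous
#' generation's males) is mated to dams sampled with replacement from the
#' previous generation's females. Sexes are assigned at random. The result
#' is topologically ordered.
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree()] object with attributes `sex` (per animal) and
#'   `generation`.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  id <- paste0("F", seq_len(cfg$n_founders))
  sire <- rep(NA_character_, cfg$n_founders)
  dam <- rep(NA_character_, cfg$n_founders)
  sex <- sample(c("M", "F"), cfg$n_founders, replace = TRUE)
  gen <- rep(0L, cfg$n_founders)
  prev <- seq_len(cfg$n_founders)
  for (g in seq_len(cfg$n_generations)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) == 0 || length(females) == 0) break
    n_sires <- max(1L, round(cfg$sire_fraction * length(prev)))
    sires <- males[sample.int(length(males), min(n_sires, length(males)))]
    new_id <- paste0("G", g, "_", seq_len(cfg$n_offspring))
    new_sire <- id[sires[sample.int(length(sires), cfg$n_offspring,
                                    replace = TRUE)]]
    new_dam <- id[females[sample.int(length(females), cfg$n_offspring,
                                     replace = TRUE)]]
    prev <- length(id) + seq_len(cfg$n_offspring)
    id <- c(id, new_id); sire <- c(sire, new_sire); dam <- c(dam, new_dam)
    sex <- c(sex, sample(c("M", "F"), cfg$n_offspring, replace = TRUE))
    gen <- c(gen, rep(g, cfg$n_offspring))
  }
  ped <- pedigree(id, sire, dam)
  ord <- match(ped$id, id)
  attr(ped, "sex") <- sex[ord]
  attr(ped, "generation") <- gen[ord]
  ped
}

#' Pick the genotyped subset of a simulated pedigree
#'
#' Genotyped animals are drawn at random from the last two generations
#' (mirroring schemes where recent cohorts are genotyped), topping up from
#' older animals only if those cohorts are too small.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @return Character vector of genotyped animal ids.
#' @export
pick_genotyped <- function(ped, cfg) {
  n_want <- cfg$n_genotyped %||%
    round((cfg$genotyped_fraction %||% 0) * nrow(ped))
  gen <- attr(ped, "generation")
  recent <- which(gen >= max(gen) - 1L)
  if (length(recent) >= n_want) {
    sample(ped$id[recent], n_want)
  } else {
    c(ped$id[recent],
      sample(ped$id[-recent], n_want - length(recent)))
  }
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn from per-SNP allele frequencies (uniform over
#' `founder_maf_range`); each offspring inherits one allele picked at
#' random from each parent, independently per SNP (no linkage). Alleles of
#' unknown parents are drawn from the founder frequencies. A per-call
#' missing rate is applied afterwards.
#'
#' @param ped a [pedigree()] object.
#' @param cfg a [sim_config()].
#' @param animal_ids animals to include in the returned panel (default:
#'   all; genotypes are simulated for the whole pedigree regardless).
#' @return A [genotype_panel()] with attribute `founder_freq`.
#' @export
simulate_genotypes <- function(ped, cfg, animal_ids = ped$id) {
  set.seed(cfg$seed + 1L)
  n <- nrow(ped); m <- cfg$n_snps
  p <- runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  a1 <- matrix(0L, n, m)
  a2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    a1[i, ] <- if (is.na(s)) rbinom(m, 1L, p) else {
      pick <- runif(m) < 0.5
      ifelse(pick, a1[s, ], a2[s, ])
    }
    a2[i, ] <- if (is.na(d)) rbinom(m, 1L, p) else {
      pick <- runif(m) < 0.5
      ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  codes <- a1 + a2
  storage.mode(codes) <- "double"
  if (cfg$genotype_missing_rate > 0)
    codes[runif(length(codes)) < cfg$genotype_missing_rate] <- NA
  rownames(codes) <- ped$id
  colnames(codes) <- paste0("snp", seq_len(m))
  keep <- match(animal_ids, ped$id)
  panel <- genotype_panel(codes[keep, , drop = FALSE])
  attr(panel, "founder_freq") <- p
  panel
}

#' Simulate phenotypes under the animal model
#'
#' Generates `y = Xb + Z1 h + Z2 a + e` for all non-founder animals (one
#' record each). Breeding values follow either the pedigree path
#' (Mendelian-sampling recursion, so that `Var(a) = sigma_a2 A`) or a
#' SNP-effect path (`a = M u`, rescaled to the target variance). Flock and
#' residual effects are i.i.d. normal; fixed-effect classes are assigned
#' at random with fixed true coefficients evenly spaced and summing to
#' zero. Ordinal traits cut the latent liability at the configured
#' thresholds (default: equal-mass cuts at the empirical liability
#' quantiles).
#'
#' @param ped a [pedigree()] object.
#' @param cfg a [sim_config()].
#' @param panel optional [genotype_panel()] covering all pedigree animals,
#'   required for `bv_method = "snp"`.
#' @return A [trait_data()] with attributes `true_bv` (named, all
#'   animals), `true_fixed`, `true_flock` and `thresholds` (ordinal only).
#' @export
simulate_phenotypes <- function(ped, cfg, panel = NULL) {
  set.seed(cfg$seed + 2L)
  tr <- cfg$trait
  n <- nrow(ped)

  a <- if (identical(tr$bv_method, "snp")) {
    if (is.null(panel) || !all(ped$id %in% panel$animal_ids))
      stop("bv_method = 'snp' needs a genotype panel covering the pedigree")
    codes <- panel$codes[match(ped$id, panel$animal_ids), , drop = FALSE]
    codes[is.na(codes)] <- 0
    u <- rnorm(ncol(codes))
    raw <- as.vector(scale(codes %*% u, center = TRUE, scale = FALSE))
    raw * sqrt(tr$sigma_a2 / stats::var(raw))
  } else {
    bv <- numeric(n)
    for (i in seq_len(n)) {
      mu <- 0
      if (!is.na(ped$sire_idx[i])) mu <- mu + 0.5 * bv[ped$sire_idx[i]]
      if (!is.na(ped$dam_idx[i])) mu <- mu + 0.5 * bv[ped$dam_idx[i]]
      bv[i] <- mu + rnorm(1, 0, sqrt(tr$sigma_a2 * ped$D[i]))
    }
    bv
  }
  names(a) <- ped$id

  recorded <- which(!(is.na(ped$sire_idx) & is.na(ped$dam_idx)))
  if (length(recorded) == 0) recorded <- seq_len(n)
  nr <- length(recorded)

  fixed <- lapply(tr$fixed_levels, function(L) {
    lv <- paste0("c", seq_len(L))
    factor(sample(lv, nr, replace = TRUE), levels = lv)
  })
  total_sd <- sqrt(tr$sigma_a2 + tr$sigma_h2 + tr$sigma_e2)
  true_fixed <- lapply(tr$fixed_levels, function(L) {
    b <- seq(-0.5, 0.5, length.out = L) * total_sd
    b - mean(b)
  })
  xb <- rep(0, nr)
  for (k in seq_along(fixed))
    xb <- xb + true_fixed[[k]][as.integer(fixed[[k]])]

  flock <- sample(paste0("flk", seq_len(tr$n_flocks)), nr, replace = TRUE)
  h <- rnorm(tr$n_flocks, 0, sqrt(tr$sigma_h2))
  names(h) <- paste0("flk", seq_len(tr$n_flocks))

  liab <- xb + h[flock] + a[recorded] + rnorm(nr, 0, sqrt(tr$sigma_e2))

  if (tr$kind == "threshold") {
    C <- tr$n_categories
    thr <- tr$thresholds %||%
      unname(quantile(liab, probs = seq_len(C - 1) / C))
    if (length(thr) != C - 1)
      stop("need ", C - 1, " thresholds for ", C, " categories")
    y <- findInterval(liab, thr) + 1
  } else {
    y <- liab
  }

  out <- trait_data(animal = ped$id[recorded], y = y,
                    fixed_effects = as.data.frame(fixed), flock = flock,
                    kind = tr$kind,
                    n_categories = if (tr$kind == "threshold")
                      tr$n_categories else NULL)
  attr(out, "true_bv") <- a
  attr(out, "true_fixed") <- true_fixed
  attr(out, "true_flock") <- h
  if (tr$kind == "threshold") attr(out, "thresholds") <- thr
  out
}

#' Simulate a complete scenario
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()], [pick_genotyped()] and
#' [simulate_phenotypes()] from one configuration.
#'
#' @param cfg a [sim_config()].
#' @param genotypes simulate SNP genotypes? (Skipping them makes
#'   pedigree-only scenarios much faster.)
#' @return A list with `ped`, `panel` (genotyped subset only, or `NULL`),
#'   `full_panel` (all animals, or `NULL`), `genotyped_ids` and `data`.
#' @export
simulate_scenario <- function(cfg, genotypes = TRUE) {
  ped <- simulate_pedigree(cfg)
  full_panel <- if (genotypes) simulate_genotypes(ped, cfg) else NULL
  set.seed(cfg$seed + 3L)
  genotyped_ids <- if (genotypes) pick_genotyped(ped, cfg) else character(0)
  data <- simulate_phenotypes(ped, cfg, panel = full_panel)
  panel <- if (genotypes) {
    genotype_panel(full_panel$codes[match(genotyped_ids,
                                          full_panel$animal_ids), ,
                                    drop = FALSE])
  } else NULL
  list(ped = ped, panel = panel, full_panel = full_panel,
       genotyped_ids = genotyped_ids, data = data)
}
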