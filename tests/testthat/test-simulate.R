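test_that("pedigree simulation honours boundaries, determinism and family structure", {
  # no offspring generations: founders only
  cfg0 <- sim_config(n_founders = 10, n_generations = 0, n_offspring = 0,
                     n_snps = 5, n_genotyped = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 10)
  expect_true(all(is.na(ped0$sire_idx)))

  cfg <- sim_config(n_founders = 200, n_generations = 5, n_offspring = 200,
                    sire_fraction = 0.05, n_snps = 5, n_genotyped = 50,
                    seed = 2)
  ped_a <- simulate_pedigree(cfg)
  ped_b <- simulate_pedigree(cfg)
  expect_identical(ped_a, ped_b)                   # fixed seed
  expect_equal(nrow(ped_a), 200 + 5 * 200)

  # polygyny: mean half-sib family size tracks offspring / sires
  sires <- table(ped_a$sire[!is.na(ped_a$sire)])
  expected_family <- cfg$n_offspring / max(1, round(0.05 * 200))
  expect_lt(abs(mean(sires) - expected_family) / expected_family, 0.5)
  # parents precede offspring
  expect_true(all(ped_a$sire_idx < seq_len(nrow(ped_a)), na.rm = TRUE))
})

test_that("gene-dropped genotypes are Mendelian and fix at extreme frequencies", {
  cfg <- sim_config(n_founders = 60, n_generations = 2, n_offspring = 60,
                    n_snps = 40, n_genotyped = 10,
                    founder_maf_range = c(1, 1),   # degenerate: fixation
                    genotype_missing_rate = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  expect_true(all(panel$codes == 2))

  cfg2 <- sim_config(n_founders = 60, n_generations = 3, n_offspring = 80,
                     n_snps = 60, genotype_missing_rate = 0,
                     n_genotyped = 10, seed = 4)
  ped2 <- simulate_pedigree(cfg2)
  panel2 <- simulate_genotypes(ped2, cfg2)
  # parent-offspring pairs share at least one allele at every SNP:
  # codes may not be (0,2) or (2,0)
  off <- which(!is.na(ped2$sire_idx))
  for (i in off[1:30]) {
    s <- ped2$sire_idx[i]
    expect_false(any(abs(panel2$codes[i, ] - panel2$codes[s, ]) == 2))
  }
})

test_that("realized genomic relationships of full sibs average one half", {
  # one sire, one dam, many full sibs
  n_sib <- 60
  ped <- pedigree(c("S", "D", paste0("o", seq_len(n_sib))),
                  c(NA, NA, rep("S", n_sib)),
                  c(NA, NA, rep("D", n_sib)))
  cfg <- sim_config(n_founders = 2, n_generations = 0, n_offspring = 0,
                    n_snps = 2000, n_genotyped = 0,
                    genotype_missing_rate = 0,
                    founder_maf_range = c(0.2, 0.5), seed = 5)
  panel <- simulate_genotypes(ped, cfg)
  # centering must use the founder (base population) frequencies: observed
  # frequencies inside a single family re-base the relationships
  G <- as.matrix(compute_G(panel, freq = attr(panel, "founder_freq")))
  sib_idx <- match(paste0("o", seq_len(n_sib)), panel$animal_ids)
  offdiag <- G[sib_idx, sib_idx][upper.tri(diag(n_sib))]
  expect_lt(abs(mean(offdiag) - 0.5), 0.05)
})

test_that("phenotypes follow the generative model: null, heritable, ordinal", {
  # no genetic or flock signal: phenotypic variance is sigma_e2
  cfg0 <- sim_config(n_founders = 300, n_generations = 2, n_offspring = 700,
                     n_snps = 2, n_genotyped = 2,
                     trait = list(sigma_a2 = 1e-8, sigma_h2 = 1e-8,
                                  sigma_e2 = 0.5, fixed_levels = c(sex = 2)),
                     seed = 6)
  ped0 <- simulate_pedigree(cfg0)
  dat0 <- simulate_phenotypes(ped0, cfg0)
  resid <- stats::residuals(stats::lm(dat0$y ~ dat0$fixed_effects$sex))
  expect_lt(abs(stats::var(resid) - 0.5) / 0.5, 0.15)

  # parent-offspring regression approximates h2 / 2
  cfg1 <- sim_config(n_founders = 800, n_generations = 2, n_offspring = 2500,
                     n_snps = 2, n_genotyped = 2,
                     trait = list(sigma_a2 = 0.3, sigma_h2 = 1e-8,
                                  sigma_e2 = 0.7,
                                  fixed_levels = c(sex = 2), n_flocks = 2),
                     seed = 7)
  ped1 <- simulate_pedigree(cfg1)
  dat1 <- simulate_phenotypes(ped1, cfg1)
  y <- stats::setNames(dat1$y, dat1$animal)
  has_rec_parent <- !is.na(ped1$sire_idx) & ped1$id %in% names(y) &
    ped1$sire %in% names(y)
  kid <- ped1$id[has_rec_parent]
  par <- ped1$sire[has_rec_parent]
  b <- stats::coef(stats::lm(y[kid] ~ y[par]))[2]
  h2 <- 0.3
  expect_lt(abs(b - h2 / 2), 0.05)

  # equal-mass thresholds give near-uniform category frequencies
  cfg2 <- sim_config(n_founders = 200, n_generations = 2, n_offspring = 900,
                     n_snps = 2, n_genotyped = 2,
                     trait = list(kind = "threshold", n_categories = 5),
                     seed = 8)
  ped2 <- simulate_pedigree(cfg2)
  dat2 <- simulate_phenotypes(ped2, cfg2)
  freq <- tabulate(dat2$y, 5) / length(dat2$y)
  expect_true(all(abs(freq - 0.2) < 0.02))
  expect_error(
    simulate_phenotypes(ped2, sim_config(
      n_founders = 200, n_generations = 2, n_offspring = 900,
      n_snps = 2, n_genotyped = 2,
      trait = list(kind = "threshold", n_categories = 5,
                   thresholds = c(0, 1)), seed = 8)),
    "thresholds")
})

test_that("simulated breeding values have covariance sigma_a2 * A", {
  ped <- random_pedigree(40, seed = 9)
  cfg <- sim_config(n_founders = 10, n_generations = 1, n_offspring = 1,
                    n_snps = 2, n_genotyped = 0,
                    trait = list(sigma_a2 = 1, sigma_h2 = 0.1,
                                 sigma_e2 = 0.1), seed = 10)
  A <- as.matrix(compute_A(ped))
  n_rep <- 400
  bvs <- sapply(seq_len(n_rep), function(r) {
    cfg$seed <- r
    attr(simulate_phenotypes(ped, cfg), "true_bv")
  })
  # spot-check a handful of entries of the empirical covariance
  emp <- stats::cov(t(bvs))
  set.seed(11)
  for (k in 1:10) {
    i <- sample(40, 1); j <- sample(40, 1)
    se <- sqrt((A[i, j]^2 + A[i, i] * A[j, j]) / n_rep)
    expect_lt(abs(emp[i, j] - A[i, j]), 3.5 * se + 0.02)
  }
})

test_that("SNP-effect and pedigree breeding-value paths agree on recovered h2", {
  base <- list(n_founders = 300, n_generations = 3, n_offspring = 300,
               n_snps = 800, n_genotyped = 10, genotype_missing_rate = 0)
  h2_for <- function(bv_method, seed) {
    cfg <- do.call(sim_config, c(base, list(
      trait = list(sigma_a2 = 0.3, sigma_h2 = 0.2, sigma_e2 = 0.5,
                   bv_method = bv_method), seed = seed)))
    ped <- simulate_pedigree(cfg)
    panel <- if (bv_method == "snp") simulate_genotypes(ped, cfg) else NULL
    dat <- simulate_phenotypes(ped, cfg, panel = panel)
    fit <- fit_linear(dat, compute_A_inverse(ped),
                      gibbs_config(3000, 500, 5, seed = seed + 1))
    heritability(fit)
  }
  hp <- h2_for("pedigree", 12)
  hs <- h2_for("snp", 13)
  expect_lt(abs(hp$mean - hs$mean), 3 * sqrt(hp$sd^2 + hs$sd^2) + 0.05)
  expect_lt(abs(hp$mean - 0.3), 0.1)
  expect_lt(abs(hs$mean - 0.3), 0.1)
})

test_that("scenario files round-trip through the package readers", {
  cfg <- sim_config(n_founders = 50, n_generations = 2, n_offspring = 50,
                    n_snps = 30, n_genotyped = 25, seed = 14)
  scn <- simulate_scenario(cfg)
  td <- withr::local_tempdir()
  write_pedigree(scn$ped, file.path(td, "ped.tsv"))
  write_phenotypes(scn$data, file.path(td, "pheno.tsv"), trait = "fl")
  write_dosage_matrix(scn$panel, file.path(td, "geno.tsv"))
  ped2 <- read_pedigree(file.path(td, "ped.tsv"))
  expect_equal(ped2$id, scn$ped$id)
  dat2 <- read_phenotypes(file.path(td, "pheno.tsv"), trait = "fl")
  expect_equal(dat2$y, scn$data$y, tolerance = 1e-12)
  expect_equal(dat2$flock, scn$data$flock)
  pan2 <- read_dosage_matrix(file.path(td, "geno.tsv"))
  expect_equal(pan2$codes, scn$panel$codes)
  expect_setequal(scn$genotyped_ids, pan2$animal_ids)
})
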