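test_that("identical seeds give bit-identical chains, different seeds differ", {
  ped <- random_pedigree(120, seed = 2)
  dat <- toy_trait_data(ped, seed = 3)
  Ainv <- compute_A_inverse(ped)
  cfg <- gibbs_config(600, 100, 5, seed = 11)
  f1 <- fit_linear(dat, Ainv, cfg)
  f2 <- fit_linear(dat, Ainv, cfg)
  expect_identical(f1$var_draws, f2$var_draws)
  expect_identical(f1$animal, f2$animal)
  f3 <- fit_linear(dat, Ainv, gibbs_config(600, 100, 5, seed = 12))
  expect_false(identical(f1$var_draws, f3$var_draws))
  # stored draw count honours the (n - burn)/thin contract
  expect_equal(nrow(f1$var_draws), (600 - 100) / 5)
  expect_true(all(f1$var_draws > 0))
})

test_that("with variances fixed at truth the posterior mean matches BLUP", {
  ped <- random_pedigree(80, seed = 21)
  dat <- toy_trait_data(ped, seed = 22)
  Ainv <- compute_A_inverse(ped)
  va <- 0.3; vh <- 0.1; ve <- 0.6
  fit <- fit_linear(dat, Ainv, gibbs_config(30000, 2000, 2, seed = 5),
                    fix_variances = list(sigma_a2 = va, sigma_h2 = vh,
                                         sigma_e2 = ve))
  # rebuild the same design for the dense MME oracle
  keep <- !is.na(dat$y)
  fe <- data.frame(sex = factor(dat$fixed_effects$sex[keep]))
  X <- stats::model.matrix(~ sex, fe)
  fl <- factor(dat$flock[keep])
  Z1 <- stats::model.matrix(~ 0 + fl)
  aidx <- match(dat$animal[keep], ped$id)
  Z2 <- matrix(0, sum(keep), nrow(ped))
  Z2[cbind(seq_len(sum(keep)), aidx)] <- 1
  sol <- blup_solution(dat$y[keep], X, Z1, Z2, Ainv$values, va, vh, ve)
  blup_a <- sol[ncol(X) + ncol(Z1) + seq_len(nrow(ped))]
  expect_lt(max(abs(fit$animal$mean - blup_a)), 0.02)
  expect_lt(max(abs(fit$fixed$mean - sol[seq_len(ncol(X))])), 0.02)
})

test_that("with an identity relationship and repeated records the model reduces to a random intercept", {
  set.seed(31)
  n_groups <- 40; reps <- 8
  ids <- paste0("g", seq_len(n_groups))
  ped <- pedigree(ids, rep(NA, n_groups), rep(NA, n_groups))  # A = I
  u <- rnorm(n_groups, 0, sqrt(0.5))
  animal <- rep(ids, each = reps)
  y <- 2 + u[match(animal, ids)] + rnorm(n_groups * reps, 0, 1)
  dat <- trait_data(animal, y)
  fit <- fit_linear(dat, compute_A_inverse(ped),
                    gibbs_config(6000, 1000, 5, seed = 7))
  oracle <- oneway_gibbs_oracle(y, animal, 6000, 1000, 5, seed = 8)
  expect_lt(abs(mean(fit$var_draws[, "sigma_a2"]) - mean(oracle[, "vu"])),
            0.08)
  expect_lt(abs(mean(fit$var_draws[, "sigma_e2"]) - mean(oracle[, "ve"])),
            0.05)
  expect_lt(abs(stats::sd(fit$var_draws[, "sigma_a2"]) -
                  stats::sd(oracle[, "vu"])), 0.08)
})

test_that("a null genetic signal yields a near-zero heritability posterior", {
  cfg <- sim_config(n_founders = 300, n_generations = 3, n_offspring = 300,
                    n_snps = 2, n_genotyped = 2, seed = 41)
  ped <- simulate_pedigree(cfg)      # polygynous: informative half-sib families
  set.seed(41)
  rec <- which(!is.na(ped$sire_idx))
  n <- length(rec)
  flock <- sample(paste0("f", 1:20), n, replace = TRUE)
  hv <- rnorm(20, 0, sqrt(0.2))
  y <- hv[as.integer(factor(flock))] + rnorm(n, 0, sqrt(0.8))  # a = 0
  dat <- trait_data(ped$id[rec], y, flock = flock)
  fit <- fit_linear(dat, compute_A_inverse(ped),
                    gibbs_config(4000, 1000, 5, seed = 43))
  expect_lt(heritability(fit)$mean, 0.05)
})

test_that("prior-predictive variance draws reproduce a proper prior without data", {
  ped <- pedigree(paste0("f", 1:5), rep(NA, 5), rep(NA, 5))
  dat <- trait_data(character(0), numeric(0))
  pri <- list(a = list(df = 8, scale = 0.4),
              h = list(df = 8, scale = 0.4),
              e = list(df = 8, scale = 0.4))
  fit <- fit_linear(dat, compute_A_inverse(ped),
                    gibbs_config(20000, 2000, 2, seed = 9, priors = pri))
  prior_mean <- 8 * 0.4 / (8 - 2)
  expect_lt(abs(mean(fit$var_draws[, "sigma_e2"]) - prior_mean), 0.05)
  expect_lt(abs(mean(fit$var_draws[, "sigma_a2"]) - prior_mean), 0.05)
})

test_that("degenerate model inputs are constrained, dropped or rejected with messages", {
  ped <- random_pedigree(60, seed = 51)
  dat <- toy_trait_data(ped, seed = 52)
  Ainv <- compute_A_inverse(ped)
  # confounded fixed effect: single class is constrained out with a warning
  dat1 <- dat
  dat1$fixed_effects$sex <- "F"
  expect_warning(fit_linear(dat1, Ainv, gibbs_config(300, 100, 2, seed = 1)),
                 "single class")
  # records with missing labels are dropped with a warning
  dat2 <- dat
  dat2$fixed_effects$sex[1:3] <- NA
  expect_warning(fit_linear(dat2, Ainv, gibbs_config(300, 100, 2, seed = 1)),
                 "3 records dropped")
  # animals absent from the relationship matrix
  dat3 <- dat
  dat3$animal[1] <- "stranger"
  expect_error(fit_linear(dat3, Ainv, gibbs_config(300, 100, 2, seed = 1)),
               "stranger")
  # threshold trait with an unobserved category
  datT <- toy_trait_data(ped, seed = 53, kind = "threshold", n_cat = 4)
  datT$n_categories <- 5
  expect_error(fit_threshold(datT, Ainv, gibbs_config(300, 100, 2, seed = 1)),
               "zero observations")
  # flat prior with too few levels to be proper
  ped0 <- pedigree(c("x", "y"), c(NA, NA), c(NA, NA))
  dat0 <- trait_data(c("x", "y"), c(0.1, -0.2))
  expect_error(fit_linear(dat0, compute_A_inverse(ped0),
                          gibbs_config(300, 100, 2, seed = 1)),
               "proper prior")
})

test_that("binary and five-category codings of one liability agree on h2", {
  cfg <- sim_config(n_founders = 250, n_generations = 3, n_offspring = 250,
                    n_snps = 2, n_genotyped = 2,
                    trait = list(kind = "linear", sigma_a2 = 0.25,
                                 sigma_h2 = 0.15, sigma_e2 = 0.6,
                                 fixed_levels = c(sex = 2)),
                    seed = 61)
  ped <- simulate_pedigree(cfg)
  dat <- simulate_phenotypes(ped, cfg)          # latent liability
  Ainv <- compute_A_inverse(ped)
  thr5 <- quantile(dat$y, (1:4) / 5)
  d5 <- trait_data(dat$animal, findInterval(dat$y, thr5) + 1,
                   dat$fixed_effects, dat$flock, kind = "threshold",
                   n_categories = 5)
  d2 <- trait_data(dat$animal, (dat$y > stats::median(dat$y)) + 1,
                   dat$fixed_effects, dat$flock, kind = "threshold",
                   n_categories = 2)
  cfgG <- gibbs_config(4000, 1000, 5, seed = 62)
  h5 <- heritability(fit_threshold(d5, Ainv, cfgG))
  h2 <- heritability(fit_threshold(d2, Ainv, cfgG))
  tol <- 3 * sqrt(h5$sd^2 + h2$sd^2)
  expect_lt(abs(h5$mean - h2$mean), max(tol, 0.05))
})

test_that("heritability summarises draws and honours its boundary cases", {
  draws <- data.frame(sigma_a2 = c(0.2, 0.4), sigma_h2 = c(0.1, 0.1),
                      sigma_e2 = c(0.7, 0.5))
  h <- heritability(draws)
  expect_equal(h$draws, c(0.2, 0.4))
  expect_equal(h$mean, 0.3)
  # no flock / no residual variation: h2 = 1
  d1 <- data.frame(sigma_a2 = 0.5, sigma_h2 = 0, sigma_e2 = 0)
  expect_equal(heritability(d1)$mean, 1)
})

test_that("draws export to a delimited samples file", {
  ped <- random_pedigree(50, seed = 71)
  dat <- toy_trait_data(ped, seed = 72)
  fit <- fit_linear(dat, compute_A_inverse(ped),
                    gibbs_config(200, 100, 2, seed = 73))
  f <- withr::local_tempfile()
  write_draws(fit, f)
  back <- utils::read.table(f, header = TRUE)
  expect_equal(as.matrix(back), fit$var_draws, ignore_attr = TRUE)
})
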