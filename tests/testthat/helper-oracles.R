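# Independent oracle implementations used to cross-check the package.

# Random pedigree with overlapping generations and occasional related
# matings (so inbreeding arises). Returns a pedigree object.
random_pedigree <- function(n, n_founders = max(4, round(n / 5)),
                            seed = 1) {
  set.seed(seed)
  id <- paste0("a", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  for (i in seq.int(n_founders + 1, n)) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- id[males[sample.int(length(males), 1)]]
    dam[i] <- id[females[sample.int(length(females), 1)]]
  }
  pedigree(id, sire, dam)
}

# Monte-Carlo gene-dropping estimate of additive relationships: founders
# get unique allele labels; offspring inherit one random allele per
# parent. a_ij is estimated as half the mean number of IBD pairs among
# the four cross-comparisons of allele labels.
gene_drop_A <- function(ped, n_rep = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  A1 <- matrix(0L, n_rep, n)
  A2 <- matrix(0L, n_rep, n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (is.na(s)) {
      A1[, i] <- 2L * i - 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      A1[, i] <- ifelse(pick, A1[, s], A2[, s])
    }
    if (is.na(d)) {
      A2[, i] <- 2L * i
    } else {
      pick <- stats::runif(n_rep) < 0.5
      A2[, i] <- ifelse(pick, A1[, d], A2[, d])
    }
  }
  list(est = function(i, j) {
    ibd <- (A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
      (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])
    x <- ibd / 2
    c(mean = mean(x), se = stats::sd(x) / sqrt(n_rep))
  })
}

# HWE exact-test oracle built on the Wigginton-style recurrence
# p(het + 2) / p(het) = 4 nAA nBB / ((het + 2)(het + 1)),
# independent of the package's closed-form log-factorial route.
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1.0)
  r <- min(nA, nB)
  het <- seq(r %% 2, r, by = 2)
  w <- numeric(length(het))
  w[1] <- 1
  if (length(het) > 1) {
    for (k in seq_len(length(het) - 1)) {
      h <- het[k]
      aa <- (nA - h) / 2
      bb <- (nB - h) / 2
      w[k + 1] <- w[k] * 4 * aa * bb / ((h + 2) * (h + 1))
    }
  }
  pr <- w / sum(w)
  obs <- pr[match(nAB, het)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Brute-force HWE genotype-count distribution for tiny n: place nA "A"
# alleles into 2n ordered slots uniformly, pair consecutive slots, count
# heterozygotes. Exact enumeration over all C(2n, nA) placements.
hwe_brute_distribution <- function(n, nA) {
  slots <- utils::combn(2 * n, nA)
  het_counts <- apply(slots, 2, function(pos) {
    x <- logical(2 * n)
    x[pos] <- TRUE
    sum(x[seq(1, 2 * n, 2)] != x[seq(2, 2 * n, 2)])
  })
  tab <- table(het_counts) / ncol(slots)
  stats::setNames(as.numeric(tab), names(tab))
}

# Known-variance BLUP via the dense mixed-model equations, for checking
# the Gibbs posterior mean in the fixed-variance limit.
blup_solution <- function(y, X, Z1, Z2, Kinv, va, vh, ve) {
  X <- as.matrix(X); Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
  W <- cbind(X, Z1, Z2)
  p <- ncol(W)
  Sig <- matrix(0, p, p)
  ix <- ncol(X)
  if (ncol(Z1) > 0)
    Sig[ix + seq_len(ncol(Z1)), ix + seq_len(ncol(Z1))] <-
      diag(ve / vh, ncol(Z1))
  Sig[ix + ncol(Z1) + seq_len(ncol(Z2)),
      ix + ncol(Z1) + seq_len(ncol(Z2))] <- ve / va * as.matrix(Kinv)
  C <- crossprod(W) + Sig
  solve(C, crossprod(W, y))
}

# Independently coded single-site Gibbs sampler for the one-random-effect
# model y = mu + u_g + e, u ~ N(0, I vu), flat variance priors.
oneway_gibbs_oracle <- function(y, g, n_iter, burn_in, thin, seed) {
  set.seed(seed)
  g <- as.integer(factor(g))
  q <- max(g)
  n <- length(y)
  mu <- 0; u <- numeric(q); vu <- 1; ve <- 1
  draws <- NULL
  for (it in seq_len(n_iter)) {
    mu <- rnorm(1, mean(y - u[g]), sqrt(ve / n))
    for (k in seq_len(q)) {
      idx <- which(g == k)
      nk <- length(idx)
      prec <- nk + ve / vu
      u[k] <- rnorm(1, sum(y[idx] - mu) / prec, sqrt(ve / prec))
    }
    vu <- sum(u^2) / rchisq(1, q - 2)
    ve <- sum((y - mu - u[g])^2) / rchisq(1, n - 2)
    if (it > burn_in && (it - burn_in) %% thin == 0)
      draws <- rbind(draws, c(vu = vu, ve = ve, mu = mu))
  }
  draws
}

# Small deterministic trait dataset on a given pedigree, for sampler
# contract tests.
toy_trait_data <- function(ped, seed = 7, kind = "linear", n_cat = 4,
                           h2 = 0.3) {
  set.seed(seed)
  rec <- which(!(is.na(ped$sire_idx) & is.na(ped$dam_idx)))
  if (length(rec) < 5) rec <- seq_len(nrow(ped))
  n <- length(rec)
  va <- h2; ve <- 1 - h2 - 0.1; vh <- 0.1
  bv <- numeric(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    mu <- 0
    if (!is.na(ped$sire_idx[i])) mu <- mu + bv[ped$sire_idx[i]] / 2
    if (!is.na(ped$dam_idx[i])) mu <- mu + bv[ped$dam_idx[i]] / 2
    bv[i] <- mu + rnorm(1, 0, sqrt(va * ped$D[i]))
  }
  flock <- sample(paste0("f", 1:4), n, replace = TRUE)
  fe <- data.frame(sex = sample(c("M", "F"), n, replace = TRUE))
  hv <- rnorm(4, 0, sqrt(vh)); names(hv) <- paste0("f", 1:4)
  liab <- bv[rec] + hv[flock] + rnorm(n, 0, sqrt(ve))
  if (kind == "threshold") {
    thr <- quantile(liab, probs = seq_len(n_cat - 1) / n_cat)
    y <- findInterval(liab, thr) + 1
  } else y <- liab
  trait_data(ped$id[rec], y, fe, flock, kind = kind,
             n_categories = if (kind == "threshold") n_cat else NULL)
}
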