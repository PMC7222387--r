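#' Trait dataset for the animal model
#'
#' One record per animal with the trait value, unordered fixed-effect
#' class labels (e.g. year, appraiser, dam age, sex, strain), an optional
#' flock class (random environmental effect) and the animal identifier
#' linking to the pedigree.
#'
#' @param animal character vector of animal identifiers.
#' @param y numeric trait values; for threshold traits, integer categories
#'   `1..n_categories`.
#' @param fixed_effects data.frame (or list) of class labels, one column
#'   per fixed effect; may be empty.
#' @param flock character vector of flock labels, or `NULL` for no flock
#'   effect.
#' @param kind `"linear"` or `"threshold"`.
#' @param n_categories number of ordinal categories (threshold traits);
#'   inferred from the data when `NULL`.
#' @return An object of class `trait_data`.
#' @export
trait_data <- function(animal, y, fixed_effects = NULL, flock = NULL,
                       kind = c("linear", "threshold"), n_categories = NULL) {
  kind <- match.arg(kind)
  animal <- as.character(animal)
  n <- length(animal)
  stopifnot(length(y) == n)
  fixed_effects <- as.data.frame(fixed_effects %||% list(),
                                 stringsAsFactors = FALSE)
  if (nrow(fixed_effects) > 0) stopifnot(nrow(fixed_effects) == n)
  if (!is.null(flock)) stopifnot(length(flock) == n)
  if (kind == "threshold") {
    if (any(y != round(y) | y < 1, na.rm = TRUE))
      stop("threshold trait values must be integer categories >= 1")
    if (is.null(n_categories)) n_categories <- max(y, na.rm = TRUE)
    if (n_categories < 2) stop("threshold traits need >= 2 categories")
  }
  structure(list(animal = animal, y = as.numeric(y),
                 fixed_effects = fixed_effects,
                 flock = if (is.null(flock)) NULL else as.character(flock),
                 kind = kind, n_categories = n_categories),
            class = "trait_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trait_data <- function(x, ...) {
  cat(sprintf("<trait_data %s> %d records, %d fixed effects%s%s\n",
              x$kind, length(x$y), ncol(x$fixed_effects),
              if (is.null(x$flock)) "" else
                sprintf(", %d flocks", length(unique(x$flock))),
              if (x$kind == "threshold")
                sprintf(", %d categories", x$n_categories) else ""))
  invisible(x)
}

#' Gibbs sampler configuration
#'
#' @param n_samples total chain length.
#' @param burn_in samples discarded before storage.
#' @param thin storage interval.
#' @param seed integer seed for the pseudo-random stream.
#' @param priors scaled-inverse-chi-square priors per variance: a list with
#'   elements `a`, `h`, `e`, each `list(df =, scale =)`. The default
#'   `df = -2, scale = 0` is flat for the variances.
#' @return A list of class `gibbs_config`.
#' @details `gibbs_config()` defaults to a desk-scale chain
#'   (10,000 / 1,000 / 10); `gibbs_config_reference()` returns the long
#'   configuration (100,000 / 10,000 / 50) used for production runs.
#' @export
gibbs_config <- function(n_samples = 10000, burn_in = 1000, thin = 10,
                         seed = 1L, priors = NULL) {
  default_prior <- list(df = -2, scale = 0)
  priors <- utils::modifyList(list(a = default_prior, h = default_prior,
                                   e = default_prior), priors %||% list())
  stopifnot(burn_in < n_samples, thin >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), priors = priors),
            class = "gibbs_config")
}

#' @rdname gibbs_config
#' @export
gibbs_config_reference <- function(seed = 1L, priors = NULL) {
  gibbs_config(100000, 10000, 50, seed, priors)
}

# Build design matrices and run the compiled sampler. Shared by the linear
# and threshold fits.
fit_gibbs <- function(data, relmat_inv, cfg, fix_variances = NULL,
                      start_variances = NULL, store_effects = FALSE) {
  stopifnot(inherits(data, "trait_data"), inherits(relmat_inv, "relmat"),
            relmat_inv$kind %in% c("A_inv", "H_inv"),
            inherits(cfg, "gibbs_config"))
  n0 <- length(data$y)
  keep <- !is.na(data$y)
  if (ncol(data$fixed_effects) > 0)
    keep <- keep & stats::complete.cases(data$fixed_effects)
  if (!is.null(data$flock)) keep <- keep & !is.na(data$flock)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " records dropped for missing values or labels")

  animal <- data$animal[keep]
  y <- data$y[keep]
  aidx <- match(animal, relmat_inv$ids)
  if (anyNA(aidx))
    stop("records for animals absent from the relationship matrix: ",
         paste(unique(animal[is.na(aidx)]), collapse = ", "))
  n <- length(y)

  # fixed effects: corner-point parameterization, levels sorted by label
  fe <- data$fixed_effects[keep, , drop = FALSE]
  for (nm in names(fe)) {
    fe[[nm]] <- factor(as.character(fe[[nm]]))
    if (nlevels(fe[[nm]]) < 2) {
      warning("fixed effect '", nm,
              "' has a single class; constrained out of the model")
      fe[[nm]] <- NULL
    }
  }
  X <- if (length(fe) > 0 && n > 0) {
    stats::model.matrix(~ ., data = fe)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  X <- methods::as(X, "CsparseMatrix")

  flock <- if (!is.null(data$flock)) factor(data$flock[keep]) else NULL
  if (!is.null(flock) && !is.null(data$flock)) {
    all_levels <- unique(data$flock)
    emptied <- setdiff(all_levels, levels(flock))
    if (length(emptied) > 0)
      warning(length(emptied), " empty flock classes dropped")
  }
  n_flock <- if (is.null(flock)) 0L else nlevels(flock)
  Z1 <- if (n_flock > 0) {
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(flock),
                         x = 1, dims = c(n, n_flock))
  } else {
    methods::new("dgCMatrix", Dim = c(n, 0L), p = 0L)
  }
  q <- length(relmat_inv$ids)
  Z2 <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                             dims = c(n, q))
  W <- methods::as(cbind(X, Z1, Z2), "CsparseMatrix")
  Kinv <- methods::as(methods::as(relmat_inv$values, "generalMatrix"),
                      "CsparseMatrix")

  # threshold setup
  threshold <- data$kind == "threshold"
  n_cat <- if (threshold) data$n_categories else 0L
  if (threshold) {
    tab <- tabulate(y, nbins = n_cat)
    if (any(tab == 0))
      stop("ordinal categories with zero observations: ",
           paste(which(tab == 0), collapse = ", "),
           "; merge categories before fitting")
    thr <- thr_init(n_cat)
    ycat <- as.integer(y)
    y_liab <- liability_init(ycat, thr)
  } else {
    thr <- numeric(0)
    ycat <- integer(0)
    y_liab <- y
  }

  pr_df <- c(cfg$priors$a$df, cfg$priors$h$df, cfg$priors$e$df)
  pr_S <- c(cfg$priors$a$scale, cfg$priors$h$scale, cfg$priors$e$scale)
  if (is.null(fix_variances)) {
    if (q + pr_df[1] <= 0 || (n_flock > 0 && n_flock + pr_df[2] <= 0) ||
        n + pr_df[3] <= 0)
      stop("posterior degrees of freedom not positive; use a proper prior")
  }
  fixv <- !is.null(fix_variances)
  fv <- if (fixv) {
    c(fix_variances$sigma_a2, fix_variances$sigma_h2 %||% 1,
      fix_variances$sigma_e2)
  } else c(1, 1, 1)
  sv <- start_variances %||% list()
  start <- c(sv$sigma_a2 %||% (stats::var(y_liab) / 2),
             sv$sigma_h2 %||% 0.1, sv$sigma_e2 %||% 1)
  start[!is.finite(start) | start <= 0] <- 1

  set.seed(cfg$seed)
  res <- gibbs_mixed(y_liab, ycat, W, Kinv,
                     ncol(X), n_flock, q,
                     cfg$n_samples, cfg$burn_in, cfg$thin,
                     pr_df, pr_S, fixv, fv,
                     n_cat, thr, store_effects, start)

  n_thr_free <- max(0, n_cat - 3)
  vd <- res$var_draws
  colnames(vd) <- c("sigma_a2", "sigma_h2", "sigma_e2",
                    if (n_thr_free > 0) paste0("threshold_", 3 + seq_len(n_thr_free) - 1))
  p_off <- ncol(X) + n_flock
  structure(list(
    var_draws = vd,
    fixed = data.frame(term = colnames(X),
                       mean = res$effect_mean[seq_len(ncol(X))],
                       sd = res$effect_sd[seq_len(ncol(X))]),
    flock = if (n_flock > 0)
      data.frame(flock = levels(flock),
                 mean = res$effect_mean[ncol(X) + seq_len(n_flock)],
                 sd = res$effect_sd[ncol(X) + seq_len(n_flock)])
      else NULL,
    animal = data.frame(animal = relmat_inv$ids,
                        mean = res$effect_mean[p_off + seq_len(q)],
                        sd = res$effect_sd[p_off + seq_len(q)]),
    effect_draws = if (store_effects) res$effect_draws else NULL,
    relationship_kind = if (relmat_inv$kind == "A_inv") "A" else "H",
    genotyped_index = relmat_inv$genotyped_index,
    trait_kind = data$kind,
    n_records = n, n_dropped = n_dropped,
    config = cfg),
    class = "gibbs_fit")
}

thr_init <- function(n_cat) {
  if (n_cat == 2) return(0)
  c(0, 1, if (n_cat > 3) 1 + seq_len(n_cat - 3))
}

liability_init <- function(ycat, thr) {
  n_cat <- length(thr) + 1
  lo <- c(thr[1] - 1, thr)
  hi <- c(thr, thr[n_cat - 1] + 1)
  (lo[ycat] + hi[ycat]) / 2
}

#' Fit the linear animal model by Gibbs sampling
#'
#' Samples the mixed model `y = Xb + Z1 h + Z2 a + e` with
#' `h ~ N(0, I sigma_h2)` (flock), `a ~ N(0, K sigma_a2)` where `K` is the
#' pedigree matrix A or the combined matrix H (supplied through its sparse
#' inverse), and `e ~ N(0, I sigma_e2)`. Location effects are updated
#' single-site from their full conditionals; variances from
#' scaled-inverse-chi-square full conditionals. Fixed effects use a
#' corner-point constraint (first level of each factor, levels sorted by
#' label). Runs are deterministic given `cfg$seed`.
#'
#' @param data a [trait_data()] with `kind = "linear"`.
#' @param relmat_inv a [relmat()] of kind `"A_inv"` or `"H_inv"` covering
#'   all pedigree animals.
#' @param cfg a [gibbs_config()].
#' @param fix_variances optional `list(sigma_a2=, sigma_h2=, sigma_e2=)`;
#'   when given, variances are held fixed (known-variance BLUP limit).
#' @param start_variances optional starting values, same shape.
#' @param store_effects keep the full thinned draws of all location
#'   effects (memory permitting).
#' @return An object of class `gibbs_fit` with elements `var_draws`
#'   (matrix of stored draws of the variances and any free thresholds),
#'   `fixed`, `flock` and `animal` posterior summaries (mean, sd per
#'   level), and bookkeeping fields.
#' @export
fit_linear <- function(data, relmat_inv, cfg = gibbs_config(),
                       fix_variances = NULL, start_variances = NULL,
                       store_effects = FALSE) {
  stopifnot(data$kind == "linear")
  fit_gibbs(data, relmat_inv, cfg, fix_variances, start_variances,
            store_effects)
}

#' Fit the threshold (liability) animal model by Gibbs sampling
#'
#' As [fit_linear()], but the ordinal categories are modeled as an
#' unobserved normal liability cut at ordered thresholds; liabilities are
#' augmented each round from truncated normals between the current
#' thresholds. Identification: the first threshold is fixed at 0; with 3 or
#' more categories the second is also fixed at 1, which leaves the residual
#' variance estimable (for binary traits the residual variance is fixed at
#' 1 instead). Remaining thresholds are sampled uniformly between the
#' adjacent liabilities.
#'
#' @inheritParams fit_linear
#' @param data a [trait_data()] with `kind = "threshold"`; every category
#'   `1..n_categories` must be observed at least once.
#' @return A `gibbs_fit`; for 4 or more categories `var_draws` also holds
#'   the sampled thresholds.
#' @export
fit_threshold <- function(data, relmat_inv, cfg = gibbs_config(),
                          fix_variances = NULL, start_variances = NULL,
                          store_effects = FALSE) {
  stopifnot(data$kind == "threshold")
  fit_gibbs(data, relmat_inv, cfg, fix_variances, start_variances,
            store_effects)
}

#' @export
print.gibbs_fit <- function(x, ...) {
  h2 <- heritability(x)
  cat(sprintf("<gibbs_fit %s/%s> %d records, %d stored draws\n",
              x$trait_kind, x$relationship_kind, x$n_records,
              nrow(x$var_draws)))
  vm <- colMeans(x$var_draws)
  cat(sprintf("  sigma_a2 = %.3f  sigma_h2 = %.3f  sigma_e2 = %.3f  h2 = %.3f (%.3f)\n",
              vm["sigma_a2"], vm["sigma_h2"], vm["sigma_e2"],
              h2$mean, h2$sd))
  invisible(x)
}

#' Posterior summary of heritability
#'
#' Heritability is computed per stored draw as
#' `h2 = sigma_a2 / (sigma_a2 + sigma_h2 + sigma_e2)` (additive variance
#' over additive + flock + residual) and then summarized by its posterior
#' mean and standard deviation.
#'
#' @param x a `gibbs_fit`, or a matrix/data.frame of draws with columns
#'   `sigma_a2`, `sigma_h2`, `sigma_e2`.
#' @param ... unused.
#' @return A list with `mean`, `sd` and the per-draw vector `draws`.
#' @export
heritability <- function(x, ...) UseMethod("heritability")

#' @export
heritability.gibbs_fit <- function(x, ...) {
  heritability(as.data.frame(x$var_draws))
}

#' @export
heritability.data.frame <- function(x, ...) {
  stopifnot(all(c("sigma_a2", "sigma_h2", "sigma_e2") %in% names(x)),
            nrow(x) >= 1)
  h2 <- x$sigma_a2 / (x$sigma_a2 + x$sigma_h2 + x$sigma_e2)
  list(mean = mean(h2), sd = stats::sd(h2), draws = h2)
}

#' @export
heritability.matrix <- function(x, ...) heritability(as.data.frame(x), ...)

#' Export stored Gibbs draws to a delimited samples file
#' @param fit a `gibbs_fit`.
#' @param path output path (tab-delimited, one row per stored draw).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  utils::write.table(as.data.frame(fit$var_draws), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
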