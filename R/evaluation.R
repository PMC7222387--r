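#' Breeding-value accuracy from the standard error of prediction
#'
#' `accuracy = sqrt(1 - SEP^2 / sigma_a2)`, where SEP is the posterior
#' standard deviation of the animal's additive effect. When Monte Carlo
#' noise pushes `SEP^2` above `sigma_a2` the accuracy is clipped to 0; the
#' number of clipped animals is attached as attribute `n_clipped`.
#'
#' @param sep numeric vector of standard errors of prediction (>= 0).
#' @param sigma_a2 additive genetic variance (> 0).
#' @return Numeric vector of accuracies in `[0, 1]`.
#' @examples
#' accuracy_from_sep(0.3, 0.36)  # sqrt(0.75)
#' @export
accuracy_from_sep <- function(sep, sigma_a2) {
  if (!is.numeric(sigma_a2) || length(sigma_a2) != 1 || sigma_a2 <= 0)
    stop("sigma_a2 must be a single positive number")
  stopifnot(all(sep >= 0))
  rel <- 1 - sep^2 / sigma_a2
  clipped <- rel < 0
  rel[clipped] <- 0
  out <- sqrt(rel)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Per-animal breeding value report
#'
#' Extracts each animal's EBV (posterior mean of the additive effect), SEP
#' (posterior standard deviation) and accuracy from a fitted model. The
#' additive variance used in the accuracy is the posterior mean from the
#' same fit.
#'
#' @param fit a `gibbs_fit` (see [fit_linear()]).
#' @param genotyped_ids identifiers of genotyped animals, used to set the
#'   genotyped flag; defaults to the genotyped index carried by the
#'   relationship matrix, if any.
#' @return A data.frame of class `bv_report` with columns `animal`, `ebv`,
#'   `sep`, `accuracy`, `genotyped`; attributes `sigma_a2`,
#'   `relationship_kind` and `n_clipped`.
#' @export
breeding_value_report <- function(fit, genotyped_ids = NULL) {
  stopifnot(inherits(fit, "gibbs_fit"))
  sigma_a2 <- mean(fit$var_draws[, "sigma_a2"])
  acc <- accuracy_from_sep(fit$animal$sd, sigma_a2)
  if (is.null(genotyped_ids) && length(fit$genotyped_index) > 0)
    genotyped_ids <- fit$animal$animal[fit$genotyped_index]
  out <- data.frame(animal = fit$animal$animal,
                    ebv = fit$animal$mean,
                    sep = fit$animal$sd,
                    accuracy = as.numeric(acc),
                    genotyped = fit$animal$animal %in% genotyped_ids,
                    stringsAsFactors = FALSE)
  structure(out, sigma_a2 = sigma_a2,
            relationship_kind = fit$relationship_kind,
            n_clipped = attr(acc, "n_clipped"),
            class = c("bv_report", "data.frame"))
}

#' Write a per-animal breeding value table
#' @param report a `bv_report`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_bv_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late window of an MCMC chain,
#' standardized by spectral-density-at-zero estimates of the window
#' variances (autoregressive fit, as in the usual implementation).
#' `|z| < 1.96` is the conventional convergence band.
#'
#' @param chain numeric vector (length >= 100).
#' @param first_frac,last_frac fractions of the chain in the early and
#'   late windows (defaults 0.1 and 0.5).
#' @return The z-score (scalar).
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  stopifnot(is.numeric(chain), length(chain) >= 100,
            first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  if (stats::var(chain) == 0)
    stop("zero-variance chain: sampler is degenerate")
  n <- length(chain)
  x1 <- chain[seq_len(floor(first_frac * n))]
  x2 <- chain[seq.int(n - floor(last_frac * n) + 1, n)]
  v1 <- spectrum0_ar(x1)
  v2 <- spectrum0_ar(x2)
  (mean(x1) - mean(x2)) / sqrt(v1 / length(x1) + v2 / length(x2))
}

# spectral density at frequency zero from an AIC-selected AR fit
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(length(x) - 1,
                                                  floor(10 * log10(length(x)))))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Compare breeding values between pedigree-only and single-step fits
#'
#' Builds a comparison of the two evaluations on the same animals:
#' mean accuracy under each model, the relative accuracy gain
#' `delta_acc = 100 * mean((acc_H - acc_P) / acc_P)` over animals (the
#' ratio-of-means variant `100 * (mean(acc_H) - mean(acc_P)) / mean(acc_P)`
#' is also reported), and Pearson and Spearman correlations between the
#' EBV vectors with two-sided p-values.
#'
#' @param fit_P breeding-value report from the pedigree-based (PBLUP) fit.
#' @param fit_H breeding-value report from the single-step (ssGBLUP) fit.
#' @param subset `"whole"` (all animals) or `"genotyped"`.
#' @return A list of class `comparison_report`.
#' @export
compare_models <- function(fit_P, fit_H, subset = c("whole", "genotyped")) {
  subset <- match.arg(subset)
  stopifnot(inherits(fit_P, "bv_report"), inherits(fit_H, "bv_report"))
  m <- match(fit_P$animal, fit_H$animal)
  if (anyNA(m)) stop("the two reports must cover the same animals")
  H <- fit_H[m, ]
  P <- fit_P
  keep <- if (subset == "genotyped") which(P$genotyped | H$genotyped)
          else seq_len(nrow(P))
  if (length(keep) == 0) stop("empty animal subset: ", subset)
  P <- P[keep, ]; H <- H[keep, ]

  ok <- P$accuracy > 0
  delta <- if (any(ok))
    100 * mean((H$accuracy[ok] - P$accuracy[ok]) / P$accuracy[ok])
  else NA_real_
  delta_rom <- 100 * (mean(H$accuracy) - mean(P$accuracy)) / mean(P$accuracy)
  pe <- stats::cor.test(P$ebv, H$ebv, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(P$ebv, H$ebv, method = "spearman"))
  structure(list(subset = subset, n_animals = nrow(P),
                 mean_accuracy_P = mean(P$accuracy),
                 mean_accuracy_H = mean(H$accuracy),
                 delta_acc_percent = delta,
                 n_excluded_zero_accuracy = sum(!ok),
                 delta_acc_ratio_of_means_percent = delta_rom,
                 pearson = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman = unname(sp$estimate), spearman_p = sp$p.value),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Model comparison (%s population, n = %d)\n", x$subset,
              x$n_animals))
  cat(sprintf("  mean accuracy: PBLUP %.3f  ssGBLUP %.3f  delta_acc %.3f%% (ratio-of-means %.3f%%)\n",
              x$mean_accuracy_P, x$mean_accuracy_H, x$delta_acc_percent,
              x$delta_acc_ratio_of_means_percent))
  cat(sprintf("  EBV correlation: pearson %.3f (p = %.2g)  spearman %.3f (p = %.2g)\n",
              x$pearson, x$pearson_p, x$spearman, x$spearman_p))
  invisible(x)
}

#' Descriptive statistics of a trait
#'
#' @param values numeric vector (length >= 2, missing values dropped).
#' @return A list with `n`, `min`, `max`, `mean`, `sd` (sample standard
#'   deviation) and `cv = sd / mean` (`NA` when the mean is 0).
#' @examples
#' descriptive_stats(c(3, 4, 5))
#' @export
descriptive_stats <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  m <- mean(values); s <- stats::sd(values)
  list(n = length(values), min = min(values), max = max(values),
       mean = m, sd = s, cv = if (m == 0) NA_real_ else s / m)
}
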