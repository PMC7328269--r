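# Solve trigamma(y) = x by Newton iteration on 1/trigamma (which is nearly
# linear), as used when fitting the scaled-F distribution of sample variances.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Method-of-moments fit of a scaled F distribution to per-probe sample
# variances via the moments of log(s^2): returns the prior df d0 and prior
# variance s0^2 of the empirical-Bayes variance moderation.
fit_f_dist <- function(s2, df) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: complete shrinkage
    # to the common variance
    d0 <- Inf
    s0_2 <- mean(s2)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Per-probe differential methylation test with moderated variance
#'
#' Fits the two-group linear model to every probe (equivalent to a
#' pooled-variance two-sample comparison on the beta scale) and moderates the
#' residual variances by empirical Bayes: the per-probe sample variances are
#' modelled as draws from a scaled F distribution whose hyperparameters
#' (prior df `d0`, prior variance `s0^2`) are estimated by method of moments
#' from the log variances across probes. The moderated statistic is
#' `t = effect / (s_tilde * sqrt(1/n1 + 1/n2))` with
#' `s_tilde^2 = (d0 * s0^2 + df * s2) / (d0 + df)`, referred to a t
#' distribution on `min(df + d0, m * df)` degrees of freedom.
#'
#' @param betas A `beta_matrix` or plain probes x samples matrix.
#' @param groups Group labels (factor with levels control/case) or a layout
#'   tibble with a `group` column; both groups need at least 2 samples.
#' @param moderate Set `FALSE` to skip variance moderation and use the
#'   ordinary pooled-variance t test.
#' @param alpha Significance level used for the FDR/Bonferroni columns.
#' @return A `dmp_result`: list with `$table` (tibble `probe_id, effect, s2,
#'   df, t, p_value, q_bh, p_bonf`), hyperparameters `$d0`, `$s0_2`, group
#'   sizes, and the input's truth mask / spike targets when present.
#' @export
fit_dmp <- function(betas, groups, moderate = TRUE, alpha = 0.05) {
  x <- if (inherits(betas, "beta_matrix")) betas$values else betas
  if (is.data.frame(groups)) groups <- groups$group
  g <- factor(groups)
  if (nlevels(g) != 2) abort("groups must have exactly two levels")
  if ("case" %in% levels(g)) g <- stats::relevel(g, ref = setdiff(levels(g), "case"))
  is_case <- g == levels(g)[2]
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) abort("both groups need at least 2 samples")
  m <- nrow(x)

  mean_case <- rowMeans(x[, is_case, drop = FALSE])
  mean_ctrl <- rowMeans(x[, !is_case, drop = FALSE])
  effect <- unname(mean_case - mean_ctrl)
  df <- n1 + n2 - 2
  rss <- rowSums((x[, is_case, drop = FALSE] - mean_case)^2) +
    rowSums((x[, !is_case, drop = FALSE] - mean_ctrl)^2)
  s2 <- unname(pmax(rss / df, .Machine$double.eps))

  if (moderate) {
    prior <- fit_f_dist(s2, df)
    d0 <- prior$d0
    s0_2 <- prior$s0_2
    s2_post <- if (is.infinite(d0)) rep(s0_2, m) else
      (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- min(df + d0, m * df)
  } else {
    d0 <- 0
    s0_2 <- NA_real_
    s2_post <- s2
    df_total <- df
  }
  t_stat <- effect / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t_stat), df = df_total)
  adj <- adjust_multiplicity(p)

  structure(list(
    table = tibble::tibble(
      probe_id = rownames(x) %||% sprintf("p%d", seq_len(m)),
      effect = effect, s2 = s2, df = df,
      t = t_stat, p_value = p, q_bh = adj$q_bh, p_bonf = adj$p_bonf
    ),
    d0 = d0, s0_2 = s0_2, df_total = df_total, n1 = n1, n2 = n2,
    alpha = alpha,
    truth_mask = if (inherits(betas, "beta_matrix")) betas$truth_mask else NULL,
    spike_target_p = if (inherits(betas, "beta_matrix")) betas$spike_target_p else NULL
  ), class = "dmp_result")
}

#' @export
print.dmp_result <- function(x, ...) {
  cat("<dmp_result> ", nrow(x$table), " probes, groups ", x$n1, "/", x$n2,
      "\n  prior df d0 = ", format(x$d0, digits = 4),
      ", prior variance s0^2 = ", format(x$s0_2, digits = 4), "\n", sep = "")
  cat("  FDR (q < ", x$alpha, "): ", sum(x$table$q_bh < x$alpha),
      "; Bonferroni: ", sum(x$table$p_bonf < x$alpha), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.dmp_result <- function(x, ...) x$table

#' @export
glance.dmp_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$table), n1 = x$n1, n2 = x$n2,
    d0 = x$d0, s0_2 = x$s0_2, df_total = x$df_total,
    mean_p = mean(x$table$p_value),
    lambda = lambda_inflation(x$table$p_value)
  )
}

#' Benjamini-Hochberg and Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return A tibble with columns `q_bh` (BH step-up q-values) and `p_bonf`
#'   (`min(1, m * p)`), aligned with `p`.
#' @export
adjust_multiplicity <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  tibble::tibble(
    q_bh = p.adjust(p, method = "BH"),
    p_bonf = p.adjust(p, method = "bonferroni")
  )
}

#' Genomic inflation factor of a p-value set
#'
#' Converts each p-value to its 1-df chi-square equivalent and takes the
#' ratio of the observed median to the null median `qchisq(0.5, 1)` (about
#' 0.4549). Uniform p-values give lambda = 1 in expectation; lambda > 1
#' indicates bulk inflation of the test statistics.
#'
#' @param p Numeric vector of p-values in (0, 1\]; exact zeros are mapped to
#'   the largest finite quantile with a warning.
#' @return The scalar inflation factor.
#' @export
lambda_inflation <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn("p-values of exactly 0 mapped to the largest finite chi-square quantile")
    p[p == 0] <- .Machine$double.xmin
  }
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Summarise a DMP result into the run-level metrics
#'
#' The whole results surface of a simulation run: the mean p-value across
#' probes (0.5 expected under a clean null), the genomic inflation factor
#' lambda (1 expected), and the counts of FDR- and Bonferroni-significant
#' probes (0 expected on null data).
#'
#' @param dmp A `dmp_result`.
#' @param alpha Significance level (default 0.05).
#' @param metadata Optional named list (design, variant, seed, ...) spliced
#'   into the row as extra columns.
#' @return A one-row tibble `mean_p, lambda, n_fdr, n_bf, n_probes, ...`.
#' @export
summarize_metrics <- function(dmp, alpha = 0.05, metadata = list()) {
  stopifnot(inherits(dmp, "dmp_result"))
  tbl <- dmp$table
  out <- tibble::tibble(
    mean_p = mean(tbl$p_value),
    lambda = lambda_inflation(tbl$p_value),
    n_fdr = sum(tbl$q_bh < alpha),
    n_bf = sum(tbl$p_bonf < alpha),
    n_probes = nrow(tbl)
  )
  if (length(metadata) > 0) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(metadata))
  }
  out
}

#' Q-Q coordinates of a p-value set
#'
#' @param p Numeric vector of p-values.
#' @return A tibble `expected, observed` of -log10 p pairs: observed order
#'   statistics against uniform plotting positions `(i - 0.5) / m`.
#' @export
qq_points <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  m <- length(p)
  tibble::tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(sort(p))
  )
}

#' Export a DMP table to delimited text
#'
#' @param dmp A `dmp_result`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_dmp_table <- function(dmp, path) {
  stopifnot(inherits(dmp, "dmp_result"))
  out <- dmp$table[, c("probe_id", "effect", "t", "p_value", "q_bh", "p_bonf")]
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path, progress = FALSE)
  else readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
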