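#' Beta-value / M-value transforms
#'
#' `to_mvalues()` is the elementwise logit on base 2, `log2(beta/(1-beta))`;
#' `from_mvalues()` inverts it. Values are assumed pre-clamped into
#' \[eps, 1 - eps\] so the transform is finite; the round trip is exact to
#' floating-point precision.
#'
#' @param betas Numeric matrix (or `beta_matrix`) of beta values.
#' @param m Numeric matrix of M-values.
#' @return A numeric matrix.
#' @export
to_mvalues <- function(betas) {
  x <- if (inherits(betas, "beta_matrix")) betas$values else betas
  log2(x / (1 - x))
}

#' @rdname to_mvalues
#' @export
from_mvalues <- function(m) {
  y <- 2^m
  y / (1 + y)
}

row_vars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

# Inverse-gamma method-of-moments hyperpriors for the per-batch scale
# parameters: shape/rate chosen so the prior mean and variance match the
# empirical mean and variance of the per-probe batch variances.
aprior <- function(delta_hat) {
  m <- mean(delta_hat)
  s2 <- var(delta_hat)
  (2 * s2 + m^2) / s2
}
bprior <- function(delta_hat) {
  m <- mean(delta_hat)
  s2 <- var(delta_hat)
  (m * s2 + m^3) / s2
}

#' Fit a parametric empirical-Bayes batch correction (ComBat)
#'
#' From-scratch implementation of the parametric location/scale empirical
#' Bayes batch adjustment. The algorithm: (1) per-probe least-squares
#' standardization against a design of batch indicators plus optional
#' covariates (e.g. the outcome-of-interest group — the `mod` matrix);
#' (2) per-batch, per-probe location (`gamma_hat`) and scale (`delta_hat`)
#' estimates on the standardized data; (3) normal / inverse-gamma hyperpriors
#' estimated across probes by method of moments; (4) iterative fixed-point
#' solution of the conditional posterior means `(gamma_star, delta_star)`.
#'
#' If `mod` is confounded with the batch (the combined design is singular),
#' the covariates are dropped from the standardization with a warning and the
#' fit is flagged (`covariates_dropped = TRUE`) so the run can proceed — the
#' fully unbalanced design is exactly this case.
#'
#' @param values Numeric probes x samples matrix (normally M-values).
#' @param batch Batch assignment, coercible to a factor; every level needs at
#'   least 2 samples.
#' @param mod Optional covariate model matrix (rows = samples). An intercept
#'   column is tolerated and removed (the batch indicators span it).
#' @param parametric Must be `TRUE`; the nonparametric pathway is not
#'   implemented and errors explicitly.
#' @param tol Relative-change convergence tolerance of the fixed-point
#'   iteration (default 1e-4).
#' @param max_iter Iteration cap per batch (default 500); hitting it flags
#'   the fit unconverged but is not fatal.
#' @param keep_standardized Keep the standardized matrix in the fit so that
#'   [combat_apply()] on the very same input skips re-standardizing (a
#'   speed/memory trade-off used by [sequential_correct()]).
#' @return An object of class `combat_fit`; see [combat_apply()].
#' @export
combat_fit <- function(values, batch, mod = NULL, parametric = TRUE,
                       tol = 1e-4, max_iter = 500L,
                       keep_standardized = FALSE) {
  if (!parametric) {
    abort("nonparametric empirical-Bayes fitting is not implemented")
  }
  if (any(!is.finite(values))) abort("values contain non-finite entries")
  batch <- droplevels(as.factor(batch))
  n_array <- length(batch)
  if (ncol(values) != n_array) abort("ncol(values) must equal length(batch)")
  n_batch <- nlevels(batch)
  batches <- split(seq_len(n_array), batch)
  n_per <- lengths(batches)
  if (any(n_per < 2L)) abort("every batch level needs at least 2 samples")

  if (n_batch == 1L) {
    # single batch: nothing to correct; identity fit
    return(structure(list(
      batch = batch, batches = batches, n_per = n_per, n_batch = 1L,
      identity = TRUE, covariates_dropped = FALSE, converged = TRUE,
      iterations = 0L
    ), class = "combat_fit"))
  }

  batch_design <- model.matrix(~ 0 + batch)
  design <- cbind(batch_design, mod)
  # batch indicators already span the intercept; drop constant covariates
  keep <- !apply(design, 2L, function(x) all(x == 1))
  keep[seq_len(n_batch)] <- TRUE
  design <- design[, keep, drop = FALSE]
  covariates_dropped <- FALSE
  if (qr(design)$rank < ncol(design)) {
    warn(paste("covariates are confounded with batch;",
               "dropping them from the standardization model"))
    design <- design[, seq_len(n_batch), drop = FALSE]
    covariates_dropped <- TRUE
  }

  # (1) standardization
  B_hat <- solve(crossprod(design), t(design) %*% t(values))
  grand_mean <- drop(crossprod(n_per / n_array,
                               B_hat[seq_len(n_batch), , drop = FALSE]))
  var_pooled <- drop(((values - t(design %*% B_hat))^2) %*%
                       rep(1 / n_array, n_array))
  var_pooled <- pmax(var_pooled, .Machine$double.eps)
  s_data <- standardize(values, design, B_hat, grand_mean, var_pooled, n_batch)

  # (2) per-batch location/scale on the standardized data
  gamma_hat <- solve(crossprod(batch_design), t(batch_design) %*% t(s_data))
  delta_hat <- t(vapply(batches, function(idx)
    row_vars(s_data[, idx, drop = FALSE]), numeric(nrow(values))))

  # (3) hyperpriors across probes
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, var)
  a_prior <- apply(delta_hat, 1L, aprior)
  b_prior <- apply(delta_hat, 1L, bprior)

  # (4) fixed-point EB posteriors, one batch at a time
  gamma_star <- matrix(NA_real_, n_batch, nrow(values))
  delta_star <- matrix(NA_real_, n_batch, nrow(values))
  iterations <- integer(n_batch)
  converged <- logical(n_batch)
  for (i in seq_len(n_batch)) {
    sdat <- s_data[, batches[[i]], drop = FALSE]
    n_i <- n_per[[i]]
    g_hat <- gamma_hat[i, ]
    g_old <- g_hat
    d_old <- delta_hat[i, ]
    count <- 0L
    repeat {
      g_new <- (t2[i] * n_i * g_hat + d_old * gamma_bar[i]) /
        (t2[i] * n_i + d_old)
      sum2 <- rowSums((sdat - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      # canonical convergence criterion: the location ratio keeps the sign
      # of g_old, so probes with negative batch location never gate
      # convergence — matching the behaviour of the reference algorithm
      change <- max(abs(g_new - g_old) / g_old,
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      count <- count + 1L
      if (is.na(change) || change < tol || count >= max_iter) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
    iterations[i] <- count
    converged[i] <- !is.na(change) && change < tol
  }

  structure(list(
    batch = batch, batches = batches, n_per = n_per, n_batch = n_batch,
    identity = FALSE, design = design, B_hat = B_hat,
    grand_mean = grand_mean, var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_bar = gamma_bar, t2 = t2, a_prior = a_prior, b_prior = b_prior,
    gamma_star = gamma_star, delta_star = delta_star,
    iterations = iterations, converged = converged,
    covariates_dropped = covariates_dropped, tol = tol,
    s_data = if (keep_standardized) s_data else NULL
  ), class = "combat_fit")
}

standardize <- function(values, design, B_hat, grand_mean, var_pooled, n_batch) {
  stand_mean <- matrix(grand_mean, nrow(values), ncol(values))
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  (values - stand_mean) / sqrt(var_pooled)
}

#' Apply a fitted batch correction
#'
#' Standardizes `values` with the fit's least-squares estimates, removes the
#' empirical-Bayes posterior batch location and scale, and restores the grand
#' mean and covariate effects.
#'
#' @param values The probes x samples matrix to adjust (same samples, in the
#'   same order, as used in [combat_fit()]).
#' @param fit A `combat_fit`.
#' @return The adjusted matrix, same dimensions and dimnames as `values`.
#' @export
combat_apply <- function(values, fit) {
  stopifnot(inherits(fit, "combat_fit"))
  if (ncol(values) != length(fit$batch)) abort("dimension mismatch with fit")
  if (fit$identity) return(values)
  if (nrow(values) != ncol(fit$B_hat)) abort("dimension mismatch with fit")
  n_batch <- fit$n_batch
  s_data <- fit$s_data %||%
    standardize(values, fit$design, fit$B_hat, fit$grand_mean,
                fit$var_pooled, n_batch)
  out <- s_data
  for (i in seq_len(n_batch)) {
    idx <- fit$batches[[i]]
    out[, idx] <- (s_data[, idx, drop = FALSE] - fit$gamma_star[i, ]) /
      sqrt(fit$delta_star[i, ])
  }
  adjusted <- out * sqrt(fit$var_pooled) +
    matrix(fit$grand_mean, nrow(values), ncol(values))
  if (ncol(fit$design) > n_batch) {
    tmp <- fit$design
    tmp[, seq_len(n_batch)] <- 0
    adjusted <- adjusted + t(tmp %*% fit$B_hat)
  }
  if (any(!is.finite(adjusted))) {
    abort("batch adjustment produced non-finite values")
  }
  dimnames(adjusted) <- dimnames(values)
  adjusted
}

#' Correct a beta matrix for batch factors, one factor at a time
#'
#' Reproduces the pipeline loop over batch names: the matrix is logit
#' transformed to M-values (by default), corrected once per factor in order
#' (the output of one pass feeds the next), back-transformed, and re-clamped.
#' ComBat itself is a single-factor method; sequential application is how
#' multi-factor correction is done in practice.
#'
#' The `variant` encodes the three usage patterns under study:
#' `"with_outcome_model"` passes the case/control indicator as a covariate
#' (`mod`) during standardization — the integrated-pipeline behaviour;
#' `"no_model"` uses batch indicators only; `"none"` returns the input
#' unchanged.
#'
#' @param betas A `beta_matrix`.
#' @param layout Layout tibble; every entry of `factors` must be one of its
#'   columns (e.g. `"row"`, `"chip"`, `"plate"`, or a sweep factor column).
#' @param factors Ordered character vector of factor labels (default
#'   `c("row", "chip")`). Empty means identity.
#' @param variant `"with_outcome_model"`, `"no_model"` or `"none"`.
#' @param on_mvalues Correct on the M-value scale (default) or directly on
#'   beta values.
#' @param eps Clamp width for the back-transform.
#' @param tol,max_iter Passed to [combat_fit()].
#' @return A `beta_matrix` with provenance `"corrected"`; `$correction`
#'   records per-factor convergence and whether the outcome column had to be
#'   dropped for a confounded factor.
#' @export
sequential_correct <- function(betas, layout,
                               factors = c("row", "chip"),
                               variant = c("with_outcome_model", "no_model",
                                           "none"),
                               on_mvalues = TRUE, eps = 0.001,
                               tol = 1e-4, max_iter = 500L) {
  stopifnot(inherits(betas, "beta_matrix"))
  variant <- match.arg(variant)
  if (variant == "none" || length(factors) == 0) return(betas)
  unknown <- setdiff(factors, names(layout))
  if (length(unknown) > 0) {
    abort(paste0("unknown factor label(s): ", paste(unknown, collapse = ", ")))
  }
  mod <- NULL
  if (variant == "with_outcome_model") {
    if (is.null(layout$group)) abort("with_outcome_model requires layout$group")
    mod <- model.matrix(~ group, data = layout)
  }
  x <- if (on_mvalues) to_mvalues(betas$values) else betas$values
  log <- purrr::map(factors, function(f) {
    fit <- combat_fit(x, layout[[f]], mod = mod, tol = tol,
                      max_iter = max_iter, keep_standardized = TRUE)
    x <<- combat_apply(x, fit)
    fit$s_data <- NULL
    tibble::tibble(
      factor = f,
      n_levels = fit$n_batch,
      converged = all(fit$converged),
      covariates_dropped = fit$covariates_dropped
    )
  })
  values <- if (on_mvalues) clamp_unit(from_mvalues(x), eps) else clamp_unit(x, eps)
  dimnames(values) <- dimnames(betas$values)
  new_beta_matrix(values, provenance = "corrected",
                  truth_mask = betas$truth_mask,
                  spike_target_p = betas$spike_target_p,
                  batch_spec = betas$batch_spec,
                  correction = list(variant = variant,
                                    on_mvalues = on_mvalues,
                                    log = dplyr::bind_rows(log)))
}

#' @export
print.combat_fit <- function(x, ...) {
  cat("<combat_fit> ", x$n_batch, " batch level(s)", sep = "")
  if (x$identity) {
    cat(" (identity)\n")
    return(invisible(x))
  }
  cat(", ", ncol(x$B_hat), " probes\n", sep = "")
  cat("  converged: ", all(x$converged), " (max ", max(x$iterations),
      " iterations)\n", sep = "")
  if (x$covariates_dropped) cat("  note: confounded covariates were dropped\n")
  invisible(x)
}

#' Tidy the empirical-Bayes hyperparameters of a batch-correction fit
#'
#' @param x A `combat_fit`.
#' @param ... Unused.
#' @return One row per batch level: sample count, prior location mean
#'   `gamma_bar`, prior location variance `t2`, inverse-gamma shape/rate
#'   `a_prior`/`b_prior`, iteration count and convergence flag.
#' @export
tidy.combat_fit <- function(x, ...) {
  if (x$identity) {
    return(tibble::tibble(batch = levels(x$batch), n = unname(x$n_per),
                          gamma_bar = 0, t2 = 0, a_prior = NA_real_,
                          b_prior = NA_real_, iterations = 0L,
                          converged = TRUE))
  }
  tibble::tibble(
    batch = levels(x$batch),
    n = unname(x$n_per),
    gamma_bar = x$gamma_bar,
    t2 = x$t2,
    a_prior = x$a_prior,
    b_prior = x$b_prior,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @rdname tidy.combat_fit
#' @return `glance()`: a one-row tibble with batch/probe counts, overall
#'   convergence, and whether confounded covariates were dropped.
#' @export
glance.combat_fit <- function(x, ...) {
  tibble::tibble(
    n_batch = x$n_batch,
    n_samples = length(x$batch),
    n_probes = if (x$identity) NA_integer_ else ncol(x$B_hat),
    converged = if (x$identity) TRUE else all(x$converged),
    max_iterations = if (x$identity) 0L else max(x$iterations),
    covariates_dropped = x$covariates_dropped
  )
}
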