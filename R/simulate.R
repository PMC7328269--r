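new_beta_matrix <- function(values, provenance, truth_mask = NULL,
                            spike_target_p = NULL, batch_spec = NULL,
                            correction = NULL) {
  structure(
    list(
      values = values,
      probe_ids = rownames(values),
      sample_ids = colnames(values),
      provenance = provenance,
      truth_mask = truth_mask %||% logical(nrow(values)),
      spike_target_p = spike_target_p %||% rep(NA_real_, nrow(values)),
      batch_spec = batch_spec,
      correction = correction
    ),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples, provenance: ", x$provenance, "\n", sep = "")
  if (any(x$truth_mask)) cat("  spiked sites: ", sum(x$truth_mask), "\n", sep = "")
  if (!is.null(x$batch_spec)) {
    cat("  injected offsets: ", nrow(x$batch_spec$offsets), " (amplitude ",
        x$batch_spec$amplitude, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
as.matrix.beta_matrix <- function(x, ...) x$values

#' Simulate a null methylation beta matrix
#'
#' Every probe/sample value is an independent normal draw with that probe's
#' profile mean and SD, clamped into \[eps, 1 - eps\] so downstream logit
#' transforms stay finite. Simulated this way the data carry no group signal
#' and no batch structure: any downstream "significant" probe is a false
#' positive by construction.
#'
#' @param profile Parameter profile tibble (see [emulate_parameter_profile()]).
#' @param layout Layout tibble defining the samples.
#' @param seed Integer seed; the matrix is a pure function of its inputs.
#' @param eps Clamp width (default 0.001).
#' @return A `beta_matrix` with provenance `"null"`.
#' @export
generate_null_betas <- function(profile, layout, seed, eps = 0.001) {
  validate_profile(profile)
  if (nrow(layout) == 0) abort("layout has zero samples")
  m <- nrow(profile)
  n <- nrow(layout)
  values <- withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(m * n), nrow = m, ncol = n)
    # mean/SD vectors recycle down columns: row j keeps profile row j
    profile$mean_beta + profile$sd_beta * z
  })
  values <- clamp_unit(values, eps)
  dimnames(values) <- list(profile$probe_id, layout$sample_id)
  new_beta_matrix(values, provenance = "null")
}

#' Inject additive batch effects
#'
#' Emulates a technical brightness offset: for every level of every requested
#' batch factor one offset is drawn Uniform(-amplitude, +amplitude), and each
#' sample's entire probe vector is shifted by the sum of its levels' offsets
#' (constant across probes), then re-clamped. The default amplitude 0.01
#' corresponds to offsets between -1% and +1% methylation.
#'
#' @param betas A `beta_matrix`.
#' @param layout Layout tibble; `factors` must be columns of it.
#' @param factors Batch factor labels (default `c("row", "chip")`).
#' @param amplitude Maximal absolute offset on the beta scale.
#' @param seed Integer seed.
#' @param eps Clamp width.
#' @return A `beta_matrix` with provenance `"batch_injected"`, carrying the
#'   drawn offsets in `$batch_spec` (a list with `amplitude`, `seed` and an
#'   `offsets` tibble `factor, level, offset`).
#' @export
inject_batch_effects <- function(betas, layout, factors = c("row", "chip"),
                                 amplitude = 0.01, seed, eps = 0.001) {
  stopifnot(inherits(betas, "beta_matrix"))
  unknown <- setdiff(factors, names(layout))
  if (length(unknown) > 0) {
    abort(paste0("unknown factor label(s): ", paste(unknown, collapse = ", ")))
  }
  if (amplitude < 0) abort("amplitude must be nonnegative")
  offsets <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(factors, function(f) {
      lev <- sort(unique(layout[[f]]))
      tibble::tibble(
        factor = f,
        level = as.character(lev),
        offset = runif(length(lev), -amplitude, amplitude)
      )
    })
  })
  shift <- rep(0, nrow(layout))
  for (f in factors) {
    ofs <- offsets[offsets$factor == f, ]
    shift <- shift + ofs$offset[match(as.character(layout[[f]]), ofs$level)]
  }
  values <- clamp_unit(sweep(betas$values, 2L, shift, "+"), eps)
  spec <- list(amplitude = amplitude, seed = as.integer(seed), offsets = offsets)
  new_beta_matrix(values, provenance = "batch_injected",
                  truth_mask = betas$truth_mask,
                  spike_target_p = betas$spike_target_p,
                  batch_spec = spec)
}

#' Mean shift that yields a prescribed two-sample p-value
#'
#' Returns the group-mean difference `delta` such that a pooled-variance
#' two-sample t test with common SD `sd` and group sizes `n1`, `n2` whose
#' sample means differ by exactly `delta` gives two-sided p = `target_p`:
#' `delta = qt(1 - p/2, n1 + n2 - 2) * sd * sqrt(1/n1 + 1/n2)`.
#'
#' @param target_p Two-sided target p-value(s) in (0, 1); vectorised.
#' @param n1,n2 Group sizes (each at least 2).
#' @param sd Common within-group standard deviation.
#' @return Numeric vector of shifts, same length as `target_p`.
#' @export
calibrate_effect_shift <- function(target_p, n1, n2, sd) {
  if (any(target_p <= 0 | target_p >= 1)) abort("target_p must lie in (0, 1)")
  if (n1 < 2 || n2 < 2) abort("both group sizes must be at least 2")
  if (any(sd <= 0)) abort("sd must be positive")
  qt(1 - target_p / 2, df = n1 + n2 - 2) * sd * sqrt(1 / n1 + 1 / n2)
}

#' Spike calibrated true group effects into a beta matrix
#'
#' Picks `n_sites` probes at random, allocates them as evenly as possible
#' across the `target_p` ladder (default 1e-1 .. 1e-20), and adds to each
#' chosen probe's case-group entries the shift that [calibrate_effect_shift()]
#' maps to its target p given that probe's profile SD. The truth mask and
#' per-probe target p are recorded for detection-rate analysis.
#'
#' @param betas A `beta_matrix` (normally null, before batch injection).
#' @param layout Layout tibble with a `group` column.
#' @param profile Parameter profile supplying each probe's SD.
#' @param n_sites Number of probes to spike (default 2000).
#' @param target_p Ladder of two-sided target p-values (default `10^-(1:20)`).
#' @param seed Integer seed.
#' @param eps Clamp width.
#' @return A `beta_matrix` with provenance `"spiked"`.
#' @export
spike_group_effects <- function(betas, layout, profile, n_sites = 2000L,
                                target_p = 10^-(1:20), seed, eps = 0.001) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (is.null(layout$group) || nlevels(factor(layout$group)) != 2) {
    abort("layout must carry a two-level group column")
  }
  m <- nrow(betas$values)
  n_sites <- as.integer(n_sites)
  if (n_sites > m) abort("more spike sites than probes")
  if (n_sites == 0L) return(betas)
  if (n_sites < length(target_p)) abort("n_sites must cover the target_p ladder")
  is_case <- layout$group == "case"
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  drawn <- withr::with_seed(as.integer(seed), {
    idx <- sample.int(m, n_sites)
    targets <- rep(target_p, length.out = n_sites)[sample.int(n_sites)]
    list(idx = idx, targets = targets)
  })
  shift <- calibrate_effect_shift(drawn$targets, n1, n2,
                                  profile$sd_beta[drawn$idx])
  values <- betas$values
  values[drawn$idx, is_case] <- values[drawn$idx, is_case] + shift
  values <- clamp_unit(values, eps)
  truth <- betas$truth_mask
  truth[drawn$idx] <- TRUE
  spike_p <- betas$spike_target_p
  spike_p[drawn$idx] <- drawn$targets
  new_beta_matrix(values, provenance = "spiked", truth_mask = truth,
                  spike_target_p = spike_p, batch_spec = betas$batch_spec)
}

#' Serialize a beta matrix to gzipped delimited text
#'
#' @param betas A `beta_matrix`.
#' @param path Output path; `.gz` compresses transparently.
#' @return `path` invisibly (`write_`), or a `beta_matrix` (`read_`).
#' @export
write_beta_matrix <- function(betas, path) {
  stopifnot(inherits(betas, "beta_matrix"))
  out <- tibble::as_tibble(betas$values, rownames = "probe_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @param provenance Provenance flag to stamp on the reloaded matrix.
#' @export
read_beta_matrix <- function(path, provenance = "null") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(x[, -1])
  rownames(values) <- x$probe_id
  new_beta_matrix(values, provenance = provenance)
}
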