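#' Nominal probe counts of the Illumina methylation array generations
#'
#' Named vector of default platform sizes used when subsampling an EPIC-sized
#' parameter profile down to the older arrays. These are configuration, not
#' constants: every function taking a `platform` argument also accepts an
#' explicit size.
#'
#' @format Named integer vector with entries `K27`, `K450`, `EPIC`.
#' @export
platform_sizes <- c(K27 = 27000L, K450 = 450000L, EPIC = 758289L)

validate_profile <- function(profile, call = rlang::caller_env()) {
  required <- c("probe_id", "mean_beta", "sd_beta", "design_type", "platform")
  missing <- setdiff(required, names(profile))
  if (length(missing) > 0) {
    abort(paste0("profile is missing column(s): ", paste(missing, collapse = ", ")),
          call = call)
  }
  if (nrow(profile) == 0) abort("profile has zero rows", call = call)
  if (anyDuplicated(profile$probe_id)) abort("duplicate probe_id values", call = call)
  if (any(profile$mean_beta < 0 | profile$mean_beta > 1)) {
    abort("mean_beta outside [0, 1]", call = call)
  }
  if (any(profile$sd_beta <= 0 | profile$sd_beta > 0.5)) {
    abort("sd_beta outside (0, 0.5]", call = call)
  }
  if (!all(profile$design_type %in% c("I", "II"))) {
    abort("design_type must be \"I\" or \"II\"", call = call)
  }
  invisible(profile)
}

#' Load a per-CpG parameter table
#'
#' Reads a delimited table of per-probe generative parameters (the mean and
#' standard deviation of each probe's beta value, as estimated from a real
#' cohort) and validates it into a parameter profile. Rows with a mean outside
#' \[0, 1\] or a non-positive SD are dropped with a message reporting the count.
#'
#' @param path Path to a CSV or TSV file (gzip transparently supported).
#' @param platform Platform label to stamp on the profile (`"EPIC"`, `"K450"`,
#'   `"K27"`, or any string).
#' @param col_map Named character vector mapping the required fields
#'   `probe_id`, `mean_beta`, `sd_beta` (and optionally `design_type`) to the
#'   column names used in the file.
#' @return A tibble with columns `probe_id`, `mean_beta`, `sd_beta`,
#'   `design_type`, `platform` — one row per retained probe.
#' @seealso [emulate_parameter_profile()] for a synthetic stand-in,
#'   [write_parameter_table()] for the inverse.
#' @export
load_parameter_table <- function(path, platform = "EPIC",
                                 col_map = c(probe_id = "probe_id",
                                             mean_beta = "mean_beta",
                                             sd_beta = "sd_beta",
                                             design_type = "design_type")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "mean_beta", "sd_beta")
  for (field in need) {
    src <- col_map[[field]] %||% field
    if (!src %in% names(raw)) {
      abort(paste0("column \"", src, "\" (mapped to ", field, ") not in file"))
    }
  }
  dt_src <- col_map[["design_type"]] %||% "design_type"
  profile <- tibble::tibble(
    probe_id = as.character(raw[[col_map[["probe_id"]]]]),
    mean_beta = as.numeric(raw[[col_map[["mean_beta"]]]]),
    sd_beta = as.numeric(raw[[col_map[["sd_beta"]]]]),
    design_type = if (dt_src %in% names(raw)) as.character(raw[[dt_src]]) else "II",
    platform = platform
  )
  ok <- is.finite(profile$mean_beta) & is.finite(profile$sd_beta) &
    profile$mean_beta >= 0 & profile$mean_beta <= 1 &
    profile$sd_beta > 0 & profile$sd_beta <= 0.5
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped (mean outside [0,1] or SD outside (0,0.5])")
    profile <- profile[ok, , drop = FALSE]
  }
  if (nrow(profile) == 0) abort("no valid rows after validation")
  if (anyDuplicated(profile$probe_id)) abort("duplicate probe ids in table")
  validate_profile(profile)
}

#' Write a parameter profile back to delimited text
#'
#' @param profile A parameter profile tibble.
#' @param path Output path; `.csv`/`.tsv` extension picks the delimiter,
#'   `.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(profile, path) {
  validate_profile(profile)
  out <- profile[, c("probe_id", "mean_beta", "sd_beta", "design_type")]
  if (grepl("\\.tsv(\\.gz)?$", path)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Emulate a per-CpG parameter profile
#'
#' Synthesises the bimodal beta-value landscape of a methylation array when no
#' measured per-probe table is available. Probe means come from a three-part
#' beta mixture: an unmethylated mode near 0.1, a methylated mode near 0.9,
#' and a minority intermediate component; probe SDs come from a right-skewed
#' log-normal with median 0.03, truncated to (0, 0.5].
#'
#' @param n_probes Number of probes to generate.
#' @param seed Integer seed; the profile is a pure function of
#'   `(n_probes, seed)`.
#' @param platform Platform label stamped on the profile.
#' @param mix_weights Length-3 numeric (unmethylated, methylated,
#'   intermediate) mixture weights; normalised internally.
#' @return A parameter profile tibble (see [load_parameter_table()]).
#' @export
emulate_parameter_profile <- function(n_probes, seed, platform = "EPIC",
                                      mix_weights = c(0.42, 0.42, 0.16)) {
  if (length(n_probes) != 1 || is.na(n_probes) || n_probes < 1) {
    abort("n_probes must be a positive integer")
  }
  n_probes <- as.integer(n_probes)
  stopifnot(length(mix_weights) == 3, all(mix_weights > 0))
  w <- mix_weights / sum(mix_weights)
  withr::with_seed(as.integer(seed), {
    comp <- sample.int(3L, n_probes, replace = TRUE, prob = w)
    mean_beta <- numeric(n_probes)
    mean_beta[comp == 1L] <- rbeta(sum(comp == 1L), 2.5, 22.5)
    mean_beta[comp == 2L] <- rbeta(sum(comp == 2L), 22.5, 2.5)
    mean_beta[comp == 3L] <- rbeta(sum(comp == 3L), 5, 5)
    sd_beta <- pmin(pmax(rlnorm(n_probes, meanlog = log(0.03), sdlog = 0.55),
                         1e-4), 0.5)
    # Infinium type-I probes sit disproportionately at the methylation
    # extremes; carried for schema realism only, unused downstream.
    p_type1 <- 0.08 + 0.2 * abs(mean_beta - 0.5)
    design_type <- ifelse(runif(n_probes) < p_type1, "I", "II")
    profile <- tibble::tibble(
      probe_id = sprintf("cg%08d", seq_len(n_probes)),
      mean_beta = mean_beta,
      sd_beta = sd_beta,
      design_type = design_type,
      platform = platform
    )
    validate_profile(profile)
  })
}

#' Subsample a profile to a smaller array platform
#'
#' Older array generations are emulated by uniform sampling without
#' replacement from the larger profile, mirroring how 27K/450K-sized data can
#' be derived from an EPIC-sized profile.
#'
#' @param profile Source parameter profile.
#' @param target Target platform label; its size is looked up in `sizes`.
#' @param seed Integer seed for the draw.
#' @param sizes Named vector of platform probe counts
#'   (default [platform_sizes]).
#' @param n_probes Explicit target size, overriding the `sizes` lookup.
#' @return A parameter profile tibble of the target size, rows in draw order.
#' @export
subsample_platform <- function(profile, target = c("K450", "K27", "EPIC"),
                               seed, sizes = platform_sizes, n_probes = NULL) {
  validate_profile(profile)
  target <- match.arg(target)
  n_target <- as.integer(n_probes %||% sizes[[target]])
  if (n_target > nrow(profile)) {
    abort(paste0("target size ", n_target, " exceeds source size ", nrow(profile)))
  }
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(nrow(profile), n_target, replace = FALSE))
  out <- profile[idx, , drop = FALSE]
  out$platform <- target
  out
}
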