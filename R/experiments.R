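#' Configure a simulation scenario
#'
#' Bundles everything one cell of the study grid needs: sample size and
#' design, correction variant and factor order, batch injection, optional
#' spike-in, replication count and master seed. Defaults encode the core
#' protocol: n = 48 samples (6 chips of 8), row + chip batch factors,
#' +/-1% injected offsets, 100 repetitions.
#'
#' @param n_samples Number of samples (default 48).
#' @param design Sample distribution: `"balanced"`, `"unbalanced"` or
#'   `"random"`.
#' @param variant Correction variant (see [sequential_correct()]).
#' @param factors Ordered batch factors to correct (default row then chip).
#' @param inject_batch Inject batch offsets before correction?
#' @param amplitude Offset amplitude on the beta scale (default 0.01).
#' @param spike_sites Number of spiked true effects (0 = none).
#' @param spike_target_p Target p ladder for the spikes.
#' @param n_reps Repetitions (default 100).
#' @param seed Master seed; every stage of every repetition derives its own
#'   substream from it.
#' @param alpha Significance level for the FDR/Bonferroni counts.
#' @param on_mvalues Correct on the M-value scale (default) or on betas.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_samples = 48L,
                            design = c("random", "balanced", "unbalanced"),
                            variant = c("with_outcome_model", "no_model",
                                        "none"),
                            factors = c("row", "chip"),
                            inject_batch = TRUE, amplitude = 0.01,
                            spike_sites = 0L, spike_target_p = 10^-(1:20),
                            n_reps = 100L, seed = 1L, alpha = 0.05,
                            on_mvalues = TRUE) {
  design <- match.arg(design)
  variant <- match.arg(variant)
  if (n_reps < 1) abort("n_reps must be at least 1")
  structure(list(
    n_samples = as.integer(n_samples), design = design, variant = variant,
    factors = factors, inject_batch = isTRUE(inject_batch),
    amplitude = amplitude, spike_sites = as.integer(spike_sites),
    spike_target_p = spike_target_p, n_reps = as.integer(n_reps),
    seed = as.integer(seed), alpha = alpha, on_mvalues = isTRUE(on_mvalues)
  ), class = "scenario_config")
}

#' Run one repetition of a scenario
#'
#' The per-repetition pipeline: build the layout, assign groups, generate a
#' null beta matrix, optionally spike true effects, optionally inject batch
#' offsets, optionally correct, test every probe, summarise. Each stage draws
#' its seed from `rep_seed`, so a repetition is fully reproducible from one
#' integer. Confounded-covariate warnings from the correction are captured
#' into the metrics row (`confounded` column), not re-emitted.
#'
#' @param profile Parameter profile tibble.
#' @param config A [scenario_config()].
#' @param rep_seed Integer seed of this repetition.
#' @param rep Repetition index recorded in the output.
#' @return A one-row metrics tibble (see [summarize_metrics()]).
#' @export
run_scenario_once <- function(profile, config, rep_seed, rep = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- derive_seeds(rep_seed, 4L)
  layout <- build_layout(config$n_samples)
  layout <- assign_groups(layout, config$design, seeds[1])
  betas <- generate_null_betas(profile, layout, seeds[2])
  if (config$spike_sites > 0L) {
    betas <- spike_group_effects(betas, layout, profile,
                                 n_sites = config$spike_sites,
                                 target_p = config$spike_target_p,
                                 seed = seeds[3])
  }
  if (config$inject_batch && config$amplitude > 0) {
    betas <- inject_batch_effects(betas, layout, factors = config$factors,
                                  amplitude = config$amplitude,
                                  seed = seeds[4])
  }
  confounded <- FALSE
  if (config$variant != "none") {
    betas <- withCallingHandlers(
      sequential_correct(betas, layout, factors = config$factors,
                         variant = config$variant,
                         on_mvalues = config$on_mvalues),
      warning = function(w) {
        if (grepl("confounded", conditionMessage(w))) {
          confounded <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  dmp <- fit_dmp(betas, layout, alpha = config$alpha)
  summarize_metrics(dmp, alpha = config$alpha, metadata = list(
    rep = rep, n_samples = config$n_samples, design = config$design,
    variant = config$variant, factors = paste(config$factors, collapse = "+"),
    inject_batch = config$inject_batch, confounded = confounded,
    rep_seed = rep_seed
  ))
}

#' Replicate a scenario and aggregate
#'
#' Runs [run_scenario_once()] `config$n_reps` times with independent seed
#' substreams derived from the master seed.
#'
#' @param profile Parameter profile tibble.
#' @param config A [scenario_config()].
#' @return A `result_table`: `tidy()` gives the per-repetition rows,
#'   `glance()` the across-repetition mean and SD of `mean_p`, `lambda`,
#'   `n_fdr`, `n_bf`.
#' @export
replicate_scenario <- function(profile, config) {
  stopifnot(inherits(config, "scenario_config"))
  rep_seeds <- derive_seeds(config$seed, config$n_reps)
  reps <- purrr::map2_dfr(rep_seeds, seq_along(rep_seeds),
                          function(s, i) run_scenario_once(profile, config, s, i))
  new_result_table(reps)
}

new_result_table <- function(reps) {
  structure(list(reps = reps), class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table> ", nrow(x$reps), " repetition(s)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.result_table <- function(x, ...) x$reps

#' @export
glance.result_table <- function(x, ...) {
  group_cols <- intersect(c("k_levels", "n_factors", "n_samples", "platform",
                            "design", "variant"), names(x$reps))
  x$reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      dplyr::across(dplyr::all_of(c("mean_p", "lambda", "n_fdr", "n_bf")),
                    list(mean = mean, sd = ~ if (length(.x) > 1) stats::sd(.x) else NA_real_)),
      .groups = "drop"
    )
}

# Null-sanity guardrail run before every sweep: an uncorrected, uninjected
# repetition must sit at the calibration point. Violations warn (they signal
# a broken pipeline, the very thing the package is built to detect); the row
# is attached to the sweep result as attr "guardrail".
null_guardrail <- function(profile, n_samples, seed) {
  cfg <- scenario_config(n_samples = n_samples, design = "random",
                         variant = "none", inject_batch = FALSE,
                         n_reps = 1L, seed = seed)
  row <- run_scenario_once(profile, cfg, rep_seed = seed)
  if (nrow(profile) >= 2e4 &&
      (row$mean_p < 0.48 || row$mean_p > 0.52 ||
       row$lambda < 0.9 || row$lambda > 1.1)) {
    warn(sprintf(paste("null guardrail violated: mean p = %.3f, lambda = %.3f",
                       "on signal-free data"), row$mean_p, row$lambda))
  }
  row
}

sweep_cell <- function(profile, config, rep_seeds, extra) {
  purrr::map2_dfr(rep_seeds, seq_along(rep_seeds), function(s, i) {
    row <- run_scenario_once(profile, config, s, i)
    dplyr::bind_cols(tibble::as_tibble(extra), row)
  })
}

#' Sweep the number of levels of one corrected batch factor
#'
#' n = 96 samples (one plate) with random groups; for each k in
#' `levels_range` a synthetic k-level batch factor with near-equal random
#' level sizes is added to the layout and corrected. No offsets are injected:
#' the factor is pure noise, so every significant probe is induced by the
#' correction itself.
#'
#' @param profile Parameter profile tibble.
#' @param n_samples Sample count (default 96).
#' @param levels_range Integer vector of level counts (default 2:12).
#' @param variant Correction variant (default `"with_outcome_model"`).
#' @param n_reps Repetitions per level count.
#' @param seed Master seed.
#' @return A `result_table` whose rows carry `k_levels`; `glance()`
#'   aggregates per k. The attribute `first_fdr_k` records the smallest k
#'   whose mean FDR count reaches 1. Like every sweep, the run starts with a
#'   null-sanity guardrail repetition (no injection, no correction) whose
#'   metrics are attached as attribute `guardrail` and which warns if the
#'   uncorrected pipeline is off calibration (mean p outside
#'   \[0.48, 0.52\] or lambda outside \[0.9, 1.1\] at 20,000+ probes).
#' @export
sweep_factor_levels <- function(profile, n_samples = 96L, levels_range = 2:12,
                                variant = "with_outcome_model", n_reps = 5L,
                                seed = 1L) {
  all_seeds <- derive_seeds(seed, length(levels_range) + 1L)
  guard <- null_guardrail(profile, n_samples, all_seeds[1])
  cell_seeds <- all_seeds[-1]
  reps <- purrr::map2_dfr(levels_range, cell_seeds, function(k, cs) {
    seeds <- derive_seeds(cs, n_reps + 1L)
    purrr::map_dfr(seq_len(n_reps), function(i) {
      stage <- derive_seeds(seeds[i], 3L)
      layout <- build_layout(n_samples)
      layout <- assign_groups(layout, "random", stage[1])
      layout$sweep <- make_sweep_factor(n_samples, k, stage[2])
      betas <- generate_null_betas(profile, layout, stage[3])
      if (k >= 2L) {
        betas <- sequential_correct(betas, layout, factors = "sweep",
                                    variant = variant)
      }
      dmp <- fit_dmp(betas, layout)
      summarize_metrics(dmp, metadata = list(
        k_levels = k, rep = i, n_samples = n_samples, design = "random",
        variant = variant, rep_seed = seeds[i]
      ))
    })
  })
  out <- new_result_table(reps)
  agg <- glance(out)
  hit <- agg$k_levels[agg$n_fdr_mean >= 1]
  attr(out, "first_fdr_k") <- if (length(hit) > 0) min(hit) else NA_integer_
  attr(out, "guardrail") <- guard
  out
}

#' Sweep the number of corrected two-level batch factors
#'
#' Adds independent random two-level factors one at a time and corrects
#' sequentially over all of them.
#'
#' @inheritParams sweep_factor_levels
#' @param max_factors Largest number of simultaneous factors.
#' @return A `result_table` with a `n_factors` column.
#' @export
sweep_factor_count <- function(profile, n_samples = 96L, max_factors = 8L,
                               variant = "with_outcome_model", n_reps = 5L,
                               seed = 1L) {
  counts <- seq_len(max_factors)
  all_seeds <- derive_seeds(seed, max_factors + 1L)
  guard <- null_guardrail(profile, n_samples, all_seeds[1])
  cell_seeds <- all_seeds[-1]
  reps <- purrr::map2_dfr(counts, cell_seeds, function(k, cs) {
    seeds <- derive_seeds(cs, n_reps)
    purrr::map_dfr(seq_len(n_reps), function(i) {
      stage <- derive_seeds(seeds[i], 2L + k)
      layout <- build_layout(n_samples)
      layout <- assign_groups(layout, "random", stage[1])
      fnames <- sprintf("f%d", seq_len(k))
      for (j in seq_len(k)) {
        layout[[fnames[j]]] <- make_sweep_factor(n_samples, 2L, stage[2L + j])
      }
      betas <- generate_null_betas(profile, layout, stage[2])
      betas <- sequential_correct(betas, layout, factors = fnames,
                                  variant = variant)
      dmp <- fit_dmp(betas, layout)
      summarize_metrics(dmp, metadata = list(
        n_factors = k, rep = i, n_samples = n_samples, design = "random",
        variant = variant, rep_seed = seeds[i]
      ))
    })
  })
  out <- new_result_table(reps)
  attr(out, "guardrail") <- guard
  out
}

#' Sweep the sample size under row + chip correction
#'
#' For each size the layout grows by whole chips (8 rows + n/8 chips as batch
#' factors), offsets are injected, and the requested designs are corrected
#' with the given variant.
#'
#' @inheritParams sweep_factor_levels
#' @param sizes Sample sizes (default `seq(48, 768, by = 48)`).
#' @param designs Designs to run at every size.
#' @param amplitude Injected offset amplitude.
#' @return A `result_table` with `n_samples` and `design` columns.
#' @export
sweep_sample_size <- function(profile, sizes = seq(48L, 768L, by = 48L),
                              designs = c("balanced", "random", "unbalanced"),
                              variant = "with_outcome_model",
                              amplitude = 0.01, n_reps = 3L, seed = 1L) {
  grid <- tidyr::expand_grid(n = sizes, design = designs)
  all_seeds <- derive_seeds(seed, nrow(grid) + 1L)
  guard <- null_guardrail(profile, min(sizes), all_seeds[1])
  cell_seeds <- all_seeds[-1]
  reps <- purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    cfg <- scenario_config(
      n_samples = grid$n[r], design = grid$design[r], variant = variant,
      factors = c("row", "chip"), inject_batch = TRUE, amplitude = amplitude,
      n_reps = n_reps, seed = cell_seeds[r]
    )
    tidy(replicate_scenario(profile, cfg))
  })
  out <- new_result_table(reps)
  attr(out, "guardrail") <- guard
  out
}

#' Compare platforms at fixed layout
#'
#' Subsamples the source profile to each requested platform size and reruns
#' the identical scenario (same layout seeds) so only the probe count varies.
#'
#' @inheritParams sweep_factor_levels
#' @param platforms Platform labels to run.
#' @param sizes Named probe counts per platform; defaults to scaled-down
#'   stand-ins proportional to the real 27K/450K/EPIC ratio when the source
#'   profile is smaller than the real arrays.
#' @param config Base [scenario_config()] shared by all platforms.
#' @return A `result_table` with a `platform` column.
#' @export
sweep_platform <- function(profile, platforms = c("K27", "K450", "EPIC"),
                           sizes = NULL, config = scenario_config(n_samples = 96L),
                           seed = 1L) {
  if (is.null(sizes)) {
    m <- as.numeric(nrow(profile))
    sizes <- round(m * platform_sizes / platform_sizes[["EPIC"]])
  }
  all_seeds <- derive_seeds(config$seed, config$n_reps + 1L)
  guard <- null_guardrail(profile, config$n_samples, all_seeds[1])
  rep_seeds <- all_seeds[-1]
  reps <- purrr::map_dfr(platforms, function(pf) {
    prof <- if (sizes[[pf]] < nrow(profile)) {
      subsample_platform(profile, pf, seed = seed, n_probes = sizes[[pf]])
    } else profile
    purrr::map2_dfr(rep_seeds, seq_along(rep_seeds), function(s, i) {
      row <- run_scenario_once(prof, config, s, i)
      dplyr::bind_cols(tibble::tibble(platform = pf), row)
    })
  })
  out <- new_result_table(reps)
  attr(out, "guardrail") <- guard
  out
}

#' Detection of spiked effects under each correction variant
#'
#' Spikes calibrated true group differences, injects batch offsets, corrects
#' with each variant (including `"none"`), and reports per target p-value the
#' fraction of spiked probes recovered at q < alpha.
#'
#' @inheritParams sweep_factor_levels
#' @param design Sample distribution (default `"unbalanced"`, the stress
#'   case).
#' @param variants Correction variants to compare.
#' @param n_sites,target_p Spike specification (defaults 2000 sites across
#'   `10^-(1:20)`).
#' @param alpha FDR level for "detected".
#' @return A tibble `variant, target_p, n_sites, detected, frac_detected`
#'   aggregated over repetitions.
#' @export
spike_detection_curve <- function(profile, n_samples = 48L,
                                  design = "unbalanced",
                                  variants = c("none", "no_model",
                                               "with_outcome_model"),
                                  n_sites = 2000L, target_p = 10^-(1:20),
                                  n_reps = 3L, seed = 1L, alpha = 0.05) {
  rep_seeds <- derive_seeds(seed, n_reps)
  purrr::map_dfr(variants, function(v) {
    cfg <- scenario_config(
      n_samples = n_samples, design = design, variant = v,
      inject_batch = TRUE, spike_sites = n_sites,
      spike_target_p = target_p, n_reps = n_reps, seed = seed
    )
    purrr::map_dfr(rep_seeds, function(s) {
      seeds <- derive_seeds(s, 4L)
      layout <- assign_groups(build_layout(n_samples), design, seeds[1])
      betas <- generate_null_betas(profile, layout, seeds[2])
      betas <- spike_group_effects(betas, layout, profile, n_sites = n_sites,
                                   target_p = target_p, seed = seeds[3])
      betas <- inject_batch_effects(betas, layout, factors = cfg$factors,
                                    amplitude = cfg$amplitude, seed = seeds[4])
      if (v != "none") {
        betas <- suppressWarnings(
          sequential_correct(betas, layout, factors = cfg$factors, variant = v))
      }
      dmp <- fit_dmp(betas, layout)
      tibble::tibble(
        variant = v,
        target_p = dmp$spike_target_p[dmp$truth_mask],
        hit = dmp$table$q_bh[dmp$truth_mask] < alpha
      )
    }) |>
      dplyr::group_by(.data$variant, .data$target_p) |>
      dplyr::summarise(n_sites = dplyr::n(), detected = sum(.data$hit),
                       frac_detected = mean(.data$hit), .groups = "drop")
  })
}

#' Export result tables with a reproducibility manifest
#'
#' Writes each table to `<name>.csv`, all per-repetition rows to a JSON-lines
#' file, and a manifest (package version, seeds, timestamps) to
#' `manifest.json`.
#'
#' @param tables Named list of `result_table` objects or tibbles.
#' @param out_dir Output directory, created if needed.
#' @param seeds Optional named list/vector of seeds to record.
#' @return Character vector of the files written, invisibly.
#' @export
export_results <- function(tables, out_dir, seeds = NULL) {
  if (length(tables) == 0) abort("no tables to export")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("tables must be a named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  all_rows <- list()
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    rows <- if (inherits(tbl, "result_table")) tidy(tbl) else tibble::as_tibble(tbl)
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(rows, path, progress = FALSE)
    files <- c(files, path)
    all_rows[[nm]] <- dplyr::mutate(rows, table = nm, .before = 1)
  }
  jsonl <- file.path(out_dir, "reps.jsonl")
  con <- file(jsonl, open = "wt")
  on.exit(close(con), add = TRUE)
  for (rows in all_rows) {
    for (i in seq_len(nrow(rows))) {
      writeLines(jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  manifest <- list(
    package = "methbatchsim",
    version = as.character(utils::packageVersion("methbatchsim")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    tables = names(tables),
    seeds = seeds
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, jsonl, manifest_path))
}
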