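test_that("the scenario pipeline is deterministic and seed-separated", {
  prof <- tiny_profile(2000, seed = 71)
  cfg <- scenario_config(n_samples = 48, design = "random",
                         variant = "no_model", inject_batch = TRUE,
                         n_reps = 2, seed = 5)
  r1 <- tidy(replicate_scenario(prof, cfg))
  r2 <- tidy(replicate_scenario(prof, cfg))
  expect_identical(r1, r2)
  cfg2 <- scenario_config(n_samples = 48, design = "random",
                          variant = "no_model", inject_batch = TRUE,
                          n_reps = 2, seed = 6)
  expect_false(identical(tidy(replicate_scenario(prof, cfg2)), r1))
})

test_that("a zero-amplitude injection equals the pure-null pipeline", {
  prof <- tiny_profile(1500, seed = 72)
  base <- scenario_config(n_samples = 48, design = "random", variant = "none",
                          inject_batch = FALSE, n_reps = 1, seed = 9)
  zero <- scenario_config(n_samples = 48, design = "random", variant = "none",
                          inject_batch = TRUE, amplitude = 0, n_reps = 1,
                          seed = 9)
  row_base <- run_scenario_once(prof, base, rep_seed = 123)
  row_zero <- run_scenario_once(prof, zero, rep_seed = 123)
  expect_equal(row_zero$mean_p, row_base$mean_p, tolerance = 1e-12)
  expect_equal(row_zero$lambda, row_base$lambda, tolerance = 1e-12)
})

test_that("uncorrected null runs sit at the expected calibration point", {
  prof <- tiny_profile(5000, seed = 73)
  cfg <- scenario_config(n_samples = 48, design = "random", variant = "none",
                         inject_batch = FALSE, n_reps = 3, seed = 21)
  agg <- glance(replicate_scenario(prof, cfg))
  expect_equal(agg$mean_p_mean, 0.5, tolerance = 0.02)
  expect_equal(agg$lambda_mean, 1, tolerance = 0.1)
  expect_equal(agg$n_reps, 3L)
})

test_that("single-repetition aggregates equal the repetition itself", {
  prof <- tiny_profile(1000, seed = 74)
  cfg <- scenario_config(n_samples = 48, design = "balanced",
                         variant = "no_model", inject_batch = TRUE,
                         n_reps = 1, seed = 31)
  res <- replicate_scenario(prof, cfg)
  expect_equal(glance(res)$mean_p_mean, tidy(res)$mean_p)
  expect_equal(glance(res)$n_fdr_mean, as.numeric(tidy(res)$n_fdr))
})

test_that("uncorrected confounded batch effects produce false positives", {
  prof <- tiny_profile(8000, seed = 75)
  cfg <- scenario_config(n_samples = 48, design = "unbalanced",
                         variant = "none", inject_batch = TRUE,
                         amplitude = 0.03, n_reps = 6, seed = 41)
  agg <- glance(replicate_scenario(prof, cfg))
  # chip offsets align with the group split, so inflation shows up untreated
  # (the offset amplitude is raised above the study default to make the
  # signal unambiguous against the random draw of per-chip offsets)
  expect_gt(agg$lambda_mean, 1.2)
})

test_that("factor-count sweeps assemble sequential corrections", {
  prof <- tiny_profile(2000, seed = 76)
  res <- sweep_factor_count(prof, n_samples = 48, max_factors = 3,
                            n_reps = 2, seed = 51)
  agg <- glance(res)
  expect_equal(agg$n_factors, 1:3)
  # every sweep opens with a null-sanity guardrail repetition
  guard <- attr(res, "guardrail")
  expect_equal(guard$variant, "none")
  expect_true(guard$mean_p > 0.4 && guard$mean_p < 0.6)
  expect_equal(unique(tidy(res)$n_probes), 2000L)
  # more corrected noise factors, more p-value depression
  expect_lt(agg$mean_p_mean[3], agg$mean_p_mean[1])
})

test_that("platform sweeps vary only the probe count", {
  prof <- tiny_profile(4000, seed = 77)
  cfg <- scenario_config(n_samples = 48, design = "unbalanced",
                         variant = "with_outcome_model", inject_batch = FALSE,
                         n_reps = 2, seed = 61)
  res <- sweep_platform(prof, platforms = c("K27", "EPIC"), config = cfg,
                        seed = 62)
  agg <- glance(res)
  expect_setequal(agg$platform, c("K27", "EPIC"))
  n27 <- unique(tidy(res)$n_probes[tidy(res)$platform == "K27"])
  expect_equal(n27, round(4000 * 27000 / 758289))
  # lambda is probe-count-free; the two platforms agree within sampling noise
  l <- setNames(agg$lambda_mean, agg$platform)
  expect_gt(l[["K27"]] / l[["EPIC"]], 0.5)
  expect_lt(l[["K27"]] / l[["EPIC"]], 2)
  # absolute counts scale with array size
  expect_lte(agg$n_fdr_mean[agg$platform == "K27"],
             agg$n_fdr_mean[agg$platform == "EPIC"])
})

test_that("spike detection separates strong from null-adjacent effects", {
  prof <- tiny_profile(3000, seed = 78)
  curve <- spike_detection_curve(prof, n_samples = 48, design = "random",
                                 variants = c("none", "with_outcome_model"),
                                 n_sites = 300,
                                 target_p = c(1e-1, 1e-8, 1e-20),
                                 n_reps = 1, seed = 71)
  expect_equal(nrow(curve), 6L)
  strong <- curve[curve$target_p == 1e-20, ]
  weak <- curve[curve$target_p == 1e-1, ]
  expect_true(all(strong$frac_detected > 0.8))
  # null-adjacent effects stay mostly undetected without correction; under
  # the outcome-model correction the induced inflation lifts them, so only
  # the ordering is asserted there
  expect_lt(weak$frac_detected[weak$variant == "none"], 0.2)
  expect_true(all(weak$frac_detected < strong$frac_detected))
})

test_that("exports round-trip and the manifest records seeds", {
  prof <- tiny_profile(800, seed = 79)
  cfg <- scenario_config(n_samples = 48, design = "random", variant = "none",
                         inject_batch = FALSE, n_reps = 2, seed = 81)
  res <- replicate_scenario(prof, cfg)
  out_dir <- withr::local_tempdir()
  files <- export_results(list(null_run = res), out_dir, seeds = list(master = 81))
  back <- readr::read_csv(file.path(out_dir, "null_run.csv"),
                          show_col_types = FALSE)
  expect_equal(back$mean_p, tidy(res)$mean_p, tolerance = 1e-12)
  expect_equal(nrow(back), 2L)
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$seeds$master, 81L)
  expect_equal(manifest$tables[[1]], "null_run")
  jsonl <- readLines(file.path(out_dir, "reps.jsonl"))
  expect_equal(length(jsonl), 2L)
  expect_error(export_results(list(res), out_dir), "named")
})

test_that("plot builders return ggplot objects", {
  withr::local_seed(91)
  p <- runif(500)
  expect_s3_class(plot_qq(p), "ggplot")
  x <- matrix(rnorm(100 * 6, 0.5, 0.05), 100, 6)
  g <- factor(rep(c("control", "case"), each = 3), levels = c("control", "case"))
  expect_s3_class(autoplot(fit_dmp(x, g)), "ggplot")
  agg <- tibble::tibble(n_samples = c(48, 96), design = "random",
                        n_fdr_mean = c(10, 5))
  expect_s3_class(plot_metric_trend(agg, "n_samples", "n_fdr"), "ggplot")
  grid <- tidyr::expand_grid(n_factors = 1:2, n_samples = c(48, 96))
  grid$n_fdr_mean <- 1:4
  expect_s3_class(plot_fdr_heatmap(grid), "ggplot")
  curve <- tibble::tibble(variant = "none", target_p = c(1e-1, 1e-5),
                          frac_detected = c(0, 0.5))
  expect_s3_class(plot_detection_curve(curve), "ggplot")
})
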