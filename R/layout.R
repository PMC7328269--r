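#' Build the physical sample layout of a BeadChip run
#'
#' Samples are placed sequentially on the measurement hardware: 8 row
#' positions per chip, 12 chips per sample plate (96 samples). Chip 1 fills
#' rows 1..8, then chip 2, and so on; a partial last chip is allowed. The
#' resulting `row`, `chip` and `plate` columns are the batch factors of every
#' downstream simulation.
#'
#' @param n_samples Number of samples to place.
#' @param chip_size Rows per chip (default 8).
#' @param chips_per_plate Chips per sample plate (default 12).
#' @return A tibble with columns `sample_id`, `plate`, `chip` (global index),
#'   `row` (position within chip), one row per sample.
#' @export
build_layout <- function(n_samples, chip_size = 8L, chips_per_plate = 12L) {
  if (length(n_samples) != 1 || is.na(n_samples) || n_samples < 1) {
    abort("n_samples must be a positive integer")
  }
  n_samples <- as.integer(n_samples)
  i <- seq_len(n_samples) - 1L
  chip <- i %/% chip_size + 1L
  tibble::tibble(
    sample_id = sprintf("S%04d", i + 1L),
    plate = (chip - 1L) %/% chips_per_plate + 1L,
    chip = chip,
    row = i %% chip_size + 1L
  )
}

#' Assign case/control groups to a layout
#'
#' Encodes the three canonical sample distributions:
#' * `unbalanced` — cases fill the first chips contiguously and the two
#'   samples adjacent to the group boundary exchange groups, leaving exactly
#'   one control among the case chips and one case among the control chips.
#'   This is the most extreme design for which chip and group remain jointly
#'   estimable: under *perfect* confounding a batch correction with an
#'   outcome model is singular and cannot run at all, so the near-confounded
#'   encoding is what "unbalanced" has to mean for any study that reports a
#'   completed outcome-model correction;
#' * `balanced` — every chip holds equal cases and controls, alternating by
#'   row position with the phase flipped on alternate chips, so each row index
#'   is occupied equally often by each group across chips (the fully crossed
#'   design);
#' * `random` — a uniformly random permutation of n/2 case and n/2 control
#'   labels (the usual practice).
#'
#' @param layout A layout tibble from [build_layout()].
#' @param design `"balanced"`, `"unbalanced"` or `"random"`.
#' @param seed Integer seed (used by the `random` design; accepted and ignored
#'   by the deterministic designs so callers can treat all three uniformly).
#' @return The layout with a `group` factor column (`levels control, case`).
#' @export
assign_groups <- function(layout, design = c("balanced", "unbalanced", "random"),
                          seed = NULL) {
  design <- match.arg(design)
  n <- nrow(layout)
  if (design %in% c("balanced", "unbalanced") && n %% 2L != 0L) {
    abort(paste0(design, " design requires an even number of samples"))
  }
  group <- switch(design,
    unbalanced = {
      g <- rep(c("case", "control"), each = n %/% 2L)
      if (n >= 4L) g[c(n %/% 2L, n %/% 2L + 1L)] <- c("control", "case")
      g
    },
    balanced = {
      # odd chips: odd rows case; even chips: odd rows control
      phase <- (layout$chip + layout$row) %% 2L
      ifelse(phase == 0L, "case", "control")
    },
    random = {
      if (is.null(seed)) abort("random design requires a seed")
      labels <- rep(c("case", "control"), length.out = 2L * (n %/% 2L))
      labels <- c(labels, rep("control", n - length(labels)))
      withr::with_seed(as.integer(seed), sample(labels))
    }
  )
  layout$group <- factor(group, levels = c("control", "case"))
  layout
}

#' Extract the batch factor table of a layout
#'
#' @param layout A layout tibble.
#' @return A tibble `sample_id, row, chip, plate` with each factor encoded as
#'   a categorical with only its occupied levels.
#' @export
batch_factor_table <- function(layout) {
  tibble::tibble(
    sample_id = layout$sample_id,
    row = factor(layout$row),
    chip = factor(layout$chip),
    plate = factor(layout$plate)
  )
}

#' Generate a random batch factor with (near-)equal level sizes
#'
#' Used by the factor-level and factor-count sweeps: `n_levels` levels are
#' assigned at random with sizes as equal as possible (difference at most 1).
#'
#' @param n_samples Number of samples.
#' @param n_levels Number of levels (2 or more, at most `n_samples`).
#' @param seed Integer seed.
#' @return A factor of length `n_samples`.
#' @export
make_sweep_factor <- function(n_samples, n_levels, seed) {
  n_samples <- as.integer(n_samples)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) abort("n_levels must be at least 1")
  if (n_levels > n_samples) abort("n_levels cannot exceed n_samples")
  base <- rep(seq_len(n_levels), length.out = n_samples)
  perm <- withr::with_seed(as.integer(seed), sample.int(n_samples))
  factor(base[order(perm)], levels = seq_len(n_levels))
}

#' Write / read a layout as a plain sample sheet
#'
#' Round-trips the layout through a delimited file with columns
#' `sample_id, plate, chip, row, group`, mirroring Illumina sample-sheet
#' semantics without vendor headers.
#'
#' @param layout A layout tibble (with or without `group`).
#' @param path Output path (`.csv` or `.tsv`).
#' @return `write_sample_sheet()` returns `path` invisibly;
#'   `read_sample_sheet()` returns the layout tibble.
#' @export
write_sample_sheet <- function(layout, path) {
  cols <- intersect(c("sample_id", "plate", "chip", "row", "group"), names(layout))
  out <- layout[, cols]
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path, progress = FALSE)
  else readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    sample_id = as.character(x$sample_id),
    plate = as.integer(x$plate),
    chip = as.integer(x$chip),
    row = as.integer(x$row)
  )
  if ("group" %in% names(x)) {
    out$group <- factor(x$group, levels = c("control", "case"))
  }
  out
}
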