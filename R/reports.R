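# Orchestration: validated run configurations, figure-style experiment
# runs with manifested outputs, and the headline-claims table.

#' Validated run configuration
#'
#' Flat key-value configuration whose defaults mirror the experimental
#' design: 128 primaries, 30-component mixtures, 20 pairs per class, 26
#' odd-man-out trials, 1000 replicate designs, ring noise 0.4 rad, JND
#' 0.01. A reduced-replicate mode (e.g. `n_replicates = 100`) is
#' appropriate for continuous-integration runs, with correspondingly
#' wider stochastic tolerances.
#'
#' @param C,N,n_pairs,n_trials,n_replicates Design sizes.
#' @param overlaps Overlap grid (default `NULL`: model default grid).
#' @param sigma_ring,jnd,sigma_rgb Noise parameters; `sigma_rgb = NULL`
#'   means calibrate from `jnd`.
#' @param seed Root seed for the run.
#' @return A `run_config` object (validated list).
#' @export
run_config <- function(C = 128, N = 30, n_pairs = 20, n_trials = 26,
                       n_replicates = 1000, overlaps = NULL,
                       sigma_ring = 0.4, jnd = 0.01, sigma_rgb = NULL,
                       seed = 1) {
  stopifnot(C >= 1, N >= 1, N <= C, n_pairs >= 1, n_trials >= 1,
            n_replicates >= 1, sigma_ring > 0, jnd > 0,
            is.null(sigma_rgb) || sigma_rgb > 0,
            is.null(overlaps) || all(overlaps >= 0 & overlaps <= N))
  structure(list(C = C, N = N, n_pairs = n_pairs, n_trials = n_trials,
                 n_replicates = n_replicates, overlaps = overlaps,
                 sigma_ring = sigma_ring, jnd = jnd, sigma_rgb = sigma_rgb,
                 seed = seed),
            class = "run_config")
}

.config_noise <- function(config) {
  noise <- noise_config(sigma_ring = config$sigma_ring,
                        sigma_rgb = config$sigma_rgb, jnd = config$jnd)
  .ensure_sigma_rgb(noise)
}

.write_manifest <- function(out_dir, files, config, elapsed) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("odorspace")),
    config = config[setdiff(names(config), NULL)],
    seed = config$seed,
    wall_time_sec = round(elapsed, 2),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run one figure-style experiment
#'
#' Reproduces one of the headline simulation panels and writes its curve
#' CSV, a rendered PDF figure, a summary JSON (critical distance and,
#' for the sum-threshold model, the sphere-packing estimate), and a
#' manifest listing every output file with its checksum. Deterministic
#' given `config$seed`: rerunning yields byte-identical CSV/JSON.
#'
#' * `"fig1"` — sum-threshold (microbe) model, discriminability vs
#'   overlap plus the sphere-count extrapolation from its D;
#' * `"fig2"` — color model, 128-primary pool;
#' * `"fig2c"` — color model, components drawn fresh from all
#'   directions;
#' * `"fig3"` — ring model at `sigma_ring`.
#'
#' @param fig_id One of `"fig1"`, `"fig2"`, `"fig2c"`, `"fig3"`.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param overlay Optional data frame (columns `O`, `fraction`) of
#'   empirical discriminability fractions drawn as symbols on the figure.
#' @return Invisibly, a list with the curve, summary, and file paths.
#' @export
run_figure <- function(fig_id = c("fig1", "fig2", "fig2c", "fig3"),
                       config = run_config(), out_dir,
                       overlay = NULL) {
  fig_id <- match.arg(fig_id)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  model <- switch(fig_id, fig1 = "microbe", fig2 = "color",
                  fig2c = "color", fig3 = "ring")
  noise <- if (model == "color") .config_noise(config) else
    noise_config(sigma_ring = config$sigma_ring, jnd = config$jnd)
  cv <- discrimination_curve(model, N = config$N, overlaps = config$overlaps,
                             C = config$C, n_pairs = config$n_pairs,
                             n_trials = config$n_trials,
                             n_replicates = config$n_replicates,
                             noise = noise,
                             fresh_vectors = fig_id == "fig2c",
                             seed = config$seed)
  cd <- critical_distance(cv)
  summary <- list(fig_id = fig_id, model = model, N = config$N,
                  D = cd$D, D_int = cd$D_int, O_star = cd$O_star)
  if (fig_id == "fig1") {
    sc <- sphere_count(config$C, config$N, cd$D_int)
    summary$sphere_count <- list(
      D = cd$D_int,
      S_interp = sc$S_interp, log10_S = sc$log10_S,
      S_floor = format(sc$S_floor), S_ceil = format(sc$S_ceil))
  }
  csv_path <- file.path(out_dir, paste0(fig_id, "_curve.csv"))
  write_curve_csv(cv, csv_path)
  pdf_path <- file.path(out_dir, paste0(fig_id, ".pdf"))
  grDevices::pdf(pdf_path, width = 5, height = 4)
  plot(cv, overlay = overlay)
  grDevices::dev.off()
  json_path <- file.path(out_dir, paste0(fig_id, "_summary.json"))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  files <- c(csv_path, pdf_path, json_path)
  manifest <- .write_manifest(out_dir, files, unclass(config),
                              proc.time()[["elapsed"]] - t0)
  invisible(list(curve = cv, critical = cd, summary = summary,
                 files = c(files, manifest)))
}

#' Read an overlay CSV of empirical discriminability fractions
#'
#' @param path CSV with columns `O` (overlap) and `fraction`.
#' @return Data frame with columns `O`, `fraction`.
#' @export
read_overlay_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("O", "fraction") %in% names(df)))
  df[, c("O", "fraction")]
}

#' Compute the headline-claims table
#'
#' Recomputes every headline number of the critique in one run and
#' compares it against the published value: the sum-threshold model's
#' critical distance (15) and sphere-count estimate (~9e11), the color
#' model's critical distance (1), the D = 1 sphere count (> 1e27) and the
#' ~60-light subset count (~1e37), the 3-D grid percept count (1e6), the
#' ring capacity at 0.4 rad (10), and the sphere-coloring bounds
#' (2 / 10 / 10,000 percepts at q = 0.5 / 0.9 / 0.9999).
#'
#' @param config A [run_config()]; reduce `n_replicates` for a faster
#'   (wider-tolerance) run.
#' @param models Character vector of encoding models that must be
#'   simulated; must contain `"microbe"` and `"color"`.
#' @return A `headline_table`: data frame with columns `claim`,
#'   `computed`, `expected`, `tolerance`, `pass`.
#' @export
run_headline_table <- function(config = run_config(), models = c("microbe", "color")) {
  stopifnot(inherits(config, "run_config"))
  if (!all(c("microbe", "color") %in% models)) {
    .odorspace_error("models must include both 'microbe' and 'color'",
                     "odorspace_config_error")
  }
  noise <- .config_noise(config)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, 4)

  mic <- discrimination_curve("microbe", N = config$N, C = config$C,
                              n_pairs = config$n_pairs,
                              n_replicates = config$n_replicates,
                              seed = seeds[1])
  mic_D <- critical_distance(mic)$D
  sc15 <- sphere_count(config$C, config$N, round(mic_D))
  col <- discrimination_curve("color", N = config$N, C = config$C,
                              n_pairs = config$n_pairs, n_trials = config$n_trials,
                              n_replicates = config$n_replicates,
                              noise = noise, seed = seeds[2])
  col_D <- critical_distance(col)$D
  sc1 <- sphere_count(config$C, config$N, 1)
  set.seed(seeds[3])
  ringcap <- ring_capacity(config$sigma_ring)

  row <- function(claim, computed, expected, tolerance) {
    data.frame(claim = claim, computed = computed, expected = expected,
               tolerance = tolerance,
               pass = abs(computed - expected) <= tolerance)
  }
  tab <- rbind(
    row("sum-threshold critical distance D", round(mic_D), 15, 1),
    row("sum-threshold sphere count, log10", sc15$log10_S, log10(9e11), log10(1.5)),
    row("color critical distance D", col_D, 1, 0),
    row("D=1 sphere count, log10 (exceeds 27)", sc1$log10_S, 29.19, 0.01),
    row("60-light subset count, log10", log10_subset_count(config$C, 60), 37, 0),
    row("grid percepts at jnd 0.01 in 3-D", grid_percept_count(config$jnd, 3), 1e6, 0),
    row("ring capacity at sigma 0.4", as.integer(ringcap), 10, 0),
    row("coloring bound k(0.5)", min_percepts_for_criterion(0.5), 2, 0),
    row("coloring bound k(0.9)", min_percepts_for_criterion(0.9), 10, 0),
    row("coloring bound k(0.9999)", min_percepts_for_criterion(0.9999), 10000, 0)
  )
  class(tab) <- c("headline_table", class(tab))
  tab
}

#' Write the headline table as JSON
#'
#' @param table A [run_headline_table()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_headline_json <- function(table, path) {
  jsonlite::write_json(as.data.frame(unclass(table)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
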