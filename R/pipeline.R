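# Orchestration of the full study emulation: simulate a cohort, analyze
# every recording (preprocess -> PSD -> band powers -> indices), and report
# per-phase summaries with the statistical battery. Every file the pipeline
# writes is timestamp-free, so two runs from the same seed are
# byte-identical; timestamps appear only in console messages.

#' Assemble a pipeline configuration
#'
#' @param n_per_group Animals per group (default 6).
#' @param phases Phase labels to simulate (default all eleven).
#' @param seed Master seed (default 42).
#' @param output_dir Directory all outputs are written under.
#' @param format Recording file format, `"edf"` or `"csv"`.
#' @param highpass_hz,epoch_s,artifact_uv Preprocessing parameters.
#' @param seg_s,overlap_frac Welch parameters.
#' @param dar_threshold,dtabr_threshold Classification thresholds.
#' @param jitter_sigma Inter-animal fraction jitter for the presets.
#' @param index_unit `"session"` (default: indices per animal session, then
#'   averaged) or `"pooled"` (band powers averaged across animals first, one
#'   index per phase from the mean powers); ratio of means and mean of
#'   ratios differ, so both conventions are exposed.
#' @return A validated `pipeline_config` list.
#' @seealso [read_pipeline_config()] for the YAML equivalent.
#' @export
pipeline_config <- function(n_per_group = 6, phases = phase_labels()$phase,
                            seed = 42, output_dir = tempfile("qeeg_run_"),
                            format = c("edf", "csv"),
                            highpass_hz = 0.3, epoch_s = 30, artifact_uv = 500,
                            seg_s = 2, overlap_frac = 0.5,
                            dar_threshold = 3.7, dtabr_threshold = 3.5,
                            jitter_sigma = 0.1,
                            index_unit = c("session", "pooled")) {
  format <- match.arg(format)
  index_unit <- match.arg(index_unit)
  cfg <- list(
    n_per_group = n_per_group, phases = phases, seed = seed,
    output_dir = output_dir, format = format,
    highpass_hz = highpass_hz, epoch_s = epoch_s, artifact_uv = artifact_uv,
    seg_s = seg_s, overlap_frac = overlap_frac,
    dar_threshold = dar_threshold, dtabr_threshold = dtabr_threshold,
    jitter_sigma = jitter_sigma, index_unit = index_unit
  )
  # validate against module preconditions before any work starts
  design <- study_design(n_per_group, phases = phases, seed = seed)
  stopifnot(highpass_hz > 0, epoch_s > 0, artifact_uv > 0,
            seg_s > 0, overlap_frac >= 0, overlap_frac < 1,
            dar_threshold > 0, dtabr_threshold > 0, jitter_sigma >= 0)
  if (1 / seg_s > 0.5 + 1e-12) {
    stop("seg_s too short: spectral resolution must reach 0.5 Hz", call. = FALSE)
  }
  cfg$design <- design
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of the [pipeline_config()] arguments may appear as top-level
#' keys; missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "...")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Analyze a single recording through the full pipeline
#'
#' High-pass filter, epoch, reject artifact epochs, estimate the Welch PSD,
#' decompose into band powers, and compute the classified qEEG indices.
#'
#' @param rec A [recording()].
#' @param highpass_hz,epoch_s,artifact_uv,seg_s,overlap_frac,dar_threshold,dtabr_threshold
#'   Pipeline parameters; see [pipeline_config()].
#' @return A one-row tibble: metadata, relative power per band (wide,
#'   `rel_delta` ... `rel_residual`), `reference_power`, `dtr`, `dar`,
#'   `dtabr`, and the two classification flags.
#' @examples
#' rec <- generate_recording(phase_presets()$ISP, duration_s = 60, seed = 1)
#' analyze_recording(rec)
#' @export
analyze_recording <- function(rec, highpass_hz = 0.3, epoch_s = 30,
                              artifact_uv = 500, seg_s = 2, overlap_frac = 0.5,
                              dar_threshold = 3.7, dtabr_threshold = 3.5) {
  es <- rec |>
    highpass_filter(cutoff_hz = highpass_hz) |>
    epoch_recording(epoch_s = epoch_s) |>
    reject_artifacts(amp_threshold_uv = artifact_uv)
  ps <- compute_psd(es, seg_s = seg_s, overlap_frac = overlap_frac)
  bp <- relative_bandpower(ps)
  qi <- classify_ischemia(compute_indices(bp), dar_threshold, dtabr_threshold)
  wide <- stats::setNames(as.list(bp$rel_power), paste0("rel_", bp$band))
  dplyr::bind_cols(
    tibble::tibble(animal = rec$animal_id, group = rec$group, phase = rec$phase),
    tibble::as_tibble(wide),
    tibble::tibble(reference_power = attr(bp, "reference_power")),
    qi
  )
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one recording file per animal per phase plus a manifest CSV
#' (`animal,group,phase,file,seed`) under `output_dir/recordings`.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest tibble, invisibly; the manifest path is attached as
#'   attribute `path`.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  rec_dir <- file.path(cfg$output_dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("simulate: seed %d, %d/group, %d phases, preset table v%s",
          cfg$seed, cfg$n_per_group, length(cfg$phases),
          attr(phase_presets(), "version"))
  cohort <- generate_cohort(cfg$design, phase_presets(cfg$jitter_sigma))
  ext <- if (cfg$format == "edf") ".edf" else ".csv"
  manifest <- cohort |>
    dplyr::mutate(file = file.path("recordings",
                                   paste0(.data$animal, "_", .data$phase, ext)))
  purrr::walk2(manifest$recording, manifest$file, function(rec, f) {
    write_recording(rec, file.path(cfg$output_dir, f), cfg$format)
  })
  manifest <- dplyr::select(manifest, "animal", "group", "phase", "file", "seed")
  mpath <- file.path(cfg$output_dir, "manifest.csv")
  readr::write_csv(manifest, mpath, progress = FALSE)
  log_msg("simulate: wrote %d recordings + manifest", nrow(manifest))
  invisible(structure(manifest, path = mpath))
}

#' Analyze a simulated cohort
#'
#' Runs [analyze_recording()] on every manifest entry and writes the
#' band-power, index and per-phase mean frequency-distribution tables.
#' Unreadable recordings are reported and skipped; the run continues.
#'
#' @param cfg A [pipeline_config()].
#' @param manifest Manifest tibble or path to `manifest.csv`; defaults to
#'   the one under `cfg$output_dir`.
#' @return A list of tibbles: `indices`, `band_powers`, `freq_dist`
#'   (invisibly); CSVs are written under `output_dir/tables`.
#' @export
run_analyze <- function(cfg, manifest = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(manifest)) manifest <- file.path(cfg$output_dir, "manifest.csv")
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, col_types = readr::cols(), progress = FALSE)
  }
  if (nrow(manifest) == 0) stop("empty manifest: nothing to analyze", call. = FALSE)
  tab_dir <- file.path(cfg$output_dir, "tables")
  dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)

  failures <- character()
  one <- function(animal, group, phase, file, seed) {
    tryCatch({
      rec <- read_recording(file.path(cfg$output_dir, file),
                            animal_id = animal, group = group, phase = phase)
      es <- rec |>
        highpass_filter(cutoff_hz = cfg$highpass_hz) |>
        epoch_recording(epoch_s = cfg$epoch_s) |>
        reject_artifacts(amp_threshold_uv = cfg$artifact_uv)
      ps <- compute_psd(es, seg_s = cfg$seg_s, overlap_frac = cfg$overlap_frac)
      bp <- relative_bandpower(ps)
      qi <- classify_ischemia(compute_indices(bp),
                              cfg$dar_threshold, cfg$dtabr_threshold)
      list(
        bands = dplyr::bind_cols(
          tibble::tibble(animal = animal, group = group, phase = phase),
          bp[, c("band", "abs_power", "rel_power")]),
        idx = dplyr::bind_cols(
          tibble::tibble(animal = animal, group = group, phase = phase), qi),
        fd = dplyr::bind_cols(
          tibble::tibble(animal = animal, group = group, phase = phase),
          frequency_distribution(ps, 40))
      )
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s/%s: %s", animal, phase, conditionMessage(e)))
      NULL
    })
  }
  res <- purrr::pmap(manifest[c("animal", "group", "phase", "file", "seed")], one)
  res <- purrr::compact(res)
  if (length(res) == 0) stop("no recording could be analyzed", call. = FALSE)
  if (length(failures) > 0) {
    log_msg("analyze: %d recording(s) failed:\n  %s",
            length(failures), paste(failures, collapse = "\n  "))
  }
  band_powers <- purrr::map_dfr(res, "bands")
  indices <- purrr::map_dfr(res, "idx")
  freq_dist <- purrr::map_dfr(res, "fd") |>
    dplyr::group_by(.data$group, .data$phase, .data$freq_hz) |>
    dplyr::summarise(psd = mean(.data$psd), .groups = "drop")
  readr::write_csv(band_powers, file.path(tab_dir, "band_powers.csv"), progress = FALSE)
  readr::write_csv(indices, file.path(tab_dir, "indices.csv"), progress = FALSE)
  readr::write_csv(freq_dist, file.path(tab_dir, "frequency_distribution.csv"),
                   progress = FALSE)
  log_msg("analyze: %d recordings -> tables/", length(res))
  invisible(list(indices = indices, band_powers = band_powers,
                 freq_dist = freq_dist))
}

#' Summarize an analyzed cohort
#'
#' Produces the acute-phase index summary (per-phase mean +/- SD of DTR,
#' DAR, DTABR over the occluded group, with Tukey letters across phases),
#' subacute per-day relative band-power summaries, and the ANOVA/Tukey
#' report for each family. Threshold crossings are reported as flags without
#' interpretation.
#'
#' @param cfg A [pipeline_config()].
#' @param analysis The list returned by [run_analyze()]; defaults to
#'   re-reading the tables under `cfg$output_dir`.
#' @return A list of tibbles (`acute_indices`, `subacute_bands`, `anova`),
#'   invisibly; CSVs and a plain-text stats report are written under
#'   `output_dir/report`.
#' @export
run_report <- function(cfg, analysis = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(analysis)) {
    tab_dir <- file.path(cfg$output_dir, "tables")
    analysis <- list(
      indices = readr::read_csv(file.path(tab_dir, "indices.csv"),
                                col_types = readr::cols(), progress = FALSE),
      band_powers = readr::read_csv(file.path(tab_dir, "band_powers.csv"),
                                    col_types = readr::cols(), progress = FALSE)
    )
  }
  rep_dir <- file.path(cfg$output_dir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  idx <- analysis$indices
  if (min(table(idx$group)) < 2) stop("fewer than 2 animals per group", call. = FALSE)

  acute_phases <- intersect(c("anesthetized", "ISP", "IRP"), unique(idx$phase))
  acute <- idx |> dplyr::filter(.data$group == "mcao", .data$phase %in% acute_phases)
  anova_rows <- list()
  acute_summary <- NULL
  if (nrow(acute) > 0 && length(acute_phases) >= 2) {
    acute_long <- tidyr::pivot_longer(acute, c("dtr", "dar", "dtabr"),
                                      names_to = "index", values_to = "value")
    if (cfg$index_unit == "pooled") {
      # indices recomputed from phase-mean band powers, summary without SD
      pooled <- analysis$band_powers |>
        dplyr::filter(.data$group == "mcao", .data$phase %in% acute_phases) |>
        dplyr::group_by(.data$phase, .data$band) |>
        dplyr::summarise(rel_power = mean(.data$rel_power), .groups = "drop")
      acute_summary <- pooled |>
        dplyr::group_by(.data$phase) |>
        dplyr::group_modify(~ compute_indices(.x)) |>
        dplyr::ungroup() |>
        tidyr::pivot_longer(c("dtr", "dar", "dtabr"),
                            names_to = "index", values_to = "mean")
    } else {
      acute_summary <- acute_long |>
        dplyr::group_by(.data$index) |>
        dplyr::group_modify(function(d, key) {
          s <- summarize_groups(d, value, phase)
          dplyr::rename(s, phase = "group")
        }) |>
        dplyr::ungroup()
    }
    for (ix in c("dtr", "dar", "dtabr")) {
      d <- dplyr::filter(acute_long, .data$index == ix)
      gl <- glance(one_way_anova(d, value, phase))
      anova_rows[[paste0("acute_", ix)]] <-
        dplyr::bind_cols(tibble::tibble(family = "acute", effect = ix), gl)
    }
  }

  # subacute: relative band power per day, mcao days vs sham control
  days <- intersect(paste0("D", 1:7), unique(idx$phase))
  subacute_summary <- NULL
  if (length(days) >= 2) {
    bp <- analysis$band_powers
    sub <- dplyr::filter(bp, .data$band != "residual")
    mcao_days <- sub |>
      dplyr::filter(.data$group == "mcao", .data$phase %in% days) |>
      dplyr::select(day = "phase", "animal", "band", "rel_power")
    control <- sub |>
      dplyr::filter(.data$group == "sham", .data$phase %in% days) |>
      dplyr::group_by(.data$animal, .data$band) |>
      dplyr::summarise(rel_power = mean(.data$rel_power), .groups = "drop") |>
      dplyr::mutate(day = "control")
    sub_long <- dplyr::bind_rows(mcao_days, control)
    subacute_summary <- sub_long |>
      dplyr::group_by(.data$band) |>
      dplyr::group_modify(function(d, key) {
        s <- summarize_groups(d, rel_power, day)
        dplyr::rename(s, day = "group")
      }) |>
      dplyr::ungroup()
    for (b in unique(sub_long$band)) {
      d <- dplyr::filter(sub_long, .data$band == b)
      gl <- glance(one_way_anova(d, rel_power, day))
      anova_rows[[paste0("subacute_", b)]] <-
        dplyr::bind_cols(tibble::tibble(family = "subacute", effect = b), gl)
    }
  }

  anova_tab <- dplyr::bind_rows(anova_rows)
  if (!is.null(acute_summary)) {
    readr::write_csv(acute_summary, file.path(rep_dir, "acute_indices.csv"),
                     progress = FALSE)
  }
  if (!is.null(subacute_summary)) {
    readr::write_csv(subacute_summary, file.path(rep_dir, "subacute_bands.csv"),
                     progress = FALSE)
  }
  if (nrow(anova_tab) > 0) {
    readr::write_csv(anova_tab, file.path(rep_dir, "anova.csv"), progress = FALSE)
  }
  flag_share <- idx |>
    dplyr::group_by(.data$group, .data$phase) |>
    dplyr::summarise(dar_ischemic = mean(.data$dar_ischemic),
                     dtabr_ischemic = mean(.data$dtabr_ischemic),
                     .groups = "drop")
  txt <- c(
    "qEEG stroke monitoring report",
    sprintf("seed: %d  animals/group: %d  index unit: %s",
            cfg$seed, cfg$n_per_group, cfg$index_unit),
    sprintf("thresholds: DAR > %g, DTABR > %g (exceedance flags, not interpretation)",
            cfg$dar_threshold, cfg$dtabr_threshold),
    "",
    "fraction of sessions flagged per group/phase:",
    utils::capture.output(as.data.frame(flag_share))
  )
  writeLines(txt, file.path(rep_dir, "report.txt"))
  log_msg("report: written under %s", rep_dir)
  invisible(list(acute_indices = acute_summary, subacute_bands = subacute_summary,
                 anova = anova_tab, flags = flag_share))
}

#' Run the full pipeline: simulate, analyze, report
#'
#' @param cfg A [pipeline_config()].
#' @return The [run_report()] result, invisibly.
#' @export
run_all <- function(cfg) {
  manifest <- run_simulate(cfg)
  analysis <- run_analyze(cfg, manifest)
  run_report(cfg, analysis)
}
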