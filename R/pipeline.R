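#' Run configuration for the simulate / analyze pipeline
#'
#' One document controls a whole run: the simulator conditions, the analysis
#' tunables, the root seed and the output directory. Values omitted from a
#' config file fall back to these defaults; the root seed spawns named child
#' seeds per stage so stages are individually reproducible.
#'
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @param boundary_sim Named list of [clock_sim_params()] arguments.
#' @param kymo_sim Named list of [kymo_synth_params()] arguments
#'   (`amplitudes` defaults to 15 unit-median log-normal draws with a
#'   defect-fated subset, see [run_simulation_study()]).
#' @param cell_sim Named list of [cell_field_params()] arguments.
#' @param analysis Named list: [analysis_config()] arguments plus `range`
#'   (boundary interval, default `c(11, 30)`), `bin_width` (default 0.1) and
#'   `slice` ([slice_config()] arguments).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "segclock-run",
                       boundary_sim = list(), kymo_sim = list(),
                       cell_sim = list(), analysis = list()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 boundary_sim = boundary_sim, kymo_sim = kymo_sim,
                 cell_sim = cell_sim, analysis = analysis),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`); keys mirror the
#'   [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
  args <- cfg[intersect(names(cfg), names(formals(run_config)))]
  do.call(run_config, args)
}

# named per-stage child seeds derived from the root seed
.stage_seeds <- function(seed) {
  s <- .child_seeds(seed, 3L)
  list(boundaries = s[1L], kymograph = s[2L], cells = s[3L])
}

.log_msg <- function(stage, level, msg) {
  message(sprintf("[%s] %s: %s", stage, level, msg))
}

#' Simulate a full synthetic study to disk
#'
#' Runs all three generators under the configured conditions and writes the
#' documented file manifest into `out_dir`: `boundary_table.tsv`,
#' `amplitude_truth.tsv` (per-cycle amplitudes behind the boundary table),
#' `kymograph.tif` + `kymograph.json` + `kymo_truth.tsv` (planted wave
#' amplitudes), `cells.csv`, and `run_config.json` (provenance: config and
#' per-stage seeds). Identical config and seed reproduce identical tables.
#'
#' @param cfg A [run_config()].
#' @return The output directory, invisibly; attribute `manifest` lists the
#'   files written.
#' @export
run_simulation_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$out_dir)) stop("cannot create output dir: ", cfg$out_dir)
  probe <- file.path(cfg$out_dir, ".write-test")
  ok <- tryCatch({ file.create(probe) && file.remove(probe) },
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok) stop("output dir not writable: ", cfg$out_dir)
  seeds <- .stage_seeds(cfg$seed)

  bs <- utils::modifyList(list(seed = seeds$boundaries), cfg$boundary_sim)
  sim <- simulate_boundary_outcomes(do.call(clock_sim_params, bs))
  write_boundary_table(sim$boundary_table,
                       file.path(cfg$out_dir, "boundary_table.tsv"))
  utils::write.table(sim$truth, file.path(cfg$out_dir, "amplitude_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_msg("simulate", "info",
           sprintf("boundary table: %d embryos", sim$params$n_embryos))

  ks <- cfg$kymo_sim
  fate <- ks$fate
  ks$fate <- NULL
  if (is.null(ks$amplitudes)) {
    # default planted waves: unit-median log-normal, defect-fated cycles at 0.6x
    set.seed(seeds$kymograph)
    fate <- ifelse(stats::rbinom(15L, 1L, 0.45) == 1L, "defected", "intact")
    ks$amplitudes <- exp(stats::rnorm(15L, 0, 0.1)) *
      ifelse(fate == "defected", 0.6, 1)
  }
  ks <- utils::modifyList(list(seed = seeds$kymograph), ks)
  kg <- synthesize_kymograph(do.call(kymo_synth_params, ks))
  write_kymograph(kg$kymograph, file.path(cfg$out_dir, "kymograph.tif"))
  truth <- kg$truth
  if (!is.null(fate)) truth$phenotype <- fate
  utils::write.table(truth, file.path(cfg$out_dir, "kymo_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_msg("simulate", "info",
           sprintf("kymograph: %d frames, %d planted waves",
                   nrow(kg$kymograph$intensity), nrow(kg$truth)))

  cs <- utils::modifyList(list(seed = seeds$cells), cfg$cell_sim)
  cells <- synthesize_cell_field(do.call(cell_field_params, cs))
  write_cell_table(cells, file.path(cfg$out_dir, "cells.csv"))
  .log_msg("simulate", "info", sprintf("cell field: %d cells", nrow(cells)))

  prov <- list(seed = cfg$seed, stage_seeds = seeds,
               boundary_sim = bs, kymo_sim = ks, cell_sim = cs,
               analysis = cfg$analysis)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c("boundary_table.tsv", "amplitude_truth.tsv", "kymograph.tif",
                "kymograph.json", "kymo_truth.tsv", "cells.csv",
                "run_config.json")
  invisible(structure(cfg$out_dir, manifest = manifest))
}

.analysis_from_cfg <- function(an) {
  keep <- intersect(names(an), names(formals(analysis_config)))
  do.call(analysis_config, an[keep])
}

#' Analyze a study directory into one report
#'
#' Reads the files written by [run_simulation_study()] (or equivalently
#' formatted real data), runs every analysis stage — penetrance,
#' expressivity, consecutive and left-right correlation summaries, the
#' kymograph amplitude pipeline with intact-mean normalization, and the
#' smFISH spatial correlation — and writes `report.json` plus a
#' human-readable `report.txt` into the directory.
#'
#' @param cfg A [run_config()] whose `out_dir` holds the stage inputs.
#' @return A `run_report` list (also serialized as JSON).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dirp <- cfg$out_dir
  paths <- list(boundary = file.path(dirp, "boundary_table.tsv"),
                kymo = file.path(dirp, "kymograph.tif"),
                cells = file.path(dirp, "cells.csv"))
  for (p in unlist(paths))
    if (!file.exists(p)) stop("stage input missing: ", p)
  an <- cfg$analysis
  range <- if (!is.null(an$range)) as.integer(an$range) else c(11L, 30L)
  bin_width <- if (!is.null(an$bin_width)) an$bin_width else 0.1
  config <- .analysis_from_cfg(an)

  tab <- read_boundary_table(paths$boundary)
  pen <- classify_embryos(tab, range)
  expr <- defect_counts(tab, range)
  cons <- summarize_correlations(consecutive_correlations(tab, range), bin_width)
  lr <- summarize_correlations(left_right_correlations(tab, range), bin_width)
  .log_msg("boundaries", "info",
           sprintf("mean consecutive r = %.4f, mean left-right r = %.4f",
                   cons$mean_r, lr$mean_r))

  kymo <- read_kymograph(paths$kymo)
  waves <- extract_wave_amplitudes(kymo, config, experiment_id = "exp1")
  # pair detected waves with the planted per-wave fates when present,
  # otherwise with the first scored embryo side of the boundary table
  truth_path <- file.path(dirp, "kymo_truth.tsv")
  fate <- NULL
  if (file.exists(truth_path)) {
    truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
    if (!is.null(truth$phenotype) &&
        nrow(truth) >= max(waves$wave_index))
      fate <- truth$phenotype[waves$wave_index]
  }
  if (is.null(fate)) {
    e1 <- tab$embryo_id[1L]
    waves <- pair_boundary_phenotypes(waves, tab, embryo_id = e1, side = "L")
  } else waves$phenotype <- fate
  waves <- normalize_amplitudes(waves)
  amp_cmp <- tryCatch(compare_amplitude_groups(waves),
                      error = function(e) NULL)
  utils::write.table(waves, file.path(dirp, "wave_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cells <- read_cell_table(paths$cells)
  scfg_args <- if (!is.null(an$slice)) an$slice else list()
  if (is.null(scfg_args$psm_length_um))
    scfg_args$psm_length_um <- max(cells$x_um)
  scfg <- do.call(slice_config, scfg_args)
  sp_r <- smfish_spatial_correlation(cells, scfg)

  report <- structure(list(
    penetrance = pen,
    expressivity = expr$summary,
    consecutive_correlation = list(mean_r = cons$mean_r, n = cons$n,
                                   n_excluded = cons$n_excluded),
    left_right_correlation = list(mean_r = lr$mean_r, n = lr$n,
                                  n_excluded = lr$n_excluded),
    amplitude_comparison = if (is.null(amp_cmp)) NULL else
      amp_cmp[c("median_intact", "median_defected", "percent_less",
                "p.value", "n_intact", "n_defected")],
    smfish_spatial_r = as.numeric(sp_r),
    provenance = list(seed = cfg$seed, range = range, bin_width = bin_width)
  ), class = "run_report")
  jsonlite::write_json(unclass(report), file.path(dirp, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dirp, "report.txt"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("segclock run report\n")
  cat("Penetrance:\n"); print.data.frame(x$penetrance)
  cat("Expressivity (defects per side):\n"); print.data.frame(x$expressivity)
  cat(sprintf("Mean consecutive-boundary r: %.4f (n = %d, %d undefined)\n",
              x$consecutive_correlation$mean_r, x$consecutive_correlation$n,
              x$consecutive_correlation$n_excluded))
  cat(sprintf("Mean left-right r: %.4f (n = %d, %d undefined)\n",
              x$left_right_correlation$mean_r, x$left_right_correlation$n,
              x$left_right_correlation$n_excluded))
  if (!is.null(x$amplitude_comparison))
    cat(sprintf("Amplitude: defected median %.1f%% less than intact (p = %.3g)\n",
                x$amplitude_comparison$percent_less,
                x$amplitude_comparison$p.value))
  cat(sprintf("smFISH spatial r: %.4f\n", x$smfish_spatial_r))
  invisible(x)
}

#' Validate analysis input files against their schemas
#'
#' Checks a boundary-phenotype TSV (required columns, phenotype codes with
#' the offending row reported), a kymograph sidecar JSON (required metadata
#' keys) and a cell-table CSV (required columns, non-negative integer
#' counts). Issues are classified `fatal` or `warning`.
#'
#' @param paths Named list with any of `boundary`, `kymo_sidecar`, `cells`.
#' @return A `validation_report` data frame: `file, severity, message`;
#'   zero rows means all inputs are well-formed.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  add <- function(file, severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(file = file,
                                                 severity = severity,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  if (!is.null(paths$boundary)) {
    p <- paths$boundary
    if (!file.exists(p)) add(p, "fatal", "file not found")
    else {
      x <- utils::read.delim(p, stringsAsFactors = FALSE)
      need <- c("embryo_id", "side", "boundary_index", "phenotype")
      miss <- setdiff(need, names(x))
      if (length(miss))
        add(p, "fatal", paste("missing column(s):",
                              paste(miss, collapse = ", ")))
      else {
        bad <- which(!is.na(x$phenotype) & !x$phenotype %in% c(0L, 1L))
        if (length(bad))
          add(p, "fatal", paste0("invalid phenotype code '",
                                 x$phenotype[bad[1L]], "' at row ", bad[1L]))
        bad <- which(!x$side %in% c("L", "R"))
        if (length(bad))
          add(p, "fatal", paste0("invalid side at row ", bad[1L]))
        if (is.null(x$condition))
          add(p, "warning", "no condition column; a single condition is assumed")
      }
    }
  }
  if (!is.null(paths$kymo_sidecar)) {
    p <- paths$kymo_sidecar
    if (!file.exists(p)) add(p, "fatal", "file not found")
    else {
      meta <- jsonlite::read_json(p, simplifyVector = TRUE)
      for (k in c("frame_interval_min", "px_size_um", "seven_somite_frame"))
        if (is.null(meta[[k]]))
          add(p, "fatal", paste0("missing required key '", k, "'"))
      if (is.null(meta$temperature_label))
        add(p, "warning", "no temperature_label; default window applies")
    }
  }
  if (!is.null(paths$cells)) {
    p <- paths$cells
    if (!file.exists(p)) add(p, "fatal", "file not found")
    else {
      x <- utils::read.csv(p, stringsAsFactors = FALSE)
      need <- c("cell_id", "x_um", "y_um", "count_gene1", "count_gene2")
      miss <- setdiff(need, names(x))
      if (length(miss))
        add(p, "fatal", paste("missing column(s):",
                              paste(miss, collapse = ", ")))
      else for (cn in c("count_gene1", "count_gene2")) {
        bad <- which(is.na(x[[cn]]) | x[[cn]] < 0 | x[[cn]] != floor(x[[cn]]))
        if (length(bad))
          add(p, "fatal", paste0(cn, " not a non-negative integer at row ",
                                 bad[1L]))
      }
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) cat("All inputs well-formed: zero issues.\n")
  else print.data.frame(x)
  invisible(x)
}
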