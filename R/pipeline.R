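#' Run configuration
#'
#' Reads and validates a pipeline configuration from a YAML file or a list.
#' Recognized sections (all optional unless noted):
#' * `out_dir` (required): working directory for stage artifacts;
#' * `seed`: master seed (default 1);
#' * `mode`: staining mode, one of `pax7-myod`, `myog-myod`, `myhc`, `auto`;
#' * `design`: `coatings` (required), `days` (required), `wells`, `fields`;
#' * `scene`: [scene_params] overrides applied to every field;
#' * `conditions`: per-`"<coating>"` or `"<coating>:<day>"` scene overrides;
#' * `channel_map`: channel -> antibody labels, recorded in the report;
#' * `segmentation`: `min_area`, `max_area`, `exclude_border`,
#'   `min_peak_distance`;
#' * `markers`: `rule` (`intersection` or `containment`),
#'   `min_myotube_area`;
#' * `stats`: `outcomes`, `exclude_day1` (outcomes dropping day 1),
#'   `ref_coating`, `alpha`.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop_param("config must be a YAML file path or a list")
  defaults <- list(
    seed = 1L, mode = "auto",
    design = list(wells = 3L, fields = 5L),
    scene = list(), conditions = list(), channel_map = list(),
    segmentation = list(min_area = 15, max_area = 230, exclude_border = TRUE,
                        min_peak_distance = 5),
    markers = list(rule = "intersection", min_myotube_area = 300),
    stats = list(outcomes = c("proliferation", "differentiation", "fusion",
                              "myotubes"),
                 exclude_day1 = c("differentiation", "myotubes"),
                 ref_coating = "matrigel", alpha = 0.05))
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$out_dir)) stop_param("config needs an out_dir")
  if (is.null(cfg$design$coatings) || is.null(cfg$design$days))
    stop_param("config design needs 'coatings' and 'days'")
  if (!cfg$mode %in% c("auto", "pax7-myod", "myog-myod", "myhc"))
    stop_param("unknown mode '", cfg$mode, "'")
  if (!cfg$stats$ref_coating %in% cfg$design$coatings)
    stop_param("stats reference coating '", cfg$stats$ref_coating,
               "' is not one of the design coatings")
  if (!cfg$markers$rule %in% c("intersection", "containment"))
    stop_param("markers rule must be 'intersection' or 'containment'")
  structure(cfg, class = "run_config")
}

stage_hash <- function(...) digest::digest(list(...), algo = "xxhash64")

log_line <- function(log_path, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n",
      sep = "", file = log_path, append = TRUE)
}

#' Run the full pipeline: simulate, quantify, indices, statistics
#'
#' Executes every stage under the configured output directory, writing
#' per-stage artifacts (`manifest.csv` + images, `field_counts.csv`,
#' `analysis_table.csv`, `contrasts.csv`, `report.md`) and a structured log
#' of every parameter and seed. Identical config and seed reproduce
#' byte-identical tables. Stage outputs are cached: a stage is skipped when
#' its inputs' content hash matches the previous run.
#'
#' @param config a `run_config`, a list, or a YAML path
#'   (see [read_run_config()]).
#' @param force rerun all stages even when cached.
#' @return list of class `pipeline_result`: `config`, `field_counts`,
#'   `analysis_table`, `summary` (per coating x day mean and SD over wells
#'   for each outcome), `fits`, `contrasts`, and file `paths`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  log_line(log_path, "run_pipeline start; seed=", cfg$seed, " mode=", cfg$mode)

  # --- stage 1: simulate -----------------------------------------------
  sim_hash <- stage_hash("simulate", cfg$seed, cfg$design, cfg$scene,
                         cfg$conditions)
  hash_file <- file.path(out, ".simulate.hash")
  manifest_path <- file.path(out, "manifest.csv")
  cached <- !force && file.exists(hash_file) && file.exists(manifest_path) &&
    readLines(hash_file, warn = FALSE)[1] == sim_hash
  if (cached) {
    manifest <- read.csv(manifest_path)
    log_line(log_path, "simulate: cached (", sim_hash, ")")
  } else {
    base <- do.call(scene_params, cfg$scene)
    manifest <- tryCatch(
      generate_study(cfg$design, out, base_params = base,
                     condition_params = cfg$conditions, seed = cfg$seed,
                     overwrite = TRUE),
      error = function(e) stop("simulate stage failed: ", conditionMessage(e),
                               call. = FALSE))
    writeLines(sim_hash, hash_file)
    log_line(log_path, "simulate: ", nrow(manifest), " fields (", sim_hash, ")")
  }

  # --- stage 2: quantify ------------------------------------------------
  qcfg <- c(cfg$segmentation, list(marker_rule = cfg$markers$rule,
                                   min_myotube_area = cfg$markers$min_myotube_area))
  q_hash <- stage_hash("quantify", sim_hash, cfg$mode, qcfg)
  q_hash_file <- file.path(out, ".quantify.hash")
  counts_path <- file.path(out, "field_counts.csv")
  cached <- !force && file.exists(q_hash_file) && file.exists(counts_path) &&
    readLines(q_hash_file, warn = FALSE)[1] == q_hash
  if (cached) {
    field_counts <- read.csv(counts_path)
    log_line(log_path, "quantify: cached (", q_hash, ")")
  } else {
    field_counts <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      paths <- list.files(file.path(out, "images"),
                          pattern = paste0("^", row$prefix, "_[a-z]+\\.tif$"),
                          full.names = TRUE)
      names(paths) <- sub("^.*_([a-z]+)\\.tif$", "\\1", basename(paths))
      stack <- read_stack(paths,
                          provenance = list(coating = row$coating,
                                            day = row$day, well = row$well,
                                            field = row$field))
      tryCatch(quantify_field(stack, mode = cfg$mode, config = qcfg),
               error = function(e) stop("quantify stage failed on ",
                                        row$prefix, ": ",
                                        conditionMessage(e), call. = FALSE))
    }))
    write.csv(field_counts, counts_path, row.names = FALSE)
    writeLines(q_hash, q_hash_file)
    log_line(log_path, "quantify: ", nrow(field_counts), " fields (", q_hash, ")")
  }

  # --- stage 3: indices -------------------------------------------------
  analysis_table <- build_analysis_table(field_counts, mode = cfg$mode)
  write.csv(analysis_table, file.path(out, "analysis_table.csv"),
            row.names = FALSE)
  summary_tab <- well_summary(analysis_table)
  write.csv(summary_tab, file.path(out, "index_summary.csv"),
            row.names = FALSE)
  log_line(log_path, "indices: ", nrow(analysis_table), " well-outcome rows")

  # --- stage 4: statistics ----------------------------------------------
  fits <- list()
  contrast_rows <- list()
  for (oc in intersect(cfg$stats$outcomes, unique(analysis_table$outcome))) {
    fit <- tryCatch(
      fit_outcome_model(analysis_table, oc,
                        exclude_day1 = oc %in% cfg$stats$exclude_day1,
                        ref_coating = cfg$stats$ref_coating,
                        alpha = cfg$stats$alpha),
      error = function(e) {
        log_line(log_path, "stats: outcome ", oc, " not fit: ",
                 conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      fits[[oc]] <- fit
      contrast_rows[[oc]] <- fit$contrasts
    }
  }
  contrasts <- if (length(contrast_rows)) do.call(rbind, contrast_rows) else
    data.frame()
  rownames(contrasts) <- NULL
  write.csv(contrasts, file.path(out, "contrasts.csv"), row.names = FALSE)
  report_path <- file.path(out, "report.md")
  write_report(report_path, cfg, summary_tab, fits, contrasts)
  log_line(log_path, "stats: ", length(fits), " outcomes fit; report written")

  structure(list(config = cfg, field_counts = field_counts,
                 analysis_table = analysis_table, summary = summary_tab,
                 fits = fits, contrasts = contrasts,
                 paths = list(manifest = manifest_path,
                              field_counts = counts_path,
                              analysis_table = file.path(out, "analysis_table.csv"),
                              contrasts = file.path(out, "contrasts.csv"),
                              report = report_path, log = log_path)),
            class = "pipeline_result")
}

# per coating x day mean and SD over wells for each outcome
well_summary <- function(analysis_table) {
  groups <- split(analysis_table,
                  interaction(analysis_table$outcome, analysis_table$coating,
                              analysis_table$day, drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(outcome = g$outcome[1], coating = g$coating[1], day = g$day[1],
               n_wells = nrow(g), mean = mean(g$value),
               sd = if (nrow(g) > 1) sd(g$value) else NA_real_)
  }))
  out <- out[order(out$outcome, out$coating, out$day), ]
  rownames(out) <- NULL
  out
}

write_report <- function(path, cfg, summary_tab, fits, contrasts) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# Culture quantification report")
  w("")
  w("Mode: ", cfg$mode, "; seed: ", cfg$seed,
    "; reference coating: ", cfg$stats$ref_coating)
  if (length(cfg$channel_map))
    w("Channel map: ", paste(names(cfg$channel_map), unlist(cfg$channel_map),
                             sep = "=", collapse = ", "))
  w("")
  w("## Index summary (mean over wells, SD in parentheses)")
  w("")
  for (oc in unique(summary_tab$outcome)) {
    w("### ", oc)
    s <- summary_tab[summary_tab$outcome == oc, ]
    for (i in seq_len(nrow(s))) {
      w("- ", s$coating[i], ", day ", s$day[i], ": ",
        sprintf("%.1f (SD %.1f, n=%d)", s$mean[i], s$sd[i], s$n_wells[i]))
    }
    w("")
  }
  w("## Coating-vs-reference contrasts")
  w("")
  if (length(fits) == 0) {
    w("No outcome models could be fit.")
  } else {
    for (oc in names(fits)) {
      f <- fits[[oc]]
      w("### ", oc, if (f$interaction_included)
        " (interaction model)" else " (additive model)")
      if (length(f$excluded_days))
        w("Day(s) excluded: ", paste(f$excluded_days, collapse = ", "))
      cs <- f$contrasts
      for (i in seq_len(nrow(cs))) {
        w("- ", cs$coating[i], " vs ", f$ref_coating, ", day ", cs$day[i],
          ": ", sprintf("%+.2f (p=%.4g)%s", cs$estimate[i], cs$p_value[i],
                        if (cs$significant[i]) " *" else ""))
      }
      w("")
    }
  }
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$field_counts), " fields, ",
      length(x$fits), " outcome model(s)\n", sep = "")
  cat("  report: ", x$paths$report, "\n", sep = "")
  invisible(x)
}
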