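#' Read and write parameter record tables
#'
#' Tidy CSV (UTF-8, comma-separated, `.` decimal, header row). Reading
#' validates the dialect: a file whose numeric columns do not parse (e.g.
#' decimal commas or semicolon separators) is rejected with an explicit
#' error.
#'
#' @param records Long record tibble.
#' @param path CSV path.
#' @return `read_records()` returns the tibble; `write_records()` returns
#'   `path` invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readr::read_lines(path, n_max = 1)
  if (!grepl(",", header) || grepl(";", header)) {
    abort(sprintf("CSV dialect error in %s: expected comma-separated, '.' decimal",
                  path))
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(grouping_mark = ""))
  if (!"value" %in% names(out)) abort("records CSV must have a 'value' column")
  v <- suppressWarnings(readr::parse_double(as.character(out$value)))
  bad <- !is.na(out$value) & is.na(v)
  if (any(bad)) {
    abort(sprintf(
      "CSV dialect error: 'value' is not numeric (e.g. '%s'); decimal commas are rejected",
      utils::head(out$value[bad], 1)))
  }
  out$value <- v
  out
}

#' Read and write 8-bit frame stacks with a JSON manifest
#'
#' One multi-page TIFF per channel plus a `manifest.json` recording times,
#' channels, seed, frame size and pixel scale. Round-trips are lossless at
#' 8 bit.
#'
#' @param run Run object (elements `frames`, `manifest`), e.g. from
#'   [generate_run_images()].
#' @param dir Output directory (created if needed).
#' @return `write_frames()` returns `dir` invisibly; `read_frames()` returns
#'   a run-shaped list (`frames`, `manifest`).
#' @export
write_frames <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- run$manifest
  man$files <- list()
  for (ch in names(run$frames)) {
    f <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(lapply(run$frames[[ch]], function(m) m / 255), f,
                    bits.per.sample = 8L)
    man$files[[ch]] <- basename(f)
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) abort(sprintf("manifest not found: %s", man_path))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (is.unsorted(man$times)) abort("manifest invalid: times not sorted")
  if (!man$bit_depth %in% c(8L, 16L)) abort("manifest invalid: bit depth must be 8 or 16")
  frames <- list()
  for (ch in names(man$files)) {
    f <- file.path(dir, man$files[[ch]])
    if (!file.exists(f)) abort(sprintf("manifest references missing file: %s", f))
    pages <- tiff::readTIFF(f, all = TRUE)
    frames[[ch]] <- setNames(
      lapply(pages, function(p) matrix(as.integer(round(p * 255)),
                                       nrow(p), ncol(p))),
      as.character(man$times)
    )
  }
  list(frames = frames, manifest = man)
}

#' Run the full phenotyping pipeline on a synthetic cohort
#'
#' End-to-end orchestration: generate the parameter cohort (controls plus
#' template-defined patients), scale to 0--10, build the control reference,
#' derive per-patient relevant-change maps and integrated group sums,
#' summarize the TM effect on the anticoagulant surface, run the
#' multi-classifier condition prediction with FDR-corrected surface
#' comparisons, and (optionally) synthesize and quantify one demonstration
#' image run. All outputs are written as CSV/JSON into `out_dir` together
#' with a machine-readable provenance file; reruns with the same seed are
#' byte-identical.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every stage.
#' @param n_controls Number of control subjects.
#' @param patients Named list of patient [effect_template()]s.
#' @param surfaces Surfaces for the patient/control comparison.
#' @param include_images Also run the image-synthesis + quantification demo.
#' @param image_dim Frame size for the demo run.
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_controls = 10,
                         patients = patient_templates(),
                         surfaces = c("M6", "M7"),
                         include_images = FALSE, image_dim = c(128, 128)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  records <- stage("cohort", generate_parameter_cohort(
    n_controls = n_controls, patients = patients, surfaces = surfaces,
    conditions = default_conditions(), seed = seed
  ))
  tm_records <- stage("cohort_tm", generate_parameter_cohort(
    n_controls = n_controls, patients = patients, surfaces = "M8",
    conditions = anticoagulant_conditions(), seed = seed + 1L
  ))
  scaled <- stage("scaling", scale_parameters(records))
  reference <- stage("reference",
                     build_reference(scaled |> filter(.data$group == "control")))
  changes <- stage("patient_changes", patient_changes(
    scaled |> filter(.data$group != "control"), reference
  ))
  sums <- stage("integration", integrate_changes(changes))
  tm <- stage("tm_effect", tm_effect(scale_parameters(tm_records)))

  pred_records <- stage("prediction_cohort", generate_parameter_cohort(
    n_controls = max(3, n_controls %/% 2), patients = list(),
    surfaces = surfaces, conditions = intervention_conditions() |>
      select(-"class"),
    seed = seed + 2L
  ))
  features <- stage("features", impute_missing(records_to_features(pred_records)))
  report <- stage("prediction", classify_conditions(features, seed = seed))
  comparisons <- stage("comparison", compare_classifiers(report))

  write_records(records, file.path(out_dir, "records.csv"))
  write_records(tm_records, file.path(out_dir, "records_tm.csv"))
  readr::write_csv(scaling_record(scaled), file.path(out_dir, "scaling.csv"))
  readr::write_csv(reference, file.path(out_dir, "reference.csv"))
  readr::write_csv(changes, file.path(out_dir, "patient_changes.csv"))
  readr::write_csv(sums, file.path(out_dir, "group_sums.csv"))
  readr::write_csv(tm, file.path(out_dir, "tm_effect.csv"))
  readr::write_csv(tidy(report), file.path(out_dir, "prediction_accuracies.csv"))
  readr::write_csv(comparisons, file.path(out_dir, "surface_comparisons.csv"))

  quant <- NULL
  if (include_images) {
    run <- stage("images", generate_run_images(seed = seed, dim = image_dim))
    quant <- stage("quantify", quantify_run(run))
    params <- stage("parameters", run_parameters(quant))
    readr::write_csv(quant |> select(-"areas"),
                     file.path(out_dir, "demo_quant.csv"))
    readr::write_csv(params, file.path(out_dir, "demo_parameters.csv"))
  }

  config <- list(
    seed = seed, n_controls = n_controls,
    patients = names(patients), surfaces = surfaces,
    include_images = include_images,
    class_bits = c(TF = 4, iFVIIa = 2, CTI = 1),
    score_provenance = "automated_rubric",
    package_version = as.character(utils::packageVersion("thrombospot"))
  )
  config$config_hash <- rlang::hash(config)
  jsonlite::write_json(config, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, scaled = scaled, reference = reference,
                 changes = changes, group_sums = sums, tm_effect = tm,
                 report = report, comparisons = comparisons, quant = quant))
}
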