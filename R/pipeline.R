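#' Default run configuration
#'
#' All stage parameters default to the pipeline's canonical values: ICP
#' tolerance 0.01 mm with a 120-iteration cap, relaxed 0.2 mm tolerance for
#' the plaque-only alignment, 90% retained variance, +-2 sigma sampling in
#' 0.5 sigma steps, 6 selected modes, a 70/30 split and tenfold
#' cross-validation. A single master seed fans out to per-stage substreams so
#' stages can be re-run in isolation.
#'
#' @param output_dir where artifacts are written.
#' @param seed master seed.
#' @param synth `NULL` to read surfaces from `paths`, or a list of
#'   [synth_config()] overrides to generate the cohort.
#' @param paths list with `wall_dir`, `calc_dir`, `clinical_csv` when reading
#'   real data.
#' @param ... stage-parameter overrides (see the config fields).
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir = "vcohort_out", seed = 1L, synth = list(),
                       paths = NULL, ...) {
  cfg <- list(
    output_dir = output_dir,
    seed = as.integer(seed),
    synth = synth,
    paths = paths,
    resample = list(wall_points = NULL, calc_points = NULL),
    align = list(tolerance_mm = 0.01, max_iter = 120L, calc_tolerance_mm = 0.2,
                 max_mean_iter = 10L, mean_tol_mm = 0.05),
    quality = list(max_modes = 10L),
    generate = list(n = 100L, variance_fraction = 0.90, boundary = 2.0,
                    step = 0.5, max_attempts_per_shape = 50L),
    validate = list(band_mm = 2.0),
    regress = list(target = "peak_gradient", n_select = 6L, folds = 10L,
                   tuning_iters = 12L),
    classify = list(label = "device_size", n_select = 6L,
                    test_fraction = 0.30)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return [run_config()] for `load_run_config`; `path` invisibly for
#'   `save_run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname load_run_config
#' @param config a [run_config()].
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(seed, stage) {
  offsets <- c(synth = 11L, resample = 22L, align = 33L, fit = 44L,
               quality = 55L, generate = 66L, validate = 77L, regress = 88L,
               classify = 99L)
  (seed * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full virtual-cohort pipeline
#'
#' Executes synth (or surface loading) -> resample -> align -> fit ->
#' quality -> generate -> validate -> regress -> classify, writing a manifest
#' (inputs, outputs, seeds, per-stage wall time) and returning all stage
#' results. Any stage failure raises an error naming the stage; artifacts of
#' completed stages are preserved under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisible list with all stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(started = format(Sys.time()), seed = config$seed,
                   stages = list())
  results <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    say("[%s] ...", name)
    out <- tryCatch(fun(), error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = unname(stage_seed(config$seed, name)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$paths)) {
    p <- config$paths
    if (!is.null(config$regress) && is.null(p$clinical_csv))
      stop("config error: regression requested but no clinical_csv given",
           call. = FALSE)
    if (!is.null(p$clinical_csv) && !file.exists(p$clinical_csv))
      stop("config error: clinical_csv not found: ", p$clinical_csv,
           call. = FALSE)
    results$input <- run_stage("synth", function() {
      walls <- lapply(list.files(p$wall_dir, "\\.(stl|ply)$", full.names = TRUE),
                      read_surface, label = "wall")
      calcs <- lapply(list.files(p$calc_dir, "\\.(stl|ply)$", full.names = TRUE),
                      read_surface, label = "calcification")
      clinical <- utils::read.csv(p$clinical_csv)
      list(walls = walls, calcs = calcs, clinical = clinical, truth = NULL)
    })
  } else {
    results$input <- run_stage("synth", function() {
      sc <- do.call(synth_config,
                    c(config$synth,
                      if (is.null(config$synth$seed))
                        list(seed = stage_seed(config$seed, "synth"))))
      synth_cohort(sc)
    })
  }
  coh <- results$input

  results$resample <- run_stage("resample", function() {
    wp <- config$resample$wall_points
    cp <- config$resample$calc_points
    s0 <- stage_seed(config$seed, "resample")
    walls <- if (is.null(wp)) coh$walls else
      lapply(seq_along(coh$walls), function(i)
        resample_surface(coh$walls[[i]], min(wp, n_points(coh$walls[[i]])),
                         seed = s0 + i))
    calcs <- if (is.null(cp)) coh$calcs else
      lapply(seq_along(coh$calcs), function(i)
        resample_surface(coh$calcs[[i]], min(cp, n_points(coh$calcs[[i]])),
                         seed = s0 + 100000L + i))
    list(walls = walls, calcs = calcs)
  })

  results$align <- run_stage("align", function() {
    a <- config$align
    wall_cohort <- align_cohort(results$resample$walls,
                                tolerance_mm = a$tolerance_mm,
                                max_iter = a$max_iter,
                                max_mean_iter = a$max_mean_iter,
                                mean_tol_mm = a$mean_tol_mm)
    calc_cohort <- align_calcifications(results$resample$calcs, wall_cohort,
                                        tolerance_mm = a$calc_tolerance_mm,
                                        max_iter = a$max_iter)
    list(wall = wall_cohort, calc = calc_cohort)
  })

  results$fit <- run_stage("fit", function()
    list(wall = ssm_fit(results$align$wall),
         calc = ssm_fit(results$align$calc)))

  results$quality <- run_stage("quality", function() {
    M <- seq_len(min(config$quality$max_modes,
                     nrow(results$align$wall$X) - 2L))
    list(wall = ssm_generalization(results$align$wall, M),
         calc = ssm_generalization(results$align$calc, M))
  })

  results$generate <- run_stage("generate", function() {
    g <- config$generate
    generate_cohort(results$fit$wall, results$fit$calc, n = g$n,
                    variance_fraction = g$variance_fraction,
                    boundary = g$boundary, step = g$step,
                    seed = stage_seed(config$seed, "generate"),
                    max_attempts_per_shape = g$max_attempts_per_shape)
  })

  results$validate <- run_stage("validate", function() {
    bm <- config$validate$band_mm
    real <- data.frame(
      annulus_mm = vapply(results$resample$walls, annulus_diameter, numeric(1),
                          band_mm = bm),
      calc_volume_mm3 = vapply(results$resample$calcs, calcification_volume,
                               numeric(1)))
    synth <- data.frame(
      annulus_mm = vapply(results$generate, function(v)
        annulus_diameter(v$wall$surface, band_mm = bm), numeric(1)),
      calc_volume_mm3 = vapply(results$generate, function(v)
        calcification_volume(v$calc$surface), numeric(1)))
    list(report = compare_cohorts(real, synth), real = real, synthetic = synth)
  })

  # shape features for the ML stages: wall and calcification mode scores side
  # by side (both anatomies carry functionally relevant information)
  clinical <- coh$clinical
  wall_scores <- mode_scores(results$fit$wall, results$align$wall)
  calc_scores <- mode_scores(results$fit$calc, results$align$calc)
  colnames(wall_scores) <- paste0("wall_", seq_len(ncol(wall_scores)))
  colnames(calc_scores) <- paste0("calc_", seq_len(ncol(calc_scores)))
  scores <- cbind(wall_scores,
                  calc_scores[match(results$align$wall$ids,
                                    results$align$calc$ids), , drop = FALSE])
  clinical <- clinical[match(results$align$wall$ids, clinical$patient_id), ]

  results$regress <- run_stage("regress", function() {
    r <- config$regress
    svm_regress(scores, clinical[[r$target]], n_select = r$n_select,
                folds = r$folds, tuning_iters = r$tuning_iters,
                seed = stage_seed(config$seed, "regress"))
  })

  results$classify <- run_stage("classify", function() {
    cl <- config$classify
    classify_device_size(scores, clinical[[cl$label]],
                         n_select = cl$n_select,
                         test_fraction = cl$test_fraction,
                         seed = stage_seed(config$seed, "classify"))
  })
  results$scores <- scores

  manifest$finished <- format(Sys.time())
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  say("pipeline complete: %d stages", manifest$n_stages)
  invisible(results)
}
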