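# End-to-end orchestration: simulate -> fit -> cohort, with a run
# manifest that pins the config snapshot, seed and output hashes so any
# output directory can be regenerated exactly.

default_pipeline_config <- function() {
  list(seed = NULL, n = NULL, out_dir = NULL,
       nails = c("pfna2", "intertan"),
       nail_length = 200, nail_distal_diameter = 10,
       population = list(), write_meshes = FALSE,
       options = list(density = 4, threshold = 0.1, linkage_radius = 2,
                      exclude_entry_mm = 15, gap_step = 2),
       paired_method = "t")
}

validate_pipeline_config <- function(cfg) {
  if (!is_scalar_num(cfg$seed))
    stop_femfit("config", "config: an explicit integer 'seed' is required")
  if (!is_scalar_num(cfg$n) || cfg$n < 1 || cfg$n != round(cfg$n))
    stop_femfit("config", "config: 'n' must be a positive integer")
  if (length(cfg$nails) < 1)
    stop_femfit("config", "config: at least one nail model is required")
  known <- c("pfna2", "pfna", "intertan")
  bad <- setdiff(unlist(cfg$nails), known)
  if (length(bad) > 0)
    stop_femfit("config", "config: unknown nail model(s): %s",
                paste(bad, collapse = ", "))
  invisible(cfg)
}

nail_from_name <- function(name, length, distal_diameter) {
  spec <- switch(name,
    pfna2 = make_pfna2_spec(length, distal_diameter),
    pfna = make_pfna_legacy_spec(length, distal_diameter),
    intertan = make_intertan_spec(length, distal_diameter))
  list(spec = spec, mesh = build_nail_mesh(spec))
}

#' Run the full virtual-fitting pipeline
#'
#' Simulates a seeded femur cohort, places every configured nail in
#' every femur, computes per-case fitness reports, aggregates the paired
#' cohort summary, and writes everything (reports, summary JSON + CSV,
#' run manifest) under the output directory. Per-case failures are
#' logged, tallied in the manifest and skipped; the pipeline continues.
#'
#' @param config a YAML file path or a config list. Required fields:
#'   `seed`, `n`. Optional: `out_dir`, `nails` (subset of `"pfna2"`,
#'   `"pfna"`, `"intertan"`; default both study designs), `nail_length`,
#'   `nail_distal_diameter`, `population` (overrides per
#'   [population_spec()]), `write_meshes`, `options` (metric options per
#'   [compute_fitness()]), `paired_method`.
#' @param out_dir overrides `config$out_dir`.
#' @param seed,n optional overrides of the config values.
#' @return (invisibly) list with `summary`, `reports`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, n = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  # YAML 1.1 parses a bare `n:` key as a boolean; recover it
  bad <- is.na(names(cfg)) | names(cfg) %in% c("FALSE", "TRUE")
  if (any(bad) && !"n" %in% names(cfg)) names(cfg)[which(bad)[1]] <- "n"
  cfg <- modifyList(default_pipeline_config(), cfg)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(n)) cfg$n <- n
  validate_pipeline_config(cfg)
  if (is.null(cfg$out_dir))
    stop_femfit("config", "config: an output directory is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "reports"), showWarnings = FALSE)

  pspec <- population_spec(cfg$n, cfg$seed, cfg$population)
  sim <- simulate_cohort(pspec,
                         out_dir = if (isTRUE(cfg$write_meshes))
                           file.path(cfg$out_dir, "femurs") else NULL)
  write.csv(sim$manifest, file.path(cfg$out_dir, "true_params.csv"),
            row.names = FALSE)

  nails <- lapply(stats::setNames(nm = unlist(cfg$nails)), nail_from_name,
                  length = cfg$nail_length,
                  distal_diameter = cfg$nail_distal_diameter)

  reports <- list()
  failures <- character()
  for (fem in sim$femurs) {
    for (nm in names(nails)) {
      res <- tryCatch({
        pl <- place_nail(fem, nails[[nm]]$mesh, nails[[nm]]$spec)
        compute_fitness(fem, nails[[nm]]$mesh, nails[[nm]]$spec, pl,
                        opts = cfg$options)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", fem$id, nm,
                                        conditionMessage(res)))
        femfit_log("case %s/%s failed: %s", fem$id, nm,
                   conditionMessage(res))
      } else {
        write_fitness_report(res, file.path(cfg$out_dir, "reports",
                                            sprintf("%s_%s.json",
                                                    fem$id, nm)))
        reports[[length(reports) + 1L]] <- res
      }
    }
  }

  summary <- NULL
  if (length(unique(vapply(reports, function(r) r$nail_id, ""))) == 2) {
    ids <- vapply(reports, function(r) r$femur_id, "")
    nailv <- vapply(reports, function(r) r$nail_id, "")
    paired_ids <- names(which(table(ids) == 2))
    summary <- build_summary(build_cohort(reports[ids %in% paired_ids]),
                             paired_method = cfg$paired_method)
    write_cohort_summary(summary, file.path(cfg$out_dir, "summary.json"))
    write_cohort_summary(summary, file.path(cfg$out_dir, "summary.csv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("femfit")),
    seed = cfg$seed, config = cfg,
    n_cases = length(reports), n_failures = length(failures),
    failures = failures,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    file_md5 = as.list(tools::md5sum(
      list.files(cfg$out_dir, pattern = "\\.(json|csv)$",
                 recursive = TRUE, full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir,
                                           "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(list(summary = summary, reports = reports,
                 manifest = manifest, out_dir = cfg$out_dir))
}

#' Path of the bundled demo pipeline configuration
#'
#' A small reproducible run (n = 10, seed = 7, both study nails) used by
#' the end-to-end determinism checks and as a template for user configs.
#'
#' @return file path of the YAML config.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "femfit")
}
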