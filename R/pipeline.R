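#' Published monolayer parameters of the four membrane models
#'
#' The reference scalar parameters (means and reported uncertainties) for
#' the cancer (CM1, CM2) and healthy (HM1, HM2) membrane-model monolayers
#' on buffered subphases containing 0, 1, 10 or 30 micromolar of the
#' calixarene additive: extrapolated area, area at 30 mN/m, collapse
#' pressure, maximum compressional modulus and modulus at 30 mN/m.  Used
#' for worked examples (e.g. the ~60% modulus drop of the CM1 film at 30
#' micromolar); the underlying raw isotherms are not published.
#'
#' @return A 16-row data.frame with columns `model_id`, `scx4_conc_uM`,
#'   `a_ex_A2`, `a_ex_sd`, `a_30_A2`, `a_30_sd`, `pi_col_mN_per_m`,
#'   `pi_col_sd`, `cs_max_mN_per_m`, `cs_max_sd`, `cs_30_mN_per_m`,
#'   `cs_30_sd`.
#' @examples
#' tab <- table1_fixture()
#' subset(tab, model_id == "CM1", c(scx4_conc_uM, cs_30_mN_per_m))
#' @export
table1_fixture <- function() {
  tab <- utils::read.csv(text = '
model_id,scx4_conc_uM,a_ex_A2,a_ex_sd,a_30_A2,a_30_sd,pi_col_mN_per_m,pi_col_sd,cs_max_mN_per_m,cs_max_sd,cs_30_mN_per_m,cs_30_sd
CM1,0,53.4,0.1,44.0,0.1,52.7,0.3,177,5,152,5
CM1,1,63.6,0.5,47.4,0.3,50.0,0.4,100,2,82,2
CM1,10,66.6,0.4,49.9,0.2,52.1,0.3,102,1,93,3
CM1,30,73.3,1.3,47.3,0.4,52.6,0.2,63,3,60,2
HM1,0,50.1,0.6,42.8,0.3,53.8,0.4,208,3,173,2
HM1,1,58.9,0.2,47.8,0.3,53.5,0.4,161,4,145,2
HM1,10,61.0,0.4,46.6,0.1,52.9,0.3,110,7,108,3
HM1,30,72.2,1.5,52.6,0.4,52.6,0.4,98,5,88,3
CM2,0,63.3,0.4,44.0,0.3,42.6,0.3,87,7,71,2
CM2,1,71.2,0.2,48.8,0.1,42.3,0.5,82,2,75,3
CM2,10,77.6,0.4,52.6,0.1,42.6,0.2,67,2,66,2
CM2,30,82.4,0.4,51.9,0.6,39.9,0.5,60,1,50,2
HM2,0,62.4,0.6,44.1,0.4,42.8,0.2,91,1,79,3
HM2,1,63.7,0.3,43.4,0.3,41.7,0.2,76,3,69,1
HM2,10,74.8,0.8,48.3,0.4,40.3,0.3,68,2,63,2
HM2,30,82.4,0.3,55.8,0.3,41.5,0.5,61,2,62,3
', strip.white = TRUE)
  tab
}

default_run_config <- function() {
  list(
    stages = c("simulate", "isotherm", "project", "interface"),
    simulate = list(concs = c(0, 1, 10, 30), replicates = 3,
                    effect_scale = 1),
    isotherm = list(window = 10, grid_spacing = 0.1, pi_ref = 30),
    project = list(source = "isotherm", pi_lo = 0, pi_hi = 35,
                   n_points = 351, max_iter = 300, tol = 1e-9),
    interface = list(n_slab = 4000, n_gas = 2000, box = c(18, 18, 23),
                     midpoint = 3.6, width = 0.5, bin_width = 0.1,
                     gamma0 = 72.8, gamma_target = 42.8,
                     rdf_bin = 0.1, rdf_rmax = 8, rdf_frames = 3),
    inputs = list()
  )
}

validate_run_config <- function(config) {
  known <- c("simulate", "isotherm", "project", "interface")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) {
      stop(sprintf("configured input '%s' does not exist", p),
           call. = FALSE)
    }
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: synthetic isotherm generation (or
#' reading curve CSVs listed in `config$inputs$isotherms`), scalar
#' parameter extraction, projection of the curve family to a 2D map with a
#' silhouette/group-separation report, and the interfacial-observable demo
#' (slab density profile, Gibbs dividing surface, pressure-tensor tension,
#' radial distribution function).  All randomness derives from `seed`, so
#' a rerun with the same configuration is bit-identical; a provenance
#' record (config, seed, versions) is written alongside the outputs.
#'
#' @param config A configuration list (see `langmuir:::default_run_config`
#'   for the shape and defaults), a YAML file path, or `NULL` for the
#'   packaged synthetic demo.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default 1).
#' @return Invisibly, the list of written file paths.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_run_config(), config %||% list())
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  curves <- NULL

  if ("simulate" %in% config$stages) {
    sim <- config$simulate
    curves <- run_stage("simulate", generate_condition_set(
      default_model_specs(), concs = sim$concs,
      replicates = sim$replicates, seed = seed,
      effect_scale = sim$effect_scale))
  } else if (length(config$inputs$isotherms)) {
    curves <- run_stage("read", lapply(config$inputs$isotherms,
                                       read_isotherm_csv))
  }

  if ("isotherm" %in% config$stages) {
    if (is.null(curves)) stop("no curves for stage 'isotherm'",
                              call. = FALSE)
    iso <- config$isotherm
    params <- run_stage("isotherm", parameter_table(
      curves, pi_ref = iso$pi_ref, window = iso$window,
      grid_spacing = iso$grid_spacing))
    f <- file.path(out_dir, "parameters.csv")
    utils::write.csv(params, f, row.names = FALSE)
    emit(f)
  }

  if ("project" %in% config$stages) {
    if (is.null(curves)) stop("no curves for stage 'project'",
                              call. = FALSE)
    pr <- config$project
    res <- run_stage("project", {
      X <- build_feature_matrix(curves, pi_lo = pr$pi_lo, pi_hi = pr$pi_hi,
                                n_points = pr$n_points)
      D <- euclidean_distance_matrix(X)
      proj <- idmap_project(D, max_iter = pr$max_iter, tol = pr$tol,
                            seed = seed)
      labels <- attr(curves, "labels") %||% X$items
      ref <- unique(labels)[1:2]
      list(proj = proj, labels = labels,
           report = group_distance_report(proj, labels, ref))
    })
    f <- file.path(out_dir, "projection.csv")
    utils::write.csv(
      data.frame(item = res$proj$items, label = res$labels,
                 y1 = res$proj$coords[, 1], y2 = res$proj$coords[, 2]),
      f, row.names = FALSE)
    emit(f)
    f <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(stress = res$proj$stress,
           stress_normalized = res$proj$stress_normalized,
           n_iter = res$proj$n_iter,
           silhouette = res$report$silhouette,
           reference_pair = res$report$reference_pair,
           relative_distances = res$report$relative_distances),
      f, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    emit(f)
  }

  if ("interface" %in% config$stages) {
    itf <- config$interface
    res <- run_stage("interface", {
      slab <- generate_gas_config(
        n = itf$n_slab, box = itf$box, profile = "sigmoid",
        midpoint = itf$midpoint, width = itf$width, species = "W",
        seed = seed + 101L)
      prof <- density_profile(slab, bin_width = itf$bin_width)
      pp <- generate_pressure_profile(itf$gamma_target, shape = "gauss",
                                      width = 1)
      summ <- interface_summary(prof, pp, gamma0 = itf$gamma0,
                                species = "W")
      frames <- lapply(seq_len(itf$rdf_frames), function(k) {
        generate_gas_config(n = itf$n_gas, box = itf$box,
                            profile = "uniform", species = "A",
                            seed = seed + 200L + k)
      })
      rdf <- pmf_from_g(radial_distribution(frames, "A", "A",
                                            bin_width = itf$rdf_bin,
                                            r_max = itf$rdf_rmax))
      list(prof = prof, summ = summ, rdf = rdf)
    })
    emit(write_density_profile_tsv(
      res$prof, file.path(out_dir, "density_profile.tsv")))
    emit(write_rdf_tsv(res$rdf, file.path(out_dir, "rdf.tsv")))
    f <- file.path(out_dir, "interface_summary.json")
    jsonlite::write_json(unclass(res$summ), f, auto_unbox = TRUE,
                         digits = NA)
    emit(f)
  }

  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = as.character(utils::packageVersion("langmuir")),
         r_version = R.version.string),
    prov, auto_unbox = TRUE, digits = NA)
  emit(prov)
  invisible(outputs)
}
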