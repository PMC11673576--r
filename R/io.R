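# File formats: isotherm CSV + YAML sidecar, pressure-profile TSV,
# extended-XYZ particle frames, and the tabular outputs of the pipeline.

#' Read an isotherm from CSV (with optional YAML sidecar)
#'
#' The CSV has header `area_per_molecule_A2,surface_pressure_mN_per_m`, one
#' row per sample in acquisition order.  A sidecar YAML file (same path
#' with extension `.yaml`, or given explicitly) may carry `model_id`,
#' `scx4_conc_uM`, `temperature_C` and `replicate`.
#'
#' @param path CSV file path.
#' @param sidecar Optional YAML path; default replaces the CSV extension
#'   with `.yaml` and is used only if that file exists.
#' @return An [isotherm_curve()].
#' @export
read_isotherm_csv <- function(path, sidecar = NULL) {
  df <- utils::read.csv(path)
  need <- c("area_per_molecule_A2", "surface_pressure_mN_per_m")
  if (!all(need %in% names(df))) {
    stop(sprintf("isotherm CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  meta <- list(model_id = "", scx4_conc_uM = 0, temperature_C = 22,
               replicate = NA_integer_)
  sidecar <- sidecar %||% sub("\\.csv$", ".yaml", path)
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, yaml::read_yaml(sidecar))
  }
  isotherm_curve(df$area_per_molecule_A2, df$surface_pressure_mN_per_m,
                 model_id = meta$model_id, scx4_conc = meta$scx4_conc_uM,
                 temperature = meta$temperature_C,
                 replicate = meta$replicate)
}

#' Write an isotherm to CSV (with YAML sidecar)
#'
#' @param curve An [isotherm_curve()].
#' @param path CSV file path; the metadata sidecar is written next to it
#'   with extension `.yaml`.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(curve, path) {
  stopifnot(inherits(curve, "isotherm_curve"))
  utils::write.csv(
    data.frame(area_per_molecule_A2 = curve$area,
               surface_pressure_mN_per_m = curve$pressure),
    path, row.names = FALSE)
  yaml::write_yaml(
    list(model_id = curve$model_id, scx4_conc_uM = curve$scx4_conc,
         temperature_C = curve$temperature, replicate = curve$replicate),
    sub("\\.csv$", ".yaml", path))
  invisible(path)
}

#' Read particle frames from an extended-XYZ file
#'
#' Format: line 1 the particle count, line 2 the box lengths `Lx Ly Lz` in
#' nm, then one `species x y z` line per particle; multiple frames are
#' concatenated.
#'
#' @param path File path.
#' @return List of [particle_configuration()] frames.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    if (is.na(n) || n < 1) stop("malformed XYZ count line", call. = FALSE)
    box <- as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    species <- vapply(parts, `[[`, character(1), 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <-
      particle_configuration(pos, species, box)
    i <- i + 2L + n
  }
  frames
}

#' Write particle frames to an extended-XYZ file
#'
#' @param configs A `particle_configuration` or list of frames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(configs, path) {
  configs <- as_config_list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(as.character(cf$n), con)
    writeLines(paste(format(cf$box, trim = TRUE), collapse = " "), con)
    writeLines(sprintf("%s %.8g %.8g %.8g", cf$species,
                       cf$positions[, 1], cf$positions[, 2],
                       cf$positions[, 3]), con)
  }
  invisible(path)
}

#' Read a pressure-tensor profile from TSV
#'
#' Columns: `z_nm`, `p_normal_MPa`, `p_tangential_MPa`.
#'
#' @param path File path.
#' @return A [pressure_profile()].
#' @export
read_pressure_profile_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("z_nm", "p_normal_MPa", "p_tangential_MPa")
  if (!all(need %in% names(df))) {
    stop(sprintf("pressure profile TSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  pressure_profile(df$z_nm, df$p_normal_MPa, df$p_tangential_MPa)
}

#' Write a pressure-tensor profile to TSV
#'
#' @param profile A [pressure_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pressure_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pressure_profile"))
  utils::write.table(
    data.frame(z_nm = profile$z, p_normal_MPa = profile$p_normal,
               p_tangential_MPa = profile$p_tangential),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate monolayer parameters for a set of curves
#'
#' Runs [parameters_at()] over a curve collection and assembles the
#' standard parameter table (one row per curve).
#'
#' @param curves List of [isotherm_curve()] objects (e.g. from
#'   [generate_condition_set()]).
#' @param ... Passed to [parameters_at()].
#' @return A data.frame with columns `model_id`, `scx4_conc_uM`,
#'   `replicate`, `a_ex_A2`, `a_30_A2`, `pi_col_mN_per_m`,
#'   `cs_max_mN_per_m`, `cs_30_mN_per_m`.
#' @export
parameter_table <- function(curves, ...) {
  rows <- lapply(curves, function(crv) {
    p <- parameters_at(crv, ...)
    data.frame(model_id = p$model_id, scx4_conc_uM = p$scx4_conc,
               replicate = crv$replicate, a_ex_A2 = p$a_ex,
               a_30_A2 = p$a_30, pi_col_mN_per_m = p$pi_col,
               cs_max_mN_per_m = p$cs_max, cs_30_mN_per_m = p$cs_30)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a density profile to TSV
#'
#' @param profile A `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  df <- data.frame(z_nm = profile$z_centers, profile$density,
                   check.names = FALSE)
  names(df)[-1] <- paste0("density_", colnames(profile$density), "_nm3")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a radial distribution (and PMF) to TSV
#'
#' Columns `r_nm`, `g` and, when present, `pmf_kBT`.
#'
#' @param rdf A `radial_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdf_tsv <- function(rdf, path) {
  stopifnot(inherits(rdf, "radial_distribution"))
  df <- data.frame(r_nm = rdf$r_centers, g = rdf$g)
  if (!is.null(rdf$pmf)) df$pmf_kBT <- rdf$pmf
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
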