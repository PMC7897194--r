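.pkg_version <- function() {
  as.character(utils::packageVersion("bqtaler"))
}

## Small stable hash for provenance headers (no external digest dependency)
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, ascii = TRUE, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed, config) {
  sprintf("# bqtaler %s seed=%s config=%s", .pkg_version(),
          if (is.null(seed)) "NA" else seed, config_hash(config))
}

write_csv_with_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    simulation = list(dt = 0.002, temperature = 308, friction = 10,
                      inertia = 0.05, n_steps = 500000L,
                      record_stride = 2500L),
    restraint = list(K_Jr = 50, tau_J_ps = 500, dJ_fb_Hz = 1.0,
                     N_le = 36L),
    system = NULL,   # optional: list(torsions = list(<name> = list(k, n, delta, theta0)))
    output = list(trajectory_csv = "traj.csv", weights_csv = NULL,
                  report_json = NULL)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) && path != "system" &&
        !startsWith(path, "system"))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !startsWith(full, "system"))
      defaults[key] <- list(.merge_config(defaults[[key]], user[[key]], full))
    else
      defaults[key] <- list(user[[key]])  # NULL-safe assignment
  }
  defaults
}

.validate_config <- function(cfg) {
  r <- cfg$restraint
  if (r$tau_J_ps <= 0) stop("configuration error: restraint.tau_J_ps must be > 0")
  if (r$dJ_fb_Hz < 0) stop("configuration error: restraint.dJ_fb_Hz must be >= 0")
  if (r$K_Jr < 0) stop("configuration error: restraint.K_Jr must be >= 0")
  if (r$N_le < 2) stop("configuration error: restraint.N_le must be >= 2")
  s <- cfg$simulation
  if (s$dt <= 0) stop("configuration error: simulation.dt must be > 0")
  if (s$temperature <= 0) stop("configuration error: simulation.temperature must be > 0")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills in the method defaults
#' (K_Jr = 50 kJ mol^-1 Hz^-4, tau_J = 500 ps, dJ_fb = 1.0 Hz, N_le = 36)
#' and validates the result. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' not found", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .validate_config(.merge_config(.default_config(), user))
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param config A `run_config` (or plain list).
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a restraint table
#'
#' CSV with columns `residue`, `coupling_kind`, `J_exp_Hz` and optionally
#' `set_label`, `residue_type` (for single beta-hydrogen couplings) and
#' `torsion` (target torsion name). Comment lines starting with `#` are
#' ignored.
#'
#' @param path CSV file.
#' @return Data frame of restraint rows.
#' @export
read_restraint_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("residue", "coupling_kind", "J_exp_Hz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("restraint table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df
}

#' Build restraint specifications from a restraint table
#'
#' Experimental couplings are capped at the attainable range of their
#' Karplus curve before becoming targets.
#'
#' @param table Data frame from [read_restraint_table()].
#' @param K_Jr,tau_J,dJ_fb,N_le Restraint parameters applied to every row.
#' @return List of [restraint_spec()] objects (one per row), each carrying
#'   a `torsion` attribute when the table has a `torsion` column.
#' @export
restraints_from_table <- function(table, K_Jr = 50, tau_J = 500,
                                  dJ_fb = 1.0, N_le = 36L) {
  lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    residue <- if ("residue_type" %in% names(table))
      row$residue_type else substr(row$residue, 1, 3)
    defn <- if (row$coupling_kind == "HA-HB_single")
      coupling_definition(row$coupling_kind, residue = residue)
    else coupling_definition(row$coupling_kind)
    spec <- restraint_spec(cap_to_curve(defn$params, row$J_exp_Hz), defn,
                           dJ_fb = dJ_fb, K_Jr = K_Jr, tau_J = tau_J,
                           N_le = N_le)
    if ("torsion" %in% names(table)) attr(spec, "torsion") <- row$torsion
    spec
  })
}

#' Write a trajectory record to CSV
#'
#' @param record A `trajectory_record` from [integrate_system()].
#' @param path Output CSV.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(record, path, seed = NULL) {
  stopifnot(inherits(record, "trajectory_record"))
  write_csv_with_header(record$frames, path, seed = seed,
                        config = record$config)
}

#' Write local-elevation weight profiles to CSV
#'
#' One block of rows per restraint, mirroring the weight-versus-angle
#' fingerprint a restrained run builds up.
#'
#' @param record A `trajectory_record`.
#' @param path Output CSV.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_weight_profiles <- function(record, path, seed = NULL) {
  stopifnot(inherits(record, "trajectory_record"))
  profs <- lapply(seq_along(record$states), function(r) {
    p <- le_profile(record$states[[r]])
    cbind(restraint = r, p)
  })
  df <- do.call(rbind, profs)
  write_csv_with_header(df, path, seed = seed, config = record$config)
}

#' Generate the deterministic fixture bundle
#'
#' Writes, under `dir`: configuration and restraint tables for the three
#' demonstration scenarios, a synthetic coupling-comparison table with a
#' pre-computed deviation histogram, a synthetic stereo-pair table with a
#' known consensus assignment, and a rigid-vector series whose order
#' parameter is exactly 1. All files are byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the synthetic tables.
#' @return Invisibly, the list of files written.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  scen <- fixture_scenarios()

  for (s in scen) {
    base <- file.path(dir, s$name)
    cfg <- .default_config()
    cfg$seed <- as.integer(seed)
    cfg$simulation$n_steps <- s$n_steps
    cfg$simulation$record_stride <- s$record_stride
    cfg$restraint$tau_J_ps <- s$restraint$tau_J
    pot <- s$system$potentials[[1]]
    cfg$system <- list(torsions = stats::setNames(list(list(
      k = pot$k, n = pot$n, delta = pot$delta,
      theta0 = as.numeric(s$system$theta0[1]))), s$torsion))
    save_config(cfg, paste0(base, "_config.yaml"))
    rt <- data.frame(residue = s$name,
                     coupling_kind = s$restraint$coupling$kind,
                     J_exp_Hz = s$restraint$J0,
                     set_label = "fixture",
                     residue_type = if (is.null(s$restraint$coupling$residue))
                       "" else s$restraint$coupling$residue,
                     torsion = s$torsion)
    write_csv_with_header(rt, paste0(base, "_restraints.csv"),
                          seed = seed, config = cfg)
    files <- c(files, paste0(base, "_config.yaml"),
               paste0(base, "_restraints.csv"))
  }

  # synthetic comparison table with a known deviation histogram:
  # deviations drawn per target bin, then shuffled
  dev_targets <- c(rep(0.4, 6), rep(1.5, 4), rep(2.5, 3), rep(3.5, 2),
                   rep(4.5, 1), rep(5.5, 1))
  hist_known <- c(4L, 3L, 2L, 1L, 1L)
  dev <- sample(dev_targets)
  J_exp <- round(stats::runif(length(dev), 4, 9.5), 1)
  sgn <- sample(c(-1, 1), length(dev), replace = TRUE)
  comp <- data.frame(label = sprintf("res%02d", seq_along(dev)),
                     J_exp = J_exp,
                     calc_md = J_exp - sgn * dev)
  comp_path <- file.path(dir, "synthetic_comparisons.csv")
  write_csv_with_header(comp, comp_path, seed = seed, config = hist_known)
  jsonlite::write_json(
    list(version = .pkg_version(), seed = seed,
         histogram = as.integer(hist_known)),
    file.path(dir, "synthetic_comparisons_expected.json"),
    auto_unbox = TRUE)

  # synthetic stereo pairs: three sources agree on the direct pairing,
  # one suggests the swap
  stereo <- data.frame(
    label = "pair1", J_exp_1 = 8.0, J_exp_2 = 6.1,
    src1_HB2 = 7.8, src1_HB3 = 5.9,
    src2_HB2 = 7.5, src2_HB3 = 6.3,
    src3_HB2 = 8.2, src3_HB3 = 5.8,
    src4_HB2 = 6.0, src4_HB3 = 8.1)
  stereo_path <- file.path(dir, "synthetic_stereo.csv")
  write_csv_with_header(stereo, stereo_path, seed = seed,
                        config = "HB2|HB3")

  # rigid vector series: S2 is exactly 1
  vec <- data.frame(time_ps = seq(0, 999), x = 0.1, y = 0.05, z = 0.02)
  vec_path <- file.path(dir, "rigid_vectors.csv")
  write_csv_with_header(vec, vec_path, seed = seed, config = "rigid")

  invisible(c(files, comp_path, stereo_path, vec_path,
              file.path(dir, "synthetic_comparisons_expected.json")))
}
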