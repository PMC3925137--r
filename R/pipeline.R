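# Orchestration: a validated configuration drives window -> geometry metrics
# -> quasi-harmonic analysis -> mode classification -> mechanical inversion,
# writing tidy TSV tables and returning a machine-readable report.

.config_defaults <- function() {
  list(
    input = NULL,                 # PDB or XYZ trajectory path
    input_format = "auto",        # "pdb", "xyz", or "auto" by extension
    temperature = 300,            # K
    discard_fraction = 0.5,       # leading frames dropped before analysis
    stride = 1,
    n_rigid = 6,
    calpha_mass = 12.011,         # Da per C-alpha site
    align = TRUE,
    alpha_variant = "variance_fraction",
    op_variant = "variance",
    hbond = list(distance = 3.5, angle = 150, fallback_distance = 3.2),
    probe_radius = 1.4,           # A, water probe
    sasa_points = 960,
    section = list(model = "envelope", r_eff = 3),
    n_orders = 4,
    seed = 1,
    outdir = NULL
  )
}

#' Validate an analysis configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and type/range-checks
#' every entry; unknown keys are rejected. Defaults: temperature 300 K,
#' discard_fraction 0.5, stride 1, n_rigid 6, water probe 1.4 A.
#'
#' @param config Path to a YAML file, or a named list of overrides (an empty
#'   file or list yields pure defaults).
#' @return Fully-defaulted, validated configuration list of class
#'   `analysis_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  with(cfg, {
    stopifnot(temperature > 0, stride >= 1, n_rigid >= 0, calpha_mass > 0,
              probe_radius > 0, sasa_points >= 16, n_orders >= 1)
  })
  if (cfg$discard_fraction < 0 || cfg$discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  if (!cfg$alpha_variant %in% c("variance_fraction", "rmsf_fraction"))
    stop("alpha_variant must be 'variance_fraction' or 'rmsf_fraction'")
  if (!cfg$op_variant %in% c("variance", "circular_sd"))
    stop("op_variant must be 'variance' or 'circular_sd'")
  if (!cfg$section$model %in% c("envelope", "fixed"))
    stop("section model must be 'envelope' or 'fixed'")
  class(cfg) <- c("analysis_config", "list")
  cfg
}

.config_fingerprint <- function(cfg) {
  s <- utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE))
  sprintf("%08x", sum(utf8ToInt(paste(s, collapse = "")) *
                        (seq_len(nchar(paste(s, collapse = ""))) %% 97 + 1)) %% .Machine$integer.max)
}

.write_tsv <- function(df, path, unit_comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(unit_comment)) writeLines(paste0("# ", unit_comment), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full fluctuation-to-mechanics analysis
#'
#' Stages: load (unless a trajectory object is supplied) -> window -> C-alpha
#' selection -> conformational metrics (RMSD series; layer dihedrals, order
#' parameter and bending angle when the topology carries layers; H-bond
#' density and SASA when backbone atoms are present) -> fluctuation matrix ->
#' spectral decomposition -> mode classification -> mechanical inversion.
#' Numeric outputs are fully determined by the configuration and input.
#'
#' @param config An [validate_config()] result, path, or override list.
#' @param trajectory Optional `fibril_trajectory` (bypasses `config$input`).
#' @return Object of class `fibril_report`: list with `metrics`,
#'   `spectrum`, `contributions`, `assignment`, `mechanics`, `geometry`,
#'   `provenance`, `warnings`.
#' @export
run_analysis <- function(config = list(), trajectory = NULL) {
  cfg <- if (inherits(config, "analysis_config")) config else validate_config(config)
  warn <- character(0)
  if (is.null(trajectory)) {
    if (is.null(cfg$input)) stop("config$input required when no trajectory given")
    if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
    fmt <- cfg$input_format
    if (fmt == "auto")
      fmt <- if (grepl("\\.xyz$", cfg$input, ignore.case = TRUE)) "xyz" else "pdb"
    trajectory <- if (fmt == "xyz") read_xyz_trajectory(cfg$input)
                  else read_pdb(cfg$input)$trajectory
  }
  traj <- window_frames(trajectory, cfg$discard_fraction, cfg$stride)
  ca <- select_calpha(traj)

  metrics <- list(rmsd = rmsd_series(ca))
  have_layers <- !anyNA(ca$atoms$layer_index) &&
    length(unique(ca$atoms$layer_index)) >= 3
  if (have_layers) {
    nf <- n_frames(ca)
    dihed <- t(vapply(seq_len(nf), function(i)
      layer_dihedral(frame_coords(ca, i), ca$atoms$layer_index),
      numeric(length(unique(ca$atoms$layer_index)) - 1)))
    metrics$dihedral_mean <- rowMeans(dihed)
    metrics$order_parameter <- apply(dihed, 1, order_parameter, variant = cfg$op_variant)
    metrics$bending_angle <- vapply(seq_len(nf), function(i)
      bending_angle(frame_coords(ca, i), ca$atoms$layer_index), numeric(1))
  }
  if (all(c("N", "O") %in% traj$atoms$atom_name)) {
    hb <- hbonds_per_residue(traj, dist_cutoff = cfg$hbond$distance,
                             angle_cutoff = cfg$hbond$angle,
                             fallback_dist = cfg$hbond$fallback_distance)
    metrics$hbonds_per_residue <- hb$series
    last <- frame_coords(traj, n_frames(traj))
    sa <- sasa(last, vdw_radii(traj$atoms$element), probe = cfg$probe_radius,
               n_sphere_points = cfg$sasa_points)
    metrics$sasa_final_A2 <- sa$total
    metrics$dG_np_kcal_mol <- nonpolar_solvation(sa$total)
  }

  Q <- fluctuation_matrix(ca, align = cfg$align)
  spec <- spectral_decompose(Q, temperature = cfg$temperature,
                             calpha_mass = cfg$calpha_mass)
  contrib <- mode_contributions(spec, n_rigid = cfg$n_rigid)
  if (cfg$alpha_variant == "rmsf_fraction") {
    a <- sqrt(contrib$modes$xi_A2); contrib$modes$alpha <- a / sum(a)
  }
  ms <- mean_structure(ca)
  # one mass per C-alpha site, consistently: the same calpha_mass that sets
  # the quasi-harmonic frequencies also sets mu and the rotary inertia
  # (formats like PDB carry no masses)
  ms$atoms$mass <- cfg$calpha_mass
  assignment <- classify_modes(spec, ms, n_orders = cfg$n_orders)
  geom <- if (cfg$section$model == "fixed") {
    estimate_cross_section(ms, "fixed", A = cfg$section$A,
                           I_y = cfg$section$I_y, I_z = cfg$section$I_z,
                           J = cfg$section$J)
  } else {
    estimate_cross_section(ms, "envelope",
                           r_eff = if (is.null(cfg$section$r_eff)) 3 else cfg$section$r_eff)
  }
  mech <- fibril_mechanics(spec, assignment, geom, n_rigid = cfg$n_rigid)

  report <- structure(list(
    metrics = metrics, spectrum = spec, contributions = contrib,
    assignment = assignment, mechanics = mech, geometry = geom,
    provenance = list(config = cfg, fingerprint = .config_fingerprint(cfg),
                      package_version = as.character(utils::packageVersion("fibrilmech")),
                      n_frames_analyzed = n_frames(ca),
                      n_atoms = nrow(ca$atoms),
                      switches = list(alpha_variant = cfg$alpha_variant,
                                      op_variant = cfg$op_variant,
                                      hbond = cfg$hbond,
                                      section = cfg$section$model)),
    warnings = warn), class = "fibril_report")

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    freqs <- natural_frequencies(spec, n_rigid = cfg$n_rigid)
    qha <- merge(freqs, contrib$modes[, c("mode", "alpha")], by = "mode",
                 all.x = TRUE, sort = TRUE)
    .write_tsv(qha[order(qha$mode), ], file.path(cfg$outdir, "spectrum.tsv"),
               "mode | xi_A2 [A^2] | omega_rad_s [rad/s] | nu_THz [THz] | alpha [-]")
    .write_tsv(as.data.frame(assignment), file.path(cfg$outdir, "modes.tsv"),
               "mode | family | order | overlap [-] | xi_A2 [A^2]")
    .write_tsv(as.data.frame(mech), file.path(cfg$outdir, "mechanics.tsv"),
               "rigidity [N m^2 (bend/torsion) or N (axial)] | modulus [Pa] | persistence_length [m]")
    met_df <- data.frame(frame = seq_along(metrics$rmsd), rmsd_A = metrics$rmsd)
    for (nm in c("dihedral_mean", "order_parameter", "bending_angle",
                 "hbonds_per_residue"))
      if (!is.null(metrics[[nm]])) met_df[[nm]] <- metrics[[nm]]
    .write_tsv(met_df, file.path(cfg$outdir, "metrics.tsv"),
               "rmsd [A] | dihedral [deg] | order parameter [rad^2] | bending angle [deg] | hbonds per residue [-]")
  }
  report
}

#' @export
print.fibril_report <- function(x, ...) {
  cat("Fibril fluctuation analysis report\n")
  cat(sprintf("  %d frames x %d C-alpha sites (config %s)\n",
              x$provenance$n_frames_analyzed, x$provenance$n_atoms,
              x$provenance$fingerprint))
  cat(sprintf("  RMSF = %.3f A over retained modes\n", x$contributions$rmsf_total))
  if (!is.null(x$mechanics) && nrow(x$mechanics)) {
    cat("  mechanics (lowest-order mode per family):\n")
    print(as.data.frame(x$mechanics), digits = 3)
  }
  invisible(x)
}
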