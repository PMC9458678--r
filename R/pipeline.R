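# Workflow entry points tying the stages together: primary SAXS analysis of
# a curve file, synthetic-data generation, and ensemble reweighting in
# either inference mode. Each run validates its configuration, writes all
# results as JSON/flat tables into an output directory, and serialises the
# resolved configuration (including seeds) so runs are reproducible.

default_run_config <- function() {
  list(
    min_cluster_size = 5,
    distance_threshold = 0.15,
    mc_steps = 51000,
    mc_burn = 1000,
    seed = 1,
    theta_grid = 10^seq(-2, 6, length.out = 13),
    bins = 40,
    temperature = 300,
    qrg_limit = 1.3,
    noise_fraction = 0.01,
    n_conformers = 50,
    form_factor_model = "unit"
  )
}

#' Resolve and validate a run configuration
#'
#' Merges user settings (a named list or a YAML file path) over the
#' defaults and validates types and ranges before any computation.
#'
#' @param config named list, path to a YAML file, or `NULL` for defaults.
#' @return validated configuration list.
#' @export
resolve_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(base, config)
  stopifnot(
    cfg$min_cluster_size >= 2, cfg$distance_threshold > 0,
    cfg$mc_steps > cfg$mc_burn, cfg$mc_burn >= 0,
    all(cfg$theta_grid > 0), cfg$bins >= 2, cfg$temperature > 0,
    cfg$qrg_limit > 0, cfg$noise_fraction >= 0, cfg$n_conformers >= 1
  )
  cfg
}

write_run_config <- function(cfg, out_dir) {
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
}

#' Primary SAXS analysis of a curve file
#'
#' Reads a 3-column (q, I, sigma) curve, performs Guinier analysis, the
#' dimensionless Kratky transform and writes a JSON summary plus the
#' transformed series into `out_dir`.
#'
#' @param curve_file path to a SAXS curve file.
#' @param out_dir output directory (created if missing).
#' @param config see [resolve_config()].
#' @return (invisibly) list with `guinier`, `kratky`, `summary`.
#' @export
analyze_saxs_run <- function(curve_file, out_dir, config = NULL) {
  cfg <- resolve_config(config)
  curve <- read_saxs_curve(curve_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gf <- guinier_fit(curve, qrg_limit = cfg$qrg_limit)
  kr <- kratky_dimensionless(curve, gf)
  summary <- list(
    rg = gf$rg, rg_se = gf$rg_se, i0 = gf$i0,
    q_min = gf$q_min, q_max = gf$q_max, n_points = gf$n_points,
    qrg_max = gf$qrg_max
  )
  jsonlite::write_json(summary, file.path(out_dir, "guinier.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(kr, file.path(out_dir, "kratky.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_run_config(cfg, out_dir)
  invisible(list(guinier = gf, kratky = kr, summary = summary))
}

#' Generate a synthetic benchmark data set
#'
#' Creates a toy multidomain ensemble, draws sparse ground-truth weights,
#' synthesizes a noisy SAXS observation, and writes the ensemble (PDB),
#' curve, per-frame profiles and truth record to `out_dir`.
#'
#' @param out_dir output directory.
#' @param config see [resolve_config()]; uses `n_conformers`,
#'   `noise_fraction`, `seed`.
#' @param true_weights optional explicit simplex weights (default: uniform).
#' @param q_grid momentum-transfer grid.
#' @return (invisibly) list with `toy`, `synthetic`, `truth`.
#' @export
simulate_run <- function(out_dir, config = NULL, true_weights = NULL,
                         q_grid = seq(0.005, 0.3, length.out = 120)) {
  cfg <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  toy <- generate_toy_ensemble(cfg$n_conformers, seed = cfg$seed)
  if (is.null(true_weights)) {
    true_weights <- rep(1 / cfg$n_conformers, cfg$n_conformers)
  }
  syn <- generate_synthetic_saxs(toy$ensemble, true_weights, q_grid,
                                 cfg$noise_fraction, seed = cfg$seed + 1L)
  write_pdb_models(toy$ensemble, file.path(out_dir, "ensemble.pdb"))
  write_saxs_curve(syn$curve, file.path(out_dir, "observed.dat"))
  jsonlite::write_json(
    list(true_weights = syn$truth$true_weights,
         noise_fraction = syn$truth$noise_fraction,
         seed = syn$truth$seed,
         generator_version = syn$truth$generator_version),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  write_run_config(cfg, out_dir)
  invisible(list(toy = toy, synthetic = syn, truth = syn$truth))
}

#' Reweight an ensemble against a SAXS curve
#'
#' Full inference pass: forward Debye profiles for every frame, then either
#' the maximum-parsimony track (structural clustering of C-alpha distance
#' features, profile clustering into a basis set, Metropolis posterior
#' sampling) or the maximum-entropy track (theta scan with L-curve elbow
#' selection). Per-frame weights, diagnostics, seeds and the configuration
#' are written to `out_dir`.
#'
#' @param ensemble atom tibble (multi-frame), e.g. from [read_coordinates()].
#' @param curve experimental scattering-curve tibble with `sigma` (or file
#'   path).
#' @param mode `"maxpars"` or `"maxent"`.
#' @param out_dir output directory.
#' @param config see [resolve_config()].
#' @return (invisibly) a list with per-frame `weights` and the mode-specific
#'   fit objects.
#' @export
reweight_run <- function(ensemble, curve, mode = c("maxpars", "maxent"),
                         out_dir, config = NULL) {
  mode <- match.arg(mode)
  cfg <- resolve_config(config)
  if (is.character(curve)) curve <- read_saxs_curve(curve)
  if (!"sigma" %in% names(curve)) abort("experimental curve lacks sigma")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frames <- ensemble_frames(ensemble)
  profiles <- lapply(frames, debye_curve, q = curve$q,
                     form_factor_model = cfg$form_factor_model)
  nfr <- length(frames)
  if (mode == "maxpars") {
    core <- hoip_domains()[hoip_domains()$name %in% c("RING1", "IBR", "RING2"), ]
    feats <- ca_distance_features(ensemble, core)
    assign_tbl <- cluster_conformers(feats, cfg$min_cluster_size)
    reps <- assign_tbl$frame[assign_tbl$representative]
    if (length(reps) < 2) {
      reps <- seq_len(nfr)  # no structural substructure: use all frames
    }
    basis <- cluster_profiles(profiles[reps], curve$sigma,
                              cfg$distance_threshold)
    post <- sample_posterior(basis, curve, steps = cfg$mc_steps,
                             burn = cfg$mc_burn, seed = cfg$seed)
    summ <- summarize_weights(post)
    basis_frames <- reps[basis$members]
    weights <- rep(0, nfr)
    weights[basis_frames] <- summ$mean
    fit <- fit_to_experiment(
      weighted_average_profile(summ$mean, basis$profiles), curve
    )
    jsonlite::write_json(
      list(mode = mode, basis_frames = basis_frames,
           weights = summ$mean, weight_sd = summ$sd,
           acceptance = post$acceptance, steps = post$steps,
           burn = post$burn, seed = post$seed,
           chi2_red = fit$chi2_red),
      file.path(out_dir, "maxpars.json"), auto_unbox = TRUE, digits = NA
    )
    result <- list(weights = weights, basis = basis, posterior = post,
                   assignments = assign_tbl, fit = fit)
  } else {
    lc <- theta_scan(profiles, curve, theta_grid = cfg$theta_grid)
    weights <- lc$selected$weights
    jsonlite::write_json(
      list(mode = mode, theta = lc$selected_theta,
           s_kl = lc$selected$s_kl, chi2_red = lc$selected$chi2_red,
           converged = lc$selected$converged,
           lcurve = lapply(seq_len(nrow(lc$curve)), function(i) as.list(lc$curve[i, ]))),
      file.path(out_dir, "maxent.json"), auto_unbox = TRUE, digits = NA
    )
    result <- list(weights = weights, lcurve = lc, fit = lc$selected)
  }
  write.table(
    data.frame(frame = seq_len(nfr), weight = weights),
    file.path(out_dir, "weights.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE
  )
  write_run_config(cfg, out_dir)
  invisible(result)
}
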