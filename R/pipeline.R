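# Configuration, pipeline stages and the command-line workflow.
#
# A single global seed fans out to per-stage seeds (derive_seed), so the
# full pipeline is deterministic end to end and each stage is reproducible
# in isolation. Every artifact embeds the config hash and the seed.

.schema <- list(
  seed = "scalar", outdir = "scalar",
  system = list(kind = "scalar", n_particles = "scalar", dim = "scalar",
                spring = "scalar", tether = "scalar", n_bath = "scalar",
                a = "scalar", d0 = "scalar", k_bath = "scalar",
                c_couple = "scalar"),
  mapping = list(sites = "vector"),
  noise = list(sigma2 = "scalar"),
  force_map = list(l2_atom = "scalar", l2_noise = "scalar",
                   n_noise_draws = "scalar"),
  data = list(sampler = "scalar", n_frames = "scalar", traj_len = "scalar",
              timestep = "scalar", friction = "scalar", stride = "scalar",
              basins = "list"),
  training = list(mode = "scalar", method = "scalar", basis = "scalar",
                  n_centers = "scalar", rbf_width = "scalar",
                  n_draws = "scalar", ridge = "scalar"),
  dynamics = list(timestep = "scalar", friction = "scalar", kT = "scalar",
                  n_steps = "scalar", stride = "scalar"),
  analysis = list(cv_min = "scalar", cv_max = "scalar", n_bins = "scalar",
                  cutoff_kT = "scalar")
)

#' Validate a run configuration
#'
#' Checks the nested config against the schema: unknown keys are rejected
#' with the offending path, required sections are present.
#'
#' @param config Nested list (typically from a YAML file).
#' @return The config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  check <- function(node, schema, path) {
    for (key in names(node)) {
      if (!key %in% names(schema))
        stop(sprintf("unknown config key '%s%s'", path, key))
      if (is.list(schema[[key]]) && is.list(node[[key]]))
        check(node[[key]], schema[[key]], paste0(path, key, "/"))
    }
  }
  check(config, .schema, "")
  for (req in c("seed", "system")) {
    if (is.null(config[[req]]))
      stop(sprintf("config lacks required section '%s'", req))
  }
  invisible(config)
}

#' Built-in run configurations
#'
#' `gaussian2`: the two-particle Gaussian network worked example (slice map
#' to particle 1, quadratic basis; the trained curvature is checked against
#' the closed-form noised-marginal precision). `double_well`: the double-well
#' chain with biased short-trajectory data, slice map to the bond particles
#' and an RBF basis over the signed bond displacement.
#'
#' @param name Preset name.
#' @return A validated config list.
#' @export
preset_config <- function(name = c("gaussian2", "double_well")) {
  name <- match.arg(name)
  cfg <- switch(name,
    gaussian2 = list(
      seed = 1, outdir = tempfile("cgnoise_run_"),
      system = list(kind = "gaussian_network", n_particles = 2, dim = 1,
                    spring = 1, tether = 1),
      mapping = list(sites = 1),
      noise = list(sigma2 = 0.1),
      force_map = list(l2_atom = 0, l2_noise = 5, n_noise_draws = 4),
      data = list(sampler = "exact", n_frames = 20000),
      training = list(mode = "combined", method = "closed_form",
                      basis = "quadratic", n_draws = 4, ridge = 0),
      dynamics = list(timestep = 0.05, friction = 1, kT = 1,
                      n_steps = 20000, stride = 10),
      analysis = list(cv_min = -4, cv_max = 4, n_bins = 61, cutoff_kT = 9)),
    double_well = list(
      seed = 1, outdir = tempfile("cgnoise_run_"),
      system = list(kind = "double_well_chain", n_bath = 4, a = 6, d0 = 1,
                    k_bath = 100, c_couple = 0.5),
      mapping = list(sites = c(1, 2)),
      noise = list(sigma2 = 0.003),
      force_map = list(l2_atom = 0, l2_noise = 5, n_noise_draws = 4),
      data = list(sampler = "biased", traj_len = 50, n_frames = 2000,
                  timestep = 0.01, friction = 1, stride = 10),
      training = list(mode = "combined", method = "closed_form",
                      basis = "rbf_displacement", n_centers = 13,
                      rbf_width = 0.35, n_draws = 8, ridge = 1e-6),
      dynamics = list(timestep = 0.01, friction = 1, kT = 1,
                      n_steps = 20000, stride = 10),
      analysis = list(cv_min = -1.9, cv_max = 1.9, n_bins = 39,
                      cutoff_kT = 9))
  )
  validate_run_config(cfg)
  cfg
}

# Hash of the scientific configuration; the artifact location is excluded
# so identical runs in different directories share a hash.
.config_hash <- function(config) {
  config$outdir <- NULL
  .object_hash(config)
}

.build_system <- function(sc) {
  switch(sc$kind,
    gaussian_network = make_gaussian_network(
      sc$n_particles, dim = if (is.null(sc$dim)) 1 else sc$dim,
      coupling_spec = list(spring = sc$spring, tether = sc$tether)),
    double_well_chain = make_double_well_chain(
      n_bath = sc$n_bath,
      params = list(a = sc$a, d0 = sc$d0, k_bath = sc$k_bath,
                    c_couple = sc$c_couple)),
    stop(sprintf("unknown system kind '%s'", sc$kind))
  )
}

.build_mapping <- function(config, system) {
  cg_mapping(sites = config$mapping$sites, n_fine = system$n_particles)
}

# Default biased seeding for the double-well chain: 80/20 basin split.
.default_basins <- function(system, n_trajs) {
  p <- system$params
  mk <- function(d) matrix(c(-d / 2, d / 2, rep(0, p$n_bath)), ncol = 1)
  nA <- round(0.8 * n_trajs)
  list(list(init = mk(-p$d0), n_traj = nA, label = "A"),
       list(init = mk(p$d0), n_traj = n_trajs - nA, label = "B"))
}

.generate_dataset <- function(config, system) {
  dc <- config$data
  seed <- derive_seed(config$seed, "generate")
  if (identical(dc$sampler, "exact")) {
    return(sample_gaussian_exact(system, dc$n_frames, seed = seed))
  }
  cfg <- integrator_config(timestep = dc$timestep, friction = dc$friction,
                           stride = dc$stride, seed = seed)
  if (identical(dc$sampler, "langevin")) {
    return(sample_fine_langevin(system, dc$n_frames * dc$stride, cfg,
                                seed = seed))
  }
  n_trajs <- ceiling(dc$n_frames / dc$traj_len)
  basins <- if (!is.null(dc$basins)) {
    lapply(dc$basins, function(b)
      list(init = matrix(unlist(b$init), ncol = 1), n_traj = b$n_traj,
           label = b$label))
  } else .default_basins(system, n_trajs)
  make_biased_dataset(system, basins, dc$traj_len, cfg, seed = seed)
}

.build_basis <- function(config, mapping, system) {
  tc <- config$training
  N <- nrow(mapping$matrix)
  dim <- system$dim
  switch(tc$basis,
    quadratic = feature_quadratic(N, dim),
    rbf_displacement = {
      w <- numeric(N * dim); w[1] <- -1; w[2] <- 1
      feature_rbf_projection(w, centers = seq(config$analysis$cv_min,
                                              config$analysis$cv_max,
                                              length.out = tc$n_centers),
                             width = tc$rbf_width)
    },
    stop(sprintf("unknown basis '%s'", tc$basis))
  )
}

.fit_model <- function(config, dataset, mapping, system) {
  tc <- config$training
  kernel <- if (tc$mode == "forces") NULL
            else noise_kernel(config$noise$sigma2, warn = FALSE)
  t_atom <- if (config$force_map$l2_atom == 0 && mapping$is_slice)
    slice_map(mapping)
  else optimize_atomistic_map(dataset, mapping,
                              l2_atom = config$force_map$l2_atom)
  v_map <- if (tc$mode == "combined") {
    optimize_noise_stage(dataset, mapping, t_atom, kernel,
                         l2_noise = config$force_map$l2_noise,
                         n_noise_draws = config$force_map$n_noise_draws,
                         seed = derive_seed(config$seed, "vmap"))
  } else if (tc$mode == "noise") noise_only_map(nrow(mapping$matrix))
  else NULL
  basis <- .build_basis(config, mapping, system)
  te <- trainable_energy("linear", basis)
  fit <- fit_linear_closed_form(te, dataset, mapping, t_atom = t_atom,
                                v_map = v_map, kernel = kernel,
                                mode = tc$mode,
                                seed = derive_seed(config$seed, "train"),
                                n_draws = if (is.null(tc$n_draws)) 1
                                          else tc$n_draws,
                                ridge = if (is.null(tc$ridge)) 0 else tc$ridge)
  list(potential = fit$potential, t_atom = t_atom, v_map = v_map,
       kernel = kernel, residual_msq = fit$residual_msq)
}

#' Run the full pipeline for a configuration
#'
#' generate -> map/force-map -> train -> simulate -> analyze. Each stage
#' writes a versioned artifact (RDS container) plus one structured log
#' record with timing, the config hash and the stage seed. Returns the paths
#' and headline scalars.
#'
#' @param config A validated config list (see [preset_config()]).
#' @return List with `artifacts` (paths), `summary` (key scalars) and the
#'   config hash.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  log <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      config_hash = hash, seed = derive_seed(config$seed, stage))
    val
  }
  system <- .build_system(config$system)
  dataset <- tick("generate", .generate_dataset(config, system))
  write_dataset(dataset, file.path(outdir, "dataset.rds"))
  mapping <- .build_mapping(config, system)
  model <- tick("train", .fit_model(config, dataset, mapping, system))
  saveRDS(list(model = model, config_hash = hash, seed = config$seed),
          file.path(outdir, "model.rds"), version = 2)

  # simulate the learned CG potential
  dyn <- config$dynamics
  R0 <- apply_map(mapping, .frame(dataset$positions, 1))
  icfg <- integrator_config(timestep = dyn$timestep, friction = dyn$friction,
                            kT = dyn$kT, n_steps = dyn$n_steps,
                            stride = dyn$stride,
                            seed = derive_seed(config$seed, "simulate"))
  traj <- tick("simulate", langevin_run(model$potential, R0, icfg))
  write_traj(traj, file.path(outdir, "traj.rds"))

  # analysis: FES of model and reference along the preset coordinate
  an <- config$analysis
  breaks <- seq(an$cv_min, an$cv_max, length.out = an$n_bins + 1)
  summary <- tick("analyze", .analyze_run(config, system, mapping, model,
                                          traj, breaks))
  write.table(summary$table, file.path(outdir, "fes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  logdf <- do.call(rbind, log)
  write.table(logdf, file.path(outdir, "log.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  list(artifacts = list(
         dataset = file.path(outdir, "dataset.rds"),
         model = file.path(outdir, "model.rds"),
         traj = file.path(outdir, "traj.rds"),
         fes = file.path(outdir, "fes.tsv"),
         log = file.path(outdir, "log.tsv")),
       summary = summary$scalars, config_hash = hash)
}

.analyze_run <- function(config, system, mapping, model, traj, breaks) {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (system$kind == "gaussian_network") {
    oracle <- gaussian_oracles(system, mapping, config$noise$sigma2,
                               grid = mids)
    # curvature of the learned energy at the origin (single CG site)
    h <- 1e-4
    curv <- (cg_energy(model$potential, matrix(h)) -
             2 * cg_energy(model$potential, matrix(0)) +
             cg_energy(model$potential, matrix(-h))) / h^2
    ref <- oracle$precision[1, 1]
    tab <- data.frame(cv = mids, reference = pmf_eval(oracle, mids),
                      model = 0.5 * curv * mids^2)
    scalars <- list(curvature = curv, curvature_ref = ref,
                    curvature_relerr = abs(curv - ref) / ref)
  } else {
    oracle <- quadrature_pmf(system, "bond_displacement", mids)
    fes_ref <- fes_from_oracle(oracle, breaks)
    fes_mod <- fes_from_potential(model$potential, breaks)
    err <- fes_error(fes_mod, fes_ref, cutoff_kT = config$analysis$cutoff_kT)
    d_series <- compute_cv(traj, cv_spec("linear_projection",
                                         w = c(-1, 1)))
    tab <- data.frame(cv = mids, reference = fes_ref$free_energy,
                      model = fes_mod$free_energy)
    scalars <- list(fes_error = err,
                    traj_mean_abs_d = mean(abs(d_series)))
  }
  list(table = tab, scalars = scalars)
}

#' Data-efficiency benchmark
#'
#' Sweeps training mode x noise level x dataset size on the double-well
#' chain, refitting the model and measuring the FES error against the
#' quadrature PMF for each cell, over several seeds. Mirrors the
#' accuracy-versus-training-size analysis at toy scale.
#'
#' @param n_frames_grid Dataset sizes (frames).
#' @param sigma2s Noise levels; 0 denotes the forces-only mode.
#' @param modes Modes evaluated at each positive noise level.
#' @param n_seeds Independent seeds per cell.
#' @param seed Global seed.
#' @param config Base config (default: the `double_well` preset).
#' @return Data frame with columns seed, sigma2, mode, n_frames, fes_error.
#' @export
benchmark_data_efficiency <- function(n_frames_grid = c(2000),
                                      sigma2s = c(0, 5e-4, 0.003, 0.005),
                                      modes = c("combined", "noise"),
                                      n_seeds = 5, seed = 1,
                                      config = preset_config("double_well")) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    for (nf in n_frames_grid) {
      cfg <- config
      cfg$seed <- derive_seed(seed, paste0("bench", s))
      cfg$data$n_frames <- nf
      system <- .build_system(cfg$system)
      dataset <- .generate_dataset(cfg, system)
      mapping <- .build_mapping(cfg, system)
      an <- cfg$analysis
      breaks <- seq(an$cv_min, an$cv_max, length.out = an$n_bins + 1)
      mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
      fes_ref <- fes_from_oracle(
        quadrature_pmf(system, "bond_displacement", mids), breaks)
      for (s2 in sigma2s) {
        mds <- if (s2 == 0) "forces" else modes
        for (md in mds) {
          cfg$noise$sigma2 <- s2
          cfg$training$mode <- md
          model <- .fit_model(cfg, dataset, mapping, system)
          err <- fes_error(fes_from_potential(model$potential, breaks),
                           fes_ref, cutoff_kT = an$cutoff_kT)
          rows[[length(rows) + 1]] <- data.frame(
            seed = s, sigma2 = s2, mode = md, n_frames = nf, fes_error = err)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Heatmap of a benchmark table
#'
#' Median FES error per (noise level x dataset size) cell for one mode.
#'
#' @param tab Output of [benchmark_data_efficiency()].
#' @param path Output PDF path.
#' @param mode Mode to plot.
#' @return The path, invisibly.
#' @export
plot_benchmark <- function(tab, path, mode = "combined") {
  sub <- tab[tab$mode == mode, ]
  s2 <- sort(unique(sub$sigma2)); nf <- sort(unique(sub$n_frames))
  Z <- matrix(NA_real_, length(s2), length(nf))
  for (i in seq_along(s2)) for (j in seq_along(nf)) {
    v <- sub$fes_error[sub$sigma2 == s2[i] & sub$n_frames == nf[j]]
    if (length(v)) Z[i, j] <- stats::median(v)
  }
  grDevices::pdf(path, width = 5, height = 4)
  on.exit(grDevices::dev.off())
  graphics::image(seq_along(s2), seq_along(nf), Z, axes = FALSE,
                  xlab = "noise level", ylab = "n frames",
                  main = sprintf("median FES error (%s)", mode))
  graphics::axis(1, at = seq_along(s2), labels = signif(s2, 2))
  graphics::axis(2, at = seq_along(nf), labels = nf)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `map`, `forcemap`, `train`, `simulate`,
#' `analyze` (all of which run the pipeline up to the requested stage from a
#' YAML config) and `benchmark`. Options: `--config FILE` or
#' `--preset NAME`, `--outdir DIR`, `--seed N`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: cgnoise <generate|map|forcemap|train|simulate|analyze|benchmark> ",
            "[--config FILE | --preset NAME] [--outdir DIR] [--seed N]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg <- if (!is.null(opt("--config"))) {
    validate_run_config(yaml::read_yaml(opt("--config")))
  } else preset_config(opt("--preset", "double_well"))
  if (!is.null(opt("--outdir"))) cfg$outdir <- opt("--outdir")
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (cmd %in% c("generate", "map", "forcemap", "train", "simulate",
                 "analyze")) {
    res <- run_pipeline(cfg)
    message(sprintf("pipeline complete (config %s); artifacts in %s",
                    res$config_hash, cfg$outdir))
    for (nm in names(res$summary))
      message(sprintf("  %s = %.6g", nm, as.numeric(res$summary[[nm]])))
  } else if (cmd == "benchmark") {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    tab <- benchmark_data_efficiency(seed = cfg$seed, config = cfg)
    write.table(tab, file.path(cfg$outdir, "benchmark.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    plot_benchmark(tab, file.path(cfg$outdir, "benchmark.pdf"))
    message(sprintf("benchmark written to %s", cfg$outdir))
  } else {
    stop(sprintf("unknown subcommand '%s'", cmd))
  }
  invisible(0L)
}
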