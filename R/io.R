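#' Write a trajectory as delimited columnar text
#'
#' Canonical plain-text output: a `#`-prefixed metadata header (all
#' parameters, seeds and integrator settings, one `# key: value` line
#' each) followed by a tab-separated table with an explicit header row.
#' Values are written with 17 significant digits so a read-back
#' round-trips exactly.
#'
#' @param ts an `"oaburst_ts"` (or plain data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  meta <- c(as.list(attr(ts, "params")), attr(ts, "meta"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v) || length(v) != 1 || is.list(v)) next
    writeLines(sprintf("# %s: %s", k,
                       if (is.numeric(v)) format(v, digits = 17) else
                         as.character(v)), con)
  }
  df <- as.data.frame(ts)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format, digits = 17, scientific = TRUE,
                    trim = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_timeseries()]
#'
#' @param path file path.
#' @return Data frame with the table columns; header metadata is
#'   attached as attribute `meta`.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    vn <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (is.na(vn)) v else vn
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t")
  attr(df, "meta") <- meta
  df
}

#' Export stationary branches as a delimited table
#'
#' @param branches list of `"stationary_branch"` objects (optionally
#'   with a `stability` attribute set by the caller).
#' @param path optional output path; when `NULL` the data frame is
#'   returned without writing.
#' @return Data frame with columns `r1, r2, sigma, label, B, p1, p2, R,
#'   Theta, beta, stability`.
#' @export
write_branches <- function(branches, path = NULL) {
  df <- do.call(rbind, lapply(branches, function(b) {
    data.frame(r1 = b$params$r1, r2 = b$params$r2, sigma = b$params$sigma,
               label = b$label, B = b$B, p1 = b$p1, p2 = b$p2, R = b$R,
               Theta = b$Theta, beta = b$beta,
               stability = if (is.null(b$stability)) NA_character_
                           else b$stability)
  }))
  if (!is.null(path)) {
    num <- vapply(df, is.numeric, TRUE)
    out <- df
    out[num] <- lapply(out[num], format, digits = 17, scientific = TRUE,
                       trim = TRUE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}

experiment_kinds <- c("simulate", "layer", "stationary", "spectrum",
                      "foldmap", "regime_map", "sweep", "perturb")

default_config <- function(kind) {
  base <- list(
    kind = kind,
    sigma = 5, eps = 0.05, eps_prime = 0.05, s1 = 0.97, s2 = 1.2,
    omega = 0.2, lambda0 = -0.05, gamma = 0.5, N = 5000,
    seed = 1L, dt = 0.01, dt_out = 0.5, M = 201,
    # reference protocol windows
    t_end = 200, transient = 100,
    sweep_t_per_step = 7000, sweep_window = 5000, delta_s1 = 0.002,
    s1_start = 0.8, s1_end = 1.4,
    r1 = 0.9, r2 = 2,
    r1_values = NULL, r2_values = NULL,
    perturb_type = "reset", perturb_lambda = 20, perturb_t_p = 2000,
    perturb_duration = 500,
    out_dir = NULL)
  if (kind == "perturb") base$t_end <- 4000
  if (kind == "simulate") base$t_end <- 2000
  base
}

#' Build an experiment configuration
#'
#' Merges user overrides into the defaults of the given experiment
#' kind.  Every default reproduces the reference protocol (200/100 time
#' unit regime maps, 7000/5000 sweep windows with step 0.002, reset at
#' t = 2000, ...).  Unknown keys are an error.
#'
#' @param kind one of `simulate`, `layer`, `stationary`, `spectrum`,
#'   `foldmap`, `regime_map`, `sweep`, `perturb`.
#' @param ... overrides, or a single named list.
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(kind = experiment_kinds, ...) {
  kind <- match.arg(kind)
  cfg <- default_config(kind)
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.list(dots[[1]]))
    dots <- dots[[1]]
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file with a `kind` entry and overrides.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$kind)) stop("config file must declare 'kind'")
  kind <- y$kind
  y$kind <- NULL
  do.call(experiment_config, c(list(kind = kind), y))
}

cfg_params <- function(cfg) {
  model_params(sigma = cfg$sigma, eps = cfg$eps, eps_prime = cfg$eps_prime,
               s1 = cfg$s1, s2 = cfg$s2, omega = cfg$omega,
               lambda0 = cfg$lambda0, gamma = cfg$gamma, N = cfg$N)
}

#' Run a configured experiment
#'
#' Dispatches on the configuration kind, runs the corresponding
#' computation deterministically (all randomness flows through the
#' configured seed) and, when `out_dir` is set, writes the data files,
#' the fully resolved configuration (YAML) and a short log into that
#' directory.
#'
#' @param config an [experiment_config()] or a path to a YAML config.
#' @return The computed result object, invisibly when written to disk.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  params <- cfg_params(config)
  t_start <- Sys.time()

  result <- switch(config$kind,
    simulate = {
      pop <- init_population(config$N, seed = config$seed)
      simulate_network(pop, NULL, params, t_end = config$t_end,
                       dt_out = config$dt_out, dt = config$dt)
    },
    layer = {
      integrate_layer(oa_field(config$r1, config$r2, M = config$M),
                      config$sigma, t_end = config$t_end,
                      dt_out = config$dt_out, dt = config$dt)
    },
    stationary = {
      brs <- find_stationary_states(config$r1, config$r2, config$sigma)
      write_branches(brs)
    },
    spectrum = {
      brs <- find_stationary_states(config$r1, config$r2, config$sigma)
      for (i in seq_along(brs)) {
        sp <- discrete_spectrum(brs[[i]])
        brs[[i]]$stability <- classify_stability(brs[[i]], spectrum = sp)
      }
      write_branches(brs)
    },
    foldmap = {
      r2v <- config$r2_values
      if (is.null(r2v)) r2v <- seq(0.5, 2.4, by = 0.1)
      fold_branches(config$sigma, r2v)
    },
    regime_map = {
      r1v <- config$r1_values
      r2v <- config$r2_values
      if (is.null(r1v)) r1v <- seq(0.5, 1.3, by = 0.1)
      if (is.null(r2v)) r2v <- seq(0.5, 2.5, by = 0.25)
      regime_map(config$sigma, r1v, r2v, t_end = config$t_end,
                 transient = config$transient, M = config$M)
    },
    sweep = {
      s1v <- seq(config$s1_start, config$s1_end, by = config$delta_s1 *
                   sign(config$s1_end - config$s1_start))
      pop <- init_population(config$N, seed = config$seed,
                             sampling_mode = "stratified")
      adiabatic_sweep(s1v, params, engine = "network",
                      t_per_step = config$sweep_t_per_step,
                      window = config$sweep_window, pop = pop,
                      dt = config$dt)
    },
    perturb = {
      pop <- init_population(config$N, seed = config$seed)
      res <- resource_state(config$s1, config$s2, config$lambda0)
      proto <- list(type = config$perturb_type,
                    lambda = config$perturb_lambda,
                    t_p = config$perturb_t_p,
                    duration = config$perturb_duration)
      apply_perturbation(list(pop = pop, res = res), params, proto,
                         t_end = config$t_end, dt = config$dt,
                         dt_out = config$dt_out)
    })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_plain <- unclass(config)
    cfg_plain <- cfg_plain[!vapply(cfg_plain, is.null, TRUE)]
    yaml::write_yaml(cfg_plain, file.path(config$out_dir, "config.yaml"))
    obj <- if (inherits(result, "oaburst_ts")) result
           else if (is.list(result) && !is.null(result$ts)) result$ts
           else result
    if (is.data.frame(obj))
      write_timeseries(obj, file.path(config$out_dir, "result.tsv"))
    writeLines(c(
      sprintf("kind: %s", config$kind),
      sprintf("seed: %d", config$seed),
      sprintf("package: oaburst %s",
              as.character(utils::packageVersion("oaburst"))),
      sprintf("elapsed_s: %.2f",
              as.numeric(difftime(Sys.time(), t_start, units = "secs")))),
      file.path(config$out_dir, "run.log"))
    return(invisible(result))
  }
  result
}

#' Deterministic test fixtures
#'
#' Small canned inputs used across the test suite: a 50-rotator
#' population, a 21-node OA field at the three-root reference point, and
#' a short list of `(r1, r2)` parameter points covering the one-root and
#' three-root regions of the self-consistency function at coupling 5.
#'
#' @param seed integer seed.
#' @return List with `population`, `field`, and `param_points` (data
#'   frame with columns `r1`, `r2`, `region`).
#' @export
generate_fixtures <- function(seed = 1L) {
  list(
    population = init_population(50, seed = seed),
    field = oa_field(0.9, 2, M = 21),
    param_points = data.frame(
      r1 = c(0.9, 1.1, 0.9, 1.2, 0.95),
      r2 = c(2, 2, 2.25, 0.5, 1.2),
      region = c("three-root", "one-root", "one-root", "one-root",
                 "three-root")))
}
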