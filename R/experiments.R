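## Experiment configuration, runners, fixtures and file I/O.

CONFIG_KEYS <- c("scenario", "alpha", "mu", "centered", "kappa", "kernel",
                 "input", "a", "N", "M", "T", "n_snapshots", "rtol", "atol",
                 "seed", "omega_grid", "n_max")

#' Experiment configuration
#'
#' Flat, YAML-serializable description of a numerical experiment. Defaults
#' reproduce the reference smooth-sigmoid setting (`a = 0.5`, `alpha = 0.1`,
#' `mu = 10`, exponential kernel, sharp Gaussian input with `sigma = 0.05`,
#' horizon `T = 2500`). Unknown keys are rejected by name.
#'
#' @param ... configuration entries overriding the defaults (see
#'   `default_config()` for the full key set).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), CONFIG_KEYS)
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @export
default_config <- function() {
  list(scenario = "constant_input",
       alpha = 0.1, mu = 10, centered = FALSE, kappa = 0.04,
       kernel = list(type = "exponential", b = 1, normalization = 1),
       input = list(kind = "gaussian_constant", amplitude = 0.1, sigma = 0.05,
                    r0 = 0, Omega0 = 0),
       a = 0.5, N = 60L, M = 60L,
       T = 2500, n_snapshots = 6L, rtol = 1e-6, atol = 1e-8,
       seed = 1L,
       omega_grid = list(from = 0.02, to = 2, by = 0.02),
       n_max = 16L)
}

#' Read / write a configuration as YAML
#'
#' Round-trips losslessly through `yaml`.
#'
#' @param cfg an [experiment_config()].
#' @param path file path.
#' @return `read_config` returns an `experiment_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

config_kernel <- function(cfg) {
  k <- cfg$kernel
  switch(k$type,
         exponential = exponential_kernel(k$b, k$normalization %||% 1),
         mexican_hat = mexican_hat_kernel(k$sigma1, k$sigma2, k$A %||% 1,
                                          k$space %||% "tensor"),
         dog = dog_kernel(k$sigma1 %||% 0.1, k$sigma2 %||% 0.2, k$A %||% 0.8),
         stop("unknown kernel type '", k$type, "'", call. = FALSE))
}

config_input <- function(cfg) {
  i <- cfg$input
  input_spec(kind = i$kind %||% "gaussian_constant",
             amplitude = i$amplitude %||% 0, sigma = i$sigma %||% 0.05,
             r0 = i$r0 %||% 0, Omega0 = i$Omega0 %||% 0)
}

config_model <- function(cfg) {
  neural_field(kernel = config_kernel(cfg),
               sigmoid = sigmoid_spec(cfg$mu, cfg$centered),
               input = config_input(cfg), alpha = cfg$alpha)
}

#' Write a field snapshot as tabular text
#'
#' Columns `r`, `theta`, `z1`, `z2`, `V` (Euclidean polar coordinates of the
#' node and the field value), in fixed notation so reruns are bitwise
#' identical.
#'
#' @param fld a [field()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_snapshot <- function(fld, path) {
  stopifnot(inherits(fld, "field"))
  g <- fld$grid
  df <- data.frame(r = rep(g$rho, g$M + 1L),
                   theta = rep(g$theta, each = g$N + 1L),
                   z1 = Re(g$z), z2 = Im(g$z), V = fld$values)
  out <- vapply(df, function(col) formatC(col, digits = 15, format = "e"),
                character(nrow(df)))
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Run a configured experiment
#'
#' Drives the simulator / bump analysis for one scenario and writes a
#' deterministic output bundle (tabular snapshots or curves, a JSON metadata
#' sidecar with all parameters, tolerances and the seed, and a short log).
#' Scenarios:
#' \describe{
#'   \item{`constant_input`}{smooth sigmoid, stationary Gaussian input; writes
#'     snapshots of the trajectory.}
#'   \item{`rotating_input`}{input center moving on the circle `r0`; snapshots.}
#'   \item{`dog_null`}{difference-of-Gaussians kernel, zero input, centered
#'     sigmoid, random small initial state; snapshots (convergence to or
#'     departure from the null state depending on `mu`).}
#'   \item{`existence_curve`}{high-gain bump existence curve and its roots.}
#'   \item{`bump`}{bump profile at the first stable root (plus curve).}
#'   \item{`spectrum`}{kernel spectrum on a frequency grid.}
#' }
#'
#' @param config an [experiment_config()].
#' @param outdir output directory (created if missing).
#' @param verbose print one line per macro step.
#' @return (invisibly) a list with the main computed objects and file paths.
#' @export
run_experiment <- function(config, outdir, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[hypfield] ", ...)
  set.seed(config$seed)
  files <- character(0)
  out <- list()
  scen <- config$scenario
  say("scenario: ", scen)

  if (scen %in% c("constant_input", "rotating_input", "dog_null")) {
    model <- config_model(config)
    grid <- polar_grid(config$a, config$N, config$M)
    Wmat <- kernel_matrix(model$kernel, grid)
    v0 <- if (scen == "dog_null")
      0.1 * rnorm(length(grid$z)) else rep(0, length(grid$z))
    times <- seq(0, config$T, length.out = max(2L, config$n_snapshots))
    say("integrating to T = ", config$T, " on ", length(grid$z), " nodes")
    traj <- integrate_field(model, grid, v0, times, rtol = config$rtol,
                            atol = config$atol, Wmat = Wmat)
    out$trajectory <- traj
    for (i in seq_along(traj$times)) {
      p <- file.path(outdir, sprintf("field_t%08.1f.tsv", traj$times[i]))
      write_field_snapshot(field(grid, traj$states[i, ], traj$times[i]), p)
      files <- c(files, p)
    }
  } else if (scen %in% c("existence_curve", "bump")) {
    bm <- bump_model(config_kernel(config), alpha = config$alpha,
                     kappa = config$kappa, input = config_input(config))
    og <- seq(config$omega_grid$from, config$omega_grid$to,
              by = config$omega_grid$by)
    say("existence curve on ", length(og), " radii")
    curve <- existence_curve(bm, og)
    out$curve <- curve
    p <- file.path(outdir, "existence_curve.tsv")
    write_existence_curve(curve, p); files <- c(files, p)
    if (scen == "bump") {
      st <- curve$roots[curve$roots$stable, , drop = FALSE]
      if (!nrow(st)) stop("no stable bump root on the grid", call. = FALSE)
      omega <- st$omega[1L]
      say("bump profile at omega = ", format(omega))
      prof <- bump_profile(bm, omega, seq(0, 2 * omega, length.out = 201L))
      spec <- stability_spectrum(bm, prof, n_max = config$n_max)
      out$profile <- prof; out$spectrum <- spec
      p1 <- file.path(outdir, "bump_profile.tsv")
      p2 <- file.path(outdir, "stability_spectrum.tsv")
      write_bump_profile(prof, p1); write_spectral_series(spec, p2)
      files <- c(files, p1, p2)
    }
  } else if (scen == "spectrum") {
    k <- config_kernel(config)
    lam <- seq(0, 40, by = 0.1)
    ks <- kernel_spectrum(k, lam, smax = if (kernel_integrable(k)) NULL else
      atanh(config$a))
    out$spectrum <- ks
    p <- file.path(outdir, "kernel_spectrum.tsv")
    write_spectrum(ks, p); files <- c(files, p)
  } else stop("unknown scenario '", scen, "'", call. = FALSE)

  meta <- list(config = unclass(config),
               package = as.character(packageVersion("hypfield")),
               files = basename(files))
  mp <- file.path(outdir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote ", length(files) + 1L, " files to ", outdir)
  invisible(c(out, list(files = c(files, mp))))
}

#' Generate reproducible synthetic fixtures
#'
#' Seeded random objects used by the test-suite and for experimentation:
#' random radial kernels with valid parameters, random smooth bounded initial
#' fields, and random SU(1,1) elements (built from Iwasawa factors, so the
#' group constraint holds by construction).
#'
#' @param kind `"mexican_hat"`, `"exponential"`, `"field"`, or `"su_element"`.
#' @param seed integer seed.
#' @param n number of objects (fields: number of grid nodes is governed by
#'   `grid`).
#' @param grid [polar_grid()] for `kind = "field"`.
#' @return list of generated objects (a single [field()] for `kind = "field"`).
#' @export
generate_fixture <- function(kind, seed = 1L, n = 1L, grid = NULL) {
  set.seed(seed)
  switch(kind,
    mexican_hat = replicate(n, {
      s <- sort(runif(2, 0.05, 1.2))
      mexican_hat_kernel(s[1L], s[2L], runif(1), space = "tensor")
    }, simplify = FALSE),
    exponential = replicate(n, exponential_kernel(runif(1, 0.1, 0.9)),
                            simplify = FALSE),
    su_element = replicate(n, {
      g <- su_multiply(su_horocyclic(rnorm(1)), su_boost(rnorm(1, 0, 0.7)))
      su_multiply(g, su_rotation(runif(1, 0, 2 * pi)))
    }, simplify = FALSE),
    field = {
      grid <- grid %||% polar_grid(0.5, 16L, 16L)
      ## smooth bounded random field: few random Fourier-Bessel-like modes
      z <- grid$z
      v <- numeric(length(z))
      for (j in 1:4) {
        cj <- runif(1, -0.3, 0.3) + 1i * runif(1, -0.3, 0.3)
        v <- v + rnorm(1, 0, 0.3) * exp(-Mod(z - cj)^2 / runif(1, 0.02, 0.2))
      }
      field(grid, v)
    },
    stop("unknown fixture kind '", kind, "'", call. = FALSE))
}

#' Polar heatmap of a field
#'
#' Minimal base-graphics rendering of a field snapshot on the truncated disk
#' (filled polar cells).
#'
#' @param fld a [field()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, `NULL`.
#' @export
plot_field <- function(fld, ...) {
  g <- fld$grid
  vals <- matrix(fld$values, g$N + 1L, g$M + 1L)
  graphics::image(g$rho, c(g$theta, 2 * pi), cbind(vals, vals[, 1L]),
                  xlab = "rho", ylab = "theta",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(NULL)
}
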