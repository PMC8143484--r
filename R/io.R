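#' Write and read paths as columnar CSV
#'
#' Columns `t, x_1, ..., x_d` with a header row; values are written with 17
#' significant digits so the round trip is exact at double precision.
#'
#' @param path an `ou_path`.
#' @param file destination file.
#' @export
write_path_csv <- function(path, file) {
  d <- ncol(path$values)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("t", paste0("x_", seq_len(d))), collapse = ","), con)
  m <- cbind(path$grid$times, path$values)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(file)
}

#' @rdname write_path_csv
#' @return `read_path_csv` returns an `ou_path`; the grid is inferred from
#'   the time column.
#' @export
read_path_csv <- function(file) {
  df <- utils::read.csv(file, colClasses = "numeric")
  if (names(df)[1] != "t") stop("first column must be t")
  tt <- df[[1]]
  n_t <- length(tt) - 1L
  g <- path_grid(T = tt[length(tt)], n_t = n_t)
  if (max(abs(g$times - tt)) > 1e-9 * max(tt))
    stop("time column is not a uniform grid")
  path_values(g, as.matrix(df[, -1, drop = FALSE]))
}

#' Read, validate, and write run configurations (JSON)
#'
#' A run configuration is a named list with components: `potential`
#' (list: `name`, optional `params`), `T`, `dt`, `eps`, `x_minus`, `x_plus`,
#' `A`, `h`, and optionally `alpha_mode`, `tau_rule`, `tau_bounds`,
#' `functional` (`"midpoint"`/`"ito_girsanov"`), `n_iterations`,
#' `snapshot_stride`, `seed`, `initial` (list: `mode`, `switch_fraction`),
#' `n_realizations` (forward command).
#'
#' @param file path to a JSON configuration.
#' @return `read_run_config` returns the validated configuration list.
#' @export
read_run_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, file) {
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(cfg) {
  bad <- character(0)
  need <- function(key, ok) if (is.null(cfg[[key]]) || !ok(cfg[[key]]))
    bad <<- c(bad, key)
  pos <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0
  need("potential", function(p) is.list(p) && is.character(p$name))
  need("T", pos); need("dt", pos); need("eps", pos); need("h", pos)
  need("x_minus", is.numeric); need("x_plus", is.numeric)
  need("A", function(a) is.numeric(a) && all(a >= 0))
  if (length(bad) > 0)
    stop(sprintf("invalid config: missing or bad keys: %s",
                 paste(bad, collapse = ", ")))
  if (length(cfg$x_minus) != length(cfg$x_plus))
    stop("invalid config: x_minus and x_plus differ in dimension")
  if (length(cfg$A) != length(cfg$x_minus))
    stop("invalid config: A must have one entry per dimension")
  cfg$alpha_mode <- cfg$alpha_mode %||% "sinc"
  cfg$tau_rule <- cfg$tau_rule %||% "uniform"
  cfg$tau_bounds <- cfg$tau_bounds %||% c(pi / 4, 3 * pi / 4)
  cfg$functional <- cfg$functional %||% "midpoint"
  cfg$n_iterations <- cfg$n_iterations %||% 1000L
  cfg$snapshot_stride <- cfg$snapshot_stride %||% 0L
  cfg$seed <- cfg$seed %||% 1L
  cfg$initial <- cfg$initial %||% list(mode = "linear")
  cfg
}

#' Built-in reduced-benchmark configuration
#'
#' The entropic-channel benchmark scaled to desk size: `T = 25`,
#' `dt = 0.005`, `eps = 0.05`, endpoints at the two basin reference points.  The
#' full-scale study (`T = 125`, `dt = 0.001`) uses the same structure.
#'
#' @param A OU parameter vector.
#' @param h MD step.
#' @param n_iterations chain length.
#' @return Configuration list (already valid).
#' @export
config_reduced_benchmark <- function(A = c(1, 4), h = 0.02,
                                     n_iterations = 500L) {
  pot <- entropic_channel_2d()
  left <- basin_reference_point(pot, "left")
  right <- basin_reference_point(pot, "right")
  validate_run_config(list(
    potential = list(name = "entropic_channel_2d"),
    T = 25, dt = 0.005, eps = 0.05,
    x_minus = left, x_plus = right,
    A = A, h = h, n_iterations = n_iterations,
    initial = list(mode = "two_segment", switch_fraction = 0.4)))
}

config_objects <- function(cfg) {
  pot <- make_potential(cfg$potential$name, cfg$potential$params %||% list())
  grid <- path_grid(T = cfg$T, dt = cfg$dt)
  spec <- functional_spec(pot, eps = cfg$eps, dt = cfg$dt,
                          form = cfg$functional)
  params <- hmc_params(h = cfg$h, A = cfg$A,
                       n_iterations = cfg$n_iterations,
                       alpha_mode = cfg$alpha_mode,
                       tau_rule = cfg$tau_rule,
                       tau_bounds = cfg$tau_bounds,
                       snapshot_stride = cfg$snapshot_stride)
  list(potential = pot, grid = grid, spec = spec, params = params)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop(sprintf("output directory '%s' exists; use force = TRUE to overwrite",
                 out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

write_manifest <- function(cfg, out_dir, command) {
  jsonlite::write_json(
    list(command = command, config = cfg, seed = cfg$seed,
         package = "ouhmc",
         package_version = as.character(utils::packageVersion("ouhmc")),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the sampler from a configuration and write artifacts
#'
#' Builds the initial path, runs [run_sampler()], and writes `snapshots/`
#' (path CSVs), `diagnostics.csv`, `final_path.csv` and `manifest.json`
#' into `out_dir`.
#'
#' @param cfg configuration list (see [read_run_config()]).
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @param progress passed to [run_sampler()].
#' @return Invisibly, the [run_sampler()] result.
#' @export
cmd_sample <- function(cfg, out_dir, force = FALSE, progress = 100L) {
  cfg <- validate_run_config(cfg)
  prepare_out_dir(out_dir, force)
  ob <- config_objects(cfg)
  set.seed(cfg$seed)
  init <- if (identical(cfg$initial$mode, "resume")) {
    # resume sampling from a previously saved path CSV
    p <- read_path_csv(cfg$initial$path)
    if (!same_grid(p$grid, ob$grid))
      stop("resume path grid does not match the configured T and dt")
    d <- path_to_displacement(p)
    if (max(abs(d$x_minus - cfg$x_minus), abs(d$x_plus - cfg$x_plus)) > 1e-8)
      stop("resume path endpoints do not match the configured x_minus/x_plus")
    d
  } else {
    build_initial_path(cfg$initial$mode, ob$grid, cfg$x_minus,
                       cfg$x_plus, potential = ob$potential,
                       eps = cfg$eps,
                       switch_fraction = cfg$initial$switch_fraction %||% 0.5)
  }
  res <- run_sampler(init, ob$params, ob$spec, progress = progress)
  utils::write.csv(res$diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  write_path_csv(reconstruct_path(res$disp), file.path(out_dir, "final_path.csv"))
  if (length(res$snapshots) > 0) {
    dir.create(file.path(out_dir, "snapshots"), showWarnings = FALSE)
    for (i in seq_along(res$snapshots))
      write_path_csv(res$snapshots[[i]],
                     file.path(out_dir, "snapshots", sprintf("path_%05d.csv", i)))
  }
  write_manifest(cfg, out_dir, "sample")
  invisible(res)
}

#' Forward Brownian-dynamics ensemble from a configuration
#'
#' Starts `cfg$n_realizations` realizations at the canonical
#' left-basin reference point (or at `cfg$x0` if given) and writes the
#' time-versus-right-fraction table.
#'
#' @inheritParams cmd_sample
#' @return Invisibly, the `forward_ensemble`.
#' @export
cmd_forward <- function(cfg, out_dir, force = FALSE) {
  cfg <- validate_run_config(cfg)
  prepare_out_dir(out_dir, force)
  ob <- config_objects(cfg)
  x0 <- cfg$x0 %||% basin_reference_point(ob$potential, "left", eps = cfg$eps)
  n <- cfg$n_realizations %||% 10000L
  rec <- cfg$record_times %||% pretty_record_times(cfg$T, cfg$dt)
  set.seed(cfg$seed)
  ens <- forward_brownian(ob$potential, x0, T = cfg$T, dt = cfg$dt,
                          eps = cfg$eps, n = n, record_times = rec)
  utils::write.csv(right_fraction_curve(ens),
                   file.path(out_dir, "right_fraction.csv"), row.names = FALSE)
  write_manifest(cfg, out_dir, "forward")
  invisible(ens)
}

pretty_record_times <- function(T, dt) {
  k <- unique(pmax(1, round(seq(0, T, length.out = 26L) / dt)))
  k * dt
}

#' Equilibrium and path analysis from a configuration
#'
#' Computes basin weights and the angular equilibrium profile by
#' quadrature, and, if snapshot paths are supplied, the pooled angle
#' histogram and the basin-fraction trace.  All tables are written as CSV.
#'
#' @inheritParams cmd_sample
#' @param snapshots optional character vector of path CSV files (from
#'   [cmd_sample()]); quadrature-only analyses need none.
#' @return Invisibly, a list of the computed tables.
#' @export
cmd_analyze <- function(cfg, out_dir, snapshots = NULL, force = FALSE) {
  cfg <- validate_run_config(cfg)
  prepare_out_dir(out_dir, force)
  ob <- config_objects(cfg)
  if (ob$potential$d != 2L)
    stop("analysis commands require a two-dimensional potential")
  bw <- basin_weights_quadrature(ob$potential, cfg$eps)
  utils::write.csv(data.frame(w_left = bw$w_left, w_right = bw$w_right),
                   file.path(out_dir, "basin_weights.csv"), row.names = FALSE)
  prof <- pbar_theta(ob$potential, cfg$eps)
  utils::write.csv(as.data.frame(prof),
                   file.path(out_dir, "pbar_theta.csv"), row.names = FALSE)
  out <- list(basin_weights = bw, pbar = prof)
  if (!is.null(snapshots)) {
    if (length(snapshots) == 0) stop("empty snapshot set")
    paths <- lapply(snapshots, read_path_csv)
    th <- theta_histogram(paths)
    utils::write.csv(th, file.path(out_dir, "theta_histogram.csv"),
                     row.names = FALSE)
    bf <- t(vapply(paths, basin_fractions, numeric(3)))
    utils::write.csv(data.frame(snapshot = seq_along(paths), bf),
                     file.path(out_dir, "basin_fraction_trace.csv"),
                     row.names = FALSE)
    out$theta_histogram <- th
    out$basin_fraction_trace <- bf
  }
  write_manifest(cfg, out_dir, "analyze")
  invisible(out)
}

#' Acceptance-rate sweep over the MD step size, from a configuration
#'
#' @inheritParams cmd_sample
#' @param h_values step sizes to probe; default a geometric grid around
#'   `cfg$h`.
#' @return Invisibly, the sweep data frame (also written as CSV).
#' @export
cmd_sweep_h <- function(cfg, out_dir, h_values = NULL, force = FALSE) {
  cfg <- validate_run_config(cfg)
  prepare_out_dir(out_dir, force)
  ob <- config_objects(cfg)
  if (is.null(h_values)) h_values <- cfg$h * 2^seq(-2, 2)
  set.seed(cfg$seed)
  init <- build_initial_path(cfg$initial$mode, ob$grid, cfg$x_minus,
                             cfg$x_plus, potential = ob$potential,
                             eps = cfg$eps,
                             switch_fraction = cfg$initial$switch_fraction %||% 0.5)
  sw <- acceptance_vs_h(init, h_values, cfg$A, ob$spec,
                        tau_rule = cfg$tau_rule, tau_bounds = cfg$tau_bounds,
                        alpha_mode = cfg$alpha_mode)
  utils::write.csv(sw, file.path(out_dir, "acceptance_vs_h.csv"),
                   row.names = FALSE)
  write_manifest(cfg, out_dir, "sweep-h")
  invisible(sw)
}
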