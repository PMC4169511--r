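## Configuration files, CSV results, run metadata and synthetic trace
## fixtures.  CSV dialect: UTF-8, comma-separated, header row, numbers
## written with 17 significant digits so write -> read round-trips are
## lossless; run metadata goes to a YAML sidecar.

.write_csv_full <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Tiny FNV-1a hash of a serialised object (config fingerprinting only).
.hash_obj <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.config_keys <- list(
  top = c("preset", "rates", "design", "engine", "n_cells", "seed", "out",
          "variant"),
  rates = c("k_A", "k_E", "k_L", "d_E", "k_M", "k_TL", "d_M", "d_G", "k_U",
            "d_L", "k_W"),
  design = c("L_ex0", "t_inc", "t_end", "S", "N_max", "dt_out"))

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a simulation run: a rate preset
#' (one of the published columns) or explicit rates with optional
#' overrides, an experiment design (`L_ex0: auto` calibrates the dose to a
#' mean of 6 attached lipoplexes), the engine, ensemble size and seed.
#' Unknown keys are rejected with their key path.
#'
#' @param path path to a YAML file.
#' @return A list of class `run_config` with `rates`, `design`, `variant`,
#'   `engine`, `n_cells`, `seed`, `out`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .config_keys$top)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rate_args <- list()
  if (!is.null(cfg$preset)) {
    if (!cfg$preset %in% names(.preset_table))
      stop("preset: unknown preset '", cfg$preset, "'", call. = FALSE)
    rate_args <- .preset_table[[cfg$preset]]
  }
  if (!is.null(cfg$rates)) {
    bad <- setdiff(names(cfg$rates), .config_keys$rates)
    if (length(bad)) stop("unknown key(s) under rates: ",
                          paste0("rates.", bad, collapse = ", "),
                          call. = FALSE)
    for (nm in names(cfg$rates)) {
      v <- cfg$rates[[nm]]
      if (!is.numeric(v) || length(v) != 1 || v < 0)
        stop("rates.", nm, " must be a single non-negative number",
             call. = FALSE)
    }
    rate_args[names(cfg$rates)] <- cfg$rates
  }
  if (!all(c("k_A", "k_E", "k_L", "d_E", "k_M") %in% names(rate_args)))
    stop("configuration must give a preset or the five free rates",
         call. = FALSE)
  rates <- do.call(rate_constants, rate_args)

  dd <- if (is.null(cfg$design)) list() else cfg$design
  bad <- setdiff(names(dd), .config_keys$design)
  if (length(bad)) stop("unknown key(s) under design: ",
                        paste0("design.", bad, collapse = ", "),
                        call. = FALSE)
  t_inc <- if (is.null(dd$t_inc)) 1 else dd$t_inc
  if (is.null(dd$L_ex0) || identical(dd$L_ex0, "auto"))
    dd$L_ex0 <- calibrate_dose(rates, t_inc = t_inc)
  design <- do.call(experiment_design, dd)

  variant <- if (is.null(cfg$variant)) {
    if (!is.null(cfg$preset) && grepl("^streamlined", cfg$preset))
      "streamlined" else "multilipoplex"
  } else cfg$variant
  if (!variant %in% c("streamlined", "multilipoplex"))
    stop("variant: must be 'streamlined' or 'multilipoplex'", call. = FALSE)
  engine <- if (is.null(cfg$engine)) "hybrid" else cfg$engine
  if (!engine %in% c("ode", "ssa", "hybrid"))
    stop("engine: must be one of ode, ssa, hybrid", call. = FALSE)
  structure(list(rates = rates, design = design, variant = variant,
                 engine = engine,
                 n_cells = if (is.null(cfg$n_cells)) 1000L else
                   as.integer(cfg$n_cells),
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 out = if (is.null(cfg$out)) "." else cfg$out),
            class = "run_config")
}

#' Write run metadata as YAML
#'
#' Records the master seed, package version and a fingerprint of the
#' configuration, enabling an exact re-run.
#'
#' @param path output file.
#' @param seed master seed of the run.
#' @param config optional configuration object to fingerprint and embed.
#' @export
write_metadata <- function(path, seed, config = NULL) {
  meta <- list(package = "lipoplexsim",
               version = as.character(packageVersion("lipoplexsim")),
               seed = as.integer(seed))
  if (!is.null(config)) {
    meta$config_hash <- .hash_obj(config)
    meta$config <- rapply(unclass(config), function(v) v, how = "list")
  }
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Write simulation results to CSV
#'
#' Writes a trajectory (time plus one column per observable and species), a
#' per-cell ensemble summary, a dose-response table or an annealing report.
#' Numeric columns keep full double precision and round-trip losslessly
#' through [read.csv()].
#'
#' @param x a `cell_trajectory`, `transfection_ensemble`, `dose_response`
#'   or `anneal_result`.
#' @param path output CSV file.
#' @param ... unused.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.cell_trajectory <- function(x, path, ...)
  .write_csv_full(as.data.frame(x), path)

#' @export
write_results.transfection_ensemble <- function(x, path, ...) {
  ce <- x$cells
  ce$onset_h <- NA_real_; ce$maxgfp <- NA_real_
  if (!is.null(x$gfp)) {
    fits <- fit_onset_batch(x$gfp, x$times, x$rates)
    ce$onset_h <- fits$t0; ce$maxgfp <- fits$maxgfp
  }
  .write_csv_full(ce, path)
}

#' @export
write_results.dose_response <- function(x, path, ...)
  .write_csv_full(as.data.frame(x), path)

#' @export
write_results.anneal_result <- function(x, path, ...) {
  df <- data.frame(parameter = names(x$best_params),
                   estimate = unname(x$best_params))
  df <- rbind(df, data.frame(parameter = "best_score",
                             estimate = x$best_score))
  .write_csv_full(df, path)
}

#' Long-format per-cell trace tables
#'
#' @param x a `transfection_ensemble` or a fixture table from
#'   [make_fixtures()] (columns `cell_id`, `time_h`, `gfp`).
#' @param path output CSV.
#' @param truth_path optional CSV for the per-cell ground truth attached to
#'   fixture tables.
#' @export
write_trace_table <- function(x, path, truth_path = NULL) {
  if (inherits(x, "transfection_ensemble")) {
    if (is.null(x$gfp)) stop("ensemble has no GFP traces", call. = FALSE)
    x <- data.frame(cell_id = rep(seq_len(x$n_cells), each = length(x$times)),
                    time_h = rep(x$times, x$n_cells),
                    gfp = as.vector(x$gfp))
  }
  stopifnot(all(c("cell_id", "time_h", "gfp") %in% names(x)))
  truth <- attr(x, "truth")
  .write_csv_full(as.data.frame(x), path)
  if (!is.null(truth_path) && !is.null(truth))
    .write_csv_full(truth, truth_path)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("cell_id", "time_h", "gfp") %in% names(df)))
  df
}

#' Trace table to time-by-cell matrix
#'
#' @param traces long-format table with `cell_id`, `time_h`, `gfp`; all
#'   cells must share the same time grid.
#' @return A list with `times` and the `gfp` matrix.
#' @export
traces_to_matrix <- function(traces) {
  cells <- sort(unique(traces$cell_id))
  tt <- sort(unique(traces$time_h))
  m <- matrix(NA_real_, length(tt), length(cells))
  for (j in seq_along(cells)) {
    sub <- traces[traces$cell_id == cells[j], ]
    sub <- sub[order(sub$time_h), ]
    if (length(sub$time_h) != length(tt) ||
        max(abs(sub$time_h - tt)) > 1e-9)
      stop("per-cell time grids differ", call. = FALSE)
    m[, j] <- sub$gfp
  }
  list(times = tt, gfp = m, cells = cells)
}

#' Synthetic single-cell GFP trace fixtures
#'
#' Generates per-cell traces from the analytic expression curve with known
#' onset times and amplitudes plus multiplicative Gaussian noise and an
#' additive detection floor — a stand-in for experimental single-cell
#' tracking tables, with the ground truth retained for recovery tests.
#'
#' @param n_cells number of cells.
#' @param rates a [rate_constants] object.
#' @param noise list with `sigma_rel` (relative SD of multiplicative
#'   Gaussian noise) and `floor` (SD of additive noise, molecules).
#' @param seed RNG seed.
#' @param times output grid (h).
#' @param t0_sampler,m0_sampler functions of `n` drawing the per-cell onset
#'   times and amplitudes; defaults draw onsets from a truncated normal
#'   around 3.2 h (width 1.6 h) and amplitudes as whole mRNA packets of 350
#'   (1 plus a Poisson number of extra packets).
#' @param maturation curve family used to generate (see
#'   [expression_curve()]).
#' @return Long-format data.frame (`cell_id`, `time_h`, `gfp`) with the
#'   ground truth (`cell_id`, `t0`, `m0`) in `attr(, "truth")`.
#' @export
make_fixtures <- function(n_cells, rates,
                          noise = list(sigma_rel = 0.05, floor = 0),
                          seed = 1, times = seq(0, 30, 0.1),
                          t0_sampler = NULL, m0_sampler = NULL,
                          maturation = FALSE) {
  set.seed(seed)
  if (is.null(t0_sampler))
    t0_sampler <- function(n) pmin(pmax(rnorm(n, 3.2, 1.6), 0.5), 10)
  if (is.null(m0_sampler))
    m0_sampler <- function(n) 350 * (1 + rpois(n, 0.7))
  t0 <- t0_sampler(n_cells)
  m0 <- m0_sampler(n_cells)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    y <- m0[i] * expr_unit(times - t0[i], rates, maturation)
    if (noise$sigma_rel > 0)
      y <- y * (1 + rnorm(length(y), 0, noise$sigma_rel))
    if (noise$floor > 0) y <- y + rnorm(length(y), 0, noise$floor)
    out[[i]] <- data.frame(cell_id = i, time_h = times, gfp = pmax(y, 0))
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- data.frame(cell_id = seq_len(n_cells), t0 = t0,
                                   m0 = m0)
  res
}
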