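# Configuration parsing and result serialization.

.config_defaults <- function() {
  list(n_agents = 100L, n_steps = 50000L, k0 = -1L, k_nb = -1L,
       za = 0.01, rho_mode = "fixed", rho = 1.0, new_belief = FALSE,
       seed = 1L, snapshot_every = NULL, epsilons = c(0.01, 0.05, 0.1))
}

#' Assemble a run configuration
#'
#' A run configuration is a validated [model_params()] plus output
#' plumbing: where to write, in which format, and how many replicates to
#' run (replicate i is seeded with `base seed + i - 1`).
#'
#' @param ... Passed to [model_params()].
#' @param out_dir Output directory (created on write), or `NULL`.
#' @param format `"csv"` or `"json"` for the attitude and metric tables.
#' @param replicates Number of replicate runs (positive integer).
#' @return An object of class `run_config` with elements `params`,
#'   `out_dir`, `format`, `replicates`.
#' @export
run_config <- function(..., out_dir = NULL, format = c("csv", "json"),
                       replicates = 1L) {
  format <- match.arg(format)
  .check_count(replicates, "replicates")
  if (!is.null(out_dir) && (!is.character(out_dir) || length(out_dir) != 1L))
    stop("`out_dir` must be a single path or NULL", call. = FALSE)
  structure(list(params = model_params(...), out_dir = out_dir,
                 format = format, replicates = as.integer(replicates)),
            class = "run_config")
}

#' Read a run configuration file
#'
#' Reads a declarative key-value configuration (JSON or YAML, decided by
#' the file extension: `.json` vs `.yml`/`.yaml`), fills unspecified keys
#' with the defaults of the headline experiment (N = 100, T = 50,000,
#' K0 = -1, Z_A = 0.01, fixed rho = 1, epsilons \{0.01, 0.05, 0.1\}) and
#' validates everything. Recognised keys: the [model_params()] arguments
#' plus `out_dir`, `format`, `replicates`. Missing files, unparsable
#' content, unknown keys and invalid values each raise a distinct,
#' descriptive error.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()] object.
#' @export
read_config <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           json = jsonlite::read_json(path, simplifyVector = TRUE),
           yml = ,
           yaml = yaml::read_yaml(path),
           stop("unsupported config extension '", ext,
                "' (use .json, .yml or .yaml)", call. = FALSE)),
    error = function(e) stop("failed to parse config ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(raw) || (length(raw) > 0L && is.null(names(raw))))
    stop("config must be a mapping of named keys", call. = FALSE)
  allowed <- c(names(.config_defaults()), "out_dir", "format", "replicates")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- utils::modifyList(.config_defaults(), raw, keep.null = TRUE)
  run_config(n_agents = vals$n_agents, n_steps = vals$n_steps,
             k0 = vals$k0, k_nb = vals$k_nb, za = vals$za,
             rho_mode = vals$rho_mode, rho = vals$rho,
             new_belief = isTRUE(vals$new_belief), seed = vals$seed,
             snapshot_every = vals$snapshot_every, epsilons = vals$epsilons,
             out_dir = raw$out_dir,
             format = if (is.null(raw$format)) "csv" else raw$format,
             replicates = if (is.null(raw$replicates)) 1L else raw$replicates)
}

# full-precision numeric serialization: %.17g round-trips doubles exactly
.fmt_num_cols <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}

.write_table <- function(df, path, format) {
  if (format == "csv") {
    utils::write.csv(.fmt_num_cols(df), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "columns", digits = I(17))
  }
}

.read_table <- function(path, format) {
  if (!file.exists(path))
    stop("expected output file not found: ", path, call. = FALSE)
  if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Write a simulation trajectory to disk
#'
#' Writes three files into `dir`: `attitudes.<fmt>` (long table with
#' columns `t`, `agent_id`, `a1`, `a2`, `a3`, `adopted` over all snapshot
#' times), `metrics.<fmt>` (the metric rows, see [metrics_table()]) and
#' `manifest.json` (all parameters, the seed, the observed attitude-bound
#' maximum and the per-agent exposure counts — enough to re-run the
#' simulation bit-identically). Numeric values are serialized at full
#' precision so that [read_trajectory()] round-trips them exactly.
#'
#' @param record A `trajectory` from [run_simulation()].
#' @param dir Output directory, created if needed.
#' @param format `"csv"` or `"json"` for the two tables.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_trajectory <- function(record, dir, format = c("csv", "json")) {
  stopifnot(inherits(record, "trajectory"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop("cannot create output directory: ", dir, call. = FALSE)
  att <- do.call(rbind, Map(function(t, snap) cbind(t = t, snap),
                            record$times, record$snapshots))
  rownames(att) <- NULL
  ext <- format
  paths <- c(attitudes = file.path(dir, paste0("attitudes.", ext)),
             metrics = file.path(dir, paste0("metrics.", ext)),
             manifest = file.path(dir, "manifest.json"))
  .write_table(att, paths[["attitudes"]], format)
  .write_table(record$metrics, paths[["metrics"]], format)
  p <- record$params
  manifest <- list(package = "beliefsim",
                   version = as.character(utils::packageVersion("beliefsim")),
                   format = format,
                   params = p[setdiff(names(p), character())],
                   times = record$times,
                   max_abs_attitude = record$max_abs_attitude,
                   exposure_counts = record$exposure_counts)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(paths)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir Directory containing `attitudes.*`, `metrics.*` and
#'   `manifest.json`.
#' @return A `trajectory` object equal (in times, snapshots and metrics)
#'   to the one written.
#' @export
read_trajectory <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  format <- man$format
  att <- .read_table(file.path(dir, paste0("attitudes.", format)), format)
  met <- .read_table(file.path(dir, paste0("metrics.", format)), format)
  pl <- man$params
  params <- model_params(n_agents = pl$n_agents, n_steps = pl$n_steps,
                         k0 = pl$k0, k_nb = pl$k_nb, za = pl$za,
                         rho_mode = pl$rho_mode, rho = pl$rho,
                         new_belief = isTRUE(pl$new_belief), seed = pl$seed,
                         snapshot_every = pl$snapshot_every,
                         epsilons = pl$epsilons)
  times <- as.integer(man$times)
  snaps <- lapply(times, function(tt) {
    s <- att[att$t == tt, c("agent_id", "a1", "a2", "a3", "adopted")]
    rownames(s) <- NULL
    s
  })
  last <- snaps[[length(snaps)]]
  final <- population(last$a1, last$a2, last$a3, last$adopted,
                      t = times[length(times)])
  structure(list(times = times, snapshots = snaps, metrics = met,
                 final = final,
                 max_abs_attitude = as.numeric(man$max_abs_attitude),
                 exposure_counts = as.integer(man$exposure_counts),
                 params = params),
            class = "trajectory")
}

#' Recompute metrics from a saved attitude table
#'
#' Rebuilds the metrics table for arbitrary extremity thresholds from a
#' long attitude table (columns `t`, `agent_id`, `a1`, `a2`, `a3`,
#' `adopted`) without re-running the simulation.
#'
#' @param attitudes A `data.frame` as written by [write_trajectory()].
#' @param epsilons Numeric vector of thresholds in (0, 1).
#' @return A metrics `data.frame`, one row per time and epsilon.
#' @export
recompute_metrics <- function(attitudes, epsilons = c(0.01, 0.05, 0.1)) {
  need <- c("t", "a1", "a2", "a3", "adopted")
  if (!is.data.frame(attitudes) || !all(need %in% names(attitudes)))
    stop("`attitudes` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(attitudes) == 0L)
    stop("`attitudes` table is empty", call. = FALSE)
  times <- sort(unique(attitudes$t))
  blocks <- lapply(times, function(tt) {
    s <- attitudes[attitudes$t == tt, ]
    metrics_table(population(s$a1, s$a2, s$a3, as.logical(s$adopted), tt),
                  epsilons)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Run a configuration and write all replicates
#'
#' Executes [run_simulation()] once per replicate (replicate i seeded with
#' `base seed + i - 1`) and writes each result with [write_trajectory()]:
#' a single replicate goes directly into `out_dir`, several into
#' `out_dir/replicate-<i>/`. Progress is logged to standard error.
#'
#' @param config A [run_config()] with a non-`NULL` `out_dir`.
#' @return Invisibly, a list of the `trajectory` objects.
#' @export
run_and_write <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$out_dir))
    stop("`config$out_dir` must be set to write results", call. = FALSE)
  runs <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    p <- config$params
    p$seed <- p$seed + i - 1
    message(sprintf("[beliefsim] replicate %d/%d: N=%d T=%d seed=%s",
                    i, config$replicates, p$n_agents, p$n_steps,
                    format(p$seed)))
    runs[[i]] <- run_simulation(p)
    dest <- if (config$replicates == 1L) config$out_dir
            else file.path(config$out_dir, sprintf("replicate-%d", i))
    write_trajectory(runs[[i]], dest, config$format)
  }
  invisible(runs)
}
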