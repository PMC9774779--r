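# Configuration I/O and deterministic tabular output.

config_schema_version <- 1L

protocol_keys <- c("presentation", "dilution_mode", "cycle_length",
                   "n_cycles", "cell_renewal_density", "dilution_count",
                   "transfer_fraction", "carry_infected",
                   "initial_total_phage", "sequential_first_host",
                   "density_floor")
params_keys <- c("burst_A", "burst_B", "burst_AB", "r", "lysis",
                 "adsorption")
sweep_keys <- c("grid_A", "grid_B", "retention_threshold")

#' Load a simulation configuration from JSON
#'
#' Reads a structured JSON document describing a protocol, kinetic
#' parameters and (optionally) a burst-size sweep, applies defaults for
#' omitted keys, and validates everything. Unknown keys are rejected with
#' their key path. Schema (all keys optional except where noted):
#'
#' \preformatted{
#' {
#'   "schema_version": 1,
#'   "protocol": { "presentation": "parallel", "dilution_mode": "fixed_count",
#'                 "cycle_length": 20, "n_cycles": 50, ... },
#'   "params":   { "burst_A": 20, "burst_B": 10, "burst_AB": [17, 17],
#'                 "r": 0.3, "lysis": 1.0, "adsorption": 1e-9 },
#'   "sweep":    { "grid_A": [5, ..., 25], "grid_B": [...],
#'                 "retention_threshold": 0.01 }
#' }
#' }
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A list with validated `config` ([protocol_config()]), `params`
#'   ([kinetic_params()]) and `sweep` ([sweep_config()] or `NULL`).
#' @export
load_config <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse config: ", conditionMessage(e),
                         call. = FALSE)
                  })
  known_top <- c("schema_version", "protocol", "params", "sweep")
  unknown <- setdiff(names(doc), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(doc$schema_version) &&
      doc$schema_version != config_schema_version) {
    stop("unsupported schema_version: ", doc$schema_version, call. = FALSE)
  }
  check_keys <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste(paste0(where, ".", unknown), collapse = ", "),
           call. = FALSE)
    }
  }
  prot <- doc$protocol
  check_keys(prot, protocol_keys, "protocol")
  config <- do.call(protocol_config, as.list(prot))
  par <- doc$params
  check_keys(par, params_keys, "params")
  params <- do.call(kinetic_params, as.list(par))
  sweep <- NULL
  if (!is.null(doc$sweep)) {
    check_keys(doc$sweep, sweep_keys, "sweep")
    sweep <- do.call(sweep_config,
                     c(list(base_protocol = config, base_params = params),
                       as.list(doc$sweep)))
  }
  list(config = config, params = params, sweep = sweep)
}

config_as_list <- function(config, params) {
  list(schema_version = config_schema_version,
       software = paste0("phagetrain ",
                         as.character(utils::packageVersion("phagetrain"))),
       protocol = unclass(config),
       params = list(burst_A = unname(params$burst["phiA", "A"]),
                     burst_B = unname(params$burst["phiB", "B"]),
                     burst_AB = unname(params$burst["phiAB", ]),
                     r = unname(params$cell_growth),
                     lysis = unname(params$lysis[1, 1]),
                     adsorption = unname(max(params$adsorption))))
}

# 10 significant digits, C locale scientific notation: byte-stable output.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.9e", x))
}

write_tsv_deterministic <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run or sweep outputs to disk
#'
#' Writes deterministic, byte-stable tab-separated outputs plus a JSON
#' metadata sidecar echoing the full effective configuration and the
#' software version. A `phage_run` produces `cycles.tsv` (per-cycle start
#' and end densities, fold growth, end cells) and, when trajectories were
#' recorded, `trajectory.tsv` (time, culture_id, all state variables). A
#' `phage_sweep` produces `grid.tsv` in long format. Numeric values are
#' written with 10 significant digits in scientific notation.
#'
#' @param result A `phage_run` or `phage_sweep`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(result, "phage_run")) {
    p <- file.path(dir, "cycles.tsv")
    write_tsv_deterministic(result$cycles, p)
    paths <- c(paths, p)
    if (!is.null(result$trajectories)) {
      p2 <- file.path(dir, "trajectory.tsv")
      write_tsv_deterministic(trajectory_frame(result), p2)
      paths <- c(paths, p2)
    }
    meta <- config_as_list(result$config, result$params)
  } else if (inherits(result, "phage_sweep")) {
    p <- file.path(dir, "grid.tsv")
    write_tsv_deterministic(result$grid, p)
    paths <- c(paths, p)
    meta <- config_as_list(result$config$base_protocol,
                           result$config$base_params)
    meta$sweep <- list(grid_A = result$config$grid_A,
                       grid_B = result$config$grid_B,
                       retention_threshold = result$config$retention_threshold)
  } else {
    stop("write_outputs expects a phage_run or phage_sweep", call. = FALSE)
  }
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}

# Long trajectory table: time, culture_id, then every state column.
trajectory_frame <- function(run) {
  stopifnot(inherits(run, "phage_run"), !is.null(run$trajectories))
  chunks <- list()
  for (i in seq_along(run$trajectories)) {
    offset <- (i - 1) * run$config$cycle_length
    trs <- run$trajectories[[i]]
    for (cu in names(trs)) {
      tr <- trs[[cu]]
      chunks[[length(chunks) + 1L]] <-
        data.frame(time = offset + tr$times, culture_id = cu, tr$states,
                   check.names = FALSE)
    }
  }
  do.call(rbind, chunks)
}

#' Read back a sweep grid written by [write_outputs()]
#'
#' @param path Path to a `grid.tsv`.
#' @return A data frame with the grid columns, numeric columns restored.
#' @export
read_grid_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df
}
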