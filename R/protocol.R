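#' Serial-transfer protocol configuration
#'
#' Describes one directed-evolution experiment: how the two hosts are
#' presented to the phage pool, how the pool is diluted between cycles, and
#' the cycle/renewal bookkeeping.
#'
#' Presentation modes: `"parallel"` grows the full pool on each host in
#' separate concurrent cultures and pools them; `"sequential"` grows the pool
#' on one host per cycle, alternating hosts; `"mixed"` grows the pool on both
#' hosts in a single culture. Dilution modes: `"fixed_count"` rescales the
#' pooled phage to a set total density (preserving proportions),
#' `"fixed_volume"` transfers a set fraction of each density,
#' `"fixed_count_by_host"` (parallel only) rescales each host culture's pool
#' separately to the set total before combining.
#'
#' @param presentation One of `"parallel"`, `"sequential"`, `"mixed"`.
#' @param dilution_mode One of `"fixed_count"`, `"fixed_volume"`,
#'   `"fixed_count_by_host"`.
#' @param cycle_length Growth-phase length in time units (default 20).
#' @param n_cycles Number of transfer cycles (default 50).
#' @param cell_renewal_density Uninfected cell density at the start of each
#'   cycle for every renewed host (default 1e7).
#' @param dilution_count Total phage density after fixed-count dilution
#'   (default 1000).
#' @param transfer_fraction Fraction transferred under fixed-volume dilution
#'   (default 0.05).
#' @param carry_infected Carry infected compartments through dilution into
#'   the next cycle? Default `FALSE` (phages recovered free of cells).
#' @param initial_total_phage Total free-phage density at the start of cycle
#'   one, split equally among the three phages (default 1000).
#' @param sequential_first_host Host presented in the first sequential cycle
#'   (default `"A"`).
#' @param density_floor Absolute density below which a diluted compartment is
#'   zeroed (default 1e-30), preventing denormal drift; deterministic ODE
#'   densities never reach exactly zero on their own.
#' @return An object of class `protocol_config`.
#' @examples
#' protocol_config("parallel", "fixed_count")
#' @export
protocol_config <- function(presentation = c("parallel", "sequential", "mixed"),
                            dilution_mode = c("fixed_count", "fixed_volume",
                                              "fixed_count_by_host"),
                            cycle_length = 20, n_cycles = 50,
                            cell_renewal_density = 1e7,
                            dilution_count = 1000,
                            transfer_fraction = 0.05,
                            carry_infected = FALSE,
                            initial_total_phage = 1000,
                            sequential_first_host = "A",
                            density_floor = 1e-30) {
  presentation <- match.arg(presentation)
  dilution_mode <- match.arg(dilution_mode)
  obj <- structure(
    list(presentation = presentation, dilution_mode = dilution_mode,
         cycle_length = cycle_length, n_cycles = as.integer(n_cycles),
         cell_renewal_density = cell_renewal_density,
         dilution_count = dilution_count,
         transfer_fraction = transfer_fraction,
         carry_infected = isTRUE(carry_infected),
         initial_total_phage = initial_total_phage,
         sequential_first_host = sequential_first_host,
         density_floor = density_floor),
    class = "protocol_config")
  validate_protocol_config(obj)
  obj
}

validate_protocol_config <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (cfg$cycle_length <= 0) stop("cycle_length must be > 0", call. = FALSE)
  if (cfg$n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (cfg$transfer_fraction <= 0 || cfg$transfer_fraction > 1) {
    stop("transfer_fraction must be in (0, 1]", call. = FALSE)
  }
  if (cfg$dilution_count <= 0) stop("dilution_count must be > 0", call. = FALSE)
  if (cfg$cell_renewal_density <= 0 || cfg$initial_total_phage < 0) {
    stop("densities must be positive", call. = FALSE)
  }
  if (!cfg$sequential_first_host %in% HOSTS) {
    stop("sequential_first_host must be one of ",
         paste(HOSTS, collapse = ", "), call. = FALSE)
  }
  if (cfg$dilution_mode == "fixed_count_by_host" &&
      cfg$presentation != "parallel") {
    stop("fixed_count_by_host dilution is only valid with parallel ",
         "presentation", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Serial-transfer protocol:", x$presentation, "presentation,",
      x$dilution_mode, "dilution\n")
  cat(sprintf("  %d cycles of %g time units; cell renewal %.3g per host\n",
              x$n_cycles, x$cycle_length, x$cell_renewal_density))
  dil <- switch(x$dilution_mode,
                fixed_count = sprintf("to total %g", x$dilution_count),
                fixed_volume = sprintf("%g%% transferred",
                                       100 * x$transfer_fraction),
                fixed_count_by_host = sprintf("to %g per host culture",
                                              x$dilution_count))
  cat("  dilution", dil, "| carry infected:", x$carry_infected, "\n")
  invisible(x)
}

# Host schedule for one cycle (0-based index): which hosts each culture
# contains. Returns a list of character vectors, one per culture.
cycle_hosts <- function(config, cycle_index) {
  switch(config$presentation,
         parallel = list(A = "A", B = "B"),
         sequential = {
           first <- config$sequential_first_host
           other <- setdiff(HOSTS, first)
           h <- if (cycle_index %% 2 == 0) first else other
           setNames(list(h), h)
         },
         mixed = list(AB = HOSTS))
}

#' Seed the cultures for one cycle
#'
#' Builds the fresh cultures at the start of a cycle: every culture receives
#' the full incoming phage density map, and each of its hosts is renewed at
#' `cell_renewal_density`. Parallel presentation yields one culture per host;
#' sequential yields a single culture whose host alternates by cycle; mixed
#' yields a single culture containing both hosts. Infected compartments start
#' at zero unless `carry_infected` is set and `incoming_infected` is given.
#'
#' @param config A [protocol_config()].
#' @param cycle_index 0-based cycle number (drives the sequential host
#'   alternation).
#' @param incoming_phage Named phage density map after the previous dilution.
#' @param incoming_infected Optional 3x2 diluted infected-density matrix
#'   (used only when `config$carry_infected`).
#' @return Named list of [culture_state()] objects.
#' @export
build_cycle_cultures <- function(config, cycle_index, incoming_phage,
                                 incoming_infected = NULL) {
  stopifnot(all(incoming_phage >= 0))
  hosts_by_culture <- cycle_hosts(config, cycle_index)
  lapply(hosts_by_culture, function(hosts) {
    cells <- setNames(numeric(2), HOSTS)
    cells[hosts] <- config$cell_renewal_density
    I <- NULL
    present <- hosts
    if (config$carry_infected && !is.null(incoming_infected)) {
      I <- incoming_infected
      # carried infected cells of a non-renewed host still lyse in the new
      # culture, so that host counts as present (with zero uninfected cells)
      present <- union(hosts, HOSTS[colSums(I) > 0])
    }
    culture_state(free_phage = incoming_phage, cells = cells, infected = I,
                  hosts_present = present)
  })
}

#' Pool end-of-cycle cultures
#'
#' Combines equal-volume cultures into the transfer pool: the pooled density
#' of each phage is the sum of its free-phage densities across cultures.
#' Infected compartments are discarded (phages recovered free of cells)
#' unless `carry_infected`, in which case they are summed likewise.
#'
#' @param cultures Non-empty list of end-of-cycle [culture_state()] objects.
#' @param carry_infected Keep pooled infected compartments?
#' @return List with `free_phage` (named phage density map) and `infected`
#'   (3x2 matrix, or `NULL` when discarded).
#' @export
pool_cultures <- function(cultures, carry_infected = FALSE) {
  if (length(cultures) == 0L) stop("no cultures to pool", call. = FALSE)
  P <- Reduce(`+`, lapply(cultures, `[[`, "free_phage"))
  I <- if (carry_infected) {
    Reduce(`+`, lapply(cultures, `[[`, "infected"))
  }
  list(free_phage = P, infected = I)
}

#' Dilute the transfer pool
#'
#' Applies the configured dilution rule to the pooled phage densities.
#' `fixed_count` rescales so the total equals `dilution_count`, preserving
#' relative proportions exactly; `fixed_volume` multiplies every density by
#' `transfer_fraction`; `fixed_count_by_host` rescales each culture's pool
#' separately to `dilution_count` and sums across cultures (so the combined
#' incoming total is `dilution_count` per culture). An all-zero pool returns
#' zeros with an extinction flag rather than dividing by zero.
#'
#' @param pooled Named phage density map (the pooled pool).
#' @param config A [protocol_config()].
#' @param per_culture_pools For `fixed_count_by_host` only: named list of
#'   per-culture phage density maps (pre-pooling).
#' @return List with `phage` (next cycle's incoming densities), `factor`
#'   (scale factor applied; per-culture vector for by-host dilution) and
#'   `extinct` (logical).
#' @export
apply_dilution <- function(pooled, config, per_culture_pools = NULL) {
  stopifnot(all(pooled >= 0))
  mode <- config$dilution_mode
  if (mode == "fixed_count_by_host") {
    if (is.null(per_culture_pools)) {
      stop("fixed_count_by_host requires per_culture_pools", call. = FALSE)
    }
    factors <- vapply(per_culture_pools, function(p) {
      tot <- sum(p)
      if (tot > 0) config$dilution_count / tot else 0
    }, numeric(1))
    out <- Reduce(`+`, Map(function(p, f) p * f, per_culture_pools,
                           as.list(factors)))
    return(list(phage = out, factor = factors, extinct = all(out == 0)))
  }
  total <- sum(pooled)
  if (total == 0) {
    return(list(phage = pooled * 0, factor = 0, extinct = TRUE))
  }
  factor <- switch(mode,
                   fixed_count = config$dilution_count / total,
                   fixed_volume = config$transfer_fraction)
  list(phage = pooled * factor, factor = factor, extinct = FALSE)
}

#' Run a serial-transfer protocol
#'
#' Executes `n_cycles` of seed-grow-pool-dilute. Each cycle seeds cultures
#' per the presentation mode, integrates the infection dynamics for
#' `cycle_length` time units, pools free phage across cultures, and dilutes
#' into the next cycle. The run starts from equal densities of the three
#' phages totalling `initial_total_phage`. Final frequencies are taken from
#' the pooled free phage at the end of the last growth phase, before the
#' final dilution.
#'
#' @param config A [protocol_config()].
#' @param params A [kinetic_params()].
#' @param solver,step Passed to [integrate_culture()].
#' @param record_trajectories Keep within-cycle trajectories (sampled at unit
#'   times)? Default `FALSE` (endpoint only; much lighter).
#' @return An object of class `phage_run`: the per-cycle records
#'   (`$cycles`, a data frame), per-cycle per-culture start/end densities
#'   (`$culture_detail`), `$final_frequencies`, `$final_total_phage`,
#'   `$extinct`, and (optionally) `$trajectories`.
#' @examples
#' cfg <- protocol_config("parallel", "fixed_count", n_cycles = 5)
#' par <- kinetic_params(burst_A = 20, burst_B = 10, burst_AB = 17, r = 0.3)
#' run <- run_protocol(cfg, par)
#' run$final_frequencies
#' @export
run_protocol <- function(config, params, solver = c("euler", "adaptive"),
                         step = 0.001, record_trajectories = FALSE) {
  solver <- match.arg(solver)
  validate_protocol_config(config)
  validate_kinetic_params(params)

  incoming_P <- setNames(rep(config$initial_total_phage / 3, 3), PHAGES)
  incoming_I <- NULL
  extinct <- FALSE
  records <- vector("list", config$n_cycles)
  detail <- vector("list", config$n_cycles)
  trajectories <- if (record_trajectories) vector("list", config$n_cycles)
  pooled_end <- incoming_P

  for (cyc in seq_len(config$n_cycles) - 1L) {
    cultures <- build_cycle_cultures(config, cyc, incoming_P, incoming_I)
    sample_dt <- if (record_trajectories) 1 else 0
    trajs <- lapply(cultures, function(cs) {
      tryCatch(
        integrate_culture(cs, params, config$cycle_length, solver = solver,
                          step = step, sample_dt = sample_dt),
        error = function(e) {
          stop("cycle ", cyc, ": ", conditionMessage(e), call. = FALSE)
        })
    })
    ends <- lapply(trajs, `[[`, "final")
    pool <- pool_cultures(ends, config$carry_infected)
    pooled_end <- pool$free_phage
    end_cells <- Reduce(`+`, lapply(ends, `[[`, "cells"))

    start_total <- sum(incoming_P)
    detail[[cyc + 1L]] <- list(
      hosts = cycle_hosts(config, cyc),
      start = incoming_P,
      end_by_culture = lapply(ends, `[[`, "free_phage"))
    records[[cyc + 1L]] <- data.frame(
      cycle_index = cyc,
      hosts = paste(unlist(cycle_hosts(config, cyc)), collapse = "+"),
      start_phiA = incoming_P["phiA"], start_phiB = incoming_P["phiB"],
      start_phiAB = incoming_P["phiAB"],
      end_phiA = pooled_end["phiA"], end_phiB = pooled_end["phiB"],
      end_phiAB = pooled_end["phiAB"],
      end_cells_A = end_cells["A"], end_cells_B = end_cells["B"],
      fold_growth = if (start_total > 0) sum(pooled_end) / start_total else NA_real_,
      row.names = NULL)
    if (record_trajectories) trajectories[[cyc + 1L]] <- trajs

    per_pools <- if (config$dilution_mode == "fixed_count_by_host") {
      lapply(ends, `[[`, "free_phage")
    }
    dil <- apply_dilution(pooled_end, config, per_pools)
    incoming_P <- dil$phage
    incoming_P[incoming_P < config$density_floor] <- 0
    if (config$carry_infected && !is.null(pool$infected)) {
      f <- if (length(dil$factor) > 1L) mean(dil$factor) else dil$factor
      incoming_I <- pool$infected * f
      incoming_I[incoming_I < config$density_floor] <- 0
    }
    if (dil$extinct) extinct <- TRUE
  }

  cycles <- do.call(rbind, records)
  total <- sum(pooled_end)
  freqs <- if (total > 0) pooled_end / total else pooled_end * 0
  structure(
    list(config = config, params = params, cycles = cycles,
         culture_detail = detail,
         final_frequencies = freqs, final_total_phage = total,
         extinct = extinct, solver = solver,
         trajectories = if (record_trajectories) trajectories),
    class = "phage_run")
}

#' Per-cycle fold growth of the phage pool
#'
#' End-of-cycle pooled free phage divided by the post-dilution total that
#' started the cycle.
#'
#' @param run A `phage_run`.
#' @param cycle 0-based cycle index (default: last cycle).
#' @return Scalar fold growth; `NA` (with a warning) if the cycle started
#'   with zero phage.
#' @export
fold_growth <- function(run, cycle = NULL) {
  stopifnot(inherits(run, "phage_run"))
  if (is.null(cycle)) cycle <- max(run$cycles$cycle_index)
  row <- run$cycles[run$cycles$cycle_index == cycle, ]
  if (nrow(row) != 1L) stop("no such cycle: ", cycle, call. = FALSE)
  if (is.na(row$fold_growth)) {
    warning("cycle ", cycle, " started with zero total phage")
  }
  row$fold_growth
}

#' @export
print.phage_run <- function(x, ...) {
  cat("Serial-transfer run:", x$config$presentation, "presentation,",
      x$config$dilution_mode, "dilution,",
      x$config$n_cycles, "cycles\n")
  cat("generalist bursts:", paste(x$params$burst["phiAB", ], collapse = "/"),
      " specialists:", x$params$burst["phiA", "A"], "/",
      x$params$burst["phiB", "B"],
      " r:", paste(unique(x$params$cell_growth), collapse = "/"), "\n")
  cat("final total phage (pre-dilution):",
      format(x$final_total_phage, digits = 4), "\n")
  cat("final frequencies:\n")
  print(round(x$final_frequencies, 4))
  if (x$extinct) cat("NOTE: pool hit demographic extinction\n")
  invisible(x)
}

#' @export
summary.phage_run <- function(object, retention_threshold = 0.01, ...) {
  cls <- classify_retention(object$final_frequencies, retention_threshold)
  out <- list(run = object, retention = cls,
              threshold = retention_threshold,
              last_fold_growth = fold_growth(object))
  class(out) <- "summary.phage_run"
  out
}

#' @export
print.summary.phage_run <- function(x, ...) {
  print(x$run)
  cat("last-cycle fold growth:", format(x$last_fold_growth, digits = 4), "\n")
  cat("retention (threshold ", x$threshold, "): ",
      paste(sprintf("%s=%s", names(x$retention), x$retention),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.phage_run <- function(x, ...) x$cycles

#' Plot per-cycle phage densities of a run
#'
#' End-of-cycle pooled free-phage density per phage on a log10 scale,
#' one line per phage, against cycle number. With
#' `type = "trajectory"` (requires `record_trajectories = TRUE` in
#' [run_protocol()]) plots the within-cycle total free phage against time,
#' the short-term dynamics view.
#'
#' @param x A `phage_run`.
#' @param type `"cycles"` (default) or `"trajectory"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted values.
#' @export
plot.phage_run <- function(x, type = c("cycles", "trajectory"), ...) {
  type <- match.arg(type)
  if (type == "cycles") {
    m <- as.matrix(x$cycles[, c("end_phiA", "end_phiB", "end_phiAB")])
    m[m <= 0] <- NA
    matplot(x$cycles$cycle_index, log10(m), type = "l", lty = 1, lwd = 2,
            col = c("#1b9e77", "#d95f02", "#7570b3"),
            xlab = "cycle", ylab = "log10 end-of-cycle density", ...)
    legend("bottomright", legend = PHAGES, lty = 1, lwd = 2,
           col = c("#1b9e77", "#d95f02", "#7570b3"), bty = "n")
    invisible(m)
  } else {
    if (is.null(x$trajectories)) {
      stop("run_protocol(..., record_trajectories = TRUE) required",
           call. = FALSE)
    }
    tt <- unlist(lapply(seq_along(x$trajectories), function(i) {
      tr <- x$trajectories[[i]][[1]]
      (i - 1) * x$config$cycle_length + tr$times
    }))
    per_phage <- sapply(PHAGES, function(ph) {
      unlist(lapply(x$trajectories, function(trs) {
        Reduce(`+`, lapply(trs, function(tr) tr$states[, paste0("P_", ph)]))
      }))
    })
    per_phage[per_phage <= 0] <- NA
    matplot(tt, log10(per_phage), type = "l", lty = 1, lwd = 1.5,
            col = c("#1b9e77", "#d95f02", "#7570b3"),
            xlab = "time", ylab = "log10 free phage density", ...)
    legend("bottomright", legend = PHAGES, lty = 1, lwd = 2,
           col = c("#1b9e77", "#d95f02", "#7570b3"), bty = "n")
    invisible(per_phage)
  }
}
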