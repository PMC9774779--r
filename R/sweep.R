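#' Burst-size sweep configuration
#'
#' A grid over the generalist's two burst sizes for a fixed protocol and
#' fixed specialist parameters, producing heat-map data of which phages are
#' retained.
#'
#' @param base_protocol A [protocol_config()].
#' @param base_params A [kinetic_params()]; the specialist bursts and all
#'   rates are held fixed while the generalist bursts are swept.
#' @param grid_A,grid_B Strictly increasing burst-size grids for the
#'   generalist on hosts A and B (default 5..25 step 1, the canonical burst
#'   range).
#' @param retention_threshold Final frequency at or above which a phage
#'   counts as retained (default 0.01).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(base_protocol, base_params,
                         grid_A = 5:25, grid_B = 5:25,
                         retention_threshold = 0.01) {
  validate_protocol_config(base_protocol)
  validate_kinetic_params(base_params)
  stopifnot(length(grid_A) >= 1, length(grid_B) >= 1,
            all(diff(grid_A) > 0), all(diff(grid_B) > 0),
            retention_threshold > 0, retention_threshold < 1)
  structure(list(base_protocol = base_protocol, base_params = base_params,
                 grid_A = as.numeric(grid_A), grid_B = as.numeric(grid_B),
                 retention_threshold = retention_threshold),
            class = "sweep_config")
}

#' Classify phage retention from final frequencies
#'
#' A phage is retained when its final frequency is at or above the
#' threshold; the heat maps' notion of "maintained" made numeric.
#'
#' @param frequencies Named phage frequency map (summing to 1 when the pool
#'   is non-empty).
#' @param threshold Retention threshold in (0, 1).
#' @return Named character map phage -> `"retained"`/`"lost"`.
#' @examples
#' classify_retention(c(phiA = 1, phiB = 0, phiAB = 0))
#' @export
classify_retention <- function(frequencies, threshold = 0.01) {
  stopifnot(all(frequencies >= 0), threshold > 0, threshold < 1)
  setNames(ifelse(frequencies >= threshold, "retained", "lost"),
           names(frequencies))
}

#' Sweep generalist burst sizes
#'
#' Runs [run_protocol()] once per grid point with the generalist's bursts
#' substituted, recording final frequencies and retention per phage.
#' Deterministic: identical inputs give identical outputs, independent of
#' evaluation order. A failed integration at one point is recorded with an
#' error marker and does not abort the sweep.
#'
#' @param config A [sweep_config()].
#' @param solver,step Passed to [run_protocol()].
#' @param progress Print a dot per grid row? Default `FALSE`.
#' @return An object of class `phage_sweep`: a data frame `$grid` with one
#'   row per grid point (`b_AB_A`, `b_AB_B`, per-phage frequency and
#'   retention, `total_phage`, `extinct`, `error`), plus the sweep
#'   configuration.
#' @examples
#' cfg <- protocol_config("parallel", "fixed_count", n_cycles = 3)
#' par <- kinetic_params(burst_A = 15, burst_B = 15, r = 0.3)
#' sw <- run_sweep(sweep_config(cfg, par, grid_A = c(5, 25), grid_B = c(5, 25)))
#' sw$grid
#' @export
run_sweep <- function(config, solver = c("euler", "adaptive"), step = 0.001,
                      progress = FALSE) {
  solver <- match.arg(solver)
  stopifnot(inherits(config, "sweep_config"))
  pts <- expand.grid(b_AB_A = config$grid_A, b_AB_B = config$grid_B,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pts))
  for (idx in seq_len(nrow(pts))) {
    bA <- pts$b_AB_A[idx]
    bB <- pts$b_AB_B[idx]
    params <- set_generalist_burst(config$base_params, bA, bB)
    res <- tryCatch(
      run_protocol(config$base_protocol, params, solver = solver,
                   step = step),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[idx]] <- data.frame(
        b_AB_A = bA, b_AB_B = bB,
        freq_phiA = NA_real_, freq_phiB = NA_real_, freq_phiAB = NA_real_,
        retained_phiA = NA, retained_phiB = NA, retained_phiAB = NA,
        total_phage = NA_real_, extinct = NA,
        error = conditionMessage(res))
    } else {
      f <- res$final_frequencies
      cls <- classify_retention(f, config$retention_threshold)
      rows[[idx]] <- data.frame(
        b_AB_A = bA, b_AB_B = bB,
        freq_phiA = f[["phiA"]], freq_phiB = f[["phiB"]],
        freq_phiAB = f[["phiAB"]],
        retained_phiA = cls[["phiA"]] == "retained",
        retained_phiB = cls[["phiB"]] == "retained",
        retained_phiAB = cls[["phiAB"]] == "retained",
        total_phage = res$final_total_phage, extinct = res$extinct,
        error = NA_character_)
    }
    if (progress && bB == config$grid_B[length(config$grid_B)]) {
      cat(".")
      utils::flush.console()
    }
  }
  if (progress) cat("\n")
  structure(list(grid = do.call(rbind, rows), config = config,
                 solver = solver),
            class = "phage_sweep")
}

#' Fraction of the burst-size grid where a phage is retained
#'
#' @param sweep A `phage_sweep`.
#' @param phage One of `"phiA"`, `"phiB"`, `"phiAB"`.
#' @return Fraction in `[0, 1]` of grid points (excluding errored points)
#'   where the phage's final frequency met the retention threshold.
#' @export
fraction_retained <- function(sweep, phage) {
  stopifnot(inherits(sweep, "phage_sweep"), phage %in% PHAGES)
  col <- sweep$grid[[paste0("retained_", phage)]]
  ok <- !is.na(col)
  if (!any(ok)) stop("no successfully evaluated grid points", call. = FALSE)
  sum(col[ok]) / sum(ok)
}

#' @export
print.phage_sweep <- function(x, ...) {
  g <- x$grid
  cat("Burst-size sweep:", x$config$base_protocol$presentation,
      "presentation,", x$config$base_protocol$dilution_mode, "dilution\n")
  cat(sprintf("  grid %d x %d (b_AB_A in [%g, %g], b_AB_B in [%g, %g])\n",
              length(x$config$grid_A), length(x$config$grid_B),
              min(x$config$grid_A), max(x$config$grid_A),
              min(x$config$grid_B), max(x$config$grid_B)))
  for (ph in PHAGES) {
    cat(sprintf("  %-6s retained in %.1f%% of grid\n", ph,
                100 * fraction_retained(x, ph)))
  }
  if (any(!is.na(g$error))) {
    cat("  ", sum(!is.na(g$error)), "grid points errored\n")
  }
  invisible(x)
}

#' @export
as.data.frame.phage_sweep <- function(x, ...) x$grid

#' Heat map of final frequency across the burst-size grid
#'
#' One panel per requested phage: final frequency (0-1 color scale) against
#' the generalist's burst size on host A (x) and host B (y). The ring marks
#' the specialist burst coordinates.
#'
#' @param x A `phage_sweep`.
#' @param phages Which phages to draw (default all three).
#' @param ... Unused.
#' @return Invisibly `x`.
#' @export
plot.phage_sweep <- function(x, phages = PHAGES, ...) {
  g <- x$grid
  nA <- length(x$config$grid_A)
  nB <- length(x$config$grid_B)
  old <- par(mfrow = c(1, length(phages)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  pal <- hcl.colors(64, "YlOrRd", rev = TRUE)
  bspec <- c(x$config$base_params$burst["phiA", "A"],
             x$config$base_params$burst["phiB", "B"])
  for (ph in phages) {
    z <- matrix(g[[paste0("freq_", ph)]], nrow = nA)
    image(x$config$grid_A, x$config$grid_B, z, zlim = c(0, 1), col = pal,
          xlab = "generalist burst on A", ylab = "generalist burst on B",
          main = ph)
    points(bspec[1], bspec[2], pch = 21, bg = "white", cex = 1.6, lwd = 2)
    box()
  }
  invisible(x)
}
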