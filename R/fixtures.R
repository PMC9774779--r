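#' Canonical scenario fixtures
#'
#' Ready-made configurations for the canonical study conditions, named after
#' the heat-map / dynamics panels they reproduce. All use the default cycle
#' of 20 time units (50 cycles), cell renewal at 1e7, lysis rate 1.0 and
#' adsorption 1e-9; only presentation, dilution, bacterial growth rate,
#' burst sizes and (for the 40-step variant) cycle length differ:
#'
#' \describe{
#'   \item{fig2}{Parallel, fixed-count 1000, r = 0.3, specialists 15/15;
#'     burst-size sweep.}
#'   \item{fig3}{Parallel, fixed-count 1000, r = 0.3, specialists 20/10;
#'     sweep.}
#'   \item{fig4}{As fig3 but r = 0.1 (the demographic-extinction regime);
#'     sweep.}
#'   \item{fig5A}{Single run of the fig4 conditions with generalist bursts
#'     17/17 (only the A-specialist survives).}
#'   \item{fig5B}{Single run of the fig3 conditions with generalist 17/17
#'     (A-specialist and generalist survive).}
#'   \item{fig6}{Parallel, fixed-volume 5\%, r = 0.1, specialists 20/10;
#'     sweep.}
#'   \item{fig7}{Parallel, per-host fixed-count 1000, r = 0.1, specialists
#'     20/10; sweep.}
#'   \item{fig8}{Sequential, fixed-count 1000, r = 0.3, specialists 20/10;
#'     sweep.}
#'   \item{fig9}{Mixed, fixed-count 1000, r = 0.3, specialists 20/10;
#'     sweep.}
#' }
#'
#' @param name One of the scenario names above.
#' @param grid_A,grid_B Optional sweep-grid override (e.g. a coarser grid).
#' @return A list with `name`, `config` ([protocol_config()]), `params`
#'   ([kinetic_params()]) and `sweep` (a [sweep_config()], or `NULL` for the
#'   single-run scenarios).
#' @examples
#' fx <- scenario_fixture("fig4")
#' fx$config
#' @export
scenario_fixture <- function(name = c("fig2", "fig3", "fig4", "fig5A",
                                      "fig5B", "fig6", "fig7", "fig8",
                                      "fig9"),
                             grid_A = 5:25, grid_B = 5:25) {
  name <- match.arg(name)
  spec <- switch(name,
    fig2  = list(pres = "parallel", dil = "fixed_count", r = 0.3,
                 bA = 15, bB = 15, sweep = TRUE),
    fig3  = list(pres = "parallel", dil = "fixed_count", r = 0.3,
                 bA = 20, bB = 10, sweep = TRUE),
    fig4  = list(pres = "parallel", dil = "fixed_count", r = 0.1,
                 bA = 20, bB = 10, sweep = TRUE),
    fig5A = list(pres = "parallel", dil = "fixed_count", r = 0.1,
                 bA = 20, bB = 10, sweep = FALSE, gen = c(17, 17)),
    fig5B = list(pres = "parallel", dil = "fixed_count", r = 0.3,
                 bA = 20, bB = 10, sweep = FALSE, gen = c(17, 17)),
    fig6  = list(pres = "parallel", dil = "fixed_volume", r = 0.1,
                 bA = 20, bB = 10, sweep = TRUE),
    fig7  = list(pres = "parallel", dil = "fixed_count_by_host", r = 0.1,
                 bA = 20, bB = 10, sweep = TRUE),
    fig8  = list(pres = "sequential", dil = "fixed_count", r = 0.3,
                 bA = 20, bB = 10, sweep = TRUE),
    fig9  = list(pres = "mixed", dil = "fixed_count", r = 0.3,
                 bA = 20, bB = 10, sweep = TRUE))
  config <- protocol_config(presentation = spec$pres,
                            dilution_mode = spec$dil)
  gen <- if (is.null(spec$gen)) c(15, 15) else spec$gen
  params <- kinetic_params(burst_A = spec$bA, burst_B = spec$bB,
                           burst_AB = gen, r = spec$r)
  sweep <- if (spec$sweep) {
    sweep_config(config, params, grid_A = grid_A, grid_B = grid_B)
  }
  list(name = name, config = config, params = params, sweep = sweep)
}

#' List the canonical scenario fixtures
#'
#' @return A data frame with one row per fixture and its headline settings.
#' @export
list_fixtures <- function() {
  names <- c("fig2", "fig3", "fig4", "fig5A", "fig5B", "fig6", "fig7",
             "fig8", "fig9")
  do.call(rbind, lapply(names, function(nm) {
    fx <- scenario_fixture(nm)
    data.frame(name = nm,
               presentation = fx$config$presentation,
               dilution = fx$config$dilution_mode,
               r = unname(fx$params$cell_growth["A"]),
               burst_A = unname(fx$params$burst["phiA", "A"]),
               burst_B = unname(fx$params$burst["phiB", "B"]),
               sweep = !is.null(fx$sweep))
  }))
}
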