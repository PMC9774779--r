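#' Per-cycle growth numbers
#'
#' The heuristic layer reduces phage growth in one culture to a single
#' number N[i,j]: descendants per phage of strain i at the end of a culture
#' of host j, measured immediately before dilution. Specialists in cultures
#' of their non-permissive host are assigned 1 (survival without growth).
#'
#' @param N_AA A-specialist growth on host A.
#' @param N_BB B-specialist growth on host B.
#' @param N_ABA,N_ABB Generalist growth on hosts A and B.
#' @return An object of class `growth_numbers`: a 3x2 phage-by-host matrix
#'   with the non-permissive entries fixed at 1.
#' @examples
#' growth_numbers(100, 100, 100, 100)
#' @export
growth_numbers <- function(N_AA, N_BB, N_ABA, N_ABB) {
  stopifnot(N_AA >= 0, N_BB >= 0, N_ABA >= 0, N_ABB >= 0)
  N <- matrix(1, 3, 2, dimnames = list(PHAGES, HOSTS))
  N["phiA", "A"] <- N_AA
  N["phiB", "B"] <- N_BB
  N["phiAB", ] <- c(N_ABA, N_ABB)
  structure(N, class = c("growth_numbers", "matrix"))
}

#' @export
print.growth_numbers <- function(x, ...) {
  cat("Per-cycle growth numbers N[i,j] (non-permissive entries = 1):\n")
  print(unclass(x))
  invisible(x)
}

#' Specialist-vs-generalist selection ratios under Parallel presentation
#'
#' After one Parallel cycle (grow on each host separately, pool), the pooled
#' descendants per phage are N_AA + 1 for the A-specialist, N_BB + 1 for the
#' B-specialist, and N_ABA + N_ABB for the generalist. The per-cycle change
#' in each specialist's ratio to the generalist is therefore
#' \deqn{(N_{A|A} + 1) / (N_{AB|A} + N_{AB|B})}
#' and the analogue for B. A value above 1 means that specialist gains on
#' the generalist each cycle. The generalist's pooled sum is its "arithmetic
#' advantage": with equal per-host growth all around, each specialist's ratio
#' is about 1/2.
#'
#' @param g A [growth_numbers()] object.
#' @return Named numeric `c(A = ..., B = ...)`.
#' @examples
#' parallel_ratios(growth_numbers(100, 100, 100, 100))
#' @export
parallel_ratios <- function(g) {
  stopifnot(inherits(g, "growth_numbers"))
  denom <- g["phiAB", "A"] + g["phiAB", "B"]
  if (denom <= 0) stop("generalist pooled growth is zero; ratios undefined",
                       call. = FALSE)
  c(A = (g["phiA", "A"] + 1) / denom,
    B = (g["phiB", "B"] + 1) / denom)
}

#' Specialist-vs-generalist selection ratios under Sequential presentation
#'
#' Over one full host alternation (grow on A, transfer, grow on B), each
#' specialist multiplies by its single-host growth times 1 (survival on the
#' non-permissive host), while the generalist multiplies by the product of
#' its growth on both hosts. The relative performances are
#' \deqn{N_{A|A} / (N_{AB|A} \cdot N_{AB|B})}
#' and the analogue for B: the generalist's advantage is multiplicative
#' (geometric), which is why sequential presentation so strongly favors
#' generalists.
#'
#' @param g A [growth_numbers()] object.
#' @return Named numeric `c(A = ..., B = ...)`.
#' @examples
#' sequential_ratios(growth_numbers(100, 100, 10, 10))
#' @export
sequential_ratios <- function(g) {
  stopifnot(inherits(g, "growth_numbers"))
  denom <- g["phiAB", "A"] * g["phiAB", "B"]
  if (denom <= 0) stop("generalist product growth is zero; ratios undefined",
                       call. = FALSE)
  c(A = g["phiA", "A"] / denom,
    B = g["phiB", "B"] / denom)
}

#' Heuristic retention prediction from selection ratios
#'
#' Classifies each phage from the closed-form per-cycle ratios. A specialist
#' whose ratio is below 1 loses ground to the generalist every cycle and is
#' predicted lost. The prediction is asymmetric: a specialist ratio above 1
#' does not force generalist loss, because the generalist can be maintained
#' by its growth on the other host; the generalist is predicted lost only
#' when both specialists beat it.
#'
#' @param g A [growth_numbers()] object.
#' @param presentation `"parallel"` or `"sequential"`.
#' @return Named character map phage -> `"retained"`/`"lost"`.
#' @examples
#' heuristic_outcome(growth_numbers(100, 100, 100, 100), "parallel")
#' @export
heuristic_outcome <- function(g, presentation = c("parallel", "sequential")) {
  presentation <- match.arg(presentation)
  r <- switch(presentation,
              parallel = parallel_ratios(g),
              sequential = sequential_ratios(g))
  out <- c(phiA = if (r["A"] < 1) "lost" else "retained",
           phiB = if (r["B"] < 1) "lost" else "retained",
           phiAB = if (r["A"] > 1 && r["B"] > 1) "lost" else "retained")
  setNames(out, PHAGES)
}

#' Diagnose a 'tyranny of generalists'
#'
#' Under Parallel presentation a generalist can displace a specialist that
#' beats it on their shared host, because the generalist's pooled output is
#' dominated by a more productive other host. This report compares per-host
#' growth with the pooled ratios and flags each specialist that wins its own
#' host (N_X|X > N_AB|X) yet is predicted lost overall (pooled ratio < 1).
#'
#' @param g A [growth_numbers()] object.
#' @return A list with `ratios` (parallel ratios), `per_host_winner` (named
#'   by host), and `tyranny` (named logical by specialist phage).
#' @examples
#' # good host A dominates the pool; the B-specialist wins on B yet is lost
#' generalist_tyranny(growth_numbers(1000, 8, 900, 4))
#' @export
generalist_tyranny <- function(g) {
  r <- parallel_ratios(g)
  winner <- c(
    A = if (g["phiA", "A"] > g["phiAB", "A"]) "phiA" else "phiAB",
    B = if (g["phiB", "B"] > g["phiAB", "B"]) "phiB" else "phiAB")
  tyr <- c(phiA = winner["A"] == "phiA" && r["A"] < 1,
           phiB = winner["B"] == "phiB" && r["B"] < 1)
  list(ratios = r, per_host_winner = winner,
       tyranny = setNames(as.logical(tyr), c("phiA", "phiB")))
}

#' Measure growth numbers from a simulated cycle
#'
#' Extracts N[i,j] from a run's records: the end-of-cycle free-phage density
#' of phage i in the culture containing host j, divided by that culture's
#' start density, immediately before dilution. Supported for parallel cycles
#' (both hosts measured) and sequential cycles (the active host; the other
#' host's specialist sits at its survival value 1). Mixed cultures are
#' refused: with both hosts in one culture the generalist's growth cannot be
#' attributed to either host.
#'
#' @param run A `phage_run`.
#' @param cycle 0-based cycle index.
#' @return A [growth_numbers()] object.
#' @export
measure_growth_numbers <- function(run, cycle) {
  stopifnot(inherits(run, "phage_run"))
  if (run$config$presentation == "mixed") {
    stop("growth numbers are per host; a mixed culture cannot attribute ",
         "the generalist's growth to one host", call. = FALSE)
  }
  d <- run$culture_detail[[cycle + 1L]]
  if (is.null(d)) stop("no such cycle: ", cycle, call. = FALSE)
  if (any(d$start <= 0)) {
    bad <- PHAGES[d$start <= 0]
    stop("cycle ", cycle, " started with zero density for ",
         paste(bad, collapse = ", "), "; growth numbers undefined",
         call. = FALSE)
  }
  N <- matrix(1, 3, 2, dimnames = list(PHAGES, HOSTS))
  for (cu in names(d$end_by_culture)) {
    hosts <- d$hosts[[cu]]
    for (h in hosts) {
      ratio <- d$end_by_culture[[cu]] / d$start
      N[, h] <- ratio
    }
  }
  # non-permissive entries are 1 by convention (and the dynamics give
  # exactly that: k = 0 means survival without growth)
  perm <- strain_set()$permissivity
  N[!perm] <- 1
  structure(N, class = c("growth_numbers", "matrix"))
}

#' Bottleneck survival probability of a single new mutant
#'
#' When the end-of-cycle pool is only partially used to seed the next round,
#' a single newly arisen mutant phage survives the transfer only if (i) it
#' is among the volumes carried forward and (ii) it lands in a culture whose
#' host permits its growth. With equal-volume arithmetic the net probability
#' is
#' \deqn{(volumes\_used / volumes\_pooled) \times (n\_useful / n\_cultures).}
#' In the canonical eight-well Parallel layout with 37 culture volumes
#' pooled, fewer than 4.5 used, and 2 useful wells out of 8, this gives
#' about 12\% x 25\% = 3\%.
#'
#' @param volumes_pooled Number of culture volumes combined into the pool.
#' @param volumes_used Volumes of that pool used in the next round
#'   (`<= volumes_pooled`).
#' @param n_cultures Number of cultures in the next round.
#' @param n_useful_cultures Cultures containing a host the mutant can grow
#'   on (in `[0, n_cultures]`).
#' @return Probability in `[0, 1]`.
#' @examples
#' bottleneck_survival(37, 4.5, 8, 2)
#' @export
bottleneck_survival <- function(volumes_pooled, volumes_used, n_cultures,
                                n_useful_cultures) {
  stopifnot(volumes_pooled > 0, volumes_used > 0,
            volumes_used <= volumes_pooled,
            n_cultures >= 1, n_useful_cultures >= 0,
            n_useful_cultures <= n_cultures)
  (volumes_used / volumes_pooled) * (n_useful_cultures / n_cultures)
}
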