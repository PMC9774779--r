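#' Time derivatives of a culture state
#'
#' Right-hand side of the within-culture infection model. For phage i and
#' host j (summing over hosts present in the culture):
#' \deqn{dP_i/dt = \sum_j (b_{ij} \lambda_{ij} I_{ij} - k_{ij} P_i C_j)}
#' \deqn{dI_{ij}/dt = k_{ij} P_i C_j - \lambda_{ij} I_{ij}}
#' \deqn{dC_j/dt = r_j C_j - \sum_i k_{ij} P_i C_j}
#' Free-phage loss to adsorption on a host equals, term by term, the gain of
#' the corresponding infected compartment. There is no free-phage decay: a
#' phage in a culture with no permissive host is inert.
#'
#' @param state A [culture_state()].
#' @param params A [kinetic_params()].
#' @return A list with components `free_phage`, `infected`, `cells` holding
#'   the rates of change, shaped like the state.
#' @examples
#' s <- culture_state(free_phage = c(phiA = 1000), cells = c(A = 1e7))
#' p <- kinetic_params(burst_A = 20, r = 0.3)
#' phage_derivatives(s, p)$cells
#' @export
phage_derivatives <- function(state, params) {
  validate_culture_state(state)
  P <- state$free_phage
  I <- state$infected
  C <- state$cells
  k <- params$adsorption
  lam <- params$lysis
  b <- params$burst
  # adsorption flux k_ij * P_i * C_j, phage x host
  ads <- k * outer(P, C)
  lys <- lam * I
  dP <- rowSums(b * lys) - rowSums(ads)
  dI <- ads - lys
  dC <- params$cell_growth * C - colSums(ads)
  list(free_phage = setNames(dP, PHAGES),
       infected = dI,
       cells = setNames(dC, HOSTS))
}

# deSolve-compatible RHS on the flat packing.
rhs_flat <- function(t, y, parms) {
  P <- y[1:3]
  I <- matrix(y[4:9], 3, 2)
  C <- y[10:11]
  ads <- parms$adsorption * outer(P, C)
  lys <- parms$lysis * I
  dP <- rowSums(parms$burst * lys) - rowSums(ads)
  dI <- ads - lys
  dC <- parms$cell_growth * C - colSums(ads)
  list(c(dP, as.numeric(dI), dC))
}

#' Integrate one culture through a growth phase
#'
#' Advances the infection model over `duration` time units. The default
#' integrator is fixed-step explicit Euler with step 0.001, implemented in
#' compiled code; `solver = "adaptive"` uses [deSolve::ode()] (lsoda) at
#' tight tolerances and serves as an independent high-accuracy reference.
#' Tiny Euler undershoots below zero (relative magnitude under 1e-12 of the
#' current total density) are clamped to zero; larger undershoots or
#' non-finite values abort with the offending time and variable.
#'
#' @param state Initial [culture_state()].
#' @param params A [kinetic_params()].
#' @param duration Positive length of the growth phase (time units).
#' @param solver `"euler"` (default) or `"adaptive"`.
#' @param step Euler step size (default 0.001).
#' @param rtol,atol Tolerances for the adaptive solver.
#' @param sample_dt Spacing of trajectory samples (default 1 time unit); the
#'   endpoint is always included.
#' @return An object of class `culture_trajectory`: list with `times`
#'   (sample times), `states` (matrix, one row per sample, columns the flat
#'   state variables), and `final` (the end-of-phase `culture_state`).
#' @examples
#' s <- culture_state(free_phage = c(phiA = 1000), cells = c(A = 1e7))
#' p <- kinetic_params(burst_A = 20, r = 0.3)
#' tr <- integrate_culture(s, p, duration = 20)
#' tr$final
#' @export
integrate_culture <- function(state, params, duration,
                              solver = c("euler", "adaptive"),
                              step = 0.001, rtol = 1e-10, atol = 1e-8,
                              sample_dt = 1) {
  solver <- match.arg(solver)
  validate_culture_state(state)
  validate_kinetic_params(params)
  stopifnot(duration > 0)
  y0 <- pack_state(state)
  if (solver == "euler") {
    out <- euler_integrate_cpp(y0, params$burst, params$lysis,
                               params$adsorption, params$cell_growth,
                               duration, step, sample_dt)
    times <- state$time + out$times
    states <- out$states
    colnames(states) <- state_names_flat()
  } else {
    times <- unique(c(seq(0, duration, by = sample_dt), duration))
    sol <- deSolve::ode(y = y0, times = times, func = rhs_flat,
                        parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (any(!is.finite(sol[, -1]))) {
      stop("integration produced non-finite state", call. = FALSE)
    }
    states <- unname(sol[, -1, drop = FALSE])
    colnames(states) <- state_names_flat()
    # lsoda can undershoot 0 within atol near exhaustion; clamp like Euler
    states[states < 0 & states > -atol] <- 0
    if (any(states < 0)) {
      stop("integration produced negative density beyond tolerance",
           call. = FALSE)
    }
    times <- state$time + times
  }
  final <- unpack_state(states[nrow(states), ], times[length(times)],
                        state$hosts_present)
  structure(list(times = times, states = states, final = final,
                 solver = solver),
            class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cat("Culture trajectory (", x$solver, "), ", length(x$times),
      " samples, t in [", format(x$times[1]), ", ",
      format(x$times[length(x$times)]), "]\n", sep = "")
  print(x$final)
  invisible(x)
}

#' @export
as.data.frame.culture_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Early exponential invasion rate of a phage on abundant cells
#'
#' While cells are effectively constant at density C, free phage and
#' infected cells follow a linear 2x2 system whose dominant eigenvalue is
#' the positive root of
#' \deqn{s^2 + (kC + \lambda) s - kC\lambda(b - 1) = 0,}
#' positive exactly when the burst size exceeds 1. This is the exponential
#' rate at which P (and P + I) grows early in a cycle when cells are in
#' excess, and is a useful diagnostic for dilution regimes in which phages
#' never exhaust their hosts.
#'
#' @param params A [kinetic_params()].
#' @param phage,host Strain identifiers; the pair must be permissive.
#' @param cell_density Fixed cell density C (> 0).
#' @return The dominant eigenvalue (scalar growth exponent).
#' @examples
#' p <- kinetic_params(burst_A = 20)
#' invasion_rate(p, "phiA", "A", 1e7)
#' @export
invasion_rate <- function(params, phage, host, cell_density) {
  stopifnot(cell_density > 0, phage %in% PHAGES, host %in% HOSTS)
  if (!params$permissivity[phage, host]) {
    stop("(", phage, ", ", host, ") is not a permissive pair", call. = FALSE)
  }
  k <- params$adsorption[phage, host]
  lam <- params$lysis[phage, host]
  b <- params$burst[phage, host]
  kc <- k * cell_density
  # positive root of s^2 + (kC + lambda) s - kC lambda (b - 1)
  (-(kc + lam) + sqrt((kc + lam)^2 + 4 * kc * lam * (b - 1))) / 2
}
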