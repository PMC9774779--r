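#' Instantaneous state of one culture
#'
#' Densities of free phage, infected cells and uninfected cells in a single
#' well-mixed culture, plus which hosts are present. Hosts not present have
#' zero cells and zero infected compartments; non-permissive infected
#' compartments are identically zero.
#'
#' @param free_phage Named numeric of free-phage densities (names in
#'   `phiA`, `phiB`, `phiAB`; missing phages default to 0).
#' @param cells Named numeric of cell densities (names in `A`, `B`;
#'   missing hosts default to 0).
#' @param infected Optional 3x2 phage-by-host matrix of infected-cell
#'   densities; defaults to all zero.
#' @param hosts_present Character subset of `c("A","B")`; defaults to the
#'   hosts with positive `cells`.
#' @param time Culture clock, dimensionless time units (one unit is roughly
#'   an hour at the canonical parameterization).
#' @return An object of class `culture_state`.
#' @examples
#' culture_state(free_phage = c(phiA = 1000), cells = c(A = 1e7))
#' @export
culture_state <- function(free_phage = NULL, cells = NULL, infected = NULL,
                          hosts_present = NULL, time = 0) {
  P <- setNames(numeric(3), PHAGES)
  if (!is.null(free_phage)) {
    if (is.null(names(free_phage)) && length(free_phage) == 3L) {
      names(free_phage) <- PHAGES
    }
    stopifnot(all(names(free_phage) %in% PHAGES))
    P[names(free_phage)] <- free_phage
  }
  C <- setNames(numeric(2), HOSTS)
  if (!is.null(cells)) {
    if (is.null(names(cells)) && length(cells) == 2L) names(cells) <- HOSTS
    stopifnot(all(names(cells) %in% HOSTS))
    C[names(cells)] <- cells
  }
  I <- matrix(0, 3, 2, dimnames = list(PHAGES, HOSTS))
  if (!is.null(infected)) {
    stopifnot(is.matrix(infected), all(dim(infected) == c(3L, 2L)))
    I[, ] <- infected
  }
  if (is.null(hosts_present)) hosts_present <- HOSTS[C > 0]
  stopifnot(all(hosts_present %in% HOSTS))
  obj <- structure(
    list(time = time, free_phage = P, infected = I, cells = C,
         hosts_present = hosts_present),
    class = "culture_state")
  validate_culture_state(obj)
  obj
}

validate_culture_state <- function(s) {
  perm <- strain_set()$permissivity
  if (any(s$free_phage < 0) || any(s$infected < 0) || any(s$cells < 0)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  if (any(s$infected[!perm] != 0)) {
    stop("infected compartment must be 0 for non-permissive pairs",
         call. = FALSE)
  }
  absent <- setdiff(HOSTS, s$hosts_present)
  if (length(absent) &&
      (any(s$cells[absent] != 0) || any(s$infected[, absent, drop = FALSE] != 0))) {
    stop("cells and infected compartments must be 0 for hosts not present",
         call. = FALSE)
  }
  invisible(s)
}

#' @export
print.culture_state <- function(x, ...) {
  cat("Culture at t =", format(x$time),
      "(hosts:", paste(x$hosts_present, collapse = ","), ")\n")
  cat("free phage: ", paste(sprintf("%s=%.4g", PHAGES, x$free_phage),
                            collapse = "  "), "\n")
  cat("cells:      ", paste(sprintf("%s=%.4g", HOSTS, x$cells),
                            collapse = "  "), "\n")
  tot_inf <- colSums(x$infected)
  cat("infected:   ", paste(sprintf("on %s=%.4g", HOSTS, tot_inf),
                            collapse = "  "), "\n")
  invisible(x)
}

# Flat packing used by the integrators: c(P[3], I[3x2 col-major], C[2]).
state_names_flat <- function() {
  c(paste0("P_", PHAGES),
    paste0("I_", rep(PHAGES, 2), "_", rep(HOSTS, each = 3)),
    paste0("C_", HOSTS))
}

pack_state <- function(s) {
  setNames(c(s$free_phage, as.numeric(s$infected), s$cells),
           state_names_flat())
}

unpack_state <- function(y, time, hosts_present) {
  culture_state(
    free_phage = setNames(y[1:3], PHAGES),
    infected = matrix(y[4:9], 3, 2, dimnames = list(PHAGES, HOSTS)),
    cells = setNames(y[10:11], HOSTS),
    hosts_present = hosts_present,
    time = time)
}
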