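#' The canonical strain set
#'
#' Two bacterial hosts (A, B) and three lytic phages: the A-specialist
#' `phiA` (permissive on A only), the B-specialist `phiB` (B only) and the
#' generalist `phiAB` (both hosts). Permissivity is the complete phage-by-host
#' map of which infections are possible; non-permissive pairs have adsorption
#' rate zero everywhere in the package.
#'
#' @return A list with `phage_ids`, `host_ids` and a logical `permissivity`
#'   matrix (phage x host).
#' @examples
#' strain_set()$permissivity
#' @export
strain_set <- function() {
  perm <- matrix(c(TRUE, FALSE,
                   FALSE, TRUE,
                   TRUE, TRUE),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(PHAGES, HOSTS))
  list(phage_ids = PHAGES, host_ids = HOSTS, permissivity = perm)
}

#' Kinetic parameters of the phage-bacteria system
#'
#' Collects the rate constants of the within-culture infection model: burst
#' sizes `b[i,j]` (progeny per lysed cell), lysis rates `lambda[i,j]` (per
#' time; the reciprocal is the mean latent period), adsorption rate constants
#' `k[i,j]` (volume per phage per time) and bacterial growth rates `r[j]`
#' (per time). Only burst size typically differs between strains; lysis rate
#' and adsorption default to the canonical values 1.0 and 1e-9 for every
#' permissive pair. Adsorption is forced to exactly zero on non-permissive
#' pairs, so a specialist in a culture of its non-permissive host neither
#' grows nor decays.
#'
#' @param burst_A Burst size of the A-specialist on host A.
#' @param burst_B Burst size of the B-specialist on host B.
#' @param burst_AB Length-2 numeric: generalist burst size on hosts A and B
#'   (recycled if length 1).
#' @param r Bacterial growth rate; scalar (both hosts) or length-2 vector
#'   named or ordered as (A, B).
#' @param lysis Lysis rate; scalar or a full 3x2 phage-by-host matrix.
#' @param adsorption Adsorption rate constant; scalar or a full 3x2 matrix.
#'   Non-permissive entries are zeroed regardless.
#' @return An object of class `kinetic_params`: list of matrices `burst`,
#'   `lysis`, `adsorption` (phage x host), vector `cell_growth` (per host)
#'   and the logical `permissivity` map.
#' @examples
#' p <- kinetic_params(burst_A = 20, burst_B = 10, burst_AB = 17, r = 0.3)
#' p$burst
#' @export
kinetic_params <- function(burst_A = 15, burst_B = 15, burst_AB = c(15, 15),
                           r = 0.3, lysis = 1.0, adsorption = 1e-9) {
  ss <- strain_set()
  if (length(burst_AB) == 1L) burst_AB <- rep(burst_AB, 2L)
  b <- matrix(0, 3, 2, dimnames = dimnames(ss$permissivity))
  b["phiA", "A"] <- burst_A
  b["phiB", "B"] <- burst_B
  b["phiAB", ] <- burst_AB
  expand <- function(x, what) {
    if (length(x) == 1L) {
      m <- matrix(x, 3, 2, dimnames = dimnames(ss$permissivity))
    } else if (is.matrix(x) && all(dim(x) == c(3L, 2L))) {
      m <- x
      dimnames(m) <- dimnames(ss$permissivity)
    } else {
      stop(what, " must be a scalar or a 3x2 phage-by-host matrix",
           call. = FALSE)
    }
    m
  }
  lam <- expand(lysis, "lysis")
  k <- expand(adsorption, "adsorption")
  k[!ss$permissivity] <- 0
  b[!ss$permissivity] <- 0
  if (length(r) == 1L) r <- rep(r, 2L)
  r <- setNames(as.numeric(r), HOSTS)
  obj <- structure(
    list(burst = b, lysis = lam, adsorption = k, cell_growth = r,
         permissivity = ss$permissivity),
    class = "kinetic_params")
  validate_kinetic_params(obj)
  obj
}

validate_kinetic_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(p$burst < 0) || any(p$lysis < 0) || any(p$adsorption < 0) ||
      any(p$cell_growth < 0)) {
    stop("kinetic parameters must be non-negative", call. = FALSE)
  }
  if (any(p$adsorption[!p$permissivity] != 0)) {
    bad <- which(p$adsorption != 0 & !p$permissivity, arr.ind = TRUE)[1, ]
    stop("adsorption must be 0 on non-permissive pair (",
         PHAGES[bad[1]], ", ", HOSTS[bad[2]], ")", call. = FALSE)
  }
  if (any(p$adsorption > 0 & p$lysis <= 0)) {
    stop("lysis rate must be positive wherever adsorption is positive",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (phage x host)\n")
  cat("burst sizes:\n")
  print(x$burst)
  cat("cell growth rate r:", paste(sprintf("%s=%g", HOSTS, x$cell_growth),
                                   collapse = ", "), "\n")
  cat("lysis rate:", format(x$lysis[1, 1]),
      "| adsorption k:", format(max(x$adsorption)), "\n")
  invisible(x)
}

#' Replace the generalist's burst sizes
#'
#' Convenience used by burst-size sweeps: returns a copy of `params` with the
#' generalist's bursts on hosts A and B set to `b_on_A`, `b_on_B`.
#'
#' @param params A [kinetic_params()] object.
#' @param b_on_A,b_on_B New generalist burst sizes on hosts A and B.
#' @return A `kinetic_params` object.
#' @export
set_generalist_burst <- function(params, b_on_A, b_on_B) {
  params$burst["phiAB", "A"] <- b_on_A
  params$burst["phiAB", "B"] <- b_on_B
  validate_kinetic_params(params)
  params
}
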