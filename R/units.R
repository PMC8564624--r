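#' Unit system for converting diffusion parameters to real values
#'
#' Bundles the per-site per-year mutation rate, the generation time and the
#' effective sequence length `L` from which the analysed SNPs derive. The
#' population mutation parameter is \eqn{\theta = 4 N_{ref} \mu} with
#' \eqn{\mu} the per-generation mutation rate of the whole analysed
#' sequence, i.e. `mu_site_year * generation_years * L`.
#'
#' The defaults are the direct germ-line rate estimated for the collared
#' flycatcher, 2.3e-9 mutations per site per year, and a two-year
#' generation time.
#'
#' @param mu_site_year mutation rate per site per year.
#' @param generation_years generation time in years.
#' @param L effective sequence length in bp (see [estimate_L()]).
#' @return an object of class `unit_system`.
#' @export
unit_system <- function(mu_site_year = 2.3e-9, generation_years = 2, L) {
  stopifnot(mu_site_year > 0, generation_years > 0, L > 0)
  structure(
    list(mu_site_year = mu_site_year, generation_years = generation_years,
         L = L, mu_locus_gen = mu_site_year * generation_years * L),
    class = "unit_system"
  )
}

#' Effective sequence length behind a filtered SNP set
#'
#' When SNPs are ascertained from `L_unfiltered` bp of callable sequence
#' but only a filtered subset enters the spectrum, the effective length is
#' scaled by the retained fraction of segregating sites:
#' `L = L_unfiltered * seg_filtered / seg_unfiltered`.
#'
#' @param L_unfiltered callable sequence length in bp.
#' @param seg_filtered segregating sites after filtering.
#' @param seg_unfiltered segregating sites before filtering.
#' @return effective length in bp; zero is flagged with a warning.
#' @export
estimate_L <- function(L_unfiltered, seg_filtered, seg_unfiltered) {
  if (L_unfiltered <= 0) stop("'L_unfiltered' must be > 0")
  if (seg_unfiltered <= 0) stop("'seg_unfiltered' must be > 0")
  if (seg_filtered < 0) stop("'seg_filtered' must be >= 0")
  if (seg_filtered > seg_unfiltered) {
    stop("'seg_filtered' cannot exceed 'seg_unfiltered'")
  }
  L <- L_unfiltered * seg_filtered / seg_unfiltered
  if (L == 0) warning("degenerate effective length: no filtered sites")
  L
}

#' Convert fitted diffusion parameters to real units
#'
#' Given a profiled \eqn{\hat\theta} and a [unit_system()], recovers the
#' reference diploid size `N_ref = theta / (4 * mu_site_year *
#' generation_years * L)`, converts times from units of
#' \eqn{2 N_{ref}} generations to years (`t * 2 * N_ref *
#' generation_years`), sizes to diploid individuals (`nu * N_ref`) and
#' migration rates to per-generation migrant fractions (`M / (2 *
#' N_ref)`).
#'
#' @param theta_hat profiled population mutation parameter.
#' @param params named diffusion-unit parameter vector (names starting
#'   `nu` are sizes, `t` times, `m` migration rates).
#' @param units a [unit_system()].
#' @return a list with `N_ref`, `theta_hat` and a named vector
#'   `real` (sizes in individuals, times in years, migration as
#'   per-generation fractions).
#' @export
convert_units <- function(theta_hat, params, units) {
  stopifnot(inherits(units, "unit_system"))
  if (!is.numeric(theta_hat) || length(theta_hat) != 1L || theta_hat <= 0) {
    stop("'theta_hat' must be a single positive number")
  }
  N_ref <- theta_hat / (4 * units$mu_locus_gen)
  real <- params
  for (nm in names(params)) {
    real[[nm]] <- switch(param_kind(nm),
      size = params[[nm]] * N_ref,
      time = params[[nm]] * 2 * N_ref * units$generation_years,
      mig = params[[nm]] / (2 * N_ref)
    )
  }
  list(N_ref = N_ref, theta_hat = theta_hat, real = real)
}

#' @rdname convert_units
#' @param real named vector of real-unit parameters (as produced by
#'   `convert_units`).
#' @param N_ref reference diploid size.
#' @return `diffusion_units` returns the named diffusion-unit vector; the
#'   two functions are exact inverses.
#' @export
diffusion_units <- function(real, N_ref, units) {
  stopifnot(inherits(units, "unit_system"), N_ref > 0)
  out <- real
  for (nm in names(real)) {
    out[[nm]] <- switch(param_kind(nm),
      size = real[[nm]] / N_ref,
      time = real[[nm]] / (2 * N_ref * units$generation_years),
      mig = real[[nm]] * 2 * N_ref
    )
  }
  out
}

param_kind <- function(nm) {
  if (grepl("^nu", nm)) return("size")
  if (grepl("^t", nm)) return("time")
  if (grepl("^m", nm)) return("mig")
  stop("cannot classify parameter '", nm, "'")
}
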