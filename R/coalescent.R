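#' Simulate genotypes and a joint SFS under the structured coalescent
#'
#' Hudson-style coalescent simulation with piecewise-constant deme sizes,
#' continuous migration, population splits (deme mergers backward in time)
#' and infinite-sites mutation. Each of the `n_sites` loci receives an
#' independent genealogy; every mutation dropped on a genealogy becomes one
#' biallelic segregating site, so the realized number of segregating sites
#' is approximately `n_sites * theta_per_site / 2 * E[total branch length]`.
#' The exact joint tabulation of derived allele counts is always returned;
#' with `return_genotypes = TRUE` the per-individual diploid genotypes are
#' returned as well (haploids are paired consecutively within populations).
#'
#' @param model a [demographic_model()].
#' @param sample_sizes haploid sample sizes per population (at least 2 per
#'   sampled population; even values are required when genotypes are
#'   requested).
#' @param n_sites number of independent loci to simulate.
#' @param theta_per_site scaled mutation rate \eqn{4 N_{ref} \mu} per locus.
#' @param seed integer seed; the simulation is bit-reproducible under it.
#' @param return_genotypes return the per-site genotype table?
#' @return a list with elements
#'   \describe{
#'     \item{`sfs`}{a [freq_spectrum()] holding the true joint tabulation
#'       of derived allele counts (unfolded; corners masked).}
#'     \item{`n_seg`}{total number of segregating sites.}
#'     \item{`genotypes`}{(if requested) integer matrix, sites x
#'       individuals, of derived-allele dosages 0/1/2.}
#'     \item{`sites`}{(if requested) data.frame of site metadata (chrom,
#'       1-based pos, allele1 = ancestral, allele2 = derived).}
#'     \item{`pop`}{(if requested) population label per individual.}
#'   }
#' @examples
#' m <- two_pop_model(t_split = 0.2, m12 = 1, m21 = 1)
#' sim <- simulate_coalescent(m, c(6, 6), n_sites = 200,
#'                            theta_per_site = 0.01, seed = 1)
#' sim$sfs
#' @export
simulate_coalescent <- function(model, sample_sizes, n_sites,
                                theta_per_site, seed = NULL,
                                return_genotypes = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != model$n_pops) {
    stop("sample_sizes must give one haploid count per model population")
  }
  if (any(sample_sizes < 2L)) {
    stop("at least 2 haploids per sampled population are required")
  }
  if (return_genotypes && any(sample_sizes %% 2L != 0L)) {
    stop("haploid sample sizes must be even to form diploid genotypes")
  }
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (theta_per_site < 0) stop("theta_per_site must be >= 0")
  epochs <- demography_epochs(model)
  if (!is.null(seed)) set.seed(as.integer(seed))
  raw <- sim_coalescent_cpp(epochs, sample_sizes, as.integer(n_sites),
                            theta_per_site, return_genotypes)
  sfs <- freq_spectrum(raw$sfs, sample_sizes, folded = FALSE)
  out <- list(sfs = sfs, n_seg = spectrum_total(sfs))
  if (return_genotypes) {
    hap <- raw$haplotypes
    n_ind <- ncol(hap) %/% 2L
    geno <- hap[, seq(1L, ncol(hap), by = 2L), drop = FALSE] +
      hap[, seq(2L, ncol(hap), by = 2L), drop = FALSE]
    n_sites_out <- nrow(geno)
    out$genotypes <- geno
    out$sites <- data.frame(
      chrom = rep("sim1", n_sites_out),
      pos = seq_len(n_sites_out) * 10L,
      allele1 = rep("A", n_sites_out),
      allele2 = rep("C", n_sites_out),
      stringsAsFactors = FALSE
    )
    ind_per_pop <- sample_sizes %/% 2L
    out$pop <- rep(paste0("pop", seq_along(sample_sizes)), ind_per_pop)
    colnames(out$genotypes) <- paste0(out$pop, "_",
                                      unlist(lapply(ind_per_pop, seq_len)))
  }
  out
}

#' Watterson's estimator of theta
#'
#' \eqn{\hat\theta_W = S / H_{n-1}} with \eqn{H_k} the k-th harmonic
#' number, for a single-population sample of `n` haploids with `S`
#' segregating sites. Used as an independent check that simulated data
#' carry the requested mutation rate.
#'
#' @param n_seg number of segregating sites.
#' @param n_hap haploid sample size.
#' @export
theta_watterson <- function(n_seg, n_hap) {
  n_seg / sum(1 / seq_len(n_hap - 1L))
}
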