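#' Genotype-likelihood matrices
#'
#' Container for per-site, per-individual likelihoods of the three diploid
#' genotypes (homozygous allele1, heterozygous, homozygous allele2).
#' Likelihoods are stored on the linear scale, normalized so the maximum
#' of each (site, individual) triple is 1; an all-equal ("flat") triple
#' means the individual has no data at the site.
#'
#' @param gl numeric array of dimension (sites, individuals, 3).
#' @param sites data.frame with columns `chrom`, `pos` (1-based),
#'   `allele1`, `allele2`.
#' @param pop character/factor of population labels, one per individual.
#' @param ids optional individual IDs.
#' @return an object of class `gl_matrix`.
#' @export
gl_matrix <- function(gl, sites, pop, ids = NULL) {
  if (length(dim(gl)) != 3L || dim(gl)[3] != 3L) {
    stop("'gl' must be a (sites x individuals x 3) array")
  }
  n_sites <- dim(gl)[1]
  n_ind <- dim(gl)[2]
  req <- c("chrom", "pos", "allele1", "allele2")
  if (!is.data.frame(sites) || !all(req %in% names(sites))) {
    stop("'sites' needs columns chrom, pos, allele1, allele2")
  }
  if (nrow(sites) != n_sites) stop("site table does not match gl rows")
  if (length(pop) != n_ind) stop("one population label per individual needed")
  if (any(gl < 0, na.rm = TRUE)) stop("likelihoods must be >= 0")
  gl[is.na(gl)] <- 0
  # normalize; all-zero triples become flat (missing)
  mx <- apply(gl, c(1, 2), max)
  flat <- mx <= 0
  mx[flat] <- 1
  gl <- gl / array(rep(mx, 3), dim = dim(gl))
  if (any(flat)) {
    idx <- which(flat, arr.ind = TRUE)
    for (k in 1:3) gl[cbind(idx, k)] <- 1
  }
  if (is.null(ids)) ids <- paste0("ind", seq_len(n_ind))
  structure(
    list(gl = gl, sites = as.data.frame(sites), pop = as.character(pop),
         ids = as.character(ids)),
    class = "gl_matrix"
  )
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat("<gl_matrix> ", nrow(x$sites), " sites x ", length(x$ids),
      " individuals\n", sep = "")
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$pop)),
                                      table(x$pop)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a gl_matrix by sites
#' @param x a [gl_matrix()].
#' @param i site indices (logical or integer).
#' @param ... unused.
#' @export
`[.gl_matrix` <- function(x, i, ...) {
  gl_matrix(x$gl[i, , , drop = FALSE], x$sites[i, , drop = FALSE],
            x$pop, x$ids)
}

# flat triples carry no data: the coverage filter's missing-data convention
gl_missing <- function(gl_site) {
  apply(gl_site, 1, function(tr) max(tr) - min(tr) < 1e-12)
}

#' Simulate genotype likelihoods from a read-sampling model
#'
#' Forward-simulates the independent-read model that the ML frequency
#' estimator inverts. Per site and individual, read depth is Poisson with
#' mean `mean_depth`; each read copies one of the two haplotypes and is
#' mis-read with probability `error_rate` (errors land uniformly on the
#' other three bases, so reads matching neither site allele are discarded).
#' The genotype likelihood of g alternate copies is the product over kept
#' reads of \eqn{P(base | g)} with \eqn{P(alt | g) = (g/2)(1-\epsilon) +
#' (1-g/2)\epsilon/3}. Zero-depth individuals get a flat (missing) triple.
#'
#' @param genotypes integer matrix (sites x individuals) of 0/1/2
#'   alternate-allele dosages, e.g. from [simulate_coalescent()].
#' @param sites site table (chrom, pos, allele1, allele2); a default is
#'   generated if `NULL`.
#' @param pop population labels per individual.
#' @param mean_depth expected reads per site per individual (>= 0).
#' @param error_rate per-base error probability, in [0, 0.5).
#' @param seed integer seed.
#' @return a [gl_matrix()] with attribute `depth` (read-depth matrix).
#' @export
simulate_genotype_likelihoods <- function(genotypes, sites = NULL,
                                          pop = NULL, mean_depth = 10,
                                          error_rate = 0.01, seed = NULL) {
  genotypes <- as.matrix(genotypes)
  if (any(!genotypes %in% 0:2)) stop("genotypes must be coded 0/1/2")
  if (mean_depth < 0) stop("'mean_depth' must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("'error_rate' must lie in [0, 0.5)")
  }
  n_sites <- nrow(genotypes)
  n_ind <- ncol(genotypes)
  if (is.null(pop)) pop <- rep("pop1", n_ind)
  if (is.null(sites)) {
    sites <- data.frame(chrom = "sim1", pos = seq_len(n_sites) * 10L,
                        allele1 = "A", allele2 = "C",
                        stringsAsFactors = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  eps <- error_rate
  depth <- matrix(rpois(n_sites * n_ind, mean_depth), n_sites, n_ind)
  kept <- matrix(rbinom(n_sites * n_ind, depth, 1 - 2 * eps / 3),
                 n_sites, n_ind)
  p_alt_read <- function(g) (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
  # conditional on a read being kept, it shows the alternate allele w.p.
  # p_alt / (1 - 2 eps / 3)
  p_alt_kept <- p_alt_read(genotypes) / (1 - 2 * eps / 3)
  alt_reads <- matrix(rbinom(n_sites * n_ind, kept, p_alt_kept),
                      n_sites, n_ind)
  ref_reads <- kept - alt_reads
  gl <- array(0, dim = c(n_sites, n_ind, 3))
  xlogp <- function(n, p) ifelse(n == 0L, 0, n * log(p))  # 0 * log(0) = 0
  for (g in 0:2) {
    # P(ref | g) = P(alt | 2 - g) by allele symmetry
    gl[, , g + 1] <- xlogp(alt_reads, p_alt_read(g)) +
      xlogp(ref_reads, p_alt_read(2 - g))
  }
  # normalize per (site, individual) on the log scale then exponentiate
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  for (k in 1:3) gl[, , k] <- exp(gl[, , k] - mx)
  out <- gl_matrix(gl, sites, pop)
  attr(out, "depth") <- kept
  out
}
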