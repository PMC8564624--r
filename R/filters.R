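#' Read a BED file of regions to exclude
#'
#' BED intervals are 0-based, half-open `[start, end)`. Only the first
#' three columns are used. Malformed lines raise an error naming the line
#' number.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("malformed BED line ", i, ": non-numeric coordinates")
    }
    if (end < start) stop("malformed BED line ", i, ": end < start")
    j <- j + 1L
    out[[j]] <- data.frame(chrom = f[1L], start = start, end = end,
                           stringsAsFactors = FALSE)
  }
  if (j == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(j)])
}

#' Remove sites that overlap masked regions
#'
#' A site is removed if its single base (1-based position `pos`, i.e.
#' 0-based coordinate `pos - 1`) intersects any BED interval — the
#' minimum-overlap-of-1-bp rule used when excluding coding, conserved and
#' CpG-rich regions from demographic analyses.
#'
#' @param sites data.frame with at least `chrom` and `pos` (1-based).
#' @param mask BED intervals as from [read_bed()]; an empty mask retains
#'   everything.
#' @return logical vector, `TRUE` for retained sites.
#' @export
apply_region_mask <- function(sites, mask) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  keep <- rep(TRUE, nrow(sites))
  if (is.null(mask) || nrow(mask) == 0L) return(keep)
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  for (ch in unique(sites$chrom)) {
    iv <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    ord <- order(iv$start)
    starts <- iv$start[ord]
    ends_cummax <- cummax(iv$end[ord])
    sel <- which(sites$chrom == ch)
    x <- sites$pos[sel] - 1  # 0-based base coordinate
    k <- findInterval(x, starts)  # intervals with start <= x
    covered <- k > 0 & ends_cummax[pmax(k, 1L)] > x
    keep[sel][covered] <- FALSE
  }
  keep
}

#' Apply the site filter chain
#'
#' Retains sites with (1) data in at least `ceiling(min_ind_frac * n_total)`
#' individuals, (2) polymorphism p-value strictly below `p_max`, and (3)
#' minor allele frequency strictly above `maf_min`, applied in that order
#' so each site is attributed to the first rule it violates. Defaults are
#' the production thresholds: 2/3 coverage, p < 1e-6, MAF > 0.05.
#'
#' @param estimates site-estimate table from [estimate_site_frequencies()].
#' @param n_total total number of individuals in the cohort.
#' @param min_ind_frac minimum fraction of individuals with data.
#' @param p_max strict upper bound on the polymorphism p-value.
#' @param maf_min strict lower bound on the minor allele frequency.
#' @return list with `retained` (filtered table), `keep` (logical vector)
#'   and `attrition` (named counts removed by each rule, in application
#'   order).
#' @export
apply_site_filters <- function(estimates, n_total, min_ind_frac = 2 / 3,
                               p_max = 1e-6, maf_min = 0.05) {
  req <- c("n_ind", "p_value", "f_hat")
  stopifnot(all(req %in% names(estimates)))
  min_ind <- ceiling(min_ind_frac * n_total)
  fail_cov <- is.na(estimates$n_ind) | estimates$n_ind < min_ind
  fail_p <- !fail_cov & (is.na(estimates$p_value) |
                           estimates$p_value >= p_max)
  fail_maf <- !fail_cov & !fail_p & (is.na(estimates$f_hat) |
                                       estimates$f_hat <= maf_min)
  keep <- !(fail_cov | fail_p | fail_maf)
  list(
    retained = estimates[keep, , drop = FALSE],
    keep = keep,
    attrition = c(coverage = sum(fail_cov), p_value = sum(fail_p),
                  maf = sum(fail_maf))
  )
}
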