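#' Site frequency spectra
#'
#' A `freq_spectrum` wraps a d-dimensional array (d = 1, 2 or 3) of site
#' counts indexed by derived (or minor) allele count in each population,
#' together with the haploid sample sizes, a folded flag and a logical mask
#' of cells that carry no likelihood weight. The `[i1+1, i2+1, ...]` cell
#' holds the number of sites at which `i1` copies of the derived allele were
#' seen in population 1, `i2` in population 2, and so on. The "corner"
#' cells (no derived copies anywhere; derived fixed everywhere) are always
#' masked: they are unobservable among variable sites.
#'
#' @param counts numeric array (or vector for one population) of
#'   non-negative cell values with dimensions `sample_sizes + 1`.
#' @param sample_sizes haploid sample sizes per population; defaults to
#'   `dim(counts) - 1`.
#' @param folded logical; is this a minor-allele (folded) spectrum?
#' @param mask optional logical array, `TRUE` for masked cells, same shape
#'   as `counts`. The corners are masked in addition to anything given
#'   here. For folded spectra the non-canonical half-lattice is masked.
#' @param pop_ids optional character vector of population labels.
#' @return an object of class `freq_spectrum`.
#' @export
freq_spectrum <- function(counts, sample_sizes = NULL, folded = FALSE,
                          mask = NULL, pop_ids = NULL) {
  if (is.null(dim(counts))) counts <- array(counts, dim = length(counts))
  dims <- dim(counts)
  if (length(dims) < 1L || length(dims) > 3L) {
    stop("spectra must have 1 to 3 population axes")
  }
  if (is.null(sample_sizes)) sample_sizes <- dims - 1L
  sample_sizes <- as.integer(sample_sizes)
  if (!identical(dims, sample_sizes + 1L)) {
    stop("dim(counts) must equal sample_sizes + 1")
  }
  if (any(counts < 0, na.rm = TRUE)) stop("spectrum cells must be >= 0")
  counts[is.na(counts)] <- 0
  m <- array(FALSE, dim = dims)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims) && !(length(dims) == 1L &&
        length(mask) == dims[1L])) {
      stop("mask must have the same shape as counts")
    }
    m <- array(as.logical(mask), dim = dims)
  }
  m[corner_index(dims, "low")] <- TRUE
  m[corner_index(dims, "high")] <- TRUE
  if (folded) m <- m | upper_half_mask(sample_sizes)
  if (!is.null(pop_ids) && length(pop_ids) != length(dims)) {
    stop("pop_ids must name every population axis")
  }
  structure(
    list(counts = counts, sample_sizes = sample_sizes, folded = folded,
         mask = m, pop_ids = pop_ids),
    class = "freq_spectrum"
  )
}

corner_index <- function(dims, which = c("low", "high")) {
  which <- match.arg(which)
  idx <- if (which == "low") rep(1L, length(dims)) else dims
  matrix(idx, nrow = 1L)
}

# Cells on the non-canonical half of the lattice (total derived count above
# n/2) for folded spectra; the exact mid-diagonal stays unmasked.
upper_half_mask <- function(sample_sizes) {
  dims <- sample_sizes + 1L
  grids <- lapply(dims, function(d) seq_len(d) - 1L)
  tot <- Reduce(`+`, make_index_grids(grids))
  array(tot > sum(sample_sizes) / 2, dim = dims)
}

make_index_grids <- function(grids) {
  dims <- vapply(grids, length, 1L)
  lapply(seq_along(grids), function(k) {
    perm <- array(0L, dim = dims)
    sweep_vals <- grids[[k]]
    idx <- slice.index(perm, k)
    array(sweep_vals[idx], dim = dims)
  })
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("<freq_spectrum> ", paste(x$sample_sizes, collapse = " x "),
      " haploids, ", if (x$folded) "folded" else "unfolded", "\n", sep = "")
  cat("  segregating sites (unmasked):",
      format(sum(x$counts[!x$mask]), digits = 8), "\n")
  if (length(x$sample_sizes) <= 2L) {
    pr <- x$counts
    pr[x$mask] <- NA
    print(round(pr, 3))
  }
  invisible(x)
}

#' Fold a spectrum onto minor-allele counts
#'
#' Adds each cell to its complement (all allele counts reversed), masks the
#' non-canonical half of the lattice, and halves the mid-frequency diagonal
#' (which would otherwise be counted twice). Folding conserves the total
#' site count and is idempotent.
#'
#' @param fs a [freq_spectrum()].
#' @return a folded `freq_spectrum`.
#' @export
fold_spectrum <- function(fs) {
  stopifnot(inherits(fs, "freq_spectrum"))
  if (fs$folded) return(fs)
  dims <- dim(fs$counts)
  rev_idx <- lapply(dims, function(d) d:1)
  reversed <- do.call(`[`, c(list(fs$counts), rev_idx, list(drop = FALSE)))
  reversed <- array(reversed, dim = dims)
  tot <- fs$counts + reversed
  grids <- lapply(dims, function(d) seq_len(d) - 1L)
  total_count <- Reduce(`+`, make_index_grids(grids))
  n_tot <- sum(fs$sample_sizes)
  on_mid <- total_count == n_tot / 2
  tot[on_mid] <- tot[on_mid] / 2
  keep_mask <- fs$mask
  freq_spectrum(tot, fs$sample_sizes, folded = TRUE, mask = keep_mask,
                pop_ids = fs$pop_ids)
}

#' Mask spectrum cells below a minor-allele-frequency cutoff
#'
#' When sites are ascertained with a strict MAF filter, spectrum cells
#' whose total minor-allele count corresponds to a frequency at or below
#' the cutoff cannot be observed; masking them keeps a model fit
#' consistent with the ascertainment.
#'
#' @param fs a [freq_spectrum()].
#' @param maf_min the strict MAF cutoff used when filtering sites.
#' @return the spectrum with the additional cells masked.
#' @export
mask_low_maf <- function(fs, maf_min) {
  stopifnot(inherits(fs, "freq_spectrum"))
  dims <- dim(fs$counts)
  grids <- lapply(dims, function(d) seq_len(d) - 1L)
  tot <- Reduce(`+`, make_index_grids(grids))
  n_tot <- sum(fs$sample_sizes)
  minor <- pmin(tot, n_tot - tot)
  extra <- minor / n_tot <= maf_min
  fs$mask <- fs$mask | extra
  fs
}

#' Total unmasked site count of a spectrum
#' @param fs a [freq_spectrum()].
#' @export
spectrum_total <- function(fs) {
  stopifnot(inherits(fs, "freq_spectrum"))
  sum(fs$counts[!fs$mask])
}

#' Read and write dadi-style .fs files
#'
#' The `.fs` text format stores, on the first line, the per-axis array
#' extents (haploid sizes + 1), a `folded`/`unfolded` token and optional
#' quoted population labels; on the second line all cell values in
#' row-major order (last population axis fastest); and on the third line a
#' 0/1 mask in the same order (1 = masked).
#'
#' @param path file path.
#' @rdname fs_io
#' @return `read_fs` returns a [freq_spectrum()]; `write_fs` returns
#'   `path` invisibly.
#' @export
read_fs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed .fs file: ", path)
  head_tok <- scan(text = lines[[1L]], what = character(), quiet = TRUE)
  is_dim <- grepl("^[0-9]+$", head_tok)
  dims <- as.integer(head_tok[is_dim])
  folded <- any(head_tok == "folded")
  pop_ids <- gsub('^"|"$', "", head_tok[!is_dim & head_tok != "folded" &
                                          head_tok != "unfolded"])
  if (!length(pop_ids)) pop_ids <- NULL
  vals <- scan(text = lines[[2L]], what = numeric(), quiet = TRUE)
  if (length(vals) != prod(dims)) stop("value count does not match dims")
  counts <- array_from_rowmajor(vals, dims)
  mask <- NULL
  if (length(lines) >= 3L) {
    mv <- scan(text = lines[[3L]], what = numeric(), quiet = TRUE)
    if (length(mv) == prod(dims)) {
      mask <- array_from_rowmajor(mv, dims) > 0
    }
  }
  freq_spectrum(counts, dims - 1L, folded = folded, mask = mask,
                pop_ids = pop_ids)
}

#' @param fs a [freq_spectrum()].
#' @param digits significant digits for cell values.
#' @rdname fs_io
#' @export
write_fs <- function(fs, path, digits = 12) {
  stopifnot(inherits(fs, "freq_spectrum"))
  dims <- dim(fs$counts)
  head_tok <- c(dims, if (fs$folded) "folded" else "unfolded")
  if (!is.null(fs$pop_ids)) head_tok <- c(head_tok,
                                          sprintf('"%s"', fs$pop_ids))
  vals <- rowmajor_vector(fs$counts)
  mask <- rowmajor_vector(fs$mask * 1L)
  writeLines(c(
    paste(head_tok, collapse = " "),
    paste(format(vals, digits = digits, scientific = TRUE, trim = TRUE),
          collapse = " "),
    paste(mask, collapse = " ")
  ), path)
  invisible(path)
}

array_from_rowmajor <- function(vals, dims) {
  if (length(dims) == 1L) return(array(vals, dim = dims))
  a <- array(vals, dim = rev(dims))
  aperm(a, rev(seq_along(dims)))
}

rowmajor_vector <- function(a) {
  dims <- dim(a)
  if (is.null(dims) || length(dims) == 1L) return(as.vector(a))
  as.vector(aperm(a, rev(seq_along(dims))))
}
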