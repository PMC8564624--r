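#' Read and write Beagle genotype-likelihood text files
#'
#' The Beagle GL format has a header line and one row per site: `marker`
#' (chrom_pos), `allele1`, `allele2` (bases coded 0=A, 1=C, 2=G, 3=T),
#' then three likelihood columns per individual (homozygous allele1,
#' heterozygous, homozygous allele2). Gzipped files are read
#' transparently.
#'
#' @param path file path (.gz allowed for reading).
#' @param pop population labels, one per individual, in file column order.
#' @rdname beagle_io
#' @return `read_beagle` returns a [gl_matrix()].
#' @export
read_beagle <- function(path, pop) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 6L || (ncol(tab) - 3L) %% 3L != 0L) {
    stop("malformed Beagle file: expected 3 + 3*N columns")
  }
  n_ind <- (ncol(tab) - 3L) %/% 3L
  if (length(pop) != n_ind) {
    stop("'pop' must label all ", n_ind, " individuals in the file")
  }
  marker <- as.character(tab[[1L]])
  us <- regexpr("_[^_]*$", marker)
  chrom <- substr(marker, 1L, us - 1L)
  pos <- as.integer(substring(marker, us + 1L))
  if (any(is.na(pos))) stop("marker names must be <chrom>_<pos>")
  base_codes <- c(`0` = "A", `1` = "C", `2` = "G", `3` = "T")
  decode <- function(x) {
    x <- as.character(x)
    ifelse(x %in% names(base_codes), base_codes[x], x)
  }
  sites <- data.frame(chrom = chrom, pos = pos,
                      allele1 = decode(tab[[2L]]),
                      allele2 = decode(tab[[3L]]),
                      stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -(1:3), drop = FALSE])
  ids <- unique(sub("\\.[0-9]+$", "", colnames(vals)))
  if (length(ids) != n_ind) ids <- paste0("ind", seq_len(n_ind))
  gl <- array(0, dim = c(nrow(tab), n_ind, 3L))
  for (g in 1:3) gl[, , g] <- vals[, seq(g, ncol(vals), by = 3L)]
  gl_matrix(gl, sites, pop, ids = ids)
}

#' @param x a [gl_matrix()].
#' @rdname beagle_io
#' @export
write_beagle <- function(x, path) {
  stopifnot(inherits(x, "gl_matrix"))
  codes <- c(A = "0", C = "1", G = "2", T = "3")
  encode <- function(a) ifelse(a %in% names(codes), codes[a], a)
  n_ind <- length(x$ids)
  cols <- vector("list", n_ind)
  for (j in seq_len(n_ind)) {
    cols[[j]] <- cbind(x$gl[, j, 1], x$gl[, j, 2], x$gl[, j, 3])
  }
  m <- do.call(cbind, cols)
  header <- c("marker", "allele1", "allele2", rep(x$ids, each = 3L))
  body <- cbind(paste0(x$sites$chrom, "_", x$sites$pos),
                encode(x$sites$allele1), encode(x$sites$allele2),
                format(m, digits = 6, scientific = FALSE, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
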