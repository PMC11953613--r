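# Expression quantification: mappability-corrected RPKM and median-of-ratios
# size-factor normalisation.

#' Mappability-corrected RPKM
#'
#' Expression normalised by the number of uniquely mappable positions of the
#' gene (its effective length) and by library size:
#' `cRPKM = raw * 1e9 / (mappable_positions * total_mapped)`.
#'
#' @param raw read counts (vectorised).
#' @param mappable_positions uniquely mappable positions per gene (> 0).
#' @param total_mapped total mapped reads of the library (> 0).
#' @return cRPKM values on the same shape as `raw`.
#' @export
compute_crpkm <- function(raw, mappable_positions, total_mapped) {
  if (any(mappable_positions <= 0)) stop("mappable_positions must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  raw * 1e9 / (mappable_positions * total_mapped)
}

#' Median-of-ratios size factors
#'
#' The standard reference-sample normalisation for count matrices: each
#' gene's geometric mean across samples forms a pseudo-reference (genes with
#' any zero count are excluded), and a sample's size factor is the median of
#' its ratios to that reference. For an even number of usable genes the
#' lower median is taken, so the factor is always an observed ratio.
#'
#' @param raw gene x sample count matrix.
#' @return Named numeric vector of strictly positive size factors. A single
#'   sample gets factor 1 by convention; no gene free of zeros is a hard
#'   error (a pseudo-reference fallback over nonzero genes would be needed).
#' @export
size_factors <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) == 1) {
    sf <- 1
    names(sf) <- colnames(raw)
    return(sf)
  }
  usable <- rowSums(raw == 0) == 0
  if (!any(usable)) {
    stop("no gene has nonzero counts in every sample; size factors are ",
         "undefined (consider a pseudo-reference over nonzero counts)")
  }
  lg <- log(raw[usable, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  ratios <- raw[usable, , drop = FALSE] / geo
  sf <- apply(ratios, 2, lower_median)
  names(sf) <- colnames(raw)
  sf
}

#' Build an expression matrix
#'
#' Combines the raw counts with per-gene mappable lengths into the container
#' used downstream: cRPKM (library size = column sum of raw counts),
#' median-of-ratios size factors and normalised counts.
#'
#' @param raw gene x sample integer count matrix with gene IDs as rownames.
#' @param mappable_positions named vector of uniquely mappable positions, one
#'   per gene.
#' @return An object of class `expression_matrix`: a list with elements
#'   `raw`, `mappable_positions`, `crpkm`, `size_factors`, `norm_counts`.
#' @export
expression_matrix <- function(raw, mappable_positions) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw))) stop("raw counts need gene IDs as rownames")
  mp <- mappable_positions[rownames(raw)]
  if (anyNA(mp)) stop("mappable_positions missing for some genes")
  total <- colSums(raw)
  if (any(total <= 0)) stop("library with zero mapped reads")
  crpkm <- compute_crpkm(raw, mp, rep(total, each = nrow(raw)))
  sf <- size_factors(raw)
  structure(
    list(raw = raw, mappable_positions = mp, crpkm = crpkm,
         size_factors = sf,
         norm_counts = sweep(raw, 2, sf, "/")),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$raw), "genes x", ncol(x$raw), "samples\n")
  cat("  size factors:",
      paste(sprintf("%.3g", x$size_factors), collapse = ", "), "\n")
  invisible(x)
}
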