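# Independence analysis of probe-set abundances and enrichment testing.
#
# If probe sets acted independently, the Pearson correlation of two OTUs'
# intensities across n arrays would follow the exact null distribution
#   f(r) = (1 - r^2)^((n-4)/2) / B(1/2, (n-2)/2),   r in [-1, 1],
# the sampling distribution of r for independent bivariate-normal data.
# Probe sharing drags observed within-class correlations toward +1.

#' Construct an OTU x array abundance matrix
#'
#' @param intensities Numeric matrix, rows = OTUs (rownames required),
#'   columns = arrays (colnames required). Rows with any missing value are
#'   dropped with a warning.
#' @param class_of Named character vector mapping OTU id to taxonomic class;
#'   OTUs without an entry get class `"unclassified"`.
#' @return An object of class `abundance_matrix` with fields `intensities`
#'   and `class_of`.
#' @export
abundance_matrix <- function(intensities, class_of = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  bad <- apply(intensities, 1L, anyNA)
  if (any(bad)) {
    warning(sprintf("dropped %d OTU row(s) with missing intensities", sum(bad)))
    intensities <- intensities[!bad, , drop = FALSE]
  }
  cls <- stats::setNames(rep("unclassified", nrow(intensities)),
                         rownames(intensities))
  if (!is.null(class_of)) {
    known <- intersect(names(class_of), names(cls))
    cls[known] <- class_of[known]
  }
  structure(list(intensities = intensities, class_of = cls),
            class = "abundance_matrix")
}

#' Read an abundance matrix from CSV
#'
#' First column `otu_id`, remaining columns one intensity per array, header
#' row of array ids. Class labels can be attached from a taxonomy table.
#'
#' @param path Path to the CSV.
#' @param taxonomy Optional taxonomy data.frame ([parse_taxonomy()]); its
#'   `class` rank supplies the class labels.
#' @return An `abundance_matrix`.
#' @export
read_abundance <- function(path, taxonomy = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  cls <- NULL
  if (!is.null(taxonomy)) {
    cls <- stats::setNames(taxonomy$class, taxonomy$otu_id)
  }
  abundance_matrix(m, class_of = cls)
}

#' Pairwise Pearson correlations within a taxonomic class
#'
#' Computes Pearson's r between the intensities of every unordered pair of
#' OTUs belonging to `group`, across all arrays. Rows with zero variance have
#' undefined r; pairs involving them are skipped and the number of skipped
#' rows reported in attribute `n_zero_variance_rows`.
#'
#' @param matrix An `abundance_matrix` with at least 4 arrays.
#' @param group Class label to analyse (must contain >= 2 OTUs).
#' @return Numeric vector of r values, one per pair (length `g*(g-1)/2` for
#'   `g` usable OTUs), with attribute `n_zero_variance_rows`.
#' @export
pairwise_correlations <- function(matrix, group) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (ncol(matrix$intensities) < 4L) stop("need at least 4 arrays")
  otus <- names(matrix$class_of)[matrix$class_of == group]
  if (length(otus) == 0L) stop("no OTUs in class: ", group)
  m <- matrix$intensities[otus, , drop = FALSE]
  v <- apply(m, 1L, stats::var)
  n_zero <- sum(v == 0)
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop("class ", group, " has fewer than 2 usable OTUs")
  cm <- stats::cor(t(m))
  structure(cm[upper.tri(cm)], n_zero_variance_rows = n_zero)
}

#' Null distribution of Pearson's r under independence
#'
#' The exact sampling distribution of the Pearson correlation coefficient of
#' two independent bivariate-normal variables observed on `n` arrays:
#' `f(r) = (1 - r^2)^((n-4)/2) / B(1/2, (n-2)/2)` on `[-1, 1]`.
#'
#' @param n Number of arrays (observations per OTU); must be >= 4.
#' @return An object of class `independence_null` with fields `n` and
#'   `density` (a vectorised function of r, zero outside `[-1, 1]`).
#' @export
null_density <- function(n) {
  if (n < 4L) stop("independence null density requires n >= 4")
  n <- as.integer(n)
  dens <- function(r) {
    out <- numeric(length(r))
    ok <- r >= -1 & r <= 1
    out[ok] <- (1 - r[ok]^2)^((n - 4) / 2) / beta(0.5, (n - 2) / 2)
    out
  }
  structure(list(n = n, density = dens), class = "independence_null")
}

#' Tail probability of the independence null
#'
#' `P(r > r0)` under [null_density()], by quadrature.
#'
#' @param null An `independence_null`.
#' @param r0 Lower limit.
#' @return Numeric scalar.
#' @export
null_tail_probability <- function(null, r0) {
  stopifnot(inherits(null, "independence_null"))
  stats::integrate(null$density, r0, 1, rel.tol = 1e-10)$value
}

#' Correlation histogram with superimposed independence null
#'
#' Bins observed r values on `[-1, 1]` (default bin width 0.02, i.e. 100 bins)
#' and scales the counts and the null curve to equal area (both are reported
#' on the density scale, area 1), mirroring the equal-area overlay used for
#' within-class abundance correlations. The right-skew diagnostic — the
#' fraction of pairs with r > 0.5, observed vs expected under the null — is
#' included.
#'
#' @param rs Non-empty numeric vector of correlation coefficients.
#' @param null An `independence_null`.
#' @param binwidth Histogram bin width (default 0.02; must divide 2 evenly).
#' @return An object of class `correlation_histogram`: list with `bin_edges`,
#'   `bin_mids`, `scaled_counts` (density scale), `null_curve` (null density
#'   at bin mids), `n_pairs`, `frac_gt_0.5_observed`, `frac_gt_0.5_expected`.
#' @export
histogram_with_null <- function(rs, null, binwidth = 0.02) {
  stopifnot(length(rs) > 0L, inherits(null, "independence_null"))
  nbin <- round(2 / binwidth)
  if (abs(nbin * binwidth - 2) > 1e-9) stop("binwidth must divide [-1,1] evenly")
  edges <- seq(-1, 1, length.out = nbin + 1L)
  rs <- pmin(pmax(rs, -1), 1)
  h <- graphics::hist(rs, breaks = edges, plot = FALSE)
  structure(
    list(bin_edges = edges,
         bin_mids = h$mids,
         scaled_counts = h$counts / (length(rs) * binwidth),
         null_curve = null$density(h$mids),
         n_pairs = length(rs),
         frac_gt_0.5_observed = mean(rs > 0.5),
         frac_gt_0.5_expected = null_tail_probability(null, 0.5)),
    class = "correlation_histogram"
  )
}

#' @export
print.correlation_histogram <- function(x, ...) {
  cat(sprintf("correlation histogram: %d pairs in %d bins\n",
              x$n_pairs, length(x$bin_mids)))
  cat(sprintf("fraction r > 0.5: observed %.4f vs %.4f expected under independence\n",
              x$frac_gt_0.5_observed, x$frac_gt_0.5_expected))
  invisible(x)
}

#' Plot a correlation histogram against its independence null
#'
#' @param x A `correlation_histogram`.
#' @param main Plot title.
#' @param ... Further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot correlation_histogram
#' @export
plot.correlation_histogram <- function(x, main = "Pairwise correlations vs independence null",
                                       ...) {
  graphics::plot(x$bin_mids, x$scaled_counts, type = "h", lwd = 3,
                 col = "grey60", xlab = "Pearson r", ylab = "density",
                 main = main, ...)
  graphics::lines(x$bin_mids, x$null_curve, col = "black", lwd = 2)
  graphics::legend("topleft", legend = c("observed", "independence null"),
                   col = c("grey60", "black"), lwd = c(3, 2), bty = "n")
  invisible(x)
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability `P(X >= k)` that at least `k` of `n` detected OTUs
#' fall in a special subpopulation of size `K` out of `N`, when the `n` are
#' drawn without replacement at random. Computed by exact summation of the
#' hypergeometric mass (no normal approximation).
#'
#' @param N Population size (e.g. probe sets kept after size filtering).
#' @param K Special-subpopulation size (e.g. zero-unique probe sets).
#' @param n Number of detected OTUs.
#' @param k Observed overlap between detections and the special subpopulation.
#' @return An object of class `enrichment_result`: list with `N`, `K`, `n`,
#'   `k`, `p_value`, and `log10_p` (computed on the log scale, usable when
#'   `p_value` underflows to 0).
#' @export
enrichment_test <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < 0) {
    stop("inconsistent hypergeometric counts")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(N = N, K = K, n = n, k = k, p_value = p,
                 log10_p = lp / log(10)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: k=%d of n=%d drawn from K=%d/%d special\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("upper-tail P(X >= %d) = %.4g (log10 p = %.1f)\n",
              x$k, x$p_value, x$log10_p))
  invisible(x)
}
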