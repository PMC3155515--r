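# Read-count differential expression between libraries: exact conditional
# binomial test under the random-sampling null, chi-squared
# observed-vs-expected test across the four libraries, Benjamini-Hochberg
# and Storey multiple-testing adjustment, and hypergeometric term
# enrichment.

#' Exact random-sampling test of one gene between two libraries
#'
#' Under the random-sampling null, a gene's count in library 1 given the
#' pairwise total \code{k1 + k2} is binomial with success probability
#' \code{N1 / (N1 + N2)}.  The two-sided exact p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#' M (log2 count difference) and A (mean log2 intensity) are computed
#' with a 0.5 pseudo-count for zero counts, for display only.
#'
#' @param k1,k2 read counts of the gene in the two libraries.
#' @param N1,N2 total read counts of the two libraries.
#' @return list of class \code{de_result}: \code{p_value}, \code{M},
#'   \code{A}, \code{testable}.
#' @export
mars_test <- function(k1, k2, N1, N2) {
  stopifnot(N1 >= 1, N2 >= 1, k1 >= 0, k2 >= 0)
  k1p <- if (k1 == 0) 0.5 else k1
  k2p <- if (k2 == 0) 0.5 else k2
  M <- log2(k1p) - log2(k2p)
  A <- (log2(k1p) + log2(k2p)) / 2
  n <- k1 + k2
  if (n == 0) {
    return(structure(list(p_value = 1, M = 0, A = A, testable = FALSE),
                     class = "de_result"))
  }
  p0 <- N1 / (N1 + N2)
  d <- dbinom(0:n, n, p0)
  p <- min(1, sum(d[d <= d[k1 + 1L] * (1 + 1e-7)]))
  structure(list(p_value = p, M = M, A = A, testable = TRUE),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> p = %.4g, M = %.3f, A = %.3f%s\n", x$p_value,
              x$M, x$A, if (x$testable) "" else " (untestable)"))
  invisible(x)
}

#' Chi-squared observed-vs-expected test across the four libraries
#'
#' Expected counts are proportional to the library totals:
#' \code{e_i = sum(n) * N_i / sum(N)}.  The statistic
#' \code{sum((n - e)^2 / e)} is referred to the chi-squared distribution
#' with 3 degrees of freedom.  Cells with expected count below 1 raise a
#' low-count flag.
#'
#' @param n length-4 vector of per-library counts of one gene.
#' @param totals length-4 vector of library totals.
#' @return list: \code{statistic}, \code{p_value}, \code{df},
#'   \code{low_count}, \code{testable}.
#' @export
chi2_test <- function(n, totals) {
  stopifnot(length(n) == 4, length(totals) == 4, all(totals >= 1))
  if (sum(n) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 3L,
                low_count = TRUE, testable = FALSE))
  }
  e <- sum(n) * totals / sum(totals)
  stat <- sum((n - e)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 3, lower.tail = FALSE),
       df = 3L, low_count = any(e < 1), testable = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values.
#' @return vector of BH-adjusted q-values (monotone, order-preserving).
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with a fixed lambda
#'
#' Estimates the null proportion as \code{pi0 = #\{p > lambda\} /
#' (m (1 - lambda))}, clipped to (0, 1], and scales the BH-adjusted
#' values: \code{q = pi0 * q_BH}.  A single fixed lambda (no spline
#' smoothing) keeps the estimate deterministic.
#'
#' @param p vector of p-values.
#' @param lambda tuning constant in (0, 1) (default 0.5).
#' @return vector of Storey q-values.
#' @export
adjust_storey <- function(p, lambda = 0.5) {
  stopifnot(lambda > 0, lambda < 1)
  m <- length(p)
  if (m == 0) return(numeric(0))
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(pi0, 1 / (m * (1 - lambda))))
  pi0 * adjust_bh(p)
}

#' Test every gene of a count table in one pairwise contrast
#'
#' Runs [mars_test()] per gene for libraries \code{contrast[1]} versus
#' \code{contrast[2]}, plus the four-library [chi2_test()], and adjusts
#' the exact p-values with both strategies.
#'
#' @param counts count data frame (as from [read_counts()] /
#'   [generate_counts()]) with a \code{totals} attribute.
#' @param contrast length-2 integer vector of library indices (1-4).
#' @return data frame: gene, counts, M, A, exact and chi-squared
#'   p-values, \code{q_bh}, \code{q_storey}.
#' @export
de_table <- function(counts, contrast = c(1L, 3L)) {
  totals <- attr(counts, "totals")
  if (is.null(totals)) stop("de_table: counts lack a totals attribute", call. = FALSE)
  a <- contrast[1]; b <- contrast[2]
  cols <- paste0("n", 1:4)
  k1 <- counts[[cols[a]]]; k2 <- counts[[cols[b]]]
  res <- lapply(seq_len(nrow(counts)), function(i) {
    mt <- mars_test(k1[i], k2[i], totals[a], totals[b])
    ct <- chi2_test(as.numeric(counts[i, cols]), totals)
    data.frame(gene_id = counts$gene_id[i], k1 = k1[i], k2 = k2[i],
               M = mt$M, A = mt$A, p_value = mt$p_value,
               testable = mt$testable, chi2_stat = ct$statistic,
               chi2_p = ct$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_bh <- adjust_bh(out$p_value)
  out$q_storey <- adjust_storey(out$p_value)
  out$contrast <- sprintf("C.%d_vs_C.%d", a, b)
  out
}

#' Hypergeometric term enrichment of a selected gene set
#'
#' For each term, tests over-representation of the selected genes in the
#' term's members restricted to the background, with the hypergeometric
#' upper tail, and adjusts across terms with Benjamini-Hochberg.
#'
#' @param selected character vector of selected genes (must be a subset
#'   of \code{background}).
#' @param background character vector of background genes.
#' @param gmt named list of term member vectors (as from [read_gmt()]).
#' @return data frame: \code{term, count, set_size, background_size,
#'   p_value, fdr}, ordered by p-value.
#' @export
enrich <- function(selected, background, gmt) {
  selected <- unique(selected); background <- unique(background)
  if (!all(selected %in% background))
    stop("enrich: selected genes must be a subset of the background",
         call. = FALSE)
  Nb <- length(background); ns <- length(selected)
  rows <- lapply(names(gmt), function(term) {
    set <- intersect(gmt[[term]], background)
    k <- length(intersect(selected, set))
    p <- phyper(k - 1, length(set), Nb - length(set), ns, lower.tail = FALSE)
    data.frame(term = term, count = k, set_size = length(set),
               background_size = Nb, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(), count = integer(),
                                      set_size = integer(),
                                      background_size = integer(),
                                      p_value = numeric(), fdr = numeric()))
  out$fdr <- adjust_bh(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
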