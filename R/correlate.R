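#' Pairwise correlation with raw and adjusted p-values
#'
#' Computes the two matrices at the heart of correlation-network
#' construction: a symmetric correlation matrix `r` with unit diagonal, and
#' the corresponding p-value matrices — raw two-sided p-values `p_raw` and
#' multiplicity-adjusted values `p_adj`. Correlations are computed on
#' pairwise-complete observations, so a sparse matrix with missing values
#' does not collapse to its complete cases. Adjustment is carried out over
#' the \eqn{m = v(v-1)/2} unique off-diagonal pairs of the matrix (never
#' over \eqn{v^2} cells).
#'
#' For Pearson and Spearman, p-values come from the two-sided t
#' approximation with \eqn{df = n - 2} complete pairs,
#' \eqn{t = r \sqrt{df / (1 - r^2)}}. Spearman uses average ranks for ties,
#' so its r equals the Pearson correlation of the column ranks. Kendall
#' (tau-b) uses the large-sample normal approximation
#' \eqn{z = 3\tau\sqrt{n(n-1)} / \sqrt{2(2n+5)}}.
#'
#' Pairs with fewer than `min_pairs` complete observations, and pairs
#' involving a variable that is constant on the shared samples, get `NA`
#' for r and p; such pairs are never selectable as edges downstream.
#'
#' @param data Data matrix as returned by [read_data_matrix()] /
#'   [as_data_matrix()] (or a plain numeric matrix/data frame).
#' @param method `"spearman"` (default, robust to non-normal abundance
#'   distributions), `"pearson"`, or `"kendall"`.
#' @param adjust_method `"BH"` (Benjamini-Hochberg false discovery rate,
#'   default), `"bonferroni"`, or `"none"`.
#' @param min_pairs Minimum number of complete observations a pair needs
#'   before its correlation is reported; default 4.
#' @return A `cn_correlation` object: list with elements `variable_ids`,
#'   `r`, `p_raw`, `p_adj`, `n_pairs` (all v x v matrices), `method`,
#'   `adjust_method`, `n_samples`. Use [tidy()] for the per-pair tibble and
#'   [select_edges()] for thresholding.
#' @examples
#' set.seed(1)
#' dm <- as_data_matrix(matrix(rnorm(60), 20, 3,
#'                             dimnames = list(NULL, c("A", "B", "C"))))
#' cr <- correlate(dm, method = "spearman")
#' tidy(cr)
#' @export
correlate <- function(data,
                      method = c("spearman", "pearson", "kendall"),
                      adjust_method = c("BH", "bonferroni", "none"),
                      min_pairs = 4) {
  method <- match.arg(method)
  adjust_method <- match.arg(adjust_method)
  x <- data_matrix_values(data)
  v <- ncol(x)
  if (v < 2L) stop("need at least 2 variables", call. = FALSE)
  if (min_pairs < 3L) stop("min_pairs must be at least 3", call. = FALSE)

  obs <- !is.na(x)
  n_pairs <- crossprod(obs)
  storage.mode(n_pairs) <- "integer"

  const <- vapply(seq_len(v), function(j) {
    vals <- x[obs[, j], j]
    length(vals) > 0 && stats::var(vals) == 0
  }, logical(1))
  if (any(const)) {
    warning("constant variable(s), correlations undefined: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  }

  r <- suppressWarnings(
    stats::cor(x, use = "pairwise.complete.obs", method = method)
  )
  r[n_pairs < min_pairs] <- NA_real_
  diag(r) <- 1

  n <- matrix(as.numeric(n_pairs), v, v)
  p_raw <- if (method == "kendall") {
    z <- 3 * r * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    2 * stats::pnorm(-abs(z))
  } else {
    df <- n - 2
    tt <- r * sqrt(df / pmax(1 - r^2, 0))
    2 * stats::pt(-abs(tt), pmax(df, 1))
  }
  p_raw[is.na(r)] <- NA_real_
  p_raw <- pmin(pmax(p_raw, 0), 1)
  diag(p_raw) <- 0

  m <- v * (v - 1) / 2
  upper <- upper.tri(r)
  p_vec <- p_raw[upper]
  p_adj_vec <- adjust_pvalues(p_vec, method = adjust_method, m = m)
  p_adj <- matrix(NA_real_, v, v, dimnames = dimnames(r))
  p_adj[upper] <- p_adj_vec
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  diag(p_adj) <- 0

  structure(
    list(variable_ids = colnames(x), r = r, p_raw = p_raw, p_adj = p_adj,
         n_pairs = n_pairs, method = method, adjust_method = adjust_method,
         n_samples = nrow(x)),
    class = "cn_correlation"
  )
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni multiplies each p-value by the family size `m` (capped at 1);
#' Benjamini-Hochberg applies the step-up procedure
#' \eqn{\tilde p_{(i)} = \min_{k \ge i} \min(1, p_{(k)} m / k)}. The output
#' order matches the input order and `NA`s are carried through while still
#' counting toward `m` when `m` is given explicitly.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @param method `"BH"`, `"bonferroni"`, or `"none"`.
#' @param m Number of tests in the family; defaults to `length(p)`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), method = "BH")
#' adjust_pvalues(0.02, method = "bonferroni", m = 10)
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none"),
                           m = length(p)) {
  method <- match.arg(method)
  p <- as.numeric(p)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1]: ",
         paste(format(p[bad]), collapse = ", "), call. = FALSE)
  }
  if (m < sum(!is.na(p))) {
    stop("m cannot be smaller than the number of non-missing p-values",
         call. = FALSE)
  }
  switch(method,
    none = p,
    bonferroni = pmin(1, p * m),
    BH = stats::p.adjust(p, method = "BH", n = m)
  )
}

#' Per-variable normality screen for correlation-method choice
#'
#' Runs the Shapiro-Wilk test on each variable's non-missing values.
#' Pearson correlation assumes (approximate) normality; the recommendation
#' is `"pearson"` only if every variable's test p-value exceeds `alpha`,
#' otherwise `"spearman"`. Variables with fewer than 3 usable observations
#' (or constant values) are untestable and count as non-normal.
#'
#' @param data Data matrix (see [correlate()]).
#' @param alpha Significance level of the normality tests, default 0.05.
#' @return A `cn_normality` object: list with `tests` (tibble of
#'   `variable`, `n`, `W`, `p_value`, `testable`, `normal`), `alpha` and
#'   `recommended_method`.
#' @export
normality_screen <- function(data, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  x <- data_matrix_values(data)
  tests <- dplyr::bind_rows(lapply(colnames(x), function(id) {
    vals <- x[, id]
    vals <- vals[!is.na(vals)]
    res <- if (length(vals) >= 3) {
      tryCatch(stats::shapiro.test(vals), error = function(e) NULL)
    }
    if (is.null(res)) {
      tibble::tibble(variable = id, n = length(vals), W = NA_real_,
                     p_value = NA_real_, testable = FALSE, normal = FALSE)
    } else {
      tibble::tibble(variable = id, n = length(vals),
                     W = unname(res$statistic), p_value = res$p.value,
                     testable = TRUE, normal = res$p.value > alpha)
    }
  }))
  structure(
    list(tests = tests, alpha = alpha,
         recommended_method = if (all(tests$normal)) "pearson" else "spearman"),
    class = "cn_normality"
  )
}

#' @export
print.cn_correlation <- function(x, ...) {
  cat("Correlation result (", x$method, ", ", x$adjust_method,
      " adjustment)\n", sep = "")
  cat("  ", length(x$variable_ids), " variables, ", x$n_samples,
      " samples, ", length(x$variable_ids) * (length(x$variable_ids) - 1) / 2,
      " unique pairs\n", sep = "")
  invisible(x)
}

#' @export
print.cn_normality <- function(x, ...) {
  nn <- sum(!x$tests$normal)
  cat("Normality screen (Shapiro-Wilk, alpha = ", x$alpha, ")\n", sep = "")
  cat("  ", nrow(x$tests), " variables, ", nn, " non-normal/untestable\n",
      "  recommended method: ", x$recommended_method, "\n", sep = "")
  invisible(x)
}
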