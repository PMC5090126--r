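#' Tidy a correlation result into a per-pair tibble
#'
#' One row per unique unordered variable pair, with the correlation, raw
#' and adjusted p-values, and the number of complete observations the pair
#' was computed on.
#'
#' @param x A `cn_correlation` object.
#' @param ... Unused.
#' @return Tibble with columns `source`, `target`, `r`, `p_raw`, `p_adj`,
#'   `n`.
#' @method tidy cn_correlation
#' @export
tidy.cn_correlation <- function(x, ...) {
  ids <- x$variable_ids
  ut <- upper.tri(x$r)
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble::tibble(
    source = ids[idx[, "row"]],
    target = ids[idx[, "col"]],
    r = x$r[ut],
    p_raw = x$p_raw[ut],
    p_adj = x$p_adj[ut],
    n = as.integer(x$n_pairs[ut])
  )
  dplyr::arrange(out, .data$source, .data$target)
}

#' One-row summary of a correlation result
#'
#' @param x A `cn_correlation` object.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_variables`, `n_pairs`,
#'   `n_defined` (pairs with a defined correlation), `method`,
#'   `adjust_method`.
#' @method glance cn_correlation
#' @export
glance.cn_correlation <- function(x, ...) {
  v <- length(x$variable_ids)
  ut <- upper.tri(x$r)
  tibble::tibble(
    n_samples = x$n_samples,
    n_variables = v,
    n_pairs = as.integer(v * (v - 1) / 2),
    n_defined = sum(!is.na(x$r[ut])),
    method = x$method,
    adjust_method = x$adjust_method
  )
}

#' Tidy a topology report
#'
#' @param x A `cn_topology` object.
#' @param type `"vertices"` (default) for the per-vertex metrics or
#'   `"edges"` for per-edge betweenness.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy cn_topology
#' @export
tidy.cn_topology <- function(x, type = c("vertices", "edges"), ...) {
  type <- match.arg(type)
  if (type == "vertices") x$vertices else x$edges
}

#' Global metrics of a topology report
#'
#' @param x A `cn_topology` object.
#' @param ... Unused.
#' @return One-row tibble of global metrics plus the power-law fit
#'   (`pl_exponent`, `pl_r_squared`).
#' @method glance cn_topology
#' @export
glance.cn_topology <- function(x, ...) {
  dplyr::bind_cols(
    x$global,
    tibble::tibble(pl_exponent = x$power_law$exponent,
                   pl_r_squared = x$power_law$r_squared)
  )
}

#' Tidy a normality screen
#'
#' @param x A `cn_normality` object.
#' @param ... Unused.
#' @return The per-variable Shapiro-Wilk tibble.
#' @method tidy cn_normality
#' @export
tidy.cn_normality <- function(x, ...) x$tests

#' @rdname tidy.cn_normality
#' @method glance cn_normality
#' @export
glance.cn_normality <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$tests),
    n_non_normal = sum(!x$tests$normal),
    alpha = x$alpha,
    recommended_method = x$recommended_method
  )
}
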