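#' Specification of a synthetic two-condition metabolomics experiment
#'
#' Describes the stated world the generator simulates: two groups of
#' samples (conditions "a" and "b", e.g. control and hypoxia), a common
#' variable set of a few tens of metabolite-like variables, and planted
#' correlation blocks. Each block is generated from a one-factor latent
#' model, \eqn{x_j = \sqrt{\rho} f + \sqrt{1-\rho}\, \epsilon_j} with
#' standard-normal factor and noise, so every within-block pair has true
#' correlation \eqn{\rho}. Shared blocks are correlated under both
#' conditions; condition-specific blocks are correlated only under theirs
#' (their variables are plain noise in the other condition, mirroring
#' correlations that appear or vanish under treatment). Remaining
#' variables are independent noise. Entries are masked missing completely
#' at random at `missing_rate`.
#'
#' @param n_samples Samples per condition; default 30.
#' @param blocks List of blocks, each a list with `id` (label prefix),
#'   `size` (number of variables), `rho` (within-block correlation,
#'   0 < rho < 1) and `condition` (`"both"`, `"a"`, or `"b"`). The default
#'   plants two shared blocks (5 and 4 variables), one control-specific
#'   block of 4 and one treatment-specific block of 5, all at rho = 0.9.
#' @param n_noise Number of unconnected noise variables; default 8.
#' @param noise_sd Standard deviation of the pure-noise variables; default 1.
#' @param missing_rate Fraction of entries masked missing, in \[0, 1);
#'   default 0.05.
#' @param seed Integer seed making the generated matrices reproducible.
#' @return A `cn_synthetic_spec` object (validated list).
#' @seealso [simulate_condition()], [simulate_paired_conditions()],
#'   [known_truth()]
#' @export
synthetic_spec <- function(n_samples = 30,
                           blocks = default_blocks(),
                           n_noise = 8,
                           noise_sd = 1,
                           missing_rate = 0.05,
                           seed = 1) {
  stopifnot(n_samples >= 3, n_noise >= 0, noise_sd > 0)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  for (b in blocks) {
    if (!all(c("id", "size", "rho", "condition") %in% names(b))) {
      stop("each block needs id, size, rho, condition", call. = FALSE)
    }
    if (b$rho <= 0 || b$rho >= 1) {
      stop("block '", b$id, "': rho must be in (0, 1)", call. = FALSE)
    }
    if (b$size < 2) stop("block '", b$id, "': size must be >= 2", call. = FALSE)
    if (!b$condition %in% c("both", "a", "b")) {
      stop("block '", b$id, "': condition must be both/a/b", call. = FALSE)
    }
  }
  ids <- vapply(blocks, `[[`, "", "id")
  check_unique(ids, "block")
  structure(
    list(n_samples = as.integer(n_samples), blocks = blocks,
         n_noise = as.integer(n_noise), noise_sd = noise_sd,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cn_synthetic_spec"
  )
}

default_blocks <- function() {
  list(
    list(id = "shr1", size = 5, rho = 0.9, condition = "both"),
    list(id = "shr2", size = 4, rho = 0.9, condition = "both"),
    list(id = "ctlA", size = 4, rho = 0.9, condition = "a"),
    list(id = "trtB", size = 5, rho = 0.9, condition = "b")
  )
}

#' Simulate one condition's data matrix
#'
#' Draws the samples-by-variables matrix for one condition of the
#' experiment described by a [synthetic_spec()]. Both conditions carry the
#' same variable set; blocks not active under the requested condition are
#' generated as independent noise. Reproducible: the same spec and
#' condition always give the same matrix (conditions use different
#' sub-seeds so their samples are independent).
#'
#' @param spec A `cn_synthetic_spec`.
#' @param condition `"a"` or `"b"`.
#' @return A data matrix tibble (see [read_data_matrix()]) with the
#'   condition stored in the `"condition"` attribute.
#' @export
simulate_condition <- function(spec, condition = c("a", "b")) {
  stopifnot(inherits(spec, "cn_synthetic_spec"))
  condition <- match.arg(condition)
  vars <- spec_variables(spec)
  n <- spec$n_samples
  withr::with_seed(spec$seed * 2L + (condition == "b"), {
    cols <- lapply(vars$groups, function(g) {
      k <- length(g$labels)
      if (g$active(condition)) {
        f <- stats::rnorm(n)
        eps <- matrix(stats::rnorm(n * k), n, k)
        sqrt(g$rho) * f + sqrt(1 - g$rho) * eps
      } else {
        matrix(stats::rnorm(n * k, sd = g$sd), n, k)
      }
    })
    x <- do.call(cbind, cols)
    colnames(x) <- vars$labels
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(x)) < spec$missing_rate,
                     nrow(x), ncol(x))
      x[mask] <- NA_real_
    }
  })
  as_data_matrix(x, sample_ids = paste0(condition, seq_len(n)),
                 condition = condition)
}

#' Simulate both conditions of the experiment
#'
#' @param spec A `cn_synthetic_spec`.
#' @return Named list with elements `a` and `b`, each a data matrix tibble.
#' @export
simulate_paired_conditions <- function(spec) {
  list(a = simulate_condition(spec, "a"),
       b = simulate_condition(spec, "b"))
}

#' Planted ground-truth edges
#'
#' All within-block variable pairs active under the given condition — the
#' edge set a perfect recovery of the correlation network would find.
#'
#' @param spec A `cn_synthetic_spec`.
#' @param condition `"a"`, `"b"`, or `"all"` (every planted pair of either
#'   condition).
#' @return Edge tibble with columns `source`, `target` and `block`.
#' @export
known_truth <- function(spec, condition = c("a", "b", "all")) {
  stopifnot(inherits(spec, "cn_synthetic_spec"))
  condition <- match.arg(condition)
  vars <- spec_variables(spec)
  rows <- lapply(vars$groups, function(g) {
    active <- condition == "all" || g$active(condition)
    if (!g$planted || !active || length(g$labels) < 2) return(NULL)
    pairs <- utils::combn(sort(g$labels), 2)
    tibble::tibble(source = pairs[1, ], target = pairs[2, ], block = g$id)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(source = character(0), target = character(0),
                          block = character(0)))
  }
  dplyr::arrange(out, .data$source, .data$target)
}

# expand a spec into variable labels and per-group generators
spec_variables <- function(spec) {
  groups <- lapply(spec$blocks, function(b) {
    list(id = b$id,
         labels = sprintf("%s_%02d", b$id, seq_len(b$size)),
         rho = b$rho, sd = 1, planted = TRUE,
         active = local({
           cond <- b$condition
           function(condition) cond == "both" || cond == condition
         }))
  })
  if (spec$n_noise > 0) {
    groups <- c(groups, list(list(
      id = "noise",
      labels = sprintf("noise_%02d", seq_len(spec$n_noise)),
      rho = 0, sd = spec$noise_sd, planted = FALSE,
      active = function(condition) FALSE
    )))
  }
  list(groups = groups,
       labels = unlist(lapply(groups, `[[`, "labels"), use.names = FALSE))
}

#' @export
print.cn_synthetic_spec <- function(x, ...) {
  v <- length(spec_variables(x)$labels)
  cat("Synthetic two-condition spec: ", x$n_samples, " samples/condition, ",
      v, " variables (", length(x$blocks), " planted blocks + ",
      x$n_noise, " noise), missing rate ", x$missing_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
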