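## Nonparametric statistics for the fruiting-body diameter comparison:
## tie-corrected Kruskal-Wallis omnibus test, Dunn pairwise post hoc z
## tests on the pooled mid-ranks, and Holm step-down adjustment. These are
## implemented from first principles (mid-ranks, tie corrections, and the
## step-down walk are written out) rather than delegating to packaged test
## functions; only the chi-square and normal tail probabilities come from
## the standard distribution functions.

# pooled mid-ranks and the tie term sum(t^3 - t)
rank_info <- function(x) {
  r <- rank(x, ties.method = "average")
  tie <- table(x)
  list(ranks = r, tie_term = sum(tie^3 - tie), n = length(x))
}

#' Kruskal-Wallis omnibus test (tie-corrected)
#'
#' H = \[12 / (N(N+1))\] * sum_i n_i (Rbar_i - (N+1)/2)^2, divided by the
#' tie correction 1 - sum(t^3 - t) / (N^3 - N); the p-value comes from the
#' chi-square upper tail with k - 1 degrees of freedom. All-tied input
#' yields H = 0, p = 1.
#'
#' @param values Numeric observations (e.g. diameters in um).
#' @param groups Group labels, same length as `values`; >= 2 groups, each
#'   non-empty, total N >= 3.
#' @param exact Use the exact permutation distribution of H instead of the
#'   chi-square approximation (feasible for small N only).
#' @return List with `H`, `df`, `p_omnibus`, `method`.
#' @examples
#' kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))  # H = 7.2
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  k <- length(unique(groups))
  if (k < 2) stop_config("kruskal_wallis: need >= 2 groups")
  if (any(table(groups) == 0) || anyNA(values) || anyNA(groups))
    stop_config("kruskal_wallis: empty group or missing values")
  N <- length(values)
  if (N < 3) stop_config("kruskal_wallis: need total N >= 3")
  H <- kw_statistic(values, groups)
  df <- k - 1
  p <- if (exact) {
    kw_exact_p(values, groups)
  } else {
    stats::pchisq(H, df = df, lower.tail = FALSE)
  }
  if (is.na(H)) { H <- 0; p <- 1 }   # all observations tied
  list(H = H, df = df, p_omnibus = p,
       method = if (exact) "exact permutation" else "chi-square approximation")
}

# tie-corrected H; NA when every observation is tied (0/0)
kw_statistic <- function(values, groups) {
  ri <- rank_info(values)
  N <- ri$n
  mean_rank <- tapply(ri$ranks, groups, mean)
  n_i <- tapply(ri$ranks, groups, length)
  H0 <- 12 / (N * (N + 1)) * sum(n_i * (mean_rank - (N + 1) / 2)^2)
  corr <- 1 - ri$tie_term / (N^3 - N)
  if (corr == 0) return(NA_real_)
  H0 / corr
}

# exact permutation p-value by full enumeration of group assignments;
# intended for N <= 10 or so
kw_exact_p <- function(values, groups) {
  N <- length(values)
  perms <- all_permutations(N)
  H_obs <- kw_statistic(values, groups)
  if (is.na(H_obs)) return(1)
  Hs <- apply(perms, 1, function(idx) kw_statistic(values[idx], groups))
  mean(Hs >= H_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Dunn post hoc pairwise comparisons
#'
#' For each group pair (i, j), on the pooled mid-ranks:
#' z = (Rbar_i - Rbar_j) / sqrt( \[N(N+1)/12 - sum(t^3 - t)/(12(N-1))\] *
#' (1/n_i + 1/n_j) ), with two-sided standard-normal p-values. When all
#' observations are tied the variance vanishes; z is defined as 0 and
#' p_raw = 1.
#'
#' @inheritParams kruskal_wallis
#' @return Data frame with `group_i`, `group_j`, `z`, `p_raw`, one row per
#'   unordered pair (pairs ordered by group label).
#' @examples
#' dunn_posthoc(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop_config("dunn_posthoc: need >= 2 groups")
  ri <- rank_info(values)
  N <- ri$n
  mean_rank <- tapply(ri$ranks, groups, mean)
  n_i <- tapply(ri$ranks, groups, length)
  var_term <- N * (N + 1) / 12 - ri$tie_term / (12 * (N - 1))
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    v <- var_term * (1 / n_i[[i]] + 1 / n_i[[j]])
    if (v <= 0) {
      z <- 0; p <- 1
    } else {
      z <- (mean_rank[[i]] - mean_rank[[j]]) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group_i = i, group_j = j, z = z, p_raw = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Holm step-down adjustment
#'
#' Sort p-values ascending, multiply the k-th by (m - k + 1), enforce the
#' running maximum, cap at 1, and return in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p_values) {
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_config("holm_adjust: p-values must lie in [0, 1]")
  o <- order(p_values)
  adj <- pmin(1, cummax(p_values[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Kruskal-Wallis omnibus plus Holm-adjusted Dunn post hoc
#'
#' The complete morphometry analysis for a group-labelled measurement
#' table, as used for fruiting-body diameters.
#'
#' @param data Data frame with a group column and a value column.
#' @param value_col,group_col Column names (defaults `diameter_um`,
#'   `group`).
#' @param exact Passed to [kruskal_wallis()].
#' @return List of class `kw_dunn` with `H`, `df`, `p_omnibus`, and
#'   `pairwise` (group_i, group_j, z, p_raw, p_holm).
#' @examples
#' cfg <- sim_config(n_genes = 10, seed = 5)
#' truth <- plant_ground_truth(cfg, generate_annotation(cfg))
#' kw_dunn(generate_morphometry(truth, n_per_group = 10, seed = 5))
#' @export
kw_dunn <- function(data, value_col = "diameter_um", group_col = "group",
                    exact = FALSE) {
  miss <- setdiff(c(value_col, group_col), names(data))
  if (length(miss)) stop_config("morphometry data lacks column(s): %s",
                                paste(miss, collapse = ", "))
  values <- data[[value_col]]
  groups <- data[[group_col]]
  omnibus <- kruskal_wallis(values, groups, exact = exact)
  pw <- dunn_posthoc(values, groups)
  pw$p_holm <- holm_adjust(pw$p_raw)
  structure(list(H = omnibus$H, df = omnibus$df,
                 p_omnibus = omnibus$p_omnibus, method = omnibus$method,
                 pairwise = pw),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s)\n",
              x$H, x$df, x$p_omnibus, x$method))
  cat("Dunn post hoc (Holm-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
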