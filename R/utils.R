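#' Two-group p-value on numeric vectors
#'
#' Shared significance engine for screen summaries and reporter assays.
#' Degenerate inputs follow a fixed convention so p-values never propagate
#' `NaN`: if every value in both groups is identical the groups are
#' indistinguishable and `p = 1`; if both groups have zero variance but
#' different means the difference is unambiguous and `p` is set to the
#' smallest positive double.
#'
#' @param x,y Numeric vectors (each length >= 1; tests need >= 2 per group
#'   to estimate variance, and `stats::t.test()` errors otherwise).
#' @param method `"student"` (pooled-variance two-sample t, the default),
#'   `"welch"`, or `"permutation"` (two-sided test on the difference of group
#'   means; exact enumeration of group assignments when feasible, otherwise
#'   Monte Carlo).
#' @param n_perm Number of Monte Carlo permutations when exact enumeration
#'   would exceed `max_exact` combinations.
#' @param max_exact Enumeration budget for the exact permutation test.
#' @return A single p-value in `[0, 1]`.
#' @export
two_group_p <- function(x, y, method = c("student", "welch", "permutation"),
                        n_perm = 1e5, max_exact = 250000) {
  method <- rlang::arg_match(method)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) return(NA_real_)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  zero_var <- (length(x) == 1 || sx == 0) && (length(y) == 1 || sy == 0)
  if (zero_var) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else .Machine$double.xmin)
  }
  if (method %in% c("student", "welch")) {
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    return(stats::t.test(x, y, var.equal = method == "student")$p.value)
  }
  perm_p(x, y, n_perm = n_perm, max_exact = max_exact)
}

# Two-sided permutation test on |mean(x) - mean(y)|. Exact when the number of
# ways to choose the x-group is within budget; ties count as at least as
# extreme, so the observed assignment is always included (p > 0).
perm_p <- function(x, y, n_perm = 1e5, max_exact = 250000) {
  pool <- c(x, y)
  nx <- length(x)
  n <- length(pool)
  obs <- abs(mean(x) - mean(y))
  tol <- 1e-12 * max(1, obs)
  n_comb <- choose(n, nx)
  if (n_comb <= max_exact) {
    idx <- utils::combn(n, nx)
    stat <- apply(idx, 2, function(i) {
      abs(mean(pool[i]) - mean(pool[-i]))
    })
    return(sum(stat >= obs - tol) / n_comb)
  }
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    take <- sample.int(n, nx)
    abs(mean(pool[take]) - mean(pool[-take])) >= obs - tol
  }, logical(1)))
  (hits + 1) / (n_perm + 1)
}

# log-normal multiplier with unit mean and the requested coefficient of
# variation; cv = 0 degenerates to exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# "A01"-style well labels for a plate of `n` wells laid out in rows of
# `ncol` columns; rows beyond Z continue AA, AB, ...
well_labels <- function(n, ncol = 24) {
  nrow <- ceiling(n / ncol)
  row_names <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(nrow)]
  labs <- as.vector(t(outer(row_names, sprintf("%02d", seq_len(ncol)), paste0)))
  labs[seq_len(n)]
}

abort_missing_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
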