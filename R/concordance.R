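#' Concordance between two sets of response calls
#'
#' Elementwise agreement between paired PR/SD/PD calls with the full
#' 3 x 3 cross-table (rows = `calls_a`, columns = `calls_b`). The number
#' of agreements is the trace of the cross-table.
#'
#' @param calls_a,calls_b equal-length vectors/factors of PR/SD/PD.
#' @return An object of class `concordance_result`: `n_total`,
#'   `n_agree`, `fraction`, `cross_table`.
#' @export
concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    stop("call vectors must have equal length")
  if (length(calls_a) < 1L) stop("need at least one pair of calls")
  a <- factor(as.character(calls_a), levels = RESPONSE_LEVELS)
  b <- factor(as.character(calls_b), levels = RESPONSE_LEVELS)
  if (anyNA(a) || anyNA(b))
    stop("calls must be PR, SD or PD")
  tab <- table(a, b, dnn = c("a", "b"))
  n_agree <- sum(diag(tab))
  structure(list(n_total = length(a), n_agree = as.integer(n_agree),
                 fraction = n_agree / length(a), cross_table = tab),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance> ", x$n_agree, "/", x$n_total, " = ",
      signif(100 * x$fraction, 4), "%\n", sep = "")
  print(x$cross_table)
  invisible(x)
}

#' Spearman rank correlation with tie correction
#'
#' The coefficient is Pearson correlation on average (midrank) ranks.
#' Two-sided p-value: for n <= 10, the exact full-permutation null
#' distribution of r (all n! orderings of one variable); for larger n,
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom. Pairs with missing values are dropped
#' (pairwise-complete).
#'
#' @param x,y equal-length numeric vectors.
#' @return An object of class `correlation_result`: `r`, `p`, `n`,
#'   `method` ("exact-permutation" or "t-approximation"). With a
#'   constant input vector the coefficient is undefined and `r`/`p` are
#'   `NA`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          method = "undefined (constant input)"),
                     class = "correlation_result"))
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= 10L) {
    # under permutation of y, r is an affine function of sum(rx * ry_perm)
    # with fixed marginals, so |r| ordering equals |s - mu| ordering
    perms <- all_permutations(n)
    s_obs <- sum(rx * ry)
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    s_null <- as.vector(ry_perm %*% cbind(rx))
    mu <- mean(s_null)
    p <- mean(abs(s_null - mu) >= abs(s_obs - mu) - 1e-9)
    method <- "exact-permutation"
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(r = r, p = min(p, 1), n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation> r = ", signif(x$r, 3), ", p = ", signif(x$p, 3),
      ", n = ", x$n, " (", x$method, ")\n", sep = "")
  invisible(x)
}

# All n! permutations of 1..n as an n! x n matrix, built by iterative
# insertion. Used for the exact Spearman null at small n.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 10L)
  p <- matrix(1L, nrow = 1L, ncol = 1L)
  if (n == 1L) return(p)
  for (k in 2L:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      if (pos == 1L) cbind(k, p)
      else if (pos == k) cbind(p, k)
      else cbind(p[, seq_len(pos - 1L), drop = FALSE], k,
                 p[, pos:(k - 1L), drop = FALSE])
    })
    p <- do.call(rbind, blocks)
  }
  p
}

# Permutation of rows applied to rx: rx fixed, y permuted. (helper used
# in spearman_cor; exported nowhere)

#' Correlation screen of covariates against burden/PSA changes
#'
#' One Spearman correlation per (covariate, delta) pair,
#' pairwise-complete, with no multiplicity adjustment (each cell reports
#' its raw p). Cells with fewer than 3 complete pairs are reported as
#' undefined.
#'
#' @param covariates named list (or data frame) of numeric vectors.
#' @param deltas named list (or data frame) of numeric vectors, e.g.
#'   `delta_tlp_pct`, `delta_mtv_pct`, `delta_psa_pct`.
#' @return Data frame with columns `covariate`, `delta`, `r`, `p`, `n`.
#' @export
correlation_screen <- function(covariates, deltas) {
  covariates <- as.list(covariates)
  deltas <- as.list(deltas)
  len <- unique(c(vapply(covariates, length, 1L),
                  vapply(deltas, length, 1L)))
  if (length(len) != 1L)
    stop("all covariate and delta vectors must have the same length")
  rows <- list()
  for (cv in names(covariates)) {
    for (dv in names(deltas)) {
      ok <- is.finite(covariates[[cv]]) & is.finite(deltas[[dv]])
      if (sum(ok) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, delta = dv, r = NA_real_, p = NA_real_,
          n = sum(ok))
      } else {
        res <- spearman_cor(covariates[[cv]], deltas[[dv]])
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, delta = dv, r = res$r, p = res$p, n = res$n)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort medians and ranges
#'
#' Standard sample medians (mean of the central pair at even n) and
#' min-max ranges of TLP, MTV and PSA at both timepoints.
#'
#' @param records cohort data frame (the [assess_cohort()] contract).
#' @return Data frame with columns `variable`, `timepoint`, `median`,
#'   `min`, `max`, `n`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) < 1L) stop("cohort must contain at least one record")
  cols <- c(tlp_pre = "tlp", tlp_post = "tlp", mtv_pre = "mtv",
            mtv_post = "mtv", psa_pre = "psa", psa_post = "psa")
  out <- lapply(names(cols), function(cn) {
    v <- records[[cn]]
    v <- v[is.finite(v)]
    data.frame(variable = cols[[cn]],
               timepoint = if (grepl("_pre$", cn)) "pre" else "post",
               median = stats::median(v), min = min(v), max = max(v),
               n = length(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
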