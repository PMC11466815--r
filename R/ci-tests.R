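# Conditional-independence and conditional-invariance testing. Both assume an
# (approximately) linear-Gaussian model; partial correlations come from
# inversion of the correlation submatrix, which also powers the fast
# minimal-IMAP kernel in src/.

#' Fisher-z partial-correlation test of conditional independence
#'
#' Tests i _||_ j | S with the z-transform of the sample partial correlation:
#' z = atanh(r), statistic sqrt(n - |S| - 3) * |z|, two-sided normal p-value.
#'
#' @param data Numeric matrix or data frame (samples x variables) with column
#'   names, or a sufficient statistic from [gauss_suffstat()].
#' @param i,j Variable names or indices.
#' @param S Conditioning set (names or indices); may be empty.
#' @param alpha_ci Level used to call dependence. Default 0.05.
#' @return A one-row tibble: `i`, `j`, `S`, `r`, `statistic`, `p`, `dependent`.
#' @export
fisher_z_ci_test <- function(data, i, j, S = character(0), alpha_ci = 0.05) {
  ss <- gauss_suffstat(data)
  idx <- resolve_vars(ss$names, c(i, j, S))
  i_ <- idx[1]; j_ <- idx[2]; S_ <- idx[-(1:2)]
  if (ss$n <= length(S_) + 3) {
    abort(sprintf("need n > |S| + 3 (n = %d, |S| = %d)", ss$n, length(S_)))
  }
  r <- partial_cor(ss$C, i_, j_, S_)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  stat <- sqrt(ss$n - length(S_) - 3) * abs(z)
  p <- 2 * pnorm(-stat)
  tibble::tibble(
    i = ss$names[i_], j = ss$names[j_],
    S = paste(ss$names[S_], collapse = ","),
    r = r, statistic = stat, p = p, dependent = p < alpha_ci
  )
}

#' Sufficient statistic for Gaussian CI testing
#'
#' @param data Samples-by-variables matrix or data frame.
#' @return List with correlation matrix `C`, sample size `n`, and `names`.
#' @export
gauss_suffstat <- function(data) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$C)) return(data)
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance column(s): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  list(C = cor(m), n = nrow(m), names = colnames(m))
}

resolve_vars <- function(nms, v) {
  if (is.character(v)) {
    idx <- match(v, nms)
    if (anyNA(idx)) abort(paste0("unknown variable(s): ",
                                 paste(v[is.na(idx)], collapse = ", ")))
    idx
  } else as.integer(v)
}

# Partial correlation of (i, j) given S via precision of the submatrix.
# Near-singular matrices get a ridge of 1e-8 on the diagonal, with a warning.
partial_cor <- function(C, i, j, S) {
  sub <- C[c(i, j, S), c(i, j, S), drop = FALSE]
  Th <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(Th)) {
    warn("near-singular conditioning covariance; applying ridge 1e-8")
    Th <- solve(sub + diag(1e-8, nrow(sub)))
  }
  -Th[1, 2] / sqrt(Th[1, 1] * Th[2, 2])
}

#' Gaussian conditional-invariance test across two experimental settings
#'
#' Regresses variable `i` on the conditioning set `S` within the control and
#' the perturbed sample, then tests (a) equality of the regression coefficient
#' vectors (Chow-type F test) and (b) equality of the residual variances
#' (two-sided F ratio). The two component p-values are combined by Bonferroni:
#' p = min(1, 2 min(p_coef, p_var)). The conditional distribution of `i` is
#' called invariant when the combined p is at least `alpha_inv`.
#'
#' @param control_data,setting_data Samples-by-variables matrices sharing
#'   column names.
#' @param i Variable tested for a mechanism shift.
#' @param S Conditioning set (possibly empty).
#' @param alpha_inv Level below which invariance is rejected. Default 0.05.
#' @return One-row tibble: `i`, `S`, `p_coef`, `p_var`, `p`, `invariant`.
#' @export
gauss_invariance_test <- function(control_data, setting_data, i,
                                  S = character(0), alpha_inv = 0.05) {
  x1 <- as.matrix(control_data); x2 <- as.matrix(setting_data)
  nms <- colnames(x1)
  idx <- resolve_vars(nms, c(i, S))
  i_ <- idx[1]; S_ <- idx[-1]
  r <- invariance_pvalue(x1, x2, i_, S_)
  tibble::tibble(
    i = nms[i_], S = paste(nms[S_], collapse = ","),
    p_coef = r$p_coef, p_var = r$p_var, p = r$p,
    invariant = r$p >= alpha_inv
  )
}

# scalar core of the invariance test; hot path for ut_igsp scoring
invariance_pvalue <- function(x1, x2, i_, S_) {
  k <- length(S_) + 1L
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 <= k + 1 || n2 <= k + 1) abort("need n > |S| + 2 in both samples")
  f1 <- ols_rss(x1, i_, S_); f2 <- ols_rss(x2, i_, S_)
  fp <- ols_rss(rbind(x1, x2), i_, S_)
  if (f1$rss + f2$rss < 1e-300) {
    # identical samples: exactly invariant by construction
    p_coef <- 1; p_var <- 1
  } else {
    df2 <- n1 + n2 - 2L * k
    Fc <- ((fp$rss - f1$rss - f2$rss) / k) / ((f1$rss + f2$rss) / df2)
    p_coef <- pf(max(Fc, 0), k, df2, lower.tail = FALSE)
    Fv <- (f1$rss / (n1 - k)) / (f2$rss / (n2 - k))
    pv <- pf(Fv, n1 - k, n2 - k)
    p_var <- 2 * min(pv, 1 - pv)
  }
  list(p_coef = p_coef, p_var = p_var, p = min(1, 2 * min(p_coef, p_var)))
}

# OLS of column i on columns S (with intercept) from cross-products.
ols_rss <- function(x, i, S) {
  X <- cbind(1, x[, S, drop = FALSE])
  y <- x[, i]
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- tryCatch(solve(XtX, Xty), error = function(e)
    solve(XtX + diag(1e-8, ncol(X)), Xty))
  rss <- sum(y^2) - drop(crossprod(beta, Xty))
  list(beta = drop(beta), rss = max(rss, 0))
}

# --- tester objects ---------------------------------------------------------
# A ci_tester is a list(test = function(i, j, S) -> logical dependent, ...).
# Structure-learning code only calls $test with integer indices, so oracle
# testers (d-separation on a known DAG) plug in alongside the Fisher-z tester.

#' Construct a Fisher-z conditional-independence tester
#'
#' @param data Samples-by-variables matrix.
#' @param alpha_ci Test level.
#' @return A tester object for [gsp()] / [ut_igsp()].
#' @export
ci_tester_fisher_z <- function(data, alpha_ci = 0.05) {
  ss <- gauss_suffstat(data)
  structure(
    list(
      kind = "fisher_z", suffstat = ss, alpha = alpha_ci,
      test = function(i, j, S) {
        r <- partial_cor(ss$C, i, j, S)
        z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
        2 * pnorm(-sqrt(ss$n - length(S) - 3) * abs(z)) < alpha_ci
      }
    ),
    class = "ci_tester"
  )
}

#' Construct an oracle conditional-independence tester from a known DAG
#'
#' Declares dependence exactly when i and j are d-connected given S in the
#' supplied DAG; used for consistency checks of the structure learners.
#'
#' @param dag Logical adjacency matrix of the true DAG.
#' @return A tester object.
#' @export
ci_tester_dsep <- function(dag) {
  structure(
    list(kind = "dsep", dag = dag, alpha = NA_real_,
         test = function(i, j, S) !d_separated(dag, i, j, S)),
    class = "ci_tester"
  )
}

#' Construct a Gaussian invariance tester over perturbed settings
#'
#' Results are memoized per (variable, conditioning set, setting), which keeps
#' permutation search affordable.
#'
#' @param control_data Control-sample matrix.
#' @param setting_datas List of perturbed-sample matrices (same columns).
#' @param alpha_inv Test level.
#' @return An invariance tester object with `$invariant(i, S, k)`.
#' @export
invariance_tester_gauss <- function(control_data, setting_datas,
                                    alpha_inv = 0.05) {
  control_data <- as.matrix(control_data)
  setting_datas <- lapply(setting_datas, as.matrix)
  # augmented cross-product matrices [1 X]'[1 X]: any regression i ~ S
  # reduces to submatrix solves, so permutation search stays cheap
  xprod <- function(x) crossprod(cbind(1, x))
  M1 <- xprod(control_data)
  n1 <- nrow(control_data)
  Mk <- lapply(setting_datas, xprod)
  nk <- vapply(setting_datas, nrow, 1L)
  rss_of <- function(M, i, S) {
    a <- c(1L, S + 1L)
    beta <- tryCatch(solve(M[a, a], M[a, i + 1L]), error = function(e)
      solve(M[a, a] + diag(1e-8, length(a)), M[a, i + 1L]))
    max(M[i + 1L, i + 1L] - drop(crossprod(beta, M[a, i + 1L])), 0)
  }
  cache <- new.env(parent = emptyenv())
  invariant <- function(i, S, k) {
    key <- paste(k, i, paste(sort(S), collapse = "."), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    kk <- length(S) + 1L
    n2 <- nk[k]
    rss1 <- rss_of(M1, i, S)
    rss2 <- rss_of(Mk[[k]], i, S)
    rssp <- rss_of(M1 + Mk[[k]], i, S)
    if (rss1 + rss2 < 1e-300) {
      p <- 1
    } else {
      df2 <- n1 + n2 - 2L * kk
      Fc <- ((rssp - rss1 - rss2) / kk) / ((rss1 + rss2) / df2)
      p_coef <- pf(max(Fc, 0), kk, df2, lower.tail = FALSE)
      Fv <- (rss1 / (n1 - kk)) / (rss2 / (n2 - kk))
      pv <- pf(Fv, n1 - kk, n2 - kk)
      p <- min(1, 2 * min(p_coef, 2 * min(pv, 1 - pv)))
    }
    res <- p >= alpha_inv
    cache[[key]] <- res
    res
  }
  structure(
    list(kind = "gauss", n_settings = length(setting_datas),
         alpha = alpha_inv, invariant = invariant),
    class = "invariance_tester"
  )
}
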