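# Module-level interpretation: top transcription factors per module, upstream
# TF regulators of an outflowing ligand (random-forest Gini importance), and
# downstream TF responses to an inflowing signal (Gamma GAM with log link).

#' Top transcription factors per gene expression module
#'
#' Per module, genes are sorted by decreasing loading score (shared loadings
#' plus, for multi-condition factorizations, the mean condition-specific
#' loading, unless a single `condition` is requested); the first `top_n`
#' genes that are known TFs are returned, in sorted order. Ties break
#' lexicographically, so results are deterministic and invariant to positive
#' rescaling of the loadings.
#'
#' @param factorization A [gem_factorization()] with loadings.
#' @param tf_list Character vector of a priori known TFs.
#' @param top_n Number of TFs per module (default 10).
#' @param condition Optional condition whose specific loadings are added to
#'   the shared loadings instead of the cross-condition mean.
#' @return Named list (one per module) of TF character vectors.
#' @export
top_tfs_per_gem <- function(factorization, tf_list, top_n = 10,
                            condition = NULL) {
  W <- factorization$shared_loadings
  if (is.null(W)) abort("factorization carries no loadings")
  V <- factorization$condition_loadings
  score <- W
  if (!is.null(V)) {
    if (!is.null(condition)) {
      if (!condition %in% names(V)) abort("unknown condition")
      score <- W + V[[condition]]
    } else {
      score <- W + Reduce(`+`, V) / length(V)
    }
  }
  genes <- rownames(score)
  if (!length(intersect(tf_list, genes))) {
    warn("no known TF appears in the factorization gene set")
    return(setNames(rep(list(character(0)), ncol(score)), colnames(score)))
  }
  out <- lapply(seq_len(ncol(score)), function(k) {
    ord <- order(-score[, k], genes)
    sorted <- genes[ord]
    head(sorted[sorted %in% tf_list], top_n)
  })
  setNames(out, colnames(score))
}

#' Rank candidate upstream TF regulators of a ligand
#'
#' Fits a random-forest regression of the target ligand's expression on the
#' candidate TF expressions, over `n_runs` differently seeded forests, and
#' ranks TFs by mean Gini importance (mean decrease in impurity), normalized
#' to sum to one within each run.
#'
#' @param expression Samples-by-genes matrix (normalized layer) covering the
#'   candidates and the target.
#' @param candidate_tfs Character vector (>= 2) of candidate TF genes.
#' @param target_ligand Target gene whose expression is modeled.
#' @param n_runs Number of forest fits (default 10).
#' @param n_trees Trees per forest (default 100).
#' @param seed Integer seed; run r uses `seed + r`.
#' @return Tibble: `tf`, `mean_importance`, `sd_importance`, `rank`.
#' @export
rank_upstream_tfs <- function(expression, candidate_tfs, target_ligand,
                              n_runs = 10, n_trees = 100, seed = 1) {
  expression <- as.matrix(expression)
  if (length(candidate_tfs) < 2) abort("need at least 2 candidate TFs")
  missing_g <- setdiff(c(candidate_tfs, target_ligand), colnames(expression))
  if (length(missing_g))
    abort(paste0("gene(s) not measured: ", paste(missing_g, collapse = ", ")))
  y <- expression[, target_ligand]
  if (sd(y) == 0) abort("target ligand expression is constant")
  X <- as.data.frame(expression[, candidate_tfs, drop = FALSE])
  names(X) <- make.names(candidate_tfs)
  df <- cbind(X, .target = y)
  imps <- vapply(seq_len(n_runs), function(r) {
    fit <- ranger::ranger(
      dependent.variable.name = ".target", data = df,
      num.trees = n_trees, importance = "impurity",
      mtry = max(1, floor(sqrt(ncol(X)))), seed = seed + r,
      num.threads = 1
    )
    imp <- fit$variable.importance
    imp <- pmax(imp, 0)
    imp / sum(imp)
  }, numeric(length(candidate_tfs)))
  tb <- tibble::tibble(
    tf = candidate_tfs,
    mean_importance = rowMeans(imps),
    sd_importance = apply(imps, 1, sd)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance), .data$tf)
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Fit a downstream TF response to an inflowing signal
#'
#' Generalized additive fit of TF expression on the inflow variable with a
#' cubic regression spline basis, Gamma errors and log link (zeros in the
#' response get a pseudocount of 1e-6); smoothing is selected by generalized
#' cross-validation. The association strength is the Spearman correlation
#' between the fitted values and the inflow. If the fit fails to converge the
#' function falls back to a monotone isotonic fit, flagged in the result.
#'
#' @param inflow_values Nonnegative inflow variable with positive variance.
#' @param tf_expression Nonnegative TF expression vector.
#' @param k Spline basis dimension (default 10 knots).
#' @return List with `fitted` (numeric vector), `rho` (Spearman correlation),
#'   `direction` (`"up"`, `"down"` or `"flat"`), `method`, and `converged`.
#' @export
fit_downstream_tf_response <- function(inflow_values, tf_expression, k = 10) {
  x <- as.numeric(inflow_values); y <- as.numeric(tf_expression)
  if (any(x < 0) || sd(x) == 0) abort("inflow must be nonnegative, non-constant")
  if (any(y < 0)) abort("TF expression must be nonnegative")
  if (sd(y) == 0) {
    return(list(fitted = rep(mean(y), length(y)), rho = 0,
                direction = "flat", method = "constant", converged = TRUE))
  }
  y[y == 0] <- 1e-6
  k <- min(k, length(unique(x)) - 1)
  fit <- tryCatch(
    mgcv::gam(y ~ s(x, bs = "cr", k = k), family = stats::Gamma(link = "log"),
              method = "GCV.Cp"),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit) && isTRUE(fit$converged)) {
    fv <- as.numeric(fitted(fit))
    method <- "gam"; converged <- TRUE
  } else {
    warn("GAM did not converge; using monotone isotonic fallback")
    ord <- order(x)
    up <- isoreg(x[ord], y[ord])
    dn <- isoreg(x[ord], -y[ord])
    use_up <- sum((up$yf - y[ord])^2) <= sum((-dn$yf - y[ord])^2)
    fv <- numeric(length(y))
    fv[ord] <- if (use_up) up$yf else -dn$yf
    method <- "isotonic"; converged <- FALSE
  }
  rho <- if (sd(fv) == 0) 0 else
    suppressWarnings(stats::cor(fv, x, method = "spearman"))
  direction <- if (abs(rho) < 1e-8) "flat" else if (rho > 0) "up" else "down"
  list(fitted = fv, rho = unname(rho), direction = direction, method = method,
       converged = converged)
}
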