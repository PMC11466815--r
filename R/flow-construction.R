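# Construction of the augmented flow-expression variables. All constructions
# run on the normalized (log) layer; geometric means propagate zeros.

geometric_mean_rows <- function(m) {
  # rowwise geometric mean; any zero makes the product zero, so work on the
  # raw scale rather than through logs
  apply(m, 1, function(r) prod(r)^(1 / length(r)))
}

#' Inflow signal for non-spatial data: receptor expression weighted by
#' downstream TF activity
#'
#' Per cell, the inflow for interaction L-R1+...+Rn is
#' `(R1 * ... * Rn)^(1/n) * (TF1 + ... + TFm) / m`, computed on the normalized
#' layer. Receptor expression measures a cell's potential to receive the
#' signal; the mean expression of the receptors' immediate downstream TF
#' targets measures whether the signal actually arrived.
#'
#' @param dataset An [expression_dataset()].
#' @param interaction An [lr_interaction()] with receptor subunits present in
#'   the dataset.
#' @param tf_fallback What to do when the interaction carries no downstream
#'   TFs (`m = 0`): `"error"` (default) or `"receptor"` (use raw receptor
#'   expression, with a warning).
#' @return Named numeric vector (one value per cell), named
#'   `inflow:PATHWAY:R1+R2`.
#' @export
construct_inflow_nonspatial <- function(dataset, interaction,
                                        tf_fallback = c("error", "receptor")) {
  tf_fallback <- match.arg(tf_fallback)
  rec <- interaction$receptor_subunits
  missing_rec <- setdiff(rec, dataset$gene_ids)
  if (length(missing_rec))
    abort(paste0("receptor subunit(s) not measured: ",
                 paste(missing_rec, collapse = ", ")))
  R <- geometric_mean_rows(dataset$normalized[, rec, drop = FALSE])
  tfs <- intersect(interaction$downstream_tfs, dataset$gene_ids)
  dropped <- setdiff(interaction$downstream_tfs, tfs)
  if (length(dropped))
    warn(paste0("downstream TF(s) not measured, ignored: ",
                paste(dropped, collapse = ", ")))
  if (!length(tfs)) {
    if (tf_fallback == "error")
      abort(sprintf("interaction %s has no measured downstream TFs (m = 0)",
                    interaction$name))
    warn(sprintf("no downstream TFs for %s; falling back to receptor expression",
                 interaction$name))
    tfbar <- 1
  } else {
    tfbar <- rowMeans(dataset$normalized[, tfs, drop = FALSE])
  }
  v <- R * tfbar
  names(v) <- dataset$cell_ids
  structure(v, flow_name = paste0("inflow:", interaction$pathway, ":",
                                  paste(rec, collapse = "+")))
}

#' Inflow signal for spatial data: summed received-communication scores
#'
#' Per spot, sums the communication scores over every interaction whose
#' ligand block equals `ligand`.
#'
#' @param dataset An [expression_dataset()] (spots must cover the score rows).
#' @param scores A [spatial_scores()] table.
#' @param ligand Ligand block name (e.g. `"SHH"` or `"L1+L2"`).
#' @return Named numeric vector per spot, named `inflow:r-LIGAND`.
#' @export
construct_inflow_spatial <- function(dataset, scores, ligand) {
  lig_block <- sub("->.*$", "", scores$interactions)
  hit <- lig_block == ligand
  if (!any(hit)) {
    abort(sprintf("ligand '%s' not among score columns; available: %s",
                  ligand, paste(unique(lig_block), collapse = ", ")))
  }
  v <- rowSums(scores$scores[, hit, drop = FALSE])
  v <- v[match(dataset$cell_ids, scores$spot_ids)]
  names(v) <- dataset$cell_ids
  if (anyNA(v)) abort("scores do not cover every spot in the dataset")
  structure(v, flow_name = paste0("inflow:r-", ligand))
}

#' Module enrichment variables from a factorization
#'
#' Row-normalizes the cell membership matrix to sum to one and log-transforms
#' with the dataset's scale factor: `log(1 + alpha * W_tilde_k)` per module k,
#' which puts module enrichment on the same scale as log-normalized gene
#' expression. All-zero membership rows map to zero.
#'
#' @param factorization A [gem_factorization()].
#' @param alpha Positive scale factor (the one used to normalize counts).
#' @return Samples-by-K matrix with columns `GEM-1..K`.
#' @export
construct_module_variables <- function(factorization, alpha) {
  W <- factorization$membership
  if (any(W < 0)) abort("membership must be nonnegative")
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be positive")
  tot <- rowSums(W)
  tot[tot == 0] <- 1
  log1p(alpha * W / tot)
}

#' Outflow signal: ligand expression
#'
#' Per cell, the geometric mean of the ligand subunit expression values on the
#' normalized layer.
#'
#' @param dataset An [expression_dataset()].
#' @param ligand_subunits Character vector of ligand subunit gene ids.
#' @return Named numeric vector per cell, named `outflow:L1+L2`.
#' @export
construct_outflow <- function(dataset, ligand_subunits) {
  missing_lig <- setdiff(ligand_subunits, dataset$gene_ids)
  if (length(missing_lig))
    abort(paste0("ligand subunit(s) not measured: ",
                 paste(missing_lig, collapse = ", ")))
  v <- geometric_mean_rows(dataset$normalized[, ligand_subunits, drop = FALSE])
  names(v) <- dataset$cell_ids
  structure(v, flow_name = paste0("outflow:",
                                  paste(ligand_subunits, collapse = "+")))
}

#' Assemble constructed variables into a flow frame
#'
#' @param inflows List (possibly empty) of vectors from
#'   [construct_inflow_nonspatial()] / [construct_inflow_spatial()]; names
#'   default to their `flow_name` attribute.
#' @param modules Samples-by-K module matrix from
#'   [construct_module_variables()], or NULL.
#' @param outflows List of vectors from [construct_outflow()].
#' @param condition Per-sample condition labels.
#' @param pathway_of Optional named pathway map for inflow variables; derived
#'   from `inflow:PATH:...` names when absent.
#' @param alpha Scale factor to record.
#' @return A [flow_frame()].
#' @export
assemble_flowframe <- function(inflows = list(), modules = NULL,
                               outflows = list(), condition,
                               pathway_of = NULL, alpha = NA_real_) {
  vec_name <- function(v, i, prefix) attr(v, "flow_name") %||%
    paste0(prefix, ":", i)
  pack <- function(lst, prefix) {
    if (!length(lst)) return(NULL)
    m <- do.call(cbind, lapply(lst, as.numeric))
    colnames(m) <- purrr::imap_chr(lst, function(v, i) vec_name(v, i, prefix))
    rownames(m) <- names(lst[[1]])
    m
  }
  infl <- pack(inflows, "inflow")
  outf <- pack(outflows, "outflow")
  parts <- list(infl, modules, outf)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) abort("no variables to assemble")
  ns <- vapply(parts, nrow, 1L)
  if (length(unique(ns)) != 1) abort("sample counts differ across parts")
  values <- do.call(cbind, parts)
  cls <- c(
    rep("inflow", if (is.null(infl)) 0 else ncol(infl)),
    rep("module", if (is.null(modules)) 0 else ncol(modules)),
    rep("outflow", if (is.null(outf)) 0 else ncol(outf))
  )
  names(cls) <- colnames(values)
  if (is.null(pathway_of)) {
    innames <- names(cls)[cls == "inflow"]
    pw <- sub("^inflow:([^:]*).*$", "\\1", innames)
    pathway_of <- setNames(pw, innames)
  }
  flow_frame(values, cls, condition, pathway_of = pathway_of, alpha = alpha)
}

#' Drop degenerate flow variables
#'
#' Removes variables whose standard deviation is zero within any retained
#' condition (for example a signal fully silenced by the perturbation), for
#' which partial correlations are undefined. Removals are reported.
#'
#' @param flowframe A [flow_frame()].
#' @return The filtered flow frame.
#' @export
drop_degenerate <- function(flowframe) {
  vals <- flow_values(flowframe)
  cond <- flowframe$condition
  degen <- vapply(colnames(vals), function(v) {
    any(vapply(split(vals[, v], cond), sd, numeric(1)) == 0)
  }, logical(1))
  if (!any(degen)) return(flowframe)
  inform(paste0("dropping degenerate variable(s): ",
                paste(names(degen)[degen], collapse = ", ")))
  keep <- names(degen)[!degen]
  flow_frame(vals[, keep, drop = FALSE], var_classes(flowframe)[keep],
             cond,
             pathway_of = attr(flowframe, "pathway_of")[
               intersect(names(attr(flowframe, "pathway_of")), keep)],
             alpha = attr(flowframe, "alpha"))
}

#' Group inflow variables by parent signaling pathway
#'
#' Reporting-level relabeling only; structure learning always runs at
#' receptor resolution.
#'
#' @param flowframe A [flow_frame()].
#' @return Named list mapping pathway -> character vector of inflow variables.
#' @export
aggregate_inflows_by_pathway <- function(flowframe) {
  vc <- var_classes(flowframe)
  infl <- names(vc)[vc == "inflow"]
  if (!length(infl)) return(list())
  pw <- attr(flowframe, "pathway_of")[infl]
  split(infl, unname(pw))
}
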