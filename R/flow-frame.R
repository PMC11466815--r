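#' Augmented flow-expression frame
#'
#' A tibble of samples by constructed flow variables, where every variable is
#' tagged with a class: `inflow` (received signal), `module` (gene expression
#' module enrichment) or `outflow` (emitted ligand). The first two columns are
#' `sample_id` and `condition`; variable metadata travel as attributes.
#'
#' @param values Numeric samples-by-variables matrix with dimnames.
#' @param var_class Named character vector mapping each variable to
#'   `"inflow"`, `"module"` or `"outflow"`.
#' @param condition Per-sample condition labels.
#' @param pathway_of Optional named character vector mapping inflow variables
#'   to their parent signaling pathway.
#' @param alpha Scale factor used for the module log-transform (recorded).
#' @return A `flow_frame` tibble.
#' @export
flow_frame <- function(values, var_class, condition,
                       pathway_of = character(0), alpha = NA_real_) {
  values <- as.matrix(values)
  vars <- colnames(values)
  if (anyDuplicated(vars)) {
    abort(paste0("duplicate variable name(s): ",
                 paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  }
  if (!setequal(names(var_class), vars))
    abort("`var_class` must name every variable exactly once")
  bad <- setdiff(unique(var_class), c("inflow", "module", "outflow"))
  if (length(bad))
    abort(paste0("unknown variable class(es): ", paste(bad, collapse = ", ")))
  if (length(condition) != nrow(values))
    abort("`condition` must have one label per sample")
  ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids, condition = as.character(condition)),
    tibble::as_tibble(values)
  )
  attr(out, "var_class") <- var_class[vars]
  attr(out, "pathway_of") <- pathway_of
  attr(out, "alpha") <- alpha
  class(out) <- c("flow_frame", class(out))
  out
}

#' @export
print.flow_frame <- function(x, ...) {
  vc <- var_classes(x)
  cat(sprintf("<flow_frame> %d samples x %d variables (%d inflow, %d module, %d outflow)\n",
              nrow(x), length(vc), sum(vc == "inflow"), sum(vc == "module"),
              sum(vc == "outflow")))
  NextMethod()
}

#' Variable metadata accessors for flow frames
#'
#' @param x A [flow_frame()].
#' @return `var_classes()`: named character vector of variable classes;
#'   `flow_values()`: the numeric samples-by-variables matrix.
#' @export
var_classes <- function(x) attr(x, "var_class")

#' @rdname var_classes
#' @export
flow_values <- function(x) {
  vars <- names(var_classes(x))
  m <- as.matrix(as.data.frame(x)[vars])
  rownames(m) <- x$sample_id
  m
}

#' Serialize a flow frame as CSV plus a JSON sidecar
#'
#' The CSV holds `sample_id`, `condition` and the variable columns; the
#' sidecar records variable classes, the pathway map and the scale factor.
#'
#' @param x A [flow_frame()].
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @export
write_flow_frame <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  side <- list(var_class = as.list(var_classes(x)),
               pathway_of = as.list(attr(x, "pathway_of")),
               alpha = attr(x, "alpha"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_flow_frame
#' @export
read_flow_frame <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  vals <- as.matrix(df[setdiff(names(df), c("sample_id", "condition"))])
  rownames(vals) <- df$sample_id
  flow_frame(vals, unlist(side$var_class), df$condition,
             pathway_of = unlist(side$pathway_of) %||% character(0),
             alpha = side$alpha %||% NA_real_)
}
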