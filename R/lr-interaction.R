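# Ligand-receptor interactions. Multi-subunit complexes use "+" between
# subunits and "->" between the ligand and receptor blocks, giving canonical
# interaction names such as "IL6->IL6R+IL6ST".

#' Construct a ligand-receptor interaction
#'
#' @param ligand_subunits Character vector of ligand subunit gene ids.
#' @param receptor_subunits Character vector of receptor subunit gene ids.
#' @param pathway Pathway name the interaction belongs to.
#' @param downstream_tfs Character vector of immediate downstream
#'   transcription-factor targets (may be empty).
#' @return An `lr_interaction` object.
#' @export
lr_interaction <- function(ligand_subunits, receptor_subunits, pathway,
                           downstream_tfs = character(0)) {
  ligand_subunits <- unique(as.character(ligand_subunits))
  receptor_subunits <- unique(as.character(receptor_subunits))
  if (!length(ligand_subunits) || any(!nzchar(ligand_subunits)))
    abort("ligand subunit list must be non-empty, with non-empty tokens")
  if (!length(receptor_subunits) || any(!nzchar(receptor_subunits)))
    abort("receptor subunit list must be non-empty, with non-empty tokens")
  structure(
    list(ligand_subunits = ligand_subunits,
         receptor_subunits = receptor_subunits,
         pathway = as.character(pathway),
         downstream_tfs = unique(as.character(downstream_tfs)),
         name = paste0(paste(ligand_subunits, collapse = "+"), "->",
                       paste(receptor_subunits, collapse = "+"))),
    class = "lr_interaction"
  )
}

#' @export
print.lr_interaction <- function(x, ...) {
  cat(sprintf("<lr_interaction> %s [%s], %d downstream TF(s)\n",
              x$name, x$pathway, length(x$downstream_tfs)))
  invisible(x)
}

#' Read a ligand-receptor interaction table
#'
#' Expects a CSV with columns `ligand`, `receptor`, `pathway`; multi-subunit
#' complexes are joined with `+`. Duplicate rows collapse to a single
#' interaction.
#'
#' @param path CSV file.
#' @return A list of [lr_interaction()] objects, named by canonical name.
#' @export
read_lr_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("ligand", "receptor", "pathway")
  if (!all(need %in% names(df)))
    abort(paste0("LR table must have columns: ", paste(need, collapse = ", ")))
  df <- dplyr::distinct(df, .data$ligand, .data$receptor, .data$pathway)
  out <- purrr::pmap(df[need], function(ligand, receptor, pathway) {
    lig <- strsplit(ligand, "+", fixed = TRUE)[[1]]
    rec <- strsplit(receptor, "+", fixed = TRUE)[[1]]
    if (any(!nzchar(c(lig, rec))))
      abort(sprintf("empty subunit token in '%s' / '%s'", ligand, receptor))
    lr_interaction(lig, rec, pathway)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out[!duplicated(names(out))]
}

#' Read a receptor-to-TF prior-knowledge table and attach TFs to interactions
#'
#' The CSV must have columns `receptor_gene` and `tf_gene`. For each
#' interaction, the downstream TF set is the union over its receptor subunits.
#' TFs absent from `gene_universe` are dropped with a warning.
#'
#' @param path CSV file.
#' @param interactions List of [lr_interaction()] objects to annotate.
#' @param gene_universe Optional character vector of measured gene ids used to
#'   drop unmeasured TFs.
#' @return The interactions, with `downstream_tfs` filled in.
#' @export
read_tf_prior <- function(path, interactions, gene_universe = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("receptor_gene", "tf_gene")
  if (!all(need %in% names(df)))
    abort(paste0("TF prior must have columns: ", paste(need, collapse = ", ")))
  if (!is.null(gene_universe)) {
    missing_tfs <- setdiff(unique(df$tf_gene), gene_universe)
    if (length(missing_tfs)) {
      warn(paste0("dropping TF(s) absent from the gene universe: ",
                  paste(missing_tfs, collapse = ", ")))
      df <- df[df$tf_gene %in% gene_universe, , drop = FALSE]
    }
  }
  by_receptor <- split(df$tf_gene, df$receptor_gene)
  lapply(interactions, function(ia) {
    tfs <- unique(unlist(by_receptor[ia$receptor_subunits], use.names = FALSE))
    ia$downstream_tfs <- tfs %||% character(0)
    ia
  })
}
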