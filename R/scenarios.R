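# Ground-truth benchmark scenarios: three SHH/BMP morphogen circuits over
# which intercellular flows are learned. Nodes are classed as the flow model
# sees them: ligands are outflow variables, bound ligand-receptor complexes
# are inflow variables, transcription factors / patterning programs are
# module variables, and free receptors are auxiliary.

#' Ground-truth scenario definitions for the synthetic benchmark
#'
#' * `"unidirectional"` — 5 nodes, 4 arcs: SHH binding PTCH1 drives FOXF1,
#'   which drives BMP4 outflow.
#' * `"shh_patterning"` — 7 nodes, 11 arcs: SHH inflow activates NKX2.2 and
#'   OLIG2; PAX6 and IRX3 are expressed by default and repressed by the
#'   activated TFs, with the classic dorsoventral cross-repression wiring
#'   (PAX6 -| NKX2.2, NKX2.2 -| PAX6, OLIG2 -| PAX6, NKX2.2 -| OLIG2,
#'   IRX3 -| OLIG2, OLIG2 -| IRX3, NKX2.2 -| IRX3).
#' * `"shh_bmp_competition"` — 9 nodes, 10 arcs: SHH and BMP4 inflows compete
#'   to drive dorsal, intermediate and ventral expression programs.
#'
#' Kinetic constants (documented package constants): Hill coefficient 2,
#' half-max constants at the model mid-scale 0.5 (0.25 for the
#' intermediate program, which responds at lower SHH), ligand binding
#' half-max 1 (the median control ligand level), unit production and
#' degradation, multiplicative log-normal structural noise with sdlog 0.2,
#' exogenous ligand/receptor heterogeneity with sdlog 0.5, and a x5
#' perturbation on SHH production.
#'
#' @param scenario_id One of `"unidirectional"`, `"shh_patterning"`,
#'   `"shh_bmp_competition"`.
#' @return A `ground_truth_scenario`: list with `id`, `nodes`, `var_class`,
#'   `arcs` (tibble `from`, `to`, `sign`), `receptors` (total-receptor map),
#'   `kinetics`, and `perturbation`.
#' @export
scenario_truth <- function(scenario_id = c("unidirectional", "shh_patterning",
                                           "shh_bmp_competition")) {
  scenario_id <- match.arg(scenario_id)
  kin <- list(hill_n = 2, K = 0.5, K_intermediate = 0.25, K_bind = 1,
              noise_sd = 0.2, exo_sd = 0.5, production = 1, degradation = 1)
  pert <- list(ligand = "SHH", multiplier = 5)
  arcs <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble::tibble(from = m[, 1], to = m[, 2], sign = m[, 3])
  }
  def <- switch(scenario_id,
    unidirectional = list(
      var_class = c(SHH = "outflow", PTCH1 = "auxiliary", `r-SHH` = "inflow",
                    FOXF1 = "module", BMP4 = "outflow"),
      arcs = arcs("SHH", "r-SHH", "+",
                  "PTCH1", "r-SHH", "+",
                  "r-SHH", "FOXF1", "+",
                  "FOXF1", "BMP4", "+"),
      receptors = list(`r-SHH` = list(ligand = "SHH", free = "PTCH1"))
    ),
    shh_patterning = list(
      var_class = c(SHH = "outflow", PTCH1 = "auxiliary", `r-SHH` = "inflow",
                    NKX2.2 = "module", OLIG2 = "module", PAX6 = "module",
                    IRX3 = "module"),
      arcs = arcs("SHH", "r-SHH", "+",
                  "PTCH1", "r-SHH", "+",
                  "r-SHH", "NKX2.2", "+",
                  "r-SHH", "OLIG2", "+",
                  "PAX6", "NKX2.2", "-",
                  "NKX2.2", "PAX6", "-",
                  "OLIG2", "PAX6", "-",
                  "NKX2.2", "OLIG2", "-",
                  "IRX3", "OLIG2", "-",
                  "OLIG2", "IRX3", "-",
                  "NKX2.2", "IRX3", "-"),
      receptors = list(`r-SHH` = list(ligand = "SHH", free = "PTCH1"))
    ),
    shh_bmp_competition = list(
      var_class = c(SHH = "outflow", PTCH1 = "auxiliary", `r-SHH` = "inflow",
                    BMP4 = "outflow", BMPR = "auxiliary", `r-BMP4` = "inflow",
                    `GEM-D` = "module", `GEM-I` = "module",
                    `GEM-V` = "module"),
      arcs = arcs("SHH", "r-SHH", "+",
                  "PTCH1", "r-SHH", "+",
                  "BMP4", "r-BMP4", "+",
                  "BMPR", "r-BMP4", "+",
                  "r-SHH", "GEM-V", "+",
                  "r-SHH", "GEM-I", "+",
                  "r-SHH", "GEM-D", "-",
                  "r-BMP4", "GEM-D", "+",
                  "r-BMP4", "GEM-V", "-",
                  "r-BMP4", "GEM-I", "-"),
      receptors = list(`r-SHH` = list(ligand = "SHH", free = "PTCH1"),
                       `r-BMP4` = list(ligand = "BMP4", free = "BMPR"))
    )
  )
  structure(
    c(list(id = scenario_id, nodes = names(def$var_class)), def,
      list(kinetics = kin, perturbation = pert)),
    class = "ground_truth_scenario"
  )
}

#' @export
print.ground_truth_scenario <- function(x, ...) {
  cat(sprintf("<ground_truth_scenario> %s: %d nodes, %d signed arcs\n",
              x$id, length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

#' List available benchmark scenarios
#'
#' @return Tibble with scenario id, node count and true-arc count.
#' @export
list_scenarios <- function() {
  ids <- c("unidirectional", "shh_patterning", "shh_bmp_competition")
  purrr::map_dfr(ids, function(id) {
    tr <- scenario_truth(id)
    tibble::tibble(scenario = id, n_nodes = length(tr$nodes),
                   n_arcs = nrow(tr$arcs))
  })
}
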