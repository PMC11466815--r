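# Shared fixtures and independent oracles used across the test files.

nodes_of <- function(p) paste0("V", seq_len(p))

# Random DAG over a random variable order.
rand_dag <- function(p, prob = 0.5, seed = NULL) {
  sigflow:::with_seed(seed, {
    nm <- nodes_of(p)
    ord <- sample(p)
    a <- matrix(FALSE, p, p, dimnames = list(nm, nm))
    for (i in seq_len(p - 1)) {
      for (j in seq((i + 1), p)) {
        if (runif(1) < prob) a[ord[i], ord[j]] <- TRUE
      }
    }
    a
  })
}

skeleton_edges <- function(a) {
  sk <- a | t(a)
  which(sk & upper.tri(sk), arr.ind = TRUE)
}

vstruct_key <- function(a) {
  vs <- sigflow:::v_structures(a)
  if (!nrow(vs)) return(character(0))
  sort(paste(vs[, 1], vs[, 2], vs[, 3]))
}

# Enumeration oracle for the CPDAG of a DAG: orient every skeleton edge in
# all 2^E ways, keep acyclic orientations with identical v-structures, and
# call an edge compelled iff it has the same direction in every member.
enum_cpdag <- function(dag) {
  ed <- skeleton_edges(dag)
  E <- nrow(ed)
  target_vs <- vstruct_key(dag)
  members <- list()
  for (mask in 0:(2^E - 1)) {
    a <- dag & FALSE
    for (e in seq_len(E)) {
      i <- ed[e, 1]; j <- ed[e, 2]
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0) a[i, j] <- TRUE
      else a[j, i] <- TRUE
    }
    if (!sigflow:::is_acyclic(a)) next
    if (!identical(vstruct_key(a), target_vs)) next
    members[[length(members) + 1L]] <- a
  }
  out <- dag | t(dag)
  for (e in seq_len(E)) {
    i <- ed[e, 1]; j <- ed[e, 2]
    dirs <- vapply(members, function(a) a[i, j], logical(1))
    if (all(dirs)) out[j, i] <- FALSE
    if (all(!dirs)) out[i, j] <- FALSE
  }
  out
}

# Exhaustive sparsest-permutation oracle over all orderings.
exhaustive_sparsest_cpdag <- function(ci_tester, p) {
  perms <- combinat_perms(p)
  best <- NULL
  for (perm in perms) {
    g <- minimal_imap_dag(NULL, perm, ci_tester)
    if (is.null(best) || sum(g) < sum(best)) best <- g
  }
  cpdag_from_dag(best)
}

combinat_perms <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(p - 1)) {
    for (pos in seq_len(p)) {
      out[[length(out) + 1L]] <- append(sub, p, after = pos - 1L)
    }
  }
  out
}

# Brute-force Moran's I straight from the formula.
moran_brute <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Tiny expression fixture with known counts.
toy_dataset <- function(counts = NULL, condition = NULL, ...) {
  if (is.null(counts)) {
    counts <- matrix(c(1, 0, 0, 2, 3, 3), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("c", 1:3), c("gA", "gB")))
  }
  if (is.null(condition)) condition <- rep("ctrl", nrow(counts))
  expression_dataset(counts, condition, ...)
}

rand_flow_network <- function(p_in = 2, p_mod = 3, p_out = 2, seed = 1) {
  sigflow:::with_seed(seed, {
    cls <- c(setNames(rep("inflow", p_in), paste0("in", seq_len(p_in))),
             setNames(rep("module", p_mod), paste0("m", seq_len(p_mod))),
             setNames(rep("outflow", p_out), paste0("out", seq_len(p_out))))
    arcs <- NULL
    for (s in names(cls)) for (t in names(cls)) {
      ok <- (cls[s] == "inflow" && cls[t] == "module") ||
        (cls[s] == "module" && cls[t] == "module" && s != t) ||
        (cls[s] == "module" && cls[t] == "outflow")
      if (ok && runif(1) < 0.4) {
        arcs <- rbind(arcs, data.frame(source = s, target = t,
                                       weight = round(runif(1, 0.1, 2), 3)))
      }
    }
    if (is.null(arcs)) arcs <- data.frame(source = "in1", target = "m1",
                                          weight = 1)
    flow_network(arcs, cls)
  })
}
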