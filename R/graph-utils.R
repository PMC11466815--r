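# Directed/partially directed graphs are logical adjacency matrices with
# dimnames; amat[i, j] is an arc i -> j. An edge with amat[i, j] and amat[j, i]
# both TRUE is undirected. Helpers here are deliberately dependency-free so the
# causal-search code stays self-contained and fast.

empty_amat <- function(nodes) {
  p <- length(nodes)
  matrix(FALSE, p, p, dimnames = list(nodes, nodes))
}

amat_from_arcs <- function(nodes, from, to) {
  a <- empty_amat(nodes)
  if (length(from)) a[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  a
}

skeleton_of <- function(amat) amat | t(amat)

n_edges <- function(amat) {
  sk <- skeleton_of(amat)
  sum(sk[upper.tri(sk)])
}

is_acyclic <- function(amat) {
  # Kahn's algorithm on the directed part only.
  a <- amat & !t(amat)
  repeat {
    deg <- colSums(a)
    src <- which(deg == 0 & (rowSums(a) + deg) > 0)
    keep <- rowSums(a) + colSums(a) > 0
    if (!any(keep)) return(TRUE)
    if (!length(src)) return(FALSE)
    a[src, ] <- FALSE
  }
}

topological_order <- function(amat) {
  # Deterministic: among ready nodes, lowest column index first.
  p <- ncol(amat)
  a <- amat
  ord <- integer(0)
  left <- rep(TRUE, p)
  while (any(left)) {
    ready <- which(left & colSums(a[left, , drop = FALSE]) == 0)
    if (!length(ready)) stop("graph is cyclic; no topological order exists")
    nxt <- ready[1L]
    ord <- c(ord, nxt)
    left[nxt] <- FALSE
    a[nxt, ] <- FALSE
  }
  ord
}

parents_of <- function(amat, j) which(amat[, j] & !amat[j, ])

#' Find the v-structures of a DAG
#'
#' A v-structure is an ordered triple (x, z, y) with arcs x -> z <- y and x, y
#' non-adjacent; it is the direction-identifying motif of a Markov equivalence
#' class.
#'
#' @param amat Logical adjacency matrix of a DAG.
#' @return A matrix with columns `x`, `z`, `y` of node indices (x < y).
#' @keywords internal
v_structures <- function(amat) {
  sk <- skeleton_of(amat)
  out <- NULL
  for (z in seq_len(ncol(amat))) {
    pa <- parents_of(amat, z)
    if (length(pa) < 2) next
    cmb <- utils::combn(pa, 2)
    for (c_i in seq_len(ncol(cmb))) {
      x <- cmb[1, c_i]; y <- cmb[2, c_i]
      if (!sk[x, y]) out <- rbind(out, c(x, z, y))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 3)
  colnames(out) <- c("x", "z", "y")
  out
}

# Meek's orientation rules R1-R4, applied to a partially directed graph until
# closure. Arcs already present are never reversed.
meek_close <- function(pdag) {
  p <- ncol(pdag)
  repeat {
    changed <- FALSE
    dir <- pdag & !t(pdag)
    und <- pdag & t(pdag)
    adj <- pdag | t(pdag)
    for (b in seq_len(p)) {
      for (a in which(und[, b])) {
        orient <- FALSE
        # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
        if (any(dir[, a] & !adj[, b] & seq_len(p) != b)) orient <- TRUE
        # R2: a -> c -> b with a - b  =>  a -> b
        if (!orient && any(dir[a, ] & dir[, b])) orient <- TRUE
        # R3: a - c -> b, a - d -> b, c and d non-adjacent  =>  a -> b
        if (!orient) {
          cand <- which(und[a, ] & dir[, b])
          if (length(cand) >= 2) {
            for (ci in seq_along(cand)) {
              for (di in seq_len(ci - 1L)) {
                if (!adj[cand[ci], cand[di]]) { orient <- TRUE; break }
              }
              if (orient) break
            }
          }
        }
        # R4: a - d, d -> c, c -> b, b and d non-adjacent  =>  a -> b
        if (!orient) {
          for (d in which(und[a, ])) {
            if (adj[b, d]) next
            if (any(dir[d, ] & dir[, b])) { orient <- TRUE; break }
          }
        }
        if (orient) {
          pdag[b, a] <- FALSE
          changed <- TRUE
          dir <- pdag & !t(pdag); und <- pdag & t(pdag)
        }
      }
    }
    if (!changed) break
  }
  pdag
}

#' Complete a DAG to its CPDAG
#'
#' Keeps the skeleton, directs the v-structure arcs, and propagates compelled
#' orientations with Meek rules R1-R4; all remaining edges are undirected. Two
#' DAGs in the same Markov equivalence class map to the same CPDAG.
#'
#' @param dag Logical adjacency matrix of a DAG (named dimnames recommended).
#' @param forced Optional logical adjacency matrix of background arcs whose
#'   direction is known (e.g. perturbation-indicator arcs); these stay directed
#'   and participate in Meek propagation.
#' @return A `cpdag_result` object (see [cpdag_result()]).
#' @export
cpdag_from_dag <- function(dag, forced = NULL) {
  if (any(dag & t(dag)) || !is_acyclic(dag))
    abort("input graph is cyclic; a DAG is required")
  sk <- skeleton_of(dag)
  pdag <- sk
  vs <- v_structures(dag)
  if (nrow(vs)) {
    pdag[cbind(vs[, "z"], vs[, "x"])] <- FALSE
    pdag[cbind(vs[, "z"], vs[, "y"])] <- FALSE
  }
  if (!is.null(forced)) {
    w <- which(forced, arr.ind = TRUE)
    if (nrow(w)) pdag[cbind(w[, 2], w[, 1])] <- FALSE
  }
  pdag <- meek_close(pdag)
  cpdag_result(pdag)
}

# d-separation via the ancestral moral graph: x _||_ y | S in the DAG iff x and
# y are disconnected in the moralized subgraph over An({x, y} u S) minus S.
d_separated <- function(dag, x, y, S) {
  p <- ncol(dag)
  anc <- rep(FALSE, p)
  frontier <- unique(c(x, y, S))
  anc[frontier] <- TRUE
  while (length(frontier)) {
    pa <- which(rowSums(dag[, frontier, drop = FALSE] & !t(dag)[, frontier, drop = FALSE]) > 0)
    frontier <- pa[!anc[pa]]
    anc[frontier] <- TRUE
  }
  keep <- which(anc)
  sub <- dag[keep, keep, drop = FALSE]
  g <- skeleton_of(sub)
  # moralize: connect parents sharing a child
  for (j in seq_along(keep)) {
    pa <- which(sub[, j] & !sub[j, ])
    if (length(pa) >= 2) g[pa, pa] <- TRUE
  }
  diag(g) <- FALSE
  drop <- match(S, keep)
  drop <- drop[!is.na(drop)]
  if (length(drop)) { g[drop, ] <- FALSE; g[, drop] <- FALSE }
  # BFS from x
  xi <- match(x, keep); yi <- match(y, keep)
  seen <- rep(FALSE, length(keep)); seen[xi] <- TRUE
  frontier <- xi
  while (length(frontier)) {
    nb <- which(rowSums(g[, frontier, drop = FALSE]) > 0)
    nb <- nb[!seen[nb]]
    if (yi %in% nb) return(FALSE)
    seen[nb] <- TRUE
    frontier <- nb
  }
  TRUE
}
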