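# CI/invariance testing, minimal IMAPs, GSP/UT-IGSP, CPDAG completion.

test_that("fisher-z statistic and p match the closed form", {
  # orthogonal columns: r = 0 -> p = 1
  x <- cbind(a = c(1, -1, 1, -1, 0, 0), b = c(1, 1, -1, -1, 1, -1),
             c = rnorm(6))
  res <- fisher_z_ci_test(x, "a", "b")
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # known partial correlation at n = 100, |S| = 1
  set.seed(77)
  z <- rnorm(100); i <- z + rnorm(100); j <- z + rnorm(100)
  d <- cbind(i = i, j = j, z = z)
  res2 <- fisher_z_ci_test(d, "i", "j", "z")
  Ci <- solve(cor(d))
  r_manual <- -Ci[1, 2] / sqrt(Ci[1, 1] * Ci[2, 2])
  expect_equal(res2$r, r_manual)
  expect_equal(res2$statistic, sqrt(100 - 1 - 3) * abs(atanh(r_manual)))
  expect_equal(res2$p, 2 * pnorm(-res2$statistic))
  expect_error(fisher_z_ci_test(d[1:4, ], "i", "j", "z"), "n >")
})

test_that("invariance test is exact on identical samples and detects shifts", {
  set.seed(10)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  same <- gauss_invariance_test(x, x, "a", c("b", "c"))
  expect_equal(same$p, 1)
  expect_true(same$invariant)
  hits <- 0
  for (s in 1:20) {
    x1 <- sigflow:::with_seed(s, matrix(rnorm(300 * 2), 300, 2,
                                        dimnames = list(NULL, c("a", "b"))))
    x2 <- sigflow:::with_seed(1000 + s,
                              matrix(rnorm(300 * 2), 300, 2,
                                     dimnames = list(NULL, c("a", "b"))))
    x2[, "a"] <- x2[, "a"] + 3  # 3 s.d. mean shift
    if (!gauss_invariance_test(x1, x2, "a", "b")$invariant) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of seeds
})

test_that("memoized invariance tester agrees with the public test", {
  set.seed(14)
  nm <- c("a", "b", "c", "d")
  x1 <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, nm))
  x2 <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, nm))
  x2[, 3] <- x2[, 3] * 2
  it <- invariance_tester_gauss(x1, list(x2))
  for (i in 1:4) {
    for (S in list(integer(0), setdiff(1:4, i)[1],
                   setdiff(1:4, i)[1:2])) {
      expect_equal(it$invariant(i, S, 1),
                   gauss_invariance_test(x1, x2, i, S)$invariant,
                   info = paste(i, paste(S, collapse = ",")))
    }
  }
})

test_that("minimal IMAP reflects the ordering's CI relations", {
  set.seed(19)
  # independent columns -> empty DAG
  x <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  expect_equal(sum(minimal_imap_dag(x, c("X", "Y", "Z"))), 0)
  # chain X -> Y -> Z
  dag <- sigflow:::amat_from_arcs(c("X", "Y", "Z"), c("X", "Y"), c("Y", "Z"))
  xc <- sample_linear_gaussian_sem(dag, 1, 1, 3000, seed = 4)
  g1 <- minimal_imap_dag(xc, c("X", "Y", "Z"))
  expect_true(g1["X", "Y"] && g1["Y", "Z"] && sum(g1) == 2)
  g2 <- minimal_imap_dag(xc, c("Z", "Y", "X"))
  expect_true(g2["Z", "Y"] && g2["Y", "X"] && sum(g2) == 2)  # X _||_ Z | Y
})

test_that("C++ fisher-z IMAP path agrees with the generic R route", {
  set.seed(23)
  for (rep in 1:10) {
    dag <- rand_dag(5, 0.5, seed = rep)
    x <- sample_linear_gaussian_sem(dag, 0.8, 1, 400, seed = 100 + rep)
    ct <- ci_tester_fisher_z(x)
    # generic route through the same tester's $test function
    slow <- structure(list(kind = "generic", names = colnames(x),
                           test = ct$test), class = "ci_tester")
    slow_nodes <- function() colnames(x)
    perm <- sample(5)
    fast <- minimal_imap_dag(x, perm, ct)
    gen <- sigflow:::empty_amat(colnames(x))
    for (b in 2:5) for (a in 1:(b - 1)) {
      S <- setdiff(perm[seq_len(b - 1)], perm[a])
      if (ct$test(perm[a], perm[b], S)) gen[perm[a], perm[b]] <- TRUE
    }
    expect_identical(fast, gen)
  }
})

test_that("CPDAG completion matches the enumeration oracle on random DAGs", {
  # chain: fully undirected; collider: fully directed
  chain <- sigflow:::amat_from_arcs(c("X", "Y", "Z"), c("X", "Y"), c("Y", "Z"))
  cp <- cpdag_from_dag(chain)
  expect_true(all(cp$amat == (chain | t(chain))))
  coll <- sigflow:::amat_from_arcs(c("X", "Y", "Z"), c("X", "Y"), c("Z", "Z"))
  coll <- sigflow:::amat_from_arcs(c("X", "Y", "Z"), c("X", "Y"), c("Z", "Z"))
  coll <- sigflow:::empty_amat(c("X", "Y", "Z"))
  coll["X", "Z"] <- TRUE; coll["Y", "Z"] <- TRUE
  expect_identical(cpdag_from_dag(coll)$amat, coll)
  expect_error(cpdag_from_dag(matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)),
               "cyclic")
  # 100 random 5-node DAGs against the 2^E enumeration oracle
  set.seed(37)
  for (rep in 1:100) {
    dag <- rand_dag(5, runif(1, 0.2, 0.7))
    expect_identical(cpdag_from_dag(dag)$amat, enum_cpdag(dag),
                     info = paste("rep", rep))
  }
})

test_that("equivalent DAGs map to the same CPDAG", {
  set.seed(41)
  found <- 0
  for (rep in 1:200) {
    dag <- rand_dag(5, 0.4)
    cp <- cpdag_from_dag(dag)
    und <- which(cp$amat & t(cp$amat) & upper.tri(cp$amat), arr.ind = TRUE)
    if (!nrow(und)) next
    # reverse one reversible edge to get another member of the class
    i <- und[1, 1]; j <- und[1, 2]
    dag2 <- dag
    if (dag2[i, j]) { dag2[i, j] <- FALSE; dag2[j, i] <- TRUE }
    else { dag2[j, i] <- FALSE; dag2[i, j] <- TRUE }
    if (!sigflow:::is_acyclic(dag2)) next
    if (!identical(vstruct_key(dag2), vstruct_key(dag))) next
    found <- found + 1
    expect_identical(cpdag_from_dag(dag2)$amat, cp$amat)
  }
  expect_gt(found, 20)
})

test_that("GSP recovers chains, colliders, and the oracle CPDAG", {
  chain <- sigflow:::amat_from_arcs(c("X", "Y", "Z"), c("X", "Y"), c("Y", "Z"))
  cp <- gsp(NULL, ci_tester_dsep(chain), seed = 1)
  expect_true(all(cp$amat == (chain | t(chain))))
  coll <- sigflow:::empty_amat(c("X", "Y", "Z"))
  coll["X", "Z"] <- TRUE; coll["Y", "Z"] <- TRUE
  cp2 <- gsp(NULL, ci_tester_dsep(coll), seed = 2)
  expect_identical(cp2$amat, coll)
})

test_that("GSP with oracle CI recovers the true CPDAG on small SEMs", {
  set.seed(53)
  hits <- 0
  for (rep in 1:40) {
    dag <- rand_dag(4, 0.5)
    cp <- gsp(NULL, ci_tester_dsep(dag), n_restarts = 10, seed = rep)
    if (identical(cp$amat, cpdag_from_dag(dag)$amat)) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("GSP is equivariant under variable relabeling", {
  set.seed(61)
  dag <- rand_dag(4, 0.5)
  x <- sample_linear_gaussian_sem(dag, 1, 1, 800, seed = 3)
  cp1 <- gsp(x, seed = 5)
  perm <- c(3, 1, 4, 2)
  xp <- x[, perm]
  cp2 <- gsp(xp, seed = 5)
  expect_identical(cp2$amat[colnames(x), colnames(x)], cp1$amat)
})

test_that("UT-IGSP orients perturbed mechanisms and reports targets", {
  dag <- sigflow:::amat_from_arcs(c("X", "Y"), "X", "Y")
  ok <- 0
  for (s in 1:20) {
    xc <- sample_linear_gaussian_sem(dag, 1, 1, 500, seed = s)
    xp <- sample_linear_gaussian_sem(dag, 1, 1, 500, seed = 500 + s,
                                     shift = c(Y = 3))
    r <- ut_igsp(xc, list(p = xp), seed = s)
    tb <- tidy(r)
    if (nrow(tb) == 1 && tb$directed && tb$from == "X" &&
        "Y" %in% r$targets$p) ok <- ok + 1
  }
  # the arc orients whenever X is not falsely flagged as a target, which
  # happens at about the invariance-test level per setting
  expect_gte(ok, 17)
})

test_that("perturbing an isolated node leaves the rest of the graph alone", {
  dag <- sigflow:::amat_from_arcs(c("A", "B", "W"), "A", "B")
  agree <- 0
  for (s in 1:10) {
    xc <- sample_linear_gaussian_sem(dag, 1, 1, 600, seed = s)
    xp <- sample_linear_gaussian_sem(dag, 1, 1, 600, seed = 700 + s,
                                     shift = c(W = 3))
    r1 <- ut_igsp(xc, list(p = xp), seed = s)
    r0 <- gsp(xc, seed = s)
    if (identical(r1$amat[c("A", "B"), c("A", "B")],
                  r0$amat[c("A", "B"), c("A", "B")])) agree <- agree + 1
  }
  expect_gte(agree, 8)
})

test_that("a copy of the control yields empty estimated targets", {
  dag <- sigflow:::amat_from_arcs(c("X", "Y", "Z"), c("X", "Y"), c("Y", "Z"))
  empty <- 0
  for (s in 1:10) {
    xc <- sample_linear_gaussian_sem(dag, 1, 1, 400, seed = s)
    xp <- sample_linear_gaussian_sem(dag, 1, 1, 400, seed = 900 + s)
    r <- ut_igsp(xc, list(p = xp), seed = s)
    if (!length(r$targets$p)) empty <- empty + 1
  }
  expect_gte(empty, 7)  # up to the 5% invariance test level per node
  expect_warning(r2 <- ut_igsp(matrix(rnorm(100), 50, 2,
                                      dimnames = list(NULL, c("X", "Y"))),
                               list(), seed = 1),
                 "falling back")
  expect_s3_class(r2, "cpdag_result")
})

test_that("minimal IMAPs are acyclic independence maps", {
  set.seed(71)
  for (rep in 1:20) {
    dag <- rand_dag(5, 0.5)
    ct <- ci_tester_dsep(dag)
    perm <- sample(5)
    g <- minimal_imap_dag(NULL, perm, ct)
    expect_true(sigflow:::is_acyclic(g))
    # every absent arc was accepted as an independence given the prefix
    for (b in 2:5) for (a in 1:(b - 1)) {
      if (!g[perm[a], perm[b]]) {
        S <- setdiff(perm[seq_len(b - 1)], perm[a])
        expect_true(sigflow:::d_separated(dag, perm[a], perm[b], S))
      }
    }
  }
})
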