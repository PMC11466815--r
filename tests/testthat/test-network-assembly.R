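# Bootstrap aggregation, edge filtering, flow-model orientation, queries.

test_that("bootstrap with B = 1 or identity resampling reproduces one run", {
  dag <- sigflow:::amat_from_arcs(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  x <- sample_linear_gaussian_sem(dag, 1, 1, 400, seed = 2)
  ff <- flow_frame(x, c(A = "inflow", B = "module", C = "outflow"),
                   rep("ctrl", nrow(x)))
  learner <- learner_gsp()
  single <- learner(flow_values(ff), seed = 11)
  b1 <- bootstrap_learn(ff, learner, B = 1, resampler = identity_resampler,
                        seed = 11)
  expect_equal(b1$averaged, single$amat + 0)
  b3 <- bootstrap_learn(ff, learner, B = 3, resampler = identity_resampler,
                        seed = 11)
  expect_equal(b3$averaged, single$amat + 0)
})

test_that("bootstrap averages are reproducible and strong edges saturate", {
  dag <- sigflow:::amat_from_arcs(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  x <- sample_linear_gaussian_sem(dag, 1.5, 1, 1000, seed = 5)
  ff <- flow_frame(x, c(A = "inflow", B = "module", C = "outflow"),
                   rep("ctrl", nrow(x)))
  b <- bootstrap_learn(ff, learner_gsp(), B = 100, seed = 7)
  expect_true(all(b$averaged >= 0 & b$averaged <= 1))
  w <- b$averaged + t(b$averaged)
  expect_gte(w["A", "B"], 0.9)
  expect_gte(w["B", "C"], 0.9)
  b2 <- bootstrap_learn(ff, learner_gsp(), B = 20, seed = 7)
  b3 <- bootstrap_learn(ff, learner_gsp(), B = 20, seed = 7)
  expect_identical(b2$averaged, b3$averaged)
})

test_that("cell resampling is stratified by condition", {
  ff <- flow_frame(matrix(rnorm(14), 7, 2,
                          dimnames = list(NULL, c("A", "B"))),
                   c(A = "inflow", B = "module"),
                   c(rep("ctrl", 5), rep("stim", 2)))
  idx <- resample_cells(ff, seed = 3)
  expect_length(idx, 7)
  expect_equal(sum(idx <= 5), 5)   # per-condition counts preserved
  expect_equal(sum(idx > 5), 2)
  # frequency of each index over many draws approximates Binomial(n, 1/n)
  n <- 5
  ff1 <- flow_frame(matrix(rnorm(2 * n), n, 2,
                           dimnames = list(NULL, c("A", "B"))),
                    c(A = "inflow", B = "module"), rep("ctrl", n))
  draws <- unlist(lapply(1:4000, function(s) resample_cells(ff1, seed = s)))
  freq <- tabulate(draws, n) / (4000 * n)
  expect_true(all(abs(freq - 1 / n) < 0.01))
})

test_that("spatial block resampling keeps every index inside its block", {
  set.seed(12)
  n <- 60
  counts <- matrix(rpois(n * 3, 4), n, 3)
  ds <- expression_dataset(counts, rep("s", n),
                           coords = cbind(runif(n), runif(n)),
                           region = rep(c("a", "b", "c"), each = 20))
  for (m in c("kmeans", "annotation")) {
    for (s in 1:50) {
      idx <- resample_spatial_blocks(ds, m, n_blocks = 5, seed = s)
      blocks <- attr(idx, "blocks")
      expect_length(idx, n)
      # multiset of resampled block labels equals the original
      expect_equal(c(unname(table(blocks[idx]))), c(unname(table(blocks))))
    }
  }
  idx1 <- resample_spatial_blocks(ds, "kmeans", n_blocks = 1, seed = 1)
  expect_length(idx1, n)  # single block: ordinary bootstrap
  adx <- resample_spatial_blocks(ds, "annotation", seed = 2)
  expect_equal(length(unique(attr(adx, "blocks"))), 3)
  expect_error(resample_spatial_blocks(ds, "kmeans", n_blocks = 100),
               "exceeds")
})

test_that("low-confidence filtering applies w(i,j) = A_ij + A_ji < w*", {
  nm <- c("a", "b", "c")
  amat <- sigflow:::empty_amat(nm)
  amat["a", "b"] <- TRUE; amat["b", "c"] <- TRUE; amat["c", "b"] <- TRUE
  avg <- matrix(0, 3, 3, dimnames = list(nm, nm))
  avg["a", "b"] <- 0.2; avg["b", "a"] <- 0.05    # w = 0.25 -> removed
  avg["b", "c"] <- 0.25; avg["c", "b"] <- 0.25   # w = 0.50 -> kept
  cp <- cpdag_result(amat, averaged = avg)
  out <- filter_low_confidence(cp, 0.3)
  expect_false(out$amat["a", "b"])
  expect_true(out$amat["b", "c"] && out$amat["c", "b"])
  expect_error(filter_low_confidence(cp, 1), "0, 1")
  # fuzz: surviving edges equal the brute-force rule; monotone in w*
  set.seed(9)
  for (rep in 1:20) {
    p <- 5
    nm <- nodes_of(p)
    avg <- matrix(runif(p * p, 0, 0.5), p, p, dimnames = list(nm, nm))
    diag(avg) <- 0
    amat <- avg > 0.1 | t(avg) > 0.1
    diag(amat) <- FALSE
    cp <- cpdag_result(amat, averaged = avg)
    w1 <- filter_low_confidence(cp, 0.3)
    w2 <- filter_low_confidence(cp, 0.6)
    wsum <- avg + t(avg)
    expect_identical(w1$amat, amat & (wsum >= 0.3))
    expect_true(all(w2$amat <= w1$amat))  # raising w* never adds edges
  }
})

test_that("flow-model orientation keeps only biological arcs", {
  nm <- c("in1", "m1", "m2", "out1", "aux")
  cls <- c(in1 = "inflow", m1 = "module", m2 = "module", out1 = "outflow",
           aux = "auxiliary")
  amat <- sigflow:::empty_amat(nm)
  amat["out1", "m1"] <- TRUE                    # arc violating the model
  amat["in1", "m1"] <- TRUE; amat["m1", "in1"] <- TRUE   # undirected
  amat["m1", "m2"] <- TRUE; amat["m2", "m1"] <- TRUE     # undirected
  amat["m2", "out1"] <- TRUE                    # valid arc
  amat["aux", "m2"] <- TRUE                     # auxiliary: dropped
  net <- apply_flow_model(cpdag_result(amat), cls)
  tb <- tidy(net)
  expect_setequal(paste(tb$source, tb$target),
                  c("in1 m1", "m1 m2", "m2 m1", "m2 out1"))
  expect_error(apply_flow_model(cpdag_result(amat), cls[-5]), "unclassed")
})

test_that("flow-model output always satisfies the invariant (fuzz)", {
  set.seed(17)
  for (rep in 1:30) {
    p <- 6
    nm <- nodes_of(p)
    cls <- setNames(sample(c("inflow", "module", "outflow", "auxiliary"),
                           p, replace = TRUE), nm)
    amat <- matrix(runif(p * p) < 0.35, p, p, dimnames = list(nm, nm))
    diag(amat) <- FALSE
    net <- apply_flow_model(cpdag_result(amat), cls)
    if (nrow(net$arcs)) {
      sc <- cls[net$arcs$source]; tc <- cls[net$arcs$target]
      expect_true(all((sc == "inflow" & tc == "module") |
                        (sc == "module" & tc == "module") |
                        (sc == "module" & tc == "outflow")))
    }
    # oracle: directed arcs of valid type survive exactly
    a_dir <- amat & !t(amat)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (a_dir[i, j] &&
          ((cls[i] == "inflow" && cls[j] == "module") ||
           (cls[i] == "module" && cls[j] %in% c("module", "outflow")))) {
        expect_true(any(net$arcs$source == nm[i] & net$arcs$target == nm[j]))
      }
    }
  }
})

test_that("flow-model arc weights carry the skeleton edge support", {
  nm <- c("in1", "m1", "out1")
  amat <- sigflow:::empty_amat(nm)
  amat["in1", "m1"] <- TRUE
  amat["m1", "out1"] <- TRUE
  avg <- matrix(0, 3, 3, dimnames = list(nm, nm))
  avg["in1", "m1"] <- 0.6; avg["m1", "in1"] <- 0.3
  avg["m1", "out1"] <- 0.8
  net <- apply_flow_model(cpdag_result(amat, averaged = avg),
                          c(in1 = "inflow", m1 = "module", out1 = "outflow"))
  tb <- tidy(net)
  expect_equal(tb$weight[tb$source == "in1"], 0.9)
  expect_equal(tb$weight[tb$source == "m1"], 0.8)
})

test_that("outflow-driver extraction equals reverse reachability", {
  net <- flow_network(
    tibble::tibble(
      source = c("in1", "m1", "m2", "m2", "in2", "m3"),
      target = c("m1", "m2", "out1", "m1", "m3", "out2"),
      weight = 1),
    c(in1 = "inflow", in2 = "inflow", m1 = "module", m2 = "module",
      m3 = "module", out1 = "outflow", out2 = "outflow"))
  sub <- extract_outflow_drivers(net, "out1")
  expect_setequal(unique(c(sub$arcs$source, sub$arcs$target)),
                  c("in1", "m1", "m2", "out1"))
  # outflow with no parents -> empty arc set
  lone <- flow_network(tibble::tibble(source = "in1", target = "m1",
                                      weight = 1),
                       c(in1 = "inflow", m1 = "module", o = "outflow"))
  sub2 <- extract_outflow_drivers(lone, "o")
  expect_equal(nrow(sub2$arcs), 0)
  expect_error(extract_outflow_drivers(net, "nope"), "unknown outflow")
  # fuzz against an igraph reverse-reachability oracle
  for (s in 1:10) {
    rn <- rand_flow_network(3, 4, 2, seed = s)
    outs <- names(rn$var_class)[rn$var_class == "outflow"][1]
    sub <- extract_outflow_drivers(rn, outs)
    g <- igraph::graph_from_data_frame(rn$arcs[1:2], directed = TRUE,
      vertices = names(rn$var_class))
    gems <- rn$arcs$source[rn$arcs$target == outs &
                             rn$var_class[rn$arcs$source] == "module"]
    reach <- if (length(gems)) {
      names(unlist(igraph::ego(g, order = 100, nodes = gems,
                               mode = "in", mindist = 0)[[1]]))
      unique(unlist(lapply(gems, function(gm)
        names(igraph::subcomponent(g, gm, mode = "in")))))
    } else character(0)
    expect_setequal(setdiff(unique(c(sub$arcs$source, sub$arcs$target)),
                            outs),
                    reach)
  }
})

test_that("inflow ranking is bootstrap-weighted out-degree", {
  net <- flow_network(
    tibble::tibble(source = c("in1", "in1", "in2"),
                   target = c("m1", "m2", "m1"),
                   weight = c(0.9, 0.8, 0.4)),
    c(in1 = "inflow", in2 = "inflow", in3 = "inflow",
      m1 = "module", m2 = "module"))
  rk <- rank_inflow_drivers(net)
  expect_equal(rk$inflow, c("in1", "in2", "in3"))
  expect_equal(rk$score, c(1.7, 0.4, 0))
  rk2 <- rank_inflow_drivers(net, weighted = FALSE)
  expect_equal(rk2$score, c(2, 1, 0))
  # oracle on random networks
  for (s in 1:5) {
    rn <- rand_flow_network(seed = 100 + s)
    rk <- rank_inflow_drivers(rn)
    for (r in seq_len(nrow(rk))) {
      expect_equal(rk$score[r],
                   sum(rn$arcs$weight[rn$arcs$source == rk$inflow[r]]))
    }
    expect_true(all(diff(rk$score) <= 0))
  }
})
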