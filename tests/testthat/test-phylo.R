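test_that("pairwise distances match closed forms and flag saturation", {
  m <- matrix("A", 3, 100, dimnames = list(c("a", "b", "c"), NULL))
  d0 <- pairwise_distances(as_alignment(m), "p")
  expect_true(all(d0 == 0))
  ## p = 0.1 pair under JC69
  set.seed(701)
  x <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  y <- x
  flip <- sample(1000, 100)
  y[flip] <- vapply(x[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  m2 <- rbind(a = x, b = y, c = x)
  d <- pairwise_distances(as_alignment(m2), "JC69")
  expect_equal(d["a", "b"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(d["a", "b"], 0.10732, tolerance = 1e-4)

  ## K2P closed form: P transitions, Q transversions
  x3 <- rep(c("A", "C", "G", "T"), each = 250)
  y3 <- x3
  y3[1:80] <- "G"                      # A->G transitions
  y3[251:270] <- "A"                   # C->A transversions
  m3 <- rbind(a = x3, b = y3, c = x3)
  P <- 80 / 1000; Q <- 20 / 1000
  k2p <- 0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
  d3 <- pairwise_distances(as_alignment(m3), "K2P")
  expect_equal(d3["a", "b"], k2p, tolerance = 1e-12)

  ## saturation: p >= 3/4 errors unless capped
  msat <- rbind(a = rep("A", 200), b = rep("C", 200), c = rep("A", 200))
  expect_error(pairwise_distances(as_alignment(msat), "JC69"), "saturated")
  dcap <- pairwise_distances(as_alignment(msat), "JC69", cap = TRUE)
  expect_equal(dcap["a", "b"], 3)
})

test_that("neighbor joining solves small additive cases exactly", {
  ## 3 taxa: branch lengths from the three-point equations
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(el[["a"]], (3 + 4 - 5) / 2)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2)

  ## additive 4-taxon matrix: split {A,B}|{C,D} with internal edge 1
  dm <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(dm) <- 0; dm["A", "B"] <- dm["B", "A"] <- 2
  dm["C", "D"] <- dm["D", "C"] <- 4
  ## make it exactly additive: AB=2 (1+1), CD=4 (2+2)? use path metric of
  ## ((A:1,B:1):1,(C:1.5,D:1.5)); -> AB=2, CD=3, AC=3.5 ...
  gen <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0);")
  dm <- ape::cophenetic.phylo(gen)
  tr4 <- nj_tree(dm)
  expect_equal(rf_distance(tr4, gen)$raw, 0)
  expect_equal(sort(ape::cophenetic.phylo(tr4)[rownames(dm), colnames(dm)]),
               sort(dm), tolerance = 1e-10)

  ## distances from any simulated tree's path lengths are recovered exactly
  set.seed(702)
  for (i in 1:5) {
    gt <- ape::rtree(sample(5:8, 1))
    dmat <- ape::cophenetic.phylo(gt)
    rec <- nj_tree(dmat)
    expect_equal(rf_distance(rec, gt)$raw, 0)
    expect_equal(sort(ape::cophenetic.phylo(rec)[rownames(dmat), colnames(dmat)]),
                 sort(dmat), tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
})

test_that("pruning likelihood matches its limits and closed forms", {
  ## identical single-site sequences at branch length ~0
  a1 <- as_alignment(c(a = "A", b = "A"))
  tr0 <- ape::read.tree(text = "(a:1e-12,b:1e-12);")
  expect_equal(log_likelihood(tr0, a1), log(0.25), tolerance = 1e-6)
  ## independence limit as t -> infinity
  trInf <- ape::read.tree(text = "(a:60,b:60);")
  expect_equal(log_likelihood(trInf, as_alignment(c(a = "A", b = "C"))),
               log(0.25 * 0.25), tolerance = 1e-6)
  ## two-taxon JC closed form: 100 sites, 10 differences, t = 0.2
  aln <- as_alignment(c(a = strrep("A", 100),
                        b = paste0(strrep("A", 90), strrep("C", 10))))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  t <- 0.2
  closed <- 90 * log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))) +
    10 * log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3)))
  expect_equal(log_likelihood(tr, aln), closed, tolerance = 1e-10)

  ## brute-force state enumeration on 3- and 4-taxon trees (with missing)
  set.seed(703)
  for (nwk in c("(a:0.2,b:0.35,c:0.1);",
                "((a:0.15,b:0.3):0.2,c:0.25,d:0.1);")) {
    tr <- ape::read.tree(text = nwk)
    n <- length(tr$tip.label)
    m <- random_alignment(n, 12, amb_frac = 0.1)
    rownames(m) <- tr$tip.label
    expect_equal(log_likelihood(tr, as_alignment(m)),
                 lik_enum_jc(tr, m), tolerance = 1e-10)
  }
  expect_error(log_likelihood(tr, aln, model = list(bf = c(1, 1, 1, 1))),
               "sum to 1")
})

test_that("ML search improves the likelihood and recovers clean topologies", {
  set.seed(704)
  gen <- simulate_tree(6, seed = 704)
  gen$tip.label <- paste0(gen$tip.label, "_1")
  tpl <- data.frame(locus = "x", kind = "CDS", strand = "+", length = 2500L,
                    region = "LSC", stringsAsFactors = FALSE)
  ev <- evolve_sequences(tpl, gen, sim_params(seed = 704, tree_scale = 0.15,
                                              locus_rates = c(x = 1)))
  aln <- as_alignment(ev[["x"]]$aln)
  fit <- optimize_tree(aln)
  expect_gte(fit$log_lik, fit$start_log_lik)
  expect_equal(rf_distance(fit$tree, gen)$raw, 0)
  ## an already-optimal start is a fixed point of the topology search
  fit2 <- optimize_tree(aln, start = fit$tree)
  expect_equal(rf_distance(fit2$tree, fit$tree)$raw, 0)
  ## pruning log-likelihood of the returned model agrees with the engine
  ll <- log_likelihood(fit$tree, aln,
                       model = list(rates = fit$gtr_rates, bf = fit$bf,
                                    alpha = fit$alpha, k = 4))
  expect_equal(ll, fit$log_lik, tolerance = 1e-6)
})

test_that("bootstrap consensus annotates majority splits with support", {
  set.seed(705)
  gen <- simulate_tree(6, seed = 705)
  gen$tip.label <- paste0(gen$tip.label, "_1")
  tpl <- data.frame(locus = "x", kind = "CDS", strand = "+", length = 3000L,
                    region = "LSC", stringsAsFactors = FALSE)
  ev <- evolve_sequences(tpl, gen, sim_params(seed = 705, tree_scale = 0.2,
                                              locus_rates = c(x = 1)))
  aln <- as_alignment(ev[["x"]]$aln)
  ## B = 1: consensus is that replicate's tree, all supports 100
  b1 <- bootstrap_consensus(aln, B = 1, seed = 1)
  sup <- b1$node.label[b1$node.label != ""]
  expect_true(all(sup == "100"))
  ## strong signal: every true split supported >= 95%
  bs <- bootstrap_consensus(aln, B = 40, seed = 2)
  expect_equal(rf_distance(bs, gen)$raw, 0)
  sup <- as.numeric(bs$node.label[bs$node.label != ""])
  expect_true(all(sup >= 95))
  ## determinism given seed
  bs2 <- bootstrap_consensus(aln, B = 40, seed = 2)
  expect_identical(ape::write.tree(bs), ape::write.tree(bs2))
})

test_that("RF distance matches explicit split enumeration", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  expect_equal(rf_distance(t1, t1)$raw, 0)
  expect_equal(rf_distance(t1, t2)$raw, 2)
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  rs <- rf_distance(star, t1)
  expect_equal(rs$raw, 2)
  expect_equal(rs$normalized, 1)
  ## brute-force agreement on random binary pairs, plus pruning to common tips
  set.seed(706)
  for (i in 1:20) {
    a <- ape::rtree(6); b <- ape::rtree(6)
    expect_equal(rf_distance(a, b)$raw, rf_brute(a, b))
    expect_equal(rf_distance(a, b)$raw,
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
  }
  big <- ape::rtree(8)
  small <- ape::keep.tip(big, big$tip.label[1:5])
  expect_equal(rf_distance(big, small)$raw, 0)
  expect_equal(rf_distance(big, small)$n_shared, 5)
  expect_error(rf_distance(ape::rtree(4),
                           ape::rtree(4, tip.label = paste0("z", 1:4))),
               "shared tips")
})

test_that("generalized RF satisfies its axioms and matching optimality", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_equal(generalized_rf(t1, t1)$normalized, 0)
  set.seed(707)
  for (i in 1:15) {
    a <- ape::rtree(sample(5:8, 1)); b <- ape::rtree(length(a$tip.label))
    g1 <- generalized_rf(a, b); g2 <- generalized_rf(b, a)
    expect_equal(g1$normalized, g2$normalized, tolerance = 1e-12)
    expect_gte(g1$normalized, 0); expect_lte(g1$normalized, 1)
    ## tip-label permutation applied to both trees leaves it unchanged
    perm <- setNames(sample(a$tip.label), a$tip.label)
    ap <- a; ap$tip.label <- unname(perm[a$tip.label])
    bp <- b; bp$tip.label <- unname(perm[b$tip.label])
    expect_equal(generalized_rf(ap, bp)$normalized, g1$normalized,
                 tolerance = 1e-12)
    ## exhaustive matching enumeration agrees
    expect_equal(g1$normalized, grf_brute(a, b), tolerance = 1e-12)
  }
})

test_that("the Hungarian matcher is optimal against brute force", {
  set.seed(708)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (i in 1:25) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    W <- matrix(runif(nr * nc), nr, nc)
    got <- plastidkit:::hungarian_max(W)$score
    n <- max(nr, nc)
    Wp <- matrix(0, n, n); Wp[1:nr, 1:nc] <- W
    best <- max(vapply(perms(seq_len(n)), function(p)
      sum(Wp[cbind(seq_len(n), p)]), 0))
    expect_equal(got, best, tolerance = 1e-12)
  }
})
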