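test_that("templates are internally consistent", {
  toy <- default_template("toy")
  expect_true(all(toy$length >= 1))
  rl <- plastidkit:::template_region_lengths(toy)
  expect_equal(rl[["genome"]], rl[["LSC"]] + 2 * rl[["IR"]] + rl[["SSC"]])
  expect_gt(rl[["LSC"]], rl[["SSC"]])
  real <- plastidkit:::template_region_lengths(default_template("realistic"))
  expect_gt(real[["LSC"]], real[["SSC"]])
  expect_true(real[["genome"]] > 120000 && real[["genome"]] < 210000)
})

test_that("simulated species trees are deterministic, unit-depth pure-birth", {
  t1 <- simulate_tree(8, seed = 801)
  t2 <- simulate_tree(8, seed = 801)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(simulate_tree(3, seed = 1)$tip.label), 3L)
  dep <- ape::node.depth.edgelength(t1)[seq_len(8)]
  expect_equal(mean(dep), 1, tolerance = 1e-12)   # ultrametric, rescaled
  expect_equal(max(dep), 1, tolerance = 1e-12)
})

test_that("zero rates give identical sequences; IRs stay mirror images", {
  p0 <- sim_params(seed = 802, n_species = 3, acc_per_species = 1,
                   spacer_rate = 0, locus_rates = c(rpoB = 0),
                   tree_scale = 0, del_rate = 0, junction_shifts = list())
  ds0 <- simulate_dataset(p0)
  seqs <- vapply(ds0$records, function(r) r$sequence, "")
  expect_true(all(seqs == seqs[[1]]))

  ds <- simulate_dataset(sim_params(seed = 803, n_species = 4,
                                    acc_per_species = 1))
  for (rec in ds$records) {
    qp <- detect_quadripartite(rec)
    reg <- qp$regions
    irb <- substr(rec$sequence, reg$start[2] + 1, reg$start[2] + reg$length[2])
    ira <- substr(rec$sequence, reg$start[4] + 1, reg$start[4] + reg$length[4])
    expect_identical(ira, revcomp(irb))
  }
})

test_that("the same seed reproduces the dataset byte-for-byte", {
  a <- simulate_dataset(sim_params(seed = 804, n_species = 3,
                                   acc_per_species = 2))
  b <- simulate_dataset(sim_params(seed = 804, n_species = 3,
                                   acc_per_species = 2))
  expect_identical(vapply(a$records, `[[`, "", "sequence"),
                   vapply(b$records, `[[`, "", "sequence"))
  expect_identical(a$truth$sc_alignment, b$truth$sc_alignment)
  expect_identical(ape::write.tree(a$truth$tree),
                   ape::write.tree(b$truth$tree))
})

test_that("pairwise divergence tracks the planted rate within noise", {
  ## Jukes-Cantor conditions: equal frequencies, kappa 1, no rate spread
  tpl <- data.frame(locus = "x", kind = "CDS", strand = "+", length = 10000L,
                    region = "LSC", stringsAsFactors = FALSE)
  for (mult in c(1, 3)) {
    p <- sim_params(seed = 805 + mult, kappa = 1,
                    bf = c(A = .25, C = .25, G = .25, T = .25), alpha = Inf,
                    tree_scale = 0.01, locus_rates = c(x = mult))
    tr <- simulate_tree(6, seed = 805)
    tr$tip.label <- paste0(tr$tip.label, "_1")
    set.seed(805 + mult)
    ev <- evolve_sequences(tpl, tr, p)
    aln <- ev[["x"]]$aln
    dpath <- ape::cophenetic.phylo(tr) * 0.01 * mult
    for (pair in list(c(1, 2), c(1, 6), c(3, 5))) {
      i <- rownames(aln)[pair[1]]; j <- rownames(aln)[pair[2]]
      pobs <- mean(aln[i, ] != aln[j, ])
      pexp <- 0.75 * (1 - exp(-4 * dpath[i, j] / 3))
      sd3 <- 3 * sqrt(pexp * (1 - pexp) / 10000)
      expect_lt(abs(pobs - pexp), sd3 + 1e-6)
    }
  }
})

test_that("true alignments concatenate to the emitted single-copy genomes", {
  ds <- simulate_dataset(sim_params(seed = 806, n_species = 4,
                                    acc_per_species = 2))
  aln <- ds$truth$sc_alignment
  for (tx in rownames(aln)[c(1, 4, 7)]) {
    ungapped <- paste(aln[tx, aln[tx, ] != "-"], collapse = "")
    rl <- ds$truth$partitions[[tx]]
    prefix_len <- rl[["LSC"]] + rl[["IR"]] + rl[["SSC"]]
    expect_identical(ungapped,
                     substr(ds$records[[tx]]$sequence, 1, prefix_len))
  }
  ## deletions only ever hit intergenic loci
  if (!is.null(ds$truth$deletion_log)) {
    tpl <- ds$truth$template
    expect_true(all(ds$truth$deletion_log$locus %in%
                      tpl$locus[tpl$kind == "spacer"]))
  }
})

test_that("junction shifts propagate: partition truth and detection agree", {
  ds <- simulate_dataset(sim_params(
    seed = 807, n_species = 4, acc_per_species = 1, del_rate = 0,
    junction_shifts = list(list(species = "sp1", junction = "JLB", bp = 550L),
                           list(species = "sp3", junction = "JSB", bp = -300L))))
  base_ir <- plastidkit:::template_region_lengths(ds$truth$template)[["IR"]]
  expect_equal(ds$truth$partitions[["sp1_1"]][["IR"]], base_ir + 550)
  expect_equal(ds$truth$partitions[["sp3_1"]][["IR"]], base_ir - 300)
  for (tx in names(ds$records)) {
    qp <- detect_quadripartite(ds$records[[tx]])
    rl <- setNames(qp$regions$length, qp$regions$region)
    tr <- ds$truth$partitions[[tx]]
    expect_equal(rl[["IRb"]], tr[["IR"]], info = tx)
    expect_equal(rl[["LSC"]], tr[["LSC"]], info = tx)
    expect_equal(rl[["SSC"]], tr[["SSC"]], info = tx)
  }
  ## records still round-trip exactly through GenBank after the events
  gb <- withr::local_tempfile(fileext = ".gb")
  write_record(ds$records[["sp1_1"]], gb)
  r2 <- read_plastome(gb)
  expect_identical(r2$sequence, ds$records[["sp1_1"]]$sequence)
})

test_that("all emitted records satisfy the record invariants", {
  ds <- simulate_dataset(sim_params(seed = 808))
  for (rec in ds$records)
    expect_silent(plastidkit:::validate_plastome_record(rec))
  expect_identical(anyDuplicated(names(ds$records)), 0L)
})
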