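random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

test_that("a genome without an inverted repeat is rejected", {
  set.seed(401)
  rec <- plastome_record("norep", random_dna(50000))
  expect_error(detect_quadripartite(rec, min_ir_len = 1000),
               "NoInvertedRepeat")
  expect_error(detect_quadripartite(plastome_record("short", random_dna(1500)),
                                    min_ir_len = 1000),
               "exceed")
})

test_that("a planted LSC+IR+SSC+revcomp(IR) construction is recovered exactly", {
  set.seed(402)
  lsc <- random_dna(85000); ir <- random_dna(25000); ssc <- random_dna(18000)
  rec <- plastome_record("planted", paste0(lsc, ir, ssc, revcomp(ir)))
  qp <- detect_quadripartite(rec)
  reg <- qp$regions
  expect_equal(reg$start[reg$region == "LSC"], 0)
  expect_equal(reg$length[reg$region == "LSC"], 85000)
  expect_equal(reg$start[reg$region == "IRb"], 85000)
  expect_equal(reg$length[reg$region == "IRb"], 25000)
  expect_equal(reg$start[reg$region == "SSC"], 110000)
  expect_equal(reg$length[reg$region == "SSC"], 18000)
  expect_equal(reg$start[reg$region == "IRa"], 128000)
  expect_equal(qp$ir_identity, 1)
  expect_equal(sum(reg$length), genome_length(rec))
})

test_that("canonicalize is idempotent and invariant to rotation/orientation", {
  ds <- simulate_dataset(sim_params(seed = 403, n_species = 3,
                                    acc_per_species = 1))
  rec <- ds$records[[2]]
  cp <- canonicalize(rec)
  ## idempotence
  again <- canonicalize(cp$record, cp$partition)
  expect_identical(again$record$sequence, cp$record$sequence)
  expect_identical(again$partition$regions, cp$partition$regions)
  ## rotation invariance
  rot <- plastidkit:::rotate_record(rec, 12345L)
  cp_rot <- canonicalize(rot)
  expect_identical(cp_rot$record$sequence, cp$record$sequence)
  expect_identical(cp_rot$partition$regions, cp$partition$regions)
  ## orientation invariance
  rc <- plastidkit:::reverse_record(rec)
  cp_rc <- canonicalize(rc)
  expect_identical(cp_rc$record$sequence, cp$record$sequence)
  ## feature tables agree up to id/order
  cols <- c("name", "kind", "strand", "start", "end")
  o <- function(r) { d <- r$features[, cols]; d <- d[do.call(order, d), ]
    rownames(d) <- NULL; d }
  expect_identical(o(cp_rot$record), o(cp$record))
})

test_that("re-detection on the canonical genome is stable", {
  ds <- simulate_dataset(sim_params(seed = 404, n_species = 3,
                                    acc_per_species = 1))
  cp <- canonicalize(ds$records[[1]])
  qp2 <- detect_quadripartite(cp$record)
  expect_identical(qp2$regions, cp$partition$regions)
  ## with tolerance 0, IRa is exactly revcomp(IRb)
  reg <- qp2$regions
  irb <- substr(cp$record$sequence, reg$start[2] + 1, reg$start[2] + reg$length[2])
  ira <- substr(cp$record$sequence, reg$start[4] + 1, reg$start[4] + reg$length[4])
  expect_identical(ira, revcomp(irb))
})

test_that("junction report finds spanning and flanking genes", {
  ## constructed record: gene ends exactly at JLB; another spans JSA
  set.seed(405)
  lsc <- random_dna(4000); ir <- random_dna(1500); ssc <- random_dna(1000)
  seq <- paste0(lsc, ir, ssc, revcomp(ir))
  feats <- data.frame(
    id = 1:3,
    name = c("endsAtJLB", "spansJSA", "inLSC"),
    kind = "gene", strand = "+",
    start = c(3800L, 6480L, 100L),
    end = c(4000L, 6530L, 400L), stringsAsFactors = FALSE)
  rec <- plastome_record("jx", seq, features = feats)
  qp <- detect_quadripartite(rec, min_ir_len = 500)
  jr <- junction_report(rec, qp)
  jlb <- jr[jr$junction == "JLB", ]
  expect_true(is.na(jlb$spanning_gene))
  expect_equal(jlb$left_gene, "endsAtJLB")
  expect_equal(jlb$left_dist, 0L)
  jsa <- jr[jr$junction == "JSA", ]  # JSA at 4000+1500+1000 = 6500
  expect_equal(jsa$spanning_gene, "spansJSA")
  expect_equal(jsa$into_left_bp, 20L)
  expect_equal(jsa$into_right_bp, 30L)
  ## unannotated record refuses
  expect_error(junction_report(plastome_record("bare", seq), qp),
               "unannotated")
})

test_that("compare_junctions recovers planted IR shifts as deltas", {
  ## identical genomes: all deltas zero
  ds0 <- simulate_dataset(sim_params(seed = 406, n_species = 3,
                                     acc_per_species = 1, del_rate = 0,
                                     junction_shifts = list()))
  reps0 <- lapply(ds0$records, function(r) {
    cp <- canonicalize(r); junction_report(cp$record, cp$partition)
  })
  cmp0 <- compare_junctions(reps0)
  expect_true(all(cmp0$ir_delta == 0))

  ## one lineage with a +550 bp JLB expansion
  ds <- simulate_dataset(sim_params(
    seed = 407, n_species = 4, acc_per_species = 1, del_rate = 0,
    junction_shifts = list(list(species = "sp2", junction = "JLB",
                                bp = 550L))))
  reps <- lapply(ds$records, function(r) {
    cp <- canonicalize(r); junction_report(cp$record, cp$partition)
  })
  cmp <- compare_junctions(reps)
  d <- unique(cmp[cmp$accession == "sp2_1", "ir_delta"])
  expect_equal(d, 550)
  expect_true(all(cmp$ir_delta[cmp$accession != "sp2_1"] == 0))
})

test_that("tolerant mode finds slightly diverged inverted repeats", {
  set.seed(408)
  lsc <- random_dna(8000); ir <- random_dna(3000); ssc <- random_dna(1500)
  ira <- revcomp(ir)
  ## introduce 3 mismatches into IRa
  pos <- c(500L, 1500L, 2500L)
  for (p in pos) substr(ira, p, p) <- setdiff(c("A", "C", "G", "T"),
                                              substr(ira, p, p))[1]
  rec <- plastome_record("tol", paste0(lsc, ir, ssc, ira))
  expect_error(detect_quadripartite(rec, min_ir_len = 2500),
               "NoInvertedRepeat")
  qp <- detect_quadripartite(rec, min_ir_len = 2500,
                             max_mismatch_frac = 0.005)
  expect_equal(qp$regions$length[qp$regions$region == "IRb"], 3000)
  expect_gte(qp$ir_identity, 1 - 0.005)
})
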