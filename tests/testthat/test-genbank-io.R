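test_that("GenBank coordinates convert to 0-based half-open", {
  gb <- c(
    "LOCUS       toy                       10 bp    DNA     circular PLN 01-JAN-2024",
    "ACCESSION   toy",
    "FEATURES             Location/Qualifiers",
    "     source          1..10",
    "     gene            3..5",
    "                     /gene=\"aaa\"",
    "ORIGIN",
    "        1 acgtacgtac",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- read_plastome(path)
  expect_equal(genome_length(rec), 10L)
  f <- rec$features
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$start, f$end), c(2L, 5L))
  expect_equal(f$name, "aaa")
  expect_true(rec$circular)
})

test_that("GenBank and FASTA round trips preserve the record", {
  ds <- simulate_dataset(sim_params(seed = 301, n_species = 3,
                                    acc_per_species = 1))
  rec <- ds$records[[1]]
  gb <- withr::local_tempfile(fileext = ".gb")
  write_record(rec, gb, "genbank")
  r2 <- read_plastome(gb)
  expect_identical(r2$sequence, rec$sequence)
  expect_identical(r2$circular, rec$circular)
  expect_identical(r2$species, rec$species)
  cols <- c("name", "kind", "strand", "start", "end")
  fi1 <- plastidkit:::feature_index(rec)[, cols]
  fi2 <- plastidkit:::feature_index(r2)[, cols]
  o <- function(d) { d <- d[do.call(order, d), ]; rownames(d) <- NULL; d }
  expect_identical(o(fi1), o(fi2))

  ## second write is byte-identical (idempotent emission)
  gb2 <- withr::local_tempfile(fileext = ".gb")
  write_record(r2, gb2, "genbank")
  expect_identical(readLines(gb), readLines(gb2))

  fa <- withr::local_tempfile(fileext = ".fa")
  write_record(rec, fa, "fasta")
  r3 <- read_plastome(fa)
  expect_identical(r3$sequence, rec$sequence)
  expect_identical(nrow(r3$features), 0L)
})

test_that("an origin-spanning gene round-trips through join syntax", {
  feats <- data.frame(id = 1L, name = "wrap", kind = "gene",
                      strand = c("+", "+"), start = c(95L, 0L),
                      end = c(100L, 7L), stringsAsFactors = FALSE)
  seq <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  rec <- plastome_record("wrapper", seq, features = feats)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_record(rec, gb, "genbank")
  expect_true(any(grepl("join(96..100,1..7)", readLines(gb), fixed = TRUE)))
  r2 <- read_plastome(gb)
  expect_setequal(r2$features$start, c(95L, 0L))
  expect_setequal(r2$features$end, c(100L, 7L))
  expect_identical(plastidkit:::feature_sequence(r2, r2$features$id[1]),
                   paste0(substr(seq, 96, 100), substr(seq, 1, 7)))
})

test_that("the written GenBank is readable by an independent parser", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  ds <- simulate_dataset(sim_params(seed = 302, n_species = 3,
                                    acc_per_species = 1))
  rec <- ds$records[[1]]
  gb <- withr::local_tempfile(fileext = ".gb")
  write_record(rec, gb, "genbank")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c("from Bio import SeqIO", "import sys",
               sprintf("r = SeqIO.read('%s', 'genbank')", gb),
               "print(len(r.seq), sum(1 for x in r.features if x.type=='gene'))"),
             script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE,
                                  stderr = FALSE))
  skip_if(length(out) == 0, "biopython unavailable")
  got <- as.integer(strsplit(out[length(out)], " ")[[1]])
  fi <- plastidkit:::feature_index(rec)
  expect_equal(got[1], genome_length(rec))
  expect_equal(got[2], sum(fi$kind %in% c("gene", "pseudogene")))
})

test_that("malformed or empty input raises a parse error", {
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("DEFINITION  nothing here"), bad)
  expect_error(read_plastome(bad), "LOCUS")
  expect_error(read_plastome(tempfile()), "not found")
})

test_that("feature_counts follows the duplicated-IR and pseudogene rules", {
  seq <- paste(rep("ACGT", 300), collapse = "")
  expect_equal(unname(feature_counts(plastome_record("x", seq))),
               rep(0L, 5))
  ## 4 rRNAs duplicated in both IRs -> 8
  mk <- function(id, name, kind, start)
    data.frame(id = id, name = name, kind = kind, strand = "+",
               start = start, end = start + 10L, stringsAsFactors = FALSE)
  f <- do.call(rbind, c(
    lapply(1:4, function(i) mk(i, paste0("rrn", i), "rRNA", i * 20L)),
    lapply(1:4, function(i) mk(4L + i, paste0("rrn", i), "rRNA", 400L + i * 20L)),
    list(mk(9L, "rps16", "pseudogene", 600L))))
  rec <- plastome_record("x", seq, features = f)
  cnt <- feature_counts(rec)
  expect_equal(cnt[["rRNA"]], 8L)
  expect_equal(cnt[["genes"]], 1L)   # the pseudogene
  expect_equal(cnt[["CDS"]], 1L)
  expect_equal(cnt[["pseudogenes"]], 1L)

  ## additivity over disjoint feature lists
  rec1 <- plastome_record("x", seq, features = f[1:4, ])
  rec2 <- plastome_record("x", seq, features = f[5:9, ])
  expect_equal(feature_counts(rec), feature_counts(rec1) + feature_counts(rec2))
})

test_that("extract_locus handles strand, IR copies, spacers and dropouts", {
  ds <- simulate_dataset(sim_params(seed = 303, n_species = 4,
                                    acc_per_species = 1,
                                    drop_loci = list(sp2 = "rps16")))
  recs <- ds$records
  lm <- extract_locus(recs, "rpoB")
  expect_s3_class(lm, "locus_matrix")
  expect_length(lm$dropped, 0)
  ## minus-strand gene: stored sequence is the revcomp of the genome slice
  rec <- recs[[1]]
  fi <- plastidkit:::feature_index(rec)
  hit <- fi[fi$name == "rpoB" & fi$kind == "gene", ]
  slice <- substr(rec$sequence, hit$start + 1, hit$end)
  expect_identical(lm$rows[[rec$accession]], revcomp(slice))
  expect_identical(revcomp(lm$rows[[rec$accession]]), slice)

  ## IR-duplicated locus: first copy by default, both on request
  one <- extract_locus(recs, "rpl2")
  both <- extract_locus(recs[1], "rpl2", copies = "both")
  expect_length(both$rows, 2)
  expect_identical(one$rows[[1]], both$rows[[1]])

  ## missing locus: accession dropped with a warning
  expect_warning(lm2 <- extract_locus(recs, "rps16"), "missing in")
  expect_identical(lm2$dropped, "sp2_1")
  expect_false("sp2_1" %in% names(lm2$rows))
  expect_error(extract_locus(recs, "nosuchgene"), "locus unknown")

  ## intergenic mode: strictly between the flanking features
  ig <- extract_locus(recs[1], "trnK-trnQ", region = "intergenic")
  a <- fi[fi$name == "trnK-UUU" & fi$kind == "gene", ]
  b <- fi[fi$name == "trnQ-UUG" & fi$kind == "gene", ]
  expect_identical(ig$rows[[1]], substr(rec$sequence, a$end + 1, b$start))
})
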