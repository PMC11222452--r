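## Synthetic annotated plastomes with known ground truth: species tree,
## per-locus rate multipliers, per-site gamma rates, intergenic deletions,
## and lineage-specific IR junction-shift events. Because the two inverted
## repeats are evolved as one locus and copied (full concerted evolution),
## and junction events only restructure the IRa copy, the true multiple
## alignment of the single-copy + IRb portion is exact: root coordinates
## with deletion gaps. Every pipeline stage can therefore be tested against
## the generating truth without external data or an aligner.

#' Genome template for the simulator
#'
#' Ordered locus map (gene/tRNA/rRNA/pseudogene/spacer, strand, length)
#' covering LSC, IRb and SSC; the IRa is emitted as the reverse complement
#' of the IRb loci in reverse order. The toy scale (~26 kb) keeps tests
#' fast; the realistic scale has region lengths of whole-plastome
#' magnitude (LSC ~87 kb, IR ~26 kb, SSC ~18 kb).
#'
#' @param scale "toy" or "realistic".
#' @return data frame of class \code{genome_template} with columns locus,
#'   kind, strand, length, region.
#' @export
default_template <- function(scale = c("toy", "realistic")) {
  scale <- match.arg(scale)
  L <- function(locus, kind, strand, length)
    data.frame(locus = locus, kind = kind, strand = strand,
               length = as.integer(length), stringsAsFactors = FALSE)
  lsc <- rbind(
    L("trnH-GUG", "tRNA", "+", 74),
    L("trnH-psbA", "spacer", "+", 350),
    L("psbA", "CDS", "-", 1062),
    L("psbA-trnK", "spacer", "+", 250),
    L("trnK-UUU", "tRNA", "-", 72),
    L("trnK-trnQ", "spacer", "+", 900),
    L("trnQ-UUG", "tRNA", "-", 72),
    L("trnQ-psbI", "spacer", "+", 260),
    L("psbI", "CDS", "+", 111),
    L("psbI-atpA", "spacer", "+", 700),
    L("atpA", "CDS", "-", 1524),
    L("atpA-rpoB", "spacer", "+", 220),
    L("rpoB", "CDS", "-", 1600),
    L("rpoB-rpoC1", "spacer", "+", 110),
    L("rpoC1", "CDS", "-", 1200),
    L("rpoC1-rpoC2", "spacer", "+", 90),
    L("rpoC2", "CDS", "-", 1800),
    L("rpoC2-matK", "spacer", "+", 240),
    L("matK", "CDS", "-", 900),
    L("matK-rbcL", "spacer", "+", 280),
    L("rbcL", "CDS", "+", 900),
    L("rbcL-accD", "spacer", "+", 310),
    L("accD", "CDS", "+", 890),
    L("accD-psaI", "spacer", "+", 610),
    L("psaI", "CDS", "+", 111),
    L("psaI-clpP", "spacer", "+", 240),
    L("clpP", "CDS", "-", 600),
    L("clpP-rps16", "spacer", "+", 200),
    L("rps16", "pseudogene", "-", 180),
    L("rps16-rpl22", "spacer", "+", 150),
    L("rpl22", "CDS", "-", 400),
    L("rpl22-rps19", "spacer", "+", 120),
    L("rps19", "CDS", "-", 279))
  irb <- rbind(
    L("rpl2", "CDS", "-", 820),
    L("rpl2-ycf2", "spacer", "+", 150),
    L("ycf2", "CDS", "+", 1200),
    L("ycf2-rrn16", "spacer", "+", 120),
    L("rrn16", "rRNA", "+", 700),
    L("rrn16-rrn23", "spacer", "+", 80),
    L("rrn23", "rRNA", "+", 900),
    L("rrn23-ndhF", "spacer", "+", 60))
  ssc <- rbind(
    L("ndhF", "CDS", "-", 900),
    L("ndhF-trnL-UAG", "spacer", "+", 420),
    L("trnL-UAG", "tRNA", "+", 80),
    L("trnL-ccsA", "spacer", "+", 120),
    L("ccsA", "CDS", "+", 500),
    L("ccsA-ndhD", "spacer", "+", 100),
    L("ndhD", "CDS", "-", 520),
    L("ndhD-ycf1", "spacer", "+", 90),
    L("ycf1", "CDS", "+", 1100),
    L("ycf1-rrn23", "spacer", "+", 60))
  lsc$region <- "LSC"; irb$region <- "IRb"; ssc$region <- "SSC"
  tpl <- rbind(lsc, irb, ssc)
  if (scale == "realistic") {
    gene_scale <- c(LSC = 6, IRb = 6, SSC = 4.5)
    spacer_scale <- c(LSC = 5.5, IRb = 10, SSC = 5)
    sc <- ifelse(tpl$kind == "spacer", spacer_scale[tpl$region],
                 gene_scale[tpl$region])
    tpl$length <- as.integer(round(tpl$length * sc))
  }
  class(tpl) <- c("genome_template", "data.frame")
  tpl
}

template_region_lengths <- function(template) {
  l <- tapply(template$length, template$region, sum)
  c(LSC = unname(l["LSC"]), IR = unname(l["IRb"]), SSC = unname(l["SSC"]),
    genome = unname(l["LSC"] + 2 * l["IRb"] + l["SSC"]))
}

#' Simulation parameters
#'
#' Defaults define the package's reference scenario: 6 species x 2
#' accessions on a pure-birth species tree, a toy-scale genome, HKY+Gamma
#' substitutions with AT-rich base frequencies, intergenic spacers evolving
#' 3x faster than coding loci, rpoB planted at 5x, intergenic deletions,
#' and lineage-specific IR junction shifts. Intraspecific divergence is a
#' small fraction (\code{delta}) of tree depth, so within-species variation
#' is far below between-species variation.
#'
#' @param n_species number of species (tips of the species tree).
#' @param acc_per_species accessions sampled per species.
#' @param scale template scale, "toy" or "realistic".
#' @param birth_rate pure-birth rate of the species tree.
#' @param delta depth of the within-species star (fraction of tree depth).
#' @param tree_scale expected substitutions per site root-to-tip at rate
#'   multiplier 1 (calibrates overall divergence).
#' @param kappa HKY transition/transversion rate ratio.
#' @param bf base frequencies (A, C, G, T).
#' @param alpha gamma shape for among-site rate variation (4 categories).
#' @param spacer_rate rate multiplier of intergenic spacers (and
#'   pseudogenes).
#' @param locus_rates named vector of per-locus multiplier overrides.
#' @param del_rate intergenic deletion events per bp per unit tree depth.
#' @param del_mean_len mean deletion length (geometric, bp).
#' @param junction_shifts list of lists (species, junction in
#'   {JLB, JSB}, bp; positive = IR expansion) applied to all accessions of
#'   the species; NULL uses the scenario defaults.
#' @param conflict_loci loci evolved on a shuffled (conflicting) topology.
#' @param drop_loci named list: species -> loci left unannotated in those
#'   records (emulating loci missing from some accessions).
#' @param seed RNG seed; same seed, byte-identical output.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_species = 6L, acc_per_species = 2L,
                       scale = "toy", birth_rate = 1, delta = 0.03,
                       tree_scale = 0.008, kappa = 2,
                       bf = c(A = 0.325, C = 0.175, G = 0.175, T = 0.325),
                       alpha = 1, spacer_rate = 3,
                       locus_rates = c(rpoB = 5),
                       del_rate = 0.0015, del_mean_len = 3,
                       junction_shifts = NULL,
                       conflict_loci = character(0),
                       drop_loci = NULL, seed = 1L) {
  if (is.null(junction_shifts)) {
    defaults <- list(list(species = "sp3", junction = "JLB", bp = -250L),
                     list(species = "sp5", junction = "JLB", bp = 300L),
                     list(species = "sp2", junction = "JSB", bp = -180L),
                     list(species = "sp6", junction = "JSB", bp = 220L))
    junction_shifts <- Filter(function(s)
      as.integer(sub("^sp", "", s$species)) <= n_species, defaults)
  }
  p <- list(n_species = as.integer(n_species),
            acc_per_species = as.integer(acc_per_species), scale = scale,
            birth_rate = birth_rate, delta = delta, tree_scale = tree_scale,
            kappa = kappa, bf = bf / sum(bf), alpha = alpha,
            spacer_rate = spacer_rate, locus_rates = locus_rates,
            del_rate = del_rate, del_mean_len = del_mean_len,
            junction_shifts = junction_shifts,
            conflict_loci = conflict_loci, drop_loci = drop_loci,
            seed = seed)
  stopifnot(p$n_species >= 3, p$acc_per_species >= 1,
            all(vapply(p$locus_rates, function(x) x >= 0, TRUE)))
  class(p) <- "sim_params"
  p
}

#' Simulate a pure-birth species tree rescaled to unit depth
#'
#' Trees are conditioned on a minimum edge length (as a fraction of
#' depth): a pure-birth draw routinely contains near-zero edges - short
#' internal edges that no locus (nor a whole-genome tree) can resolve,
#' and near-simultaneous speciations that blur the interspecific /
#' intraspecific divergence contrast the scenarios rely on. Rejection
#' sampling keeps the draw with every edge at least \code{min_edge}.
#'
#' @param n_taxa number of tips (>= 3); labels sp1..spN.
#' @param birth_rate birth rate.
#' @param seed optional seed (omit to use the current RNG stream).
#' @param min_edge minimum edge length, fraction of unit depth.
#' @return ultrametric \code{phylo} with root-to-tip depth 1.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL,
                          min_edge = 0.05) {
  stopifnot(n_taxa >= 3)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL; best_min <- -Inf
  for (try in seq_len(500L)) {
    tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
    dep <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / dep
    m <- min(tr$edge.length)
    if (m > best_min) { best <- tr; best_min <- m }
    if (m >= min_edge) break
  }
  tr <- best
  tr$tip.label <- paste0("sp", seq_len(n_taxa))
  tr
}

## graft a star of accessions (depth delta) onto each species tip
accession_tree <- function(species_tree, acc_per_species, delta) {
  if (acc_per_species == 1L) {
    tr <- species_tree
    tr$tip.label <- paste0(tr$tip.label, "_1")
    return(tr)
  }
  nt <- length(species_tree$tip.label)
  tip_edge <- match(seq_len(nt), species_tree$edge[, 2])
  nwk <- ape::write.tree(species_tree)
  for (i in seq_len(nt)) {
    lab <- species_tree$tip.label[i]
    len <- species_tree$edge.length[tip_edge[i]]
    d <- min(delta, len / 2)
    accs <- paste0(lab, "_", seq_len(acc_per_species))
    repl <- paste0("\\1(", paste0(accs, ":", format(d, digits = 12),
                                  collapse = ","), "):",
                   format(len - d, digits = 12))
    nwk <- sub(paste0("([(,])", lab, ":[0-9.eE+-]+"), repl, nwk)
  }
  ape::read.tree(text = nwk)
}

## HKY exchangeabilities in phangorn order (AC, AG, AT, CG, CT, GT)
hky_rates <- function(kappa) c(1, kappa, 1, 1, kappa, 1)

#' Evolve per-locus sequences along a tree
#'
#' Each locus gets per-site discrete-gamma rates times its multiplier;
#' substitutions are simulated under HKY along the (unit-depth) tree, with
#' the root drawn from the stationary frequencies. Loci listed in
#' \code{params$conflict_loci} evolve on a tip-shuffled copy of the tree.
#' IR loci are evolved once (the IRa copy is added at assembly).
#'
#' @param template a \code{genome_template}.
#' @param tree accession \code{phylo}, unit depth.
#' @param params a \code{sim_params}.
#' @return named list per locus: list(aln = taxa x sites character matrix,
#'   rates = true per-site rates, multiplier).
#' @export
evolve_sequences <- function(template, tree, params) {
  k <- 4L
  crates <- gamma_category_rates(params$alpha, k)
  conflict_tree <- NULL
  if (length(params$conflict_loci)) {
    conflict_tree <- tree
    conflict_tree$tip.label <- sample(tree$tip.label)
  }
  out <- vector("list", nrow(template))
  names(out) <- template$locus
  for (i in seq_len(nrow(template))) {
    locus <- template$locus[i]
    len <- template$length[i]
    mult <- locus_multiplier(locus, template$kind[i], params)
    cat_of_site <- sample.int(k, len, replace = TRUE)
    tr <- if (locus %in% params$conflict_loci) conflict_tree else tree
    aln <- matrix("", length(tr$tip.label), len,
                  dimnames = list(tr$tip.label, NULL))
    for (ci in seq_len(k)) {
      sites <- which(cat_of_site == ci)
      if (!length(sites)) next
      ## rate 0 (e.g. all multipliers 0) still needs a draw from the
      ## stationary root distribution; clamp keeps simSeq well-defined
      sim <- phangorn::simSeq(tr, l = length(sites), Q = hky_rates(params$kappa),
                              bf = params$bf,
                              rate = max(params$tree_scale * mult * crates[ci],
                                         1e-12))
      aln[, sites] <- toupper(as.character(sim))[rownames(aln), , drop = FALSE]
    }
    out[[i]] <- list(aln = aln, rates = mult * crates[cat_of_site],
                     multiplier = mult)
  }
  out
}

locus_multiplier <- function(locus, kind, params) {
  if (locus %in% names(params$locus_rates))
    return(unname(params$locus_rates[locus]))
  if (kind %in% c("spacer", "pseudogene")) params$spacer_rate else 1
}

## draw deletion masks (TRUE = deleted) per taxon for intergenic loci,
## inherited along branches
deletion_masks <- function(template, tree, params) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  spacers <- which(template$kind == "spacer")
  masks <- lapply(seq_len(nnode), function(i)
    lapply(template$length[spacers], function(l) logical(l)))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  ord <- rev(seq_len(nrow(tree$edge)))  # preorder traversal of edges
  log <- list()
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    el <- tree$edge.length[e]
    masks[[ch]] <- masks[[p]]
    for (si in seq_along(spacers)) {
      len <- template$length[spacers[si]]
      nev <- stats::rpois(1, params$del_rate * len * el)
      if (!nev) next
      for (v in seq_len(nev)) {
        dl <- 1L + stats::rgeom(1, 1 / params$del_mean_len)
        st <- sample.int(len, 1)
        idx <- st:min(len, st + dl - 1L)
        masks[[ch]][[si]][idx] <- TRUE
        log[[length(log) + 1L]] <- data.frame(
          node = ch, locus = template$locus[spacers[si]],
          start = st, len = length(idx))
      }
    }
  }
  tips <- stats::setNames(masks[seq_len(ntip)], tree$tip.label)
  list(tip_masks = tips, spacers = spacers,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Assemble annotated circular plastomes from evolved loci
#'
#' Concatenates loci into LSC + IRb + SSC + IRa (the IRa being the reverse
#' complement of the IRb loci in reverse order), emits feature
#' annotations, applies per-lineage junction-shift events, and returns the
#' records together with the ground-truth object.
#'
#' @param evolved output of \code{\link{evolve_sequences}} with deletion
#'   gaps already applied ("-" characters).
#' @param template the \code{genome_template} used.
#' @param params a \code{sim_params}.
#' @return list(records, truth); \code{truth} holds true partitions per
#'   accession, per-locus alignments, the single-copy+IRb alignment, the
#'   event log and per-locus true rates.
#' @export
assemble_plastomes <- function(evolved, template, params) {
  taxa <- rownames(evolved[[1]]$aln)
  species_of <- sub("_[0-9]+$", "", taxa)
  shifts <- params$junction_shifts
  records <- list()
  partitions <- list()
  shift_log <- list()
  for (tx in taxa) {
    sp <- sub("_[0-9]+$", "", tx)
    drop <- params$drop_loci[[sp]] %||% character(0)
    asm <- assemble_one(tx, evolved, template, drop)
    genome <- asm$genome; feats <- asm$features; rl <- asm$region_lengths
    for (sh in shifts) {
      if (!identical(sh$species, sp)) next
      res <- apply_junction_shift(genome, feats, rl, sh$junction, sh$bp)
      genome <- res$genome; feats <- res$features; rl <- res$region_lengths
      shift_log[[length(shift_log) + 1L]] <-
        data.frame(accession = tx, junction = sh$junction, bp = sh$bp)
    }
    rec <- plastome_record(tx, genome, species = sp, circular = TRUE,
                           features = feats)
    records[[tx]] <- rec
    partitions[[tx]] <- c(rl, genome = nchar(genome))
  }
  truth <- list(partitions = partitions,
                shift_log = if (length(shift_log)) do.call(rbind, shift_log) else NULL)
  list(records = records, truth = truth)
}

## concatenate loci for one taxon; returns genome, features (0-based
## half-open), baseline region lengths
assemble_one <- function(tx, evolved, template, drop_loci = character(0)) {
  region_seq <- c(LSC = "", IRb = "", SSC = "")
  feats <- list(); fid <- 0L
  offsets <- c(LSC = 0L)  # filled as we go; absolute coords assigned later
  pieces <- list()
  pos_in_region <- c(LSC = 0L, IRb = 0L, SSC = 0L)
  for (i in seq_len(nrow(template))) {
    reg <- template$region[i]
    row <- evolved[[template$locus[i]]]$aln[tx, ]
    s <- paste(row[row != "-"], collapse = "")
    pieces[[length(pieces) + 1L]] <- list(
      locus = template$locus[i], kind = template$kind[i],
      strand = template$strand[i], region = reg,
      rel_start = pos_in_region[[reg]], len = nchar(s), seq = s)
    pos_in_region[[reg]] <- pos_in_region[[reg]] + nchar(s)
    region_seq[[reg]] <- paste0(region_seq[[reg]], s)
  }
  rl <- c(LSC = nchar(region_seq[["LSC"]]), IR = nchar(region_seq[["IRb"]]),
          SSC = nchar(region_seq[["SSC"]]))
  off <- c(LSC = 0L, IRb = rl[["LSC"]], SSC = rl[["LSC"]] + rl[["IR"]])
  ira_off <- rl[["LSC"]] + rl[["IR"]] + rl[["SSC"]]
  for (p in pieces) {
    if (p$kind == "spacer" || p$locus %in% drop_loci || p$len == 0L) next
    ## GenBank convention: every CDS/tRNA/rRNA has a parallel gene feature
    kinds <- if (p$kind == "pseudogene") "pseudogene" else c("gene", p$kind)
    st <- off[[p$region]] + p$rel_start
    for (kk in kinds) {
      fid <- fid + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        id = fid, name = p$locus, kind = kk, strand = p$strand,
        start = st, end = st + p$len, stringsAsFactors = FALSE)
    }
    if (p$region == "IRb") {  # mirrored IRa copy
      ira_st <- ira_off + (rl[["IR"]] - (p$rel_start + p$len))
      for (kk in kinds) {
        fid <- fid + 1L
        feats[[length(feats) + 1L]] <- data.frame(
          id = fid, name = p$locus, kind = kk,
          strand = if (p$strand == "+") "-" else "+",
          start = ira_st, end = ira_st + p$len, stringsAsFactors = FALSE)
      }
    }
  }
  genome <- paste0(region_seq[["LSC"]], region_seq[["IRb"]],
                   region_seq[["SSC"]], revcomp(region_seq[["IRb"]]))
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  list(genome = genome, features = features, region_lengths = rl)
}

## apply one IR boundary move at JLB (LSC/IRb) or JSB (IRb/SSC);
## bp > 0 = IR expansion into the single-copy region. Because both IR
## copies must stay identical, the mirrored change happens in IRa, which
## is where sequence is inserted or removed.
apply_junction_shift <- function(genome, features, rl, junction, bp) {
  stopifnot(junction %in% c("JLB", "JSB"))
  n <- nchar(genome)
  L1 <- rl[["LSC"]]; L2 <- L1 + rl[["IR"]]; L3 <- L2 + rl[["SSC"]]
  N <- abs(as.integer(bp))
  if (N == 0) return(list(genome = genome, features = features,
                          region_lengths = rl))
  shift_feats <- function(f, from, by) {
    sel <- f$start >= from
    f$start[sel] <- f$start[sel] + by
    f$end[f$end > from] <- f$end[f$end > from] + by
    f
  }
  delete_span <- function(f, from, to) {
    len <- to - from
    keep <- !(f$start >= from & f$end <= to)
    f <- f[keep, , drop = FALSE]
    f$end[f$end > from & f$end <= to] <- from
    f$start[f$start >= from & f$start < to] <- to
    sel_s <- f$start >= to; f$start[sel_s] <- f$start[sel_s] - len
    sel_e <- f$end > from; f$end[sel_e] <- f$end[sel_e] - len
    f[f$end > f$start, , drop = FALSE]
  }
  if (junction == "JLB" && bp > 0) {
    if (N >= rl[["LSC"]]) stop("shift exceeds LSC length")
    chunk <- substr(genome, L1 - N + 1L, L1)
    genome <- paste0(genome, revcomp(chunk))
    rl[["LSC"]] <- rl[["LSC"]] - N; rl[["IR"]] <- rl[["IR"]] + N
  } else if (junction == "JLB" && bp < 0) {
    if (N >= rl[["IR"]]) stop("shift exceeds IR length")
    genome <- substr(genome, 1L, n - N)
    features <- features[features$start < n - N, , drop = FALSE]
    features$end <- pmin(features$end, n - N)
    rl[["LSC"]] <- rl[["LSC"]] + N; rl[["IR"]] <- rl[["IR"]] - N
  } else if (junction == "JSB" && bp > 0) {
    if (N >= rl[["SSC"]]) stop("shift exceeds SSC length")
    chunk <- substr(genome, L2 + 1L, L2 + N)
    genome <- paste0(substr(genome, 1L, L3), revcomp(chunk),
                     substr(genome, L3 + 1L, n))
    features <- shift_feats(features, L3, N)
    rl[["SSC"]] <- rl[["SSC"]] - N; rl[["IR"]] <- rl[["IR"]] + N
  } else {  # JSB contraction: IRb tail becomes SSC; IRa loses its head
    if (N >= rl[["IR"]]) stop("shift exceeds IR length")
    features <- delete_span(features, L3, L3 + N)
    genome <- paste0(substr(genome, 1L, L3), substr(genome, L3 + N + 1L, n))
    rl[["SSC"]] <- rl[["SSC"]] + N; rl[["IR"]] <- rl[["IR"]] - N
  }
  list(genome = genome, features = features, region_lengths = rl)
}

## boundary bases (1-based positions) to change so the IR pair cannot
## extend outward (LSC end vs LSC start) or inward (SSC start vs SSC end)
fix_ir_boundaries <- function(genome, rl) {
  comp <- function(b) chartr("ACGT", "TGCA", b)
  bases <- c("A", "C", "G", "T")
  out <- list()
  pa <- rl[["LSC"]]                       # last LSC base, 1-based
  s0 <- substr(genome, 1L, 1L)
  if (substr(genome, pa, pa) == comp(s0))
    out[[length(out) + 1L]] <- list(pos1 = pa,
                                    base = setdiff(bases, comp(s0))[1])
  pb1 <- rl[["LSC"]] + rl[["IR"]] + 1L    # first SSC base
  pb2 <- rl[["LSC"]] + rl[["IR"]] + rl[["SSC"]]  # last SSC base
  b2 <- substr(genome, pb2, pb2)
  if (substr(genome, pb1, pb1) == comp(b2))
    out[[length(out) + 1L]] <- list(pos1 = pb1,
                                    base = setdiff(bases, comp(b2))[1])
  out
}

## map a 0-based position in the (unchanged) LSC+IRb+SSC genome prefix to
## its locus and alignment column for one taxon (skipping deleted bases)
genome_pos_to_locus <- function(pos0, tx, evolved, template) {
  cum <- 0L
  for (i in seq_len(nrow(template))) {
    locus <- template$locus[i]
    row <- evolved[[locus]]$aln[tx, ]
    nb <- sum(row != "-")
    if (pos0 < cum + nb) {
      col <- which(row != "-")[pos0 - cum + 1L]
      return(list(locus = locus, col = col))
    }
    cum <- cum + nb
  }
  stop("position beyond single-copy prefix")
}

#' Simulate a complete annotated dataset with ground truth
#'
#' One call producing the full fixture set: accession-level records with
#' annotations, the true trees, per-locus true rates and exact alignments
#' (root coordinates; "-" marks deleted bases), true quadripartite
#' partitions per accession, and the event log. With more than one
#' accession per species, within-species branch lengths are a small
#' fraction of tree depth, so intraspecific divergence is far below
#' interspecific divergence.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return list(records, truth) of class \code{sim_dataset}.
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  template <- default_template(params$scale)
  sp_tree <- simulate_tree(params$n_species, params$birth_rate)
  acc_tree <- accession_tree(sp_tree, params$acc_per_species, params$delta)
  evolved <- evolve_sequences(template, acc_tree, params)
  dm <- deletion_masks(template, acc_tree, params)
  ## stamp deletions into the alignments as gaps
  for (si in seq_along(dm$spacers)) {
    locus <- template$locus[dm$spacers[si]]
    for (tx in names(dm$tip_masks)) {
      mask <- dm$tip_masks[[tx]][[si]]
      if (any(mask)) evolved[[locus]]$aln[tx, mask] <- "-"
    }
  }
  asm <- assemble_plastomes(evolved, template, params)
  ## guarantee the constructed IR pair is the *maximal* reverse repeat:
  ## if the single-copy base flanking a boundary happens to complement its
  ## partner, the repeat would extend past the construction by chance;
  ## break such complementarity (one base per boundary, mirrored into the
  ## truth alignments)
  for (tx in names(asm$records)) {
    fx <- fix_ir_boundaries(asm$records[[tx]]$sequence,
                            asm$truth$partitions[[tx]])
    if (length(fx)) {
      g <- asm$records[[tx]]$sequence
      for (f in fx) {
        substr(g, f$pos1, f$pos1) <- f$base
        lc <- genome_pos_to_locus(f$pos1 - 1L, tx, evolved, template)
        evolved[[lc$locus]]$aln[tx, lc$col] <- f$base
      }
      asm$records[[tx]]$sequence <- g
    }
  }
  sc_aln <- do.call(cbind, lapply(template$locus,
                                  function(l) evolved[[l]]$aln))
  locus_cols <- split(seq_len(ncol(sc_aln)),
                      rep(seq_len(nrow(template)), template$length))
  names(locus_cols) <- template$locus
  alignments <- lapply(evolved, function(e) e$aln)
  truth <- list(
    species_tree = sp_tree, tree = acc_tree,
    multipliers = vapply(evolved, function(e) e$multiplier, 0),
    site_rates = lapply(evolved, function(e) e$rates),
    alignments = alignments,
    sc_alignment = as_alignment(sc_aln),
    locus_cols = locus_cols,
    template = template,
    partitions = asm$truth$partitions,
    shift_log = asm$truth$shift_log,
    deletion_log = dm$log,
    params = params)
  structure(list(records = asm$records, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated plastome dataset:", length(x$records), "accessions,",
      length(x$truth$alignments), "loci, genome ~",
      genome_length(x$records[[1]]), "bp\n")
  invisible(x)
}
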