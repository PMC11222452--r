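## End-to-end marker selection: candidate loci from diversity hotspots and
## phylogenetic informativeness, per-locus trees, generalized
## Robinson-Foulds congruence with the whole-plastome reference tree, and
## a combination search over the top-ranked loci.

#' Pipeline configuration
#'
#' @param window,step sliding-window size/step (bp) for the diversity
#'   profile.
#' @param k_pi number of top-diversity hotspot regions (default 5).
#' @param k_PI number of top phylogenetic-informativeness loci (default 10).
#' @param top_m combination search breadth: all non-empty subsets of the
#'   top_m most congruent single loci are evaluated (default 3).
#' @param tree_method "ml" (GTR+Gamma with NNI search) or "nj" for
#'   per-locus and reference tree inference.
#' @param locus_tree "best" scores the best tree per locus set;
#'   "consensus" scores its bootstrap majority-rule consensus.
#' @param boot_method replicate inference for bootstrap supports.
#' @param B bootstrap replicates for reference-tree support (0 = skip).
#' @param threshold majority-rule consensus threshold.
#' @param rate_method site-rate estimator ("fitch_norm" or "ml_jc").
#' @param deletion gap policy for the diversity profile.
#' @param aligner external aligner command for unaligned input ("mafft");
#'   only invoked when sequences are not already aligned.
#' @param seed RNG seed used for every stochastic step.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(window = 600L, step = 200L, k_pi = 5L,
                            k_PI = 10L, top_m = 3L,
                            tree_method = c("ml", "nj"),
                            locus_tree = c("best", "consensus"),
                            boot_method = c("nj", "ml"), B = 100L,
                            threshold = 0.5,
                            rate_method = c("fitch_norm", "ml_jc"),
                            deletion = c("complete", "pairwise"),
                            aligner = "mafft", seed = 1L) {
  cfg <- list(window = as.integer(window), step = as.integer(step),
              k_pi = as.integer(k_pi), k_PI = as.integer(k_PI),
              top_m = as.integer(top_m),
              tree_method = match.arg(tree_method),
              locus_tree = match.arg(locus_tree),
              boot_method = match.arg(boot_method), B = as.integer(B),
              threshold = threshold, rate_method = match.arg(rate_method),
              deletion = match.arg(deletion), aligner = aligner,
              seed = seed)
  if (cfg$k_pi < 1L || cfg$k_PI < 1L || cfg$top_m < 1L)
    stop("k_pi, k_PI and top_m must all be >= 1")
  if (cfg$window < 2L || cfg$step < 1L) stop("invalid window/step")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Merge diversity-hotspot and informativeness candidates
#'
#' Union of the two candidate lists; loci present in both are tagged
#' "both". Order is by best rank across the two sources.
#'
#' @param top_pi_regions character vector of hotspot region names, ranked.
#' @param top_PI_loci character vector of informative loci, ranked.
#' @return data frame: locus, provenance ("pi", "PI" or "both"), rank.
#' @export
select_candidate_loci <- function(top_pi_regions, top_PI_loci) {
  stopifnot(length(top_pi_regions) >= 1, length(top_PI_loci) >= 1)
  all_loci <- union(top_pi_regions, top_PI_loci)
  r1 <- match(all_loci, top_pi_regions)
  r2 <- match(all_loci, top_PI_loci)
  prov <- ifelse(!is.na(r1) & !is.na(r2), "both",
                 ifelse(!is.na(r1), "pi", "PI"))
  best <- pmin(r1, r2, na.rm = TRUE)
  out <- data.frame(locus = all_loci, provenance = prov, rank = best,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$locus), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## alignment for one locus: from a supplied truth/provider list, or by
## extraction + external alignment
locus_alignment <- function(records, locus, config, alignments = NULL) {
  if (!is.null(alignments) && locus %in% names(alignments))
    return(as_alignment(alignments[[locus]]))
  ref <- records[[1]]
  fi <- feature_index(ref)
  mode <- if (any(locus_name_matches(fi$name, locus))) "feature" else "intergenic"
  lm <- suppressWarnings(extract_locus(records, locus, region = mode))
  align_provider(lm$rows, config$aligner)
}

align_provider <- function(seqs, aligner = "mafft") {
  if (length(unique(nchar(seqs))) == 1L) return(as_alignment(seqs))
  if (!nzchar(Sys.which(aligner)))
    stop("sequences are unaligned and aligner '", aligner,
         "' is not available")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(">", names(seqs), "\n", seqs), fin)
  system2(aligner, c("--auto", "--quiet", fin), stdout = fout)
  read_alignment(fout)
}

#' Evaluate one locus set against the reference tree
#'
#' Extracts (or receives) the per-locus alignments, keeps the accessions
#' that have every locus in the set (others are excluded and listed),
#' concatenates, infers a tree per the configuration, and scores the
#' generalized Robinson-Foulds distance to the reference tree on the
#' common tip set.
#'
#' @param records list of \code{plastome_record}.
#' @param loci character vector of locus names (1..top_m).
#' @param reference_tree reference \code{phylo}.
#' @param config a \code{pipeline_config}.
#' @param alignments optional named list of precomputed per-locus
#'   alignments (taxa x sites matrices).
#' @return object of class \code{marker_eval}.
#' @export
evaluate_locus_set <- function(records, loci, reference_tree, config,
                               alignments = NULL) {
  alns <- lapply(loci, function(l)
    locus_alignment(records, l, config, alignments))
  keep <- Reduce(intersect, lapply(alns, rownames))
  all_acc <- vapply(records, function(r) r$accession, "")
  excluded <- setdiff(all_acc, keep)
  if (length(keep) < 4L)
    stop("insufficient taxa: only ", length(keep),
         " accessions carry {", paste(loci, collapse = ", "), "}")
  cat_aln <- as_alignment(do.call(cbind, lapply(alns, function(a)
    a[keep, , drop = FALSE])))
  tree <- infer_tree(cat_aln, config)
  dist <- generalized_rf(tree, reference_tree)
  structure(list(loci = sort(loci), accessions = keep, excluded = excluded,
                 n_sites = ncol(cat_aln), tree = tree, distance = dist),
            class = "marker_eval")
}

infer_tree <- function(aln, config) {
  if (config$locus_tree == "consensus")
    return(bootstrap_consensus(aln, B = max(config$B, 1L),
                               threshold = config$threshold,
                               method = config$boot_method))
  if (config$tree_method == "nj") {
    d <- tryCatch(pairwise_distances(aln, "JC69"),
                  error = function(e) pairwise_distances(aln, "p"))
    nj_tree(d)
  } else {
    optimize_tree(aln)$tree
  }
}

#' @export
print.marker_eval <- function(x, ...) {
  cat(sprintf("Marker set {%s}: %d accessions, %d sites, gen-RF = %.4g\n",
              paste(x$loci, collapse = ", "), length(x$accessions),
              x$n_sites, x$distance$normalized))
  invisible(x)
}

#' Evaluate all non-empty subsets of the top loci
#'
#' @param records list of \code{plastome_record}.
#' @param top_m_loci character vector of loci to combine.
#' @param reference_tree reference \code{phylo}.
#' @param config a \code{pipeline_config}.
#' @param alignments optional precomputed per-locus alignments.
#' @return list of \code{marker_eval}, sorted by ascending distance (ties:
#'   fewer loci, then alphabetically).
#' @export
search_combinations <- function(records, top_m_loci, reference_tree, config,
                                alignments = NULL) {
  stopifnot(length(top_m_loci) >= 1)
  m <- length(top_m_loci)
  subsets <- unlist(lapply(seq_len(m), function(sz)
    utils::combn(top_m_loci, sz, simplify = FALSE)), recursive = FALSE)
  evals <- lapply(subsets, function(ss)
    evaluate_locus_set(records, ss, reference_tree, config, alignments))
  ord <- order(vapply(evals, function(e) e$distance$normalized, 0),
               lengths(lapply(evals, `[[`, "loci")),
               vapply(evals, function(e) paste(e$loci, collapse = "+"), ""))
  evals[ord]
}

#' Run the full marker-selection pipeline
#'
#' Whole-plastome alignment to reference ML tree (with bootstrap supports),
#' interspecific sliding-window diversity to top-k_pi hotspot regions,
#' per-CDS site rates and net phylogenetic informativeness to top-k_PI
#' loci, union of candidates, per-candidate congruence evaluation, and a
#' combination search over the top_m most congruent single loci. Fully
#' reproducible given the seed in the configuration.
#'
#' @param records list of annotated \code{plastome_record} (>= 5, spanning
#'   >= 2 species).
#' @param config a \code{pipeline_config}.
#' @param alignments optional named list of per-locus alignments (e.g. the
#'   simulator's exact truth); missing loci are extracted and aligned via
#'   the configured aligner.
#' @param reference_alignment optional whole-plastome alignment; built via
#'   the aligner when absent.
#' @param reference_record annotated record anchoring window naming;
#'   default: the record of the reference alignment's reference row.
#' @return object of class \code{marker_report}.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         alignments = NULL, reference_alignment = NULL,
                         reference_record = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(records) < 5L) stop("need >= 5 accessions")
  species <- vapply(records, function(r) r$species, "")
  if (length(unique(species)) < 2L) stop("need >= 2 species")
  if (!is.null(config$seed)) set.seed(config$seed)
  stage <- "reference alignment"
  out <- tryCatch({
    ref_aln <- reference_alignment %||%
      align_provider(vapply(records, function(r) r$sequence, ""),
                     config$aligner)
    ref_aln <- as_alignment(ref_aln)
    ref_acc <- attr(ref_aln, "reference")
    reference_record <- reference_record %||%
      records[[which(vapply(records, function(r) r$accession, "") == ref_acc)[1]]]

    stage <- "reference tree"
    ref_fit <- if (config$tree_method == "nj")
      list(tree = infer_tree(ref_aln, config)) else optimize_tree(ref_aln)
    consensus <- if (config$B >= 1L)
      bootstrap_consensus(ref_aln, B = config$B, threshold = config$threshold,
                          method = config$boot_method) else NULL
    ## congruence is scored against the majority-rule consensus when
    ## bootstrapping is on: splits without majority support are not part
    ## of the reference, so loci are not penalized for disagreeing with
    ## arbitrarily resolved edges (the split-based distances handle the
    ## polytomies natively)
    score_ref <- consensus %||% ref_fit$tree

    stage <- "diversity profile"
    inter_rows <- vapply(split(seq_along(records), species), function(ix) {
      accs <- vapply(records[ix], function(r) r$accession, "")
      if (ref_acc %in% accs) ref_acc else accs[1]
    }, "")
    inter_aln <- as_alignment(ref_aln[inter_rows, , drop = FALSE],
                              reference = ref_acc)
    profile <- sliding_window_pi(inter_aln, config$window, config$step,
                                 deletion = config$deletion)
    hotspots <- top_k_regions(profile, reference_record, k = config$k_pi)

    stage <- "informativeness"
    fi <- feature_index(reference_record)
    cds <- unique(fi$name[fi$kind == "CDS"])
    guide <- rescale_unit_depth(ref_fit$tree)
    profiles <- lapply(cds, function(locus) {
      aln <- locus_alignment(records, locus, config, alignments)
      gt <- ape::keep.tip(guide, intersect(guide$tip.label, rownames(aln)))
      pi_profile(estimate_site_rates(aln, gt, method = config$rate_method,
                                     locus = locus))
    })
    top_pi_loci <- rank_loci_by_pi(profiles, k = config$k_PI)

    stage <- "candidate evaluation"
    candidates <- select_candidate_loci(hotspots$region, top_pi_loci$locus)
    singles <- list()
    for (locus in candidates$locus) {
      ev <- tryCatch(
        evaluate_locus_set(records, locus, score_ref, config, alignments),
        error = function(e) {
          warning("skipping candidate '", locus, "': ", conditionMessage(e))
          NULL
        })
      if (!is.null(ev)) singles[[locus]] <- ev
    }
    if (!length(singles)) stop("no candidate locus could be evaluated")
    ## order by congruence; equally congruent markers are ranked by their
    ## candidate evidence (diversity/informativeness rank), then name
    sd <- vapply(singles, function(e) e$distance$normalized, 0)
    crank <- candidates$rank[match(names(singles), candidates$locus)]
    singles <- singles[order(sd, crank, names(singles))]

    stage <- "combination search"
    top_loci <- names(singles)[seq_len(min(config$top_m, length(singles)))]
    combos <- search_combinations(records, top_loci, score_ref, config,
                                  alignments)

    structure(list(
      candidates = candidates, hotspots = hotspots, pi_rank = top_pi_loci,
      diversity_profile = profile, reference_fit = ref_fit,
      reference_tree = ref_fit$tree, consensus = consensus,
      evaluations = singles, combinations = combos,
      best_single = singles[[1]], best_combination = combos[[1]],
      config = config), class = "marker_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Marker-selection report\n")
  cat("  candidates (", nrow(x$candidates), "): ",
      paste(x$candidates$locus, collapse = ", "), "\n", sep = "")
  cat("  single-locus congruence (generalized RF, ascending):\n")
  for (e in x$evaluations)
    cat(sprintf("    %-16s %.4f  (%d accessions)\n",
                paste(e$loci, collapse = "+"), e$distance$normalized,
                length(e$accessions)))
  cat("  best single locus:", x$best_single$loci, "\n")
  cat("  best combination: ", paste(x$best_combination$loci, collapse = "+"),
      sprintf(" (%.4f)\n", x$best_combination$distance$normalized))
  invisible(x)
}
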