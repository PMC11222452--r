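## Sliding-window nucleotide diversity, identity profiles, GC content,
## hotspot naming, and inter- vs intra-specific size-variation statistics.
##
## Alignments are consumed, never computed: rows come from an external
## aligner (any MAFFT-compatible tool) or from the simulator's exact truth.

#' Build a multiple alignment object
#'
#' @param x named character vector of equal-length aligned sequences, or a
#'   character matrix (rows = accessions, single characters), or a path
#'   readable by \code{\link{read_alignment}}.
#' @param reference accession whose ungapped coordinates anchor windows;
#'   defaults to the first row.
#' @return character matrix of class \code{plastid_alignment} with a
#'   \code{reference} attribute.
#' @export
as_alignment <- function(x, reference = NULL) {
  if (inherits(x, "plastid_alignment") && is.null(reference)) return(x)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("aligned sequences must be named")
    if (length(unique(nchar(x))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else if (is.matrix(x)) {
    m <- toupper(x)
    if (is.null(rownames(m))) stop("alignment matrix must have row names")
  } else stop("cannot coerce to alignment")
  reference <- reference %||% rownames(m)[1]
  if (!reference %in% rownames(m)) stop("reference not among rows")
  structure(m, class = "plastid_alignment", reference = reference)
}

#' Read an aligned FASTA file
#' @param path aligned FASTA.
#' @param reference reference accession (default first entry).
#' @return a \code{plastid_alignment}.
#' @export
read_alignment <- function(path, reference = NULL) {
  x <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(x), paste, "", collapse = ""))
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  as_alignment(seqs, reference)
}

#' Write an alignment to FASTA
#' @param alignment a \code{plastid_alignment} (or coercible).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_alignment <- function(alignment, path) {
  m <- as_alignment(alignment)
  con <- file(path, "w"); on.exit(close(con))
  for (r in rownames(m)) {
    writeLines(paste0(">", r), con)
    writeLines(paste(m[r, ], collapse = ""), con)
  }
  invisible(path)
}

## alignment column -> 0-based ungapped reference coordinate (NA at
## reference gaps)
alignment_column_map <- function(alignment) {
  ref <- attr(alignment, "reference")
  rr <- alignment[ref, ]
  isbase <- rr != "-"
  cm <- cumsum(isbase) - 1L
  cm[!isbase] <- NA_integer_
  cm
}

#' GC content of a DNA string
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguity codes and gaps are excluded
#' from numerator and denominator.
#'
#' @param sequence DNA string.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(sequence) {
  ch <- seq_chars(toupper(sequence))
  n_gc <- sum(ch %in% c("G", "C"))
  n_tot <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_tot == 0) stop("no unambiguous bases")
  n_gc / n_tot
}

## integer codes: 1..4 = ACGT, 0 = ambiguity/missing, -1 = gap
encode_alignment <- function(m) {
  code <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  code[m == "A"] <- 1L; code[m == "C"] <- 2L
  code[m == "G"] <- 3L; code[m == "T"] <- 4L
  code[m == "-"] <- -1L
  code
}

## mean pairwise difference over a code sub-matrix (columns already
## selected); ambiguities are missing per pair
pi_from_codes <- function(cd) {
  n <- nrow(cd)
  tot <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- cd[i, ] > 0L & cd[j, ] > 0L
    npair <- npair + 1L
    nc <- sum(ok)
    tot <- tot + if (nc) sum(cd[i, ok] != cd[j, ok]) / nc else 0
  }
  tot / npair
}

#' Sliding-window nucleotide diversity
#'
#' Per window, pi is the mean over sequence pairs of the per-site
#' difference fraction, computed on the window's retained columns. Under
#' the default complete-deletion policy, columns containing any gap are
#' removed from the window before computing pi; under pairwise deletion,
#' gaps are treated as missing per pair. Ambiguity codes are always
#' missing per pair. Windows are anchored in alignment columns; reference
#' coordinates are carried along for region naming.
#'
#' @param alignment a \code{plastid_alignment} (>= 2 rows).
#' @param window window size in alignment columns (default 600).
#' @param step step size (default 200).
#' @param deletion "complete" or "pairwise".
#' @param scope free-text label ("interspecific" or
#'   "intraspecific(species)") recorded in the profile.
#' @return data frame of class \code{diversity_profile} with columns
#'   win_start, win_end (0-based half-open alignment columns), ref_start,
#'   ref_end, n_sites, pi.
#' @export
sliding_window_pi <- function(alignment, window = 600L, step = 200L,
                              deletion = c("complete", "pairwise"),
                              scope = "interspecific") {
  deletion <- match.arg(deletion)
  m <- as_alignment(alignment)
  if (nrow(m) < 2L) stop("pi undefined for a single sequence")
  L <- ncol(m)
  window <- min(window, L)
  cd <- encode_alignment(m)
  cmap <- alignment_column_map(m)
  starts <- seq(1L, max(1L, L - window + 1L), by = step)
  rows <- lapply(starts, function(s) {
    cols <- s:(s + window - 1L)
    sub <- cd[, cols, drop = FALSE]
    if (deletion == "complete") {
      keep <- colSums(sub == -1L) == 0L
      sub <- sub[, keep, drop = FALSE]
    } else {
      sub[sub == -1L] <- 0L
    }
    usable <- ncol(sub) > 0L && any(colSums(sub > 0L) >= 2L)
    pi <- if (usable) pi_from_codes(sub) else NA_real_
    refc <- cmap[cols]
    refc <- refc[!is.na(refc)]
    data.frame(win_start = s - 1L, win_end = s + window - 1L,
               ref_start = if (length(refc)) min(refc) else NA_integer_,
               ref_end = if (length(refc)) max(refc) + 1L else NA_integer_,
               n_sites = ncol(sub), pi = pi)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(window = window, step = step,
                              deletion = deletion)
  attr(out, "scope") <- scope
  attr(out, "reference") <- attr(m, "reference")
  class(out) <- c("diversity_profile", "data.frame")
  out
}

#' @export
print.diversity_profile <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Diversity profile (%s): %d windows of %d (step %d), %s deletion\n",
              attr(x, "scope"), nrow(x), p$window, p$step, p$deletion))
  cat(sprintf("  mean pi = %.4g, max pi = %.4g\n",
              mean(x$pi, na.rm = TRUE), suppressWarnings(max(x$pi, na.rm = TRUE))))
  invisible(x)
}

#' @export
plot.diversity_profile <- function(x, ...) {
  graphics::plot((x$win_start + x$win_end) / 2, x$pi, type = "l",
                 xlab = "alignment position", ylab = expression(pi), ...)
  invisible(x)
}

## name a reference interval [s, e) after the annotation: overlapping
## gene(s), or "left-right" for a spacer between consecutive features
name_region <- function(ref_start, ref_end, record) {
  fi <- feature_index(record)
  fi <- fi[fi$kind %in% c("gene", "tRNA", "rRNA", "pseudogene"), , drop = FALSE]
  fi <- fi[!duplicated(fi[c("name", "start", "end")]), , drop = FALSE]
  if (!nrow(fi)) return(sprintf("%d-%d", ref_start, ref_end))
  ov <- fi$start < ref_end & fi$end > ref_start
  if (any(ov)) {
    nm <- unique(fi$name[ov][order(fi$start[ov])])
    if (length(nm) == 1L) return(nm[1])
    return(paste(nm[c(1, length(nm))], collapse = "-"))
  }
  left <- fi[fi$end <= ref_start, , drop = FALSE]
  right <- fi[fi$start >= ref_end, , drop = FALSE]
  ln <- if (nrow(left)) left$name[which.max(left$end)] else fi$name[which.max(fi$end)]
  rn <- if (nrow(right)) right$name[which.min(right$start)] else fi$name[which.min(fi$start)]
  paste(ln, rn, sep = "-")
}

#' Top-k diversity hotspot regions, named from the annotation
#'
#' Windows are taken in decreasing order of pi; a window overlapping or
#' abutting an already-selected region is merged into it, otherwise it
#' founds a new region, until k regions exist. Each region is named after
#' the feature(s) it overlaps on the reference, or "geneA-geneB" when it
#' lies in the spacer between consecutive features.
#'
#' @param profile a \code{diversity_profile}.
#' @param record annotated reference \code{\link{plastome_record}}.
#' @param k number of regions (default 5).
#' @return data frame: region name, peak pi, reference interval, ranked by
#'   peak pi.
#' @export
top_k_regions <- function(profile, record, k = 5L) {
  x <- profile[!is.na(profile$pi) & !is.na(profile$ref_start), , drop = FALSE]
  if (!nrow(x)) stop("profile has no usable windows")
  x <- x[order(-x$pi, x$win_start), , drop = FALSE]
  regions <- list()
  for (i in seq_len(nrow(x))) {
    s <- x$ref_start[i]; e <- x$ref_end[i]; p <- x$pi[i]
    touch <- which(vapply(regions, function(r)
      s <= r$end && e >= r$start, TRUE))
    if (length(touch)) {  # merge window and coalesce touching regions
      keep <- touch[1]
      best <- touch[which.max(vapply(regions[touch], `[[`, 0, "peak"))]
      pk <- regions[[best]][c("peak", "peak_start", "peak_end")]
      regions[[keep]]$start <- min(s, vapply(regions[touch], `[[`, 0, "start"))
      regions[[keep]]$end <- max(e, vapply(regions[touch], `[[`, 0, "end"))
      regions[[keep]][c("peak", "peak_start", "peak_end")] <- pk
      regions[touch[-1]] <- NULL
    } else {
      regions[[length(regions) + 1L]] <- list(start = s, end = e, peak = p,
                                              peak_start = s, peak_end = e)
    }
    if (length(regions) == k && i < nrow(x) &&
        !any(vapply(regions, function(r)
          x$ref_start[i + 1L] <= r$end && x$ref_end[i + 1L] >= r$start, TRUE)))
      break
  }
  if (length(regions) < k)
    warning("only ", length(regions), " distinct regions available")
  ## regions are named after their peak window, so a hotspot centred on
  ## one locus keeps that locus's name even when merging absorbs flanks
  out <- do.call(rbind, lapply(regions, function(r) {
    data.frame(region = name_region(r$peak_start, r$peak_end, record),
               peak_pi = r$peak, ref_start = r$start, ref_end = r$end,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$peak_pi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window percent identity to the reference
#'
#' mVISTA-style profile computed from a supplied alignment: for each
#' non-reference row and each window, identity = matching columns /
#' compared columns, where gap-vs-base counts as a mismatch and gap-vs-gap
#' is skipped. With an annotated reference record, windows are labelled
#' coding or non-coding by the majority of their reference positions.
#'
#' @param alignment a \code{plastid_alignment} (>= 2 rows).
#' @param window window size in columns (default 100).
#' @param step step (default 40).
#' @param record optional annotated reference record for the
#'   coding/non-coding split.
#' @return data frame of class \code{identity_profile}: accession,
#'   win_start, win_end, identity (percent), label; a \code{summary}
#'   attribute holds mean identity by accession x label.
#' @export
identity_profile <- function(alignment, window = 100L, step = 40L,
                             record = NULL) {
  m <- as_alignment(alignment)
  if (nrow(m) < 2L) stop("need at least two rows")
  ref <- attr(m, "reference")
  L <- ncol(m)
  window <- min(window, L)
  starts <- seq(1L, max(1L, L - window + 1L), by = step)
  cmap <- alignment_column_map(m)
  coding <- NULL
  if (!is.null(record)) {
    fi <- feature_index(record)
    fi <- fi[fi$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
    cod <- rep(FALSE, genome_length(record))
    for (i in seq_len(nrow(fi)))
      cod[(fi$start[i] + 1L):fi$end[i]] <- TRUE
    coding <- cod
  }
  rr <- m[ref, ]
  rows <- list()
  for (acc in setdiff(rownames(m), ref)) {
    a <- m[acc, ]
    for (s in starts) {
      cols <- s:(s + window - 1L)
      x <- rr[cols]; y <- a[cols]
      both_gap <- x == "-" & y == "-"
      cmp <- !both_gap
      id <- if (any(cmp)) 100 * sum(x[cmp] == y[cmp]) / sum(cmp) else NA_real_
      lab <- NA_character_
      if (!is.null(coding)) {
        refc <- cmap[cols]; refc <- refc[!is.na(refc)]
        if (length(refc))
          lab <- if (mean(coding[refc + 1L]) > 0.5) "coding" else "non-coding"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, win_start = s - 1L, win_end = s + window - 1L,
        identity = id, label = lab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(coding)) {
    agg <- stats::aggregate(identity ~ accession + label, data = out, FUN = mean)
    attr(out, "summary") <- agg
  }
  class(out) <- c("identity_profile", "data.frame")
  out
}

#' Welch t-test of inter- vs intra-specific size variation
#'
#' The intraspecific sample is |length difference| over all within-species
#' accession pairs, the interspecific sample over all between-species
#' pairs, computed for the whole genome and each quadripartite region.
#'
#' @param records list of \code{plastome_record} (species taken from each
#'   record).
#' @param partitions matching list of \code{quadripartite} partitions.
#' @return data frame of class \code{size_variation}: region, sample sizes,
#'   means, Welch t statistic and two-sided p-value.
#' @export
size_variation_test <- function(records, partitions) {
  stopifnot(length(records) == length(partitions))
  species <- vapply(records, function(r) r$species, "")
  if (length(unique(species)) < 2L) stop("need >= 2 species")
  if (!any(table(species) >= 2L)) stop("intraspecific sample empty")
  lens <- data.frame(
    whole = vapply(records, genome_length, 0),
    LSC = vapply(partitions, function(p) region_lengths(p)[["LSC"]], 0),
    SSC = vapply(partitions, function(p) region_lengths(p)[["SSC"]], 0),
    IR = vapply(partitions, function(p) region_lengths(p)[["IRb"]], 0))
  pairs <- utils::combn(length(records), 2)
  same <- species[pairs[1, ]] == species[pairs[2, ]]
  rows <- lapply(names(lens), function(reg) {
    d <- abs(lens[[reg]][pairs[1, ]] - lens[[reg]][pairs[2, ]])
    intra <- d[same]; inter <- d[!same]
    res <- tryCatch(stats::t.test(inter, intra), error = function(e) NULL)
    if (is.null(res) || !is.finite(res$p.value)) {
      ## degenerate (zero-variance) samples: equal means -> no evidence
      p <- if (isTRUE(all.equal(mean(inter), mean(intra)))) 1 else 0
      tstat <- 0
    } else { p <- res$p.value; tstat <- unname(res$statistic) }
    data.frame(region = reg, n_inter = length(inter), n_intra = length(intra),
               mean_inter = mean(inter), mean_intra = mean(intra),
               t = tstat, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("size_variation", "data.frame")
  out
}
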