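## Detection of the plastome quadripartite structure (LSC / IRb / SSC /
## IRa) from the raw circular sequence, canonical re-orientation, and
## junction (IR border) reporting.
##
## The inverted-repeat pair is found by k-mer seeding (k = 25) of the
## doubled sequence against its reverse complement (doubling handles
## repeats that span the origin). Seed hits from one repeat pair fall on a
## single diagonal of the (forward, reverse-complement) comparison, so
## maximal exact repeats are maximal runs of consecutive seeds on one
## diagonal. The longer single-copy region is labelled LSC.

.qp_k <- 25L

#' Detect the quadripartite LSC/IRb/SSC/IRa partition
#'
#' @param record a circular \code{\link{plastome_record}}.
#' @param min_ir_len minimum acceptable inverted-repeat length (bp).
#' @param max_mismatch_frac allowed mismatch fraction between the two IR
#'   copies; 0 requires exact reverse complementarity, values up to 0.005
#'   chain near-exact repeats for real records whose IRs differ slightly.
#' @return object of class \code{quadripartite}: region starts and lengths
#'   (0-based, on the input orientation, wrapping the circle), the
#'   IR identity fraction and the genome length.
#' @export
detect_quadripartite <- function(record, min_ir_len = 1000L,
                                 max_mismatch_frac = 0) {
  s <- record$sequence
  n <- nchar(s)
  if (n <= 2L * min_ir_len)
    stop("genome length must exceed 2 * min_ir_len")
  k <- .qp_k
  s2 <- paste0(s, s)
  r2 <- revcomp(s2)
  m <- 2L * n - k + 1L
  km_f <- substring(s2, 1:m, k:(2L * n))
  km_r <- substring(r2, 1:m, k:(2L * n))
  h <- split(1:m, km_r)
  sel <- which(km_f %in% names(h))
  if (!length(sel))
    stop("NoInvertedRepeat: no reverse repeat of length >= ", min_ir_len)
  hits <- h[km_f[sel]]
  i <- rep(sel, lengths(hits))
  j <- unlist(hits, use.names = FALSE)
  d <- j - i
  o <- order(d, i)
  i <- i[o]; d <- d[o]
  run <- cumsum(c(TRUE, diff(i) != 1L | diff(d) != 0L))
  i0 <- tapply(i, run, min)
  ilen <- tabulate(run)
  dd <- tapply(d, run, `[`, 1L)
  runs <- data.frame(i0 = as.integer(i0), len = as.integer(ilen) + k - 1L,
                     d = as.integer(dd))
  if (max_mismatch_frac > 0) runs <- chain_runs(runs, s2, r2, max_mismatch_frac)

  ## candidate repeat pairs on the circle
  best <- NULL
  runs <- runs[order(-runs$len, runs$i0), , drop = FALSE]
  for (r in seq_len(nrow(runs))) {
    L <- min(runs$len[r], n %/% 2L)
    if (L < min_ir_len) break
    a <- (runs$i0[r] - 1L) %% n                       # 0-based start copy A
    pend <- 2L * n - runs$d[r] - runs$i0[r] - runs$len[r] + 2L
    b <- (pend - 1L) %% n                              # 0-based start copy B
    if (a == b) next                                   # self-palindrome
    gap_ab <- (b - (a + L)) %% n
    gap_ba <- (a - (b + L)) %% n
    if (gap_ab + gap_ba + 2L * L != n) next            # overlapping copies
    cand <- list(a = a, b = b, L = L, gap_ab = gap_ab, gap_ba = gap_ba)
    if (is.null(best) || cand$L > best$L ||
        (cand$L == best$L && min(cand$a, cand$b) < min(best$a, best$b)))
      best <- cand
  }
  if (is.null(best))
    stop("NoInvertedRepeat: no reverse repeat of length >= ", min_ir_len)
  with(best, {
    if (gap_ab == gap_ba)
      warning("single-copy regions of equal length; LSC label arbitrary")
    if (gap_ab >= gap_ba) {
      lsc_start <- (a + L) %% n; lsc_len <- gap_ab
      irb_start <- b; ssc_start <- (b + L) %% n; ssc_len <- gap_ba
      ira_start <- a
    } else {
      lsc_start <- (b + L) %% n; lsc_len <- gap_ba
      irb_start <- a; ssc_start <- (a + L) %% n; ssc_len <- gap_ab
      ira_start <- b
    }
    ira <- circ_substr(s, ira_start, L)
    irb <- circ_substr(s, irb_start, L)
    idm <- mean(seq_chars(ira) == seq_chars(revcomp(irb)))
    structure(list(regions = data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(lsc_start, irb_start, ssc_start, ira_start),
      length = c(lsc_len, L, ssc_len, L), stringsAsFactors = FALSE),
      ir_identity = idm, genome_length = n), class = "quadripartite")
  })
}

## chain same-diagonal runs separated by small gaps (tolerant mode)
chain_runs <- function(runs, s2, r2, max_frac) {
  out <- list()
  for (dv in unique(runs$d)) {
    rr <- runs[runs$d == dv, , drop = FALSE]
    rr <- rr[order(rr$i0), , drop = FALSE]
    cur <- rr[1, ]
    mism <- 0L
    for (q in seq_len(nrow(rr))[-1]) {
      gap <- rr$i0[q] - (cur$i0 + cur$len)
      newlen <- rr$i0[q] + rr$len[q] - cur$i0
      if (gap >= 0 && (mism + gap) / newlen <= max_frac) {
        mism <- mism + gap
        cur$len <- newlen
      } else {
        out[[length(out) + 1L]] <- cur; cur <- rr[q, ]; mism <- 0L
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

circ_substr <- function(s, start0, len) {
  n <- nchar(s)
  start0 <- start0 %% n
  if (start0 + len <= n) substr(s, start0 + 1L, start0 + len)
  else paste0(substr(s, start0 + 1L, n), substr(s, 1L, start0 + len - n))
}

#' @export
print.quadripartite <- function(x, ...) {
  cat("Quadripartite partition (genome", x$genome_length, "bp):\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("  IR identity: %.4f\n", x$ir_identity))
  invisible(x)
}

region_lengths <- function(partition) {
  setNames(partition$regions$length, partition$regions$region)
}

#' Rotate and orient a record into canonical quadripartite order
#'
#' The genome is rotated (and reverse-complemented if needed) so position 0
#' is the first base of the LSC and the region order is LSC, IRb, SSC, IRa.
#' Both orientations admit that order; the one whose canonical sequence is
#' lexicographically smaller is chosen, which makes the result invariant to
#' rotation and to reverse complementation of the input. Feature
#' coordinates are remapped (features crossing the new origin become
#' two-segment joins). Applying the function to its own output is the
#' identity.
#'
#' @param record a \code{\link{plastome_record}}.
#' @param partition matching \code{quadripartite} partition (detected if
#'   missing).
#' @return list with elements \code{record} and \code{partition}.
#' @export
canonicalize <- function(record, partition = NULL) {
  if (is.null(partition)) partition <- detect_quadripartite(record)
  fwd <- orient_canonical(record, partition, reverse = FALSE)
  rev <- orient_canonical(record, partition, reverse = TRUE)
  pick <- if (rev$record$sequence < fwd$record$sequence) rev else fwd
  pick
}

orient_canonical <- function(record, partition, reverse) {
  n <- genome_length(record)
  rec <- record
  reg <- partition$regions
  if (reverse) {
    rec <- reverse_record(rec)
    reg$start <- (n - (reg$start + reg$length)) %% n
    ## reversing swaps which IR precedes the SSC
    reg$region[reg$region %in% c("IRa", "IRb")] <-
      rev(reg$region[reg$region %in% c("IRa", "IRb")])
  }
  off <- reg$start[reg$region == "LSC"]
  rec <- rotate_record(rec, off)
  reg$start <- (reg$start - off) %% n
  reg <- reg[match(c("LSC", "IRb", "SSC", "IRa"), reg$region), , drop = FALSE]
  rownames(reg) <- NULL
  part <- structure(list(regions = reg, ir_identity = partition$ir_identity,
                         genome_length = n), class = "quadripartite")
  list(record = rec, partition = part)
}

rotate_record <- function(record, off) {
  n <- genome_length(record)
  off <- off %% n
  if (off == 0) return(record)
  s <- rotate_seq(record$sequence, off)
  f <- record$features
  if (nrow(f)) {
    ns <- (f$start - off) %% n
    ne <- ns + (f$end - f$start)
    keep <- ne <= n
    plain <- f[keep, , drop = FALSE]
    plain$start <- ns[keep]; plain$end <- ne[keep]
    wrap <- f[!keep, , drop = FALSE]
    if (nrow(wrap)) {
      ws <- ns[!keep]; we <- ne[!keep]
      hi <- wrap; hi$start <- ws; hi$end <- n
      lo <- wrap; lo$start <- 0L; lo$end <- we - n
      plain <- rbind(plain, hi, lo)
    }
    f <- plain[order(plain$id, plain$start), , drop = FALSE]
    ## re-join segments of one feature made contiguous by the rotation
    if (nrow(f) > 1L) {
      drop <- logical(nrow(f))
      for (i in 2:nrow(f)) {
        j <- i - 1L
        while (j >= 1L && drop[j]) j <- j - 1L
        if (j >= 1L && f$id[i] == f$id[j] && f$start[i] == f$end[j]) {
          f$end[j] <- f$end[i]
          drop[i] <- TRUE
        }
      }
      f <- f[!drop, , drop = FALSE]
    }
    rownames(f) <- NULL
  }
  record$sequence <- s
  record$features <- f
  record
}

reverse_record <- function(record) {
  n <- genome_length(record)
  record$sequence <- revcomp(record$sequence)
  f <- record$features
  if (nrow(f)) {
    ns <- n - f$end; ne <- n - f$start
    f$start <- ns; f$end <- ne
    f$strand <- ifelse(f$strand == "+", "-", "+")
    f <- f[order(f$id, f$start), , drop = FALSE]
    rownames(f) <- NULL
    record$features <- f
  }
  record
}

.junction_names <- c("JLB", "JSB", "JSA", "JLA")

#' Report genes at the four IR junctions
#'
#' For each junction (JLB = LSC/IRb, JSB = IRb/SSC, JSA = SSC/IRa,
#' JLA = IRa/LSC) the report gives the gene spanning the border (with the
#' bp it extends into each side) or the nearest gene on each side with its
#' distance. Junction positions are the coordinate of the first base of the
#' downstream region, so a gene ending exactly at a junction has left
#' distance 0. Only gene, tRNA, rRNA and pseudogene features are
#' considered. Requires a record in canonical orientation.
#'
#' @param record canonical annotated \code{\link{plastome_record}}.
#' @param partition matching canonical \code{quadripartite}.
#' @return object of class \code{junction_report} (data frame, one row per
#'   junction).
#' @export
junction_report <- function(record, partition) {
  fi <- feature_index(record)
  fi <- fi[fi$kind %in% c("gene", "tRNA", "rRNA", "pseudogene"), , drop = FALSE]
  fi <- fi[!duplicated(fi[c("name", "start", "end")]), , drop = FALSE]
  if (!nrow(fi))
    stop("record '", record$accession,
         "' is unannotated; annotate it or skip junction reporting")
  n <- partition$genome_length
  reg <- partition$regions
  jpos <- c(JLB = reg$start[reg$region == "IRb"],
            JSB = reg$start[reg$region == "SSC"],
            JSA = reg$start[reg$region == "IRa"],
            JLA = reg$start[reg$region == "LSC"])
  ## circular span per feature: origin-spanning joins (a segment ending at
  ## n plus one starting at 0) start at the high-coordinate segment
  segs <- record$features
  span <- lapply(fi$id, function(id) {
    f <- segs[segs$id == id, , drop = FALSE]
    if (nrow(f) >= 2L && any(f$end == n) && any(f$start == 0L)) {
      st <- min(f$start[f$end == n])
      len <- (n - st) + max(f$end[f$start == 0L])
    } else {
      st <- min(f$start); len <- max(f$end) - st
    }
    c(st, len)
  })
  span_start <- vapply(span, `[`, 0, 1L)
  span_len <- vapply(span, `[`, 0, 2L)
  rows <- lapply(.junction_names, function(jn) {
    p <- jpos[[jn]]
    into_l <- (p - span_start) %% n
    into_r <- span_len - into_l
    sp_i <- which(into_l > 0 & into_r > 0)
    spanning <- if (length(sp_i)) sp_i[which.max(pmin(into_l[sp_i], into_r[sp_i]))] else NA
    ldist <- (p - (span_start + span_len)) %% n
    rdist <- (span_start - p) %% n
    li <- which.min(ldist); ri <- which.min(rdist)
    data.frame(accession = record$accession, junction = jn, position = p,
               spanning_gene = if (!is.na(spanning)) fi$name[spanning] else NA_character_,
               into_left_bp = if (!is.na(spanning)) as.integer(into_l[spanning]) else NA_integer_,
               into_right_bp = if (!is.na(spanning)) as.integer(into_r[spanning]) else NA_integer_,
               left_gene = fi$name[li], left_dist = as.integer(ldist[li]),
               right_gene = fi$name[ri], right_dist = as.integer(rdist[ri]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ir_length") <- reg$length[reg$region == "IRb"]
  class(out) <- c("junction_report", "data.frame")
  out
}

#' Compare IR junctions across accessions
#'
#' Binds junction reports into one table and adds, per accession, the IR
#' length delta relative to the across-set median (positive = expansion,
#' negative = contraction).
#'
#' @param reports list of \code{junction_report} objects (>= 2).
#' @return data frame of class \code{junction_comparison}; one row per
#'   accession x junction.
#' @export
compare_junctions <- function(reports) {
  stopifnot(length(reports) >= 2)
  irl <- vapply(reports, function(r) as.numeric(attr(r, "ir_length")), 0)
  med <- stats::median(irl)
  rows <- Map(function(r, l) {
    d <- as.data.frame(r)
    d$ir_length <- l
    d$ir_delta <- l - med
    d
  }, reports, irl)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("junction_comparison", "data.frame")
  out
}

#' Export the four regions of a partition as BED intervals
#' @param record record the partition belongs to.
#' @param partition a \code{quadripartite}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_partition_bed <- function(record, partition, path) {
  reg <- partition$regions
  n <- partition$genome_length
  lines <- character(0)
  for (i in seq_len(nrow(reg))) {
    s <- reg$start[i]; e <- s + reg$length[i]
    if (e <= n) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", record$accession, s, e,
                                reg$region[i]))
    } else {  # wrapping region: two BED lines
      lines <- c(lines,
                 sprintf("%s\t%d\t%d\t%s", record$accession, s, n, reg$region[i]),
                 sprintf("%s\t%d\t%d\t%s", record$accession, 0L, e - n, reg$region[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
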