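#' Construct an annotated plastome record
#'
#' The universal input container of the package: one circular (usually)
#' chloroplast genome with its feature table. Coordinates are internally
#' 0-based half-open; GenBank 1-based inclusive coordinates are converted at
#' the I/O boundary. A feature may consist of several segments (a GenBank
#' \code{join}), e.g. when it spans the origin of the circular sequence.
#'
#' @param accession accession identifier (unique within a dataset).
#' @param sequence DNA string over the IUPAC alphabet; stored uppercased.
#' @param species species name (free text).
#' @param circular logical; is the molecule circular?
#' @param features data frame with columns \code{id} (integer grouping join
#'   segments), \code{name}, \code{kind} (one of gene, CDS, tRNA, rRNA,
#'   pseudogene), \code{strand} ("+" or "-"), \code{start}, \code{end}
#'   (0-based half-open).
#' @return object of class \code{plastome_record}.
#' @export
plastome_record <- function(accession, sequence, species = NA_character_,
                            circular = TRUE, features = NULL) {
  if (is.null(features)) features <- empty_features()
  rec <- structure(list(accession = as.character(accession),
                        species = as.character(species),
                        sequence = toupper(sequence),
                        circular = isTRUE(circular),
                        features = features),
                   class = "plastome_record")
  validate_plastome_record(rec)
  rec
}

empty_features <- function() {
  data.frame(id = integer(), name = character(), kind = character(),
             strand = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

validate_plastome_record <- function(rec) {
  stopifnot(inherits(rec, "plastome_record"))
  n <- nchar(rec$sequence)
  if (n == 0L) stop("plastome record '", rec$accession, "': empty sequence")
  bad <- setdiff(unique(seq_chars(rec$sequence)), .iupac)
  if (length(bad))
    stop("plastome record '", rec$accession,
         "': non-IUPAC characters in sequence: ", paste(bad, collapse = " "))
  f <- rec$features
  req <- c("id", "name", "kind", "strand", "start", "end")
  if (!all(req %in% names(f))) stop("features table lacks required columns")
  if (nrow(f)) {
    if (any(f$end <= f$start)) stop("feature segment with end <= start")
    if (any(f$start < 0L) || any(f$end > n))
      stop("feature segment outside [0, genome length)")
    if (!all(f$kind %in% c("gene", "CDS", "tRNA", "rRNA", "pseudogene")))
      stop("unknown feature kind: ",
           paste(setdiff(unique(f$kind),
                         c("gene", "CDS", "tRNA", "rRNA", "pseudogene")),
                 collapse = " "))
    if (!all(f$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  invisible(rec)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("Plastome record", x$accession,
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat("  ", nchar(x$sequence), "bp,",
      if (x$circular) "circular" else "linear", "\n")
  cat("  ", length(unique(x$features$id)), "features\n")
  invisible(x)
}

#' Genome length of a record
#' @param record a \code{plastome_record}.
#' @return integer length in bp.
#' @export
genome_length <- function(record) nchar(record$sequence)

## one row per feature (not per segment): overall span and metadata
feature_index <- function(record) {
  f <- record$features
  if (!nrow(f)) {
    return(data.frame(id = integer(), name = character(), kind = character(),
                      strand = character(), start = integer(),
                      end = integer(), nseg = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(f)), f$id)
  rows <- lapply(sp, function(ix) {
    data.frame(id = f$id[ix[1]], name = f$name[ix[1]], kind = f$kind[ix[1]],
               strand = f$strand[ix[1]], start = min(f$start[ix]),
               end = max(f$end[ix]), nseg = length(ix),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

## spliced, strand-oriented sequence of one feature id
feature_sequence <- function(record, id) {
  f <- record$features[record$features$id == id, , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  ## origin-spanning joins are stored as (high-coordinate, low-coordinate)
  ## segment pairs; genomic order = order given by segment order on the
  ## circle, which for a 2-segment wrap is (end-at-n segment first)
  if (nrow(f) == 2L && f$end[nrow(f)] == nchar(record$sequence) &&
      f$start[1] == 0L) {
    f <- f[c(2L, 1L), , drop = FALSE]
  }
  parts <- substring(record$sequence, f$start + 1L, f$end)
  s <- paste(parts, collapse = "")
  if (f$strand[1] == "-") s <- revcomp(s)
  s
}
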