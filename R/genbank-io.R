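## GenBank flat-file and FASTA input/output for plastome records.
##
## GenBank coordinates are 1-based inclusive and are converted to the
## package's 0-based half-open convention on read (and back on write).
## Origin-spanning joins on circular molecules are preserved as two
## segments. Only the feature kinds the comparative analyses consume are
## kept (gene, CDS, tRNA, rRNA; a gene carrying /pseudo becomes kind
## "pseudogene").

.gb_kinds <- c("gene", "CDS", "tRNA", "rRNA")

#' Read a plastome record from GenBank or FASTA
#'
#' @param path path to the file.
#' @param format "auto" (by extension/content), "genbank" or "fasta".
#'   FASTA records have an empty feature table.
#' @return a \code{\link{plastome_record}}.
#' @export
read_plastome <- function(path, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && grepl("^>", first)) "fasta" else "genbank"
  }
  if (format == "fasta") read_plastome_fasta(path) else read_plastome_genbank(path)
}

read_plastome_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  if (!length(x)) stop("parse error in ", path, ": no FASTA entry found")
  hdr <- names(x)[1]
  acc <- strsplit(hdr, "\\s+")[[1]][1]
  sp <- sub("^\\S+\\s*", "", hdr)
  if (identical(sp, "") || identical(sp, hdr)) sp <- NA_character_
  s <- toupper(paste(as.character(x)[[1]], collapse = ""))
  if (!nchar(s)) stop("empty sequence in ", path)
  plastome_record(acc, s, species = sp, circular = TRUE)
}

read_plastome_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc)) stop("parse error in ", path, ": no LOCUS line")
  locus <- strsplit(trimws(lines[iloc[1]]), "\\s+")[[1]]
  circular <- !("linear" %in% tolower(locus))  # default circular
  acc <- locus[2]
  iacc <- grep("^ACCESSION", lines)
  if (length(iacc)) {
    a <- strsplit(trimws(lines[iacc[1]]), "\\s+")[[1]]
    if (length(a) >= 2) acc <- a[2]
  }
  species <- NA_character_
  iorg <- grep("^\\s{2}ORGANISM", lines)
  if (length(iorg)) species <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[iorg[1]]))

  ## ORIGIN block
  iori <- grep("^ORIGIN", lines)
  if (!length(iori)) stop("parse error in ", path, ": no ORIGIN block")
  iend <- grep("^//", lines)
  iend <- if (length(iend)) iend[iend > iori[1]][1] else length(lines) + 1L
  seqlines <- lines[(iori[1] + 1L):(iend - 1L)]
  s <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nchar(s)) stop("empty sequence in ", path)

  ## FEATURES block
  ifea <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(ifea)) {
    block <- lines[(ifea[1] + 1L):(iori[1] - 1L)]
    feats <- parse_gb_features(block, path)
  }
  plastome_record(acc, s, species = species, circular = circular,
                  features = feats)
}

parse_gb_features <- function(block, path) {
  ## a new feature starts at indentation 5; continuation/qualifiers at 21
  starts <- grep("^ {5}\\S", block)
  if (!length(starts)) return(empty_features())
  ends <- c(starts[-1] - 1L, length(block))
  out <- list(); fid <- 0L
  for (i in seq_along(starts)) {
    chunk <- block[starts[i]:ends[i]]
    head <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
    key <- head[1]
    if (!(key %in% .gb_kinds)) next
    ## location possibly wrapped over several lines until first qualifier
    qual_at <- grep("^\\s+/", chunk)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(chunk)
    loc <- paste(trimws(c(sub("^\\s*\\S+\\s*", "", chunk[1]),
                          chunk[seq_len(loc_end)[-1]])), collapse = "")
    quals <- chunk[grep("^\\s+/", chunk)]
    gene <- qual_value(quals, "gene") %||% qual_value(quals, "standard_name") %||%
      qual_value(quals, "product") %||% NA_character_
    pseudo <- any(grepl("^\\s*/pseudo\\b", quals))
    parsed <- tryCatch(parse_gb_location(loc),
                       error = function(e)
                         stop("parse error in ", path, " near feature '",
                              key, " ", loc, "': ", conditionMessage(e)))
    kind <- if (pseudo && key == "gene") "pseudogene" else key
    if (pseudo && key == "CDS") next  # pseudogene counted once, via gene
    fid <- fid + 1L
    out[[length(out) + 1L]] <- data.frame(
      id = fid, name = gene %||% NA_character_, kind = kind,
      strand = parsed$strand, start = parsed$start, end = parsed$end,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_features())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

qual_value <- function(quals, key) {
  pat <- paste0("^\\s*/", key, "=\"?([^\"]*)\"?\\s*$")
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(pat, "\\1", hit[1])
}

## "complement(join(a..b,c..d))" -> strand, 0-based half-open segments
parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  ## inner complement() per segment (join(complement(..)..)) not supported
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", parts))
  single <- regmatches(parts, regexec("^[<>]?(\\d+)$", parts))
  st <- en <- integer(length(parts))
  for (i in seq_along(parts)) {
    if (length(m[[i]]) == 3L) {
      st[i] <- as.integer(m[[i]][2]); en[i] <- as.integer(m[[i]][3])
    } else if (length(single[[i]]) == 2L) {
      st[i] <- en[i] <- as.integer(single[[i]][2])
    } else stop("cannot parse location segment '", parts[i], "'")
  }
  if (any(en < st)) stop("location segment with end < start")
  list(strand = strand, start = st - 1L, end = en)
}

#' Write a plastome record to GenBank or FASTA
#'
#' The emitted file re-reads to an equivalent record: identical sequence and
#' identical (name, kind, strand, intervals) for every feature.
#'
#' @param record a \code{\link{plastome_record}}.
#' @param path output path.
#' @param format "genbank" or "fasta".
#' @return invisibly, \code{path}.
#' @export
write_record <- function(record, path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  validate_plastome_record(record)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (format == "fasta") {
    hdr <- paste0(">", record$accession,
                  if (!is.na(record$species)) paste0(" ", record$species))
    writeLines(hdr, con)
    s <- record$sequence
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
    return(invisible(path))
  }
  n <- nchar(record$sequence)
  ## 79-column LOCUS line (name 13-28, length ..40, topology 56-63)
  writeLines(sprintf("LOCUS       %-16s%12d bp    DNA     %-8s PLN 01-JAN-2024",
                     record$accession, n,
                     if (record$circular) "circular" else "linear"), con)
  if (!is.na(record$species)) {
    writeLines(paste0("DEFINITION  ", record$species,
                      " chloroplast, complete genome."), con)
    writeLines(paste0("SOURCE      ", record$species), con)
    writeLines(paste0("  ORGANISM  ", record$species), con)
  }
  writeLines(paste0("ACCESSION   ", record$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  fi <- feature_index(record)
  for (i in seq_len(nrow(fi))) {
    f <- record$features[record$features$id == fi$id[i], , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) == 2L && f$end[nrow(f)] == n && f$start[1] == 0L)
      f <- f[c(2L, 1L), , drop = FALSE]  # origin-spanning order
    segs <- sprintf("%d..%d", f$start + 1L, f$end)
    loc <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")") else segs
    if (fi$strand[i] == "-") loc <- paste0("complement(", loc, ")")
    key <- if (fi$kind[i] == "pseudogene") "gene" else fi$kind[i]
    writeLines(sprintf("     %-15s %s", key, loc), con)
    if (!is.na(fi$name[i]))
      writeLines(sprintf("                     /gene=\"%s\"", fi$name[i]), con)
    if (fi$kind[i] == "pseudogene")
      writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1, n, 60)
  for (p in pos) {
    chunk <- substring(s, seq(p, min(p + 59, n), 10),
                       pmin(seq(p, min(p + 59, n), 10) + 9, n))
    writeLines(sprintf("%9d %s", p, paste(chunk, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Count annotated features by category
#'
#' Every annotated occurrence is counted once, so loci duplicated in the two
#' inverted repeats count twice (e.g. 4 rRNA loci duplicated in both IRs
#' give an rRNA count of 8). Pseudogenes are included in the gene and CDS
#' tallies, the reporting convention of plastome feature tables.
#'
#' @param record a \code{\link{plastome_record}}.
#' @return named integer vector: genes, CDS, tRNA, rRNA, pseudogenes.
#' @export
feature_counts <- function(record) {
  fi <- feature_index(record)
  k <- fi$kind
  c(genes = sum(k == "gene") + sum(k == "pseudogene"),
    CDS = sum(k == "CDS") + sum(k == "pseudogene"),
    tRNA = sum(k == "tRNA"),
    rRNA = sum(k == "rRNA"),
    pseudogenes = sum(k == "pseudogene"))
}

#' Export feature counts for a set of records as a table
#' @param records list of \code{plastome_record}.
#' @return data frame, one row per accession.
#' @export
feature_count_table <- function(records) {
  rows <- lapply(records, function(r) {
    cnt <- feature_counts(r)
    data.frame(accession = r$accession, species = r$species,
               size_bp = genome_length(r), genes = cnt[["genes"]],
               CDS = cnt[["CDS"]], tRNA = cnt[["tRNA"]], rRNA = cnt[["rRNA"]],
               pseudogenes = cnt[["pseudogenes"]],
               gc_percent = round(100 * gc_content(r$sequence), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract one locus across accessions
#'
#' Feature mode returns the spliced, strand-oriented sequence of the named
#' feature (the copy with the smaller start coordinate when the locus is
#' duplicated in the inverted repeats, or both copies with
#' \code{copies = "both"}). Intergenic mode returns the sequence strictly
#' between the two named features on the genome orientation. Accessions
#' lacking the locus are listed in \code{dropped} with a warning, mirroring
#' per-locus accession exclusion in downstream tree building.
#'
#' @param records list of \code{plastome_record}.
#' @param locus locus name (feature mode), matched case-insensitively with
#'   optional tRNA anticodon suffix.
#' @param region "feature" or "intergenic".
#' @param flanks for intergenic mode, character vector of the two flanking
#'   feature names; defaults to splitting \code{locus} on "-".
#' @param copies "first" or "both" for IR-duplicated loci.
#' @return object of class \code{locus_matrix}: list with \code{locus},
#'   \code{rows} (named character vector of sequences) and \code{dropped}.
#' @export
extract_locus <- function(records, locus, region = c("feature", "intergenic"),
                          flanks = NULL, copies = c("first", "both")) {
  region <- match.arg(region)
  copies <- match.arg(copies)
  stopifnot(length(records) >= 1)
  rows <- character(0); dropped <- character(0)
  for (rec in records) {
    s <- tryCatch({
      if (region == "feature") extract_feature_seq(rec, locus, copies)
      else extract_intergenic_seq(rec, flanks %||% split_spacer_name(rec, locus))
    }, error = function(e) NULL)
    if (is.null(s)) dropped <- c(dropped, rec$accession)
    else if (length(s) > 1L) {  # copies = "both" on an IR-duplicated locus
      rows[paste0(rec$accession, ".copy", seq_along(s))] <- s
    } else rows[rec$accession] <- s
  }
  if (!length(rows)) stop("locus unknown: '", locus,
                          "' found in zero accessions")
  if (length(dropped))
    warning("locus '", locus, "' missing in: ", paste(dropped, collapse = ", "))
  structure(list(locus = locus, rows = rows, dropped = dropped),
            class = "locus_matrix")
}

extract_feature_seq <- function(record, locus, copies = "first") {
  fi <- feature_index(record)
  ## prefer gene-level features; fall back to any kind with that name
  hit <- fi[locus_name_matches(fi$name, locus), , drop = FALSE]
  if (!nrow(hit)) stop("no feature '", locus, "'")
  pref <- hit[hit$kind %in% c("gene", "pseudogene"), , drop = FALSE]
  if (nrow(pref)) hit <- pref
  hit <- hit[order(hit$start), , drop = FALSE]
  if (copies == "both" && nrow(hit) > 1L) {
    return(vapply(hit$id, function(id) feature_sequence(record, id), ""))
  }
  feature_sequence(record, hit$id[1])
}

extract_intergenic_seq <- function(record, flanks) {
  if (length(flanks) != 2L) stop("need two flanking feature names")
  fi <- feature_index(record)
  a <- fi[locus_name_matches(fi$name, flanks[1]), , drop = FALSE]
  b <- fi[locus_name_matches(fi$name, flanks[2]), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("flanking feature missing")
  ## choose the adjacent pair: minimal positive gap start(b) - end(a)
  best <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- min(a$end[i], b$end[j]); hi <- max(a$start[i], b$start[j])
    gap <- hi - lo
    if (gap < 0) next
    if (is.null(best) || gap < best$gap) best <- list(lo = lo, hi = hi, gap = gap)
  }
  if (is.null(best)) stop("features overlap; no spacer")
  if (best$gap == 0) return("")
  substr(record$sequence, best$lo + 1L, best$hi)
}

## parse "geneA-geneB" into flanking names, trying each '-' split point so
## names that themselves contain '-' (trnL-UAG) resolve correctly
split_spacer_name <- function(record, locus) {
  fi <- feature_index(record)
  pos <- gregexpr("-", locus, fixed = TRUE)[[1]]
  if (pos[1] == -1) stop("not a spacer name: ", locus)
  for (p in pos) {
    a <- substr(locus, 1, p - 1); b <- substr(locus, p + 1, nchar(locus))
    if (any(locus_name_matches(fi$name, a)) &&
        any(locus_name_matches(fi$name, b))) return(c(a, b))
  }
  strsplit(locus, "-", fixed = TRUE)[[1]][1:2]
}

#' @export
print.locus_matrix <- function(x, ...) {
  cat("Locus matrix '", x$locus, "': ", length(x$rows), " accessions",
      if (length(x$dropped)) paste0(" (", length(x$dropped), " dropped)"),
      "\n", sep = "")
  invisible(x)
}
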