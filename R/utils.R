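#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet (ambiguity codes map to the complement of
#' the set they denote; gaps are preserved).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

## IUPAC DNA alphabet accepted in records
.iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical form of a locus name for matching across annotation dialects:
## case-folded, and for tRNAs the anticodon suffix is optional
## (trnH == trnH-GUG). A small alias table covers common spelling variants.
.locus_aliases <- c(
  "trnk"  = "trnk-uuu",
  "trnq"  = "trnq-uug",
  "trnh"  = "trnh-gug",
  "trnl"  = "trnl-uaa",
  "psbd-psbc" = "psbd"
)

norm_locus_name <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("_", "-", y, fixed = TRUE)
  hit <- match(y, names(.locus_aliases))
  y[!is.na(hit)] <- .locus_aliases[hit[!is.na(hit)]]
  y
}

## TRUE where a feature name matches a query, allowing tRNA anticodon
## suffixes to be dropped on either side.
locus_name_matches <- function(feature_names, query) {
  fn <- norm_locus_name(feature_names)
  q <- norm_locus_name(query)
  exact <- fn == q
  strip <- function(z) sub("^(trn[a-z]{1,2})-[acgu]{3}$", "\\1", z)
  exact | strip(fn) == strip(q)
}

## rotate a string so that 0-based position `off` becomes position 0
rotate_seq <- function(s, off) {
  n <- nchar(s)
  off <- ((off %% n) + n) %% n
  if (off == 0) return(s)
  paste0(substr(s, off + 1, n), substr(s, 1, off))
}

## split a string into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## trapezoid rule
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
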