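#' @keywords internal
"_PACKAGE"

#' @importFrom Biostrings readBStringSet DNAString reverseComplement GENETIC_CODE
#' @importFrom GenomicRanges GRanges start end strand mcols findOverlaps pintersect reduce
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom stats quantile binom.test rpois runif setNames aggregate
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a multi-record DNA FASTA file
#'
#' Sequences are uppercased on ingest; soft-masking information is deliberately
#' discarded. Only the characters `A`, `C`, `G`, `T`, `N` (either case) are
#' accepted; anything else is a format error naming the offending record and
#' 1-based position.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase DNA sequences (names are the
#'   FASTA ids), with a `"descriptions"` attribute holding the full header
#'   lines.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA format error: empty record id in ", path)
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate id '", ids[duplicated(ids)][1L], "'")
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad != -1L) {
      stop("FASTA format error: illegal character '",
           substr(seqs[[i]], bad, bad), "' in record '", ids[[i]],
           "' at position ", as.integer(bad))
    }
    if (nchar(seqs[[i]]) < 1L) {
      stop("FASTA format error: empty sequence in record '", ids[[i]], "'")
    }
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(headers, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param seq A DNA string over `A,C,G,T,N`.
#' @return The reverse complement, as a character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Internal feature representation: a data.frame with at least the columns
#   seqid (chr), start (0-based inclusive), end (exclusive), strand (+/-/.),
# plus optional type, score and free attribute columns (family, class,
# element_id, ...). All internal coordinates are 0-based half-open; the only
# conversion points are read_features()/write_features().

#' Construct a feature table
#'
#' @param seqid,start,end,strand Core interval columns; `start` is 0-based
#'   inclusive, `end` exclusive, `strand` one of `+`, `-`, `.`.
#' @param ... Further equal-length attribute columns (e.g. `type`, `score`,
#'   `family`, `element_id`).
#' @return A `data.frame` in the package's internal feature convention.
#' @export
features <- function(seqid, start, end, strand = ".", ...) {
  df <- data.frame(seqid = as.character(seqid), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   ..., stringsAsFactors = FALSE)
  validate_features(df)
  df
}

validate_features <- function(df) {
  stopifnot(all(c("seqid", "start", "end", "strand") %in% names(df)))
  if (any(df$end <= df$start)) {
    stop("feature format error: end must be > start (0-based half-open)")
  }
  if (any(df$start < 0L)) stop("feature format error: negative start")
  bad <- setdiff(unique(df$strand), c("+", "-", "."))
  if (length(bad)) stop("feature format error: unknown strand symbol '", bad[1L], "'")
  invisible(df)
}

#' Read features from GFF3 or BED
#'
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; BED coordinates pass through unchanged. Attribute
#' fields (e.g. `family`, `class`, `element_id`) are retained verbatim as
#' columns.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @return A feature `data.frame` (see [features()]).
#' @export
read_features <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("feature format error: file does not exist: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed"),
    error = function(e) stop("feature format error in ", path, ": ",
                             conditionMessage(e)))
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  drop <- intersect(c("source", "phase"), names(mc))
  mc <- mc[, setdiff(names(mc), drop), drop = FALSE]
  for (nm in names(mc)) {
    if (is.factor(mc[[nm]])) mc[[nm]] <- as.character(mc[[nm]])
  }
  df <- cbind(df, mc)
  validate_features(df)
  df
}

#' Write features to GFF3 or BED
#'
#' The exact inverse of [read_features()]: internal 0-based half-open
#' coordinates become 1-based inclusive in GFF3 and stay 0-based in BED.
#' `read_features(write_features(f))` reproduces `f`'s coordinates, strand,
#' score and attributes.
#'
#' @param df Feature `data.frame` (see [features()]).
#' @param path Output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @param source GFF3 source column value.
#' @return `path`, invisibly.
#' @export
write_features <- function(df, path, dialect = c("gff3", "bed"), source = "g4telo") {
  dialect <- match.arg(dialect)
  if (nrow(df) == 0L) {
    writeLines(if (dialect == "gff3") "##gff-version 3" else character(0), path)
    return(invisible(path))
  }
  validate_features(df)
  gr <- GenomicRanges::GRanges(
    df$seqid, IRanges::IRanges(df$start + 1L, df$end),
    strand = chartr(".", "*", df$strand))
  extra <- df[, setdiff(names(df), c("seqid", "start", "end", "strand")),
              drop = FALSE]
  if (ncol(extra)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(extra)
  if (dialect == "gff3" && is.null(gr$type)) gr$type <- "feature"
  rtracklayer::export(gr, path, format = if (dialect == "gff3") "gff3" else "bed")
  invisible(path)
}
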