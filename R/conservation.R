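# DNA-vs-amino-acid conservation bias: codon threading of a protein alignment
# back onto in-frame CDS, pairwise identity / BLOSUM62 similarity, and
# per-region conservation reports.

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codons <- function(codons) {
  gc <- genetic_code()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

blosum62 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      tab <<- e$BLOSUM62
    }
    tab
  }
})

#' Read an aligned FASTA file (protein or DNA rows)
#'
#' @param path FASTA path.
#' @return A named character vector of equal-length aligned rows (uppercase).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment must contain at least 2 rows")
  rows <- toupper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  rows
}

#' Thread in-frame coding sequences onto a protein alignment
#'
#' Produces a codon-level alignment ("alignment by translation"): every
#' protein gap column becomes `---`, every residue becomes its source codon.
#' A single terminal stop codon on a CDS is trimmed when the protein row lacks
#' it. The translation of each CDS must reproduce its ungapped protein row
#' (`X` matches any residue).
#'
#' @param protein_msa Named character vector of aligned amino-acid rows
#'   (letters, `X`, gap `-`).
#' @param cds Named character vector of in-frame CDS, ids matching
#'   `protein_msa`.
#' @return A list of class `"codon_msa"` with `ids`, `aa` (protein rows) and
#'   `dna` (codon rows, length 3x the protein column count).
#' @export
thread_codons <- function(protein_msa, cds) {
  ids <- names(protein_msa)
  if (is.null(ids) || !all(ids %in% names(cds))) {
    stop("threading error: CDS missing for some alignment ids")
  }
  dna <- character(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    aa_row <- strsplit(protein_msa[[id]], "", fixed = TRUE)[[1]]
    aa_ungapped <- aa_row[aa_row != "-"]
    s <- toupper(cds[[id]])
    if (nchar(s) %% 3L != 0L) {
      stop("threading error for '", id, "': CDS length not a multiple of 3")
    }
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(cods) == length(aa_ungapped) + 1L &&
        cods[length(cods)] %in% STOP_CODONS) {
      cods <- cods[-length(cods)]
    }
    if (length(cods) != length(aa_ungapped)) {
      stop("threading error for '", id, "': CDS has ", length(cods),
           " codons but protein row has ", length(aa_ungapped), " residues")
    }
    tr <- translate_codons(cods)
    bad <- which(tr != aa_ungapped & aa_ungapped != "X" & tr != "X")
    if (length(bad)) {
      stop("threading error for '", id, "': codon ", bad[1L], " ('",
           cods[bad[1L]], "') translates to '", tr[bad[1L]],
           "', protein row has '", aa_ungapped[bad[1L]], "'")
    }
    out <- character(length(aa_row))
    out[aa_row == "-"] <- "---"
    out[aa_row != "-"] <- cods
    dna[k] <- paste(out, collapse = "")
  }
  structure(list(ids = ids, aa = unname(protein_msa), dna = dna),
            class = "codon_msa")
}

#' Percent pairwise identity between two aligned rows
#'
#' Columns with a gap in either row are excluded from numerator and
#' denominator (pairwise gap deletion).
#'
#' @param row_i,row_j Equal-length aligned strings.
#' @return Percent identity over gap-free columns.
#' @export
pairwise_identity <- function(row_i, row_j) {
  a <- strsplit(row_i, "", fixed = TRUE)[[1]]
  b <- strsplit(row_j, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("undefined identity: no gap-free columns")
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Percent pairwise similarity between two aligned amino-acid rows
#'
#' The fraction of comparable columns whose BLOSUM62 score is strictly
#' positive; columns containing a gap or `X` in either row are excluded.
#'
#' @param aa_row_i,aa_row_j Equal-length aligned amino-acid strings.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return Percent similarity.
#' @export
pairwise_similarity <- function(aa_row_i, aa_row_j, matrix = NULL) {
  if (is.null(matrix)) matrix <- blosum62()
  a <- strsplit(aa_row_i, "", fixed = TRUE)[[1]]
  b <- strsplit(aa_row_j, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  ok <- a != "-" & b != "-" & a != "X" & b != "X"
  if (!any(ok)) stop("undefined similarity: no comparable columns")
  sc <- matrix[cbind(a[ok], b[ok])]
  100 * sum(sc > 0) / sum(ok)
}

slice_codon_msa <- function(cmsa, region) {
  cs <- region$start; ce <- region$end
  ncol_aa <- nchar(cmsa$aa[1])
  if (cs < 0L || ce > ncol_aa || ce <= cs) {
    stop("region out of alignment bounds: ", region$name)
  }
  structure(list(ids = cmsa$ids,
                 aa = substring(cmsa$aa, cs + 1L, ce),
                 dna = substring(cmsa$dna, 3L * cs + 1L, 3L * ce)),
            class = "codon_msa")
}

#' Conservation report over a codon alignment
#'
#' Mean pairwise DNA identity, amino-acid identity and BLOSUM62 similarity
#' over all unordered row pairs, optionally restricted to a region of
#' protein-alignment columns (the DNA rows are sliced through the 3x codon
#' mapping so DNA and AA cover exactly the same residues). The differences
#' are DNA minus AA, so a negative `diff_identity` means DNA is *less*
#' conserved than protein at the identity level.
#'
#' @param cmsa A `codon_msa` from [thread_codons()].
#' @param region Optional single-row `data.frame` with `name`, `start`, `end`
#'   (0-based half-open protein-alignment columns).
#' @return A list of class `"conservation_report"`: `mean_dna_identity`,
#'   `mean_aa_identity`, `mean_aa_similarity`, `diff_identity`,
#'   `diff_similarity`, `n_pairs` (and `region` when sliced).
#' @export
conservation_report <- function(cmsa, region = NULL) {
  stopifnot(inherits(cmsa, "codon_msa"), length(cmsa$ids) >= 2L)
  if (!is.null(region)) cmsa <- slice_codon_msa(cmsa, region)
  n <- length(cmsa$ids)
  dna_id <- aa_id <- aa_sim <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dna_id <- c(dna_id, pairwise_identity(cmsa$dna[i], cmsa$dna[j]))
      aa_id <- c(aa_id, pairwise_identity(cmsa$aa[i], cmsa$aa[j]))
      aa_sim <- c(aa_sim, pairwise_similarity(cmsa$aa[i], cmsa$aa[j]))
    }
  }
  rep <- list(mean_dna_identity = mean(dna_id),
              mean_aa_identity = mean(aa_id),
              mean_aa_similarity = mean(aa_sim),
              diff_identity = mean(dna_id) - mean(aa_id),
              diff_similarity = mean(dna_id) - mean(aa_sim),
              n_pairs = length(dna_id))
  if (!is.null(region)) rep$region <- region$name
  structure(rep, class = "conservation_report")
}

#' Count PQS per region with boundary double counting
#'
#' A PQS overlapping a region by at least 1 bp counts for that region;
#' a PQS straddling a boundary counts for every region it touches (the double
#' counting is intended and reported separately).
#'
#' @param pqs Feature `data.frame` of PQS intervals on CDS coordinates.
#' @param regions Feature-style `data.frame` with `name`, `start`, `end` on
#'   the same coordinates.
#' @return A list with `counts` (named per region), `n_boundary` (PQS counted
#'   more than once) and `n_distinct`.
#' @export
count_pqs_by_region <- function(pqs, regions) {
  counts <- stats::setNames(integer(nrow(regions)), regions$name)
  touched <- integer(nrow(pqs))
  for (r in seq_len(nrow(regions))) {
    hit <- pqs$end > regions$start[r] & pqs$start < regions$end[r]
    counts[r] <- sum(hit)
    touched <- touched + hit
  }
  list(counts = counts, n_boundary = sum(touched > 1L),
       n_distinct = sum(touched > 0L))
}

#' Read a region specification file
#'
#' A flat text file with three tab-separated columns `name`, `start`, `end`
#' in 0-based half-open protein-alignment columns; `#` lines are comments.
#' An example layout for a Het-A-like GAG alignment (N-terminal fragment,
#' conserved core, C-terminal fragment) ships as
#' `system.file("extdata", "heta_gag_regions.tsv", package = "g4telo")`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `name`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "start", "end"),
                          stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("region format error: end must be > start")
  df
}
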