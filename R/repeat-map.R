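# Strand-aware intersection of PQS hits with repeat annotations and the
# derived orientation, density, bp-proportion and partition statistics.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start + 1L, df$end),
                         strand = chartr(".", "*", df$strand))
}

#' Intersect PQS hits with repeat features
#'
#' bedtools-intersect semantics: one record per (hit, repeat) pair overlapping
#' by at least 1 bp, so a PQS overlapping two repeats yields two records. The
#' relative orientation is `sense` when the G-rich strand of the PQS equals
#' the repeat's coding-strand orientation, `antisense` otherwise. Hits
#' overlapping no repeat are returned separately as `unassigned`.
#'
#' @param hits PQS hit `data.frame` (from [scan()] or [read_features()]).
#' @param repeats Repeat feature `data.frame` with `family` (and optionally
#'   `clade`, `element_id`, `is_fragment`) columns; strand must be `+` or `-`.
#' @return A list with `records` (one row per overlapping pair: hit columns
#'   prefixed `pqs_`, repeat columns prefixed `repeat_`, plus
#'   `relative_orientation` and `overlap_bp`) and `unassigned` (hit rows with
#'   no overlap).
#' @export
intersect_pqs_repeats <- function(hits, repeats) {
  stopifnot("family" %in% names(repeats))
  if (any(!repeats$strand %in% c("+", "-"))) {
    stop("repeat features must carry strand + or -")
  }
  if (nrow(hits) == 0L) {
    return(list(records = data.frame(), unassigned = hits))
  }
  ov <- GenomicRanges::findOverlaps(as_granges0(hits), as_granges0(repeats),
                                    minoverlap = 1L, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (!length(qh)) {
    return(list(records = data.frame(), unassigned = hits))
  }
  overlap_bp <- pmin(hits$end[qh], repeats$end[sh]) -
    pmax(hits$start[qh], repeats$start[sh])
  rec <- data.frame(
    seqid = hits$seqid[qh],
    pqs_start = hits$start[qh], pqs_end = hits$end[qh],
    pqs_strand = hits$strand[qh], pqs_score = hits$score[qh],
    pqs_id = qh,
    repeat_start = repeats$start[sh], repeat_end = repeats$end[sh],
    repeat_strand = repeats$strand[sh], repeat_id = sh,
    family = repeats$family[sh],
    relative_orientation = ifelse(hits$strand[qh] == repeats$strand[sh],
                                  "sense", "antisense"),
    overlap_bp = overlap_bp,
    stringsAsFactors = FALSE)
  if ("clade" %in% names(repeats)) rec$clade <- repeats$clade[sh]
  if ("element_id" %in% names(repeats)) rec$element_id <- repeats$element_id[sh]
  list(records = rec, unassigned = hits[-unique(qh), , drop = FALSE])
}

#' Per-family orientation counts
#'
#' Counts records per family in the four cells of (repeat genomic strand
#' `+`/`-`) x (relative orientation `sense`/`antisense`); the four counters of
#' a family sum to its record count.
#'
#' @param records The `records` table from [intersect_pqs_repeats()].
#' @return A `data.frame` with `family`, `repeat_strand`, `orientation`, `n`
#'   (complete four-cell grid per family).
#' @export
orientation_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to summarize")
  grid <- expand.grid(family = unique(records$family),
                      repeat_strand = c("+", "-"),
                      orientation = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(f, s, o) {
    sum(records$family == f & records$repeat_strand == s &
          records$relative_orientation == o)
  }, grid$family, grid$repeat_strand, grid$orientation)
  grid[order(grid$family, grid$repeat_strand, grid$orientation), ]
}

overlap_len0 <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' PQS density per 10 kbp
#'
#' A hit is assigned to the region when its midpoint lies inside it (the
#' midpoint rule avoids double counting at region boundaries). N bases inside
#' the region, supplied as mask intervals, are removed from the effective
#' length before normalizing.
#'
#' @param hits Hit `data.frame`.
#' @param region A single-row feature `data.frame` (seqid, start, end).
#' @param n_mask Optional feature `data.frame` of N intervals on the same
#'   seqid.
#' @return Density in PQS per 10 kbp.
#' @export
pqs_density <- function(hits, region, n_mask = NULL) {
  stopifnot(nrow(region) == 1L)
  eff <- region$end - region$start
  if (!is.null(n_mask) && nrow(n_mask)) {
    nm <- n_mask[n_mask$seqid == region$seqid, , drop = FALSE]
    if (nrow(nm)) {
      red <- IRanges::reduce(IRanges::IRanges(nm$start + 1L, nm$end))
      eff <- eff - sum(overlap_len0(IRanges::start(red) - 1L, IRanges::end(red),
                                    region$start, region$end))
    }
  }
  if (eff <= 0L) stop("undefined density: zero effective region length after N removal")
  mids <- (hits$start + hits$end) / 2
  cnt <- sum(hits$seqid == region$seqid & mids >= region$start & mids < region$end)
  10000 * cnt / eff
}

#' PQS base-pair proportion per family
#'
#' For each family, the summed PQS overlap in bp divided by the summed length
#' of the family's PQS-containing fragments, as a percentage. Fragments
#' without any PQS are excluded from the denominator; families with no
#' PQS-containing fragment are excluded from the output entirely.
#'
#' @param records The `records` table from [intersect_pqs_repeats()].
#' @param fragments The repeat `data.frame` that was intersected (row order
#'   must match; `repeat_id` indexes into it).
#' @return A `data.frame` with `family`, `n_fragments`, `pqs_bp`,
#'   `fragment_bp`, `percent`.
#' @export
bp_proportion <- function(records, fragments) {
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(family = character(0), n_fragments = integer(0),
                      pqs_bp = integer(0), fragment_bp = integer(0),
                      percent = numeric(0)))
  }
  fams <- sort(unique(records$family))
  out <- lapply(fams, function(f) {
    rec <- records[records$family == f, , drop = FALSE]
    frag_idx <- sort(unique(rec$repeat_id))
    flen <- sum(fragments$end[frag_idx] - fragments$start[frag_idx])
    data.frame(family = f, n_fragments = length(frag_idx),
               pqs_bp = sum(rec$overlap_bp), fragment_bp = flen,
               percent = 100 * sum(rec$overlap_bp) / flen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome partition summary
#'
#' The fraction of the genome covered by repeats (after merging overlaps) and
#' the fraction of all PQS falling inside repeats (midpoint rule, so each PQS
#' is counted at most once regardless of how many repeat features it touches).
#'
#' @param hits Hit `data.frame`.
#' @param repeats Repeat feature `data.frame`.
#' @param genome_length Total genome length in bp.
#' @return A list with `repeat_percent` and `pqs_in_repeat_percent`.
#' @export
partition_summary <- function(hits, repeats, genome_length) {
  stopifnot(genome_length > 0)
  if (nrow(repeats) == 0L) {
    return(list(repeat_percent = 0, pqs_in_repeat_percent = 0))
  }
  red <- GenomicRanges::reduce(as_granges0(repeats), ignore.strand = TRUE)
  repeat_bp <- sum(IRanges::width(red))
  if (nrow(hits) == 0L) {
    return(list(repeat_percent = 100 * repeat_bp / genome_length,
                pqs_in_repeat_percent = 0))
  }
  mids <- (hits$start + hits$end) / 2
  rdf <- data.frame(seqid = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red))
  inside <- vapply(seq_len(nrow(hits)), function(i) {
    any(rdf$seqid == hits$seqid[i] & mids[i] >= rdf$start & mids[i] < rdf$end)
  }, logical(1))
  list(repeat_percent = 100 * repeat_bp / genome_length,
       pqs_in_repeat_percent = 100 * mean(inside))
}
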