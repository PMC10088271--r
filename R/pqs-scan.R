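#' Scanner parameters
#'
#' Parameters of the G-run quadruplex scanner. The default score threshold of
#' 47 is the point at which predicted motifs have been reported to match
#' experimental G4 formation in about three quarters of cases; the additive
#' scoring scheme (tetrad bonus, loop penalty beyond a free allowance, defect
#' penalty) is fully specified so that scores are exactly reproducible: a
#' canonical three-tetrad motif with short loops scores 60 and clears the
#' default threshold, while a perfect two-tetrad motif scores 30 and does not.
#'
#' @param min_run,max_run Minimum/maximum number of guanines in a G-run.
#' @param loop_min,loop_max Allowed loop lengths between consecutive runs.
#' @param max_len Maximum total candidate length in bp.
#' @param max_defective_runs Maximum number of runs carrying a single-base
#'   bulge (0 or 1).
#' @param min_score Minimum reported score.
#' @param tetrad_bonus Score contribution per stacked tetrad beyond the first.
#' @param loop_penalty Penalty per loop base beyond `loop_free`.
#' @param loop_free Loop length free of penalty.
#' @param defect_penalty Penalty per defective (bulged) run.
#' @return A list of class `"scan_params"`.
#' @export
scan_params <- function(min_run = 3L, max_run = 7L, loop_min = 1L,
                        loop_max = 12L, max_len = 50L,
                        max_defective_runs = 1L, min_score = 47L,
                        tetrad_bonus = 30L, loop_penalty = 2L,
                        loop_free = 3L, defect_penalty = 10L) {
  p <- list(min_run = as.integer(min_run), max_run = as.integer(max_run),
            loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
            max_len = as.integer(max_len),
            max_defective_runs = as.integer(max_defective_runs),
            min_score = as.integer(min_score),
            tetrad_bonus = as.integer(tetrad_bonus),
            loop_penalty = as.integer(loop_penalty),
            loop_free = as.integer(loop_free),
            defect_penalty = as.integer(defect_penalty))
  stopifnot(p$min_run >= 2L, p$max_run >= p$min_run, p$loop_min >= 1L,
            p$loop_max >= p$loop_min,
            p$max_len >= 4L * p$min_run + 3L * p$loop_min,
            p$max_defective_runs %in% c(0L, 1L), p$min_score > 0L)
  class(p) <- "scan_params"
  p
}

empty_hits <- function() {
  data.frame(seqid = character(0), start = integer(0), end = integer(0),
             strand = character(0), type = character(0), score = integer(0),
             n_tetrads = integer(0), n_defects = integer(0),
             loops = character(0), runs = character(0), motif = character(0),
             stringsAsFactors = FALSE)
}

# All run spans usable as one of the four G-tracts of a candidate, on the
# given sequence axis. A span is either all-G with min_run..max_run bases, or
# a "defective" run: two G stretches separated by exactly one non-G, non-N
# base, together holding min_run..max_run G's. gmax is the longest contiguous
# G stretch inside the span (the tetrad contribution ceiling).
run_spans <- function(chars, params) {
  isg <- chars == "G"
  r <- rle(isg)
  rend <- cumsum(r$lengths)            # 1-based inclusive end of each block
  rstart <- rend - r$lengths + 1L      # 1-based start
  gi <- which(r$values)
  out_s <- integer(0); out_e <- integer(0); out_g <- integer(0); out_d <- integer(0)
  for (k in gi) {
    L <- r$lengths[k]
    if (L >= params$min_run) {
      for (w in params$min_run:min(params$max_run, L)) {
        s <- rstart[k]:(rend[k] - w + 1L)
        out_s <- c(out_s, s); out_e <- c(out_e, s + w)
        out_g <- c(out_g, rep(w, length(s))); out_d <- c(out_d, rep(0L, length(s)))
      }
    }
  }
  if (params$max_defective_runs > 0L) {
    for (idx in seq_along(gi)[-length(gi)]) {
      k1 <- gi[idx]; k2 <- gi[idx + 1L]
      gap <- rstart[k2] - rend[k1] - 1L
      if (gap != 1L) next
      if (chars[rend[k1] + 1L] == "N") next
      L1 <- r$lengths[k1]; L2 <- r$lengths[k2]
      for (i in 1:min(L1, params$max_run - 1L)) {
        jmax <- min(L2, params$max_run - i)
        jmin <- max(1L, params$min_run - i)
        if (jmin > jmax) next
        for (j in jmin:jmax) {
          out_s <- c(out_s, rend[k1] - i + 1L)
          out_e <- c(out_e, rstart[k2] + j - 1L + 1L)
          out_g <- c(out_g, max(i, j)); out_d <- c(out_d, 1L)
        }
      }
    }
  }
  if (!length(out_s)) {
    return(data.frame(start = integer(0), end = integer(0), gmax = integer(0),
                      defect = integer(0)))
  }
  # 0-based half-open spans, sorted by start then end
  df <- data.frame(start = out_s - 1L, end = out_e - 1L, gmax = out_g, defect = out_d)
  df[order(df$start, df$end, df$defect), , drop = FALSE]
}

#' Enumerate all quadruplex candidates on one strand
#'
#' Emits every 4-tuple of G-runs satisfying the run, loop, length, defect and
#' N constraints, scored as
#' `tetrad_bonus * (t - 1) - loop_penalty * sum(max(0, l_i - loop_free)) -
#' defect_penalty * n_defects`, where `t` is the minimum over the four runs of
#' the longest contiguous G stretch inside the run. Candidates scoring below
#' `min_score` or spanning an `N` are dropped. No overlap resolution is done
#' here; see [scan()].
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @param params A [scan_params()] object.
#' @param seqid Sequence name for the output rows.
#' @return A hit `data.frame` (strand `"+"` on the given axis), one row per
#'   candidate.
#' @export
enumerate_candidates <- function(seq, params = scan_params(), seqid = "seq") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 4L * params$min_run + 3L * params$loop_min) return(empty_hits())
  rs <- run_spans(chars, params)
  m <- nrow(rs)
  if (m < 4L) return(empty_hits())
  cumn <- cumsum(chars == "N")                  # N count in [1..i]
  n_in <- function(s, e) {                      # N count in 0-based [s,e)
    cumn[e] - if (s > 0L) cumn[s] else 0L
  }
  s_ <- rs$start; e_ <- rs$end; g_ <- rs$gmax; d_ <- rs$defect
  # successors of run a: runs whose start lies in [end_a+loop_min, end_a+loop_max];
  # s_ is sorted, so the index range comes from two binary searches
  succ <- function(a) {
    lo <- findInterval(e_[a] + params$loop_min - 1L, s_) + 1L
    hi <- findInterval(e_[a] + params$loop_max, s_)
    if (lo > hi) integer(0) else lo:hi
  }
  # exact upper bound on the final score of any extension of a partial chain:
  # t can only shrink, loop/defect penalties only grow
  bound_ok <- function(tmin, pen) {
    params$tetrad_bonus * (tmin - 1L) - pen >= params$min_score
  }
  res <- vector("list", 0L)
  for (a in seq_len(m)) {
    lim <- s_[a] + params$max_len
    if (4L * params$min_run + 3L * params$loop_min + s_[a] > n) next
    if (!bound_ok(g_[a], params$defect_penalty * d_[a])) next
    for (b in succ(a)) {
      if (e_[b] > lim) next
      db <- d_[a] + d_[b]
      if (db > params$max_defective_runs) next
      l1 <- s_[b] - e_[a]
      pen_b <- params$loop_penalty * max(0L, l1 - params$loop_free) +
        params$defect_penalty * db
      t_b <- min(g_[a], g_[b])
      if (!bound_ok(t_b, pen_b)) next
      for (cc in succ(b)) {
        if (e_[cc] > lim) next
        dc <- db + d_[cc]
        if (dc > params$max_defective_runs) next
        l2 <- s_[cc] - e_[b]
        pen_c <- pen_b + params$loop_penalty * max(0L, l2 - params$loop_free) +
          params$defect_penalty * (dc - db)
        t_c <- min(t_b, g_[cc])
        if (!bound_ok(t_c, pen_c)) next
        for (dd in succ(cc)) {
          if (e_[dd] > lim) next
          nd <- dc + d_[dd]
          if (nd > params$max_defective_runs) next
          if (n_in(s_[a], e_[dd]) > 0L) next
          t <- min(t_c, g_[dd])
          l3 <- s_[dd] - e_[cc]
          score <- params$tetrad_bonus * (t - 1L) -
            params$loop_penalty * (max(0L, l1 - params$loop_free) +
                                   max(0L, l2 - params$loop_free) +
                                   max(0L, l3 - params$loop_free)) -
            params$defect_penalty * nd
          if (score < params$min_score) next
          res[[length(res) + 1L]] <- list(
            start = s_[a], end = e_[dd], score = score, n_tetrads = t,
            n_defects = nd, loops = paste(l1, l2, l3, sep = ","),
            runs = paste(sprintf("%d-%d", c(s_[a], s_[b], s_[cc], s_[dd]) - s_[a],
                                 c(e_[a], e_[b], e_[cc], e_[dd]) - s_[a]),
                         collapse = ","))
        }
      }
    }
  }
  if (!length(res)) return(empty_hits())
  df <- do.call(rbind, lapply(res, function(x) {
    data.frame(seqid = seqid, start = x$start, end = x$end, strand = "+",
               type = "PQS", score = x$score, n_tetrads = x$n_tetrads,
               n_defects = x$n_defects, loops = x$loops, runs = x$runs,
               stringsAsFactors = FALSE)
  }))
  df$motif <- substring(seq, df$start + 1L, df$end)
  rownames(df) <- NULL
  df
}

#' Greedy overlap resolution among same-strand candidates
#'
#' Repeatedly keeps the highest-scoring candidate and discards candidates
#' overlapping it on the same axis. Ties are broken deterministically:
#' leftmost start, then shortest, then lexicographically smallest motif.
#'
#' @param cands Candidate `data.frame` from [enumerate_candidates()].
#' @return The selected subset, sorted by start.
#' @export
greedy_select <- function(cands) {
  if (nrow(cands) < 2L) return(cands)
  ord <- order(-cands$score, cands$start, cands$end - cands$start, cands$motif)
  cands <- cands[ord, , drop = FALSE]
  keep <- logical(nrow(cands))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(cands))) {
    s <- cands$start[i]; e <- cands$end[i]
    if (!any(s < ke & e > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, s); ke <- c(ke, e)
    }
  }
  out <- cands[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan both strands of a sequence for PQS
#'
#' The forward strand is scanned directly; the reverse strand is scanned on
#' the reverse complement and hit coordinates are mapped back to the forward
#' axis with strand `"-"`. Overlaps are resolved greedily within each strand
#' (in the orientation of the G-rich strand, which makes the output exactly
#' mirror-symmetric under reverse complement); overlapping hits on opposite
#' strands are both kept. `motif`, `runs` and `loops` always describe the
#' G-rich strand 5'->3'; `runs` are relative to the motif start.
#'
#' @param seq DNA string, or a length-1 named character vector.
#' @param params A [scan_params()] object.
#' @param seqid Sequence name; defaults to the name of `seq` if present.
#' @return A hit `data.frame` sorted by (seqid, start).
#' @export
scan <- function(seq, params = scan_params(), seqid = NULL) {
  if (is.null(seqid)) seqid <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- toupper(unname(seq[[1]]))
  n <- nchar(seq)
  fwd <- greedy_select(enumerate_candidates(seq, params, seqid = seqid))
  rc <- revcomp(seq)
  rev <- greedy_select(enumerate_candidates(rc, params, seqid = seqid))
  if (nrow(rev)) {
    new_start <- n - rev$end
    rev$end <- n - rev$start
    rev$start <- new_start
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  out <- out[order(out$seqid, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every record of a FASTA file and write hits as GFF3
#'
#' @param path Input FASTA path.
#' @param out Output GFF3 path (type column `PQS`, score column = scanner
#'   score). If `NULL`, no file is written.
#' @param params A [scan_params()] object.
#' @return The combined hit `data.frame`, invisibly if `out` is given.
#' @export
scan_fasta <- function(path, out = NULL, params = scan_params()) {
  seqs <- read_fasta(path)
  hits <- do.call(rbind, lapply(names(seqs), function(id) {
    scan(seqs[[id]], params, seqid = id)
  }))
  if (is.null(hits)) hits <- empty_hits()
  if (!is.null(out)) {
    write_features(hits, out, "gff3")
    return(invisible(hits))
  }
  hits
}
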