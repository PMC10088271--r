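# Independent brute-force oracles used to validate the scanner, the NG86
# pathway counting and the exact binomial test. These are deliberately naive
# (regex validity checks, exhaustive permutation / outcome enumeration) and
# share no code with the package implementation.

# Every valid run span by exhaustive substring testing: all-G substrings of
# min_run..max_run bases, or G+ X G+ substrings (X a single non-G, non-N
# base) holding min_run..max_run G's.
oracle_run_spans <- function(seq, params) {
  n <- nchar(seq)
  out <- list()
  for (w in params$min_run:(params$max_run + 1L)) {
    if (w > n) break
    starts <- 1:(n - w + 1L)
    subs <- substring(seq, starts, starts + w - 1L)
    perfect <- grepl("^G+$", subs) & w >= params$min_run & w <= params$max_run
    gcount <- nchar(gsub("[^G]", "", subs))
    bulged <- grepl("^G+[^GN]G+$", subs) &
      gcount >= params$min_run & gcount <= params$max_run
    keep <- which(perfect | bulged)
    for (i in keep) {
      r <- rle(strsplit(subs[i], "", fixed = TRUE)[[1]] == "G")
      gmax <- max(r$lengths[r$values])
      out[[length(out) + 1L]] <- data.frame(
        start = starts[i] - 1L, end = starts[i] + w - 1L, gmax = gmax,
        defect = as.integer(bulged[i]))
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      gmax = integer(0), defect = integer(0)))
  }
  do.call(rbind, out)
}

# Exhaustive candidate enumeration: all ordered 4-tuples of valid run spans.
# A span whose best conceivable score (tetrad bonus from its own gmax minus
# its own defect penalty, with zero loop penalties) is already below
# min_score can never be part of a reported candidate, since the candidate's
# t is the minimum gmax and penalties only subtract; dropping those spans
# first keeps the enumeration exhaustive over reportable candidates.
oracle_enumerate <- function(seq, params) {
  seq <- toupper(seq)
  rs <- oracle_run_spans(seq, params)
  feasible <- params$tetrad_bonus * (rs$gmax - 1L) -
    params$defect_penalty * rs$defect >= params$min_score
  rs <- rs[feasible, , drop = FALSE]
  rs <- rs[order(rs$start, rs$end, rs$defect), , drop = FALSE]
  m <- nrow(rs)
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = integer(0), motif = character(0))
  if (m < 4L) return(empty)
  # adjacency by loop-length bounds, computed once
  gap <- outer(rs$end, rs$start, function(e, s) s - e)
  ok <- gap >= params$loop_min & gap <= params$loop_max
  succ <- lapply(seq_len(m), function(a) which(ok[a, ]))
  res <- list()
  for (a in seq_len(m)) for (b in succ[[a]]) for (cc in succ[[b]]) {
    for (dd in succ[[cc]]) {
      if (rs$end[dd] - rs$start[a] > params$max_len) next
      ndef <- rs$defect[a] + rs$defect[b] + rs$defect[cc] + rs$defect[dd]
      if (ndef > params$max_defective_runs) next
      motif <- substring(seq, rs$start[a] + 1L, rs$end[dd])
      if (grepl("N", motif, fixed = TRUE)) next
      la <- rs$start[b] - rs$end[a]
      lb <- rs$start[cc] - rs$end[b]
      lc <- rs$start[dd] - rs$end[cc]
      t <- min(rs$gmax[c(a, b, cc, dd)])
      score <- params$tetrad_bonus * (t - 1L) -
        params$loop_penalty * sum(pmax(0L, c(la, lb, lc) - params$loop_free)) -
        params$defect_penalty * ndef
      if (score < params$min_score) next
      res[[length(res) + 1L]] <- data.frame(
        start = rs$start[a], end = rs$end[dd], score = score, motif = motif,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

# Independent greedy selector: repeatedly take the best remaining candidate
# (highest score; ties leftmost start, then shortest, then smallest motif)
# and delete everything overlapping it.
oracle_greedy <- function(cands) {
  kept <- list()
  while (nrow(cands)) {
    o <- order(-cands$score, cands$start, cands$end - cands$start, cands$motif)
    best <- cands[o[1L], , drop = FALSE]
    kept[[length(kept) + 1L]] <- best
    cands <- cands[cands$end <= best$start | cands$start >= best$end, ,
                   drop = FALSE]
  }
  if (!length(kept)) return(cands)
  out <- do.call(rbind, kept)
  out[order(out$start), , drop = FALSE]
}

oracle_scan <- function(seq, params) {
  seq <- toupper(seq)
  n <- nchar(seq)
  fwd <- oracle_greedy(oracle_enumerate(seq, params))
  if (nrow(fwd)) fwd$strand <- "+"
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "",
                           fixed = TRUE)[[1]]), collapse = "")
  rev <- oracle_greedy(oracle_enumerate(rc, params))
  if (nrow(rev)) {
    rev$strand <- "-"
    new_start <- n - rev$end
    rev$end <- n - rev$start
    rev$start <- new_start
  }
  out <- rbind(fwd, rev)
  if (!nrow(out)) return(out)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Comparable projection of a hit table for oracle equivalence checks.
hit_key <- function(df) {
  if (!nrow(df)) return(character(0))
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  paste(df$start, df$end, df$strand, df$score, df$motif)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Brute-force NG86 pathway oracle: enumerates permutations explicitly via
# recursion and counts synonymous/nonsynonymous steps, dropping pathways
# through stops.
oracle_path_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (!length(dpos)) return(c(0, 0))
  paths <- list()
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- prefix
      return()
    }
    for (p in remaining) recurse(c(prefix, p), setdiff(remaining, p))
  }
  recurse(integer(0), dpos)
  syn <- c(); nsyn <- c()
  for (path in paths) {
    cur <- a; s <- 0; ns <- 0; ok <- TRUE
    for (p in path) {
      nxt <- cur; nxt[p] <- b[p]
      if (code[[paste(nxt, collapse = "")]] == "*") { ok <- FALSE; break }
      if (code[[paste(cur, collapse = "")]] == code[[paste(nxt, collapse = "")]]) {
        s <- s + 1
      } else ns <- ns + 1
      cur <- nxt
    }
    if (ok) { syn <- c(syn, s); nsyn <- c(nsyn, ns) }
  }
  if (!length(syn)) return(c(NA_real_, NA_real_))
  c(mean(syn), mean(nsyn))
}

# Exact two-sided binomial probability by exhaustive enumeration over counts.
oracle_binom_two_sided <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-12)])
}

random_sense_codon <- function() {
  code <- Biostrings::GENETIC_CODE
  sample(names(code)[code != "*"], 1L)
}
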