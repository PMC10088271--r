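# Codon-level selection signatures: Nei-Gojobori (1986) synonymous /
# nonsynonymous site and difference counting with Jukes-Cantor correction,
# delta-GC against full synonymous codon families, and third-position
# cytosine / amino-acid usage contrasts between PQS and non-PQS loci.

.ng_cache <- new.env(parent = emptyenv())

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[!gc %in% "*"]
}

#' Synonymous and nonsynonymous site counts of one codon (NG86)
#'
#' At each of the three positions the synonymous fraction is the number of
#' the single-nucleotide changes that are synonymous divided by the number of
#' changes not producing a stop codon (changes to stop codons are excluded
#' from both numerator and denominator, and the remaining fraction of the
#' position is nonsynonymous, so S + N = 3 for every codon).
#'
#' @param codon A sense codon (3-letter DNA string).
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  gc <- genetic_code()
  if (is.na(gc[codon]) || gc[[codon]] == "*") {
    stop("ng86_site_counts: invalid or stop codon '", codon, "'")
  }
  key <- paste0("S_", codon)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa0 <- gc[[codon]]
  S <- 0
  for (pos in 1:3) {
    alts <- bases[bases != ch[pos]]
    muts <- vapply(alts, function(b) {
      x <- ch; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    valid <- muts[gc[muts] != "*"]
    if (length(valid)) S <- S + sum(gc[valid] == aa0) / length(valid)
  }
  out <- c(S = S, N = 3 - S)
  .ng_cache[[key]] <- out
  out
}

# Mean synonymous/nonsynonymous step counts over all equally weighted
# mutational pathways between two sense codons, pathways passing through a
# stop codon excluded (remaining pathways re-weighted). Returns c(Sd, Nd), or
# c(NA, NA) if every pathway is blocked.
ng86_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  key <- paste0("D_", c1, "_", c2)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  gc <- genetic_code()
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(a != b)
  perms <- switch(as.character(length(dpos)),
                  "1" = list(dpos),
                  "2" = list(dpos, rev(dpos)),
                  "3" = {
                    p <- list()
                    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
                      if (length(unique(c(i, j, k))) == 3L) {
                        p[[length(p) + 1L]] <- dpos[c(i, j, k)]
                      }
                    }
                    p
                  })
  syn <- numeric(0); nsyn <- numeric(0)
  for (ord in perms) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      cod_from <- paste(cur, collapse = ""); cod_to <- paste(nxt, collapse = "")
      if (gc[[cod_to]] == "*") { ok <- FALSE; break }
      if (gc[[cod_from]] == gc[[cod_to]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { syn <- c(syn, s); nsyn <- c(nsyn, n) }
  }
  out <- if (length(syn)) c(Sd = mean(syn), Nd = mean(nsyn)) else c(Sd = NA_real_, Nd = NA_real_)
  .ng_cache[[key]] <- out
  out
}

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)

# Lookup tables over the 61 sense codons: per-codon S sites and pairwise
# Sd/Nd matrices, built once from ng86_site_counts()/ng86_path_diffs().
ng_tables <- function() {
  if (!is.null(.ng_cache$tables)) return(.ng_cache$tables)
  sc <- sense_codons()
  Svec <- vapply(sc, function(c) ng86_site_counts(c)[["S"]], numeric(1))
  Sd <- Nd <- matrix(NA_real_, length(sc), length(sc), dimnames = list(sc, sc))
  for (i in seq_along(sc)) {
    for (j in i:length(sc)) {
      d <- ng86_path_diffs(sc[i], sc[j])
      Sd[i, j] <- Sd[j, i] <- d[["Sd"]]
      Nd[i, j] <- Nd[j, i] <- d[["Nd"]]
    }
  }
  .ng_cache$tables <- list(S = Svec, Sd = Sd, Nd = Nd)
  .ng_cache$tables
}

#' Pairwise Nei-Gojobori dN/dS with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; for codon pairs differing
#' at more than one position all mutational pathways are weighted equally and
#' pathways through stop codons are excluded. Codon pairs containing a gap,
#' an `N` or a stop codon are skipped (and counted). Proportions are
#' corrected with the Jukes-Cantor transform `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param cds_i,cds_j Equal-length in-frame (possibly gapped) DNA strings.
#' @return A list of class `"dnds_result"`: `S_sites`, `N_sites`, `Sd`, `Nd`,
#'   `ps`, `pn`, `ds`, `dn`, `ratio` (NA when ds = dn = 0, `Inf` when ds = 0
#'   and dn > 0), `n_codons` (comparable), `n_skipped`.
#' @export
ng86_pairwise <- function(cds_i, cds_j) {
  cds_i <- toupper(cds_i); cds_j <- toupper(cds_j)
  stopifnot(nchar(cds_i) == nchar(cds_j), nchar(cds_i) %% 3L == 0L)
  idx <- seq(1L, nchar(cds_i), 3L)
  ci <- substring(cds_i, idx, idx + 2L)
  cj <- substring(cds_j, idx, idx + 2L)
  tab <- ng_tables()
  sense <- names(tab$S)
  usable <- ci %in% sense & cj %in% sense
  n_skipped <- sum(!usable)
  ci <- ci[usable]; cj <- cj[usable]
  sd_k <- tab$Sd[cbind(ci, cj)]
  blocked <- is.na(sd_k)
  n_skipped <- n_skipped + sum(blocked)
  ci <- ci[!blocked]; cj <- cj[!blocked]; sd_k <- sd_k[!blocked]
  nd_k <- tab$Nd[cbind(ci, cj)]
  S_sites <- sum((tab$S[ci] + tab$S[cj]) / 2)
  N_sites <- 3 * length(ci) - S_sites
  Sd <- sum(sd_k); Nd <- sum(nd_k)
  n_codons <- length(ci)
  ps <- if (S_sites > 0) Sd / S_sites else 0
  pn <- if (N_sites > 0) Nd / N_sites else 0
  if (ps >= 0.75 || pn >= 0.75) {
    stop("ng86_pairwise: saturation (proportion >= 3/4), Jukes-Cantor undefined")
  }
  ds <- jc_correct(ps); dn <- jc_correct(pn)
  ratio <- if (ds > 0) dn / ds else if (dn > 0) Inf else NA_real_
  structure(list(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, ds = ds, dn = dn, ratio = ratio,
                 n_codons = n_codons, n_skipped = n_skipped),
            class = "dnds_result")
}

#' Per-region mean dN/dS over all row pairs of a codon alignment
#'
#' Arithmetic means of pairwise `ds`, `dn` and `ratio` over all unordered row
#' pairs; pairs with an undefined or infinite ratio are excluded from the
#' ratio mean and their number is reported.
#'
#' @param cmsa A `codon_msa` from [thread_codons()] (or any list with `ids`
#'   and `dna` rows).
#' @param regions Optional `data.frame` (`name`, `start`, `end`) of 0-based
#'   half-open protein-column intervals; when `NULL` a single region spanning
#'   the whole alignment is used.
#' @return A `data.frame` with one row per region: `region`, `mean_ds`,
#'   `mean_dn`, `mean_ratio`, `n_pairs`, `n_ratio_excluded`.
#' @export
dnds_alignment <- function(cmsa, regions = NULL) {
  stopifnot(length(cmsa$ids) >= 2L)
  if (is.null(regions)) {
    regions <- data.frame(name = "all", start = 0L,
                          end = nchar(cmsa$dna[1]) %/% 3L)
  }
  n <- length(cmsa$ids)
  out <- lapply(seq_len(nrow(regions)), function(r) {
    rows <- substring(cmsa$dna, 3L * regions$start[r] + 1L, 3L * regions$end[r])
    ds <- dn <- ratio <- numeric(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        res <- ng86_pairwise(rows[i], rows[j])
        ds <- c(ds, res$ds); dn <- c(dn, res$dn); ratio <- c(ratio, res$ratio)
      }
    }
    ok <- is.finite(ratio)
    data.frame(region = regions$name[r], mean_ds = mean(ds), mean_dn = mean(dn),
               mean_ratio = if (any(ok)) mean(ratio[ok]) else NA_real_,
               n_pairs = length(ds), n_ratio_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Delta-GC of a codon against its synonymous family
#'
#' The GC fraction of the codon minus the mean GC fraction over the codon's
#' full synonymous family under the standard nuclear code. For the proline
#' family `{CCT, CCC, CCA, CCG}` the family mean is 10/12 (83.3%), so
#' `delta_gc("CCG")` is +1/6. Single-codon families give exactly 0.
#'
#' @param codon A sense codon (vectorized).
#' @return Signed GC fraction difference(s).
#' @export
delta_gc <- function(codon) {
  codon <- toupper(codon)
  gc <- genetic_code()
  aa <- gc[codon]
  if (anyNA(aa) || any(aa == "*")) {
    stop("delta_gc: invalid or stop codon '",
         codon[which(is.na(aa) | aa == "*")[1]], "'")
  }
  gc_frac <- function(c3) {
    vapply(strsplit(c3, "", fixed = TRUE),
           function(x) sum(x %in% c("G", "C")) / 3, numeric(1))
  }
  fam_mean <- vapply(aa, function(a) {
    fam <- names(gc)[gc == a]
    mean(gc_frac(fam))
  }, numeric(1))
  unname(gc_frac(codon) - fam_mean)
}

#' Mean GC of a synonymous codon family
#'
#' @param aa One-letter amino acid code.
#' @return Mean GC fraction over the amino acid's codons.
#' @export
synonymous_family_gc <- function(aa) {
  gc <- genetic_code()
  fam <- names(gc)[gc == aa]
  if (!length(fam)) stop("unknown amino acid '", aa, "'")
  mean(vapply(strsplit(fam, "", fixed = TRUE),
              function(x) sum(x %in% c("G", "C")) / 3, numeric(1)))
}

#' Partition the codons of a CDS by PQS overlap
#'
#' A codon belongs to the PQS set iff it overlaps any PQS interval by at
#' least 1 bp (so a PQS ending mid-codon still claims that codon). The
#' partition is exhaustive and disjoint.
#'
#' @param cds An in-frame DNA string.
#' @param pqs_intervals `data.frame` with `start`, `end` (0-based half-open bp
#'   on the CDS).
#' @return A `data.frame` with `codon`, `index` (0-based codon index) and
#'   `in_pqs`.
#' @export
partition_by_pqs <- function(cds, pqs_intervals) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3L == 0L)
  ncod <- nchar(cds) %/% 3L
  idx <- seq_len(ncod) - 1L
  cods <- substring(cds, 3L * idx + 1L, 3L * idx + 3L)
  in_pqs <- rep(FALSE, ncod)
  if (!is.null(pqs_intervals) && nrow(pqs_intervals)) {
    for (r in seq_len(nrow(pqs_intervals))) {
      in_pqs <- in_pqs | (3L * idx + 3L > pqs_intervals$start[r] &
                            3L * idx < pqs_intervals$end[r])
    }
  }
  data.frame(codon = cods, index = idx, in_pqs = in_pqs,
             stringsAsFactors = FALSE)
}

#' Third-position cytosine and amino-acid usage contrasts
#'
#' Compares the PQS and non-PQS codon sets: the fraction of codons with `C`
#' at the third position in each set, their ratio, and per amino acid the
#' ratio of usage frequencies (PQS over non-PQS). A zero non-PQS frequency
#' yields an `Inf` ratio with the raw counts still reported.
#'
#' @param pqs_codons,nonpqs_codons Character vectors of codons.
#' @return A list with `C3_pqs`, `C3_nonpqs`, `C3_ratio` and `aa_freq`
#'   (a `data.frame` of per-amino-acid frequencies, counts and ratios).
#' @export
codon_position_stats <- function(pqs_codons, nonpqs_codons) {
  if (!length(pqs_codons) || !length(nonpqs_codons)) {
    stop("codon_position_stats: both partitions must be non-empty")
  }
  c3 <- function(x) mean(substr(x, 3, 3) == "C")
  C3_pqs <- c3(pqs_codons); C3_nonpqs <- c3(nonpqs_codons)
  aa_p <- translate_codons(toupper(pqs_codons))
  aa_n <- translate_codons(toupper(nonpqs_codons))
  aas <- sort(unique(c(aa_p, aa_n)))
  aa_freq <- data.frame(
    aa = aas,
    n_pqs = vapply(aas, function(a) sum(aa_p == a), integer(1)),
    n_nonpqs = vapply(aas, function(a) sum(aa_n == a), integer(1)),
    stringsAsFactors = FALSE)
  aa_freq$freq_pqs <- aa_freq$n_pqs / length(aa_p)
  aa_freq$freq_nonpqs <- aa_freq$n_nonpqs / length(aa_n)
  aa_freq$ratio <- ifelse(aa_freq$freq_nonpqs > 0,
                          aa_freq$freq_pqs / aa_freq$freq_nonpqs, Inf)
  rownames(aa_freq) <- NULL
  list(C3_pqs = C3_pqs, C3_nonpqs = C3_nonpqs,
       C3_ratio = if (C3_nonpqs > 0) C3_pqs / C3_nonpqs else Inf,
       aa_freq = aa_freq)
}
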