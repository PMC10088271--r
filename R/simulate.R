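# Synthetic-data generators with planted ground truth: PQS-bearing
# retrotransposon-like elements (5'UTR / gag / pol / 3'UTR architecture),
# head-to-tail telomeric arrays with poly(A) spacers, tandem-repeat arrays,
# and homologous CDS families evolved under region-specific selection.

local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  do.call(on.exit,
          list(bquote(assign(".Random.seed", .(old), globalenv())), add = TRUE),
          envir = envir)
  set.seed(seed)
  invisible(NULL)
}

sample_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Simulation configuration
#'
#' Bundles the generator parameters: background GC, element architecture
#' (region lengths in bp), the PQS plant plan, array size/strand and poly(A)
#' spacer length. Defaults emulate a Het-A-like telomeric element: ~6.6 kb,
#' GC 0.40, four antisense PQS of three tetrads with short loops, three of
#' them in *gag* and one in the 3'UTR.
#'
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param gc_background Background GC fraction in (0, 1).
#' @param element_arch Named lengths (bp) of `utr5`, `gag`, `pol`, `utr3`.
#' @param pqs_plan `data.frame` with `region`, `count`, `orientation`
#'   (`sense`/`antisense`), `n_tetrads`, `loops` (comma-separated three loop
#'   lengths).
#' @param array_n Number of head-to-tail copies in an array.
#' @param array_strand Genomic strand of the whole array (`+` or `-`).
#' @param polyA_len Poly(A) spacer length between copies (>= 20 bp so that no
#'   quadruplex candidate can bridge two copies).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = NULL, gc_background = 0.40,
                       element_arch = c(utr5 = 400L, gag = 2400L,
                                        pol = 3000L, utr3 = 800L),
                       pqs_plan = data.frame(
                         region = c("gag", "utr3"), count = c(3L, 1L),
                         orientation = "antisense", n_tetrads = 3L,
                         loops = "1,1,1", stringsAsFactors = FALSE),
                       array_n = 10L, array_strand = "+",
                       polyA_len = 150L) {
  stopifnot(gc_background > 0, gc_background < 1, all(element_arch > 0),
            array_n >= 1L, array_strand %in% c("+", "-"), polyA_len >= 20L)
  structure(list(seed = seed, gc_background = gc_background,
                 element_arch = element_arch, pqs_plan = pqs_plan,
                 array_n = as.integer(array_n), array_strand = array_strand,
                 polyA_len = as.integer(polyA_len)),
            class = "sim_config")
}

#' Construct a canonical PQS motif
#'
#' Four runs of `n_tetrads` guanines separated by the stated loops, with loop
#' bases drawn from `loop_alphabet` (G is excluded by construction so runs
#' cannot merge at plant boundaries). Under default scanner parameters the
#' motif scores `30 * (n_tetrads - 1) - 2 * sum(pmax(0, loops - 3))`; a
#' warning is raised when that falls below the default reporting threshold.
#'
#' @param n_tetrads Number of stacked tetrads (>= 2).
#' @param loop_lengths Integer vector of the three loop lengths.
#' @param loop_alphabet Characters to draw loop bases from (no `G`).
#' @return The motif as a DNA string (G-rich strand, 5'->3').
#' @export
make_pqs_motif <- function(n_tetrads, loop_lengths, loop_alphabet = c("A", "T")) {
  stopifnot(n_tetrads >= 2L, length(loop_lengths) == 3L, all(loop_lengths >= 1L),
            !"G" %in% loop_alphabet)
  dflt <- scan_params(min_score = 1L)
  if (n_tetrads > dflt$max_run || any(loop_lengths > dflt$loop_max)) {
    stop("make_pqs_motif: parameters outside default scanner bounds")
  }
  run <- strrep("G", n_tetrads)
  loops <- vapply(loop_lengths, function(l) {
    paste(sample(loop_alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
  motif <- paste0(run, loops[1], run, loops[2], run, loops[3], run)
  score <- 30L * (n_tetrads - 1L) - 2L * sum(pmax(0L, loop_lengths - 3L))
  if (score < scan_params()$min_score) {
    warning("planted motif score ", score,
            " is below the default reporting threshold ", scan_params()$min_score)
  }
  attr(motif, "score") <- score
  motif
}

#' Generate background DNA of controlled GC content
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2`. When `clean` is
#' `TRUE` the sequence is rescanned and any span carrying an accidental PQS at
#' or above the default threshold is resampled until the sequence is free of
#' them, so planted-motif recovery on top of this background is exact.
#'
#' @param length Sequence length (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed Optional integer seed.
#' @param clean Resample accidental PQS away (default `TRUE`).
#' @param params Scanner parameters used for the cleaning rescan.
#' @return A DNA string of the requested length.
#' @export
gen_background <- function(length, gc, seed = NULL, clean = TRUE,
                           params = scan_params()) {
  stopifnot(length >= 1L)
  if (gc <= 0 || gc >= 1) stop("gc must be inside (0, 1)")
  local_seed(seed)
  chars <- sample_bases(length, gc)
  if (clean) chars <- clean_chars(chars, gc, params)
  paste(chars, collapse = "")
}

# Resample any scanner hit span (outside `protect` 0-based half-open
# intervals) until the sequence carries no hit besides the protected ones.
clean_chars <- function(chars, gc, params, protect = NULL, max_iter = 60L) {
  prot <- rep(FALSE, length(chars))
  if (!is.null(protect) && nrow(protect)) {
    for (r in seq_len(nrow(protect))) {
      prot[(protect$start[r] + 1L):protect$end[r]] <- TRUE
    }
  }
  for (iter in seq_len(max_iter)) {
    hits <- scan(paste(chars, collapse = ""), params)
    if (nrow(hits) && !is.null(protect) && nrow(protect)) {
      planted <- paste(protect$start, protect$end, protect$strand)
      hits <- hits[!paste(hits$start, hits$end, hits$strand) %in% planted, ,
                   drop = FALSE]
    }
    if (nrow(hits) == 0L) return(chars)
    for (h in seq_len(nrow(hits))) {
      span <- (hits$start[h] + 1L):hits$end[h]
      # widen a little so hits hugging a protected motif get their flanks fixed
      span <- unique(c(pmax(1L, span[1] - 5L):span[1], span,
                       span[length(span)]:pmin(length(chars), span[length(span)] + 5L)))
      span <- span[!prot[span]]
      if (length(span)) chars[span] <- sample_bases(length(span), gc)
    }
  }
  stop("clean_chars: failed to remove accidental PQS after ", max_iter,
       " resampling rounds")
}

#' Generate one retrotransposon-like element with planted PQS
#'
#' Builds a background element with the configured 5'UTR/gag/pol/3'UTR
#' architecture and plants the PQS plan inside the named regions. Motifs
#' requested antisense are planted as reverse complements on the coding
#' strand, mirroring the antisense G-rich strand bias of telomeric elements.
#' The background is rejection-resampled so that rescanning recovers exactly
#' the planted hits at their truth coordinates.
#'
#' @param config A [sim_config()].
#' @return A list of class `"synthetic_truth"`: `seq` (named DNA string),
#'   `features` (truth feature `data.frame`: element span, region spans,
#'   planted PQS with strand and score) and `config`.
#' @export
gen_element <- function(config = sim_config()) {
  local_seed(config$seed)
  arch <- config$element_arch
  stopifnot(all(c("utr5", "gag", "pol", "utr3") %in% names(arch)))
  offs <- cumsum(c(0L, unname(arch)))
  L <- offs[length(offs)]
  region_start <- stats::setNames(offs[-length(offs)], names(arch))
  chars <- sample_bases(L, config$gc_background)
  pqs <- list()
  plan <- config$pqs_plan
  for (r in seq_len(nrow(plan))) {
    reg <- plan$region[r]
    if (!reg %in% names(arch)) stop("pqs_plan region '", reg, "' not in element_arch")
    loops <- as.integer(strsplit(plan$loops[r], ",")[[1]])
    cnt <- plan$count[r]
    rs <- region_start[[reg]]; rl <- arch[[reg]]
    slot <- rl %/% cnt
    motif_len <- 4L * plan$n_tetrads[r] + sum(loops)
    if (slot < motif_len + 70L) {
      stop("gen_element: region '", reg, "' too small for ", cnt,
           " non-overlapping plant sites")
    }
    for (k in seq_len(cnt)) {
      jitter <- sample.int(slot - motif_len - 60L, 1L)
      s <- rs + (k - 1L) * slot + 30L + jitter  # 0-based plant start
      motif <- make_pqs_motif(plan$n_tetrads[r], loops)
      planted <- if (plan$orientation[r] == "antisense") revcomp(motif) else motif
      chars[(s + 1L):(s + motif_len)] <- strsplit(planted, "", fixed = TRUE)[[1]]
      # non-G/C flanks so runs cannot extend across the plant boundary
      if (s >= 1L) chars[s] <- sample(c("A", "T"), 1L)
      if (s + motif_len < L) chars[s + motif_len + 1L] <- sample(c("A", "T"), 1L)
      pqs[[length(pqs) + 1L]] <- data.frame(
        seqid = "element", start = s, end = s + motif_len,
        strand = if (plan$orientation[r] == "antisense") "-" else "+",
        type = "PQS", score = attr(motif, "score"), region = reg,
        stringsAsFactors = FALSE)
    }
  }
  pqs <- if (length(pqs)) do.call(rbind, pqs) else NULL
  if (!is.null(pqs)) {
    if (nrow(pqs) > 1L) {
      o <- order(pqs$start)
      gaps <- pqs$start[o][-1] - pqs$end[o][-nrow(pqs)]
      if (any(gaps < 13L)) stop("gen_element: overlapping or too-close plant positions")
    }
    chars <- clean_chars(chars, config$gc_background, scan_params(), protect = pqs)
  } else {
    chars <- clean_chars(chars, config$gc_background, scan_params())
  }
  feat <- rbind(
    data.frame(seqid = "element", start = 0L, end = L, strand = "+",
               type = "element", score = NA_real_, region = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(seqid = "element", start = unname(region_start),
               end = unname(region_start + arch), strand = "+",
               type = names(arch), score = NA_real_, region = names(arch),
               stringsAsFactors = FALSE),
    if (!is.null(pqs)) pqs)
  rownames(feat) <- NULL
  structure(list(seq = stats::setNames(paste(chars, collapse = ""), "element"),
                 features = feat, config = config),
            class = "synthetic_truth")
}

#' Concatenate an element into a head-to-tail telomeric array
#'
#' `n` identical copies of the element are laid head-to-tail, each followed by
#' a poly(A) spacer (the tail that points toward the centromere in a real
#' array). With a one-orientation array, all planted antisense PQS end up on
#' a single genomic strand. `array_strand = "-"` reverse-complements the
#' whole array and mirrors the truth annotation.
#'
#' @param element A `synthetic_truth` from [gen_element()].
#' @param n Number of copies (>= 1).
#' @param array_strand Genomic orientation of the array.
#' @param polyA_len Poly(A) spacer length (>= 20).
#' @param seqid Name of the array sequence.
#' @return A `synthetic_truth` with the array sequence and shifted truth
#'   features (each copy's features carry `element_id` `copy_1` ... `copy_n`).
#' @export
gen_htt_array <- function(element, n, array_strand = "+", polyA_len = 150L,
                          seqid = "htt_array") {
  stopifnot(inherits(element, "synthetic_truth"), n >= 1L, polyA_len >= 20L,
            array_strand %in% c("+", "-"))
  eseq <- unname(element$seq[[1]])
  el <- nchar(eseq)
  unit <- paste0(eseq, strrep("A", polyA_len))
  seq <- strrep(unit, n)
  L <- nchar(seq)
  feats <- lapply(seq_len(n), function(k) {
    f <- element$features
    off <- (k - 1L) * (el + polyA_len)
    f$start <- f$start + off
    f$end <- f$end + off
    f$seqid <- seqid
    f$element_id <- paste0("copy_", k)
    pa <- data.frame(seqid = seqid, start = off + el, end = off + el + polyA_len,
                     strand = "+", type = "polyA", score = NA_real_,
                     region = NA_character_, element_id = paste0("copy_", k),
                     stringsAsFactors = FALSE)
    rbind(f, pa)
  })
  feat <- do.call(rbind, feats)
  if (array_strand == "-") {
    seq <- revcomp(seq)
    new_start <- L - feat$end
    feat$end <- L - feat$start
    feat$start <- new_start
    feat$strand <- chartr("+-", "-+", feat$strand)
  }
  feat <- feat[order(feat$start, feat$end), ]
  rownames(feat) <- NULL
  structure(list(seq = stats::setNames(seq, seqid), features = feat,
                 config = element$config, array_strand = array_strand,
                 n_copies = n),
            class = "synthetic_truth")
}

#' Planted PQS truth rows of a synthetic sequence
#'
#' @param truth A `synthetic_truth`.
#' @return The truth feature rows of type `"PQS"`.
#' @export
truth_pqs <- function(truth) {
  truth$features[truth$features$type == "PQS", , drop = FALSE]
}

#' Generate a tandem-repeat array with point substitutions
#'
#' @param monomer Monomer DNA string (>= 10 bp).
#' @param n_copies Number of concatenated copies.
#' @param per_base_sub_rate Independent substitution probability per base,
#'   in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A list with `seq`, `features` (copy spans) and the parameters.
#' @export
gen_tandem_array <- function(monomer, n_copies, per_base_sub_rate = 0,
                             seed = NULL) {
  stopifnot(nchar(monomer) >= 10L, n_copies >= 1L)
  if (per_base_sub_rate < 0 || per_base_sub_rate >= 1) {
    stop("per_base_sub_rate must be in [0, 1)")
  }
  local_seed(seed)
  ml <- nchar(monomer)
  chars <- strsplit(strrep(toupper(monomer), n_copies), "", fixed = TRUE)[[1]]
  mut <- which(stats::runif(length(chars)) < per_base_sub_rate)
  bases <- c("A", "C", "G", "T")
  for (i in mut) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  feat <- data.frame(seqid = "tandem_array",
                     start = (seq_len(n_copies) - 1L) * ml,
                     end = seq_len(n_copies) * ml,
                     strand = "+", type = "monomer",
                     element_id = paste0("copy_", seq_len(n_copies)),
                     stringsAsFactors = FALSE)
  list(seq = stats::setNames(paste(chars, collapse = ""), "tandem_array"),
       features = feat, n_copies = n_copies, sub_rate = per_base_sub_rate)
}

aa_has_c3 <- function() {
  if (!is.null(.ng_cache$aa_has_c3)) return(.ng_cache$aa_has_c3)
  gc <- genetic_code()
  aas <- setdiff(unique(gc), "*")
  out <- stats::setNames(vapply(aas, function(a) {
    any(substr(names(gc)[gc == a], 3, 3) == "C")
  }, logical(1)), aas)
  .ng_cache$aa_has_c3 <- out
  out
}

# Draw one codon: amino acid proline with probability p_pro (others uniform),
# then the third position is steered so the overall P(third base == C) equals
# c3_target exactly in expectation.
draw_codon <- function(p_pro, c3_target) {
  gc <- genetic_code()
  aas <- setdiff(unique(gc), "*")
  others <- setdiff(aas, "P")
  aa <- if (stats::runif(1) < p_pro) "P" else sample(others, 1L)
  fam <- names(gc)[gc == aa]
  has_c <- substr(fam, 3, 3) == "C"
  hasc <- aa_has_c3()
  p_hasc <- p_pro + (1 - p_pro) * sum(hasc[others]) / length(others)
  if (!any(has_c)) return(sample(fam, 1L))
  q <- c3_target / p_hasc
  if (q > 1) stop("gen_cds_family: C3 target unreachable (", round(q, 2), " > 1)")
  if (stats::runif(1) < q) sample(fam[has_c], 1L) else sample(fam[!has_c], 1L)
}

#' Simulate a homologous CDS family under region-specific selection
#'
#' An ancestor CDS is drawn codon-wise (optionally with elevated proline and
#' third-position-cytosine usage inside designated PQS codon loci, planted so
#' the expected PQS/non-PQS usage ratios equal the requested multipliers).
#' Each descendant then evolves independently: per codon, a Poisson number of
#' single-base substitution attempts with mean `subs_per_codon`; an attempt
#' is accepted with probability 1 when synonymous, `omega[region]` when
#' nonsynonymous, and rejected when it would create a stop codon. No indels
#' are introduced, so the family is trivially aligned.
#'
#' @param n_seqs Number of descendant sequences (>= 2).
#' @param n_codons Ancestor length in codons.
#' @param subs_per_codon Expected substitution attempts per codon per lineage.
#' @param regions Optional `data.frame` (`name`, `start`, `end`) of 0-based
#'   half-open codon intervals tiling the CDS.
#' @param omega Named nonsynonymous acceptance probability per region
#'   (default 1 everywhere).
#' @param pqs_codon_regions Optional `data.frame` (`start`, `end`) of codon
#'   intervals treated as PQS loci for the usage bias.
#' @param pro_mult,c3_mult Planted proline / third-position-C multipliers
#'   inside PQS loci.
#' @param p_pro0,c3_target0 Baseline proline probability and third-position-C
#'   probability outside PQS loci.
#' @param seed Optional integer seed.
#' @return A list of class `"cds_family"`: `ancestor`, `cds` (named vector of
#'   descendants), `cmsa` (a `codon_msa`), `regions`, `pqs_codon_regions` and
#'   the planted parameters.
#' @export
gen_cds_family <- function(n_seqs, n_codons, subs_per_codon = 0.3,
                           regions = NULL, omega = NULL,
                           pqs_codon_regions = NULL, pro_mult = 1,
                           c3_mult = 1, p_pro0 = 0.05, c3_target0 = 0.25,
                           seed = NULL) {
  stopifnot(n_seqs >= 2L, n_codons >= 2L, subs_per_codon >= 0)
  if (is.null(regions)) {
    regions <- data.frame(name = "all", start = 0L, end = n_codons,
                          stringsAsFactors = FALSE)
  }
  if (is.null(omega)) omega <- stats::setNames(rep(1, nrow(regions)), regions$name)
  if (any(omega < 0)) stop("omega must be >= 0")
  local_seed(seed)
  in_pqs <- rep(FALSE, n_codons)
  if (!is.null(pqs_codon_regions) && nrow(pqs_codon_regions)) {
    for (r in seq_len(nrow(pqs_codon_regions))) {
      in_pqs[(pqs_codon_regions$start[r] + 1L):pqs_codon_regions$end[r]] <- TRUE
    }
  }
  codon_region <- rep(NA_character_, n_codons)
  for (r in seq_len(nrow(regions))) {
    codon_region[(regions$start[r] + 1L):regions$end[r]] <- regions$name[r]
  }
  if (anyNA(codon_region)) stop("regions must tile the CDS")
  anc <- vapply(seq_len(n_codons), function(i) {
    if (in_pqs[i]) draw_codon(min(1, p_pro0 * pro_mult), c3_target0 * c3_mult)
    else draw_codon(p_pro0, c3_target0)
  }, character(1))
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  evolve <- function() {
    cods <- anc
    nev <- stats::rpois(n_codons, subs_per_codon)
    for (i in which(nev > 0L)) {
      w <- omega[[codon_region[i]]]
      for (e in seq_len(nev[i])) {
        ch <- strsplit(cods[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(3L, 1L)
        ch2 <- ch
        ch2[pos] <- sample(setdiff(bases, ch[pos]), 1L)
        cand <- paste(ch2, collapse = "")
        if (gc[[cand]] == "*") next
        if (gc[[cand]] == gc[[cods[i]]] || stats::runif(1) < w) cods[i] <- cand
      }
    }
    paste(cods, collapse = "")
  }
  cds <- stats::setNames(vapply(seq_len(n_seqs), function(k) evolve(),
                                character(1)),
                         paste0("seq_", seq_len(n_seqs)))
  aa <- vapply(cds, function(s) {
    idx <- seq(1L, nchar(s), 3L)
    paste(translate_codons(substring(s, idx, idx + 2L)), collapse = "")
  }, character(1))
  cmsa <- structure(list(ids = names(cds), aa = unname(aa), dna = unname(cds)),
                    class = "codon_msa")
  structure(list(ancestor = paste(anc, collapse = ""), cds = cds, cmsa = cmsa,
                 regions = regions, omega = omega,
                 pqs_codon_regions = pqs_codon_regions,
                 pro_mult = pro_mult, c3_mult = c3_mult,
                 p_pro0 = p_pro0, c3_target0 = c3_target0,
                 subs_per_codon = subs_per_codon),
            class = "cds_family")
}
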