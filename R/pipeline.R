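# End-to-end orchestration: scan -> annotate -> density -> partition ->
# conserve -> dnds -> codonstats -> enrich, with a machine-readable JSON run
# manifest written last.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

n_mask_from_seq <- function(seq, seqid) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]] == "N")
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- r$values
  data.frame(seqid = rep(seqid, sum(keep)), start = s[keep], end = e[keep],
             strand = rep(".", sum(keep)), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains the pipeline stages over one set of inputs and writes every stage's
#' output into `out_dir`: `pqs.gff3` (scan), `records.tsv` and
#' `orientation_summary.tsv` (annotate), `density.tsv` (per sequence, N bases
#' removed from the effective length), `partition.tsv`,
#' `bp_proportion.tsv`, `enrichment.tsv` (per-family strand asymmetry, plus
#' Tukey upper outliers of per-element PQS counts when clades are annotated),
#' and — when a protein alignment and CDS are supplied —
#' `conservation.tsv`, `dnds.tsv` and `codon_stats.tsv`. A `manifest.json`
#' with parameters, input digests, seed, package version and wall time is
#' written last; a `RUN.partial` marker is left behind when a stage fails.
#'
#' @param fasta Path to the genome/array FASTA.
#' @param repeats Path to the repeat annotation GFF3 (must carry `family`).
#' @param out_dir Output directory (created if missing).
#' @param protein_aln,cds Optional paths to a protein alignment FASTA and the
#'   matching in-frame CDS FASTA.
#' @param regions Optional path to a region TSV (`name`, `start`, `end` in
#'   protein-alignment columns) used by the conservation and dN/dS stages.
#' @param params Scanner parameters ([scan_params()]).
#' @param seed Optional integer seed recorded in the manifest (the analysis
#'   stages are deterministic; the seed matters only when the inputs were
#'   generated in the same session).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(fasta, repeats, out_dir, protein_aln = NULL,
                         cds = NULL, regions = NULL, params = scan_params(),
                         seed = NULL) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(out_dir, "RUN.partial")
  file.create(partial)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- c(fasta = fasta, repeats = repeats, protein_aln = protein_aln,
              cds = cds, regions = regions)
  res <- list()

  seqs <- stage("scan", read_fasta(fasta))
  hits <- stage("scan", scan_fasta(fasta, params = params))
  write_features(hits, file.path(out_dir, "pqs.gff3"), "gff3")
  res$hits <- hits

  rep_feat <- stage("annotate", read_features(repeats, "gff3"))
  ix <- stage("annotate", intersect_pqs_repeats(hits, rep_feat))
  write_tsv(ix$records, file.path(out_dir, "records.tsv"))
  if (nrow(ix$records)) {
    write_tsv(orientation_summary(ix$records),
              file.path(out_dir, "orientation_summary.tsv"))
    write_tsv(bp_proportion(ix$records, rep_feat),
              file.path(out_dir, "bp_proportion.tsv"))
  }
  res$records <- ix$records

  dens <- stage("density", do.call(rbind, lapply(names(seqs), function(id) {
    region <- data.frame(seqid = id, start = 0L, end = nchar(seqs[[id]]))
    data.frame(seqid = id, length = nchar(seqs[[id]]),
               n_pqs = sum(hits$seqid == id),
               pqs_per_10kbp = pqs_density(hits, region,
                                           n_mask_from_seq(seqs[[id]], id)),
               stringsAsFactors = FALSE)
  })))
  write_tsv(dens, file.path(out_dir, "density.tsv"))
  res$density <- dens

  part <- stage("partition",
                partition_summary(hits, rep_feat, sum(nchar(seqs))))
  write_tsv(data.frame(repeat_percent = part$repeat_percent,
                       pqs_in_repeat_percent = part$pqs_in_repeat_percent),
            file.path(out_dir, "partition.tsv"))
  res$partition <- part

  enr <- stage("enrich", local({
    out <- lapply(sort(unique(ix$records$family)), function(f) {
      rec <- ix$records[ix$records$family == f, , drop = FALSE]
      ns <- sum(rec$relative_orientation == "sense")
      na <- sum(rec$relative_orientation == "antisense")
      s <- strand_asymmetry_test(ns, na)
      data.frame(family = f, n_sense = ns, n_antisense = na,
                 asymmetry_index = s$asymmetry_index,
                 p_two_sided = s$p_two_sided, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }))
  if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  res$enrichment <- enr

  if (!is.null(protein_aln) && !is.null(cds)) {
    aln <- stage("conserve", read_alignment(protein_aln))
    cds_seqs <- stage("conserve", read_fasta(cds))
    cmsa <- stage("conserve", thread_codons(aln, cds_seqs))
    regs <- if (!is.null(regions)) stage("conserve", read_regions(regions)) else NULL
    reps <- list(conservation_report(cmsa))
    if (!is.null(regs)) {
      reps <- c(reps, lapply(seq_len(nrow(regs)), function(r) {
        conservation_report(cmsa, regs[r, ])
      }))
    }
    cons <- do.call(rbind, lapply(reps, function(x) {
      data.frame(region = if (is.null(x$region)) "all" else x$region,
                 mean_dna_identity = x$mean_dna_identity,
                 mean_aa_identity = x$mean_aa_identity,
                 mean_aa_similarity = x$mean_aa_similarity,
                 diff_identity = x$diff_identity,
                 diff_similarity = x$diff_similarity,
                 n_pairs = x$n_pairs, stringsAsFactors = FALSE)
    }))
    write_tsv(cons, file.path(out_dir, "conservation.tsv"))
    res$conservation <- cons

    dnds <- stage("dnds", dnds_alignment(cmsa, regs))
    write_tsv(dnds, file.path(out_dir, "dnds.tsv"))
    res$dnds <- dnds

    cstats <- stage("codonstats", local({
      pqs_cods <- character(0); non_cods <- character(0)
      for (id in cmsa$ids) {
        ungapped <- gsub("-", "", cmsa$dna[match(id, cmsa$ids)], fixed = TRUE)
        h <- scan(ungapped, params, seqid = id)
        part <- partition_by_pqs(ungapped, h)
        pqs_cods <- c(pqs_cods, part$codon[part$in_pqs])
        non_cods <- c(non_cods, part$codon[!part$in_pqs])
      }
      if (length(pqs_cods) && length(non_cods)) {
        codon_position_stats(pqs_cods, non_cods)
      } else NULL
    }))
    if (!is.null(cstats)) {
      write_tsv(data.frame(C3_pqs = cstats$C3_pqs, C3_nonpqs = cstats$C3_nonpqs,
                           C3_ratio = cstats$C3_ratio),
                file.path(out_dir, "codon_stats.tsv"))
      write_tsv(cstats$aa_freq, file.path(out_dir, "codon_stats_aa.tsv"))
    }
    res$codon_stats <- cstats
  }

  manifest <- list(
    tool = "g4telo",
    version = as.character(utils::packageVersion("g4telo")),
    seed = seed,
    params = unclass(params),
    inputs = as.list(vapply(inputs[!vapply(inputs, is.null, logical(1))],
                            function(p) unname(tools::md5sum(p)), character(1))),
    outputs = list.files(out_dir),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.remove(partial)
  res$manifest <- manifest
  invisible(res)
}
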