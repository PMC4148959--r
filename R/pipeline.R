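## End-to-end orchestration: trim -> classify/pool OEA -> multi-k assembly
## (joint and/or per population) -> similarity-graph merge + filters (+
## rescue) -> breakpoints, carriers, population frequencies. Works on an
## in-memory cohort table (simulator output or files read back through the
## formats module); every stage is deterministic given inputs and config.

#' Pipeline configuration
#'
#' Aggregates the stage configurations and the assembly mode.
#'
#' @param trim a [trim_config()].
#' @param assembly an [assembly_config()].
#' @param filter a [filter_config()].
#' @param carrier a [carrier_config()].
#' @param min_mapq unique-mapping MAPQ threshold for OEA classification.
#' @param mode `"joint"` (pool all samples), `"per_population"`, or
#'   `"both"` (union, deduplicated keeping the longer sequence).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(trim = trim_config(),
                            assembly = assembly_config(),
                            filter = filter_config(),
                            carrier = carrier_config(),
                            min_mapq = 20L,
                            mode = c("joint", "per_population", "both")) {
  structure(list(trim = trim, assembly = assembly, filter = filter,
                 carrier = carrier, min_mapq = as.integer(min_mapq),
                 mode = match.arg(mode)),
            class = "pipeline_config")
}

#' Discover micSeqs in an in-memory cohort
#'
#' The core pipeline on a pair table carrying read sequences, provenance
#' and alignments (the simulator's output format; files are read into the
#' same shape via [read_fastq_pairs()] + [read_alignments()]).
#'
#' @param pairs cohort pair table.
#' @param reference named character vector (or `DNAStringSet`) of the
#'   reference genome.
#' @param cfg a [pipeline_config()].
#' @param contaminants optional contaminant sequences.
#' @param annotation optional `GRanges` gene annotation
#'   (see [read_bed_annotation()]).
#' @return list with `calls` (list of micSeq call objects: `id`, `seq`,
#'   `breakpoint`, `carriers`, `pop_freq`, `gene_context`, `filter_trail`),
#'   `failed` (filtered candidates), and `stage_counts` (named integers).
#' @export
discover_micseqs <- function(pairs, reference, cfg = pipeline_config(),
                             contaminants = NULL, annotation = NULL) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  counts <- c(pairs_in = nrow(pairs))
  tr <- trim_pairs(pairs, cfg$trim)
  pairs <- tr$pairs
  counts["pairs_dropped_trim"] <- tr$n_dropped
  if (!nrow(pairs)) {
    return(list(calls = list(), failed = list(),
                stage_counts = c(counts, oea = 0L, contigs = 0L,
                                 candidates = 0L, calls = 0L)))
  }
  classes <- classify_pairs(pairs, cfg$min_mapq)
  counts["concordant"] <- sum(classes == "CONCORDANT")
  counts["discordant_both_mapped"] <- sum(classes == "DISCORDANT_BOTH_MAPPED")
  counts["oea"] <- sum(classes == "OEA")
  counts["full_orphan"] <- sum(classes == "FULL_ORPHAN")
  oea_tab <- extract_oea(pairs, pairs, classes)
  samples <- unique(pairs[, .(sample_id, population)])
  groups <- switch(cfg$mode,
    joint = list(joint = oea_tab),
    per_population = split(oea_tab, by = "population"),
    both = c(list(joint = oea_tab), split(oea_tab, by = "population")))
  all_cands <- list(); all_failed <- list()
  for (gname in names(groups)) {
    res <- discover_in_group(groups[[gname]], reference, cfg, contaminants,
                             names(reference))
    for (cand in res$passed) {
      cand$assembly_group <- gname
      all_cands[[length(all_cands) + 1L]] <- cand
    }
    all_failed <- c(all_failed, res$failed)
  }
  if (cfg$mode == "both") all_cands <- dedupe_calls(all_cands)
  counts["candidates"] <- length(all_cands) + length(all_failed)
  calls <- list()
  for (cand in all_cands) {
    bp <- estimate_breakpoint(cand)
    cc <- call_carriers(cand$seq, oea_tab, samples, cfg$carrier)
    if (!cc$kept) next
    gene_context <- if (!is.null(annotation))
      classify_gene_context(bp, annotation) else NA_character_
    calls[[length(calls) + 1L]] <- structure(
      list(id = cand$id, seq = cand$seq, len = cand$len,
           assembly_group = cand$assembly_group %||% "joint",
           breakpoint = bp, anchor_cluster = cand$anchor_cluster,
           carriers = cc$carriers, pop_freq = cc$pop_freq,
           overall_freq = cc$overall_freq, gene_context = gene_context,
           filter_trail = cand$filter_trail),
      class = "micseq_call")
  }
  counts["calls"] <- length(calls)
  list(calls = calls, failed = all_failed, stage_counts = counts)
}

## assembly + merge + filters + rescue for one pooled OEA group
discover_in_group <- function(oea_tab, reference, cfg, contaminants,
                              ref_chroms) {
  passed <- list(); failed <- list()
  if (!nrow(oea_tab)) return(list(passed = passed, failed = failed))
  bins <- pool_oea(list(oea_tab), ref_chroms)
  for (chrom in names(bins)) {
    oea <- bins[[chrom]]
    oriented <- orient_orphan(oea$orphan_seq, oea$anchor_strand)
    contigs <- assemble_multik(oriented, cfg$assembly, oea$sample_id)
    if (!nrow(contigs)) next
    res <- merge_candidates(contigs, oea, reference, contaminants,
                            cfg$filter)
    surv <- rescue_regions(res$passed, oea, cfg$assembly)
    # strip reference-derived flanks; cores below the minimum micSeq
    # length are discarded
    surv <- lapply(surv, trim_reference_flanks, reference = reference,
                   cfg = cfg$filter)
    keep <- vapply(surv, function(x) x$len >= cfg$assembly$min_contig_len,
                   logical(1))
    passed <- c(passed, surv[keep])
    failed <- c(failed, res$failed, surv[!keep])
  }
  list(passed = passed, failed = failed)
}

## union semantics for mode "both": calls aligning at >= 95% identity over
## >= 90% of the shorter are one call; keep the longer sequence
dedupe_calls <- function(cands) {
  n <- length(cands)
  if (n <= 1L) return(cands)
  keep <- rep(TRUE, n)
  ord <- order(-vapply(cands, `[[`, numeric(1), "len"))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    for (jj in seq_along(ord)) {
      if (jj <= ii) next
      j <- ord[jj]
      if (!keep[j]) next
      shorter <- min(cands[[i]]$len, cands[[j]]$len)
      res <- local_align_2str(cands[[j]]$seq, cands[[i]]$seq)
      if (res$identity >= 0.95 && res$q_span >= 0.9 * shorter) keep[j] <- FALSE
    }
  }
  cands[keep]
}

#' @export
print.micseq_call <- function(x, ...) {
  bp <- x$breakpoint
  cat(sprintf("<micSeq %s> %d nt @ %s:%d%s freq=%.3f (%s)\n",
              x$id, x$len, bp$chrom, bp$start,
              if (bp$end > bp$start) sprintf("-%d", bp$end) else "",
              x$overall_freq,
              paste(sprintf("%s=%.2f", names(x$pop_freq), x$pop_freq),
                    collapse = " ")))
  invisible(x)
}

#' Run the pipeline and write a run directory
#'
#' Executes [discover_micseqs()] and writes `micseqs.fasta`, `calls.tsv`,
#' `filter_report.tsv`, `clusters.bed`, `oea.tsv` and a `MANIFEST` with
#' per-stage row counts.
#'
#' @inheritParams discover_micseqs
#' @param out_dir output directory (created).
#' @return the [discover_micseqs()] result, invisibly, with `out_dir`
#'   attached.
#' @export
run_pipeline <- function(pairs, reference, out_dir,
                         cfg = pipeline_config(), contaminants = NULL,
                         annotation = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- discover_micseqs(pairs, reference, cfg, contaminants, annotation)
  calls <- res$calls
  if (length(calls)) {
    write_fasta(data.table(id = vapply(calls, `[[`, character(1), "id"),
                           seq = vapply(calls, `[[`, character(1), "seq")),
                file.path(out_dir, "micseqs.fasta"))
    call_rows <- rbindlist(lapply(calls, function(x) {
      pf <- x$pop_freq
      data.table(id = x$id, chrom = x$breakpoint$chrom,
                 bp_start = x$breakpoint$start, bp_end = x$breakpoint$end,
                 len = x$len, overall_freq = x$overall_freq,
                 pop_freq = paste(sprintf("%s=%.4f", names(pf), pf),
                                  collapse = ";"),
                 gene_context = x$gene_context,
                 assembly_group = x$assembly_group)
    }))
    fwrite(call_rows, file.path(out_dir, "calls.tsv"), sep = "\t")
    cl <- rbindlist(lapply(calls, function(x)
      data.table(chrom = x$anchor_cluster$chrom,
                 start = x$anchor_cluster$window_start,
                 end = x$anchor_cluster$window_end, name = x$id)))
    fwrite(cl, file.path(out_dir, "clusters.bed"), sep = "\t",
           col.names = FALSE)
  } else {
    file.create(file.path(out_dir, "micseqs.fasta"))
    fwrite(data.table(id = character(0)), file.path(out_dir, "calls.tsv"),
           sep = "\t")
  }
  trail_rows <- rbindlist(lapply(c(res$calls, res$failed), function(x)
    rbindlist(lapply(x$filter_trail, function(t)
      data.table(id = x$id, filter = t$filter, pass = t$pass,
                 detail = t$detail)))), fill = TRUE)
  if (nrow(trail_rows)) {
    fwrite(trail_rows, file.path(out_dir, "filter_report.tsv"), sep = "\t")
  }
  manifest <- data.table(stage = names(res$stage_counts),
                         count = as.integer(res$stage_counts))
  fwrite(manifest, file.path(out_dir, "MANIFEST"), sep = "\t")
  attr(res, "out_dir") <- out_dir
  invisible(res)
}
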