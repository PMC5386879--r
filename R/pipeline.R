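# Interval boundaries coming out of the marker-based stages sit on the
# outermost *concordant* marker; the stretch up to the first discordant
# marker is unresolved by the array and cannot exclude a variant, so the
# screening interval is widened to end just inside the flanking markers.
pad_to_flanking_markers <- function(iv, ds) {
  if (!nrow(iv)) return(iv)
  start <- iv$start
  end <- iv$end
  for (i in seq_len(nrow(iv))) {
    pos <- ds$markers$pos[ds$markers$chrom == iv$chrom[i]]
    left <- pos[pos < iv$start[i]]
    right <- pos[pos > iv$end[i]]
    if (length(left)) start[i] <- max(left) + 1
    if (length(right)) end[i] <- min(right) - 1
  }
  genome_intervals(iv$chrom, start, end, iv$source)
}

#' Run the full mapping pipeline on a (simulated or loaded) study
#'
#' Executes, in order: sample call-rate screening and marker QC, the
#' single-point parametric linkage scan with positive-LOD region assembly,
#' per-case ROH detection with allele-sharing across cases and deterministic
#' boundary refinement, intersection of the linkage and homozygosity interval
#' sets with gap-tolerant merging into critical intervals, the segregation
#' filter cascade on the sequencing-tier variant table with consequence
#' annotation, and the gDNA/cDNA allele-balance test. All stage outputs and
#' counts are collected into one summary; with `out_dir` set, the report
#' bundle (cascade TSV, critical-interval BED, candidate VCF, NMD + summary
#' JSON) is written to disk.
#'
#' @param study an [simulate_study()] result (or an equivalent list built
#'   from files on disk).
#' @param qc a [qc_criteria()].
#' @param model a [disease_model()].
#' @param roh a [roh_params()], or `NULL` (default) to use the PLINK-style
#'   defaults with the SNP-count parameters rescaled to the pruned dataset's
#'   marker density. The stock values (50-SNP window, 100-SNP minimum run)
#'   encode physical extents of roughly 0.15 Mb and 0.3 x the minimum run
#'   length at dense-array spacing; applied verbatim to a sparser map they
#'   would silently raise the effective window and length thresholds by an
#'   order of magnitude, so the pipeline preserves the physical extents
#'   instead (window floored at 10 SNPs, run at 20; the per-window missing
#'   tolerance scales with the window).
#' @param max_gap_bp gap bridged when merging critical intervals.
#' @param alpha significance level of the NMD test.
#' @param theta_grid grid for the linkage scan.
#' @param out_dir optional output directory.
#' @return List of class `"nfs_pipeline_result"` with elements `qc_report`,
#'   `scan`, `linked`, `shared`, `critical`, `cascade`, `candidates`, `nmd`,
#'   `summary` (flat named list of stage counts) and `seed`.
#' @export
run_pipeline <- function(study, qc = qc_criteria(), model = disease_model(),
                         roh = NULL, max_gap_bp = 1.5e6, alpha = 0.05,
                         theta_grid = default_theta_grid(), out_dir = NULL) {
  ped <- study$pedigree
  pruned <- prune_markers(ped, study$dataset, qc)
  ds <- pruned$dataset
  cases <- intersect(ped$id[ped$affection == "affected"], ds$samples)
  if (is.null(roh)) {
    spans <- tapply(ds$markers$pos, ds$markers$chrom,
                    function(p) diff(range(p)))
    density <- nrow(ds$markers) / sum(spans)
    base <- roh_params()
    window <- max(10, round(0.15e6 * density))   # ~0.15 Mb of markers
    roh <- roh_params(
      window_snps = window,
      max_missing_in_window = max(1, round(base$max_missing_in_window *
                                             window / base$window_snps)),
      min_run_snps = max(20, round(0.3 * base$min_run_length_bp * density)))
  }

  scan <- linkage_scan(ped[ped$id %in% ds$samples, , drop = FALSE], ds, model,
                       theta_grid)
  linked <- linked_regions(scan)

  shared <- shared_roh(ds, cases, roh)
  shared <- compile_roh_boundaries(shared, ds, cases)

  critical <- merge_with_gaps(intersect_intervals(linked, shared), max_gap_bp)
  critical <- pad_to_flanking_markers(critical, ds)

  casc <- run_cascade(study$wgs$variants, study$wgs$roles, critical,
                      list(study$transcript$model))
  nmd <- nmd_classify(study$nmd_counts$gdna, study$nmd_counts$cdna, alpha)

  summary <- list(
    seed = study$seed,
    markers_input = pruned$report$n_input,
    markers_surviving_qc = pruned$report$n_survivors,
    linked_regions = nrow(linked),
    shared_roh_intervals = nrow(shared),
    critical_intervals = nrow(critical),
    critical_span_mb = if (nrow(critical)) sum(span_mb(critical, 3)) else 0,
    cascade = stats::setNames(as.list(casc$report$n), casc$report$step),
    n_candidates = nrow(casc$candidates$sites),
    candidate_ids = casc$candidates$sites$id,
    nmd_classification = nmd$classification)

  res <- structure(list(qc_report = pruned$report, scan = scan,
                        linked = linked, shared = shared, critical = critical,
                        cascade = casc$report, candidates = casc$candidates,
                        nmd = nmd, summary = summary, seed = study$seed),
                   class = "nfs_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(res$critical, file.path(out_dir, "critical_intervals.bed"))
    if (nrow(res$candidates$sites)) {
      write_vcf(res$candidates, file.path(out_dir, "candidates.vcf"))
    }
    con <- file(file.path(out_dir, "cascade.tsv"), "w")
    writeLines(provenance_line("cascade report",
                               sprintf("seed=%s", study$seed)), con)
    suppressWarnings(utils::write.table(res$cascade, con, quote = FALSE,
                                        sep = "\t", row.names = FALSE))
    close(con)
    jsonlite::write_json(unclass(res$nmd),
                         file.path(out_dir, "nmd.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @method print nfs_pipeline_result
#' @export
print.nfs_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<nfs_pipeline_result>\n")
  cat(sprintf("  markers: %d in, %d after QC\n", s$markers_input,
              s$markers_surviving_qc))
  cat(sprintf("  linked regions (>1 Mb, LOD > 0): %d\n", s$linked_regions))
  cat(sprintf("  shared ROH intervals: %d\n", s$shared_roh_intervals))
  cat(sprintf("  critical intervals: %d (%.2f Mb total)\n",
              s$critical_intervals, s$critical_span_mb))
  cat("  cascade:",
      paste(sprintf("%s=%d", names(s$cascade), unlist(s$cascade)),
            collapse = " -> "), "\n")
  cat(sprintf("  candidates: %s\n",
              if (s$n_candidates) paste(s$candidate_ids, collapse = ", ")
              else "none"))
  if (s$n_candidates) {
    cat(sprintf("    %s %s (%s)\n", x$candidates$sites$hgvs_c,
                x$candidates$sites$hgvs_p, x$candidates$sites$csq_class))
  }
  cat(sprintf("  NMD classification: %s\n", s$nmd_classification))
  invisible(x)
}
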