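#' Case / carrier / control sample roles
#'
#' @param cases,carriers,controls disjoint id sets; cases and carriers must be
#'   non-empty.
#' @return List of class `"sample_roles"`.
#' @export
sample_roles <- function(cases, carriers, controls = character()) {
  cases <- as.character(cases); carriers <- as.character(carriers)
  controls <- as.character(controls)
  if (!length(cases) || !length(carriers)) {
    stop("cases and carriers must be non-empty")
  }
  all_ids <- c(cases, carriers, controls)
  if (anyDuplicated(all_ids)) {
    stop("role sets overlap: ", paste(all_ids[duplicated(all_ids)], collapse = ", "))
  }
  structure(list(cases = cases, carriers = carriers, controls = controls),
            class = "sample_roles")
}

check_roles_present <- function(vs, roles) {
  miss <- setdiff(c(roles$cases, roles$carriers, roles$controls), vs$samples)
  if (length(miss)) {
    stop("role sample(s) absent from variant set: ", paste(miss, collapse = ", "))
  }
}

# logical vector over records: cases hom-alt and carriers het
coseg_case_carrier <- function(vs, roles) {
  gc <- vs$geno[, roles$cases, drop = FALSE]
  gk <- vs$geno[, roles$carriers, drop = FALSE]
  rowSums(is.na(gc) | gc != 2L) == 0 & rowSums(is.na(gk) | gk != 1L) == 0
}

control_clean <- function(vs, roles, controls_allow_missing = TRUE) {
  if (!length(roles$controls)) {
    warning("empty control set: control condition is vacuously true")
    return(rep(TRUE, nrow(vs$sites)))
  }
  g0 <- vs$geno[, roles$controls, drop = FALSE]
  if (controls_allow_missing) {
    rowSums(!is.na(g0) & g0 != 0L) == 0
  } else {
    rowSums(is.na(g0) | g0 != 0L) == 0
  }
}

#' Mendelian segregation filter
#'
#' Keeps records that are homozygous for the alternate allele in every case,
#' heterozygous in every carrier, and homozygous reference in every control;
#' by default a missing control call also counts as clean (set
#' `controls_allow_missing = FALSE` for the strict mode). Any deviation in a
#' case or carrier (including a missing call) excludes the record.
#'
#' @param vs a [variant_set()].
#' @param roles a [sample_roles()]; all ids must be present in `vs`.
#' @param controls_allow_missing treat missing control genotypes as clean.
#' @return The surviving [variant_set()].
#' @export
segregation_filter <- function(vs, roles, controls_allow_missing = TRUE) {
  check_roles_present(vs, roles)
  keep <- coseg_case_carrier(vs, roles) &
    control_clean(vs, roles, controls_allow_missing)
  subset_variants(vs, keep)
}

#' Restrict records to a set of genome intervals
#'
#' @param vs a [variant_set()].
#' @param intervals a [genome_intervals()] frame (1-based inclusive ends).
#' @return The records whose position falls inside any interval.
#' @export
restrict_to_intervals <- function(vs, intervals) {
  keep <- rep(FALSE, nrow(vs$sites))
  for (i in seq_len(nrow(intervals))) {
    keep <- keep | (vs$sites$chrom == intervals$chrom[i] &
                      vs$sites$pos >= intervals$start[i] &
                      vs$sites$pos <= intervals$end[i])
  }
  subset_variants(vs, keep)
}

protein_changing_classes <- c("missense", "nonsense", "frameshift", "splice")

#' Run the full segregation-filter cascade
#'
#' Applies, in order: the case/carrier genotype-pattern filter, the control
#' condition, restriction to the critical intervals, and the consequence-class
#' restriction to protein-changing variants (missense, nonsense, frameshift,
#' canonical splice). The report's main steps are monotone non-increasing; a
#' per-chromosome breakdown of in-interval counts is attached as the
#' `by_chrom` attribute.
#'
#' @param vs a [variant_set()].
#' @param roles a [sample_roles()].
#' @param intervals critical [genome_intervals()].
#' @param transcripts list of [transcript_model()]s used for consequence
#'   annotation (records outside every transcript are noncoding).
#' @param controls_allow_missing see [segregation_filter()].
#' @return `list(candidates =, report =)`: the surviving records with
#'   annotation columns (`csq_class`, `hgvs_c`, `hgvs_p`), and a
#'   `"cascade_report"` data frame of step labels and counts.
#' @export
run_cascade <- function(vs, roles, intervals, transcripts,
                        controls_allow_missing = TRUE) {
  check_roles_present(vs, roles)
  s1 <- subset_variants(vs, coseg_case_carrier(vs, roles))
  s2 <- subset_variants(s1, control_clean(s1, roles, controls_allow_missing))
  s3 <- restrict_to_intervals(s2, intervals)
  by_chrom <- vapply(unique(intervals$chrom), function(chr) {
    nrow(restrict_to_intervals(s2, intervals[intervals$chrom == chr, ,
                                             drop = FALSE])$sites)
  }, numeric(1))
  csq <- lapply(seq_len(nrow(s3$sites)), function(i) {
    annotate_against_transcripts(transcripts, s3$sites$chrom[i],
                                 s3$sites$pos[i], s3$sites$ref[i],
                                 s3$sites$alt[i])
  })
  cls <- vapply(csq, `[[`, "", "class")
  keep <- cls %in% protein_changing_classes
  candidates <- subset_variants(s3, keep)
  candidates$sites$csq_class <- cls[keep]
  candidates$sites$hgvs_c <- vapply(csq[keep], function(x) x$hgvs_c %||% NA_character_, "")
  candidates$sites$hgvs_p <- vapply(csq[keep], function(x) x$hgvs_p %||% NA_character_, "")
  report <- data.frame(
    step = c("input", "cases_hom_carriers_het", "controls_clean",
             "in_critical_intervals", "protein_changing"),
    n = c(nrow(vs$sites), nrow(s1$sites), nrow(s2$sites), nrow(s3$sites),
          nrow(candidates$sites)),
    stringsAsFactors = FALSE)
  attr(report, "by_chrom") <- by_chrom
  class(report) <- c("cascade_report", "data.frame")
  list(candidates = candidates, report = report)
}
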