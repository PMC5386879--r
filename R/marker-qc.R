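#' Marker pruning criteria
#'
#' Defaults reproduce the family-based pruning used for recessive mapping:
#' drop markers that are noninformative (monomorphic across the study
#' individuals' non-missing calls), on a sex chromosome, missing in any study
#' individual, carry a Mendel error, or have minor allele frequency below 0.2;
#' samples with call rate below 0.95 are excluded before marker pruning.
#'
#' @param min_maf minimum minor allele frequency (in `[0, 0.5]`).
#' @param excluded_chroms chromosomes removed wholesale.
#' @param max_missing_in_study maximum number of missing study calls per
#'   marker.
#' @param drop_mendel_error_markers,drop_noninformative logical switches.
#' @param min_sample_call_rate samples below this call rate are dropped first.
#' @return List of class `"qc_criteria"`.
#' @export
qc_criteria <- function(min_maf = 0.2, excluded_chroms = c("X", "Y"),
                        max_missing_in_study = 0,
                        drop_mendel_error_markers = TRUE,
                        drop_noninformative = TRUE,
                        min_sample_call_rate = 0.95) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  structure(list(min_maf = min_maf, excluded_chroms = excluded_chroms,
                 max_missing_in_study = max_missing_in_study,
                 drop_mendel_error_markers = drop_mendel_error_markers,
                 drop_noninformative = drop_noninformative,
                 min_sample_call_rate = min_sample_call_rate),
            class = "qc_criteria")
}

#' Per-sample genotype call rate
#'
#' @param ds a [marker_dataset()].
#' @param sample sample id.
#' @return Fraction of non-missing calls over all markers.
#' @export
sample_call_rate <- function(ds, sample) {
  if (!sample %in% ds$samples) stop("unknown sample: ", sample)
  mean(!is.na(ds$geno[sample, ]))
}

#' Minor allele frequency of one marker
#'
#' Folded allele frequency over the non-missing calls of the study
#' individuals.
#'
#' @param ds a [marker_dataset()].
#' @param marker marker name or column index.
#' @param samples study individuals (default: all).
#' @return MAF in `[0, 0.5]`; `NA` when every call is missing (the marker is
#'   then noninformative).
#' @export
minor_allele_frequency <- function(ds, marker, samples = ds$samples) {
  j <- if (is.character(marker)) match(marker, ds$markers$name) else marker
  if (is.na(j)) stop("unknown marker: ", marker)
  g <- ds$geno[samples, j]
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

# Is child genotype possible given (possibly missing) parent genotypes at a
# biallelic locus? Dosage coding; NA parents constrain nothing.
mendel_compatible <- function(child, father, mother) {
  if (is.na(child)) return(TRUE)
  can_give <- function(par) {
    if (is.na(par)) return(c(TRUE, TRUE))      # allele 1 / allele 2
    c(par <= 1, par >= 1)
  }
  f <- can_give(father)
  m <- can_give(mother)
  ok <- FALSE
  for (af in 0:1) for (am in 0:1) {
    if (f[af + 1] && m[am + 1] && af + am == child) ok <- TRUE
  }
  ok
}

#' Detect single-locus Mendel errors
#'
#' Flags offspring genotypes impossible under Mendelian transmission given
#' the non-missing parent genotypes. Missing calls never raise an error.
#'
#' @param ped a [pedigree()].
#' @param ds a [marker_dataset()] containing the pedigree samples.
#' @return Data frame with columns `marker`, `offspring`.
#' @export
detect_mendel_errors <- function(ped, ds) {
  kids <- which(!is_founder(ped) & ped$id %in% ds$samples)
  out <- list()
  for (i in kids) {
    cid <- ped$id[i]
    fg <- if (ped$sire[i] %in% ds$samples) ds$geno[ped$sire[i], ] else
      rep(NA_integer_, nrow(ds$markers))
    mg <- if (ped$dam[i] %in% ds$samples) ds$geno[ped$dam[i], ] else
      rep(NA_integer_, nrow(ds$markers))
    cg <- ds$geno[cid, ]
    bad <- vapply(seq_along(cg), function(j) {
      !mendel_compatible(cg[j], fg[j], mg[j])
    }, logical(1))
    if (any(bad)) {
      out[[length(out) + 1]] <- data.frame(marker = ds$markers$name[bad],
                                           offspring = cid,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(marker = character(), offspring = character()))
  }
  do.call(rbind, out)
}

#' Prune markers against the QC criteria
#'
#' Samples with call rate below `criteria$min_sample_call_rate` are removed
#' first. Each removed marker is attributed to the *first* failing criterion
#' in the order: noninformative, sex chromosome, missing in a study
#' individual, Mendel error, MAF below threshold.
#'
#' @param ped a [pedigree()].
#' @param ds a [marker_dataset()].
#' @param criteria a [qc_criteria()].
#' @return `list(dataset =, report =)`; the report (class `"qc_report"`)
#'   carries per-criterion removal counts, survivor count and per-sample call
#'   rates (with excluded samples flagged).
#' @export
prune_markers <- function(ped, ds, criteria = qc_criteria()) {
  rates <- vapply(ds$samples, function(s) sample_call_rate(ds, s), numeric(1))
  keep_samples <- rates >= criteria$min_sample_call_rate
  if (!all(keep_samples)) {
    ds <- marker_dataset(ds$markers, ds$samples[keep_samples],
                         ds$geno[keep_samples, , drop = FALSE])
    ped <- ped[ped$id %in% ds$samples | ped$id %in% ped$sire | ped$id %in% ped$dam,
               , drop = FALSE]
    class(ped) <- c("pedigree", "data.frame")
  }
  nm <- nrow(ds$markers)
  g <- ds$geno
  # noninformative = monomorphic: at most one allele observed among the
  # study individuals' non-missing calls (all-missing markers included)
  monomorphic <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || sum(x) == 0 || sum(x) == 2 * length(x)
  })
  noninf <- if (criteria$drop_noninformative) monomorphic else
    rep(FALSE, nm)
  sexchr <- ds$markers$chrom %in% criteria$excluded_chroms
  missing_n <- colSums(is.na(g))
  toomiss <- missing_n > criteria$max_missing_in_study
  mendel <- rep(FALSE, nm)
  if (criteria$drop_mendel_error_markers) {
    err <- detect_mendel_errors(ped, ds)
    mendel[match(unique(err$marker), ds$markers$name)] <- TRUE
  }
  maf <- vapply(seq_len(nm), function(j) minor_allele_frequency(ds, j),
                numeric(1))
  lowmaf <- !is.na(maf) & maf < criteria$min_maf
  fail <- cbind(noninformative = noninf, sex_chromosome = sexchr,
                missing_in_study = toomiss, mendel_error = mendel,
                low_maf = lowmaf)
  first_fail <- apply(fail, 1, function(x) if (any(x)) which(x)[1] else 0L)
  removed <- tabulate(first_fail[first_fail > 0], nbins = ncol(fail))
  keep <- first_fail == 0L
  if (!any(keep)) {
    stop("no markers survive QC; review the pruning criteria")
  }
  report <- structure(list(
    removed = stats::setNames(removed, colnames(fail)),
    n_input = nm, n_survivors = sum(keep),
    sample_call_rates = rates,
    excluded_samples = names(rates)[!keep_samples]),
    class = "qc_report")
  list(dataset = subset_markers(ds, keep), report = report)
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d markers in, %d removed, %d survive\n",
              x$n_input, sum(x$removed), x$n_survivors))
  for (k in names(x$removed)) cat(sprintf("  %-18s %d\n", k, x$removed[[k]]))
  if (length(x$excluded_samples)) {
    cat("  samples excluded (call rate):",
        paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}
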