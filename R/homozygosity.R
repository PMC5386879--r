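#' Run-of-homozygosity scan parameters
#'
#' Defaults mirror the documented defaults of PLINK's windowed `--homozyg`
#' scan, which the published analysis cites without parameter values; every
#' parameter is exposed here.
#'
#' @param window_snps sliding window size in SNPs.
#' @param max_het_in_window,max_missing_in_window tolerated heterozygous and
#'   missing calls per homozygous window.
#' @param min_window_hit_fraction a SNP is in-ROH when at least this fraction
#'   of the windows covering it is homozygous.
#' @param min_run_length_bp,min_run_snps minimum segment span (`end - start`)
#'   and SNP count.
#' @param allele_match_fraction fraction of mutually non-missing markers at
#'   which all cases must be identically homozygous for a shared segment
#'   (below 1 to tolerate genotyping error).
#' @return List of class `"roh_params"`.
#' @export
roh_params <- function(window_snps = 50, max_het_in_window = 1,
                       max_missing_in_window = 5,
                       min_window_hit_fraction = 0.05,
                       min_run_length_bp = 1e6, min_run_snps = 100,
                       allele_match_fraction = 0.95) {
  stopifnot(window_snps >= 1, max_het_in_window >= 0,
            max_missing_in_window >= 0,
            min_window_hit_fraction >= 0, min_window_hit_fraction <= 1,
            allele_match_fraction >= 0, allele_match_fraction <= 1)
  structure(list(window_snps = window_snps,
                 max_het_in_window = max_het_in_window,
                 max_missing_in_window = max_missing_in_window,
                 min_window_hit_fraction = min_window_hit_fraction,
                 min_run_length_bp = min_run_length_bp,
                 min_run_snps = min_run_snps,
                 allele_match_fraction = allele_match_fraction),
            class = "roh_params")
}

#' Detect runs of homozygosity for one sample
#'
#' Windowed scan per chromosome: a window of `window_snps` consecutive SNPs is
#' homozygous when it contains at most `max_het_in_window` heterozygous and
#' `max_missing_in_window` missing calls; a SNP is in-ROH when the fraction of
#' homozygous windows covering it reaches `min_window_hit_fraction`; maximal
#' in-ROH runs passing the length and SNP-count thresholds become segments
#' whose boundaries are the first and last in-ROH marker positions. A
#' chromosome with fewer SNPs than the window collapses to a single
#' all-SNP window.
#'
#' @param ds a [marker_dataset()] (map-sorted by construction).
#' @param sample sample id.
#' @param params a [roh_params()].
#' @return Data frame of class `"roh_segments"`: `sample`, `chrom`, `start`,
#'   `end`, `n_snps`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(ds, sample, params = roh_params()) {
  if (!sample %in% ds$samples) stop("unknown sample: ", sample)
  out <- list()
  for (chr in unique(ds$markers$chrom)) {
    j <- which(ds$markers$chrom == chr)
    g <- ds$geno[sample, j]
    pos <- ds$markers$pos[j]
    n <- length(j)
    w <- min(params$window_snps, n)
    nw <- n - w + 1
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    ch <- c(0, cumsum(het))
    cm <- c(0, cumsum(mis))
    win_het <- ch[(1:nw) + w] - ch[1:nw]
    win_mis <- cm[(1:nw) + w] - cm[1:nw]
    homoz <- win_het <= params$max_het_in_window &
      win_mis <= params$max_missing_in_window
    lo <- pmax(1L, seq_len(n) - w + 1L)
    hi <- pmin(seq_len(n), nw)
    hh <- c(0, cumsum(homoz))
    hits <- hh[hi + 1] - hh[lo]
    in_roh <- hits / (hi - lo + 1) >= params$min_window_hit_fraction
    r <- rle(in_roh)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      span <- pos[i2] - pos[i1]
      nsnp <- i2 - i1 + 1
      if (span >= params$min_run_length_bp && nsnp >= params$min_run_snps) {
        out[[length(out) + 1]] <- data.frame(
          sample = sample, chrom = chr, start = pos[i1], end = pos[i2],
          n_snps = nsnp, n_het = sum(het[i1:i2]), n_missing = sum(mis[i1:i2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), n_snps = integer(), n_het = integer(),
               n_missing = integer())
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

# intersect two sorted interval frames (plain columns chrom/start/end)
intersect_interval_frames <- function(a, b) {
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    aa <- a[a$chrom == chr, , drop = FALSE]
    bb <- b[b$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(aa))) for (k in seq_len(nrow(bb))) {
      s <- max(aa$start[i], bb$start[k])
      e <- min(aa$end[i], bb$end[k])
      if (s <= e) out[[length(out) + 1]] <- data.frame(chrom = chr, start = s,
                                                       end = e)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Find ROH shared with identical alleles across all cases
#'
#' Intersects the per-case ROH segments across all cases. Because the
#' windowed detector places segment boundaries with up to a window of slack,
#' each overlap is first trimmed inward to the outermost markers at which all
#' cases are identically homozygous; the trimmed overlap must then carry
#' identical homozygous genotypes in all cases at a fraction of at least
#' `allele_match_fraction` of the mutually non-missing markers, and is
#' re-checked against `min_run_length_bp`. Missing genotypes neither confirm
#' nor break sharing. A single case returns its own segments unchanged.
#'
#' @param ds a [marker_dataset()].
#' @param case_ids ids of the affected individuals.
#' @param params a [roh_params()].
#' @return A [genome_intervals()] frame with `source = "roh_shared"`.
#' @export
shared_roh <- function(ds, case_ids, params = roh_params()) {
  if (!length(case_ids)) stop("no case ids supplied")
  segs <- lapply(case_ids, function(s) detect_roh(ds, s, params))
  ivs <- Reduce(intersect_interval_frames,
                lapply(segs, function(s) s[c("chrom", "start", "end")]))
  if (!nrow(ivs)) return(genome_intervals())
  if (length(case_ids) == 1) {
    return(genome_intervals(ivs$chrom, ivs$start, ivs$end,
                            source = "roh_shared"))
  }
  out <- list()
  for (i in seq_len(nrow(ivs))) {
    j <- which(ds$markers$chrom == ivs$chrom[i] &
                 ds$markers$pos >= ivs$start[i] &
                 ds$markers$pos <= ivs$end[i])
    if (!length(j)) next
    sub <- ds$geno[case_ids, j, drop = FALSE]
    match_col <- apply(sub, 2, function(x) {
      all(!is.na(x)) && all(x %in% c(0L, 2L)) && length(unique(x)) == 1
    })
    if (!any(match_col)) next
    lo <- which(match_col)[1]
    hi <- which(match_col)[sum(match_col)]
    j <- j[lo:hi]
    start <- ds$markers$pos[j[1]]
    end <- ds$markers$pos[j[length(j)]]
    if (end - start < params$min_run_length_bp) next
    sub <- ds$geno[case_ids, j, drop = FALSE]
    typed <- colSums(is.na(sub)) == 0
    if (any(typed)) {
      mc <- apply(sub[, typed, drop = FALSE], 2, function(x) {
        all(x %in% c(0L, 2L)) && length(unique(x)) == 1
      })
      if (mean(mc) < params$allele_match_fraction) next
    }
    out[[length(out) + 1]] <- data.frame(chrom = ivs$chrom[i], start = start,
                                         end = end)
  }
  if (!length(out)) return(genome_intervals())
  df <- do.call(rbind, out)
  genome_intervals(df$chrom, df$start, df$end, source = "roh_shared")
}

#' Refine shared-ROH boundaries marker by marker
#'
#' Deterministic replacement for manual inspection of raw genotypes: each
#' boundary is pushed outward marker by marker while every case stays
#' homozygous for the same allele (missing calls do not confirm and stop the
#' extension), and trimmed at the first violating marker.
#'
#' @param intervals shared intervals from [shared_roh()].
#' @param ds a [marker_dataset()].
#' @param case_ids the affected individuals.
#' @return A [genome_intervals()] frame with refined boundaries.
#' @export
compile_roh_boundaries <- function(intervals, ds, case_ids) {
  if (!nrow(intervals)) return(intervals)
  confirming <- function(j) {
    x <- ds$geno[case_ids, j]
    all(!is.na(x)) && all(x %in% c(0L, 2L)) && length(unique(x)) == 1
  }
  starts <- numeric(nrow(intervals))
  ends <- numeric(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    j_chr <- which(ds$markers$chrom == intervals$chrom[i])
    pos <- ds$markers$pos[j_chr]
    lo <- which(pos >= intervals$start[i])[1]
    hi <- max(which(pos <= intervals$end[i]))
    while (lo > 1 && confirming(j_chr[lo - 1])) lo <- lo - 1
    while (hi < length(j_chr) && confirming(j_chr[hi + 1])) hi <- hi + 1
    starts[i] <- pos[lo]
    ends[i] <- pos[hi]
  }
  genome_intervals(intervals$chrom, starts, ends, source = "roh_shared")
}
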