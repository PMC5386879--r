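#' Intersect two interval sets
#'
#' Pairwise overlaps on matching chromosomes: the overlap of `[a1, a2]` and
#' `[b1, b2]` is `[max(a1, b1), min(a2, b2)]` when non-empty (single-base
#' overlaps count).
#'
#' @param a,b [genome_intervals()] frames (internally sorted).
#' @return A [genome_intervals()] frame; `source` concatenates the operand
#'   tags.
#' @export
intersect_intervals <- function(a, b) {
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    aa <- a[a$chrom == chr, , drop = FALSE]
    bb <- b[b$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(aa))) for (k in seq_len(nrow(bb))) {
      s <- max(aa$start[i], bb$start[k])
      e <- min(aa$end[i], bb$end[k])
      if (s <= e) {
        src <- paste(stats::na.omit(unique(c(aa$source[i], bb$source[k]))),
                     collapse = "+")
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = s, end = e,
          source = if (nzchar(src)) src else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(genome_intervals())
  df <- do.call(rbind, out)
  genome_intervals(df$chrom, df$start, df$end, df$source)
}

#' Merge near-adjacent intervals
#'
#' Consecutive intervals on the same chromosome whose gap
#' (`next start - previous end`) is strictly less than `max_gap_bp` are
#' unioned (overlapping intervals always merge). The default 1.5 Mb encodes
#' the rule of conservatively bridging interrupting non-homozygous segments
#' shorter than 1.5 Mb into one critical interval.
#'
#' @param x a [genome_intervals()] frame.
#' @param max_gap_bp strict upper bound on a bridged gap.
#' @return A [genome_intervals()] frame; merged intervals get a
#'   `merged-from:<n>` source tag recording their constituent count.
#' @export
merge_with_gaps <- function(x, max_gap_bp = 1.5e6) {
  if (nrow(x) <= 1) return(x)
  out <- list()
  for (chr in unique(x$chrom)) {
    xx <- x[x$chrom == chr, , drop = FALSE]
    cur <- xx[1, , drop = FALSE]
    n_const <- 1
    flush <- function(cur, n_const) {
      if (n_const > 1) cur$source <- sprintf("merged-from:%d", n_const)
      cur
    }
    if (nrow(xx) >= 2) for (i in 2:nrow(xx)) {
      gap <- xx$start[i] - cur$end
      if (gap < max_gap_bp) {
        cur$end <- max(cur$end, xx$end[i])
        n_const <- n_const + 1
      } else {
        out[[length(out) + 1]] <- flush(cur, n_const)
        cur <- xx[i, , drop = FALSE]
        n_const <- 1
      }
    }
    out[[length(out) + 1]] <- flush(cur, n_const)
  }
  df <- do.call(rbind, out)
  genome_intervals(df$chrom, df$start, df$end, df$source)
}

#' Interval span in megabases
#'
#' Span is the plain coordinate difference `(end - start) / 1e6`, rounded
#' half-up to `decimals` places. Computed this way, printed boundary
#' coordinates reproduce printed interval sizes exactly.
#'
#' @param x a [genome_intervals()] frame (vectorised over rows).
#' @param decimals decimal places for half-up rounding.
#' @return Numeric vector of spans in Mb.
#' @examples
#' span_mb(genome_intervals("7", 36013146, 53111271), 0)  # 17
#' span_mb(genome_intervals("27", 10880351, 12070934), 1) # 1.2
#' @export
span_mb <- function(x, decimals = 1) {
  raw <- (x$end - x$start) / 1e6
  f <- 10^decimals
  floor(raw * f + 0.5) / f
}
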