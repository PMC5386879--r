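#' autozyg: autozygosity mapping and recessive candidate variant prioritisation
#'
#' Genotype calls are represented throughout as integer allele-2 dosages:
#' `0` = homozygous for the first allele (reference-like), `1` = heterozygous,
#' `2` = homozygous for the second (alternate-like) allele, `NA` = missing.
#' Genome coordinates are 1-based and inclusive at both ends; conversion to
#' BED's 0-based half-open convention happens only in [write_bed()] /
#' [read_bed()].
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns `id`,
#' `sire`, `dam`, `sex` and `affection`. An individual is a founder if and
#' only if both parent ids are `NA`; individuals with exactly one recorded
#' parent are rejected.
#'
#' @param id character vector of unique individual ids.
#' @param sire,dam parent ids (`NA` for founders). Must resolve to ids within
#'   the pedigree.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`.
#' @return A data frame of class `"pedigree"`.
#' @examples
#' ped <- pedigree(
#'   id  = c("S1", "D1", "A1"),
#'   sire = c(NA, NA, "S1"), dam = c(NA, NA, "D1"),
#'   sex = c("male", "female", "unknown"),
#'   affection = c("unaffected", "unaffected", "affected"))
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_,
                     sex = "unknown", affection = "unknown") {
  n <- length(id)
  ped <- data.frame(
    id = as.character(id),
    sire = rep_len(as.character(sire), n),
    dam = rep_len(as.character(dam), n),
    sex = rep_len(as.character(sex), n),
    affection = rep_len(as.character(affection), n),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "sire", "dam", "sex", "affection") %in% names(ped)))
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent)) {
    stop("individual(s) with exactly one recorded parent: ",
         paste(ped$id[one_parent], collapse = ", "))
  }
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    bad <- !is.na(p) & !(p %in% ped$id)
    if (any(bad)) {
      stop("unresolved ", col, " id(s): ", paste(unique(p[bad]), collapse = ", "))
    }
  }
  if (!all(ped$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be 'male', 'female' or 'unknown'")
  }
  if (!all(ped$affection %in% c("affected", "unaffected", "unknown"))) {
    stop("affection must be 'affected', 'unaffected' or 'unknown'")
  }
  sire_sex <- ped$sex[match(ped$sire[!is.na(ped$sire)], ped$id)]
  if (any(sire_sex == "female")) stop("a sire is recorded as female")
  dam_sex <- ped$sex[match(ped$dam[!is.na(ped$dam)], ped$id)]
  if (any(dam_sex == "male")) stop("a dam is recorded as male")
  ped_topological_order(ped)  # errors on cycles
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Founder indicator
#'
#' @param ped a [pedigree()].
#' @return Logical vector, `TRUE` where both parent ids are missing.
#' @export
is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)

#' Topological order of a pedigree (parents before children).
#' Errors if the parent graph is cyclic.
#' @noRd
ped_topological_order <- function(ped) {
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(ped$sire) | ped$sire %in% ped$id[placed]) &
      (is.na(ped$dam)  | ped$dam  %in% ped$id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  }
  ord
}

#' Construct a marker dataset
#'
#' Couples a marker map with a sample-by-marker genotype matrix. Markers are
#' sorted by chromosome (order of first appearance) and position; positions
#' must be strictly increasing within a chromosome.
#'
#' @param markers data frame with columns `name`, `chrom`, `pos` and
#'   optionally `a1`, `a2` (allele symbols; `a1` is the allele counted as 0).
#' @param samples character vector of sample ids (row order of `geno`).
#' @param geno integer matrix, `length(samples)` rows by `nrow(markers)`
#'   columns, with values 0/1/2/`NA` (allele-2 dosage).
#' @return A list of class `"marker_dataset"` with elements `markers`,
#'   `samples`, `geno`.
#' @export
marker_dataset <- function(markers, samples, geno) {
  stopifnot(is.data.frame(markers),
            all(c("name", "chrom", "pos") %in% names(markers)))
  if (is.null(markers$a1)) markers$a1 <- "A"
  if (is.null(markers$a2)) markers$a2 <- "B"
  samples <- as.character(samples)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(markers)) {
    stop(sprintf("genotype matrix is %d x %d but expected %d samples x %d markers",
                 nrow(geno), ncol(geno), length(samples), nrow(markers)))
  }
  if (anyDuplicated(samples)) stop("duplicate sample id(s)")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("genotype codes must be 0, 1, 2 or NA")
  chrom_lev <- unique(markers$chrom)
  ord <- order(match(markers$chrom, chrom_lev), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  nondecr <- tapply(markers$pos, factor(markers$chrom, levels = chrom_lev),
                    function(p) any(diff(p) <= 0))
  if (any(unlist(nondecr), na.rm = TRUE)) {
    stop("marker positions must be strictly increasing within a chromosome")
  }
  rownames(markers) <- NULL
  dimnames(geno) <- list(samples, markers$name)
  structure(list(markers = markers, samples = samples, geno = geno),
            class = "marker_dataset")
}

#' @method print marker_dataset
#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("<marker_dataset> %d samples x %d markers on %d chromosome(s)\n",
              length(x$samples), nrow(x$markers), length(unique(x$markers$chrom))))
  invisible(x)
}

#' Subset the markers of a dataset
#' @param ds a [marker_dataset()].
#' @param keep logical or integer index over markers.
#' @return A `marker_dataset` restricted to the selected markers.
#' @export
subset_markers <- function(ds, keep) {
  marker_dataset(ds$markers[keep, , drop = FALSE], ds$samples,
                 ds$geno[, keep, drop = FALSE])
}

#' Construct a set of genome intervals
#'
#' Coordinates are 1-based and inclusive at both ends. The interval *span*
#' used throughout the package is `end - start` (a plain coordinate
#' difference), which reproduces printed interval sizes computed from boundary
#' coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued positions, `start <= end`.
#' @param source optional per-interval provenance tag.
#' @return Data frame of class `"genome_intervals"` with columns `chrom`,
#'   `start`, `end`, `source`, sorted by chromosome and start.
#' @export
genome_intervals <- function(chrom = character(), start = numeric(),
                             end = numeric(), source = NA_character_) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  source = rep_len(as.character(source), n),
                  stringsAsFactors = FALSE)
  if (any(x$start > x$end)) stop("interval start exceeds end")
  if (any(x$start < 1, na.rm = TRUE)) stop("positions are 1-based (start >= 1)")
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("genome_intervals", "data.frame")
  x
}

as_genome_intervals <- function(df, source = NA_character_) {
  genome_intervals(df$chrom, df$start, df$end,
                   if (!is.null(df$source)) df$source else source)
}

#' Construct a set of biallelic variant records
#'
#' @param sites data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (one row per biallelic record).
#' @param samples character vector of sample ids.
#' @param geno integer matrix of alt-allele dosage, `nrow(sites)` rows by
#'   `length(samples)` columns (0/1/2/`NA`).
#' @return List of class `"variant_set"`.
#' @export
variant_set <- function(sites, samples, geno) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(sites)))
  samples <- as.character(samples)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites) || ncol(geno) != length(samples)) {
    stop("genotype matrix dimensions do not match sites/samples")
  }
  if (anyDuplicated(samples)) stop("duplicate sample id(s)")
  rownames(sites) <- NULL
  dimnames(geno) <- list(sites$id, samples)
  structure(list(sites = sites, samples = samples, geno = geno),
            class = "variant_set")
}

#' @method print variant_set
#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d biallelic records x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

subset_variants <- function(vs, keep) {
  variant_set(vs$sites[keep, , drop = FALSE], vs$samples,
              vs$geno[keep, , drop = FALSE])
}

#' Allele counts for one template source
#'
#' Quantitative abstraction of per-allele signal (sequencing read counts or
#' integerised chromatogram peak heights) at a heterozygous site.
#'
#' @param source `"gdna"` or `"cdna"`.
#' @param ref_count,alt_count non-negative integer counts; `alt_count` counts
#'   the mutant allele.
#' @return List of class `"allele_counts"`.
#' @export
allele_counts <- function(source, ref_count, alt_count) {
  source <- match.arg(source, c("gdna", "cdna"))
  if (ref_count < 0 || alt_count < 0) stop("counts must be non-negative")
  structure(list(source = source, ref_count = as.integer(ref_count),
                 alt_count = as.integer(alt_count)),
            class = "allele_counts")
}
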