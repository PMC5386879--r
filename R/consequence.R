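# Transcript-aware consequence annotation: genomic -> CDS mapping, codon
# translation, HGVS c./p. naming and stop-gain truncation fraction.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Construct a transcript model
#'
#' Holds the exon structure, strand, CDS genomic boundaries and the spliced
#' CDS sequence (coding strand, starting at the initiator ATG, excluding the
#' terminal stop codon unless the caller includes it).
#'
#' @param id transcript id.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame of `start`, `end` (1-based inclusive, sorted,
#'   non-overlapping, in genomic order).
#' @param cds_start,cds_end genomic coordinates of the CDS extremes.
#' @param cds_seq CDS nucleotide string; length must be a multiple of 3, equal
#'   the exonic width of the CDS range, start with ATG and translate without
#'   internal stop.
#' @return List of class `"transcript_model"`.
#' @export
transcript_model <- function(id, chrom, strand, exons, cds_start, cds_end,
                             cds_seq) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$start > exons$end)) stop("exon start exceeds end")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap")
  }
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) %% 3 != 0) stop("CDS length is not a multiple of 3")
  if (substr(cds_seq, 1, 3) != "ATG") stop("CDS must start with ATG")
  codons <- substring(cds_seq, seq(1, nchar(cds_seq), 3),
                      seq(3, nchar(cds_seq), 3))
  aas <- vapply(codons, translate_codon, "")
  if (any(aas[-length(aas)] == "*")) stop("CDS translation has an internal stop")
  m <- structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                      cds_start = cds_start, cds_end = cds_end,
                      cds_seq = cds_seq),
                 class = "transcript_model")
  if (length(coding_positions(m)) != nchar(cds_seq)) {
    stop("CDS sequence length does not match the exonic CDS width")
  }
  m
}

# genomic positions of coding bases in CDS order (strand-aware)
coding_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    s <- max(model$exons$start[i], model$cds_start)
    e <- min(model$exons$end[i], model$cds_end)
    if (s <= e) s:e else integer(0)
  }))
  if (model$strand == "-") rev(pos) else pos
}

#' Map a genomic position to a CDS coordinate
#'
#' @param model a [transcript_model()].
#' @param genomic_pos 1-based genomic position.
#' @return The 1-based CDS coordinate (counted on the coding strand, so minus
#'   strand transcripts count from the 3' genomic side), or `NA` for
#'   intronic/UTR/intergenic positions.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  match(genomic_pos, coding_positions(model))
}

#' Codon index and within-codon offset of a CDS position
#'
#' @param cds_pos 1-based CDS coordinate(s).
#' @return `list(codon =, offset =)` with `codon = ceiling(cds_pos / 3)` and
#'   `offset = ((cds_pos - 1) %% 3) + 1`, so `3 * (codon - 1) + offset`
#'   recovers `cds_pos`.
#' @examples
#' codon_of(388)  # codon 130, offset 1
#' @export
codon_of <- function(cds_pos) {
  if (any(cds_pos < 1)) stop("CDS positions are 1-based")
  list(codon = ceiling(cds_pos / 3), offset = ((cds_pos - 1) %% 3) + 1)
}

#' Fraction of the open reading frame truncated by a premature stop
#'
#' Counts the stop codon's own position as lost: `codon_index - 1` residues
#' are retained.
#'
#' @param codon_index codon of the premature stop (1-based).
#' @param protein_length_codons total codons in the ORF (excluding the natural
#'   stop if the CDS excludes it).
#' @return `(protein_length_codons - (codon_index - 1)) / protein_length_codons`.
#' @export
truncated_fraction <- function(codon_index, protein_length_codons) {
  if (codon_index < 1 || codon_index > protein_length_codons) {
    stop("codon_index must lie within the protein")
  }
  (protein_length_codons - (codon_index - 1)) / protein_length_codons
}

# distance to the nearest coding-exon boundary on the intron side, or NA
splice_distance <- function(model, pos) {
  d <- Inf
  for (i in seq_len(nrow(model$exons))) {
    s <- max(model$exons$start[i], model$cds_start)
    e <- min(model$exons$end[i], model$cds_end)
    if (s > e) next
    if (pos < s && (i > 1)) d <- min(d, s - pos)
    if (pos > e && (i < nrow(model$exons))) d <- min(d, pos - e)
  }
  if (is.finite(d)) d else NA_real_
}

new_consequence <- function(class, hgvs_c = NA_character_,
                            hgvs_p = NA_character_, codon_index = NA_integer_,
                            truncated_fraction = NA_real_,
                            cds_pos = NA_integer_) {
  structure(list(class = class, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                 codon_index = codon_index,
                 truncated_fraction = truncated_fraction, cds_pos = cds_pos),
            class = "consequence")
}

#' Annotate a variant against a transcript model
#'
#' Substitutes the alternate allele into the affected codon, translates
#' reference and alternate codons with the standard nuclear code, classifies
#' the change (synonymous, missense, nonsense, frameshift, splice, noncoding)
#' and emits HGVS `c.` and `p.` strings (three-letter residues, `*` for a
#' stop). Indels whose length change is not a multiple of 3 are frameshifts;
#' in-frame coding indels are reported as missense (protein-changing without
#' a new stop). Positions within 2 bp of a coding exon/intron boundary on the
#' intron side are canonical-splice.
#'
#' @param model a [transcript_model()].
#' @param chrom,pos,ref,alt the variant (VCF conventions, plus-strand
#'   alleles).
#' @return A `"consequence"` list: `class`, `hgvs_c`, `hgvs_p`, `codon_index`,
#'   `truncated_fraction`, `cds_pos`.
#' @export
annotate_variant <- function(model, chrom, pos, ref, alt) {
  if (chrom != model$chrom) return(new_consequence("noncoding"))
  cpos <- coding_positions(model)
  L <- nchar(model$cds_seq) / 3
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    cds <- match(pos, cpos)
    if (is.na(cds)) {
      d <- splice_distance(model, pos)
      if (!is.na(d) && d <= 2) {
        return(new_consequence("splice",
                               hgvs_c = sprintf("c.splice%+d%s>%s", d,
                                                toupper(ref), toupper(alt))))
      }
      return(new_consequence("noncoding"))
    }
    ref_cds <- toupper(ref); alt_cds <- toupper(alt)
    if (model$strand == "-") {
      ref_cds <- comp_base(ref_cds); alt_cds <- comp_base(alt_cds)
    }
    if (substr(model$cds_seq, cds, cds) != ref_cds) {
      stop(sprintf("reference mismatch at %s:%d (CDS %d): expected %s, got %s",
                   chrom, pos, cds, substr(model$cds_seq, cds, cds), ref_cds))
    }
    co <- codon_of(cds)
    codon_start <- 3 * (co$codon - 1) + 1
    ref_codon <- substr(model$cds_seq, codon_start, codon_start + 2)
    alt_codon <- ref_codon
    substr(alt_codon, co$offset, co$offset) <- alt_cds
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alt_codon)
    hgvs_c <- sprintf("c.%d%s>%s", cds, ref_cds, alt_cds)
    if (aa_alt == aa_ref) {
      return(new_consequence("synonymous", hgvs_c,
                             sprintf("p.%s%d=", AA3[aa_ref], co$codon),
                             cds_pos = cds))
    }
    if (aa_alt == "*") {
      return(new_consequence("nonsense", hgvs_c,
                             sprintf("p.%s%d*", AA3[aa_ref], co$codon),
                             codon_index = co$codon,
                             truncated_fraction = truncated_fraction(co$codon, L),
                             cds_pos = cds))
    }
    return(new_consequence("missense", hgvs_c,
                           sprintf("p.%s%d%s", AA3[aa_ref], co$codon,
                                   AA3[aa_alt]),
                           codon_index = co$codon, cds_pos = cds))
  }
  # indel: VCF-style, first base shared; changed bases start at pos + 1
  span <- pos + seq_len(max(nchar(ref), nchar(alt))) - 1
  cds_hit <- match(span, cpos)
  if (all(is.na(cds_hit))) {
    d <- min(vapply(span, function(p) {
      x <- splice_distance(model, p); if (is.na(x)) Inf else x
    }, numeric(1)))
    if (is.finite(d) && d <= 2) return(new_consequence("splice"))
    return(new_consequence("noncoding"))
  }
  cds <- min(cds_hit, na.rm = TRUE)
  co <- codon_of(cds)
  len_change <- nchar(alt) - nchar(ref)
  codon_start <- 3 * (co$codon - 1) + 1
  aa_ref <- translate_codon(substr(model$cds_seq, codon_start, codon_start + 2))
  if (len_change %% 3 != 0) {
    hgvs_c <- if (len_change < 0) {
      sprintf("c.%d_%ddel", cds, cds - len_change - 1)
    } else {
      sprintf("c.%d_%dins", cds, cds + 1)
    }
    return(new_consequence("frameshift", hgvs_c,
                           sprintf("p.(%s%dfs)", AA3[aa_ref], co$codon),
                           codon_index = co$codon, cds_pos = cds))
  }
  new_consequence("missense",
                  sprintf("c.%d_%dinframe", cds, cds + abs(len_change)),
                  sprintf("p.(%s%ddelins)", AA3[aa_ref], co$codon),
                  codon_index = co$codon, cds_pos = cds)
}

# first protein-changing (or otherwise most severe) annotation across models
annotate_against_transcripts <- function(transcripts, chrom, pos, ref, alt) {
  best <- new_consequence("noncoding")
  rank <- c(noncoding = 0, synonymous = 1, splice = 2, missense = 2,
            frameshift = 3, nonsense = 4)
  for (m in transcripts) {
    csq <- annotate_variant(m, chrom, pos, ref, alt)
    if (rank[csq$class] > rank[best$class]) best <- csq
  }
  best
}

#' Parse an HGVS c. substitution string
#'
#' Inverse of the `c.` naming emitted by [annotate_variant()] for SNVs.
#'
#' @param x string like `"c.388G>T"`.
#' @return `list(cds_pos =, ref =, alt =)`.
#' @export
parse_hgvs_c <- function(x) {
  m <- regmatches(x, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", x))[[1]]
  if (length(m) != 4) stop("not a c. substitution: ", x)
  list(cds_pos = as.integer(m[2]), ref = m[3], alt = m[4])
}
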