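provenance_line <- function(what, params = "") {
  sprintf("# autozyg %s %s%s",
          as.character(utils::packageVersion("autozyg")), what,
          if (nzchar(params)) paste0(" | ", params) else "")
}

#' Read pedigree and genotypes from PLINK text PED/MAP files
#'
#' The PED file must carry six leading columns (family id, individual id,
#' sire, dam, sex, phenotype) followed by two allele columns per marker; the
#' MAP file carries chromosome, marker name, genetic position and physical
#' position. Allele pair `0 0` becomes a missing call; phenotype 2 maps to
#' affected, 1 to unaffected, 0 or -9 to unknown. Per marker the two observed
#' allele symbols are sorted and the genotype code counts copies of the
#' second; monomorphic markers get `a2 = NA` and all-zero codes.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return `list(pedigree =, dataset =)` with a [pedigree()] and a
#'   [marker_dataset()]; marker order follows the MAP file (after per
#'   chromosome position sorting).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "name", "cm", "pos"))
  nm <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6 + 2 * nm)
  if (length(bad)) {
    stop(sprintf("PED line %d: expected %d fields (6 + 2 x %d markers) but found %d",
                 bad[1], 6 + 2 * nm, nm, nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  ids <- m[, 2]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in PED: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sex <- c("1" = "male", "2" = "female")[m[, 5]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("2" = "affected", "1" = "unaffected")[m[, 6]]
  aff[is.na(aff)] <- "unknown"
  ped <- pedigree(id = ids,
                  sire = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
                  dam  = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
                  sex = unname(sex), affection = unname(aff))
  geno <- matrix(NA_integer_, nrow(m), nm)
  a1 <- a2 <- rep(NA_character_, nm)
  for (j in seq_len(nm)) {
    x <- m[, 5 + 2 * j]
    y <- m[, 6 + 2 * j]
    miss <- x == "0" | y == "0"
    alleles <- sort(unique(c(x[!miss], y[!miss])))
    if (length(alleles) > 2) {
      stop(sprintf("marker %s has more than two alleles in PED", map$name[j]))
    }
    a1[j] <- if (length(alleles) >= 1) alleles[1] else NA_character_
    a2[j] <- if (length(alleles) == 2) alleles[2] else NA_character_
    g <- (x == a2[j]) + (y == a2[j])
    g[miss] <- NA_integer_
    if (is.na(a2[j])) g[!miss] <- 0L
    geno[, j] <- as.integer(g)
  }
  markers <- data.frame(name = map$name, chrom = as.character(map$chrom),
                        pos = map$pos, a1 = a1, a2 = a2,
                        stringsAsFactors = FALSE)
  list(pedigree = ped, dataset = marker_dataset(markers, ids, geno))
}

#' Write pedigree and genotypes as PLINK text PED/MAP
#'
#' The inverse of [read_ped_map()]. No provenance comment is written: comment
#' lines are not part of the PLINK text dialect.
#'
#' @param ped a [pedigree()] whose ids match `ds$samples`.
#' @param ds a [marker_dataset()].
#' @param ped_path,map_path output paths.
#' @param famid family id written in column 1.
#' @export
write_ped_map <- function(ped, ds, ped_path, map_path, famid = "FAM1") {
  stopifnot(setequal(ped$id, ds$samples))
  mk <- ds$markers
  utils::write.table(
    data.frame(mk$chrom, mk$name, 0, mk$pos),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  ped <- ped[match(ds$samples, ped$id), , drop = FALSE]
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affection]
  a1 <- mk$a1
  a2 <- ifelse(is.na(mk$a2), mk$a1, mk$a2)
  lines <- vapply(seq_along(ds$samples), function(i) {
    g <- ds$geno[i, ]
    x <- ifelse(is.na(g), "0", ifelse(g >= 1, a2, a1))
    y <- ifelse(is.na(g), "0", ifelse(g == 2, a2, a1))
    paste(c(famid, ped$id[i],
            ifelse(is.na(ped$sire[i]), "0", ped$sire[i]),
            ifelse(is.na(ped$dam[i]), "0", ped$dam[i]),
            sex[i], aff[i], rbind(x, y)), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(NULL)
}

# Map one GT string vector to alt-k dosage for a record with `nalt` ALT
# alleles. Phased separators are accepted; half calls, non-diploid calls and
# malformed strings become missing (with one warning per file, handled by the
# caller).
gt_to_dosage <- function(gt, k, nalt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  bad <- logical(length(gt))
  out <- rep(NA_integer_, length(gt))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) == 2L && all(p == ".")) next          # ./. stays NA silently
    if (length(p) != 2L || any(!p %in% as.character(0:nalt))) {
      bad[i] <- TRUE                                    # half call / malformed
      next
    }
    a <- as.integer(p)
    if (all(a %in% c(0L, k))) out[i] <- sum(a == k)
    # alleles referencing other alts stay missing for this record
  }
  list(dosage = out, malformed = bad)
}

#' Read a VCF file into a set of biallelic variant records
#'
#' Parsed with \pkg{vcfR}. GT `0/0` maps to 0, `0/1`//`1/0` to 1, `1/1` to 2
#' and `./.` to `NA`; phased separators are accepted. Multi-allelic sites are
#' decomposed into one biallelic record per ALT allele; genotypes referencing
#' another ALT become missing for that record. Half calls and malformed GT
#' strings become missing with a warning.
#'
#' @param path path to a VCF 4.x file with a GT FORMAT subfield.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF has no sample genotype columns")
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stop("VCF record without GT in FORMAT")
  samples <- colnames(gt)[-1]
  fix <- v@fix
  n <- nrow(fix)
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  id <- fix[, "ID"]; ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  id[is.na(id) | id == "."] <- sprintf("rec%06d", which(is.na(id) | id == "."))
  out_sites <- list(); out_geno <- list()
  any_malformed <- FALSE
  for (r in seq_len(n)) {
    gstr <- vapply(strsplit(gt[r, -1], ":", fixed = TRUE), function(x) {
      if (length(x) >= gt_idx[r]) x[gt_idx[r]] else NA_character_
    }, character(1))
    gstr[is.na(gstr)] <- "./."       # vcfR reports absent GT fields as NA
    alts <- strsplit(alt[r], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      conv <- gt_to_dosage(gstr, k, length(alts))
      any_malformed <- any_malformed || any(conv$malformed)
      out_sites[[length(out_sites) + 1L]] <- data.frame(
        chrom = chrom[r], pos = pos[r],
        id = if (length(alts) == 1) id[r] else sprintf("%s_alt%d", id[r], k),
        ref = ref[r], alt = alts[k], stringsAsFactors = FALSE)
      out_geno[[length(out_geno) + 1L]] <- conv$dosage
    }
  }
  if (any_malformed) {
    warning("malformed or half-called GT string(s) set to missing")
  }
  sites <- do.call(rbind, out_sites)
  geno <- do.call(rbind, out_geno)
  variant_set(sites, samples, geno)
}

#' Write a variant set as a minimal VCF 4.2 file
#'
#' Emits GT-only records. The header carries a deterministic provenance line
#' (tool version, no timestamp), so identical inputs give byte-identical
#' files.
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @export
write_vcf <- function(vs, path) {
  gmap <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(vs$sites)), function(r) {
    g <- vs$geno[r, ]
    gt <- ifelse(is.na(g), "./.", gmap[g + 1L])
    paste(c(vs$sites$chrom[r], format(vs$sites$pos[r], scientific = FALSE),
            vs$sites$id[r], vs$sites$ref[r], vs$sites$alt[r],
            ".", ".", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=autozyg_", as.character(utils::packageVersion("autozyg"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(NULL)
}

#' Write genome intervals as BED3
#'
#' Internal 1-based inclusive intervals `[start, end]` are emitted as BED's
#' 0-based half-open `[start - 1, end)`; [read_bed()] inverts the conversion
#' exactly. A provenance comment line is written first.
#'
#' @param intervals a [genome_intervals()] frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  lines <- provenance_line("BED3 (0-based half-open)")
  if (nrow(intervals)) {
    lines <- c(lines, sprintf("%s\t%s\t%s", intervals$chrom,
                              format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                              format(intervals$end, scientific = FALSE, trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a BED3 file into 1-based inclusive intervals
#' @param path path to a BED file; `#`/`track` lines are skipped.
#' @return A [genome_intervals()] frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(genome_intervals())
  f <- strsplit(lines, "\t", fixed = TRUE)
  genome_intervals(chrom = vapply(f, `[`, "", 1),
                   start = as.numeric(vapply(f, `[`, "", 2)) + 1,
                   end = as.numeric(vapply(f, `[`, "", 3)))
}

#' Write a transcript model as an exon table plus CDS FASTA
#'
#' @param model a [transcript_model()].
#' @param exon_path output TSV (columns transcript, chrom, strand, exon_start,
#'   exon_end, cds_start, cds_end).
#' @param fasta_path output FASTA holding the spliced CDS on the coding
#'   strand.
#' @export
write_transcript <- function(model, exon_path, fasta_path) {
  tab <- data.frame(transcript = model$id, chrom = model$chrom,
                    strand = model$strand,
                    exon_start = model$exons$start, exon_end = model$exons$end,
                    cds_start = model$cds_start, cds_end = model$cds_end)
  con <- file(exon_path, "w")
  writeLines(provenance_line("exon table"), con)
  suppressWarnings(utils::write.table(tab, con, quote = FALSE, sep = "\t",
                                      row.names = FALSE))
  close(con)
  seq <- Biostrings::DNAStringSet(model$cds_seq)
  names(seq) <- model$id
  Biostrings::writeXStringSet(seq, fasta_path)
  invisible(NULL)
}

#' Read a transcript model from an exon table plus CDS FASTA
#' @param exon_path,fasta_path paths written by [write_transcript()].
#' @return A [transcript_model()].
#' @export
read_transcript <- function(exon_path, fasta_path) {
  tab <- utils::read.table(exon_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  id <- tab$transcript[1]
  transcript_model(
    id = id, chrom = as.character(tab$chrom[1]), strand = tab$strand[1],
    exons = data.frame(start = tab$exon_start, end = tab$exon_end),
    cds_start = tab$cds_start[1], cds_end = tab$cds_end[1],
    cds_seq = as.character(seqs[[match(id, names(seqs))]]))
}

#' Write and read allele-count tables (TSV: source, ref_count, alt_count)
#' @param counts list of [allele_counts()].
#' @param path file path.
#' @export
write_allele_counts <- function(counts, path) {
  tab <- data.frame(source = vapply(counts, `[[`, "", "source"),
                    ref_count = vapply(counts, `[[`, 0L, "ref_count"),
                    alt_count = vapply(counts, `[[`, 0L, "alt_count"))
  con <- file(path, "w")
  writeLines(provenance_line("allele counts"), con)
  suppressWarnings(utils::write.table(tab, con, quote = FALSE, sep = "\t",
                                      row.names = FALSE))
  close(con)
  invisible(NULL)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    allele_counts(tab$source[i], tab$ref_count[i], tab$alt_count[i])
  })
}
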