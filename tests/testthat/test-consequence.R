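test_that("codon arithmetic ties CDS positions to protein residues", {
  expect_equal(codon_of(388), list(codon = 130, offset = 1))
  expect_equal(codon_of(3), list(codon = 1, offset = 3))
  expect_equal(codon_of(4), list(codon = 2, offset = 1))
  expect_error(codon_of(0), "1-based")
  p <- 1:300
  co <- codon_of(p)
  expect_equal(3 * (co$codon - 1) + co$offset, p)
})

test_that("truncated fraction counts the stop codon itself as lost", {
  expect_equal(truncated_fraction(130, 650), 521 / 650)
  expect_gt(truncated_fraction(130, 650), 0.80)
  expect_equal(truncated_fraction(1, 100), 1)
  expect_equal(truncated_fraction(100, 100), 1 / 100)
  expect_error(truncated_fraction(0, 10), "within")
  expect_error(truncated_fraction(11, 10), "within")
})

test_that("transcript model validation rejects inconsistent geometry", {
  ex <- data.frame(start = 1000, end = 1011)
  expect_error(transcript_model("t", "1", "+", ex, 1000, 1011, "ATGAAA"),
               "exonic CDS width")
  expect_error(transcript_model("t", "1", "+", ex, 1000, 1011,
                                "ATGAAAATGAAAA"), "multiple of 3")
  expect_error(transcript_model("t", "1", "+", ex, 1000, 1011,
                                "AAAAAAAAAAAA"), "start with ATG")
  expect_error(transcript_model("t", "1", "+", ex, 1000, 1011,
                                "ATGTAAAAAACC"), "internal stop")
  ex2 <- data.frame(start = c(1000, 1005), end = c(1006, 1010))
  expect_error(transcript_model("t", "1", "+", ex2, 1000, 1010, "ATGAAA"),
               "overlap")
})

test_that("genomic-to-CDS mapping is strand aware", {
  m <- transcript_model("t", "1", "+", data.frame(start = 1000, end = 1011),
                        1000, 1011, "ATGGAGAAATGC")
  expect_equal(genomic_to_cds(m, 1000), 1)
  expect_equal(genomic_to_cds(m, 1011), 12)
  expect_true(is.na(genomic_to_cds(m, 999)))
  mm <- transcript_model("t", "1", "-", data.frame(start = 1000, end = 1011),
                         1000, 1011, "ATGGAGAAATGC")
  expect_equal(genomic_to_cds(mm, 1011), 1)   # minus strand counts from 3'
  expect_equal(genomic_to_cds(mm, 1000), 12)
  # the simulator's fixture maps the planted site to CDS 388 on both strands
  for (strand in c("+", "-")) {
    tx <- simulate_transcript(sim_params(strand = strand), seed = 7)
    expect_equal(genomic_to_cds(tx$model, tx$variant$pos), 388)
  }
})

test_that("SNV annotation classifies, names and checks the reference", {
  tx <- simulate_transcript(sim_params(), seed = 3)
  m <- tx$model
  v <- tx$variant
  csq <- annotate_variant(m, v$chrom, v$pos, v$ref, v$alt)
  expect_identical(csq$class, "nonsense")
  expect_identical(csq$hgvs_c, "c.388G>T")
  expect_identical(csq$hgvs_p, "p.Glu130*")
  expect_equal(csq$codon_index, 130)
  expect_equal(csq$truncated_fraction, truncated_fraction(130, 855))
  # GAG -> GAA at the third codon base is synonymous (both Glu)
  syn <- annotate_variant(m, v$chrom, v$pos + 2, "G", "A")
  expect_identical(syn$class, "synonymous")
  expect_identical(syn$hgvs_c, "c.390G>A")
  # wrong reference allele is a hard error
  expect_error(annotate_variant(m, v$chrom, v$pos, "A", "T"),
               "reference mismatch")
  # a deletion of two bases shifts the frame
  fs <- annotate_variant(m, v$chrom, v$pos, "GAG", "G")
  expect_identical(fs$class, "frameshift")
  expect_match(fs$hgvs_p, "fs\\)$")
  # canonical splice dinucleotide, deep intron, and intergenic positions
  exon1_end <- m$exons$end[1]
  expect_identical(annotate_variant(m, v$chrom, exon1_end + 2, "A", "C")$class,
                   "splice")
  expect_identical(annotate_variant(m, v$chrom, exon1_end + 100,
                                    "A", "C")$class, "noncoding")
  expect_identical(annotate_variant(m, v$chrom, 1, "A", "C")$class,
                   "noncoding")
  expect_identical(annotate_variant(m, "9", v$pos, "G", "T")$class,
                   "noncoding")
})

test_that("HGVS c. strings round-trip through the parser", {
  tx <- simulate_transcript(sim_params(), seed = 5)
  set.seed(5)
  s <- strsplit(tx$model$cds_seq, "")[[1]]
  for (rep in 1:20) {
    cds <- sample(4:length(s), 1)          # avoid mutating the start codon
    ref <- s[cds]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    h <- sprintf("c.%d%s>%s", cds, ref, alt)
    back <- parse_hgvs_c(h)
    expect_equal(back$cds_pos, cds)
    expect_identical(back$ref, ref)
    expect_identical(back$alt, alt)
  }
  expect_error(parse_hgvs_c("c.12del"), "not a c")
})

test_that("annotation agrees with a mutate-and-translate oracle", {
  set.seed(71)
  for (strand in c("+", "-")) {
    tx <- simulate_transcript(sim_params(strand = strand,
                                         protein_length_codons = 200,
                                         stop_codon_index = 40), seed = 11)
    m <- tx$model
    cpos <- sort(unlist(lapply(seq_len(nrow(m$exons)), function(i) {
      m$exons$start[i]:m$exons$end[i]
    })))
    for (rep in 1:40) {
      gpos <- sample(cpos, 1)
      ref <- substr(m$cds_seq, genomic_to_cds(m, gpos), genomic_to_cds(m, gpos))
      if (m$strand == "-") ref <- chartr("ACGT", "TGCA", ref)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- annotate_variant(m, m$chrom, gpos, ref, alt)$class
      want <- naive_snv_class(m, gpos, ref, alt)
      expect_identical(got, want)
    }
  }
})

test_that("transcript models round-trip through exon table + FASTA", {
  tx <- simulate_transcript(sim_params(strand = "-"), seed = 9)
  ex <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcript(tx$model, ex, fa)
  back <- read_transcript(ex, fa)
  expect_identical(back$cds_seq, tx$model$cds_seq)
  expect_equal(back$exons, tx$model$exons)
  expect_identical(back$strand, "-")
  csq <- annotate_variant(back, tx$variant$chrom, tx$variant$pos,
                          tx$variant$ref, tx$variant$alt)
  expect_identical(csq$hgvs_p, "p.Glu130*")
})
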