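test_that("identical parameters and seed give bit-identical studies", {
  p <- small_sim_params()
  a <- simulate_study(p, seed = 9)
  b <- simulate_study(p, seed = 9)
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$wgs$variants$geno, b$wgs$variants$geno)
  expect_identical(a$transcript$model$cds_seq, b$transcript$model$cds_seq)
  expect_identical(a$nmd_counts, b$nmd_counts)
  fa <- withr::local_tempfile(fileext = ".vcf")
  fb <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(a$wgs$variants, fa)
  write_vcf(b$wgs$variants, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(simulate_study(p, seed = 10)$dataset$geno,
                         a$dataset$geno))
})

test_that("founder pool: uniform Beta gives folded mean 1/4; one causal hap", {
  p <- sim_params(n_chromosomes = 1, n_markers_per_chrom = 5000,
                  founder_maf_beta = c(1, 1), n_founder_haplotypes = 8)
  pool <- simulate_founder_haplotypes(p, seed = 21)
  # E[min(p, 1-p)] = 1/4 for p ~ Beta(1,1); Monte-Carlo vs analytic, 3 SE
  folded <- pmin(pool$freqs, 1 - pool$freqs)
  se <- stats::sd(folded) / sqrt(length(folded))
  expect_lt(abs(mean(folded) - 0.25), 3 * se)
  expect_identical(sum(pool$causal), 1L)
  expect_identical(pool$causal[1], 1L)
})

test_that("gene drop: no-recombination limit and affection conditioning", {
  ped <- nfs_pedigree()
  p <- sim_params(n_chromosomes = 1, n_markers_per_chrom = 300,
                  recomb_rate_cM_per_Mb = 0, missing_rate = 0,
                  genotype_error_rate = 0)
  pool <- simulate_founder_haplotypes(p, seed = 4)
  gd <- gene_drop(ped, pool, p, seed = 4)
  # without crossovers every affected is autozygous across the chromosome
  blk <- gd$truth$autozygous_blocks
  expect_equal(nrow(blk), 3)
  expect_equal(blk$start, rep(min(pool$markers$pos), 3))
  expect_equal(blk$end, rep(max(pool$markers$pos), 3))
  expect_true(all(gd$truth$causal_dose[ped$affection == "affected"] == 2))
  expect_true(all(gd$truth$causal_dose[ped$affection == "unaffected"] < 2))
})

test_that("gene drop is Mendel-consistent without error, noisy with error", {
  ped <- nfs_pedigree()
  p0 <- sim_params(n_chromosomes = 2, n_markers_per_chrom = 5000,
                   missing_rate = 0, genotype_error_rate = 0)
  pool <- simulate_founder_haplotypes(p0, seed = 5)
  gd0 <- gene_drop(ped, pool, p0, seed = 5)
  expect_identical(nrow(detect_mendel_errors(ped, gd0$dataset)), 0L)
  p1 <- sim_params(n_chromosomes = 2, n_markers_per_chrom = 5000,
                   missing_rate = 0, genotype_error_rate = 0.01)
  gd1 <- gene_drop(ped, pool, p1, seed = 5)
  expect_gt(nrow(detect_mendel_errors(ped, gd1$dataset)), 0)
})

test_that("WGS table: causal passes the filter, background matches freqs", {
  st <- simulate_study(small_sim_params(), seed = 13)
  surv <- segregation_filter(st$wgs$variants, st$wgs$roles)
  expect_true(st$wgs$causal_id %in% surv$sites$id)
  # empirical alt-allele frequencies track the generating frequencies
  vs <- st$wgs$variants
  bg <- setdiff(names(st$wgs$bg_freqs), st$wgs$coseg_ids)
  bg <- bg[bg %in% vs$sites$id]
  g <- vs$geno[match(bg, vs$sites$id), , drop = FALSE]
  emp <- rowMeans(g, na.rm = TRUE) / 2
  f <- st$wgs$bg_freqs[bg]
  n2 <- 2 * rowSums(!is.na(g))
  z <- (emp - f) / sqrt(f * (1 - f) / n2)
  expect_gt(mean(abs(z) < 4), 0.99)
})

test_that("transcript fixture plants the premature stop as designed", {
  p <- sim_params()
  tx <- simulate_transcript(p, seed = 2)
  csq <- annotate_variant(tx$model, tx$variant$chrom, tx$variant$pos,
                          tx$variant$ref, tx$variant$alt)
  expect_identical(csq$class, "nonsense")
  expect_identical(csq$hgvs_c, "c.388G>T")
  expect_identical(csq$hgvs_p, "p.Glu130*")
  # reverse-strand embedding yields the same protein annotation
  pm <- sim_params(strand = "-")
  txm <- simulate_transcript(pm, seed = 2)
  csqm <- annotate_variant(txm$model, txm$variant$chrom, txm$variant$pos,
                           txm$variant$ref, txm$variant$alt)
  expect_identical(csqm$hgvs_c, "c.388G>T")
  expect_identical(csqm$hgvs_p, "p.Glu130*")
  # truncation arithmetic on a 650-codon fixture
  p650 <- sim_params(protein_length_codons = 650)
  t650 <- simulate_transcript(p650, seed = 2)
  c650 <- annotate_variant(t650$model, t650$variant$chrom, t650$variant$pos,
                           t650$variant$ref, t650$variant$alt)
  expect_equal(c650$truncated_fraction, (650 - 129) / 650, tolerance = 1e-12)
})

test_that("NMD count fixture validates inputs", {
  expect_error(simulate_nmd_counts(0.5, 0, 100, seed = 1), "positive")
  expect_error(simulate_nmd_counts(1.5, 100, 100, seed = 1), "fraction")
  counts <- simulate_nmd_counts(0.25, 100, 100, seed = 1)
  expect_identical(counts$gdna$ref_count + counts$gdna$alt_count, 100L)
  expect_identical(counts$cdna$source, "cdna")
})

test_that("study bundle writes its full report set to disk", {
  st <- simulate_study(small_sim_params(), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$causal_pos, st$truth$causal_pos)
  back <- read_ped_map(paths[["ped"]], paths[["map"]])
  expect_identical(back$pedigree$id, st$pedigree$id)
})
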