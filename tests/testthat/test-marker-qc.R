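test_that("call rate and minor allele frequency match hand counts", {
  ds <- make_ds(rbind(c(0, 1, 2, NA), c(0, 0, 0, 0)))
  expect_equal(sample_call_rate(ds, "S01"), 0.75)
  expect_equal(sample_call_rate(ds, "S02"), 1)
  expect_error(sample_call_rate(ds, "nope"), "unknown sample")

  # {hom_ref x3, het x2, hom_alt x2}: alt count 6 of 14 -> MAF 3/7
  ds2 <- make_ds(matrix(c(0, 0, 0, 1, 1, 2, 2), ncol = 1))
  expect_equal(minor_allele_frequency(ds2, 1), 3 / 7)
  expect_equal(minor_allele_frequency(make_ds(matrix(0, 5, 1)), 1), 0)
  expect_equal(minor_allele_frequency(make_ds(matrix(1, 7, 1)), 1), 0.5)
  expect_true(is.na(minor_allele_frequency(make_ds(matrix(NA_integer_, 3, 1)),
                                           1)))
})

test_that("Mendel error detection follows single-locus transmission rules", {
  ped <- trio_pedigree()
  check <- function(f, m, c) {
    ds <- make_ds(rbind(f, m, c), samples = c("F", "M", "C1"))
    nrow(detect_mendel_errors(ped, ds)) > 0
  }
  expect_true(check(0, 0, 1))     # hom_ref x hom_ref -> het impossible
  expect_false(check(0, 2, 1))    # hom_ref x hom_alt -> het required
  expect_true(check(0, 2, 0))
  expect_false(check(NA, NA, 2))  # both parents missing: never an error
  expect_true(check(0, NA, 2))    # one typed parent still constrains
  expect_true(check(NA, 0, 2))
  expect_false(check(0, NA, 1))
  expect_false(check(1, 1, NA))   # missing child never an error
})

test_that("pruning attributes removals to the first failing criterion", {
  ped <- nfs_pedigree()
  ids <- ped$id  # S1 D1 D2 D3 A1 A2 A3
  het_all <- rep(1, 7)
  survivor <- c(1, 1, 1, 1, 0, 2, 1)            # MAF 0.5, Mendel-consistent
  g <- cbind(
    rep(0, 7),                                  # m1 noninformative
    het_all, survivor,                          # m2 m3: X chromosome
    c(1, 1, 1, 1, NA, 1, 2),                    # m4 missing in a study animal
    c(0, 0, 1, 1, 1, 1, 1),                     # m5 Mendel error (S1xD1 -> A1)
    c(1, 0, 0, 0, 0, 0, 0),                     # m6 MAF 1/14 (het founder)
    c(0, 0, 0, 1, 0, 0, 0),                     # m7 MAF 1/14
    het_all, survivor, rev(survivor))           # m8-m10 survive
  ds <- make_ds(g, chrom = c("1", "X", "X", rep("1", 7)),
                pos = c(10, 10, 20, 20, 30, 40, 50, 60, 70, 80) * 1000,
                samples = ids)
  out <- prune_markers(ped, ds, qc_criteria(min_sample_call_rate = 0))
  expect_equal(unname(out$report$removed),
               c(1, 2, 1, 1, 2))                # per-criterion counts
  expect_equal(out$report$n_survivors, 3)
  expect_equal(sum(out$report$removed) + out$report$n_survivors,
               out$report$n_input)
  # disabling everything is the identity
  off <- qc_criteria(min_maf = 0, excluded_chroms = character(),
                     max_missing_in_study = 7,
                     drop_mendel_error_markers = FALSE,
                     drop_noninformative = FALSE, min_sample_call_rate = 0)
  expect_equal(prune_markers(ped, ds, off)$report$n_survivors, 10)
  # an X marker is removed under defaults
  expect_false(any(out$dataset$markers$chrom == "X"))
})

test_that("pruning is idempotent and order-independent", {
  st <- simulate_study(small_sim_params(), seed = 6)
  crit <- qc_criteria(min_sample_call_rate = 0)
  once <- prune_markers(st$pedigree, st$dataset, crit)
  twice <- prune_markers(st$pedigree, once$dataset, crit)
  expect_identical(twice$dataset$markers$name, once$dataset$markers$name)
  expect_identical(sum(twice$report$removed), 0L)
  # shuffled marker input: constructor re-sorts, survivors identical
  perm <- sample(nrow(st$dataset$markers))
  shuffled <- marker_dataset(st$dataset$markers[perm, ], st$dataset$samples,
                             st$dataset$geno[, perm])
  again <- prune_markers(st$pedigree, shuffled, crit)
  expect_setequal(again$dataset$markers$name, once$dataset$markers$name)
})

test_that("clean fully-typed data loses only noninformative markers", {
  p <- small_sim_params(missing_rate = 0, genotype_error_rate = 0)
  st <- simulate_study(p, seed = 8)
  crit <- qc_criteria(min_maf = 0)
  out <- prune_markers(st$pedigree, st$dataset, crit)
  removed <- out$report$removed
  expect_equal(unname(removed[c("sex_chromosome", "missing_in_study",
                                "mendel_error", "low_maf")]), rep(0L, 4))
  expect_gt(removed[["noninformative"]], 0)
})

test_that("samples below the call-rate floor are excluded before pruning", {
  ped <- nfs_pedigree()
  g <- matrix(rep(c(1, 1, 1, 1, 0, 1, 2), 40), nrow = 7)
  g[2, 1:30] <- NA                       # D1 call rate 10/40 = 0.25
  ds <- make_ds(g, samples = ped$id)
  out <- prune_markers(ped, ds, qc_criteria(min_maf = 0,
                                            max_missing_in_study = 7))
  expect_identical(out$report$excluded_samples, "D1")
  expect_false("D1" %in% out$dataset$samples)
})
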