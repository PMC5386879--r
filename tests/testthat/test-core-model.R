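test_that("pedigree constructor enforces structural invariants", {
  expect_s3_class(nfs_pedigree(), "pedigree")
  expect_error(pedigree(id = c("a", "a")), "duplicate")
  expect_error(pedigree(id = c("a", "b"), sire = c(NA, "a"),
                        dam = c(NA, NA)), "one recorded parent")
  expect_error(pedigree(id = "a", sire = "x", dam = "y"), "unresolved")
  expect_error(pedigree(id = c("a", "b"), sire = c("b", "a"),
                        dam = c("b", "a")), "cycle|unresolved|ancestor")
  expect_error(pedigree(id = c("a", "b", "c"), sire = c(NA, NA, "a"),
                        dam = c(NA, NA, "b"),
                        sex = c("female", "female", "unknown")),
               "sire is recorded as female")
  ped <- nfs_pedigree()
  expect_identical(sum(is_founder(ped)), 4L)
})

test_that("marker_dataset validates dimensions and map sorting", {
  expect_error(marker_dataset(data.frame(name = "m1", chrom = "1", pos = 1),
                              c("a", "b"), matrix(0L, 2, 2)),
               "expected 2 samples x 1 markers")
  ds <- make_ds(matrix(0L, 2, 3), pos = c(30, 10, 20))
  expect_equal(ds$markers$pos, c(10, 20, 30))  # sorted by position
  expect_error(make_ds(matrix(0L, 2, 2), pos = c(5, 5)),
               "strictly increasing")
  expect_error(make_ds(matrix(5L, 2, 2)), "genotype codes")
})

test_that("PED/MAP files round-trip through write and read", {
  ped <- nfs_pedigree()
  ds <- random_polymorphic_dataset(7, 25, seed = 11)
  ds$geno[3, 4] <- NA  # ensure a missing call survives the trip
  ds <- marker_dataset(ds$markers, ped$id, ds$geno)
  pedf <- withr::local_tempfile(fileext = ".ped")
  mapf <- withr::local_tempfile(fileext = ".map")
  write_ped_map(ped, ds, pedf, mapf)
  back <- read_ped_map(pedf, mapf)
  expect_equal(unname(back$dataset$geno), unname(ds$geno))
  expect_equal(back$dataset$markers$name, ds$markers$name)
  expect_equal(back$dataset$markers$pos, ds$markers$pos)
  expect_equal(back$pedigree$sire, ped$sire)
  expect_equal(back$pedigree$affection, ped$affection)
  # writing the re-read dataset reproduces the file byte for byte
  pedf2 <- withr::local_tempfile(fileext = ".ped")
  mapf2 <- withr::local_tempfile(fileext = ".map")
  write_ped_map(back$pedigree, back$dataset, pedf2, mapf2)
  expect_identical(readLines(pedf2), readLines(pedf))
  expect_identical(readLines(mapf2), readLines(mapf))
})

test_that("PED parsing maps missing genotypes and rejects malformed rows", {
  mapf <- withr::local_tempfile(fileext = ".map")
  pedf <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"), mapf)
  writeLines(c("FAM1 F 0 0 1 1 A A A G",
               "FAM1 M 0 0 2 1 0 0 G G",
               "FAM1 C F M 1 2 A A A G"), pedf)
  out <- read_ped_map(pedf, mapf)
  expect_true(is.na(out$dataset$geno["M", "m1"]))       # "0 0" -> missing
  expect_identical(out$pedigree$affection,
                   c("unaffected", "unaffected", "affected"))
  expect_identical(out$pedigree$sex, c("male", "female", "male"))
  writeLines(c("FAM1 F 0 0 1 A A A G"), pedf)           # 5 leading columns
  expect_error(read_ped_map(pedf, mapf), "line 1")
  writeLines(c("FAM1 F 0 0 1 1 A A A G",
               "FAM1 F 0 0 1 1 A A A G"), pedf)
  expect_error(read_ped_map(pedf, mapf), "duplicate")
})

test_that("VCF reader maps GT states, decomposes multi-allelics, round-trips", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv1\tG\tT\t.\t.\t.\tGT\t0/1\t1/1\t./.",
    "1\t200\tv2\tA\tC,T\t.\t.\t.\tGT\t0/1\t2/2\t1/2",
    "1\t300\tv3\tG\tA\t.\t.\t.\tGT\t0|1\t0/0\t1|1"), f)
  vs <- read_vcf(f)
  expect_equal(nrow(vs$sites), 4)                       # v2 decomposed
  expect_equal(unname(vs$geno[1, ]), c(1L, 2L, NA))
  a1 <- vs$geno[vs$sites$id == "v2_alt1", ]
  a2 <- vs$geno[vs$sites$id == "v2_alt2", ]
  expect_equal(unname(a1), c(1L, NA, NA))               # other-alt calls -> NA
  expect_equal(unname(a2), c(NA, 2L, NA))
  expect_equal(unname(vs$geno[4, ]), c(1L, 0L, 2L))     # phased accepted
  # half calls become missing with a warning
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\tv1\tG\tT\t.\t.\t.\tGT\t0/."), f)
  expect_warning(v2 <- read_vcf(f), "missing")
  expect_true(is.na(v2$geno[1, 1]))
  # biallelic write -> read round trip
  vs0 <- toy_variants(rbind(c(0, 1, 2), c(2, NA, 0)))
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs0, out)
  back <- read_vcf(out)
  expect_equal(unname(back$geno), unname(vs0$geno))
  expect_equal(back$sites$pos, vs0$sites$pos)
})

test_that("BED conversion is an exact 1-based/0-based bijection", {
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(genome_intervals("chr7", 36013146, 53111271), f)
  lines <- readLines(f)
  expect_identical(lines[length(lines)], "chr7\t36013145\t53111271")
  write_bed(genome_intervals("1", 100, 100), f)         # single base
  expect_identical(readLines(f)[2], "1\t99\t100")
  write_bed(genome_intervals(), f)                      # empty set
  expect_equal(nrow(read_bed(f)), 0)
  set.seed(5)
  ivs <- genome_intervals(sample(c("1", "2"), 30, TRUE),
                          s <- sample.int(1e6, 30), s + sample.int(1e4, 30))
  write_bed(ivs, f)
  back <- read_bed(f)
  expect_equal(back$start, ivs$start)
  expect_equal(back$end, ivs$end)
})
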