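test_that("LOD at theta = 0.5 is exactly zero and grids must include it", {
  ped <- nfs_pedigree()
  set.seed(31)
  for (rep in 1:8) {
    geno <- sample(c(0:2, NA), 7, replace = TRUE, prob = c(.35, .3, .3, .05))
    r <- lod_score(ped, geno, runif(1, 0.1, 0.9))
    expect_lt(abs(r$lod[r$theta == 0.5]), 1e-9)
    expect_gte(r$max_lod, 0)
  }
  expect_error(lod_score(ped, rep(1, 7), 0.5, theta_grid = c(0, 0.1)),
               "0.5")
})

test_that("peeling equals the enumeration oracle on mixed pedigrees", {
  set.seed(77)
  model <- disease_model()
  thetas <- c(0, 0.1, 0.3, 0.5)
  for (ped in enum_test_pedigrees()[c(1, 3, 4)]) {
    for (rep in 1:6) {
      n <- nrow(ped)
      geno <- sample(c(0:2, NA), n, replace = TRUE,
                     prob = c(.35, .2, .35, .1))
      p <- runif(1, 0.1, 0.9)
      ll <- pedigree_loglik(ped, geno, p, model, thetas)
      oracle <- vapply(thetas, function(th) {
        enum_loglik(ped, geno, p, theta = th)
      }, numeric(1))
      both_inf <- is.infinite(ll) & is.infinite(oracle)
      expect_true(all(both_inf | abs(ll - oracle) < 1e-9))
    }
  }
})

test_that("monomorphic markers carry no linkage information", {
  ped <- nfs_pedigree()
  ll <- pedigree_loglik(ped, rep(0L, 7), 0.3, disease_model(),
                        seq(0, 0.5, 0.1))
  expect_lt(diff(range(ll)), 1e-12)
})

test_that("cosegregation peaks at theta 0; an obligate recombinant forbids it", {
  # carrier x carrier nuclear family, affected child homozygous at a fully
  # informative marker
  ped <- nuclear_pedigree(1)
  r <- lod_score(ped, c(1, 1, 2), 0.5)
  expect_equal(r$theta_hat, 0)
  expect_equal(r$max_lod, r$lod[1])
  oracle0 <- enum_loglik(ped, c(1, 1, 2), 0.5, theta = 0)
  oracle5 <- enum_loglik(ped, c(1, 1, 2), 0.5, theta = 0.5)
  expect_equal(r$max_lod, (oracle0 - oracle5) / log(10), tolerance = 1e-9)

  # three affected sibs, one carrying the other parental allele: impossible
  # at theta 0, best explained by an interior recombination fraction
  ped3 <- nuclear_pedigree(3)
  r3 <- lod_score(ped3, c(1, 1, 2, 2, 0), 0.5)
  expect_identical(r3$lod[r3$theta == 0], -Inf)
  expect_gt(r3$theta_hat, 0)
  grid <- r3$theta[-1]
  oracle <- vapply(grid, function(th) {
    enum_loglik(ped3, c(1, 1, 2, 2, 0), 0.5, theta = th)
  }, numeric(1))
  expect_equal(r3$theta_hat, grid[which.max(oracle)])
})

test_that("all-missing and Mendel-impossible markers are flagged, LOD 0", {
  ped <- nfs_pedigree()
  r <- lod_score(ped, rep(NA_integer_, 7), 0.5)
  expect_true(r$degenerate)
  expect_equal(r$max_lod, 0)
  scan <- linkage_scan(ped, make_ds(matrix(c(0, 0, 0, 0, 1, 0, 0), 7, 2),
                                    samples = nfs_pedigree()$id))
  expect_true(all(scan$degenerate))   # het child of hom x hom parents
  expect_true(all(scan$max_lod == 0))
})

test_that("scan agrees with per-marker scoring and handles empty input", {
  st <- simulate_study(small_sim_params(), seed = 15)
  ds <- prune_markers(st$pedigree, st$dataset)$dataset
  scan <- linkage_scan(st$pedigree, ds)
  set.seed(1)
  for (j in sample(nrow(ds$markers), 5)) {
    g <- ds$geno[st$pedigree$id, j]
    p <- (sum(g[1:4], na.rm = TRUE) + 1) / (2 * sum(!is.na(g[1:4])) + 2)
    r <- lod_score(st$pedigree, g, p)
    expect_equal(scan$max_lod[j], r$max_lod, tolerance = 1e-9)
    expect_equal(scan$theta_hat[j], r$theta_hat)
  }
  empty <- subset_markers(ds, integer(0))
  expect_equal(nrow(linkage_scan(st$pedigree, empty)), 0)
})

test_that("region assembly bridges uninformative markers, breaks on negatives", {
  mk_scan <- function(pos, max_lod, min_lod = pmin(max_lod, 0),
                      chrom = "1") {
    data.frame(marker = sprintf("m%d", seq_along(pos)), chrom = chrom,
               pos = pos, max_lod = max_lod, min_lod = min_lod,
               theta_hat = 0, degenerate = FALSE)
  }
  pos <- seq(1e6, 10e6, by = 0.5e6)  # 19 markers
  # positive run over 2 Mb flanked by negative evidence
  lods <- c(0, -1, 1, 1, 1, 1, 1, -2, rep(0, 11))
  reg <- linked_regions(mk_scan(pos, pmax(lods, 0), pmin(lods, 0)))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, pos[3])
  expect_equal(reg$end, pos[7])
  # flat-zero markers inside a supporting run do not break it
  lods2 <- c(-1, 1, 0, 0, 1, 0, 1, -1, rep(0, 11))
  reg2 <- linked_regions(mk_scan(pos, pmax(lods2, 0), pmin(lods2, 0)))
  expect_equal(nrow(reg2), 1)
  expect_equal(c(reg2$start, reg2$end), c(pos[2], pos[7]))
  # a short positive run is discarded; all non-positive gives nothing
  short <- mk_scan(c(1e6, 1.2e6, 1.4e6), c(1, 1, 1), c(0, 0, 0))
  expect_equal(nrow(linked_regions(short)), 0)
  expect_equal(nrow(linked_regions(mk_scan(pos, rep(0, 19), rep(-1, 19)))), 0)
})
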