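# Small fixture builders shared across the suite.

make_ds <- function(geno, chrom = "1", pos = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  nm <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(nm) * 1000
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(geno)))
  chrom <- rep_len(chrom, nm)
  marker_dataset(
    data.frame(name = sprintf("m%03d", seq_len(nm)), chrom = chrom, pos = pos,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE),
    samples, geno)
}

# every marker polymorphic and fully observed in at least two samples, so
# PED round trips reproduce the allele coding
random_polymorphic_dataset <- function(n_samples, n_markers, seed,
                                       missing_rate = 0.05) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_samples * n_markers, replace = TRUE),
              n_samples, n_markers)
  g[runif(length(g)) < missing_rate] <- NA
  g[1, ] <- 0L
  g[2, ] <- 2L
  make_ds(g)
}

trio_pedigree <- function() {
  pedigree(id = c("F", "M", "C1"), sire = c(NA, NA, "F"),
           dam = c(NA, NA, "M"), sex = c("male", "female", "unknown"),
           affection = c("unaffected", "unaffected", "affected"))
}

nuclear_pedigree <- function(n_kids, affection_kids = "affected") {
  kids <- sprintf("C%d", seq_len(n_kids))
  pedigree(id = c("F", "M", kids),
           sire = c(NA, NA, rep("F", n_kids)),
           dam = c(NA, NA, rep("M", n_kids)),
           sex = c("male", "female", rep("unknown", n_kids)),
           affection = c("unaffected", "unaffected",
                         rep_len(affection_kids, n_kids)))
}

three_gen_pedigree <- function() {
  # 8 members: grandparents -> one parent, plus an unrelated founder pair
  # whose daughter marries in, with two grandchildren
  pedigree(
    id = c("GF", "GM", "P1", "F2", "M2", "P2", "K1", "K2"),
    sire = c(NA, NA, "GF", NA, NA, "F2", "P1", "P1"),
    dam = c(NA, NA, "GM", NA, NA, "M2", "P2", "P2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "unknown", "unknown"),
    affection = c(rep("unaffected", 6), "affected", "unknown"))
}

enum_test_pedigrees <- function() {
  list(trio_pedigree(), nuclear_pedigree(2), nuclear_pedigree(3),
       nfs_pedigree(), nfs_pedigree("dam"), three_gen_pedigree())
}

# variant set with explicit genotype rows (variants x samples)
toy_variants <- function(geno, chrom = "1", pos = NULL, ref = "G", alt = "T",
                         samples = NULL) {
  geno <- as.matrix(geno)
  nv <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(nv) * 100
  if (is.null(samples)) samples <- sprintf("W%02d", seq_len(ncol(geno)))
  variant_set(
    data.frame(chrom = rep_len(chrom, nv), pos = pos,
               id = sprintf("v%03d", seq_len(nv)),
               ref = rep_len(ref, nv), alt = rep_len(alt, nv),
               stringsAsFactors = FALSE),
    samples, geno)
}

small_sim_params <- function(...) {
  sim_params(n_chromosomes = 2, n_markers_per_chrom = 400, ...)
}
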