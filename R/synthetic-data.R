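# Gene-dropping simulator: produces every input the pipeline consumes
# (pedigree array genotypes, case/carrier/control variant tables, a transcript
# fixture carrying a plantable stop-gain, and gDNA/cDNA allele counts) with
# known ground truth.

#' Simulation parameters
#'
#' The defaults define the package's reference study conditions: a desk-scale
#' genome of 3 chromosomes x 50 Mb carrying 2000 evenly spaced biallelic
#' markers each (about 40 markers/Mb), founder allele frequencies drawn from
#' Beta(2, 2), a pool of 8 founder haplotypes of which exactly one carries a
#' fully penetrant recessive stop-gain allele, recombination at 1 cM/Mb with
#' no interference, genotype missingness 0.005 and error 0.001, a
#' whole-genome-sequencing tier of 2 cases / 2 carriers / 75 controls with
#' 2000 background variants, and a carrier cDNA mutant-allele fraction of
#' 0.25 at depth 100.
#'
#' @param n_chromosomes,chrom_length_bp,n_markers_per_chrom genome shape.
#' @param founder_maf_beta two Beta parameters for founder allele frequencies.
#' @param n_founder_haplotypes size of the founder haplotype pool.
#' @param recomb_rate_cM_per_Mb linear genetic map rate.
#' @param causal_chrom,causal_pos_bp location of the planted recessive
#'   variant (not itself an array marker).
#' @param missing_rate,genotype_error_rate per-call array noise rates.
#' @param n_cases_wgs,n_carriers_wgs,n_controls sequenced sample counts.
#' @param n_background_variants non-causal variants in the WGS table.
#' @param coseg_fraction fraction of background variants given a (partially)
#'   cosegregating genotype pattern, to exercise the filter cascade's
#'   counting.
#' @param protein_length_codons,stop_codon_index,n_exons,strand transcript
#'   fixture geometry; the defaults plant the premature stop at codon 130 of
#'   an 855-codon ST14-like ORF.
#' @param cdna_mutant_fraction,nmd_depth allele-balance fixture settings.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(n_chromosomes = 3, chrom_length_bp = 50e6,
                       n_markers_per_chrom = 2000,
                       founder_maf_beta = c(2, 2),
                       n_founder_haplotypes = 8,
                       recomb_rate_cM_per_Mb = 1.0,
                       causal_chrom = "1", causal_pos_bp = 25e6,
                       missing_rate = 0.005, genotype_error_rate = 0.001,
                       n_cases_wgs = 2, n_carriers_wgs = 2, n_controls = 75,
                       n_background_variants = 2000, coseg_fraction = 0.01,
                       protein_length_codons = 855, stop_codon_index = 130,
                       n_exons = 4, strand = "+",
                       cdna_mutant_fraction = 0.25, nmd_depth = 100) {
  p <- list(n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
            n_markers_per_chrom = n_markers_per_chrom,
            founder_maf_beta = founder_maf_beta,
            n_founder_haplotypes = n_founder_haplotypes,
            recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
            causal_chrom = as.character(causal_chrom),
            causal_pos_bp = causal_pos_bp,
            missing_rate = missing_rate,
            genotype_error_rate = genotype_error_rate,
            n_cases_wgs = n_cases_wgs, n_carriers_wgs = n_carriers_wgs,
            n_controls = n_controls,
            n_background_variants = n_background_variants,
            coseg_fraction = coseg_fraction,
            protein_length_codons = protein_length_codons,
            stop_codon_index = stop_codon_index, n_exons = n_exons,
            strand = strand, cdna_mutant_fraction = cdna_mutant_fraction,
            nmd_depth = nmd_depth)
  rates <- c(p$missing_rate, p$genotype_error_rate, p$coseg_fraction,
             p$cdna_mutant_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (p$causal_pos_bp < 1 || p$causal_pos_bp > p$chrom_length_bp) {
    stop("causal position outside the chromosome")
  }
  if (p$stop_codon_index < 1 ||
      p$stop_codon_index > p$protein_length_codons) {
    stop("stop codon index outside the protein")
  }
  structure(p, class = "sim_params")
}

#' The mapping-family pedigree
#'
#' Three affected half-siblings and their four parents — the family layout
#' used to map naked foal syndrome (NFS), a recessive genodermatosis of an
#' inbred horse breed, and the package's reference study design. Whether the
#' shared parent is the sire or a dam is configurable (both occur in
#' practice; the data model supports either).
#'
#' @param shared_parent `"sire"` (default) or `"dam"`.
#' @return A 7-member [pedigree()].
#' @export
nfs_pedigree <- function(shared_parent = c("sire", "dam")) {
  shared_parent <- match.arg(shared_parent)
  if (shared_parent == "sire") {
    pedigree(
      id  = c("S1", "D1", "D2", "D3", "A1", "A2", "A3"),
      sire = c(NA, NA, NA, NA, "S1", "S1", "S1"),
      dam  = c(NA, NA, NA, NA, "D1", "D2", "D3"),
      sex = c("male", "female", "female", "female",
              "female", "male", "female"),
      affection = c(rep("unaffected", 4), rep("affected", 3)))
  } else {
    pedigree(
      id  = c("D1", "S1", "S2", "S3", "A1", "A2", "A3"),
      sire = c(NA, NA, NA, NA, "S1", "S2", "S3"),
      dam  = c(NA, NA, NA, NA, "D1", "D1", "D1"),
      sex = c("female", "male", "male", "male",
              "male", "female", "male"),
      affection = c(rep("unaffected", 4), rep("affected", 3)))
  }
}

#' Simulate the founder haplotype pool
#'
#' Marker allele frequencies are drawn per marker from the configured Beta
#' distribution and haplotype alleles are independent Bernoulli draws (no
#' background linkage disequilibrium). Exactly one pool haplotype (index 1)
#' carries the causal allele, embedded in that haplotype's own unique marker
#' background, so autozygosity for it is detectable as a shared homozygous
#' haplotype.
#'
#' @param params a [sim_params()].
#' @param seed integer seed (all randomness is local to the call).
#' @return List of class `"haplotype_pool"`: `markers`, `haplotypes` (markers
#'   x pool matrix of 0/1), `causal` (0/1 per haplotype), `freqs` (drawn
#'   allele-1 frequencies), `causal_chrom`, `causal_pos`.
#' @export
simulate_founder_haplotypes <- function(params = sim_params(), seed = 1) {
  set.seed(seed)
  chroms <- as.character(seq_len(params$n_chromosomes))
  nm <- params$n_markers_per_chrom
  spacing <- params$chrom_length_bp / (nm + 1)
  markers <- do.call(rbind, lapply(chroms, function(chr) {
    data.frame(name = sprintf("chr%s_m%05d", chr, seq_len(nm)),
               chrom = chr, pos = round(seq_len(nm) * spacing),
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }))
  ntot <- nrow(markers)
  H <- params$n_founder_haplotypes
  freqs <- stats::rbeta(ntot, params$founder_maf_beta[1],
                        params$founder_maf_beta[2])
  haps <- matrix(stats::rbinom(ntot * H, 1, rep(freqs, H)), nrow = ntot)
  structure(list(markers = markers, haplotypes = haps,
                 causal = c(1L, rep(0L, H - 1)), freqs = freqs,
                 causal_chrom = params$causal_chrom,
                 causal_pos = params$causal_pos_bp),
            class = "haplotype_pool")
}

# one gamete: returns index vector (1 or 2, per locus) selecting which
# parental haplotype each locus is copied from. Crossover count per
# chromosome is Poisson with mean equal to the genetic length in Morgans
# (linear map, no interference), positions uniform.
draw_gamete_phase <- function(chrom_idx, pos, chrom_length_bp, rate_cM_per_Mb) {
  phase <- integer(length(pos))
  morgans <- chrom_length_bp / 1e6 * rate_cM_per_Mb / 100
  for (chr in unique(chrom_idx)) {
    sel <- chrom_idx == chr
    k <- stats::rpois(1, morgans)
    x <- sort(stats::runif(k, 0, chrom_length_bp))
    start <- sample(1:2, 1)
    phase[sel] <- 1 + (start - 1 + findInterval(pos[sel], x)) %% 2
  }
  phase
}

#' Drop genes through a pedigree
#'
#' Founders draw two distinct haplotypes from the pool (sharing across
#' founders models inbreeding); every transmission recombines the parental
#' haplotypes with Poisson crossovers at uniform positions. The causal locus
#' travels as an extra linked locus at its genomic position. Sampling is
#' conditioned by rejection: founder assignments and per-offspring gametes are
#' redrawn until every individual's realised causal genotype matches its
#' stated affection (affected iff homozygous causal under full penetrance),
#' with a bounded total retry count. Genotype errors and missingness are then
#' applied independently per call at the configured rates.
#'
#' @param ped a [pedigree()].
#' @param pool a [simulate_founder_haplotypes()] pool.
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @param max_retries total rejection budget before erroring.
#' @return `list(dataset =, truth =)`: the [marker_dataset()] (causal locus
#'   excluded) and a truth record with per-individual causal dosage, founder
#'   haplotype origins per marker, and each affected individual's true
#'   autozygous block around the causal locus.
#' @export
gene_drop <- function(ped, pool, params = sim_params(), seed = 1,
                      max_retries = 10000) {
  set.seed(seed)
  n <- nrow(ped)
  topo <- ped_topological_order(ped)
  founder <- is_founder(ped)
  H <- ncol(pool$haplotypes)
  if (H < 2) stop("the haplotype pool needs at least two haplotypes")
  causal_hap <- which(pool$causal == 1L)[1]

  # augmented loci: markers plus the causal locus inserted on its chromosome
  mk <- pool$markers
  ins_after <- max(c(0, which(mk$chrom == pool$causal_chrom &
                                mk$pos < pool$causal_pos)))
  n_aug <- nrow(mk) + 1
  causal_idx <- ins_after + 1
  aug_chrom <- append(mk$chrom, pool$causal_chrom, after = ins_after)
  aug_pos <- append(mk$pos, pool$causal_pos, after = ins_after)
  head_rows <- pool$haplotypes[seq_len(ins_after), , drop = FALSE]
  tail_rows <- if (ins_after < nrow(mk)) {
    pool$haplotypes[(ins_after + 1):nrow(mk), , drop = FALSE]
  } else {
    pool$haplotypes[0, , drop = FALSE]
  }
  pool_aug <- rbind(head_rows, matrix(pool$causal, nrow = 1), tail_rows)
  chrom_int <- match(aug_chrom, unique(aug_chrom))

  aff_ok <- function(status, dose) {
    switch(status, affected = dose == 2L, unaffected = dose < 2L, TRUE)
  }
  attempts <- 0
  bump <- function() {
    attempts <<- attempts + 1
    if (attempts > max_retries) {
      stop("affection pattern not realised within the retry budget; ",
           "check that the pedigree admits carrier x carrier matings")
    }
  }
  parents_can_make_affected <- function(hapA, hapB, i) {
    # both parents must carry the causal allele for child i to be affected
    fa <- match(ped$sire[i], ped$id); mo <- match(ped$dam[i], ped$id)
    all(vapply(c(fa, mo), function(p) {
      hapA[[p]][causal_idx] + hapB[[p]][causal_idx] >= 1
    }, logical(1)))
  }

  repeat {
    hapA <- vector("list", n); hapB <- vector("list", n)
    origA <- vector("list", n); origB <- vector("list", n)
    ok <- TRUE
    # founders: draw pool columns, retry at the founder level
    repeat {
      fok <- TRUE
      for (i in which(founder)) {
        cols <- sample.int(H, 2, replace = FALSE)
        hapA[[i]] <- pool_aug[, cols[1]]; hapB[[i]] <- pool_aug[, cols[2]]
        origA[[i]] <- rep(cols[1], n_aug); origB[[i]] <- rep(cols[2], n_aug)
      }
      doses <- vapply(which(founder), function(i) {
        hapA[[i]][causal_idx] + hapB[[i]][causal_idx]
      }, numeric(1))
      fok <- all(mapply(aff_ok, ped$affection[founder], doses))
      if (fok) {
        kids_aff <- which(!founder & ped$affection == "affected")
        fok <- all(vapply(kids_aff, function(i) {
          # only checks founder parents here; non-founder parents are
          # re-checked during the drop
          parents_can_make_affected(hapA, hapB, i)
        }, logical(1)))
      }
      if (fok) break
      bump()
    }
    for (i in topo[!founder[topo]]) {
      fa <- match(ped$sire[i], ped$id); mo <- match(ped$dam[i], ped$id)
      local_tries <- 0
      repeat {
        phf <- draw_gamete_phase(chrom_int, aug_pos, params$chrom_length_bp,
                                 params$recomb_rate_cM_per_Mb)
        phm <- draw_gamete_phase(chrom_int, aug_pos, params$chrom_length_bp,
                                 params$recomb_rate_cM_per_Mb)
        hA <- ifelse(phf == 1, hapA[[fa]], hapB[[fa]])
        oA <- ifelse(phf == 1, origA[[fa]], origB[[fa]])
        hB <- ifelse(phm == 1, hapA[[mo]], hapB[[mo]])
        oB <- ifelse(phm == 1, origA[[mo]], origB[[mo]])
        dose <- hA[causal_idx] + hB[causal_idx]
        if (aff_ok(ped$affection[i], dose)) break
        bump()
        local_tries <- local_tries + 1
        if (local_tries >= 200) { ok <- FALSE; break }  # unsatisfiable branch
      }
      if (!ok) break
      hapA[[i]] <- hA; hapB[[i]] <- hB; origA[[i]] <- oA; origB[[i]] <- oB
    }
    if (ok) break
    bump()
  }

  geno_aug <- t(vapply(seq_len(n), function(i) hapA[[i]] + hapB[[i]],
                       numeric(n_aug)))
  causal_dose <- as.integer(geno_aug[, causal_idx])
  geno <- geno_aug[, -causal_idx, drop = FALSE]
  # per-call genotype error (replace by one of the two other codes), then
  # missingness
  ncall <- length(geno)
  err <- stats::runif(ncall) < params$genotype_error_rate
  if (any(err)) {
    shift <- sample(1:2, sum(err), replace = TRUE)
    geno[err] <- (geno[err] + shift) %% 3
  }
  geno[stats::runif(ncall) < params$missing_rate] <- NA
  ds <- marker_dataset(mk, ped$id, geno)

  # true autozygous block per individual: contiguous run around the causal
  # locus where both haplotype origins equal the causal pool haplotype
  block_of <- function(i) {
    both <- origA[[i]] == causal_hap & origB[[i]] == causal_hap
    if (!both[causal_idx]) return(NULL)
    on_chrom <- aug_chrom == pool$causal_chrom
    idx <- which(on_chrom & both)
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    blk <- runs[[which(vapply(runs, function(r) causal_idx %in% r, TRUE))]]
    data.frame(id = ped$id[i], chrom = pool$causal_chrom,
               start = aug_pos[min(blk)], end = aug_pos[max(blk)],
               stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, lapply(which(causal_dose == 2L), block_of))
  truth <- list(causal_chrom = pool$causal_chrom,
                causal_pos = pool$causal_pos,
                causal_dose = stats::setNames(causal_dose, ped$id),
                autozygous_blocks = blocks,
                attempts = attempts)
  list(dataset = ds, truth = truth)
}

#' Simulate the sequencing-tier variant table
#'
#' Emits the planted causal variant (homozygous alternate in the cases,
#' heterozygous in the carriers, homozygous reference or missing in the
#' controls) plus background variants with Hardy-Weinberg genotypes at
#' uniform population frequencies; relatedness between the sequenced family
#' members is ignored for background variants. A `coseg_fraction` of the
#' background variants gets the case/carrier pattern with occasional
#' heterozygous controls, mimicking (partial) cosegregation so the cascade's
#' counting is exercised. The causal site is fully genotyped in cases and
#' carriers.
#'
#' @param params a [sim_params()].
#' @param ped the mapping pedigree (cases and carriers are drawn from it).
#' @param truth truth record from [gene_drop()].
#' @param tx transcript fixture from [simulate_transcript()] (supplies the
#'   causal REF/ALT alleles).
#' @param seed integer seed.
#' @return `list(variants =, roles =, causal_id =)`.
#' @export
simulate_wgs_variants <- function(params, ped, truth, tx, seed = 1) {
  set.seed(seed)
  affected <- ped$id[ped$affection == "affected"]
  if (length(affected) < params$n_cases_wgs) stop("not enough affected individuals")
  cases <- affected[seq_len(params$n_cases_wgs)]
  par1 <- ped[match(cases[1], ped$id), ]
  carriers <- unique(c(par1$sire, par1$dam))[seq_len(params$n_carriers_wgs)]
  controls <- sprintf("CTRL%03d", seq_len(params$n_controls))
  samples <- c(cases, carriers, controls)
  roles <- sample_roles(cases, carriers, controls)

  nb <- params$n_background_variants
  chroms <- as.character(seq_len(params$n_chromosomes))
  bg_chrom <- sample(chroms, nb, replace = TRUE)
  bg_pos <- ceiling(stats::runif(nb, 1, params$chrom_length_bp))
  bases <- c("A", "C", "G", "T")
  bg_ref <- sample(bases, nb, replace = TRUE)
  bg_alt <- vapply(bg_ref, function(r) sample(setdiff(bases, r), 1), "")
  freq <- stats::runif(nb, 0.05, 0.95)
  geno <- vapply(seq_along(samples), function(s) {
    stats::rbinom(nb, 2, freq)
  }, numeric(nb))
  n_coseg <- round(params$coseg_fraction * nb)
  idx <- integer(0)
  if (n_coseg > 0) {
    idx <- sample.int(nb, n_coseg)
    geno[idx, match(cases, samples)] <- 2L
    geno[idx, match(carriers, samples)] <- 1L
    geno[idx, match(controls, samples)] <-
      stats::rbinom(n_coseg * length(controls), 1, 0.01)
  }
  geno[stats::runif(length(geno)) < params$missing_rate] <- NA

  causal_geno <- c(rep(2L, length(cases)), rep(1L, length(carriers)),
                   ifelse(stats::runif(length(controls)) < params$missing_rate,
                          NA_integer_, 0L))
  sites <- rbind(
    data.frame(chrom = truth$causal_chrom, pos = truth$causal_pos,
               id = "var_causal", ref = tx$variant$ref, alt = tx$variant$alt,
               stringsAsFactors = FALSE),
    data.frame(chrom = bg_chrom, pos = bg_pos,
               id = sprintf("var%05d", seq_len(nb)), ref = bg_ref,
               alt = unname(bg_alt), stringsAsFactors = FALSE))
  geno <- rbind(causal_geno, geno)
  ord <- order(match(sites$chrom, chroms), sites$pos)
  vs <- variant_set(sites[ord, , drop = FALSE], samples,
                    geno[ord, , drop = FALSE])
  list(variants = vs, roles = roles, causal_id = "var_causal",
       bg_freqs = stats::setNames(freq, sprintf("var%05d", seq_len(nb))),
       coseg_ids = sprintf("var%05d", idx))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build a transcript fixture carrying a plantable stop-gain site
#'
#' Constructs a multi-exon transcript around the causal position whose codon
#' `stop_codon_index` is GAG (Glu); the planted single-nucleotide variant
#' mutates its first codon base G to T, creating a TAG stop — i.e. HGVS
#' `c.(3k-2)G>T`, `p.Glu{k}*`. The exon layout and strand are configurable;
#' on the minus strand the genomic alleles are complemented. The CDS excludes
#' the natural terminal stop codon, so the protein length equals
#' `protein_length_codons`.
#'
#' @param params a [sim_params()] (protein length, stop codon index, exon
#'   count, strand, causal coordinates).
#' @param seed integer seed for the random codon fill.
#' @return `list(model =, variant =)` with a [transcript_model()] and the
#'   genomic variant `list(chrom, pos, ref, alt, cds_pos)`.
#' @export
simulate_transcript <- function(params = sim_params(), seed = 1) {
  set.seed(seed)
  L <- params$protein_length_codons
  k <- params$stop_codon_index
  codons <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                      c("A","C","G","T")), 1, paste,
                          collapse = ""), STOP_CODONS)
  cds <- sample(codons, L, replace = TRUE)
  cds[1] <- "ATG"
  cds[k] <- "GAG"
  cds_seq <- paste(cds, collapse = "")
  cds_len <- 3 * L
  ne <- max(1, params$n_exons)
  # exon widths: roughly equal thirds with a deterministic remainder split
  base_w <- cds_len %/% ne
  widths <- rep(base_w, ne)
  widths[ne] <- widths[ne] + cds_len - sum(widths)
  introns <- rep(2000, max(0, ne - 1))
  target <- 3 * (k - 1) + 1                     # CDS coordinate of the G
  cumw <- cumsum(widths)
  # ascending genomic coding index of the target CDS base
  j <- if (params$strand == "+") target else cds_len - target + 1
  e <- which(j <= cumw)[1]
  offset <- j - c(0, cumw)[e]                   # 1-based within exon e
  upstream <- sum(widths[seq_len(e - 1)]) + sum(introns[seq_len(e - 1)])
  gstart <- params$causal_pos_bp - (offset - 1) - upstream
  if (gstart < 1) stop("transcript does not fit upstream of the causal position")
  starts <- gstart + c(0, cumsum(widths[-ne] + introns))
  exons <- data.frame(start = starts, end = starts + widths - 1)
  model <- transcript_model(
    id = "TX1", chrom = params$causal_chrom, strand = params$strand,
    exons = exons, cds_start = min(exons$start), cds_end = max(exons$end),
    cds_seq = cds_seq)
  ref <- "G"; alt <- "T"
  if (params$strand == "-") { ref <- comp_base(ref); alt <- comp_base(alt) }
  list(model = model,
       variant = list(chrom = params$causal_chrom, pos = params$causal_pos_bp,
                      ref = ref, alt = alt, cds_pos = target))
}

#' Simulate gDNA/cDNA allele counts for a heterozygous carrier
#'
#' gDNA alt counts are Binomial(depth, 0.5); cDNA alt counts are
#' Binomial(depth, `true_cdna_mutant_fraction`), so fractions below 0.5 model
#' nonsense-mediated decay of the mutant transcript.
#'
#' @param true_cdna_mutant_fraction expected mutant fraction in cDNA.
#' @param depth_gdna,depth_cdna positive total counts.
#' @param seed integer seed.
#' @return `list(gdna =, cdna =)` of [allele_counts()].
#' @export
simulate_nmd_counts <- function(true_cdna_mutant_fraction, depth_gdna,
                                depth_cdna, seed = 1) {
  if (true_cdna_mutant_fraction < 0 || true_cdna_mutant_fraction > 1) {
    stop("fraction must be in [0, 1]")
  }
  if (depth_gdna <= 0 || depth_cdna <= 0) stop("depths must be positive")
  set.seed(seed)
  alt_g <- stats::rbinom(1, depth_gdna, 0.5)
  alt_c <- stats::rbinom(1, depth_cdna, true_cdna_mutant_fraction)
  list(gdna = allele_counts("gdna", depth_gdna - alt_g, alt_g),
       cdna = allele_counts("cdna", depth_cdna - alt_c, alt_c))
}

#' Simulate one complete study
#'
#' Bundles the founder pool, the mapping pedigree with array genotypes, the
#' sequencing-tier variant table, the transcript fixture and the carrier
#' allele counts, all driven from one seed.
#'
#' @param params a [sim_params()].
#' @param seed integer master seed.
#' @param shared_parent passed to [nfs_pedigree()].
#' @return List of class `"nfs_study"`: `pedigree`, `dataset`, `wgs`
#'   (variants + roles), `transcript`, `nmd_counts`, `truth`, `params`,
#'   `seed`.
#' @export
simulate_study <- function(params = sim_params(), seed = 1,
                           shared_parent = "sire") {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 5)
  pool <- simulate_founder_haplotypes(params, seeds[1])
  ped <- nfs_pedigree(shared_parent)
  gd <- gene_drop(ped, pool, params, seeds[2])
  tx <- simulate_transcript(params, seeds[3])
  wgs <- simulate_wgs_variants(params, ped, gd$truth, tx, seeds[4])
  nmd <- simulate_nmd_counts(params$cdna_mutant_fraction, params$nmd_depth,
                             params$nmd_depth, seeds[5])
  structure(list(pedigree = ped, dataset = gd$dataset, wgs = wgs,
                 transcript = tx, nmd_counts = nmd, truth = gd$truth,
                 params = params, seed = seed),
            class = "nfs_study")
}

#' Write a simulated study to disk
#'
#' Emits PED/MAP, a VCF, the truth interval BED, the exon table + CDS FASTA,
#' the allele-count TSV and a truth JSON into `dir`.
#'
#' @param study an [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "family.ped"),
             map = file.path(dir, "family.map"),
             vcf = file.path(dir, "wgs.vcf"),
             bed = file.path(dir, "truth_blocks.bed"),
             exons = file.path(dir, "transcript_exons.tsv"),
             fasta = file.path(dir, "transcript_cds.fa"),
             counts = file.path(dir, "nmd_counts.tsv"),
             truth = file.path(dir, "truth.json"))
  write_ped_map(study$pedigree, study$dataset, paths["ped"], paths["map"])
  write_vcf(study$wgs$variants, paths["vcf"])
  blocks <- study$truth$autozygous_blocks
  if (is.null(blocks)) {
    write_bed(genome_intervals(), paths["bed"])
  } else {
    write_bed(genome_intervals(blocks$chrom, blocks$start, blocks$end,
                               source = "truth"), paths["bed"])
  }
  write_transcript(study$transcript$model, paths["exons"], paths["fasta"])
  write_allele_counts(study$nmd_counts, paths["counts"])
  jsonlite::write_json(list(causal_chrom = study$truth$causal_chrom,
                            causal_pos = study$truth$causal_pos,
                            causal_dose = as.list(study$truth$causal_dose),
                            seed = study$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
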