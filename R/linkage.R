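# Single-point parametric linkage under a two-locus (disease + marker) model.
#
# Internal state encodings:
#   haplotype h in 1:4  <->  (d, m) bits: d = (h-1) %/% 2, m = (h-1) %% 2
#   ordered genotype g in 1:16 <-> (paternal hap, maternal hap):
#     hp(g) = (g-1) %/% 4 + 1, hm(g) = (g-1) %% 4 + 1
# Founder haplotype frequencies factorise as disease freq x marker freq
# (linkage equilibrium); transmissions recombine the two loci with
# probability theta.

hap_d <- function(h) (h - 1L) %/% 2L
hap_m <- function(h) (h - 1L) %% 2L
state_hp <- function(g) (g - 1L) %/% 4L + 1L
state_hm <- function(g) (g - 1L) %% 4L + 1L

#' Disease inheritance model
#'
#' @param disease_allele_freq population frequency of the disease allele
#'   (default 0.7, the frequency used for the mapping family's breed).
#' @param penetrance probability of being affected with 0, 1 and 2 copies of
#'   the disease allele; the default `c(0, 0, 1)` is a fully penetrant
#'   autosomal recessive model.
#' @return List of class `"disease_model"`.
#' @export
disease_model <- function(disease_allele_freq = 0.7, penetrance = c(0, 0, 1)) {
  if (disease_allele_freq <= 0 || disease_allele_freq >= 1) {
    stop("disease allele frequency must be in (0, 1)")
  }
  if (length(penetrance) != 3 || any(penetrance < 0 | penetrance > 1)) {
    stop("penetrance must be three probabilities (0, 1, 2 copies)")
  }
  structure(list(q = disease_allele_freq, penetrance = penetrance),
            class = "disease_model")
}

# P(gamete haplotype h | parent ordered genotype g) for one theta: 4 x 16.
gamete_matrix <- function(theta) {
  G <- matrix(0, 4, 16)
  for (g in 1:16) {
    hpair <- c(state_hp(g), state_hm(g))
    for (h in 1:4) {
      w <- 0
      for (sd in 1:2) for (sm in 1:2) {
        pr <- if (sd == sm) (1 - theta) / 2 else theta / 2
        if (hap_d(h) == hap_d(hpair[sd]) && hap_m(h) == hap_m(hpair[sm])) {
          w <- w + pr
        }
      }
      G[h, g] <- w
    }
  }
  G
}

# --- tiny discrete-factor toolkit (all variables have 16 states, values are
# matrices with one column per theta so the whole grid peels at once) --------

ve_factor <- function(vars, vals) list(vars = as.integer(vars), vals = vals)

ve_digits <- function(R, k) {
  idx <- 0:(R - 1)
  vapply(seq_len(k), function(j) as.integer((idx %/% 16^(j - 1)) %% 16),
         integer(R))
}

ve_mult <- function(f1, f2) {
  uv <- union(f1$vars, f2$vars)
  k <- length(uv)
  R <- 16L^k
  dg <- ve_digits(R, k)
  row_index <- function(f) {
    i <- rep(1L, R)
    pos <- match(f$vars, uv)
    for (j in seq_along(f$vars)) i <- i + dg[, pos[j]] * 16L^(j - 1)
    i
  }
  ve_factor(uv, f1$vals[row_index(f1), , drop = FALSE] *
                 f2$vals[row_index(f2), , drop = FALSE])
}

ve_marginalise <- function(f, v) {
  p <- match(v, f$vars)
  k <- length(f$vars)
  nt <- ncol(f$vals)
  a <- 16L^(p - 1)
  b <- 16L^(k - p)
  arr <- array(f$vals, dim = c(a, 16L, b * nt))
  out <- arr[, 1L, , drop = FALSE]
  for (s in 2:16) out <- out + arr[, s, , drop = FALSE]
  ve_factor(f$vars[-p], matrix(out, nrow = a * b, ncol = nt))
}

# Greedy elimination order: repeatedly remove the variable whose combined
# factor has the fewest variables. Computed on structure only.
ve_elim_order <- function(var_sets, all_vars) {
  order_out <- integer(0)
  sets <- var_sets
  remaining <- all_vars
  while (length(remaining)) {
    width <- vapply(remaining, function(v) {
      length(Reduce(union, sets[vapply(sets, function(s) v %in% s, TRUE)]))
    }, numeric(1))
    v <- remaining[which.min(width)]
    inv <- vapply(sets, function(s) v %in% s, TRUE)
    merged <- setdiff(Reduce(union, sets[inv]), v)
    sets <- c(sets[!inv], list(merged))
    remaining <- setdiff(remaining, v)
    order_out <- c(order_out, v)
  }
  order_out
}

#' Build a reusable peeling engine for one pedigree and theta grid
#'
#' Precomputes the transmission factors (which depend only on theta) and the
#' elimination order, so that per-marker likelihoods reduce to plugging in
#' evidence and founder priors.
#'
#' @param ped a [pedigree()].
#' @param model a [disease_model()].
#' @param theta_grid recombination fractions in `[0, 0.5]`.
#' @return A function `f(geno, p_alt)` returning the natural-log likelihood
#'   vector over `theta_grid`; `geno` is the integer genotype vector aligned
#'   to `ped$id`, `p_alt` the marker's allele-2 frequency.
#' @export
peeling_engine <- function(ped, model, theta_grid) {
  stopifnot(all(theta_grid >= 0 & theta_grid <= 0.5))
  n <- nrow(ped)
  nt <- length(theta_grid)
  founder <- is_founder(ped)
  fa_idx <- match(ped$sire, ped$id)
  mo_idx <- match(ped$dam, ped$id)

  # transmission factor values: rows index (child, father, mother) little-
  # endian base 16, one column per theta
  cidx <- rep(1:16, 256)
  fidx <- rep(rep(1:16, each = 16), 16)
  midx <- rep(1:16, each = 256)
  trans_vals <- vapply(theta_grid, function(th) {
    G <- gamete_matrix(th)
    G[cbind(state_hp(cidx), fidx)] * G[cbind(state_hm(cidx), midx)]
  }, numeric(4096))
  trans_vals <- matrix(trans_vals, nrow = 4096, ncol = nt)

  trans_factors <- lapply(which(!founder), function(i) {
    ve_factor(c(i, fa_idx[i], mo_idx[i]), trans_vals)
  })
  var_sets <- c(lapply(seq_len(n), identity), lapply(trans_factors, `[[`, "vars"))
  elim_order <- ve_elim_order(var_sets, seq_len(n))

  dcount <- hap_d(state_hp(1:16)) + hap_d(state_hm(1:16))
  mcount <- hap_m(state_hp(1:16)) + hap_m(state_hm(1:16))
  pen <- model$penetrance
  aff_weight <- rbind(affected = pen[dcount + 1],
                      unaffected = 1 - pen[dcount + 1],
                      unknown = rep(1, 16))
  q <- model$q

  function(geno, p_alt) {
    hapfreq <- c((1 - q) * (1 - p_alt), (1 - q) * p_alt,
                 q * (1 - p_alt), q * p_alt)
    prior16 <- hapfreq[state_hp(1:16)] * hapfreq[state_hm(1:16)]
    factors <- vector("list", n)
    for (i in seq_len(n)) {
      ev <- aff_weight[ped$affection[i], ]
      if (!is.na(geno[i])) ev <- ev * (mcount == geno[i])
      if (founder[i]) ev <- ev * prior16
      factors[[i]] <- ve_factor(i, matrix(ev, 16, nt))
    }
    factors <- c(factors, trans_factors)
    logscale <- numeric(nt)
    for (v in elim_order) {
      inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
      f <- Reduce(ve_mult, factors[inv])
      f <- ve_marginalise(f, v)
      cm <- apply(f$vals, 2, max)
      pos <- cm > 0
      if (any(pos)) {
        f$vals[, pos] <- sweep(f$vals[, pos, drop = FALSE], 2, cm[pos], "/")
        logscale[pos] <- logscale[pos] + log(cm[pos])
      }
      factors <- c(factors[!inv], list(f))
    }
    tot <- Reduce(`*`, lapply(factors, function(f) f$vals[1, ]))
    ifelse(tot > 0, log(tot) + logscale, -Inf)
  }
}

#' Pedigree log-likelihood at one or more recombination fractions
#'
#' Joint probability of the marker genotypes and affection statuses given the
#' disease model and recombination fraction theta between the marker and the
#' disease locus, summing over founder two-locus ordered genotypes (haplotype
#' frequency = product of allele frequencies, i.e. linkage equilibrium) and
#' all transmissions. Data impossible under the model yield `-Inf`, not an
#' error.
#'
#' @param ped a [pedigree()].
#' @param geno integer genotype vector (0/1/2/`NA`) aligned to `ped$id`.
#' @param p_alt marker allele-2 frequency.
#' @param model a [disease_model()].
#' @param theta recombination fraction(s) in `[0, 0.5]`.
#' @return Numeric vector of natural-log likelihoods, one per `theta`.
#' @export
pedigree_loglik <- function(ped, geno, p_alt, model = disease_model(),
                            theta = 0) {
  peeling_engine(ped, model, theta)(geno, p_alt)
}

#' Single-marker LOD score over a theta grid
#'
#' `LOD(theta) = log10 L(theta) - log10 L(0.5)`. The maximum over the grid is
#' reported with its argmax (ties broken toward the smallest theta). A marker
#' with no non-missing genotype, or one whose genotypes are impossible at
#' every theta, gets LOD 0 and is flagged `degenerate`.
#'
#' @param ped a [pedigree()].
#' @param geno genotype vector aligned to `ped$id`.
#' @param p_alt marker allele-2 frequency.
#' @param model a [disease_model()].
#' @param theta_grid grid of recombination fractions; must include 0.5.
#' @return List of class `"lod_result"`: `theta`, `lod`, `max_lod`,
#'   `theta_hat`, `degenerate`.
#' @export
lod_score <- function(ped, geno, p_alt, model = disease_model(),
                      theta_grid = default_theta_grid()) {
  if (!any(theta_grid == 0.5)) stop("theta grid must include 0.5")
  ll <- pedigree_loglik(ped, geno, p_alt, model, theta_grid)
  ll_half <- ll[which(theta_grid == 0.5)[1]]
  degenerate <- all(is.na(geno)) || !is.finite(ll_half)
  if (degenerate) {
    lod <- rep(0, length(theta_grid))
  } else {
    lod <- (ll - ll_half) / log(10)
  }
  imax <- which(lod == max(lod))[1]
  structure(list(theta = theta_grid, lod = lod, max_lod = lod[imax],
                 theta_hat = theta_grid[imax], degenerate = degenerate),
            class = "lod_result")
}

#' @rdname lod_score
#' @export
default_theta_grid <- function() seq(0, 0.5, by = 0.01)

# ML allele-2 frequency from founder genotypes with one pseudo-count per
# allele; 0.5 when no founder is typed.
founder_allele_freq <- function(ped, geno) {
  g <- geno[is_founder(ped)]
  g <- g[!is.na(g)]
  if (!length(g)) return(0.5)
  (sum(g) + 1) / (2 * length(g) + 2)
}

#' Genome-wide single-point linkage scan
#'
#' One LOD maximisation per marker under the given disease model. Marker
#' allele frequencies are estimated from founder genotypes (pseudo-count 1
#' per allele). Identical (genotype pattern, frequency) combinations are
#' computed once.
#'
#' @param ped a [pedigree()].
#' @param ds a [marker_dataset()]; sample ids must cover `ped$id`.
#' @param model a [disease_model()].
#' @param theta_grid grid including 0.5.
#' @return Data frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `max_lod`, `theta_hat`, `degenerate`.
#' @export
linkage_scan <- function(ped, ds, model = disease_model(),
                         theta_grid = default_theta_grid()) {
  if (!any(theta_grid == 0.5)) stop("theta grid must include 0.5")
  nm <- nrow(ds$markers)
  out <- data.frame(marker = ds$markers$name, chrom = ds$markers$chrom,
                    pos = ds$markers$pos, max_lod = numeric(nm),
                    min_lod = numeric(nm), theta_hat = numeric(nm),
                    degenerate = logical(nm), stringsAsFactors = FALSE)
  if (nm == 0) return(out)
  if (!all(ped$id %in% ds$samples)) stop("dataset lacks pedigree sample(s)")
  G <- ds$geno[ped$id, , drop = FALSE]
  engine <- peeling_engine(ped, model, theta_grid)
  i_half <- which(theta_grid == 0.5)[1]
  freqs <- apply(G, 2, function(g) founder_allele_freq(ped, g))
  key <- paste(apply(G, 2, paste, collapse = ","), signif(freqs, 12))
  first <- !duplicated(key)
  cache <- vector("list", sum(first))
  names(cache) <- key[first]
  for (j in which(first)) {
    g <- G[, j]
    if (all(is.na(g))) {
      cache[[key[j]]] <- c(0, 0, 0.5, TRUE)
      next
    }
    ll <- engine(g, freqs[j])
    if (!is.finite(ll[i_half])) {
      cache[[key[j]]] <- c(0, 0, 0.5, TRUE)
      next
    }
    lod <- (ll - ll[i_half]) / log(10)
    imax <- which(lod == max(lod))[1]
    cache[[key[j]]] <- c(lod[imax], min(lod), theta_grid[imax], FALSE)
  }
  res <- do.call(rbind, cache)[key, , drop = FALSE]
  out$max_lod <- res[, 1]
  out$min_lod <- res[, 2]
  out$theta_hat <- res[, 3]
  out$degenerate <- as.logical(res[, 4])
  out
}

#' Assemble linked regions from a scan
#'
#' Single-point LOD scores at markers where the informative parent is
#' homozygous are identically zero (uninformative), so positive-LOD markers
#' are interleaved with flat-zero ones even under perfect cosegregation.
#' A region is therefore a maximal marker run uninterrupted by *opposing*
#' markers (LOD below `-tol` anywhere on the theta grid, i.e. evidence
#' against linkage) that contains at least one *supporting* marker
#' (`max_lod > tol`); uninformative and degenerate markers pass through.
#' The interval spans the first to the last supporting marker of the run;
#' runs whose span (`end - start`) is `<= min_length_bp` are discarded.
#'
#' @param scan data frame from [linkage_scan()] (map-sorted).
#' @param min_length_bp minimum span in bp (default 1e6).
#' @param tol numerical tolerance around a LOD of zero.
#' @return A [genome_intervals()] frame with `source = "linkage"`.
#' @export
linked_regions <- function(scan, min_length_bp = 1e6, tol = 1e-9) {
  out <- list()
  supporting <- scan$max_lod > tol & !scan$degenerate
  opposing <- scan$min_lod < -tol & !supporting & !scan$degenerate
  for (chr in unique(scan$chrom)) {
    sel <- scan$chrom == chr
    pos <- scan$pos[sel]
    sup <- supporting[sel]
    opp <- opposing[sel]
    block <- cumsum(opp)
    for (b in unique(block)) {
      i <- which(block == b & !opp & sup)
      if (!length(i)) next
      span <- pos[max(i)] - pos[min(i)]
      if (span > min_length_bp) {
        out[[length(out) + 1]] <- data.frame(chrom = chr, start = pos[min(i)],
                                             end = pos[max(i)])
      }
    }
  }
  if (!length(out)) return(genome_intervals())
  df <- do.call(rbind, out)
  genome_intervals(df$chrom, df$start, df$end, source = "linkage")
}
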