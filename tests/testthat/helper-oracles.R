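# Independent oracles used across the suite. These deliberately avoid the
# package's internal algorithms: the likelihood oracle enumerates the full
# joint state space of ordered two-locus genotypes; the ROH oracle re-runs the
# windowed definition with naive loops; the consequence oracle mutates and
# translates the whole CDS.

# --- enumeration likelihood oracle ------------------------------------------
# states 1:16 are ordered (paternal hap, maternal hap); haplotype 1:4 encodes
# (disease bit, marker bit).
enum_hap_d <- function(h) (h - 1) %/% 2
enum_hap_m <- function(h) (h - 1) %% 2

# transmission probability table T[child, father, mother], derived from first
# principles: per gamete, pick the source haplotype of the disease allele and
# of the marker allele; same source w.p. (1-theta)/2 each, different w.p.
# theta/2 each.
enum_trans_table <- function(theta) {
  gam <- matrix(0, 4, 16)
  for (g in 1:16) {
    hp <- (g - 1) %/% 4 + 1
    hm <- (g - 1) %% 4 + 1
    hs <- c(hp, hm)
    for (h in 1:4) {
      for (sd in 1:2) for (sm in 1:2) {
        if (enum_hap_d(h) == enum_hap_d(hs[sd]) &&
            enum_hap_m(h) == enum_hap_m(hs[sm])) {
          gam[h, g] <- gam[h, g] + (if (sd == sm) (1 - theta) / 2 else theta / 2)
        }
      }
    }
  }
  tt <- array(0, c(16, 16, 16))
  for (gc in 1:16) {
    hp <- (gc - 1) %/% 4 + 1
    hm <- (gc - 1) %% 4 + 1
    for (gf in 1:16) for (gm in 1:16) {
      tt[gc, gf, gm] <- gam[hp, gf] * gam[hm, gm]
    }
  }
  tt
}

# full-joint enumeration of P(genotypes, affection | theta), chunked so large
# pedigrees stay within memory
enum_loglik <- function(ped, geno, p_alt, q = 0.7, pen = c(0, 0, 1), theta,
                        chunk = 5e5) {
  n <- nrow(ped)
  founder <- is.na(ped$sire) & is.na(ped$dam)
  fa <- match(ped$sire, ped$id)
  mo <- match(ped$dam, ped$id)
  mcount <- enum_hap_m((0:15) %/% 4 + 1) + enum_hap_m((0:15) %% 4 + 1)
  dcount <- enum_hap_d((0:15) %/% 4 + 1) + enum_hap_d((0:15) %% 4 + 1)
  hapfreq <- c((1 - q) * (1 - p_alt), (1 - q) * p_alt,
               q * (1 - p_alt), q * p_alt)
  prior <- hapfreq[(0:15) %/% 4 + 1] * hapfreq[(0:15) %% 4 + 1]
  penw <- function(status) {
    switch(status, affected = pen[dcount + 1],
           unaffected = 1 - pen[dcount + 1], rep(1, 16))
  }
  states <- lapply(seq_len(n), function(i) {
    s <- 1:16
    if (!is.na(geno[i])) s <- s[mcount[s] == geno[i]]
    s
  })
  lens <- lengths(states)
  if (any(lens == 0)) return(-Inf)
  tt <- enum_trans_table(theta)
  total <- prod(lens)
  radix <- cumprod(c(1, lens[-n]))
  acc <- 0
  done <- 0
  while (done < total) {
    m <- min(chunk, total - done)
    idx <- done + seq_len(m) - 1
    smat <- vapply(seq_len(n), function(i) {
      states[[i]][(idx %/% radix[i]) %% lens[i] + 1]
    }, numeric(m))
    smat <- matrix(smat, nrow = m)
    p <- rep(1, m)
    for (i in seq_len(n)) {
      w <- penw(ped$affection[i])
      if (founder[i]) w <- w * prior
      p <- p * w[smat[, i]]
      if (!founder[i]) {
        p <- p * tt[cbind(smat[, i], smat[, fa[i]], smat[, mo[i]])]
      }
    }
    acc <- acc + sum(p)
    done <- done + m
  }
  if (acc > 0) log(acc) else -Inf
}

# --- naive windowed ROH oracle ----------------------------------------------
naive_roh_one_chrom <- function(g, pos, params) {
  n <- length(g)
  w <- min(params$window_snps, n)
  nw <- n - w + 1
  homoz <- logical(nw)
  for (j in seq_len(nw)) {
    win <- g[j:(j + w - 1)]
    homoz[j] <- sum(win == 1, na.rm = TRUE) <= params$max_het_in_window &&
      sum(is.na(win)) <= params$max_missing_in_window
  }
  in_roh <- logical(n)
  for (k in seq_len(n)) {
    covering <- max(1, k - w + 1):min(k, nw)
    in_roh[k] <- mean(homoz[covering]) >= params$min_window_hit_fraction
  }
  segs <- list()
  k <- 1
  while (k <= n) {
    if (!in_roh[k]) { k <- k + 1; next }
    j <- k
    while (j < n && in_roh[j + 1]) j <- j + 1
    if (pos[j] - pos[k] >= params$min_run_length_bp &&
        j - k + 1 >= params$min_run_snps) {
      segs[[length(segs) + 1]] <- c(start = pos[k], end = pos[j])
    }
    k <- j + 1
  }
  segs
}

# --- mutate-and-translate consequence oracle --------------------------------
naive_snv_class <- function(model, pos, ref, alt) {
  cpos <- autozyg::genomic_to_cds(model, pos)
  if (is.na(cpos)) return("non_cds")
  s <- strsplit(model$cds_seq, "")[[1]]
  base <- toupper(ref)
  alt_b <- toupper(alt)
  if (model$strand == "-") {
    base <- chartr("ACGT", "TGCA", base)
    alt_b <- chartr("ACGT", "TGCA", alt_b)
  }
  stopifnot(s[cpos] == base)
  translate_all <- function(v) {
    n <- length(v) %/% 3
    vapply(seq_len(n), function(k) {
      unname(Biostrings::GENETIC_CODE[paste(v[c(3 * k - 2, 3 * k - 1, 3 * k)],
                                            collapse = "")])
    }, "")
  }
  p_ref <- translate_all(s)
  s2 <- s
  s2[cpos] <- alt_b
  p_alt <- translate_all(s2)
  if (identical(p_ref, p_alt)) return("synonymous")
  changed <- which(p_ref != p_alt)
  if (p_alt[changed[1]] == "*") "nonsense" else "missense"
}
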