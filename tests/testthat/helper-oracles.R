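# Independent oracles, deliberately written in plain loops so they share no
# code path with the package implementation.

# brute-force threshold caller: one decision per (position, alt allele)
brute_force_calls <- function(pileup, min_depth = 6, min_alt = 3,
                              min_vaf = 0.1) {
  out <- list()
  keys <- unique(paste(pileup$chrom, pileup$pos))
  for (key in keys) {
    rows <- pileup[paste(pileup$chrom, pileup$pos) == key, ]
    depth <- sum(rows$count)
    for (i in seq_len(nrow(rows))) {
      if (rows$allele[i] == rows$ref[i] || rows$count[i] == 0) next
      ac <- rows$count[i]
      if (depth >= min_depth && ac >= min_alt && ac / depth >= min_vaf) {
        out[[length(out) + 1]] <- data.frame(
          chrom = rows$chrom[i], pos = rows$pos[i], ref = rows$ref[i],
          alt = rows$allele[i], depth = depth, alt_count = ac)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_count = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
}

# rule-table ACMG oracle over applied-strength counts; data-driven instead of
# an if-chain. An extra very-strong criterion counts as strong, matching the
# documented package convention.
acmg_oracle <- function(nvs, ns, nm, np, ba = 0, nbs = 0, nbp = 0) {
  s_eff <- ns + max(nvs - 1, 0)
  counts <- c(vs = min(nvs, 1), s = s_eff, m = nm, p = np)
  path_rules <- list(
    list(cls = 5, req = c(vs = 1, s = 1, m = 0, p = 0)),
    list(cls = 5, req = c(vs = 1, s = 0, m = 2, p = 0)),
    list(cls = 5, req = c(vs = 1, s = 0, m = 1, p = 1)),
    list(cls = 5, req = c(vs = 1, s = 0, m = 0, p = 2)),
    list(cls = 5, req = c(vs = 0, s = 2, m = 0, p = 0)),
    list(cls = 5, req = c(vs = 0, s = 1, m = 3, p = 0)),
    list(cls = 5, req = c(vs = 0, s = 1, m = 2, p = 2)),
    list(cls = 5, req = c(vs = 0, s = 1, m = 1, p = 4)),
    list(cls = 4, req = c(vs = 1, s = 0, m = 1, p = 0)),
    list(cls = 4, req = c(vs = 0, s = 1, m = 1, p = 0)),
    list(cls = 4, req = c(vs = 0, s = 1, m = 0, p = 2)),
    list(cls = 4, req = c(vs = 0, s = 0, m = 3, p = 0)),
    list(cls = 4, req = c(vs = 0, s = 0, m = 2, p = 2)),
    list(cls = 4, req = c(vs = 0, s = 0, m = 1, p = 4))
  )
  path_cls <- NA
  for (r in path_rules) {
    if (all(counts >= r$req)) { path_cls <- r$cls; break }
  }
  ben_cls <- if (ba >= 1) 1
    else if (nbs >= 2) 1
    else if (nbs >= 1 && nbp >= 1) 2
    else if (nbp >= 2) 2
    else NA
  if (!is.na(path_cls) && !is.na(ben_cls)) return(3)
  if (!is.na(path_cls)) return(path_cls)
  if (!is.na(ben_cls)) return(ben_cls)
  3
}

# build a criteria tibble directly from strength counts (bypasses parsing)
criteria_from_counts <- function(nvs, ns, nm, np, ba = 0, nbs = 0, nbp = 0) {
  tibble::tibble(
    code = "synthetic",
    applied_strength = c(rep("very_strong", nvs), rep("strong", ns),
                         rep("moderate", nm), rep("supporting", np),
                         rep("stand_alone", ba), rep("strong", nbs),
                         rep("supporting", nbp)),
    side = c(rep("pathogenic", nvs + ns + nm + np),
             rep("benign", ba + nbs + nbp)),
    modified = FALSE
  )
}

# tiny deterministic depth track / target builders
flat_depth_track <- function(targets, depth, sample = "s1") {
  out <- list()
  for (i in seq_len(nrow(targets))) {
    pos <- (targets$start[i] + 1):targets$end[i]
    out[[i]] <- data.frame(chrom = targets$chrom[i], pos = pos,
                           sample = sample, depth = depth)
  }
  do.call(rbind, out)
}

# HWE genotype sampler for the tracking-concordance closed form
hwe_genotypes <- function(maf, n) {
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample(c("AA", "AB", "BB"), n, replace = TRUE, prob = probs)
}
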