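# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written against different formulations than the
# package implementation (contingency-table counts, exhaustive path sums,
# brute-force pair counting).

# Build a hap_panel from a binary matrix (rows = haplotypes).
make_panel <- function(haps, positions = NULL, chrom = "1",
                       ref = NULL, alt = NULL, ids = NULL) {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  if (is.null(positions)) positions <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("C", m)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  hap_panel(tibble::tibble(chrom = chrom, pos = positions, site_id = ids,
                           ref = ref, alt = alt),
            haps, sprintf("S%02d", seq_len(nrow(haps) / 2)))
}

# r2 from the raw 2x2 haplotype contingency table (count formulation).
oracle_r2 <- function(x, y) {
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  num <- (n11 * n00 - n10 * n01)^2
  den <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  num / den
}

# Exhaustive path-enumeration posterior for the copying HMM: sums the joint
# probability of every state path and accumulates the state marginal at the
# context SNP nearest the query position (left on ties).
oracle_copying_posterior <- function(ref, target, pos, qpos, lambda, eps) {
  H <- nrow(ref)
  S <- ncol(ref)
  t <- which.min(abs(pos - qpos))
  post <- numeric(H)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), S)))
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    pr <- 1 / H
    for (s in seq_len(S)) {
      if (s > 1) {
        rho <- exp(-lambda * (pos[s] - pos[s - 1]))
        pr <- pr * (if (path[s] == path[s - 1]) rho + (1 - rho) / H else (1 - rho) / H)
      }
      pr <- pr * (if (ref[path[s], s] == target[s]) 1 - eps else eps)
    }
    post[path[t]] <- post[path[t]] + pr
  }
  post / sum(post)
}

# Brute-force Mann-Whitney U for sample `a`: pairs with a_i > b_j, ties 1/2.
oracle_mwu <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# All multisets of {1, 2, 3} with sizes 1..max_size (U depends only on the
# multiset, so this covers every distinct case of the small-list family).
all_multisets_123 <- function(max_size = 6L) {
  out <- list()
  for (n in seq_len(max_size)) {
    cmb <- utils::combn(n + 2L, 2L)
    for (j in seq_len(ncol(cmb))) {
      # stars-and-bars decode: counts of values 1, 2, 3
      c1 <- cmb[1, j] - 1L
      c2 <- cmb[2, j] - cmb[1, j] - 1L
      c3 <- n - c1 - c2
      out[[length(out) + 1L]] <- rep(1:3, times = c(c1, c2, c3))
    }
  }
  out
}

# Minimal phased VCF writer for reader tests.
write_test_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_rec <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

# Panels where haplotype identity equals panel identity: compare field-wise.
expect_same_panel <- function(a, b) {
  expect_equal(a$sites$chrom, b$sites$chrom)
  expect_equal(a$sites$pos, b$sites$pos)
  expect_equal(a$sites$site_id, b$sites$site_id)
  expect_equal(a$sites$ref, b$sites$ref)
  expect_equal(a$sites$alt, b$sites$alt)
  expect_equal(a$sites$vclass, b$sites$vclass)
  expect_equal(unname(a$haps), unname(b$haps))
  expect_equal(a$samples, b$samples)
}
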