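#' Phased haplotype panel
#'
#' The central container of the package: an ordered table of bi-allelic
#' variant sites together with a strictly binary phased haplotype matrix.
#' Haplotype rows `2i - 1` and `2i` belong to sample `i`; matrix entries are
#' 0 (reference allele) or 1 (alternate allele), with no missing values.
#'
#' @param sites A data frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `site_id`, `ref`, `alt`.  Variant class (`SNP`,
#'   `insertion`, `deletion`), indel length, `lof` flag and `region_label`
#'   are derived/initialized if absent.
#' @param haps Integer or numeric matrix, `2N x M`, entries in `{0, 1}`,
#'   one column per site in `sites` order.
#' @param samples Character vector of `N` sample identifiers.
#'
#' @details Sites are sorted by `(chrom, pos)` on construction.  Two sites
#'   at the same position are refused (`indelLD_duplicate_site`): position
#'   collisions between an indel and a SNP must be resolved upstream with
#'   [merge_panels()] semantics (the indel wins).
#'
#' @return An object of class `hap_panel`.
#' @seealso [read_vcf()], [merge_panels()], [simulate_panel()]
#' @export
hap_panel <- function(sites, haps, samples) {
  sites <- as_tibble(sites)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    stop_indelLD("parse_error", "`sites` needs columns chrom, pos, ref, alt.")
  }
  if (!("site_id" %in% names(sites))) {
    sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  }
  cls <- classify_alleles(sites$ref, sites$alt)
  sites$vclass <- cls$vclass
  sites$indel_length <- cls$indel_length
  if (!("lof" %in% names(sites))) sites$lof <- FALSE
  if (!("region_label" %in% names(sites))) sites$region_label <- NA_character_
  sites$pos <- as.integer(sites$pos)

  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  haps <- haps[, ord, drop = FALSE]

  x <- structure(list(sites = sites, haps = haps, samples = as.character(samples)),
                 class = "hap_panel")
  validate_hap_panel(x)
}

# Derive variant class and indel length from REF/ALT strings.
classify_alleles <- function(ref, alt) {
  ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop_indelLD("unsupported_allele",
                 sprintf("Non-ACGT allele at site %d (ref '%s', alt '%s').",
                         bad, ref[bad], alt[bad]))
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  mnp <- lr == la & lr > 1L
  if (any(mnp)) {
    stop_indelLD("unsupported_allele",
                 sprintf("Equal-length multi-base alleles (MNP) at site %d.", which(mnp)[1]))
  }
  vclass <- ifelse(lr == la, "SNP", ifelse(lr > la, "deletion", "insertion"))
  len <- abs(lr - la)
  if (any(vclass != "SNP" & len >= 50L)) {
    stop_indelLD("unsupported_allele",
                 "Indels must be shorter than 50 bp in this panel type.")
  }
  list(vclass = vclass, indel_length = as.integer(len))
}

validate_hap_panel <- function(x) {
  s <- x$sites
  h <- x$haps
  if (nrow(h) %% 2L != 0L) {
    stop_indelLD("parse_error", "Haplotype matrix must have an even number of rows.")
  }
  if (nrow(h) != 2L * length(x$samples)) {
    stop_indelLD("sample_mismatch", "Haplotype rows must equal 2 x number of samples.")
  }
  if (ncol(h) != nrow(s)) {
    stop_indelLD("parse_error", "One haplotype column per site is required.")
  }
  if (nrow(s) > 0 && (anyNA(h) || !all(h == 0L | h == 1L))) {
    stop_indelLD("missing_or_unphased_genotype",
                 "Haplotype matrix entries must be strictly 0/1 with no missing values.")
  }
  dup <- duplicated(site_key(s$chrom, s$pos))
  if (any(dup)) {
    stop_indelLD("duplicate_site",
                 sprintf("Two sites share position %s.",
                         site_key(s$chrom, s$pos)[dup][1]))
  }
  x
}

#' @export
print.hap_panel <- function(x, ...) {
  s <- x$sites
  cat(sprintf("<hap_panel> %d samples (%d haplotypes), %d sites\n",
              length(x$samples), nrow(x$haps), nrow(s)))
  if (nrow(s) > 0) {
    tab <- table(factor(s$vclass, levels = c("SNP", "insertion", "deletion")))
    cat(sprintf("  SNP: %d  insertion: %d  deletion: %d  (LOF-flagged: %d)\n",
                tab[["SNP"]], tab[["insertion"]], tab[["deletion"]], sum(s$lof)))
  }
  invisible(x)
}

#' Number of sites / samples in a panel
#' @param panel A [hap_panel()].
#' @return Integer scalar.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' @rdname n_sites
#' @export
n_samples <- function(panel) length(panel$samples)

#' Site table of a panel
#'
#' @param panel A [hap_panel()].
#' @return The sites tibble (one row per variant site).
#' @export
panel_sites <- function(panel) panel$sites

# Subset a panel to site indices (keeps order of `idx` after re-sorting).
subset_sites <- function(panel, idx) {
  structure(list(sites = panel$sites[idx, , drop = FALSE],
                 haps = panel$haps[, idx, drop = FALSE],
                 samples = panel$samples),
            class = "hap_panel")
}

# Alt-allele frequency of every column.
alt_freq <- function(panel) colMeans(panel$haps)

# Diploid genotype (0/1/2 alt alleles) of every sample at site `i`.
site_genotypes <- function(panel, i) {
  col <- panel$haps[, i]
  col[c(TRUE, FALSE)] + col[c(FALSE, TRUE)]
}

#' @export
tidy.hap_panel <- function(x, ...) {
  f <- alt_freq(x)
  mutate(x$sites,
         alt_count = as.integer(round(f * nrow(x$haps))),
         maf = pmin(f, 1 - f),
         minor_count = as.integer(round(pmin(f, 1 - f) * nrow(x$haps))))
}
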