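#' Pairwise haplotype r-squared
#'
#' LD between two sites from phased haplotypes via the 2x2 haplotype table:
#' `D = p11 - p*q`, `r2 = D^2 / (p(1-p) q(1-q))`, with `p`, `q` the
#' alt-allele frequencies and `p11` the frequency of haplotypes carrying
#' the alt allele at both sites.  Symmetric in its arguments and invariant
#' under swapping allele labels at either site.  Genotype-correlation LD is
#' deliberately not provided: panels here are phased, which removes the
#' EM/composite ambiguity of unphased calculators.
#'
#' @param panel A [hap_panel()].
#' @param i,j Site indices; both sites must be polymorphic in the panel
#'   (else `indelLD_monomorphic_site`).
#' @return r-squared in `[0, 1]` (up to floating-point tolerance).
#' @export
pairwise_r2 <- function(panel, i, j) {
  m <- n_sites(panel)
  if (!is_count(i) || !is_count(j) || i < 1 || j < 1 || i > m || j > m) {
    stop_indelLD("index_error", "Site index out of range.")
  }
  x <- panel$haps[, i]
  y <- panel$haps[, j]
  p <- mean(x)
  q <- mean(y)
  if (p == 0 || p == 1 || q == 0 || q == 1) {
    stop_indelLD("monomorphic_site", "Both sites must be polymorphic.")
  }
  d <- mean(x * y) - p * q
  d^2 / (p * (1 - p) * q * (1 - q))
}

# Vectorized r2 of column y against matrix X (all columns polymorphic).
r2_columns <- function(y, X) {
  p <- mean(y)
  q <- colMeans(X)
  p11 <- as.vector(crossprod(X, y)) / length(y)
  d <- p11 - p * q
  d^2 / (p * (1 - p) * q * (1 - q))
}

#' Window-limited LD scan
#'
#' Computes r-squared between each focal site and every polymorphic SNP
#' within a `+/- window` bp region on the same chromosome (the focal site
#' itself excluded).  Partners are SNPs whether the focal is an indel
#' (indel-SNP LD) or a SNP (SNP-SNP control LD).  Monomorphic focals are
#' dropped, monomorphic partners skipped; both are tallied.
#'
#' @param panel A [hap_panel()].
#' @param focal Integer vector of focal site indices.  Defaults to all
#'   indel sites.
#' @param window Window radius in bp (default 100000); distances are
#'   `|pos_a - pos_b|` and the window is a closed interval.
#' @return An `ld_pairs` tibble: `focal_index`, `focal_id`, `focal_pos`,
#'   `partner_index`, `partner_id`, `partner_pos`, `chrom`, `distance`,
#'   `r2`.  Attributes: `focal_indices` (polymorphic focals scanned,
#'   including those that yielded no pair), `n_monomorphic_focal`,
#'   `n_monomorphic_partner`, `window`.
#' @export
ld_scan <- function(panel, focal = NULL, window = 1e5) {
  s <- panel$sites
  if (is.null(focal)) focal <- which(s$vclass != "SNP")
  focal <- as.integer(focal)
  if (length(focal) && (min(focal) < 1L || max(focal) > n_sites(panel))) {
    stop_indelLD("index_error", "Focal index out of range.")
  }
  f <- alt_freq(panel)
  poly <- f > 0 & f < 1
  n_mono_focal <- sum(!poly[focal])
  focal <- focal[poly[focal]]

  snp <- s$vclass == "SNP"
  n_mono_partner <- 0L
  out <- vector("list", length(focal))
  for (k in seq_along(focal)) {
    fi <- focal[k]
    cand <- which(snp & s$chrom == s$chrom[fi] &
                    abs(s$pos - s$pos[fi]) <= window)
    cand <- cand[cand != fi]
    n_mono_partner <- n_mono_partner + sum(!poly[cand])
    cand <- cand[poly[cand]]
    if (!length(cand)) next
    out[[k]] <- tibble(
      focal_index = fi, focal_id = s$site_id[fi], focal_pos = s$pos[fi],
      partner_index = cand, partner_id = s$site_id[cand],
      partner_pos = s$pos[cand], chrom = s$chrom[fi],
      distance = abs(s$pos[cand] - s$pos[fi]),
      r2 = r2_columns(panel$haps[, fi], panel$haps[, cand, drop = FALSE]))
  }
  pairs <- bind_rows(out)
  if (nrow(pairs) == 0L) {
    pairs <- tibble(focal_index = integer(), focal_id = character(),
                    focal_pos = integer(), partner_index = integer(),
                    partner_id = character(), partner_pos = integer(),
                    chrom = character(), distance = integer(), r2 = double())
  }
  class(pairs) <- c("ld_pairs", class(pairs))
  attr(pairs, "focal_indices") <- focal
  attr(pairs, "n_monomorphic_focal") <- n_mono_focal
  attr(pairs, "n_monomorphic_partner") <- n_mono_partner
  attr(pairs, "window") <- window
  pairs
}

# Restrict an ld_pairs table to a subset of focal indices, preserving the
# scan metadata attributes (plain `[` would drop them).
subset_pairs <- function(pairs, focal_keep) {
  out <- pairs[pairs$focal_index %in% focal_keep, , drop = FALSE]
  class(out) <- class(pairs)
  attr(out, "focal_indices") <- intersect(attr(pairs, "focal_indices"), focal_keep)
  attr(out, "window") <- attr(pairs, "window")
  out
}

# Distance-bin index: bin b covers [b*w + 1, (b+1)*w], b = 0, 1, ...
dist_bin <- function(distance, bin_width) {
  pmax(0L, as.integer(ceiling(distance / bin_width)) - 1L)
}

finish_curve <- function(per_bin, bin_width, stat) {
  max_bin <- max(per_bin$bin, 0L)
  curve <- left_join(tibble(bin = 0:max_bin), per_bin, by = "bin")
  curve <- mutate(curve,
                  bin_start = bin * bin_width,
                  bin_width = bin_width,
                  n = ifelse(is.na(n), 0L, n),
                  value = ifelse(n == 0L, NA_real_, value))
  curve <- select(curve, bin_start, bin_width, value, n)
  class(curve) <- c("ld_curve", class(curve))
  attr(curve, "stat") <- stat
  curve
}

#' Distance-binned average r-squared curve
#'
#' Mean r-squared of all pairs within each distance bin (default 100 bp
#' bins).  Bin `b` covers distances `[b*w + 1, (b+1)*w]`; empty bins are
#' emitted with `n = 0` and `value = NA`.
#'
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @param bin_width Bin width in bp (default 100).
#' @return An `ld_curve` tibble: `bin_start`, `bin_width`, `value`, `n`.
#' @export
average_r2_curve <- function(pairs, bin_width = 100) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_indelLD("domain_error", "`bin_width` must be positive.")
  }
  if (nrow(pairs) == 0L) stop_indelLD("domain_error", "`pairs` is empty.")
  per_bin <- summarise(group_by(mutate(pairs, bin = dist_bin(distance, bin_width)), bin),
                       value = mean(r2), n = dplyr::n(), .groups = "drop")
  finish_curve(per_bin, bin_width, "average_r2")
}

#' Distance-binned mean max r-squared curve
#'
#' For each focal variant and distance bin (default 1 kb), the maximum
#' r-squared among that focal's partners in the bin; the curve value is the
#' mean of these per-focal maxima over all focal variants with at least one
#' partner in the bin, and `n` counts contributing focals.
#'
#' @inheritParams average_r2_curve
#' @param bin_width Bin width in bp (default 1000).
#' @return An `ld_curve` tibble.
#' @export
mean_max_r2_curve <- function(pairs, bin_width = 1000) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_indelLD("domain_error", "`bin_width` must be positive.")
  }
  if (nrow(pairs) == 0L) stop_indelLD("domain_error", "`pairs` is empty.")
  per_focal <- summarise(group_by(mutate(pairs, bin = dist_bin(distance, bin_width)),
                                  focal_index, bin),
                         max_r2 = max(r2), .groups = "drop")
  per_bin <- summarise(group_by(per_focal, bin),
                       value = mean(max_r2), n = dplyr::n(), .groups = "drop")
  finish_curve(per_bin, bin_width, "mean_max_r2")
}

# Tagged-at-threshold indicator: strict > for thresholds below 1,
# equality within 1e-9 for perfect LD.
tagged_at <- function(max_r2, threshold) {
  if (threshold >= 1) max_r2 >= 1 - 1e-9 else max_r2 > threshold
}

#' Tag-SNP summary by stratum and LD threshold
#'
#' Percentage of focal variants with at least one partner SNP at medium
#' (`r2 > 0.5`), high (`r2 > 0.8`) or perfect (`r2 = 1`, tolerance 1e-9)
#' LD, per stratum.  Focal variants with no partner at all count in the
#' denominator.
#'
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @param strata Stratum labels for the focal variants: a character/factor
#'   vector named by focal index, or a data frame with columns
#'   `focal_index` and `stratum`.  Defaults to a single `"all"` stratum
#'   over the scanned focals.
#' @param thresholds LD thresholds (default `c(0.5, 0.8, 1.0)`).
#' @return A `tagging_table` tibble: `stratum`, `threshold`, `n_focal`,
#'   `n_tagged`, `percent`.
#' @export
tagging_summary <- function(pairs, strata = NULL, thresholds = c(0.5, 0.8, 1.0)) {
  focals <- attr(pairs, "focal_indices") %||% unique(pairs$focal_index)
  strata <- normalize_strata(strata, focals)
  max_r2 <- rep(0, length(focals))
  names(max_r2) <- as.character(focals)
  if (nrow(pairs) > 0L) {
    mx <- summarise(group_by(pairs, focal_index), m = max(r2), .groups = "drop")
    max_r2[as.character(mx$focal_index)] <- mx$m
  }
  rows <- list()
  for (lev in levels(strata)) {
    in_str <- strata == lev
    for (t in thresholds) {
      n_tag <- sum(tagged_at(max_r2[in_str], t))
      rows[[length(rows) + 1L]] <- tibble(
        stratum = lev, threshold = t,
        n_focal = sum(in_str), n_tagged = n_tag,
        percent = if (sum(in_str) == 0L) NA_real_ else 100 * n_tag / sum(in_str))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("tagging_table", class(out))
  out
}

normalize_strata <- function(strata, focals) {
  if (is.null(strata)) {
    return(factor(rep("all", length(focals))))
  }
  if (is.data.frame(strata)) {
    strata <- setNames(as.character(strata$stratum), as.character(strata$focal_index))
  }
  if (is.null(names(strata))) {
    if (length(strata) != length(focals)) {
      stop_indelLD("domain_error", "Unnamed `strata` must match the focal set length.")
    }
    names(strata) <- as.character(focals)
  }
  lab <- strata[as.character(focals)]
  if (anyNA(lab)) {
    stop_indelLD("domain_error", "Every focal variant needs a stratum label.")
  }
  factor(as.character(lab))
}

#' Frequency-matched tagging cross-tabulation
#'
#' For focal variants in the `low` and `common` MAF bins, the percentage
#' with at least one partner SNP of each MAF bin at high LD (`r2 > 0.8`):
#' a 2x2 cross-tabulation showing whether variants are tagged by
#' frequency-matched SNPs.
#'
#' @param panel The [hap_panel()] the pairs were computed from.
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @param scheme A [maf_bin_scheme()].
#' @param threshold High-LD threshold (default 0.8, strict).
#' @return A tibble: `focal_bin`, `partner_bin`, `n_focal`, `n_tagged`,
#'   `percent` (NA when a stratum is empty).
#' @export
freq_matched_tagging <- function(panel, pairs, scheme = maf_bin_scheme(),
                                 threshold = 0.8) {
  freqs <- site_frequencies(panel)
  bins <- maf_bin(freqs$maf, freqs$minor_count, scheme)$bin
  focals <- attr(pairs, "focal_indices") %||% unique(pairs$focal_index)
  rows <- list()
  for (fb in c("low", "common")) {
    in_fb <- focals[bins[focals] == fb]
    for (pb in c("low", "common")) {
      if (length(in_fb) == 0L) {
        rows[[length(rows) + 1L]] <- tibble(focal_bin = fb, partner_bin = pb,
                                            n_focal = 0L, n_tagged = 0L,
                                            percent = NA_real_)
        next
      }
      sub <- filter(pairs, focal_index %in% in_fb,
                    bins[partner_index] == pb, r2 > threshold)
      n_tag <- length(unique(sub$focal_index))
      rows[[length(rows) + 1L]] <- tibble(
        focal_bin = fb, partner_bin = pb,
        n_focal = length(in_fb), n_tagged = n_tag,
        percent = 100 * n_tag / length(in_fb))
    }
  }
  bind_rows(rows)
}

#' Extended-haplotype span of high-LD partner sets
#'
#' For each focal variant with at least one partner above the LD
#' threshold, the positional extent (max - min position, bp) of the set
#' formed by the focal site and its qualifying partners — an interpretation
#' of "haplotype length" as the span of the high-LD neighbourhood.
#'
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @param threshold Qualifying threshold (default 0.8, strict).
#' @param focal Optional single focal index; if it has no qualifying
#'   partner an `indelLD_no_high_ld_partner` error is raised.
#' @return A tibble `focal_index`, `focal_id`, `span_bp`, `n_partners`
#'   (focals without qualifying partners omitted; their count in attribute
#'   `n_no_partner`).
#' @export
haplotype_span <- function(pairs, threshold = 0.8, focal = NULL) {
  focals <- attr(pairs, "focal_indices") %||% unique(pairs$focal_index)
  qual <- filter(pairs, r2 > threshold)
  if (!is.null(focal)) {
    qual <- filter(qual, focal_index == focal)
    if (nrow(qual) == 0L) {
      stop_indelLD("no_high_ld_partner",
                   sprintf("Focal %d has no partner with r2 > %g.", focal, threshold))
    }
  }
  if (nrow(qual) == 0L) {
    spans <- tibble(focal_index = integer(), focal_id = character(),
                    span_bp = double(), n_partners = integer())
  } else {
    spans <- summarise(group_by(qual, focal_index, focal_id),
                       span_bp = max(c(partner_pos, focal_pos)) -
                         min(c(partner_pos, focal_pos)),
                       n_partners = dplyr::n(), .groups = "drop")
  }
  attr(spans, "n_no_partner") <- length(setdiff(focals, spans$focal_index))
  spans
}

#' Per-focal maximum r-squared
#'
#' Convenience summary used for stratum comparisons: the best partner
#' r-squared of every scanned focal variant (0 when it has no partner).
#'
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @return Tibble `focal_index`, `max_r2`, `n_high_ld` (partners with
#'   `r2 > 0.8`).
#' @export
focal_max_r2 <- function(pairs) {
  focals <- attr(pairs, "focal_indices") %||% unique(pairs$focal_index)
  base <- tibble(focal_index = focals, max_r2 = 0, n_high_ld = 0L)
  if (nrow(pairs) > 0L) {
    mx <- summarise(group_by(pairs, focal_index),
                    m = max(r2), nh = sum(r2 > 0.8), .groups = "drop")
    i <- match(mx$focal_index, base$focal_index)
    base$max_r2[i] <- mx$m
    base$n_high_ld[i] <- mx$nh
  }
  base
}
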