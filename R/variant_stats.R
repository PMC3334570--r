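#' Per-site allele frequencies
#'
#' Minor allele frequencies are always re-computed from the panel's own
#' haplotypes (never taken from release annotations), so population or
#' sample subsetting is automatically reflected.
#'
#' @param panel A [hap_panel()].
#' @return A tibble with one row per site: `site_id`, `vclass`,
#'   `alt_count`, `maf` (in `[0, 0.5]`) and `minor_count` (minor-allele
#'   haplotype count; 1 marks a singleton).
#' @export
site_frequencies <- function(panel) {
  f <- alt_freq(panel)
  nh <- nrow(panel$haps)
  tibble(site_index = seq_len(n_sites(panel)),
         site_id = panel$sites$site_id,
         vclass = panel$sites$vclass,
         alt_count = as.integer(round(f * nh)),
         maf = pmin(f, 1 - f),
         minor_count = as.integer(round(pmin(f, 1 - f) * nh)))
}

#' @rdname site_frequencies
#' @param site_index Single site index.
#' @return `minor_allele_freq()`: the folded frequency `min(f, 1 - f)`.
#' @export
minor_allele_freq <- function(panel, site_index) {
  if (!is_count(site_index) || site_index < 1 || site_index > n_sites(panel)) {
    stop_indelLD("index_error", "`site_index` out of range.")
  }
  f <- mean(panel$haps[, site_index])
  min(f, 1 - f)
}

#' Minor-allele-frequency binning scheme
#'
#' The conventional three-way split used throughout the package: variants
#' below `excluded_below` are excluded outright (in the source data these
#' were all singletons), `low` covers `[excluded_below, low_upper)` and
#' `common` covers `[low_upper, 0.5]`.  A MAF of exactly `low_upper` (5%)
#' is binned `common`; the boundary is configurable.
#'
#' @param excluded_below Exclusion cutoff (default 0.01).
#' @param low_upper Low/common boundary (default 0.05).
#' @return A `maf_bin_scheme` list.
#' @export
maf_bin_scheme <- function(excluded_below = 0.01, low_upper = 0.05) {
  if (!(excluded_below > 0 && excluded_below < low_upper && low_upper <= 0.5)) {
    stop_indelLD("domain_error", "Need 0 < excluded_below < low_upper <= 0.5.")
  }
  structure(list(excluded_below = excluded_below, low_upper = low_upper,
                 bins = c("excluded", "low", "common")),
            class = "maf_bin_scheme")
}

#' Bin minor allele frequencies
#'
#' @param f Minor allele frequency vector, each in `[0, 0.5]`.
#' @param minor_count Optional matching minor-allele counts, used to report
#'   singleton status.
#' @param scheme A [maf_bin_scheme()].
#' @return A tibble with `maf`, `bin` (factor excluded/low/common) and
#'   `singleton` (`NA` when `minor_count` not given).
#' @export
maf_bin <- function(f, minor_count = NULL, scheme = maf_bin_scheme()) {
  if (any(is.na(f)) || any(f < 0) || any(f > 0.5 + 1e-12)) {
    stop_indelLD("domain_error", "MAF values must lie in [0, 0.5].")
  }
  bin <- ifelse(f < scheme$excluded_below, "excluded",
                ifelse(f < scheme$low_upper, "low", "common"))
  tibble(maf = f,
         bin = factor(bin, levels = scheme$bins),
         singleton = if (is.null(minor_count)) NA else minor_count == 1L)
}

#' Remove rare sites from a panel
#'
#' Applies the rare-variant exclusion rule: sites of the given classes with
#' MAF below `min_maf` are dropped.  By default only indels are filtered
#' (the rule under which rare indels, all singletons in the source data,
#' were removed); monomorphic sites of the filtered classes go with them.
#'
#' @param panel A [hap_panel()].
#' @param min_maf Exclusion cutoff (default 0.01).
#' @param classes Variant classes the rule applies to.
#' @return Filtered panel with attribute `n_rare_removed`.
#' @export
filter_rare_sites <- function(panel, min_maf = 0.01,
                              classes = c("insertion", "deletion")) {
  f <- alt_freq(panel)
  maf <- pmin(f, 1 - f)
  drop <- panel$sites$vclass %in% classes & maf < min_maf
  out <- subset_sites(panel, which(!drop))
  attr(out, "n_rare_removed") <- sum(drop)
  out
}

#' Classify indel size
#'
#' Splits indels at the conventional 6-bp boundary: `small` for lengths up
#' to `small_cutoff`, `large` above it.  SNP input is an error
#' (`indelLD_class_error`).
#'
#' @param indel_length Integer vector of indel lengths (bp), or a panel
#'   sites row subset with `vclass`/`indel_length` columns.
#' @param small_cutoff Inclusive small-size cutoff (default 6).
#' @return Factor with levels `small`, `large`.
#' @export
classify_indel_size <- function(indel_length, small_cutoff = 6L) {
  if (is.data.frame(indel_length)) {
    if (any(indel_length$vclass == "SNP")) {
      stop_indelLD("class_error", "Size classification applies to indels only.")
    }
    indel_length <- indel_length$indel_length
  }
  if (any(indel_length < 1L)) {
    stop_indelLD("class_error", "Size classification applies to indels only.")
  }
  factor(ifelse(indel_length <= small_cutoff, "small", "large"),
         levels = c("small", "large"))
}

#' Annotate sites with genomic region labels
#'
#' Interval lookup against a BED file (0-based half-open; converted to
#' 1-based closed internally, so a site at the BED `start` coordinate is
#' *not* contained).  Each site receives the label of the first covering
#' interval in file order, else `"intergenic"`.
#'
#' @param panel A [hap_panel()].
#' @param bed Path to a BED file (`chrom  start  end  label`) or a data
#'   frame with those columns.
#' @param label_map Optional named character vector mapping raw BED labels
#'   to region classes; unmapped labels pass through unchanged.
#' @return The panel with `region_label` filled in.
#' @export
annotate_regions <- function(panel, bed, label_map = NULL) {
  bed <- read_bed(bed)
  s <- panel$sites
  lab <- rep("intergenic", nrow(s))
  for (k in rev(seq_len(nrow(bed)))) {       # reverse so first interval wins
    inside <- s$chrom == bed$chrom[k] &
      s$pos >= bed$start[k] + 1L & s$pos <= bed$end[k]
    lab[inside] <- bed$label[k]
  }
  if (!is.null(label_map)) {
    mapped <- !is.na(label_map[lab])
    lab[mapped] <- unname(label_map[lab[mapped]])
  }
  panel$sites$region_label <- lab
  panel
}

read_bed <- function(bed) {
  if (is.character(bed) && length(bed) == 1L) {
    bed <- tryCatch(
      readr::read_tsv(bed, col_names = c("chrom", "start", "end", "label"),
                      col_types = readr::cols(chrom = readr::col_character(),
                                              start = readr::col_integer(),
                                              end = readr::col_integer(),
                                              label = readr::col_character()),
                      progress = FALSE),
      error = function(e) stop_indelLD("parse_error", conditionMessage(e)))
  }
  bed <- as_tibble(bed)
  if (!all(c("chrom", "start", "end") %in% names(bed)) ||
      anyNA(bed$start) || anyNA(bed$end) || any(bed$end < bed$start)) {
    stop_indelLD("parse_error", "Malformed BED input.")
  }
  if (!("label" %in% names(bed)) || all(is.na(bed$label))) bed$label <- "region"
  bed
}

#' Two-proportion z-test
#'
#' Pooled two-sided z-test for equality of two binomial proportions,
#' without continuity correction:
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' `p = (x1 + x2)/(n1 + n2)`.
#'
#' @param x1,n1,x2,n2 Successes and trials of the two groups.
#' @return An `indel_htest` object with `statistic` (z), `p_value`,
#'   `estimate` (the two proportions) and a `degenerate` flag.  When the
#'   pooled proportion is 0 or 1 the test is degenerate: `p_value = 1` by
#'   convention, flagged and signalled as an `indelLD_degenerate_test`
#'   warning.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (!all(vapply(list(x1, n1, x2, n2), is_count, logical(1))) ||
      x1 > n1 || x2 > n2 || n1 == 0 || n2 == 0) {
    stop_indelLD("domain_error", "Need 0 <= x <= n with n > 0 in both groups.")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  degenerate <- pp == 0 || pp == 1
  if (degenerate) {
    warn_indelLD("degenerate_test",
                 "Pooled proportion is 0 or 1; p-value set to 1 by convention.")
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(statistic = z, p_value = p,
                 estimate = c(prop1 = p1, prop2 = p2),
                 n = c(n1 = n1, n2 = n2),
                 test_name = "two_proportion", degenerate = degenerate),
            class = "indel_htest")
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank ties; two-sided p-value from the
#' normal approximation with tie-corrected variance and continuity
#' correction.  `statistic` is `U` for the first sample, i.e. the number of
#' pairs `(a_i, b_j)` with `a_i > b_j`, ties counting one half.
#'
#' @param a,b Non-empty numeric vectors.
#' @return An `indel_htest` object.
#' @export
mann_whitney_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L || anyNA(a) || anyNA(b)) {
    stop_indelLD("domain_error", "Both samples must be non-empty and free of NA.")
  }
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  ties <- table(r)
  mu <- na * nb / 2
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  degenerate <- sigma2 <= 0
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    cc <- if (u_a == mu) 0 else 0.5 * sign(u_a - mu)
    z <- (u_a - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(statistic = u_a, p_value = p,
                 n = c(n_a = na, n_b = nb),
                 test_name = "mann_whitney", degenerate = degenerate),
            class = "indel_htest")
}

#' @export
print.indel_htest <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g%s\n",
              x$test_name, x$statistic, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' @export
tidy.indel_htest <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         method = x$test_name, degenerate = x$degenerate)
}

#' @export
glance.indel_htest <- function(x, ...) tidy(x)
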