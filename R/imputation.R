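#' Haplotype-copying model parameters
#'
#' Parameters of the Li-Stephens-style copying HMM used for imputation.
#' The default switch rate gives an expected copy-segment length of about
#' 25 kb, the scale of common-variant extended haplotypes; the default
#' emission mismatch probability 0.005 mirrors treating observed panel
#' genotypes as correct with likelihood 0.995.
#'
#' @param switch_rate Per-bp hidden-state switch intensity, lambda > 0
#'   (default 4e-5).
#' @param emission_error Allele mismatch probability, in (0, 0.5)
#'   (default 0.005).
#' @param window Context window radius in bp (default 100000).
#' @return A `copying_params` list.
#' @export
copying_params <- function(switch_rate = 4e-5, emission_error = 0.005,
                           window = 1e5) {
  if (!is.numeric(switch_rate) || switch_rate <= 0) {
    stop_indelLD("domain_error", "`switch_rate` must be positive.")
  }
  if (!is.numeric(emission_error) || emission_error <= 0 || emission_error >= 0.5) {
    stop_indelLD("domain_error", "`emission_error` must lie in (0, 0.5).")
  }
  if (!is.numeric(window) || window <= 0) {
    stop_indelLD("domain_error", "`window` must be positive.")
  }
  structure(list(switch_rate = switch_rate, emission_error = emission_error,
                 window = window),
            class = "copying_params")
}

#' Copying-model posterior weights over reference haplotypes
#'
#' Forward-backward posteriors of the haplotype-copying HMM.  The hidden
#' state space is the `H` reference haplotypes; between adjacent context
#' SNPs at distance `d` the chain stays with probability
#' `exp(-lambda d) + (1 - exp(-lambda d))/H` and switches to each specific
#' other state with probability `(1 - exp(-lambda d))/H`; emissions match
#' the target allele with probability `1 - eps`.  Posterior weights are
#' read at the context SNP nearest the query position (left on ties) and
#' sum to 1.
#'
#' @param target_hap Binary vector of target alleles over the context SNPs.
#' @param ref_haps `H x S` binary matrix of reference haplotypes.
#' @param positions Strictly increasing bp positions of the `S` context
#'   SNPs.
#' @param query_pos Query position (bp).
#' @param params A [copying_params()].
#' @return Numeric vector of `H` posterior weights.
#' @export
copying_posteriors <- function(target_hap, ref_haps, positions, query_pos,
                               params = copying_params()) {
  ref_haps <- as.matrix(ref_haps)
  if (nrow(ref_haps) == 0L) {
    stop_indelLD("empty_reference_panel", "Need at least one reference haplotype.")
  }
  if (ncol(ref_haps) == 0L || length(target_hap) == 0L) {
    stop_indelLD("no_context", "Need at least one context SNP.")
  }
  if (length(target_hap) != ncol(ref_haps) || length(positions) != ncol(ref_haps)) {
    stop_indelLD("domain_error", "Target, reference and positions disagree in length.")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop_indelLD("domain_error", "`positions` must be strictly increasing.")
  }
  storage.mode(ref_haps) <- "integer"
  copying_weights_cpp(ref_haps, as.integer(target_hap), as.numeric(positions),
                      as.numeric(query_pos), params$switch_rate,
                      params$emission_error)
}

# Polymorphic SNP context within +/- window of site `focal`.
context_snp_indices <- function(panel, focal, window) {
  s <- panel$sites
  f <- alt_freq(panel)
  which(s$vclass == "SNP" & s$chrom == s$chrom[focal] &
          abs(s$pos - s$pos[focal]) <= window &
          f > 0 & f < 1 & seq_len(nrow(s)) != focal)
}

#' Impute one indel genotype by haplotype copying
#'
#' Leave-one-individual-out imputation of a focal variant for one sample:
#' the sample's two haplotypes are removed from the reference panel, the
#' focal alleles are masked in the target, and each target haplotype's
#' alt-allele probability is the copying-posterior-weighted mean of the
#' remaining reference haplotypes' focal alleles.  The two haplotypes are
#' combined under phased independence into a genotype posterior over
#' ref/ref, ref/alt, alt/alt.
#'
#' @param panel A [hap_panel()].
#' @param sample Sample index (1..N) or sample id.
#' @param focal Focal site index (normally an indel).
#' @param params A [copying_params()].
#' @param include_focal Diagnostic switch: when `TRUE` the focal column
#'   itself is added to the context (no masking), which must reproduce the
#'   true genotype — useful only for validating the evaluation machinery.
#' @return A `genotype_posterior` list: `p_refref`, `p_refalt`, `p_altalt`,
#'   `hard_call` (factor), `tie` flag.
#' @export
impute_indel_genotype <- function(panel, sample, focal,
                                  params = copying_params(),
                                  include_focal = FALSE) {
  if (is.character(sample)) sample <- match(sample, panel$samples)
  if (is.na(sample) || !is_count(sample) || sample < 1 ||
      sample > n_samples(panel)) {
    stop_indelLD("index_error", "Unknown sample.")
  }
  if (!is_count(focal) || focal < 1 || focal > n_sites(panel)) {
    stop_indelLD("index_error", "Focal index out of range.")
  }
  if (n_samples(panel) < 2L) {
    stop_indelLD("empty_reference_panel",
                 "Leave-one-out imputation needs at least two samples.")
  }
  ctx <- context_snp_indices(panel, focal, params$window)
  if (include_focal) ctx <- sort(unique(c(ctx, focal)))
  if (length(ctx) == 0L) {
    stop_indelLD("no_context", "No polymorphic context SNP within the window.")
  }
  post <- loo_posteriors_cpp(panel$haps[, ctx, drop = FALSE],
                             panel$haps[, focal],
                             as.numeric(panel$sites$pos[ctx]),
                             as.numeric(panel$sites$pos[focal]),
                             params$switch_rate, params$emission_error)[sample, ]
  if (post[4] == 1) {
    # focal monomorphic after leave-out: posterior collapses to the single
    # remaining allele
    a <- panel$haps[-c(2 * sample - 1L, 2 * sample), focal][1]
    post[1:3] <- if (a == 0L) c(1, 0, 0) else c(0, 0, 1)
  }
  pref <- genotype_class_counts(panel, focal)
  call <- pick_hard_call(post[1:3], pref)
  structure(list(p_refref = post[1], p_refalt = post[2], p_altalt = post[3],
                 hard_call = factor(c("refref", "refalt", "altalt")[call$idx],
                                    levels = c("refref", "refalt", "altalt")),
                 tie = call$tie),
            class = "genotype_posterior")
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat(sprintf("genotype posterior: ref/ref %.4f, ref/alt %.4f, alt/alt %.4f -> %s\n",
              x$p_refref, x$p_refalt, x$p_altalt, as.character(x$hard_call)))
  invisible(x)
}

genotype_class_counts <- function(panel, focal) {
  tabulate(site_genotypes(panel, focal) + 1L, nbins = 3L)
}

# argmax with ties broken toward the genotype class more frequent in the
# panel, then toward the lower class index.
pick_hard_call <- function(p, pref_counts, tol = 1e-12) {
  cand <- which(p >= max(p) - tol)
  tie <- length(cand) > 1L
  if (tie) cand <- cand[order(-pref_counts[cand], cand)]
  list(idx = cand[1], tie = tie)
}

#' Concordance table constructor
#'
#' @param counts 3x3 matrix of genotype counts, rows = true class, columns
#'   = imputed class, in order ref/ref, ref/alt, alt/alt.
#' @return A `concordance_table` with per-class concordance (diagonal over
#'   row sum) and overall concordance (trace over total).
#' @export
concordance_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || any(counts < 0)) {
    stop_indelLD("domain_error", "`counts` must be a non-negative 3x3 matrix.")
  }
  dimnames(counts) <- list(true = c("refref", "refalt", "altalt"),
                           imputed = c("refref", "refalt", "altalt"))
  rs <- rowSums(counts)
  per_class <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  total <- sum(counts)
  structure(list(counts = counts,
                 per_class = setNames(per_class, rownames(counts)),
                 overall = if (total > 0) sum(diag(counts)) / total else NA_real_,
                 n = total),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> n = %d genotypes\n", x$n))
  print(x$counts)
  cat(sprintf("per-class: ref/ref %.3f  ref/alt %.3f  alt/alt %.3f  overall %.3f\n",
              x$per_class[1], x$per_class[2], x$per_class[3], x$overall))
  invisible(x)
}

#' @export
tidy.concordance_table <- function(x, ...) {
  d <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  as_tibble(setNames(d, c("true_class", "imputed_class", "n")))
}

#' @export
glance.concordance_table <- function(x, ...) {
  tibble(n = x$n, overall = x$overall,
         refref = x$per_class[["refref"]],
         refalt = x$per_class[["refalt"]],
         altalt = x$per_class[["altalt"]])
}

# Shared leave-one-out evaluation engine.
# ctx_list: list parallel to focal_set with the context-SNP indices to use
# for each focal variant (possibly empty -> focal skipped, tallied).
loo_engine <- function(panel, focal_set, ctx_list, strata, params) {
  strata <- normalize_strata(strata, focal_set)
  counts <- lapply(levels(strata), function(...) matrix(0L, 3L, 3L))
  names(counts) <- levels(strata)
  n_no_context <- 0L
  n_skipped <- 0L
  n_ties <- 0L
  pos <- panel$sites$pos
  for (k in seq_along(focal_set)) {
    f <- focal_set[k]
    ctx <- ctx_list[[k]]
    if (length(ctx) == 0L) {
      n_no_context <- n_no_context + 1L
      next
    }
    post <- loo_posteriors_cpp(panel$haps[, ctx, drop = FALSE], panel$haps[, f],
                               as.numeric(pos[ctx]), as.numeric(pos[f]),
                               params$switch_rate, params$emission_error)
    keep <- post[, 4] == 0
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) next
    g_true <- site_genotypes(panel, f) + 1L
    pref <- tabulate(g_true, nbins = 3L)
    lab <- as.character(strata[k])
    for (i in which(keep)) {
      call <- pick_hard_call(post[i, 1:3], pref)
      if (call$tie) n_ties <- n_ties + 1L
      counts[[lab]][g_true[i], call$idx] <- counts[[lab]][g_true[i], call$idx] + 1L
    }
  }
  tables <- lapply(counts, concordance_table)
  attr(tables, "n_no_context") <- n_no_context
  attr(tables, "n_skipped_monomorphic") <- n_skipped
  attr(tables, "n_ties") <- n_ties
  tables
}

finalize_conc <- function(tables, strata_given) {
  if (!strata_given) {
    out <- tables[[1]]
    attr(out, "n_no_context") <- attr(tables, "n_no_context")
    attr(out, "n_skipped_monomorphic") <- attr(tables, "n_skipped_monomorphic")
    attr(out, "n_ties") <- attr(tables, "n_ties")
    return(out)
  }
  class(tables) <- "concordance_by_stratum"
  tables
}

#' Leave-one-individual-out imputation concordance
#'
#' Evaluates the copying imputer over every (focal variant, sample) pair:
#' each individual is left out in turn, its focal genotype imputed from all
#' polymorphic SNPs within the window, and the hard call compared to the
#' panel genotype.  Counts accumulate into 3x3 true-by-imputed tables,
#' genotype-weighted (every evaluated genotype counts once), separately per
#' stratum when `strata` is given.  Focal/sample combinations where the
#' focal variant is monomorphic after leave-out are skipped and tallied.
#'
#' @param panel A [hap_panel()].
#' @param focal_set Integer vector of focal (indel) site indices.
#' @param strata Optional stratum labels for the focal set (vector parallel
#'   to `focal_set`, named by index, or a `focal_index`/`stratum` data
#'   frame).
#' @param params A [copying_params()].
#' @param include_focal Diagnostic switch adding the unmasked focal column
#'   to its own context (see [impute_indel_genotype()]); concordance must
#'   then be perfect.
#' @return A [concordance_table()] (no strata) or a named list of them
#'   (class `concordance_by_stratum`), with skip tallies as attributes.
#' @export
loo_concordance <- function(panel, focal_set, strata = NULL,
                            params = copying_params(), include_focal = FALSE) {
  check_focal_set(panel, focal_set)
  ctx_list <- lapply(focal_set, function(f) {
    ctx <- context_snp_indices(panel, f, params$window)
    if (include_focal) sort(unique(c(ctx, f))) else ctx
  })
  finalize_conc(loo_engine(panel, focal_set, ctx_list, strata, params),
                !is.null(strata))
}

check_focal_set <- function(panel, focal_set) {
  if (length(focal_set) == 0L) {
    stop_indelLD("domain_error", "`focal_set` is empty.")
  }
  if (min(focal_set) < 1L || max(focal_set) > n_sites(panel)) {
    stop_indelLD("index_error", "Focal index out of range.")
  }
  f <- alt_freq(panel)[focal_set]
  if (any(f == 0 | f == 1)) {
    stop_indelLD("monomorphic_site", "Focal variants must be polymorphic.")
  }
  invisible(TRUE)
}

#' r-squared-binned imputation experiment
#'
#' Groups each focal variant's context SNPs by their pairwise r-squared
#' with the focal variant into bins of width `bin_width` (left-open,
#' right-closed; the first bin closed at 0), then reruns the leave-one-out
#' evaluation using only the SNPs of one bin at a time.  With the default
#' width this yields exactly 20 bins, 0-0.05 through 0.95-1; focal variants
#' with no SNP in a bin are excluded from that bin's denominators.
#'
#' @inheritParams loo_concordance
#' @param bin_width r-squared bin width (default 0.05).
#' @return An `r2_binned_concordance` tibble with one row per bin:
#'   `bin`, `r2_low`, `r2_high`, `label`, `n_genotypes`, `n_focals`, and a
#'   `table` list-column of [concordance_table()]s.
#' @export
r2_binned_concordance <- function(panel, focal_set, params = copying_params(),
                                  bin_width = 0.05) {
  check_focal_set(panel, focal_set)
  nb <- as.integer(round(1 / bin_width))
  ctx_all <- lapply(focal_set, context_snp_indices,
                    panel = panel, window = params$window)
  r2_all <- lapply(seq_along(focal_set), function(k) {
    ctx <- ctx_all[[k]]
    if (length(ctx) == 0L) return(numeric(0))
    r2_columns(panel$haps[, focal_set[k]], panel$haps[, ctx, drop = FALSE])
  })
  bin_of <- lapply(r2_all, function(r2) pmin(nb, pmax(1L, ceiling(r2 / bin_width))))

  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    ctx_b <- lapply(seq_along(focal_set), function(k) ctx_all[[k]][bin_of[[k]] == b])
    n_focals <- sum(lengths(ctx_b) > 0L)
    tab <- finalize_conc(loo_engine(panel, focal_set, ctx_b, NULL, params), FALSE)
    rows[[b]] <- tibble(bin = b,
                        r2_low = (b - 1) * bin_width, r2_high = b * bin_width,
                        label = sprintf("%.2f-%.2f", (b - 1) * bin_width, b * bin_width),
                        n_genotypes = tab$n, n_focals = n_focals,
                        table = list(tab))
  }
  out <- bind_rows(rows)
  class(out) <- c("r2_binned_concordance", class(out))
  out
}

#' Frequency-matched imputation concordance
#'
#' Identical to [loo_concordance()] but each focal variant's context is
#' restricted to SNPs in the same MAF bin as the focal variant itself —
#' the test of whether frequency-matched SNPs alone carry the imputation
#' signal.  Focal variants with no frequency-matched context SNP are
#' skipped and tallied (`n_no_context`).
#'
#' @inheritParams loo_concordance
#' @param scheme A [maf_bin_scheme()].
#' @export
freq_matched_concordance <- function(panel, focal_set, scheme = maf_bin_scheme(),
                                     strata = NULL, params = copying_params()) {
  check_focal_set(panel, focal_set)
  freqs <- site_frequencies(panel)
  bins <- maf_bin(freqs$maf, freqs$minor_count, scheme)$bin
  ctx_list <- lapply(seq_along(focal_set), function(k) {
    ctx <- context_snp_indices(panel, focal_set[k], params$window)
    ctx[bins[ctx] == bins[focal_set[k]]]
  })
  finalize_conc(loo_engine(panel, focal_set, ctx_list, strata, params),
                !is.null(strata))
}

#' @export
tidy.r2_binned_concordance <- function(x, ...) {
  tidyr::unnest(mutate(select(x, bin, r2_low, r2_high, label, table),
                       table = map(table, glance)),
                table)
}

#' @export
tidy.concordance_by_stratum <- function(x, ...) {
  bind_rows(lapply(names(x), function(nm) {
    mutate(glance(x[[nm]]), stratum = nm, .before = 1)
  }))
}
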