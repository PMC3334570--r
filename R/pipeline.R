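#' Analysis configuration
#'
#' Bundles every knob of the end-to-end analysis: the input panel (a
#' [hap_panel()], a [sim_config()], or VCF paths), the MAF binning scheme,
#' LD window and thresholds, copying-model parameters, stratification
#' toggles and optional focal sampling.  All stochastic steps derive from
#' `seed`.
#'
#' @param panel Optional pre-built [hap_panel()].
#' @param sim Optional [sim_config()] used when `panel` is `NULL`.
#' @param vcf_indels,vcf_snps Optional VCF paths read and merged when
#'   neither `panel` nor `sim` is given.
#' @param lof_sites Optional LOF site list (path or data frame).
#' @param regions_bed Optional BED path/data frame for region annotation.
#' @param array_sites Optional site list restricting the SNP panel (array
#'   emulation; focal indels are always retained).
#' @param scheme A [maf_bin_scheme()].
#' @param window LD / imputation window radius in bp.
#' @param thresholds Tagging thresholds.
#' @param params A [copying_params()] (its window defaults to `window`).
#' @param strata Character vector of stratification toggles, subset of
#'   `c("maf_bin", "size", "lof")`.
#' @param focal_sample_n Optional number of focal indels to sample (the
#'   default analyzes all focal indels).
#' @param snp_control_n Optional number of SNPs sampled as a SNP-SNP LD
#'   control stratum.
#' @param run_imputation Run the leave-one-out concordance stages.
#' @param run_r2_bins Run the r-squared-binned imputation experiment
#'   (the most expensive stage; off by default).
#' @param min_indel_maf Rare-indel exclusion cutoff (default
#'   `scheme$excluded_below`).
#' @param seed Integer seed for focal/SNP-control sampling.
#' @param out_dir Optional directory: when set, [run_full_analysis()]
#'   writes the report bundle there.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(panel = NULL, sim = NULL, vcf_indels = NULL,
                            vcf_snps = NULL, lof_sites = NULL,
                            regions_bed = NULL, array_sites = NULL,
                            scheme = maf_bin_scheme(), window = 1e5,
                            thresholds = c(0.5, 0.8, 1.0),
                            params = copying_params(window = window),
                            strata = c("maf_bin", "size", "lof"),
                            focal_sample_n = NULL, snp_control_n = NULL,
                            run_imputation = TRUE, run_r2_bins = FALSE,
                            min_indel_maf = NULL, seed = 1L,
                            out_dir = NULL) {
  if (is.null(panel) && is.null(sim) &&
      (is.null(vcf_indels) || is.null(vcf_snps))) {
    stop_indelLD("config_error",
                 "Provide `panel`, `sim`, or both `vcf_indels` and `vcf_snps`.")
  }
  strata <- match.arg(strata, c("maf_bin", "size", "lof"), several.ok = TRUE)
  structure(list(panel = panel, sim = sim, vcf_indels = vcf_indels,
                 vcf_snps = vcf_snps, lof_sites = lof_sites,
                 regions_bed = regions_bed, array_sites = array_sites,
                 scheme = scheme, window = window, thresholds = thresholds,
                 params = params, strata = strata,
                 focal_sample_n = focal_sample_n,
                 snp_control_n = snp_control_n,
                 run_imputation = isTRUE(run_imputation),
                 run_r2_bins = isTRUE(run_r2_bins),
                 min_indel_maf = min_indel_maf %||% scheme$excluded_below,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

site_class_table <- function(panel, scheme) {
  freqs <- site_frequencies(panel)
  bins <- maf_bin(freqs$maf, freqs$minor_count, scheme)
  sz <- rep(NA_character_, nrow(freqs))
  ind <- panel$sites$vclass != "SNP"
  if (any(ind)) {
    sz[ind] <- as.character(classify_indel_size(panel$sites$indel_length[ind]))
  }
  mutate(freqs,
         maf_bin = bins$bin, singleton = bins$singleton,
         indel_size = sz,
         lof = panel$sites$lof,
         region_label = panel$sites$region_label,
         chrom = panel$sites$chrom, pos = panel$sites$pos)
}

focal_strata_table <- function(site_table, focal, toggles) {
  st <- site_table[focal, , drop = FALSE]
  out <- tibble(focal_index = focal)
  if ("maf_bin" %in% toggles) out$maf_bin <- as.character(st$maf_bin)
  if ("size" %in% toggles) out$size <- st$indel_size
  if ("lof" %in% toggles) out$lof <- ifelse(st$lof, "LOF", "non-LOF")
  out
}

#' Run the full indel LD + imputation analysis
#'
#' Executes the pipeline end to end: obtain the panel (simulate, read, or
#' as given), LOF flagging, rare-indel removal, optional region
#' annotation and array-site restriction, MAF/size classification, the
#' windowed LD scan, average and mean-max r-squared curves, tagging tables
#' (overall, per stratum, frequency-matched), extended-haplotype spans,
#' stratum comparison tests, the tag-SNP lookup table and — when enabled —
#' the leave-one-out, frequency-matched and r-squared-binned imputation
#' experiments.
#'
#' @param config An [analysis_config()].
#' @return A `report_bundle`: a named list of tibbles/objects plus a
#'   `manifest` (config hash, seed, package version) sufficient to
#'   reproduce every table.  Written to `config$out_dir` when set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))

  truth <- NULL
  if (!is.null(config$panel)) {
    panel <- config$panel
  } else if (!is.null(config$sim)) {
    simout <- simulate_panel(config$sim)
    panel <- simout$panel
    truth <- simout$truth
  } else {
    panel <- merge_panels(read_vcf(config$vcf_indels, expect = "indels"),
                          read_vcf(config$vcf_snps, expect = "snps"))
  }
  if (!is.null(config$lof_sites)) {
    lof <- if (is.character(config$lof_sites)) read_site_list(config$lof_sites)
           else config$lof_sites
    panel <- flag_lof(panel, lof)
  }
  panel <- filter_rare_sites(panel, min_maf = config$min_indel_maf)
  if (!is.null(config$regions_bed)) {
    panel <- annotate_regions(panel, config$regions_bed)
  }
  if (!is.null(config$array_sites)) {
    arr <- if (is.character(config$array_sites)) read_site_list(config$array_sites)
           else config$array_sites
    panel <- restrict_to_sites(panel, arr, keep_indels = TRUE)
  }

  site_table <- site_class_table(panel, config$scheme)

  focal <- which(panel$sites$vclass != "SNP")
  poly <- site_table$minor_count > 0L
  focal <- focal[poly[focal]]
  set.seed(config$seed)
  if (!is.null(config$focal_sample_n) && length(focal) > config$focal_sample_n) {
    focal <- sort(sample(focal, config$focal_sample_n))
  }
  if (length(focal) == 0L) stop_indelLD("empty_panel", "No focal indels to analyze.")

  pairs <- ld_scan(panel, focal, window = config$window)
  avg_curve <- average_r2_curve(pairs)
  mm_curve <- mean_max_r2_curve(pairs)

  snp_pairs <- NULL
  class_tagging <- NULL
  if (!is.null(config$snp_control_n)) {
    snps <- which(panel$sites$vclass == "SNP" & poly)
    snps <- sort(sample(snps, min(config$snp_control_n, length(snps))))
    snp_pairs <- ld_scan(panel, snps, window = config$window)
    class_tagging <- bind_rows(
      mutate(tagging_summary(pairs, NULL, config$thresholds),
             stratum = "indel"),
      mutate(tagging_summary(snp_pairs, NULL, config$thresholds),
             stratum = "SNP"))
    class_tagging <- mutate(class_tagging, stratum_var = "class", .before = 1)
  }

  fstrata <- focal_strata_table(site_table, focal, config$strata)
  tagging <- mutate(tagging_summary(pairs, NULL, config$thresholds),
                    stratum_var = "all", .before = 1)
  for (v in setdiff(names(fstrata), "focal_index")) {
    lab <- setNames(fstrata[[v]], as.character(fstrata$focal_index))
    lab <- lab[!is.na(lab)]
    if (length(unique(lab)) == 0L) next
    tt <- tagging_summary(subset_pairs(pairs, as.integer(names(lab))),
                          lab, config$thresholds)
    tagging <- bind_rows(tagging, mutate(tt, stratum_var = v, .before = 1))
  }
  if (!is.null(class_tagging)) tagging <- bind_rows(tagging, class_tagging)

  fm_tagging <- freq_matched_tagging(panel, pairs, config$scheme)
  spans <- haplotype_span(pairs, threshold = 0.8)
  fmax <- focal_max_r2(pairs)
  lookup <- build_tag_lookup(panel, pairs, threshold = 0.8)

  bundle <- list(panel = panel, truth = truth, site_table = site_table,
                 focal_indices = focal, focal_strata = fstrata,
                 pairs = pairs, snp_pairs = snp_pairs,
                 average_r2 = avg_curve, mean_max_r2 = mm_curve,
                 tagging = tagging, freq_matched_tagging = fm_tagging,
                 spans = spans, focal_max_r2 = fmax, tag_lookup = lookup)

  if (config$run_imputation) {
    strata_lab <- setNames(as.character(site_table$maf_bin[focal]),
                           as.character(focal))
    bundle$concordance <- loo_concordance(panel, focal, strata = strata_lab,
                                          params = config$params)
    bundle$freq_matched_concordance <-
      freq_matched_concordance(panel, focal, scheme = config$scheme,
                               params = config$params)
    if (config$run_r2_bins) {
      bundle$r2_binned <- r2_binned_concordance(panel, focal,
                                                params = config$params)
    }
  }

  bundle$comparisons <- compare_strata_report(bundle)
  bundle$manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    n_samples = n_samples(panel), n_sites = n_sites(panel),
    n_focal = length(focal),
    package = "indelLD",
    version = as.character(utils::packageVersion("indelLD")))
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d focal indels, %d LD pairs, tables: %s\n",
              length(x$focal_indices), nrow(x$pairs),
              paste(setdiff(names(x), c("panel", "manifest")), collapse = ", ")))
  invisible(x)
}

#' Tag-SNP lookup table
#'
#' One row per (indel, SNP) pair in high LD (`r2 > threshold`, strict):
#' the community-lookup deliverable.  Sorted by indel position, then
#' descending r-squared.
#'
#' @param panel The scanned [hap_panel()].
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @param threshold High-LD threshold (default 0.8).
#' @return A tibble `indel_id`, `chrom`, `indel_pos`, `ref`, `alt`,
#'   `snp_id`, `snp_pos`, `r2`, `distance`; indels with no qualifying SNP
#'   are absent (count in attribute `n_untagged`).
#' @export
build_tag_lookup <- function(panel, pairs, threshold = 0.8) {
  focals <- attr(pairs, "focal_indices") %||% unique(pairs$focal_index)
  hits <- filter(pairs, r2 > threshold)
  s <- panel$sites
  out <- tibble(indel_id = hits$focal_id,
                chrom = hits$chrom,
                indel_pos = hits$focal_pos,
                ref = s$ref[hits$focal_index],
                alt = s$alt[hits$focal_index],
                snp_id = hits$partner_id,
                snp_pos = hits$partner_pos,
                r2 = hits$r2,
                distance = hits$distance)
  out <- arrange(out, chrom, indel_pos, desc(r2))
  attr(out, "n_untagged") <- length(setdiff(focals, hits$focal_index))
  out
}

#' Pairwise stratum comparison report
#'
#' Compares strata pairwise: tagging percentages with the two-proportion
#' z-test and extended-haplotype spans / per-focal max r-squared
#' distributions with the Mann-Whitney test.  No multiple-testing
#' correction is applied (flagged in the `note` attribute so readers are
#' not misled).
#'
#' @param bundle A `report_bundle` from [run_full_analysis()] (needs
#'   `tagging`, `spans`, `focal_max_r2`, `focal_strata`).
#' @return Tibble of comparisons: `stratum_var`, `quantity`, `stratum_a`,
#'   `stratum_b`, `test`, `statistic`, `p_value`.  Empty when fewer than
#'   two strata exist.
#' @export
compare_strata_report <- function(bundle) {
  rows <- list()
  tg <- bundle$tagging
  if (!is.null(tg)) {
    for (v in setdiff(unique(tg$stratum_var), "all")) {
      sub <- filter(tg, stratum_var == v, n_focal > 0)
      levs <- unique(sub$stratum)
      if (length(levs) < 2L) next
      cmb <- utils::combn(levs, 2L)
      for (j in seq_len(ncol(cmb))) {
        for (t in unique(sub$threshold)) {
          a <- filter(sub, stratum == cmb[1, j], threshold == t)
          b <- filter(sub, stratum == cmb[2, j], threshold == t)
          ht <- suppressWarnings(
            two_proportion_test(a$n_tagged, a$n_focal, b$n_tagged, b$n_focal))
          rows[[length(rows) + 1L]] <- tibble(
            stratum_var = v, quantity = sprintf("tagging_pct_r2_%g", t),
            stratum_a = cmb[1, j], stratum_b = cmb[2, j],
            test = "two_proportion", statistic = ht$statistic,
            p_value = ht$p_value)
        }
      }
    }
  }
  fs <- bundle$focal_strata
  if (!is.null(fs) && nrow(fs) > 0L) {
    numeric_tables <- list(
      haplotype_span = bundle$spans[c("focal_index", "span_bp")],
      max_r2 = bundle$focal_max_r2[c("focal_index", "max_r2")])
    for (v in setdiff(names(fs), "focal_index")) {
      lab <- setNames(fs[[v]], as.character(fs$focal_index))
      levs <- unique(lab[!is.na(lab)])
      if (length(levs) < 2L) next
      cmb <- utils::combn(levs, 2L)
      for (qn in names(numeric_tables)) {
        tab <- numeric_tables[[qn]]
        if (is.null(tab) || nrow(tab) == 0L) next
        val <- tab[[2]]
        grp <- lab[as.character(tab$focal_index)]
        for (j in seq_len(ncol(cmb))) {
          a <- val[!is.na(grp) & grp == cmb[1, j]]
          b <- val[!is.na(grp) & grp == cmb[2, j]]
          if (length(a) == 0L || length(b) == 0L) next
          ht <- mann_whitney_test(a, b)
          rows[[length(rows) + 1L]] <- tibble(
            stratum_var = v, quantity = qn,
            stratum_a = cmb[1, j], stratum_b = cmb[2, j],
            test = "mann_whitney", statistic = ht$statistic,
            p_value = ht$p_value)
        }
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(stratum_var = character(), quantity = character(),
           stratum_a = character(), stratum_b = character(),
           test = character(), statistic = double(), p_value = double())
  attr(out, "note") <- "p-values are not corrected for multiple testing"
  out
}

#' Write a report bundle to disk
#'
#' Emits every tabular component as TSV plus a JSON manifest; output is
#' deterministic for a fixed configuration, so reruns are byte-identical.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_indelLD("io_error", sprintf("Cannot create directory '%s'.", dir))
  }
  paths <- c()
  emit <- function(x, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(x), p, progress = FALSE)
    paths[[name]] <<- p
  }
  emit(bundle$site_table, "site_table")
  emit(bundle$pairs, "ld_pairs")
  emit(bundle$average_r2, "average_r2_curve")
  emit(bundle$mean_max_r2, "mean_max_r2_curve")
  emit(bundle$tagging, "tagging")
  emit(bundle$freq_matched_tagging, "freq_matched_tagging")
  emit(bundle$spans, "haplotype_spans")
  emit(bundle$tag_lookup, "tag_lookup")
  emit(bundle$comparisons, "stratum_comparisons")
  if (!is.null(bundle$truth)) emit(bundle$truth, "truth")
  if (!is.null(bundle$concordance)) {
    emit(tidy(bundle$concordance), "concordance_by_maf_bin")
  }
  if (!is.null(bundle$freq_matched_concordance)) {
    emit(glance(bundle$freq_matched_concordance), "freq_matched_concordance")
  }
  if (!is.null(bundle$r2_binned)) emit(tidy(bundle$r2_binned), "r2_binned_concordance")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest"]] <- mp
  invisible(unlist(paths))
}
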