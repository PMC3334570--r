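#' Simulation configuration for founder-mosaic haplotype panels
#'
#' Defines the study conditions of the bundled simulator: sample haplotypes
#' are recombinant mosaics of a small founder set (yielding
#' distance-decaying LD), founder allele frequencies follow a truncated
#' `f^-sfs_exponent` density (a 1/f-like site frequency spectrum), and a
#' fraction of sites is overlaid with indel alleles showing a deletion
#' excess (odds 1.25:1) and a geometric length distribution calibrated so
#' about 90% of indels are at most 6 bp.
#'
#' @param n_samples Diploid sample count (default 60, a single-population
#'   panel of typical reference size).
#' @param region_length Region length in bp (default 1e6).
#' @param n_sites Target polymorphic site count (default 1000; sites
#'   monomorphic in the sample are dropped, so this is a target, not a
#'   guarantee).
#' @param founder_count Number of founder haplotypes K >= 2 (default 20).
#' @param switch_rate_sim Per-bp founder-mosaic switch intensity (default
#'   4e-5, giving ~25 kb founder segments — the scale of measured
#'   extended haplotypes around common variants).
#' @param mutation_rate Per-entry fresh-mutation flip probability (default
#'   1e-3).
#' @param sfs_exponent Exponent of the founder-frequency density
#'   `f^-sfs_exponent` on `[f_min, 0.5]` (default 1; 0 gives a uniform
#'   density).
#' @param f_min Lower truncation of founder frequencies (default 0.025).
#' @param indel_fraction Fraction of sites overlaid as indels (default
#'   0.08, the indel:SNP ratio of large resequencing call sets).
#' @param deletion_odds Deletion:insertion odds (default 1.25).
#' @param length_geom_p Geometric parameter of `length = 1 + Geom(p)`,
#'   capped at 49 bp; the default `1 - 0.1^(1/6)` makes
#'   `P(length <= 6) = 0.9`.
#' @param lof_rate Probability that an indel inside an exon interval is
#'   labelled loss-of-function (default 0.44).
#' @param exon_bed Optional exon intervals (BED path or data frame) for LOF
#'   labelling; `NULL` disables LOF labels.
#' @param seed Mandatory integer seed; every simulator output is a pure
#'   function of this configuration.  Stage streams are derived as `seed`,
#'   `seed + 1`, `seed + 2`, `seed + 3` (founders, mosaic, indel overlay,
#'   site-list subsampling).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 60L, region_length = 1e6, n_sites = 1000L,
                       founder_count = 20L, switch_rate_sim = 4e-5,
                       mutation_rate = 1e-3, sfs_exponent = 1, f_min = 0.025,
                       indel_fraction = 0.08, deletion_odds = 1.25,
                       length_geom_p = 1 - 0.1^(1 / 6), lof_rate = 0.44,
                       exon_bed = NULL, seed) {
  if (missing(seed) || !is_count(abs(seed))) {
    stop_indelLD("config_error", "An integer `seed` is mandatory.")
  }
  if (seed > 2^31 - 10) {
    stop_indelLD("config_error", "`seed` must stay below 2^31 - 10.")
  }
  if (!is_count(n_samples) || n_samples < 2) {
    stop_indelLD("config_error", "`n_samples` must be an integer >= 2.")
  }
  if (!is_count(founder_count) || founder_count < 2) {
    stop_indelLD("config_error", "`founder_count` must be an integer >= 2.")
  }
  if (n_sites > region_length) {
    stop_indelLD("config_error", "`n_sites` cannot exceed `region_length`.")
  }
  if (!is_prob(indel_fraction)) {
    stop_indelLD("config_error", "`indel_fraction` must lie in [0, 1].")
  }
  if (!is_prob(mutation_rate) || !is_prob(lof_rate) ||
      !is_prob(length_geom_p) || length_geom_p == 0) {
    stop_indelLD("config_error", "Probabilities must lie in [0, 1] (geom p > 0).")
  }
  if (deletion_odds <= 0) {
    stop_indelLD("config_error", "`deletion_odds` must be positive.")
  }
  if (!(f_min > 0 && f_min < 0.5)) {
    stop_indelLD("config_error", "`f_min` must lie in (0, 0.5).")
  }
  structure(list(n_samples = as.integer(n_samples),
                 region_length = as.integer(region_length),
                 n_sites = as.integer(n_sites),
                 founder_count = as.integer(founder_count),
                 switch_rate_sim = switch_rate_sim,
                 mutation_rate = mutation_rate,
                 sfs_exponent = sfs_exponent, f_min = f_min,
                 indel_fraction = indel_fraction,
                 deletion_odds = deletion_odds,
                 length_geom_p = length_geom_p, lof_rate = lof_rate,
                 exon_bed = exon_bed, seed = as.integer(seed)),
            class = "sim_config")
}

# Inverse-CDF sampler for the truncated f^-a density on [f_min, 0.5].
sample_sfs_freq <- function(n, a, f_min) {
  u <- runif(n)
  if (abs(a - 1) < 1e-12) {
    exp(log(f_min) + u * log(0.5 / f_min))
  } else {
    (f_min^(1 - a) + u * (0.5^(1 - a) - f_min^(1 - a)))^(1 / (1 - a))
  }
}

#' Simulate founder haplotypes
#'
#' Draws `n_sites` positions uniformly without replacement over the region,
#' a per-site founder frequency from the truncated `f^-sfs_exponent`
#' density, and founder alleles as independent Bernoulli draws; sites that
#' come out monomorphic across founders are redrawn.
#'
#' @param config A [sim_config()].
#' @return List with `founders` (K x M binary matrix), `positions`
#'   (sorted bp) and `freq` (the drawn founder frequencies).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_sites
  k <- config$founder_count
  positions <- sort(sample.int(config$region_length, m))
  freq <- sample_sfs_freq(m, config$sfs_exponent, config$f_min)
  founders <- matrix(as.integer(runif(k * m) < rep(freq, each = k)), nrow = k)
  for (iter in seq_len(1000L)) {
    mono <- which(colSums(founders) %in% c(0L, k))
    if (!length(mono)) break
    freq[mono] <- sample_sfs_freq(length(mono), config$sfs_exponent, config$f_min)
    founders[, mono] <- as.integer(runif(k * length(mono)) <
                                     rep(freq[mono], each = k))
  }
  if (length(which(colSums(founders) %in% c(0L, k)))) {
    stop_indelLD("config_error", "Could not draw polymorphic founder sites.")
  }
  list(founders = founders, positions = positions, freq = freq)
}

#' Sample mosaic haplotypes from founders
#'
#' Each of the `2 * n_samples` haplotypes copies a uniformly chosen founder
#' and, between consecutive sites at distance `d`, switches to a uniformly
#' chosen founder with probability `1 - exp(-switch_rate_sim * d)`.  Fresh
#' mutations then flip each entry with probability `mutation_rate`.  Sites
#' monomorphic in the sample are dropped (tallied in attribute
#' `n_monomorphic_dropped`).
#'
#' @param founders Output of [simulate_founders()].
#' @param config The same [sim_config()].
#' @return A [hap_panel()] of SNP sites (chromosome `"1"`), with the
#'   surviving founder frequencies in attribute `sim_freq`.
#' @export
mosaic_sample <- function(founders, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  fo <- founders$founders
  pos <- founders$positions
  k <- nrow(fo)
  m <- ncol(fo)
  nh <- 2L * config$n_samples
  gap <- diff(pos)
  p_switch <- 1 - exp(-config$switch_rate_sim * gap)

  haps <- matrix(0L, nrow = nh, ncol = m)
  for (h in seq_len(nh)) {
    switches <- c(FALSE, runif(m - 1L) < p_switch)
    seg <- cumsum(switches) + 1L
    founder_of_seg <- sample.int(k, max(seg), replace = TRUE)
    haps[h, ] <- fo[cbind(founder_of_seg[seg], seq_len(m))]
  }
  if (config$mutation_rate > 0) {
    flip <- matrix(runif(nh * m) < config$mutation_rate, nrow = nh)
    haps <- (haps + flip) %% 2L
    storage.mode(haps) <- "integer"
  }

  # random SNP ref/alt pairs
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, m, replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  cs <- colSums(haps)
  keep <- which(cs > 0L & cs < nh)
  sites <- tibble(chrom = "1", pos = pos[keep],
                  site_id = sprintf("s%05d", keep),
                  ref = ref[keep], alt = unname(alt)[keep])
  panel <- hap_panel(sites, haps[, keep, drop = FALSE],
                     sprintf("sample%03d", seq_len(config$n_samples)))
  attr(panel, "n_monomorphic_dropped") <- m - length(keep)
  attr(panel, "sim_freq") <- founders$freq[keep]
  panel
}

#' Overlay indel alleles onto a simulated SNP panel
#'
#' Relabels a random `indel_fraction` of sites as indels: deletions with
#' probability `deletion_odds / (1 + deletion_odds)`, lengths
#' `1 + Geom(length_geom_p)` capped at 49 bp, allele strings synthesized
#' accordingly (anchor-base VCF convention).  Indels inside `exon_bed`
#' intervals are labelled LOF with probability `lof_rate`.
#'
#' @param panel A panel from [mosaic_sample()].
#' @param config The same [sim_config()].
#' @return List with the modified `panel` and a `truth` tibble
#'   (`site_id`, `pos`, `vclass`, `indel_length`, `founder_freq`,
#'   `sample_maf`, `lof`, `best_tag_id` placeholder).
#' @export
overlay_indels <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  m <- n_sites(panel)
  n_indel <- round(config$indel_fraction * m)
  idx <- sort(sample.int(m, n_indel))
  bases <- c("A", "C", "G", "T")

  if (n_indel > 0) {
    is_del <- runif(n_indel) < config$deletion_odds / (1 + config$deletion_odds)
    len <- pmin(49L, 1L + rgeom(n_indel, config$length_geom_p))
    anchor <- panel$sites$ref[idx]
    extra <- vapply(len, function(L) {
      paste(bases[sample.int(4L, L, replace = TRUE)], collapse = "")
    }, character(1))
    long_allele <- paste0(anchor, extra)
    panel$sites$ref[idx] <- ifelse(is_del, long_allele, anchor)
    panel$sites$alt[idx] <- ifelse(is_del, anchor, long_allele)
    cls <- classify_alleles(panel$sites$ref, panel$sites$alt)
    panel$sites$vclass <- cls$vclass
    panel$sites$indel_length <- cls$indel_length
  }

  lof <- rep(FALSE, m)
  if (!is.null(config$exon_bed) && n_indel > 0) {
    bed <- read_bed(config$exon_bed)
    s <- panel$sites
    exonic <- rep(FALSE, m)
    for (k in seq_len(nrow(bed))) {
      exonic <- exonic | (s$chrom == bed$chrom[k] &
                            s$pos >= bed$start[k] + 1L & s$pos <= bed$end[k])
    }
    cand <- idx[exonic[idx]]
    lof[cand] <- runif(length(cand)) < config$lof_rate
  }
  panel$sites$lof <- lof

  f <- alt_freq(panel)
  truth <- tibble(site_id = panel$sites$site_id,
                  pos = panel$sites$pos,
                  vclass = panel$sites$vclass,
                  indel_length = panel$sites$indel_length,
                  founder_freq = attr(panel, "sim_freq") %||% NA_real_,
                  sample_maf = pmin(f, 1 - f),
                  lof = lof,
                  best_tag_id = NA_character_)
  list(panel = panel, truth = truth)
}

#' Simulate a complete phased panel with indel overlay
#'
#' Convenience wrapper running [simulate_founders()], [mosaic_sample()] and
#' [overlay_indels()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `panel` ([hap_panel()]) and `truth` (tibble).
#' @export
simulate_panel <- function(config) {
  founders <- simulate_founders(config)
  panel <- mosaic_sample(founders, config)
  overlay_indels(panel, config)
}

#' Fill best-tag-SNP ids into a truth table
#'
#' @param truth Truth tibble from [overlay_indels()].
#' @param pairs An `ld_pairs` tibble from [ld_scan()].
#' @param panel The scanned panel (for index-to-id mapping).
#' @return The truth tibble with `best_tag_id` filled for focal variants
#'   that have at least one partner.
#' @export
fill_truth_tags <- function(truth, pairs, panel) {
  if (nrow(pairs) == 0L) return(truth)
  best <- summarise(group_by(pairs, focal_id),
                    best_tag_id = partner_id[which.max(r2)], .groups = "drop")
  i <- match(truth$site_id, best$focal_id)
  truth$best_tag_id <- ifelse(is.na(i), truth$best_tag_id, best$best_tag_id[i])
  truth
}

#' Insert a perfect-LD tag SNP next to every indel
#'
#' Benchmark construction for the perfect-LD limit of the imputer: for each
#' indel, a SNP with a haplotype column identical to the indel's (hence
#' r-squared exactly 1) is inserted at the nearest free position.  Used to
#' validate that leave-one-out concordance approaches 1 when a perfect tag
#' exists; it is not a model of real data.
#'
#' @param panel A [hap_panel()].
#' @return The augmented panel; new sites are named `<indel_id>_tag`.
#' @export
add_perfect_tags <- function(panel) {
  s <- panel$sites
  idx <- which(s$vclass != "SNP")
  if (!length(idx)) return(panel)
  taken <- new.env(parent = emptyenv())
  for (k in site_key(s$chrom, s$pos)) assign(k, TRUE, envir = taken)
  new_sites <- list()
  new_cols <- list()
  for (i in idx) {
    for (off in c(1L, -1L, 2L, -2L, 3L, -3L)) {
      p <- s$pos[i] + off
      if (p < 1L) next
      k <- site_key(s$chrom[i], p)
      if (!exists(k, envir = taken)) {
        assign(k, TRUE, envir = taken)
        new_sites[[length(new_sites) + 1L]] <-
          tibble(chrom = s$chrom[i], pos = p,
                 site_id = paste0(s$site_id[i], "_tag"), ref = "A", alt = "C")
        new_cols[[length(new_cols) + 1L]] <- panel$haps[, i]
        break
      }
    }
  }
  if (!length(new_sites)) return(panel)
  hap_panel(bind_rows(select(s, chrom, pos, site_id, ref, alt) |>
                        mutate(lof = s$lof, region_label = s$region_label),
                      bind_rows(new_sites)),
            cbind(panel$haps, do.call(cbind, new_cols)),
            panel$samples)
}

#' Write simulator outputs
#'
#' Emits the merged panel as a phased VCF, separate indel-only and SNP-only
#' VCFs (to exercise [merge_panels()]), the truth table as TSV, and
#' optionally a seeded random subsample of SNP positions emulating a sparse
#' array panel.
#'
#' @param panel A [hap_panel()].
#' @param truth Truth tibble (or `NULL`).
#' @param dir Output directory (created if needed).
#' @param sitelist_fraction Optional fraction of SNP sites for the array
#'   emulation site list.
#' @param seed Seed for the site-list subsample (defaults to the
#'   convention `config seed + 3`; required if `sitelist_fraction` given).
#' @return Named list of written paths, invisibly.
#' @export
write_sim_outputs <- function(panel, truth, dir, sitelist_fraction = NULL,
                              seed = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_indelLD("io_error", sprintf("Cannot create directory '%s'.", dir))
  }
  paths <- list(merged = file.path(dir, "panel.vcf"),
                indels = file.path(dir, "indels.vcf"),
                snps = file.path(dir, "snps.vcf"),
                truth = file.path(dir, "truth.tsv"))
  write_vcf(panel, paths$merged)
  is_snp <- panel$sites$vclass == "SNP"
  if (any(!is_snp)) write_vcf(subset_sites(panel, which(!is_snp)), paths$indels)
  if (any(is_snp)) write_vcf(subset_sites(panel, which(is_snp)), paths$snps)
  if (!is.null(truth)) readr::write_tsv(truth, paths$truth, progress = FALSE)
  if (!is.null(sitelist_fraction)) {
    if (is.null(seed)) {
      stop_indelLD("config_error", "Site-list subsampling needs a `seed`.")
    }
    set.seed(seed)
    snp_sites <- panel$sites[is_snp, c("chrom", "pos")]
    keep <- runif(nrow(snp_sites)) < sitelist_fraction
    paths$sitelist <- file.path(dir, "array_sites.tsv")
    write_site_list(snp_sites[keep, , drop = FALSE], paths$sitelist)
  }
  invisible(paths)
}
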