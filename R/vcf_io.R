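#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF v4.x file with fully phased `GT` fields into a
#' [hap_panel()].  Only bi-allelic SNPs and short indels (< 50 bp) enter the
#' panel: multi-allelic records, equal-length multi-base (MNP) records and
#' indels of 50 bp or longer are dropped and counted in the `dropped`
#' attribute of the result.  Position collisions between an indel and a SNP
#' inside one file are resolved by keeping the indel (see [merge_panels()]).
#'
#' @param path Path to a VCF v4.x file (plain text).
#' @param expect One of `"mixed"` (default), `"snps"`, `"indels"`.  With
#'   `"snps"`/`"indels"` the reader asserts that every retained record is of
#'   that class and raises an `indelLD_class_error` otherwise.
#'
#' @return A [hap_panel()] with attribute `dropped`, a named integer vector
#'   counting `multiallelic`, `mnp`, `long_indel` and `pos_collision_snp`
#'   records removed during reading.
#'
#' @details Missing or unphased genotypes (`./.`, `0/1`, ...) are a hard
#'   error (`indelLD_missing_or_unphased_genotype`): the panels this package
#'   models are complete phased call sets, and silently imputing or dropping
#'   entries would bias every downstream statistic.  Symbolic or non-ACGT
#'   alleles raise `indelLD_unsupported_allele`.
#' @export
read_vcf <- function(path, expect = c("mixed", "snps", "indels")) {
  expect <- match.arg(expect)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(fix) || nrow(fix) == 0L) {
    stop_indelLD("empty_panel", sprintf("No records in VCF '%s'.", path))
  }
  samples <- colnames(gt)[-1]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  dropped <- c(multiallelic = 0L, mnp = 0L, long_indel = 0L, pos_collision_snp = 0L)

  multi <- grepl(",", alt, fixed = TRUE)
  dropped[["multiallelic"]] <- sum(multi)
  keep <- !multi

  bad <- keep & (!grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt))
  if (any(bad)) {
    i <- which(bad)[1]
    stop_indelLD("unsupported_allele",
                 sprintf("Unsupported allele at %s:%d (ref '%s', alt '%s').",
                         chrom[i], pos[i], ref[i], alt[i]))
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  mnp <- keep & lr == la & lr > 1L
  dropped[["mnp"]] <- sum(mnp)
  keep <- keep & !mnp
  long <- keep & abs(lr - la) >= 50L
  dropped[["long_indel"]] <- sum(long)
  keep <- keep & !long

  idx <- which(keep)
  if (length(idx) == 0L) {
    stop_indelLD("empty_panel", sprintf("No usable bi-allelic records in '%s'.", path))
  }

  # First GT subfield per record x sample; must be a phased bi-allelic call.
  gtf <- gt[idx, -1, drop = FALSE]
  gtf[] <- sub(":.*$", "", gtf)
  ok <- matrix(gtf %in% c("0|0", "0|1", "1|0", "1|1"), nrow = nrow(gtf))
  if (!all(ok)) {
    bad1 <- which(!ok, arr.ind = TRUE)[1, ]
    stop_indelLD("missing_or_unphased_genotype",
                 sprintf("Missing or unphased genotype '%s' at %s:%d (sample %s).",
                         gtf[bad1[1], bad1[2]], chrom[idx][bad1[1]],
                         pos[idx][bad1[1]], samples[bad1[2]]))
  }
  a1 <- matrix(as.integer(substring(gtf, 1L, 1L)), nrow = length(idx))
  a2 <- matrix(as.integer(substring(gtf, 3L, 3L)), nrow = length(idx))
  # hap rows ordered sample1_hap1, sample1_hap2, sample2_hap1, ...
  haps <- matrix(0L, nrow = 2L * length(samples), ncol = length(idx))
  haps[seq(1L, by = 2L, length.out = length(samples)), ] <- t(a1)
  haps[seq(2L, by = 2L, length.out = length(samples)), ] <- t(a2)

  site_id <- ifelse(is.na(id[idx]) | id[idx] == ".",
                    paste0(chrom[idx], "_", pos[idx]), id[idx])
  sites <- tibble(chrom = chrom[idx], pos = pos[idx], site_id = site_id,
                  ref = ref[idx], alt = alt[idx])

  # Resolve in-file indel/SNP position collisions: the indel is retained.
  cls <- classify_alleles(sites$ref, sites$alt)
  key <- site_key(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    coll <- split(seq_len(nrow(sites)), key)
    drop_cols <- integer(0)
    for (grp in coll[lengths(coll) > 1L]) {
      is_snp <- cls$vclass[grp] == "SNP"
      if (sum(!is_snp) == 1L && sum(is_snp) >= 1L) {
        drop_cols <- c(drop_cols, grp[is_snp])
      } else {
        stop_indelLD("duplicate_site",
                     sprintf("Unresolvable position collision at %s.", key[grp[1]]))
      }
    }
    dropped[["pos_collision_snp"]] <- length(drop_cols)
    sites <- sites[-drop_cols, , drop = FALSE]
    haps <- haps[, -drop_cols, drop = FALSE]
    cls$vclass <- cls$vclass[-drop_cols]
  }

  panel <- hap_panel(sites, haps, samples)
  if (expect == "snps" && any(panel$sites$vclass != "SNP")) {
    stop_indelLD("class_error", "Expected a SNP-only VCF but found indel records.")
  }
  if (expect == "indels" && any(panel$sites$vclass == "SNP")) {
    stop_indelLD("class_error", "Expected an indel-only VCF but found SNP records.")
  }
  attr(panel, "dropped") <- dropped
  panel
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a deterministic plain-text VCF v4.2 with phased `GT` fields, sites
#' in `(chrom, pos)` order.  The inverse of [read_vcf()] for all fields a
#' VCF can carry (LOF flags and region labels are side-channel annotations,
#' not VCF columns).
#'
#' @param panel A [hap_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  s <- panel$sites
  h <- panel$haps
  ns <- length(panel$samples)
  g1 <- h[seq(1L, by = 2L, length.out = ns), , drop = FALSE]
  g2 <- h[seq(2L, by = 2L, length.out = ns), , drop = FALSE]
  gt <- matrix(paste0(t(g1), "|", t(g2)), nrow = nrow(s))
  body <- paste(s$chrom, s$pos, s$site_id, s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=indelLD",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read / write a two-column site list
#'
#' Site lists (`chrom`, `pos` TSV) emulate sparse genotyping-array panels
#' (OMNI/HapMap-style site subsets) and carry predicted LOF site lists.
#'
#' @param path TSV path.  A `chrom<TAB>pos` header is written by
#'   [write_site_list()] and tolerated (or absent) on read.
#' @return A tibble with columns `chrom` (character) and `pos` (integer);
#'   duplicate keys are removed with a warning.
#' @export
read_site_list <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^chrom\\b", first)
  x <- readr::read_tsv(path, col_names = c("chrom", "pos"),
                       skip = if (has_header) 1L else 0L,
                       col_types = readr::cols(chrom = readr::col_character(),
                                               pos = readr::col_integer()),
                       progress = FALSE)
  if (anyNA(x$pos)) stop_indelLD("parse_error", sprintf("Malformed site list '%s'.", path))
  dup <- duplicated(site_key(x$chrom, x$pos))
  if (any(dup)) {
    warn_indelLD("duplicate_site", sprintf("%d duplicate site-list keys removed.", sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  x
}

#' @rdname read_site_list
#' @param sites A data frame with `chrom` and `pos` columns.
#' @export
write_site_list <- function(sites, path) {
  sites <- arrange(as_tibble(sites)[c("chrom", "pos")], chrom, pos)
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

#' Merge an indel panel and a SNP panel
#'
#' Combines two panels over the same samples into one ordered panel.  When
#' an indel and a SNP share a position the indel is retained and the SNP
#' discarded (counted in attribute `discarded_snps`); two sites of the same
#' class at one position are an error (`indelLD_duplicate_site`).
#'
#' @param indel_panel,snp_panel [hap_panel()] objects with identical
#'   `samples` in identical order.
#' @return Merged [hap_panel()] sorted by `(chrom, pos)`, with attribute
#'   `discarded_snps`.
#' @export
merge_panels <- function(indel_panel, snp_panel) {
  if (!identical(indel_panel$samples, snp_panel$samples)) {
    stop_indelLD("sample_mismatch",
                 "Panels must carry identical samples in identical order.")
  }
  sites <- bind_rows(indel_panel$sites, snp_panel$sites)
  haps <- cbind(indel_panel$haps, snp_panel$haps)

  key <- site_key(sites$chrom, sites$pos)
  drop_cols <- integer(0)
  if (anyDuplicated(key)) {
    for (grp in split(seq_len(nrow(sites)), key)) {
      if (length(grp) == 1L) next
      is_snp <- sites$vclass[grp] == "SNP"
      if (sum(!is_snp) == 1L && sum(is_snp) == 1L) {
        drop_cols <- c(drop_cols, grp[is_snp])
      } else {
        stop_indelLD("duplicate_site",
                     sprintf("Two %s records share position %s.",
                             if (all(!is_snp)) "indel" else "SNP", key[grp[1]]))
      }
    }
  }
  if (length(drop_cols)) {
    sites <- sites[-drop_cols, , drop = FALSE]
    haps <- haps[, -drop_cols, drop = FALSE]
  }
  out <- hap_panel(sites, haps, indel_panel$samples)
  attr(out, "discarded_snps") <- length(drop_cols)
  out
}

#' Restrict a panel to an array-like site list
#'
#' Emulates genotyping-array panels: SNPs are kept only if present in the
#' site list; focal indels can be retained regardless so that array
#' emulation does not delete the variants under study.
#'
#' @param panel A [hap_panel()].
#' @param sites A site list from [read_site_list()] (or any data frame with
#'   `chrom`, `pos`).
#' @param keep_indels Keep indel sites irrespective of the list (default
#'   `TRUE`).
#' @return Restricted [hap_panel()]; empty results raise
#'   `indelLD_empty_panel`.
#' @export
restrict_to_sites <- function(panel, sites, keep_indels = TRUE) {
  keys <- site_key(sites$chrom, sites$pos)
  s <- panel$sites
  in_list <- site_key(s$chrom, s$pos) %in% keys
  keep <- in_list | (keep_indels & s$vclass != "SNP")
  if (!any(keep)) {
    stop_indelLD("empty_panel", "No panel sites remain after site-list restriction.")
  }
  subset_sites(panel, which(keep))
}

#' Flag predicted loss-of-function indels
#'
#' Sets `lof = TRUE` for exactly the indel sites whose `(chrom, pos)` key
#' appears in the LOF site list.  SNPs are never flagged; a list entry that
#' matches only a SNP position triggers a warning
#' (`indelLD_lof_snp_collision`) and no flag.
#'
#' @param panel A [hap_panel()].
#' @param lof_sites Site list of predicted LOF indel positions.
#' @return The panel with its `lof` column updated.
#' @export
flag_lof <- function(panel, lof_sites) {
  keys <- site_key(lof_sites$chrom, lof_sites$pos)
  s <- panel$sites
  pk <- site_key(s$chrom, s$pos)
  hit <- pk %in% keys
  snp_only <- setdiff(keys[keys %in% pk[s$vclass == "SNP"]],
                      pk[s$vclass != "SNP"])
  if (length(snp_only)) {
    warn_indelLD("lof_snp_collision",
                 sprintf("%d LOF list entr%s matched SNP-only positions; not flagged.",
                         length(snp_only), if (length(snp_only) == 1L) "y" else "ies"))
  }
  panel$sites$lof <- hit & s$vclass != "SNP"
  panel
}
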