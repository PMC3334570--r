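test_that("the simulator is a pure function of its configuration", {
  cfg <- sim_config(seed = 5L, n_sites = 150L, region_length = 2e5L,
                    n_samples = 10L)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_same_panel(a$panel, b$panel)
  expect_equal(a$truth, b$truth)

  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1, f2)

  # a different seed changes the output
  c2 <- simulate_panel(sim_config(seed = 6L, n_sites = 150L,
                                  region_length = 2e5L, n_samples = 10L))
  expect_false(identical(a$panel$haps, c2$panel$haps))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_sites = 100L, region_length = 50L, seed = 1L),
               class = "indelLD_config_error")
  expect_error(sim_config(founder_count = 1L, seed = 1L),
               class = "indelLD_config_error")
  expect_error(sim_config(seed = 1L, indel_fraction = 1.2),
               class = "indelLD_config_error")
  expect_error(sim_config(), class = "indelLD_config_error")  # seed mandatory
})

test_that("founder frequencies follow the truncated SFS density", {
  cfg1 <- sim_config(seed = 8L, n_sites = 4000L, region_length = 1e5L,
                     sfs_exponent = 0)
  f0 <- simulate_founders(cfg1)
  expect_true(all(f0$freq >= cfg1$f_min & f0$freq <= 0.5))
  # exponent 0 draws from the uniform density on [f_min, 0.5]; retained
  # frequencies are conditioned on founder polymorphism, so compare to the
  # conditional mean under that uniform density (numeric-integration oracle)
  k <- cfg1$founder_count
  w <- function(f) 1 - (1 - f)^k - f^k
  cond_mean <- integrate(function(f) f * w(f), cfg1$f_min, 0.5)$value /
    integrate(w, cfg1$f_min, 0.5)$value
  expect_lt(abs(mean(f0$freq) - cond_mean), 0.01)

  cfg2 <- sim_config(seed = 8L, n_sites = 4000L, region_length = 1e5L,
                     sfs_exponent = 1.5)
  f1 <- simulate_founders(cfg2)
  # steeper exponents shift mass toward rare founder alleles
  expect_lt(mean(f1$freq), mean(f0$freq))
  # no founder column is monomorphic
  expect_true(all(colSums(f0$founders) %in% 1:(cfg1$founder_count - 1)))
})

test_that("low-frequency fraction responds monotonically to the SFS exponent", {
  frac_low <- function(a) {
    cfg <- sim_config(seed = 33L, n_sites = 600L, region_length = 1e6L,
                      sfs_exponent = a)
    p <- simulate_panel(cfg)$panel
    st <- site_frequencies(p)
    mean(st$maf >= 0.01 & st$maf < 0.05)
  }
  expect_lt(frac_low(0), frac_low(2))
})

test_that("the no-switch no-mutation limit copies founders exactly", {
  cfg <- sim_config(seed = 12L, n_sites = 80L, region_length = 1e5L,
                    n_samples = 8L, switch_rate_sim = 0, mutation_rate = 0)
  fo <- simulate_founders(cfg)
  p <- mosaic_sample(fo, cfg)
  kept <- match(p$sites$pos, fo$positions)
  for (h in seq_len(nrow(p$haps))) {
    matches <- apply(fo$founders[, kept, drop = FALSE], 1,
                     function(f) all(f == p$haps[h, ]))
    expect_true(any(matches))
  }
})

test_that("indel overlay honours fraction, classes and length cap", {
  cfg0 <- sim_config(seed = 19L, n_sites = 200L, region_length = 2e5L,
                     n_samples = 10L, indel_fraction = 0)
  out0 <- simulate_panel(cfg0)
  expect_true(all(out0$panel$sites$vclass == "SNP"))

  cfg1 <- sim_config(seed = 19L, n_sites = 400L, region_length = 2e5L,
                     n_samples = 10L, indel_fraction = 0.5)
  out1 <- simulate_panel(cfg1)
  s <- out1$panel$sites
  n_ind <- sum(s$vclass != "SNP")
  expect_equal(n_ind, round(0.5 * n_sites(out1$panel)))
  expect_true(all(s$indel_length[s$vclass != "SNP"] >= 1L))
  expect_true(all(s$indel_length < 50L))
  # truth table mirrors the emitted sites
  expect_equal(out1$truth$vclass, s$vclass)
  expect_equal(out1$truth$site_id, s$site_id)
  expect_equal(out1$truth$sample_maf,
               site_frequencies(out1$panel)$maf, tolerance = 1e-12)
})

test_that("LOF labels arise only inside exon intervals", {
  bed <- tibble::tibble(chrom = "1", start = 0L, end = 50000L, label = "exonic")
  cfg <- sim_config(seed = 27L, n_sites = 500L, region_length = 2e5L,
                    n_samples = 10L, indel_fraction = 0.4, lof_rate = 0.9,
                    exon_bed = bed)
  out <- simulate_panel(cfg)
  s <- out$panel$sites
  expect_true(any(s$lof))
  expect_true(all(s$pos[s$lof] <= 50000L))
  expect_true(all(s$vclass[s$lof] != "SNP"))
})

test_that("simulated panels show LD decaying with distance", {
  drops <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 400L + s, n_sites = 120L, region_length = 2e5L,
                      n_samples = 20L, indel_fraction = 0.15)
    p <- simulate_panel(cfg)$panel
    focal <- which(p$sites$vclass != "SNP")
    pr <- ld_scan(p, focal, window = 1e5)
    near <- mean(pr$r2[pr$distance <= 2e4])
    far <- mean(pr$r2[pr$distance > 8e4])
    near - far
  }, numeric(1))
  expect_gt(mean(drops, na.rm = TRUE), 0)
})

test_that("write_sim_outputs round-trips panels and partitions by class", {
  cfg <- sim_config(seed = 15L, n_sites = 120L, region_length = 1e5L,
                    n_samples = 8L, indel_fraction = 0.2)
  out <- simulate_panel(cfg)
  dir <- file.path(tempdir(), "simout")
  paths <- write_sim_outputs(out$panel, out$truth, dir,
                             sitelist_fraction = 0.3, seed = cfg$seed + 3L)
  expect_same_panel(read_vcf(paths$merged), out$panel)
  merged_again <- merge_panels(read_vcf(paths$indels, expect = "indels"),
                               read_vcf(paths$snps, expect = "snps"))
  expect_same_panel(merged_again, out$panel)

  sl <- read_site_list(paths$sitelist)
  n_snp <- sum(out$panel$sites$vclass == "SNP")
  expect_true(abs(nrow(sl) - 0.3 * n_snp) < 4 * sqrt(n_snp * 0.3 * 0.7) + 1)
  restricted <- restrict_to_sites(out$panel, sl, keep_indels = TRUE)
  expect_true(all(out$panel$sites$vclass[out$panel$sites$vclass != "SNP"] %in%
                    restricted$sites$vclass))
})

test_that("add_perfect_tags gives every indel an r2 = 1 partner nearby", {
  cfg <- sim_config(seed = 44L, n_sites = 150L, region_length = 1e5L,
                    n_samples = 10L, indel_fraction = 0.2)
  p <- simulate_panel(cfg)$panel
  p2 <- add_perfect_tags(p)
  idx <- which(p2$sites$vclass != "SNP")
  pr <- ld_scan(p2, idx, window = 100)
  mx <- focal_max_r2(pr)
  expect_true(all(mx$max_r2 >= 1 - 1e-9))
})
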