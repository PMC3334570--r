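test_that("pairwise r2 reproduces hand-derived haplotype-table values", {
  # identical columns: perfect LD
  p1 <- make_panel(cbind(c(0, 0, 1, 1), c(0, 0, 1, 1)))
  expect_equal(pairwise_r2(p1, 1, 2), 1, tolerance = 1e-12)

  # label swap at one site leaves r2 = 1
  p2 <- make_panel(cbind(c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_equal(pairwise_r2(p2, 1, 2), 1, tolerance = 1e-12)

  # worked 6-haplotype example: p = 1/3, q = 1/6, p11 = 1/6, D = 1/9
  p3 <- make_panel(cbind(c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)))
  expect_equal(pairwise_r2(p3, 1, 2), 0.4, tolerance = 1e-12)

  mono <- make_panel(cbind(c(0, 0, 0, 0), c(0, 1, 0, 1)))
  expect_error(pairwise_r2(mono, 1, 2), class = "indelLD_monomorphic_site")
  expect_error(pairwise_r2(p3, 1, 9), class = "indelLD_index_error")
})

test_that("pairwise r2 is symmetric and allele-label invariant", {
  set.seed(11)
  for (k in 1:50) {
    nh <- 2 * sample(2:6, 1)
    repeat {
      h <- matrix(rbinom(nh * 2, 1, runif(1, 0.2, 0.8)), nh)
      if (all(colMeans(h) > 0 & colMeans(h) < 1)) break
    }
    p <- make_panel(h)
    r <- pairwise_r2(p, 1, 2)
    expect_equal(r, pairwise_r2(p, 2, 1), tolerance = 1e-12)
    expect_equal(r, pairwise_r2(make_panel(cbind(1 - h[, 1], h[, 2])), 1, 2),
                 tolerance = 1e-9)
    expect_equal(r, oracle_r2(h[, 1], h[, 2]), tolerance = 1e-12)
    expect_gte(r, 0)
    expect_lte(r, 1 + 1e-12)
  }
})

test_that("ld_scan respects the window and skips monomorphic partners", {
  haps <- cbind(c(0, 1, 1, 0),        # SNP at 150000 (in window)
                c(0, 1, 0, 1),        # focal indel at 200000
                c(0, 0, 0, 0),        # monomorphic SNP at 210000
                c(1, 1, 0, 0),        # SNP at 299999 (in window)
                c(0, 1, 1, 1))        # SNP at 350000 (distance 150000: out)
  p <- make_panel(haps,
                  positions = c(150000L, 200000L, 210000L, 299999L, 350000L),
                  ref = c("A", "AT", "A", "A", "A"),
                  alt = c("C", "A", "C", "C", "C"))
  pr <- ld_scan(p, focal = 2L, window = 1e5)
  expect_equal(sort(pr$partner_pos), c(150000L, 299999L))
  expect_equal(attr(pr, "n_monomorphic_partner"), 1L)
  expect_equal(nrow(pr), 2L)
  expect_true(all(pr$distance <= 1e5))

  # monomorphic focal is dropped with a tally
  pr2 <- ld_scan(p, focal = c(2L, 3L), window = 1e5)
  expect_equal(attr(pr2, "n_monomorphic_focal"), 1L)
  expect_equal(attr(pr2, "focal_indices"), 2L)
})

test_that("average r2 curve bins distances and averages within bins", {
  haps <- matrix(rbinom(8 * 4, 1, 0.5), 8)
  p <- make_panel(haps, positions = c(1000L, 1050L, 1090L, 2000L),
                  ref = c("AT", "A", "A", "A"), alt = c("A", "C", "C", "C"))
  pr <- ld_scan(p, focal = 1L)
  cv <- average_r2_curve(pr, bin_width = 100)
  # distances 50, 90 -> bin 0; distance 1000 -> bin 9
  expect_equal(cv$n[1], 2L)
  expect_equal(cv$value[1], mean(pr$r2[pr$distance <= 100]), tolerance = 1e-12)
  expect_equal(cv$n[10], 1L)
  expect_equal(cv$value[10], pr$r2[pr$distance == 1000], tolerance = 1e-12)
  # interior empty bins are emitted with n = 0 and NA value
  expect_true(all(cv$n[2:9] == 0L))
  expect_true(all(is.na(cv$value[2:9])))
  expect_error(average_r2_curve(pr, bin_width = 0), class = "indelLD_domain_error")
})

test_that("mean max r2 curve averages per-focal maxima", {
  # two focal indels, partners in one 1 kb bin with known r2 values
  pairs <- tibble::tibble(
    focal_index = c(1L, 1L, 2L),
    focal_id = c("i1", "i1", "i2"),
    focal_pos = c(10000L, 10000L, 50000L),
    partner_index = c(3L, 4L, 5L),
    partner_id = c("s1", "s2", "s3"),
    partner_pos = c(10400L, 10900L, 50700L),
    chrom = "1",
    distance = c(400L, 900L, 700L),
    r2 = c(0.3, 0.9, 0.4))
  attr(pairs, "focal_indices") <- c(1L, 2L)
  cv <- mean_max_r2_curve(pairs, bin_width = 1000)
  # focal 1 max = 0.9, focal 2 max = 0.4 -> mean 0.65, n = 2 focals
  expect_equal(cv$value[1], 0.65, tolerance = 1e-12)
  expect_equal(cv$n[1], 2L)
})

test_that("tagging thresholds are strict below 1 and exact at 1", {
  mk_pairs <- function(r2s) {
    pr <- tibble::tibble(focal_index = 1L, focal_id = "i1", focal_pos = 1000L,
                         partner_index = seq_along(r2s) + 1L,
                         partner_id = paste0("s", seq_along(r2s)),
                         partner_pos = 2000L + seq_along(r2s),
                         chrom = "1", distance = 1000L, r2 = r2s)
    attr(pr, "focal_indices") <- 1L
    pr
  }
  tg <- tagging_summary(mk_pairs(c(0.85, 0.2)))
  expect_equal(tg$percent, c(100, 100, 0))    # counted at 0.5 and 0.8, not 1
  tg2 <- tagging_summary(mk_pairs(c(0.5, 0.8)))
  expect_equal(tg2$percent, c(100, 0, 0))     # strict: 0.8 > 0.5 but not > 0.8
  tg3 <- tagging_summary(mk_pairs(1))
  expect_equal(tg3$percent, c(100, 100, 100))
})

test_that("tagging percentages are monotone in threshold and count no-pair focals", {
  set.seed(5)
  haps <- matrix(rbinom(40 * 30, 1, 0.4), 40)
  refs <- c(rep("AT", 5), rep("A", 25))
  alts <- c(rep("A", 5), rep("C", 25))
  p <- make_panel(haps, positions = sort(sample.int(5e4, 30)),
                  ref = refs, alt = alts)
  pr <- ld_scan(p, focal = 1:5, window = 2e4)
  tg <- tagging_summary(pr)
  expect_equal(tg$n_focal, rep(length(attr(pr, "focal_indices")), 3))
  pct <- tg$percent[order(tg$threshold)]
  expect_true(all(diff(pct) <= 1e-12))

  # duplicated column registers as perfect LD despite floating point
  h2 <- cbind(c(0, 1, 1, 0, 1, 0), c(0, 1, 1, 0, 1, 0))
  p2 <- make_panel(h2, ref = c("AT", "A"), alt = c("A", "C"))
  pr2 <- ld_scan(p2, focal = 1L)
  tg2 <- tagging_summary(pr2)
  expect_equal(tg2$percent[tg2$threshold == 1], 100)
})

test_that("frequency-matched tagging cross-tabulates focal and partner bins", {
  nh <- 120L
  low_pat <- c(rep(1L, 3), rep(0L, nh - 3))             # MAF 0.025 (low)
  com_pat <- rep(c(1L, 0L), nh / 2)                      # MAF 0.5 (common)
  com_off <- c(rep(1L, 30), rep(0L, nh - 30))            # MAF 0.25, unrelated
  haps <- cbind(low_pat, low_pat, com_pat, com_pat, com_off)
  p <- make_panel(haps, positions = c(1000L, 1500L, 3000L, 3500L, 4000L),
                  ref = c("AT", "A", "AGG", "A", "A"),
                  alt = c("A", "C", "A", "C", "C"))
  pr <- ld_scan(p, focal = c(1L, 3L), window = 1e5)
  fm <- freq_matched_tagging(p, pr)
  get <- function(fb, pb) fm$percent[fm$focal_bin == fb & fm$partner_bin == pb]
  expect_equal(get("low", "low"), 100)       # low indel tagged by its low twin
  expect_equal(get("low", "common"), 0)
  expect_equal(get("common", "common"), 100)
  expect_equal(get("common", "low"), 0)
})

test_that("haplotype span is the extent of the high-LD partner set", {
  pairs <- tibble::tibble(
    focal_index = c(1L, 1L, 1L, 2L),
    focal_id = c("i1", "i1", "i1", "i2"),
    focal_pos = c(20000L, 20000L, 20000L, 70000L),
    partner_index = 3:6,
    partner_id = paste0("s", 1:4),
    partner_pos = c(25000L, 10500L, 30700L, 70100L),
    chrom = "1",
    distance = c(5000L, 9500L, 10700L, 100L),
    r2 = c(0.9, 0.85, 0.95, 0.1))
  attr(pairs, "focal_indices") <- c(1L, 2L)
  one <- haplotype_span(pairs, focal = 1L)
  expect_equal(one$span_bp, 30700 - 10500)
  expect_error(haplotype_span(pairs, focal = 2L),
               class = "indelLD_no_high_ld_partner")
  all_sp <- haplotype_span(pairs)
  expect_equal(nrow(all_sp), 1L)
  expect_equal(attr(all_sp, "n_no_partner"), 1L)

  # single qualifying partner: span is the focal-partner distance
  single <- tibble::tibble(focal_index = 1L, focal_id = "i1",
                           focal_pos = 20000L, partner_index = 2L,
                           partner_id = "s1", partner_pos = 25000L,
                           chrom = "1", distance = 5000L, r2 = 0.99)
  attr(single, "focal_indices") <- 1L
  expect_equal(haplotype_span(single)$span_bp, 5000)
})
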