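test_that("copying posteriors are uniform over identical references and normalized", {
  ref <- matrix(1L, nrow = 4, ncol = 3)
  w <- copying_posteriors(c(1L, 1L, 1L), ref, c(100, 200, 300), 150)
  expect_equal(w, rep(0.25, 4), tolerance = 1e-12)

  set.seed(3)
  for (k in 1:20) {
    H <- sample(2:6, 1); S <- sample(1:5, 1)
    ref <- matrix(rbinom(H * S, 1, 0.5), H)
    tgt <- rbinom(S, 1, 0.5)
    pos <- sort(sample.int(1e5, S))
    w <- copying_posteriors(tgt, ref, pos, sample.int(1e5, 1),
                            copying_params(switch_rate = 1e-4))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= 0))
  }
})

test_that("copying posteriors match exhaustive path enumeration on small instances", {
  set.seed(21)
  for (k in 1:25) {
    H <- sample(2:4, 1); S <- sample(1:4, 1)
    ref <- matrix(rbinom(H * S, 1, 0.5), H)
    tgt <- rbinom(S, 1, 0.5)
    pos <- sort(sample.int(5e4, S))
    lambda <- runif(1, 1e-6, 2e-4)
    eps <- runif(1, 0.001, 0.4)
    qpos <- runif(1, 0, 5e4)
    w <- copying_posteriors(tgt, ref, pos, qpos,
                            copying_params(switch_rate = lambda,
                                           emission_error = eps))
    expect_equal(w, oracle_copying_posterior(ref, tgt, pos, qpos, lambda, eps),
                 tolerance = 1e-9)
  }
})

test_that("copying posteriors reject empty panels and empty context", {
  expect_error(copying_posteriors(integer(0), matrix(0L, 2, 0), numeric(0), 5),
               class = "indelLD_no_context")
  expect_error(copying_posteriors(c(1L), matrix(0L, 0, 1), c(100), 5),
               class = "indelLD_empty_reference_panel")
})

# A deterministic panel in which every indel has an exact duplicate SNP
# column adjacent to it, plus unrelated SNP noise.
tagged_fixture <- function(seed = 4, n_samples = 12) {
  set.seed(seed)
  nh <- 2 * n_samples
  indel <- rbinom(nh, 1, 0.4)
  while (length(unique(indel)) < 2) indel <- rbinom(nh, 1, 0.4)
  noise <- matrix(rbinom(nh * 6, 1, 0.5), nh)
  haps <- cbind(noise[, 1:3], indel, indel, noise[, 4:6])
  make_panel(haps,
             positions = c(1000L, 2000L, 3000L, 5000L, 5001L, 7000L, 8000L, 9000L),
             ref = c("A", "A", "A", "AT", "A", "A", "A", "A"),
             alt = c("C", "C", "C", "A", "C", "C", "C", "C"))
}

test_that("a perfect-LD tag SNP drives the hard call to the true genotype", {
  p <- tagged_fixture()
  truth <- site_genotypes(p, 4)
  params <- copying_params(emission_error = 0.001)
  for (i in seq_len(n_samples(p))) {
    g <- impute_indel_genotype(p, i, 4L, params)
    expect_equal(as.integer(g$hard_call) - 1L, truth[i])
    expect_equal(g$p_refref + g$p_refalt + g$p_altalt, 1, tolerance = 1e-9)
  }
})

test_that("an all-reference panel after leave-out yields p_refref = 1", {
  set.seed(6)
  nh <- 8
  indel <- c(1L, 1L, rep(0L, nh - 2))          # only sample 1 carries alt
  haps <- cbind(matrix(rbinom(nh * 3, 1, 0.5), nh), indel)
  p <- make_panel(haps, positions = c(100L, 200L, 300L, 400L),
                  ref = c("A", "A", "A", "AT"), alt = c("C", "C", "C", "A"))
  g <- impute_indel_genotype(p, 1, 4L)
  expect_equal(g$p_refref, 1)
  expect_equal(as.character(g$hard_call), "refref")
})

test_that("swapping the focal allele encoding swaps p_refref and p_altalt", {
  p <- tagged_fixture(seed = 9)
  flipped <- p
  flipped$haps[, 4] <- 1L - flipped$haps[, 4]
  r <- flipped$sites$ref[4]
  flipped$sites$ref[4] <- flipped$sites$alt[4]
  flipped$sites$alt[4] <- r
  for (i in c(1L, 5L, 9L)) {
    a <- impute_indel_genotype(p, i, 4L)
    b <- impute_indel_genotype(flipped, i, 4L)
    expect_lt(abs(a$p_refref - b$p_altalt), 1e-12)
    expect_lt(abs(a$p_altalt - b$p_refref), 1e-12)
    expect_lt(abs(a$p_refalt - b$p_refalt), 1e-12)
  }
})

test_that("leave-one-out table row sums equal evaluated true class counts", {
  p <- tagged_fixture(seed = 14, n_samples = 15)
  ct <- loo_concordance(p, 4L)
  truth <- site_genotypes(p, 4)
  # samples whose removal leaves the indel polymorphic
  nh <- nrow(p$haps)
  evaluable <- vapply(seq_len(n_samples(p)), function(i) {
    rest <- p$haps[-c(2 * i - 1, 2 * i), 4]
    length(unique(rest)) > 1
  }, logical(1))
  expect_equal(unname(rowSums(ct$counts)),
               as.vector(table(factor(truth[evaluable], levels = 0:2))))
  expect_equal(ct$n, sum(evaluable))
  expect_equal(ct$overall,
               sum(diag(ct$counts)) / sum(ct$counts), tolerance = 1e-12)
})

test_that("including the unmasked focal column gives perfect concordance", {
  p <- tagged_fixture(seed = 23, n_samples = 10)
  ct <- loo_concordance(p, 4L, include_focal = TRUE,
                        params = copying_params(emission_error = 0.001))
  expect_equal(ct$overall, 1)
  expect_true(all(ct$counts[upper.tri(ct$counts)] == 0))
  expect_true(all(ct$counts[lower.tri(ct$counts)] == 0))
})

test_that("r2-binned evaluation emits exactly twenty labelled bins", {
  p <- tagged_fixture(seed = 31)
  rb <- r2_binned_concordance(p, 4L)
  expect_equal(nrow(rb), 20L)
  expect_equal(rb$label[1], "0.00-0.05")
  expect_equal(rb$label[20], "0.95-1.00")
  expect_equal(rb$r2_low, seq(0, 0.95, by = 0.05))
  # the perfect tag lands in the top bin and imputes hets there
  top <- rb$table[[20]]
  expect_gte(top$per_class[["refalt"]], 0.99)
  # bins with no SNPs contribute no genotypes
  expect_true(any(rb$n_genotypes == 0L))
  expect_equal(rb$n_focals[rb$n_genotypes == 0L],
               rep(0L, sum(rb$n_genotypes == 0L)))
  # per-focal genotype totals never exceed the full evaluation set
  expect_true(all(rb$n_genotypes <= n_samples(p)))
})

test_that("frequency-matched restriction uses only same-bin SNPs", {
  nh <- 120L
  low_focal <- c(rep(1L, 4), rep(0L, nh - 4))
  common_tag <- rep(c(1L, 0L), nh / 2)
  haps <- cbind(low_focal, common_tag, matrix(rbinom(nh * 2, 1, 0.5), nh))
  p <- make_panel(haps, positions = c(1000L, 1100L, 1200L, 1300L),
                  ref = c("AT", "A", "A", "A"), alt = c("A", "C", "C", "C"))
  # all context SNPs are common; the low-frequency focal must be skipped
  fm <- freq_matched_concordance(p, 1L)
  expect_equal(attr(fm, "n_no_context"), 1L)
  expect_equal(fm$n, 0)

  # a common focal with a perfect common tag keeps its concordance
  p2 <- tagged_fixture(seed = 40, n_samples = 30)
  full <- loo_concordance(p2, 4L)
  fm2 <- freq_matched_concordance(p2, 4L)
  expect_equal(fm2$per_class[["refalt"]], full$per_class[["refalt"]],
               tolerance = 0.05)
})

test_that("imputation input validation raises classed errors", {
  p <- tagged_fixture()
  expect_error(impute_indel_genotype(p, 99, 4L), class = "indelLD_index_error")
  expect_error(loo_concordance(p, integer(0)), class = "indelLD_domain_error")
  mono <- make_panel(cbind(rep(0L, 8), rbinom(8, 1, 0.5)),
                     positions = c(100L, 200L))
  expect_error(loo_concordance(mono, 1L), class = "indelLD_monomorphic_site")
})
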