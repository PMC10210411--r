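test_that("logCPM matches its closed form", {
  m <- matrix(c(0, 1e6, 10, 20), nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lc <- logcpm(m)
  expect_equal(lc["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["g2", "s2"], log2(20.5 / 31 * 1e6), tolerance = 1e-12)

  # jointly doubling counts leaves values nearly unchanged for counts >> prior
  big <- matrix(c(100, 400, 250, 800), nrow = 2)
  expect_equal(logcpm(2 * big), logcpm(big), tolerance = 1e-3)
  expect_error(logcpm(matrix(c(0, 0, 1, 2), nrow = 2)), "zero library size")
})

test_that("trigamma inverse round-trips", {
  expect_equal(trigamma_inverse(trigamma(2.5)), 2.5, tolerance = 1e-8)
  x <- c(0.1, 1, 7, 123)
  expect_equal(trigamma_inverse(trigamma(x)), x, tolerance = 1e-6)
  expect_true(is.na(trigamma_inverse(-1)))
})

test_that("EB prior recovers known hyperparameters", {
  withr::with_seed(91, {
    d0 <- 4
    s0 <- 0.25
    df <- 10
    sigma2 <- s0 * d0 / stats::rchisq(50000, d0)
    s_sq <- sigma2 * stats::rchisq(50000, df) / df
  })
  pr <- estimate_eb_prior(s_sq, df)
  expect_gt(pr$d0, 3.2)
  expect_lt(pr$d0, 4.8)
  expect_gt(pr$s0_sq, 0.22)
  expect_lt(pr$s0_sq, 0.28)

  # cross-check against the reference scaled-F fit
  ff <- limma::fitFDist(s_sq, df1 = df)
  expect_equal(pr$d0, ff$df2, tolerance = 0.05)
  expect_equal(pr$s0_sq, ff$scale, tolerance = 0.01)
})

test_that("EB prior degenerates correctly at zero spread", {
  df <- 10
  s_sq <- rep(0.5, 100)
  pr <- estimate_eb_prior(s_sq, df)
  expect_identical(pr$d0, Inf)
  # moment formula: log s0^2 = mean(log s^2) - digamma(df/2) + log(df/2)
  expect_equal(pr$s0_sq, 0.5 * exp(log(df / 2) - digamma(df / 2)), tolerance = 1e-12)
  # the bias term vanishes as df grows, so s0^2 -> the common variance
  pr_big <- estimate_eb_prior(rep(0.5, 100), df = 1e8)
  expect_equal(pr_big$s0_sq, 0.5, tolerance = 1e-6)

  expect_error(estimate_eb_prior(rep(1, 5), 10), "at least 20")
  expect_error(estimate_eb_prior(rep(1, 30), 0.5), "df must")
  expect_warning(estimate_eb_prior(c(rep(1, 30), -1), 10), "floored")
})

test_that("d0 = 0 prior reduces batch_de to the ordinary pooled t-test", {
  withr::with_seed(92, {
    counts <- matrix(stats::rnbinom(10 * 12, mu = 200, size = 10), nrow = 10)
  })
  rownames(counts) <- paste0("g", 1:10)
  colnames(counts) <- paste0("s", 1:12)
  groups <- rep(c("AA", "EA"), each = 6)
  res <- batch_de(counts, groups, prior = list(d0 = 0, s0_sq = 1))
  lc <- logcpm(counts)
  for (i in c(1, 5, 10)) {
    tt <- stats::t.test(lc[i, 1:6], lc[i, 7:12], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$logFC[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  expect_error(batch_de(counts, rep("AA", 12)), "both groups")
  expect_error(batch_de(counts[, 1:3], c("AA", "EA", "EA")), "at least 2 samples")
})

test_that("batch_de is calibrated under the null", {
  withr::with_seed(93, {
    counts <- matrix(stats::rnbinom(2000 * 100, mu = 150, size = 5), nrow = 2000)
  })
  rownames(counts) <- paste0("g", 1:2000)
  groups <- rep(c("AA", "EA"), each = 50)
  res <- batch_de(counts, groups)
  frac <- mean(res$p < 0.05)
  band <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / 2000)
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("wFisher reduces exactly to known cases", {
  # K = 1 is the identity for either sign
  expect_equal(wfisher_combine(0.037, 1, 50)$meta_p, 0.037, tolerance = 1e-12)
  expect_equal(wfisher_combine(0.037, -1, 50)$meta_p, 0.037, tolerance = 1e-12)
  expect_equal(wfisher_combine(0.037, -1, 50)$direction, -1)

  # equal weights: the statistic is classical Fisher on the one-sided p's
  withr::with_seed(94, {
    for (rep in 1:5) {
      p <- runif(4)
      signs <- sample(c(-1, 1), 4, replace = TRUE)
      res <- wfisher_combine(p, signs, rep(25, 4))
      p_one <- ifelse(signs > 0, p / 2, 1 - p / 2)
      fisher_p <- stats::pchisq(-2 * sum(log(p_one)), df = 8, lower.tail = FALSE)
      expect_equal(res$meta_one, fisher_p, tolerance = 1e-12)
      expect_equal(res$meta_p, min(1, 2 * min(fisher_p, 1 - fisher_p)), tolerance = 1e-12)
    }
  })

  # zero-weight batches are dropped; all-zero weights are an error
  a <- wfisher_combine(c(0.01, 0.5), c(1, 1), c(30, 0))
  expect_equal(a$meta_p, 0.01, tolerance = 1e-12)
  expect_error(wfisher_combine(c(0.1, 0.2), c(1, 1), c(0, 0)), "positive weight")
  expect_error(wfisher_combine(c(0.1, 1.2), c(1, 1), c(5, 5)), "\\(0, 1\\]")
  expect_warning(wfisher_combine(c(0, 0.5), c(1, 1), c(5, 5)), "clamped")
})

test_that("wFisher meta p is uniform under the null", {
  withr::with_seed(95, {
    meta <- replicate(5000, {
      p <- runif(2)
      signs <- sample(c(-1, 1), 2, replace = TRUE)
      wfisher_combine(p, signs, c(70, 330))$meta_p
    })
  })
  ks <- suppressWarnings(stats::ks.test(meta, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("wFisher evidence is monotone in each input p on the positive branch", {
  grid <- seq(0.02, 0.9, by = 0.02)
  for (p_fix in c(0.05, 0.3, 0.7)) {
    res <- vapply(
      grid,
      function(p1) unlist(wfisher_combine(c(p1, p_fix), c(1, 1), c(100, 300))[c("meta_one", "meta_p")]),
      numeric(2)
    )
    expect_true(all(diff(res["meta_one", ]) >= -1e-12))
    below <- res["meta_one", ] <= 0.5
    expect_true(all(diff(res["meta_p", below]) >= -1e-12))
  }
})

test_that("logFC combination is the sample-size-weighted mean", {
  expect_equal(combine_logfc(c(1, 2), c(100, 300)), 1.75)
  expect_equal(combine_logfc(3.2, 77), 3.2)
  expect_equal(combine_logfc(c(1, 3), c(50, 50)), 2)
  expect_error(combine_logfc(c(1, 2), c(0, 0)), "positive")
})

test_that("meta_de pipeline wires batches, cutoff, and concordance correctly", {
  clin <- simulate_clinical(20, 20, seed = 96)
  cfg <- sim_config(
    seed = 97, n_AA = 20, n_EA = 20, G = 10000,
    de_fraction = 0, libsize_range = c(1e6, 2e6)
  )
  sim <- simulate_counts(clin, cfg)
  res <- meta_de(sim$counts, sim$samples, alpha_family = 0.01)
  expect_equal(attr(res, "cutoff"), 1e-6)
  expect_equal(attr(res, "n_genes"), 10000L, ignore_attr = TRUE)
  expect_equal(nrow(res), 10000)
  gl <- glance(res)
  expect_equal(gl$cutoff, 1e-6)
  expect_s3_class(autoplot(res), "ggplot")

  # determinism
  res2 <- meta_de(sim$counts, sim$samples, alpha_family = 0.01)
  expect_equal(res$meta_p, res2$meta_p)

  expect_error(meta_de(sim$counts[, 1:10], sim$samples[1:9, ]), "sample metadata")
  one_batch <- sim$samples
  one_batch$batch <- "v1"
  expect_error(meta_de(sim$counts, one_batch), "exactly two batches")
})

test_that("discordant genes are never called significant", {
  withr::with_seed(98, {
    G <- 50
    n <- 40
    counts <- matrix(stats::rnbinom(G * n, mu = 200, size = 10), nrow = G)
  })
  rownames(counts) <- paste0("g", 1:G)
  colnames(counts) <- paste0("s", 1:n)
  samples <- tibble::tibble(
    sample = colnames(counts),
    group = rep(rep(c("AA", "EA"), each = 10), 2),
    batch = rep(c("v1", "v2"), each = 20)
  )
  # plant an effect that flips sign between batches for gene 1
  counts[1, 1:10] <- counts[1, 1:10] * 16 # AA up in v1
  counts[1, 31:40] <- counts[1, 31:40] * 16 # EA up in v2
  res <- meta_de(counts, samples)
  expect_false(res$concordant[1])
  expect_false(res$significant[1])
  expect_true(all(res$significant <= res$concordant))
})

test_that("meta-analysis recovers planted effects with correct signs", {
  clin <- simulate_clinical(100, 100, seed = 99)
  cfg <- sim_config(
    seed = 100, n_AA = 100, n_EA = 100, G = 1000,
    de_fraction = 0.05, effect_size = 2, libsize_range = c(1e6, 2e6)
  )
  sim <- simulate_counts(clin, cfg)
  res <- meta_de(sim$counts, sim$samples)
  joined <- dplyr::inner_join(res, sim$truth, by = "gene")
  de <- joined[joined$is_de, ]
  sensitivity <- mean(de$significant)
  expect_gte(sensitivity, 0.8)
  hits <- de[de$significant, ]
  expect_true(all(sign(hits$meta_logFC) == sign(hits$beta)))
  expect_lt(mean(abs(de$meta_logFC - de$beta)), 0.3)
})
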