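test_that("random sequence generation is seeded and composition-checked", {
  a <- gen_random_sequences(10, 30, seed = 101)
  b <- gen_random_sequences(10, 30, seed = 101)
  expect_identical(a, b)
  expect_false(identical(a, gen_random_sequences(10, 30, seed = 102)))

  expect_silent(gen_random_sequences(2, 5, c(0.3, 0.3, 0.2, 0.2)))
  expect_error(gen_random_sequences(2, 5, c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")

  # chi-square goodness of fit on base counts at uniform frequencies
  seqs <- gen_random_sequences(4000, 10, seed = 103)
  counts <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                         c("A", "C", "G", "U")))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("token-space clusters follow the planted generative law", {
  par <- toy_hmm()
  # transition = identity, start in state 1 -> all tokens from state 1's row
  frozen <- hmm_parameters(c(1, 0), diag(2), par$emission, binding_state = 1)
  sim <- gen_hmm_observation_clusters(frozen, n = 200, n_tokens = 20,
                                      seed = 104)
  expect_true(all(unlist(sim$state_paths) == 1))
  tok <- unlist(sim$observations)
  pyr <- match(c("CCC", "CCU", "CUC", "CUU", "UCC", "UCU", "UUC", "UUU"),
               triplet_alphabet())
  expect_gt(mean(tok %in% pyr), 0.75)  # planted row holds 0.8 mass

  # empirical token frequencies near the stationary mixture
  sim2 <- gen_hmm_observation_clusters(par, n = 2000, n_tokens = 30,
                                       seed = 105)
  freq <- tabulate(unlist(sim2$observations), 64) /
    length(unlist(sim2$observations))
  # exact expected state occupancy averaged over the 30 positions
  A <- par$transition
  p <- par$initial; occ <- c(0, 0)
  for (t in 1:30) { occ <- occ + p; p <- as.numeric(p %*% A) }
  occ <- occ / 30
  mix <- occ[1] * par$emission[1, ] + occ[2] * par$emission[2, ]
  # derived bound: 2x the expected multinomial sampling TV at this n
  # (E[TV] ~ sqrt(2/pi)/2 * sum_i sqrt(p_i(1-p_i)/N); tokens are also
  # autocorrelated within clusters, which only inflates it)
  N <- length(unlist(sim2$observations))
  noise_tv <- sqrt(2 / pi) / 2 * sum(sqrt(mix * (1 - mix) / N))
  expect_lt(0.5 * sum(abs(freq - mix)), 2 * noise_tv)

  expect_identical(gen_hmm_observation_clusters(par, 5, 10, seed = 1),
                   gen_hmm_observation_clusters(par, 5, 10, seed = 1))
})

test_that("planted tracts sit where the truth record says", {
  sim <- gen_planted_tract_sequences(50, 80, 20, seed = 106)
  expect_true(all(nchar(sim$sequences) == 80))
  expect_true(all(sim$tract_start >= 0 & sim$tract_start <= 60))

  # pure alternating-CU tract: recorded coordinates agree with a regex scan
  cu <- gen_planted_tract_sequences(30, 60, 20,
                                    tract_freqs = c(0, 0.5, 0, 0.5),
                                    seed = 107)
  for (i in seq_along(cu$sequences)) {
    tract <- substr(cu$sequences[[i]], cu$tract_start[i] + 1,
                    cu$tract_start[i] + 20)
    expect_true(grepl("^[CU]+$", tract))
  }
  # whole-sequence tract
  whole <- gen_planted_tract_sequences(5, 20, 20,
                                       tract_freqs = c(0, 0.5, 0, 0.5),
                                       seed = 108)
  expect_true(all(grepl("^[CU]+$", whole$sequences)))
  expect_error(gen_planted_tract_sequences(5, 10, 20), "impossible geometry")
})

test_that("generative exon tables reflect the planted logit", {
  # beta = 0 -> class proportions near (1/3, 1/3, 1/3)
  beta0 <- matrix(0, 2, 5)
  sim <- gen_exon_dataset(n_per_class = 1000, mode = "generative",
                          beta = beta0, seed = 109)
  prop <- table(sim$labels) / length(sim$labels)
  expect_true(all(abs(prop - 1 / 3) < 0.04))

  # distinct class means with zero covariance: screening retains the feature
  cc <- gen_exon_dataset(n_per_class = 60, mode = "class_conditional",
                         class_means = rbind(c(0, 0), c(2, 0), c(0, 0)),
                         seed = 110)
  keep <- screen_features_ttest(cc$features[, c("x1", "x2")], cc$labels)
  expect_true("x1" %in% keep)
  expect_identical(gen_exon_dataset(seed = 7), gen_exon_dataset(seed = 7))
})

test_that("PSI tables carry the planted deltas and recover labels", {
  noiseless <- gen_psi_table(n_per_class = c(5, 5, 0), mu_repressed = 40,
                             sd = 0, ctrl_range = c(20, 20), seed = 111)
  rep_rows <- noiseless$truth$class == "repressed"
  expect_equal(noiseless$psi$psi_knockdown[rep_rows],
               noiseless$psi$psi_control[rep_rows] + 40, tolerance = 1e-12)

  sim <- gen_psi_table(n_per_class = 100, mu_repressed = 40, mu_enhanced = 40,
                       sd = 2, seed = 112)
  lab <- classify_exons_from_psi(sim$psi)
  agree <- mean(lab$label == sim$truth$class)
  expect_gte(agree, 0.95)

  expect_error(gen_psi_table(sd = -1), "negative")
  # clipping is reported
  expect_message(clip <- gen_psi_table(n_per_class = c(0, 50, 0),
                                       mu_repressed = 40, sd = 0,
                                       ctrl_range = c(75, 95), seed = 113),
                 "clipping")
  expect_gt(clip$n_clipped, 0)
  expect_true(all(clip$psi$psi_knockdown <= 100))
})

test_that("regulated exon genome plants signal where promised", {
  world <- gen_regulated_exon_genome(n_repressed = 10, n_neutral = 10,
                                     n_enhanced = 5, seed = 114)
  expect_length(world$genome, 25)
  expect_identical(world$truth$class,
                   rep(c("repressed", "neutral", "enhanced"), c(10, 10, 5)))
  # upstream 250-nt window of repressed exons is pyrimidine-enriched
  pyr_frac <- function(s) mean(strsplit(s, "")[[1]] %in% c("C", "U"))
  up_frac <- vapply(seq_len(25), function(i) {
    ex <- world$exons[i, ]
    r <- define_regulatory_regions(ex, nchar(world$genome[[ex$chrom]]))
    pyr_frac(as.character(extract_region_sequence(world$genome,
                                                  r$upstream_intron)))
  }, 0)
  expect_gt(mean(up_frac[world$truth$class == "repressed"]),
            mean(up_frac[world$truth$class == "neutral"]) + 0.2)
})
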