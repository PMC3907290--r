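test_that("encode_triplets yields overlapping 3-mers in the A<C<G<U alphabet", {
  alpha <- triplet_alphabet()
  expect_identical(alpha[c(1, 64)], c("AAA", "UUU"))
  expect_identical(alpha[encode_triplets("CUCUCU")],
                   c("CUC", "UCU", "CUC", "UCU"))
  expect_identical(alpha[encode_triplets("ACG")], "ACG")
  expect_error(encode_triplets("AC"), "too-short")
  # every triplet encodes to its own alphabet position
  expect_identical(vapply(alpha, function(t) encode_triplets(t), 1L,
                          USE.NAMES = FALSE), 1:64)
})

test_that("forward_loglik matches closed forms and the enumeration oracle", {
  unif <- uniform_hmm()
  obs <- encode_triplets("ACGUACGUAC")
  expect_equal(forward_loglik(unif, obs), length(obs) * log(1 / 64),
               tolerance = 1e-12)

  par <- toy_hmm()
  o1 <- encode_triplets("UCU")
  expect_equal(forward_loglik(par, o1),
               log(par$initial[1] * par$emission[1, o1] +
                     par$initial[2] * par$emission[2, o1]),
               tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(31)
  for (T_ in c(2, 5, 8)) {
    obs <- sample(1:64, T_, replace = TRUE)
    expect_lt(abs(forward_loglik(par, obs) - brute_force_loglik(par, obs)),
              1e-10)
  }
  expect_error(forward_loglik(par, integer(0)), "empty")
})

test_that("posterior state probabilities sum to 1 at every position", {
  par <- toy_hmm()
  set.seed(5)
  for (rep in 1:5) {
    obs <- sample(1:64, sample(3:40, 1), replace = TRUE)
    g <- posterior_state_probs(par, obs)
    expect_true(all(abs(rowSums(g) - 1) < 1e-9))
  }
})

test_that("viterbi matches brute force and breaks ties toward binding", {
  par <- toy_hmm()
  set.seed(17)
  for (T_ in c(2, 4, 6, 8)) {
    obs <- sample(1:64, T_, replace = TRUE)
    vp <- viterbi_path(par, obs)
    expect_length(vp, T_)
    expect_lt(abs(path_logprob(par, obs, vp) -
                    brute_force_viterbi_logprob(par, obs)), 1e-10)
  }
  # boundary switching on a pyrimidine/purine junction
  seq <- "UCUCUCUCAAAGAAAGGG"
  vp <- viterbi_path(par, encode_triplets(seq))
  expect_identical(vp[1:4], rep("binding", 4))
  expect_identical(vp[length(vp) - 0:3], rep("nonbinding", 4))
  # uniform emissions, binding-start, sticky transitions -> all binding
  sticky <- hmm_parameters(c(1, 0), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                           matrix(1 / 64, 2, 64), binding_state = 1)
  expect_identical(unique(viterbi_path(sticky, encode_triplets("ACGUACGU"))),
                   "binding")
})

test_that("label_binding_state picks the pyrimidine-heavy state, invariantly", {
  par <- toy_hmm()
  expect_identical(par$binding_state, 1L)
  flipped <- hmm_parameters(rev(par$initial),
                            par$transition[2:1, 2:1],
                            par$emission[2:1, ])
  expect_identical(label_binding_state(flipped)$binding_state, 2L)
  # relabeling never changes the likelihood
  obs <- encode_triplets("UCUCAAAGG")
  expect_identical(forward_loglik(par, obs),
                   forward_loglik(label_binding_state(par), obs))
  expect_warning(label_binding_state(uniform_hmm()), "tied")
})

test_that("baum-welch recovers planted parameters from token-space clusters", {
  planted <- planted_recovery_hmm()
  sim <- gen_hmm_observation_clusters(planted, n = 2000, n_tokens = 28,
                                      seed = 11)
  fit <- baum_welch_train(sim$observations, n_restarts = 2, seed = 5,
                          max_iter = 200)
  err <- recovery_errors(fit, planted)
  expect_lt(err$emission_tv, 0.05)
  expect_lt(err$transition_err, 0.1)
  # EM guarantee: monotone non-decreasing log-likelihood trace
  expect_true(all(diff(attr(fit, "loglik_trace")) >= -1e-8))
  # probability rows sum to 1
  expect_equal(sum(fit$initial), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$transition), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rowSums(fit$emission), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate corpus concentrates a state on its two triplets", {
  fit <- suppressWarnings(baum_welch_train(rep("UCUCUCUCUCUC", 60),
                                           n_restarts = 3, seed = 2,
                                           max_iter = 100))
  mass <- rowSums(fit$emission[, c("UCU", "CUC"), drop = FALSE])
  expect_true(any(mass >= 0.99))
  expect_true(all(diff(attr(fit, "loglik_trace")) >= -1e-8))
})

test_that("training drops too-short clusters and errors when none remain", {
  expect_message(fit <- baum_welch_train(c("UCUCUC", "AC", "GU", "ACGUAC"),
                                         n_restarts = 1, seed = 1,
                                         max_iter = 10),
                 "dropping 2")
  expect_s3_class(fit, "ptb_hmm")
  expect_error(baum_welch_train(c("AC", "GU"), n_restarts = 1, seed = 1),
               "too short")
})

test_that("log-odds score is zero under matched uniform model and background", {
  unif <- uniform_hmm()
  for (s in c("ACGUACG", "UUUUUU", "CUCUCUCUCU"))
    expect_equal(log_odds_score(unif, s), 0, tolerance = 1e-12)
})

test_that("log-odds equals enumeration forward minus uniform background", {
  par <- toy_hmm()
  seq <- "UCUCAAA"  # 5 tokens
  obs <- encode_triplets(seq)
  expected <- (brute_force_loglik(par, obs) - length(obs) * log(1 / 64)) / log(2)
  expect_equal(log_odds_score(par, seq), expected, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("scores grow along pyrimidine repeat expansions (length monotonicity)", {
  par <- toy_hmm()
  s1 <- log_odds_score(par, "UCUCUC")
  s2 <- log_odds_score(par, "UCUCUCUCUCUC")
  s3 <- log_odds_score(par, strrep("UC", 12))
  expect_true(s1 < s2 && s2 < s3)
})

test_that("HMM JSON serialization round-trips", {
  par <- toy_hmm()
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(par, f)
  back <- read_hmm_json(f)
  expect_equal(back$initial, par$initial, tolerance = 1e-12)
  expect_equal(back$transition, par$transition, tolerance = 1e-12)
  expect_equal(unname(back$emission), unname(par$emission), tolerance = 1e-12)
  expect_identical(back$binding_state, par$binding_state)
  obs <- encode_triplets("UCUCUCAA")
  expect_equal(forward_loglik(back, obs), forward_loglik(par, obs),
               tolerance = 1e-10)
})
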