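test_that("PSI labelling follows the minor-isoform and delta rules", {
  psi <- data.frame(exon_id = c("a", "b", "c", "d", "e"),
                    psi_control = c(20, 2, 50, 70, 40),
                    psi_knockdown = c(60, 40, 53, 30, 55))
  lab <- classify_exons_from_psi(psi)
  expect_identical(lab$label,
                   c("repressed",   # minor 20/40 > 5, delta +40
                     "excluded",    # control minor isoform 2 <= 5
                     "non_regulated",  # |delta| = 3 <= 5
                     "enhanced",    # minor 30/30 > 5, delta -40
                     "excluded"))   # delta +15: neither rule
  expect_error(classify_exons_from_psi(
    data.frame(exon_id = "x", psi_control = 105, psi_knockdown = 50)),
    "out of")
  # non-alternative exons never become non_regulated
  psi$alternative <- FALSE
  lab2 <- classify_exons_from_psi(psi)
  expect_false(any(lab2$label == "non_regulated"))
})

test_that("t-test screening keeps separated features, drops flat ones", {
  set.seed(61)
  n <- 50
  labels <- rep(c("non_regulated", "repressed", "enhanced"), each = n)
  x <- data.frame(
    x1 = c(rnorm(n), rnorm(n, 2), rnorm(n)),   # 2-sd separation -> retained
    x2 = rnorm(3 * n),                          # pure noise (may or may not pass)
    x3 = rep(1, 3 * n))                         # constant -> dropped, warning
  expect_warning(keep <- screen_features_ttest(x, labels), "zero variance")
  expect_true("x1" %in% keep)
  expect_false("x3" %in% keep)
  # boundary: p exactly at alpha is dropped (strict <)
  expect_identical(screen_features_ttest(x["x1"], labels, alpha = 0), character(0))
})

test_that("closed-form probabilities from the g-functions", {
  # beta = 0 -> (1/3, 1/3, 1/3)
  model <- structure(list(coefficients = rbind(repressed = c(`(Intercept)` = 0),
                                               enhanced = c(`(Intercept)` = 0)),
                          features = character(0)), class = "ptb_logit")
  p0 <- predict_probabilities(model, data.frame(x1 = 1:3))
  expect_true(all(abs(as.matrix(p0) - 1 / 3) < 1e-12))

  # g_R = ln 2, g_E = 0 -> (0.5, 0.25, 0.25)
  model$coefficients <- rbind(repressed = c(`(Intercept)` = log(2)),
                              enhanced = c(`(Intercept)` = 0))
  p1 <- predict_probabilities(model, data.frame(x1 = 0))
  expect_equal(as.numeric(p1), c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # probabilities sum to 1 for randomized coefficients and inputs
  set.seed(62)
  for (i in 1:10) {
    B <- matrix(rnorm(10), 2, 5)
    colnames(B) <- c("(Intercept)", paste0("x", 1:4))
    rownames(B) <- c("repressed", "enhanced")
    m <- structure(list(coefficients = B, features = paste0("x", 1:4)),
                   class = "ptb_logit")
    x <- as.data.frame(matrix(rnorm(20), 5, 4,
                              dimnames = list(NULL, paste0("x", 1:4))))
    P <- as.matrix(predict_probabilities(m, x))
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
    # baseline is anchored: shifting both g by a constant changes probabilities
    B2 <- B; B2[, 1] <- B2[, 1] + 1
    m2 <- structure(list(coefficients = B2, features = paste0("x", 1:4)),
                    class = "ptb_logit")
    expect_false(isTRUE(all.equal(predict_probabilities(m2, x), as.data.frame(P),
                                  check.attributes = FALSE)))
  }
})

test_that("multinomial fit recovers planted coefficients within 2 SE", {
  beta <- rbind(repressed = c(-0.5, -0.8, 1.2, 0.6, 0.5),
                enhanced = c(-1.0, -0.5, 0.0, -0.4, 0.9))
  n_cover <- 0; n_total <- 0
  n_seeds <- 8
  for (seed in seq_len(n_seeds)) {
    sim <- gen_exon_dataset(n_per_class = 1000, mode = "generative",
                            beta = beta, seed = 600 + seed)
    fit <- fit_multinomial(sim$features, sim$labels)
    covered <- abs(fit$coefficients - beta) <= 2 * fit$se
    n_cover <- n_cover + sum(covered); n_total <- n_total + length(covered)
  }
  # ~95% coverage expected; require at least 85% overall
  expect_gt(n_cover / n_total, 0.85)
})

test_that("fit reports separation and stabilizes with ridge", {
  x <- data.frame(x1 = c(rep(-2, 10), rep(2, 10), rep(0, 10)))
  labels <- rep(c("non_regulated", "repressed", "enhanced"), each = 10)
  expect_warning(fit <- fit_multinomial(x, labels), "separation")
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
  expect_error(fit_multinomial(x[1:20, , drop = FALSE], labels[1:20]),
               "absent")
})

test_that("outlier detection flags gross outliers, not clean data", {
  set.seed(63)
  sim <- gen_exon_dataset(n_per_class = c(70, 70, 60),
                          mode = "class_conditional",
                          class_means = rbind(c(0, 0), c(2.5, 0), c(0, 2.5)),
                          seed = 64)
  fit <- fit_multinomial(sim$features, sim$labels)
  clean_flags <- detect_outlier_exons(fit, sim$features, sim$labels)
  # planted gross outlier: a non_regulated exon moved 10 sd into repressed space
  x2 <- sim$features
  idx <- which(sim$labels == "non_regulated")[1]
  x2$x1[idx] <- 10
  fit2 <- fit_multinomial(x2, sim$labels)
  flags2 <- detect_outlier_exons(fit2, x2, sim$labels)
  expect_true(idx %in% flags2$index)
  # cutoff = Inf disables flagging
  expect_identical(nrow(detect_outlier_exons(fit2, x2, sim$labels,
                                             cutoff = Inf)), 0L)
})

test_that("stepwise selection drops planted noise, keeps signal", {
  set.seed(65)
  n <- 170
  labels <- sample(rep(c("non_regulated", "repressed", "enhanced"),
                       length.out = n))
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  x$x1 <- x$x1 + 1.5 * (labels == "repressed")     # informative
  res <- stepwise_select(x, labels, c("x1", "x2"))
  expect_true("x1" %in% res$features)
  expect_false("x2" %in% res$features)
  # empty candidate set -> intercept-only model
  res0 <- stepwise_select(x, labels, character(0))
  expect_identical(res0$features, character(0))
  expect_identical(colnames(res0$model$coefficients), "(Intercept)")
})

test_that("roc_curve matches the concordant-pair oracle", {
  scores <- c(0.9, 0.2, 0.4, 0.8)
  positive <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(scores, positive)
  expect_equal(r$auc, 0.5)  # 2 concordant pairs / 4
  expect_equal(r$auc, pair_auc(scores, positive))

  set.seed(66)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)  # with ties
    pos <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(pos) || all(pos)) next
    expect_equal(roc_curve(s, pos)$auc, pair_auc(s, pos), tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(roc_curve(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # permuted labels: AUC near 0.5 at n = 400
  set.seed(67)
  s <- rnorm(400); pos <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  expect_lt(abs(roc_curve(s, pos)$auc - 0.5), 0.05)
})

test_that("LOOCV separates a separable synthetic world", {
  set.seed(68)
  sim <- gen_exon_dataset(n_per_class = c(25, 25, 12),
                          mode = "class_conditional",
                          class_means = rbind(c(0, 0, 0, 0),
                                              c(-1.5, 2, 1, 1),
                                              c(-1.5, 0, -0.5, 1.5)),
                          seed = 69)
  cv <- loocv_roc(sim$features, sim$labels)
  expect_gt(cv$auc_repressed, 0.9)
  expect_true(all(abs(rowSums(cv$held_out[, 1:3]) - 1) < 1e-9))
  expect_error(loocv_roc(sim$features[1:4, ], c("repressed", "enhanced",
                                                "non_regulated", "repressed")),
               ">= 2")
})

test_that("ranking and thresholds follow the 0.65 / 0.20 boundary rules", {
  pred <- data.frame(exon_id = c("a", "b", "c", "d", "e"),
                     p_repressed = c(0.89, 0.65, 0.2, 0.05, 0.70))
  ranked <- rank_and_threshold(pred)
  expect_identical(ranked$exon_id, c("a", "e", "b", "c", "d"))
  expect_identical(ranked$call,
                   c("predicted_repressed", "predicted_repressed",
                     "intermediate",            # exactly 0.65: strict >
                     "predicted_unregulated",   # exactly 0.20: <=
                     "predicted_unregulated"))
  expect_equal(attr(ranked, "fraction_repressed"), 2 / 5)
})

test_that("binned response rises along a planted logistic curve", {
  set.seed(71)
  n <- 2000
  x <- runif(n, -3, 3)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x))
  br <- binned_response(x, y, edges = seq(-3, 3, by = 1))
  expect_true(all(br$bins$n > 0))
  expect_true(all(diff(br$bins$mean_response) > -0.1))  # monotone within noise
  expect_lt(br$tests$p_value[3], 0.01)

  # flat world: all y = 1
  flat <- binned_response(x, rep(1, n), edges = c(-3, 0, 3))
  expect_true(all(flat$bins$mean_response == 1))
  # empty bin reported with n = 0 and excluded from tests
  sparse <- binned_response(c(0.5, 0.6, 2.5), c(0, 1, 1),
                            edges = c(0, 1, 2, 3))
  expect_identical(sparse$bins$n, c(2L, 0L, 1L))
  expect_true(is.na(sparse$bins$mean_response[2]))
  expect_error(binned_response(numeric(0), numeric(0), c(0, 1)), "no non-empty")
})

test_that("regulation model JSON round-trips and predicts identically", {
  set.seed(72)
  sim <- gen_exon_dataset(n_per_class = c(40, 40, 20), seed = 73)
  model <- suppressWarnings(train_regulation_model(sim$features, sim$labels))
  f <- withr::local_tempfile(fileext = ".json")
  write_regulation_model_json(model, f)
  back <- read_regulation_model_json(f)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  p1 <- predict_probabilities(model, sim$features)
  p2 <- predict_probabilities(back, sim$features)
  expect_equal(p1, p2, tolerance = 1e-12)
})
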