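# Multinomial logistic regression for exon regulation: labelling from PSI
# tables, t-test feature screening, outlier removal, maximum-likelihood
# fitting with non_regulated as the baseline class, backward-AIC stepwise
# selection, leave-one-out cross-validation with ROC/AUC, threshold calls
# and binned-response validation.

REGULATION_CLASSES <- c("non_regulated", "repressed", "enhanced")

#' Classify exons from PSI tables
#'
#' An exon is called repressed/enhanced when (1) the PSI of its minor isoform
#' (min(PSI, 100-PSI)) exceeds \code{min_minor} in both control and
#' knockdown, and (2) dPSI = knockdown - control is >= \code{min_delta}
#' (repressed; splicing increases when the repressor is depleted) or
#' <= -\code{min_delta} (enhanced). Exons flagged alternative with
#' |dPSI| <= \code{nonreg_max_delta} are non_regulated; everything else is
#' excluded.
#'
#' @param psi data.frame with columns exon_id, psi_control, psi_knockdown
#'   and optional logical \code{alternative} (default TRUE).
#' @param min_minor minor-isoform PSI floor, percent.
#' @param min_delta |dPSI| needed for a regulated call, percent.
#' @param nonreg_max_delta |dPSI| ceiling for non_regulated, percent.
#' @return data.frame(exon_id, delta_psi, label).
#' @export
classify_exons_from_psi <- function(psi, min_minor = 5, min_delta = 30,
                                    nonreg_max_delta = 5) {
  stopifnot(all(c("exon_id", "psi_control", "psi_knockdown") %in% names(psi)))
  if (any(psi$psi_control < 0 | psi$psi_control > 100 |
            psi$psi_knockdown < 0 | psi$psi_knockdown > 100))
    stopf("PSI out of [0, 100]")
  alt <- if ("alternative" %in% names(psi)) psi$alternative else TRUE
  minor_ok <- pmin(psi$psi_control, 100 - psi$psi_control) > min_minor &
    pmin(psi$psi_knockdown, 100 - psi$psi_knockdown) > min_minor
  delta <- psi$psi_knockdown - psi$psi_control
  label <- rep("excluded", nrow(psi))
  label[minor_ok & delta >= min_delta] <- "repressed"
  label[minor_ok & delta <= -min_delta] <- "enhanced"
  label[abs(delta) <= nonreg_max_delta & alt & label == "excluded"] <-
    "non_regulated"
  data.frame(exon_id = psi$exon_id, delta_psi = delta, label = label,
             stringsAsFactors = FALSE)
}

#' Screen candidate features by two-sample t-tests
#'
#' A feature is retained when its Welch t-test p-value comparing either
#' regulated class against the non_regulated baseline is strictly below
#' \code{alpha} (default 0.25, a deliberately permissive screen). Features
#' with zero variance in both compared groups are dropped with a warning.
#'
#' @param x numeric feature matrix/data.frame (columns = candidates).
#' @param labels character vector over the three classes.
#' @param alpha screening level.
#' @return character vector of retained feature names.
#' @export
screen_features_ttest <- function(x, labels, alpha = 0.25) {
  x <- as.data.frame(x)
  keep <- character(0)
  for (f in names(x)) {
    p_min <- Inf
    for (cls in c("repressed", "enhanced")) {
      a <- x[[f]][labels == cls]; b <- x[[f]][labels == "non_regulated"]
      if (length(a) < 2 || length(b) < 2) next
      if (stats::sd(a) == 0 && stats::sd(b) == 0) next
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
      p_min <- min(p_min, p)
    }
    if (is.infinite(p_min)) {
      warnf("feature '%s' has zero variance in all compared groups; dropped", f)
    } else if (p_min < alpha) {
      keep <- c(keep, f)
    }
  }
  keep
}

# --- multinomial logit core ------------------------------------------------

# Design matrix with intercept from a feature frame restricted to `features`.
design_matrix <- function(x, features) {
  x <- as.data.frame(x)
  cbind(`(Intercept)` = 1, as.matrix(x[, features, drop = FALSE]))
}

# labels -> n x 3 indicator matrix in REGULATION_CLASSES order
class_indicators <- function(labels) {
  y <- matrix(0, length(labels), 3,
              dimnames = list(NULL, REGULATION_CLASSES))
  for (k in REGULATION_CLASSES) y[labels == k, k] <- 1
  y
}

# Probabilities for coefficient matrix B (2 x p, rows repressed/enhanced).
mlogit_probs <- function(B, X) {
  gR <- as.numeric(X %*% B[1, ]); gE <- as.numeric(X %*% B[2, ])
  m <- pmax(0, gR, gE)
  den <- exp(-m) + exp(gR - m) + exp(gE - m)
  cbind(non_regulated = exp(-m) / den,
        repressed = exp(gR - m) / den,
        enhanced = exp(gE - m) / den)
}

mlogit_negll <- function(theta, X, Y, ridge = 0) {
  B <- matrix(theta, nrow = 2)
  P <- mlogit_probs(B, X)
  -sum(Y * log(pmax(P, 1e-300))) + ridge * sum(theta^2) / 2
}

mlogit_grad <- function(theta, X, Y, ridge = 0) {
  B <- matrix(theta, nrow = 2)
  P <- mlogit_probs(B, X)
  gR <- crossprod(X, P[, "repressed"] - Y[, "repressed"])
  gE <- crossprod(X, P[, "enhanced"] - Y[, "enhanced"])
  as.numeric(rbind(as.numeric(gR), as.numeric(gE))) + ridge * theta
}

#' Fit the three-class multinomial logistic regression
#'
#' Maximum-likelihood fit with non_regulated as the baseline: the two
#' g-functions (logits) g_repressed and g_enhanced are each linear in the
#' retained features, and g_class(x) = log(p_class / p_non_regulated).
#' Complete separation (diverging coefficients or a singular Hessian) is
#' detected, reported, and refit with a small ridge penalty.
#'
#' @param x feature data.frame.
#' @param labels class labels (all three classes must be present).
#' @param features columns of \code{x} to use; NULL = all numeric columns
#'   named x1..; empty character vector = intercept-only model.
#' @param ridge optional ridge penalty (0 = plain ML).
#' @return object of class \code{ptb_logit}: coefficient matrix (2 x p,
#'   rows repressed/enhanced), standard errors, Wald z and p-values,
#'   log-likelihood, AIC, convergence/separation flags.
#' @export
fit_multinomial <- function(x, labels, features = NULL, ridge = 0) {
  x <- as.data.frame(x)
  if (is.null(features))
    features <- grep("^x[0-9]+$", names(x), value = TRUE)
  miss <- setdiff(REGULATION_CLASSES, unique(labels))
  if (length(miss) > 0)
    stopf("class '%s' absent from the training table", miss[1])
  X <- design_matrix(x, features)
  Y <- class_indicators(labels)
  p <- ncol(X)
  theta0 <- rep(0, 2 * p)
  fit <- stats::optim(theta0, mlogit_negll, mlogit_grad, X = X, Y = Y,
                      ridge = ridge, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  theta <- fit$par
  separated <- max(abs(theta)) > 15
  H <- stats::optimHess(theta, mlogit_negll, mlogit_grad, X = X, Y = Y,
                        ridge = ridge)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (ridge == 0 && (separated || is.null(cov) ||
                     any(!is.finite(diag(cov))) || any(diag(cov) <= 0))) {
    warnf("complete or quasi-complete separation detected; refitting with ridge")
    out <- fit_multinomial(x, labels, features, ridge = 1e-2)
    out$separated <- TRUE
    return(out)
  }
  B <- matrix(theta, nrow = 2,
              dimnames = list(c("repressed", "enhanced"), colnames(X)))
  se <- if (!is.null(cov)) matrix(sqrt(pmax(diag(cov), 0)), nrow = 2,
                                  dimnames = dimnames(B)) else B * NA
  wald <- B / se
  ll <- -mlogit_negll(theta, X, Y, ridge = 0)
  structure(list(coefficients = B, se = se, wald_z = wald,
                 wald_p = 2 * stats::pnorm(-abs(wald)),
                 features = features, loglik = ll,
                 aic = -2 * ll + 2 * length(theta),
                 n = nrow(X), converged = fit$convergence == 0,
                 separated = separated, ridge = ridge,
                 class_counts = table(factor(labels, REGULATION_CLASSES))),
            class = "ptb_logit")
}

#' @export
print.ptb_logit <- function(x, ...) {
  cat(sprintf("Multinomial logit (baseline: non_regulated), n = %d\n", x$n))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = " ")))
  cat(sprintf("  logLik = %.3f, AIC = %.3f%s\n", x$loglik, x$aic,
              if (isTRUE(x$separated)) " [separation: ridge-stabilized]" else ""))
  for (r in rownames(x$coefficients)) {
    cat(sprintf("  g_%s: %s\n", r,
                paste(sprintf("%s=%.3f(%.3f)", colnames(x$coefficients),
                              x$coefficients[r, ], x$se[r, ]), collapse = " ")))
  }
  invisible(x)
}

#' Class probabilities from the fitted g-functions
#'
#' p_repressed = exp(g_R) / (1 + exp(g_R) + exp(g_E)), p_enhanced
#' analogously, p_non_regulated = 1 / (1 + exp(g_R) + exp(g_E)); rows sum
#' to 1 to machine precision.
#'
#' @param model a \code{ptb_logit}.
#' @param x feature data.frame (standardized with the model's reference).
#' @return data.frame p_repressed, p_enhanced, p_non_regulated.
#' @export
predict_probabilities <- function(model, x) {
  X <- design_matrix(x, model$features)
  P <- mlogit_probs(model$coefficients, X)
  data.frame(p_repressed = P[, "repressed"], p_enhanced = P[, "enhanced"],
             p_non_regulated = P[, "non_regulated"])
}

#' Flag outlier exons under an interim fit
#'
#' Flags exons whose standardized Pearson residual
#' (y_ic - p_ic) / sqrt(p_ic (1 - p_ic)), maximized over the three class
#' indicators, exceeds \code{cutoff} in absolute value. Flags are reported,
#' never silently applied.
#'
#' @param model interim \code{ptb_logit}.
#' @param x feature data.frame.
#' @param labels class labels.
#' @param cutoff residual cutoff (default 3; Inf disables flagging).
#' @return data.frame(index, exon_id, max_abs_residual) of flagged exons.
#' @export
detect_outlier_exons <- function(model, x, labels, cutoff = 3) {
  P <- as.matrix(predict_probabilities(model, x))
  colnames(P) <- c("repressed", "enhanced", "non_regulated")
  Y <- class_indicators(labels)[, colnames(P)]
  R <- (Y - P) / sqrt(P * (1 - P))
  mx <- apply(abs(R), 1, max)
  flagged <- which(mx > cutoff)
  ids <- if ("exon_id" %in% names(x)) x$exon_id else as.character(seq_len(nrow(x)))
  data.frame(index = flagged, exon_id = ids[flagged],
             max_abs_residual = mx[flagged], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Backward stepwise selection by AIC
#'
#' Starting from the screened candidate set, repeatedly drops the feature
#' whose removal lowers AIC most, refitting at each step; deterministic
#' given the table. An empty candidate set yields the intercept-only model.
#'
#' @param x feature data.frame.
#' @param labels class labels.
#' @param candidates candidate feature names.
#' @return list(features, model).
#' @export
stepwise_select <- function(x, labels, candidates) {
  current <- candidates
  model <- fit_multinomial(x, labels, features = current)
  repeat {
    if (length(current) == 0) break
    best_drop <- NULL; best_aic <- model$aic
    for (f in current) {
      cand <- setdiff(current, f)
      m <- suppressWarnings(fit_multinomial(x, labels, features = cand))
      if (m$aic < best_aic - 1e-9) { best_aic <- m$aic; best_drop <- f }
    }
    if (is.null(best_drop)) break
    current <- setdiff(current, best_drop)
    model <- suppressWarnings(fit_multinomial(x, labels, features = current))
  }
  list(features = current, model = model)
}

#' Train the full regulation model
#'
#' Runs the three-step protocol on a labelled feature table: t-test
#' screening (p < alpha), outlier-exon removal under an interim fit, and
#' backward-AIC stepwise selection, then the final ML fit.
#'
#' @param x feature data.frame (x1..x4 and any extra candidate columns).
#' @param labels class labels.
#' @param candidates candidate feature columns (default x1..x4 and any
#'   numeric x-prefixed extras).
#' @param alpha screening level.
#' @param outlier_cutoff residual cutoff for exon removal (Inf disables).
#' @param stepwise run backward-AIC selection.
#' @return a \code{ptb_logit} with attributes \code{screened},
#'   \code{outliers_removed}.
#' @export
train_regulation_model <- function(x, labels, candidates = NULL, alpha = 0.25,
                                   outlier_cutoff = 3, stepwise = TRUE) {
  x <- as.data.frame(x)
  if (is.null(candidates))
    candidates <- grep("^x[0-9]+$", names(x), value = TRUE)
  screened <- screen_features_ttest(x[, candidates, drop = FALSE], labels,
                                    alpha = alpha)
  interim <- suppressWarnings(fit_multinomial(x, labels, features = screened))
  out_tab <- if (is.finite(outlier_cutoff))
    detect_outlier_exons(interim, x, labels, cutoff = outlier_cutoff)
  else data.frame(index = integer(0))
  keep <- setdiff(seq_len(nrow(x)), out_tab$index)
  xs <- x[keep, , drop = FALSE]; ls <- labels[keep]
  res <- if (stepwise) stepwise_select(xs, ls, screened)
  else list(features = screened,
            model = suppressWarnings(fit_multinomial(xs, ls, features = screened)))
  model <- res$model
  attr(model, "screened") <- screened
  attr(model, "outliers_removed") <- out_tab
  model
}

# --- ROC / cross-validation ------------------------------------------------

#' ROC points and trapezoid AUC
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param positive logical vector of true positives.
#' @return list(points = data.frame(threshold, sensitivity, specificity,
#'   fpr), auc).
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  if (!any(positive) || all(positive)) stopf("need both classes for a ROC")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(th, function(t) mean(scores[positive] >= t), 0)
  spec <- vapply(th, function(t) mean(scores[!positive] < t), 0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  list(points = data.frame(threshold = th, sensitivity = sens,
                           specificity = spec, fpr = fpr), auc = auc)
}

#' Leave-one-out cross-validation with per-logit ROC
#'
#' For each exon the model is retrained on all others -- feature screening
#' (and optionally stepwise selection) re-run inside the fold to avoid
#' selection leakage -- and the held-out exon's class probabilities
#' recorded. ROCs are computed per logit: repressed-vs-rest on p_repressed
#' and enhanced-vs-rest on p_enhanced.
#'
#' @param x feature data.frame.
#' @param labels class labels (>= 2 exons per class).
#' @param candidates candidate features (default x1..).
#' @param alpha screening level inside each fold.
#' @param stepwise run stepwise selection inside each fold (default FALSE;
#'   the screen-only protocol is much faster and equally honest).
#' @param outlier_cutoff outlier cutoff inside each fold (Inf disables,
#'   default).
#' @return object of class \code{ptb_cv}: held-out probability table,
#'   ROC/AUC per logit.
#' @export
loocv_roc <- function(x, labels, candidates = NULL, alpha = 0.25,
                      stepwise = FALSE, outlier_cutoff = Inf) {
  x <- as.data.frame(x)
  if (is.null(candidates))
    candidates <- grep("^x[0-9]+$", names(x), value = TRUE)
  counts <- table(factor(labels, REGULATION_CLASSES))
  if (any(counts < 2)) stopf("need >= 2 exons per class for LOOCV")
  n <- nrow(x)
  held <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("p_repressed", "p_enhanced",
                                         "p_non_regulated")))
  for (i in seq_len(n)) {
    xs <- x[-i, , drop = FALSE]; ls <- labels[-i]
    m <- suppressWarnings(suppressMessages(
      train_regulation_model(xs, ls, candidates = candidates, alpha = alpha,
                             outlier_cutoff = outlier_cutoff,
                             stepwise = stepwise)))
    held[i, ] <- as.numeric(predict_probabilities(m, x[i, , drop = FALSE]))
  }
  held <- as.data.frame(held)
  held$label <- labels
  roc_r <- roc_curve(held$p_repressed, labels == "repressed")
  roc_e <- roc_curve(held$p_enhanced, labels == "enhanced")
  structure(list(held_out = held,
                 roc_repressed = roc_r$points, auc_repressed = roc_r$auc,
                 roc_enhanced = roc_e$points, auc_enhanced = roc_e$auc),
            class = "ptb_cv")
}

#' @export
print.ptb_cv <- function(x, ...) {
  cat(sprintf("LOOCV over %d exons: AUC(repressed) = %.3f, AUC(enhanced) = %.3f\n",
              nrow(x$held_out), x$auc_repressed, x$auc_enhanced))
  invisible(x)
}

#' Rank exons and apply decision thresholds
#'
#' Sorts by p_repressed (descending, ties by exon id) and calls
#' predicted-repressed when p > \code{repress_threshold} (strict),
#' predicted-unregulated when p <= \code{negative_threshold}, intermediate
#' otherwise. Defaults 0.65 / 0.20.
#'
#' @param predictions data.frame with exon_id and p_repressed (extra columns
#'   preserved).
#' @param repress_threshold repressed-call threshold (strict >).
#' @param negative_threshold unregulated-call threshold (<=).
#' @return ranked data.frame with a \code{call} column and attribute
#'   \code{fraction_repressed}.
#' @export
rank_and_threshold <- function(predictions, repress_threshold = 0.65,
                               negative_threshold = 0.20) {
  stopifnot(all(is.finite(predictions$p_repressed)))
  o <- order(-predictions$p_repressed, predictions$exon_id)
  out <- predictions[o, , drop = FALSE]
  out$call <- ifelse(out$p_repressed > repress_threshold, "predicted_repressed",
                     ifelse(out$p_repressed <= negative_threshold,
                            "predicted_unregulated", "intermediate"))
  attr(out, "fraction_repressed") <- mean(out$call == "predicted_repressed")
  rownames(out) <- NULL
  out
}

#' Binned response analysis
#'
#' Bins a per-exon scalar (feature or probability), reports the mean
#' response per bin with counts, and one-tailed Student's t-tests between
#' adjacent non-empty bins (alternative: the right bin's mean is greater).
#'
#' @param x per-exon scalar.
#' @param y per-exon response (binary 0/1 or dPSI).
#' @param edges bin edges (left-open, right-closed except the first bin).
#' @return list(bins = data.frame(bin, lo, hi, n, mean_response),
#'   tests = data.frame(bin_left, bin_right, p_value)).
#' @export
binned_response <- function(x, y, edges) {
  stopifnot(length(x) == length(y), length(edges) >= 2)
  b <- cut(x, breaks = edges, include.lowest = TRUE)
  n <- as.integer(table(b))
  if (all(n == 0)) stopf("no non-empty bins")
  means <- tapply(y, b, mean)
  bins <- data.frame(bin = levels(b), lo = edges[-length(edges)],
                     hi = edges[-1], n = n,
                     mean_response = as.numeric(means), row.names = NULL,
                     stringsAsFactors = FALSE)
  nonempty <- which(bins$n > 0)
  tests <- NULL
  if (length(nonempty) >= 2) {
    pairs <- cbind(nonempty[-length(nonempty)], nonempty[-1])
    tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      yi <- y[!is.na(b) & as.integer(b) == i]
      yj <- y[!is.na(b) & as.integer(b) == j]
      p <- if (length(yi) >= 2 && length(yj) >= 2 &&
                 (stats::sd(yi) > 0 || stats::sd(yj) > 0))
        stats::t.test(yj, yi, alternative = "greater")$p.value else NA_real_
      data.frame(bin_left = bins$bin[i], bin_right = bins$bin[j], p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(bins = bins, tests = tests)
}

# --- serialization ---------------------------------------------------------

#' Serialize a regulation model to JSON
#'
#' @param model a \code{ptb_logit}.
#' @param path output path.
#' @param ref_stats optional standardization reference (data.frame).
#' @param thresholds decision thresholds recorded with the model.
#' @export
write_regulation_model_json <- function(model, path, ref_stats = NULL,
                                        thresholds = c(repress = 0.65,
                                                       negative = 0.20)) {
  doc <- list(baseline = "non_regulated",
              features = model$features,
              coefficients = list(
                repressed = as.list(model$coefficients["repressed", ]),
                enhanced = as.list(model$coefficients["enhanced", ])),
              se = list(repressed = as.list(model$se["repressed", ]),
                        enhanced = as.list(model$se["enhanced", ])),
              loglik = model$loglik, aic = model$aic, n = model$n,
              separated = model$separated, ridge = model$ridge,
              thresholds = as.list(thresholds),
              reference_stats = ref_stats)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized regulation model
#'
#' @param path JSON path written by [write_regulation_model_json()].
#' @return a \code{ptb_logit} (without Wald tables).
#' @export
read_regulation_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- names(doc$coefficients$repressed)
  B <- rbind(repressed = unlist(doc$coefficients$repressed),
             enhanced = unlist(doc$coefficients$enhanced))
  colnames(B) <- cn
  se <- rbind(repressed = unlist(doc$se$repressed),
              enhanced = unlist(doc$se$enhanced))
  structure(list(coefficients = B, se = se, features = doc$features,
                 loglik = doc$loglik, aic = doc$aic, n = doc$n,
                 converged = TRUE, separated = isTRUE(doc$separated),
                 ridge = doc$ridge %||% 0,
                 thresholds = unlist(doc$thresholds),
                 reference_stats = doc$reference_stats),
            class = "ptb_logit")
}
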