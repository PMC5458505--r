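#' Iterative variance-inflation-factor pruning
#'
#' Computes VIF_j = 1/(1 - R^2_j) from regressing each feature on the
#' others and repeatedly removes the feature with the largest VIF while the
#' maximum exceeds \code{cutoff}. Zero-variance features are removed first
#' (they carry no information and have no defined VIF). Under perfect
#' collinearity (infinite VIF) the involved feature with the larger column
#' index is removed first.
#'
#' @param X Numeric feature matrix or data frame.
#' @param cutoff VIF threshold (default 10).
#' @return Character vector of surviving feature names.
#' @export
prune_collinear_vif <- function(X, cutoff = 10) {
  X <- as.data.frame(X)
  keep <- names(X)[vapply(X, function(v) stats::var(v) > 0, logical(1))]
  while (length(keep) > 1) {
    vifs <- vapply(seq_along(keep), function(j) {
      # exact collinearity gives a perfect fit by construction
      r2 <- suppressWarnings(
        summary(stats::lm(X[[keep[j]]] ~ .,
                          data = X[keep[-j]]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    mx <- max(vifs)
    if (mx <= cutoff) break
    worst <- max(which(vifs >= mx - 1e-9))   # tie-break: larger index first
    keep <- keep[-worst]
  }
  keep
}

# ridge-penalized logistic regression (Newton iterations); fallback for
# complete separation where the ML estimate diverges
ridge_logistic <- function(X, y, lambda = 0.05, max_iter = 100) {
  Xm <- as.matrix(X)
  mu <- colMeans(Xm)
  sc <- apply(Xm, 2, stats::sd)
  sc[sc == 0] <- 1
  Xs <- sweep(sweep(Xm, 2, mu), 2, sc, "/")   # penalty on standardized scale
  Xd <- cbind(1, Xs)
  beta <- numeric(ncol(Xd))
  pen <- diag(c(0, rep(lambda, ncol(Xd) - 1)))
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  b <- beta[-1] / sc
  stats::setNames(c(beta[1] - sum(b * mu), b),
                  c("(Intercept)", colnames(X)))
}

glm_has_separation <- function(fit) {
  p <- stats::fitted(fit)
  any(p > 1 - 1e-8) || any(p < 1e-8)
}

#' Bidirectional stepwise logistic model selection by AIC
#'
#' Fits the full logistic model on the (VIF-pruned) features and applies
#' bidirectional stepwise selection minimising AIC, starting from the full
#' model. Deterministic given the data. Under complete separation the
#' selected model is refitted with a small ridge penalty and a warning is
#' issued.
#'
#' @param X Feature matrix or data frame (VIF-pruned).
#' @param y Binary labels (0/1), both classes present.
#' @return List with \code{features} (selected names, possibly empty for an
#'   intercept-only model), \code{coef} (named coefficients including
#'   intercept), \code{aic}, and \code{ridged} flag.
#' @export
stepwise_select_aic <- function(X, y) {
  X <- as.data.frame(X)
  if (length(unique(y)) < 2) stop("both classes must be present")
  df <- cbind(data.frame(.y = y), X)
  env <- new.env(parent = environment())
  assign("df", df, envir = env)
  full <- suppressWarnings(
    eval(quote(stats::glm(.y ~ ., family = stats::binomial(), data = df)),
         env))
  sel <- suppressWarnings(
    MASS::stepAIC(full, direction = "both",
                  scope = list(lower = stats::as.formula(".y ~ 1")),
                  trace = 0))
  feats <- setdiff(all.vars(stats::formula(sel))[-1], ".y")
  ridged <- FALSE
  if (length(feats) && glm_has_separation(sel)) {
    warning("complete separation: refitting selected model with a small ",
            "ridge penalty")
    co <- ridge_logistic(X[feats], y)
    ridged <- TRUE
  } else {
    co <- stats::coef(sel)
  }
  list(features = feats, coef = co, aic = stats::AIC(sel), ridged = ridged)
}

#' Bootstrap stability of the stepwise selection
#'
#' Reruns the stepwise AIC selection on bootstrap resamples of the rows and
#' reports the selection frequency of each feature. Resamples containing a
#' single class are redrawn (at most 100 retries each).
#'
#' @param X Feature matrix or data frame (VIF-pruned).
#' @param y Binary labels.
#' @param n_boot Number of resamples (>= 1).
#' @param seed RNG seed.
#' @return Named numeric vector of per-feature selection frequencies.
#' @export
bootstrap_stability <- function(X, y, n_boot = 100, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  X <- as.data.frame(X)
  set.seed(seed)
  counts <- stats::setNames(numeric(ncol(X)), names(X))
  n <- nrow(X)
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      if (try == 100) stop("could not draw a two-class resample")
    }
    sel <- suppressWarnings(stepwise_select_aic(X[idx, , drop = FALSE], y[idx]))
    counts[sel$features] <- counts[sel$features] + 1
  }
  counts / n_boot
}

#' Leave-one-out predicted probabilities
#'
#' Refits the logistic model on the selected features leaving each
#' observation out in turn and predicts its probability.
#'
#' @param X Feature data frame.
#' @param y Binary labels.
#' @param features Selected feature names (may be empty: intercept only).
#' @return Numeric vector of LOO probabilities.
#' @export
loo_probabilities <- function(X, y, features) {
  X <- as.data.frame(X)[features]
  n <- length(y)
  vapply(seq_len(n), function(i) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) return(mean(yi))
    if (length(features)) {
      df <- cbind(data.frame(.y = yi), X[-i, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(.y ~ ., stats::binomial(), data = df))
      if (glm_has_separation(fit)) {
        beta <- ridge_logistic(X[-i, , drop = FALSE], yi)
        stats::plogis(sum(beta * c(1, as.numeric(X[i, ]))))
      } else {
        as.numeric(stats::predict(fit, newdata = X[i, , drop = FALSE],
                                  type = "response"))
      }
    } else mean(yi)
  }, numeric(1))
}

#' Probability threshold equalising the printed error rates
#'
#' Scans thresholds from 0 to 1 on a 0.5% grid and returns the one
#' minimising |FPR - FNR| on the supplied (typically leave-one-out)
#' probabilities, with FNR = FN/(TP+FN) and, under the default
#' \code{"paper"} convention, FPR = FP/(FP+FN) (as printed in the source
#' method description); \code{"standard"} uses FP/(FP+TN). Rates with a
#' zero denominator are taken as 0. Ties are broken toward the lower
#' threshold. If all probabilities are equal the threshold is 0.5, with a
#' warning.
#'
#' @param prob Predicted probabilities (e.g. from
#'   \code{\link{loo_probabilities}}).
#' @param y Binary labels.
#' @param grid_step Threshold grid resolution (default 0.005).
#' @param fpr_convention \code{"paper"} or \code{"standard"}.
#' @return List with \code{prob_threshold}, \code{fpr}, \code{fnr}.
#' @export
choose_probability_threshold <- function(prob, y, grid_step = 0.005,
                                         fpr_convention = c("paper",
                                                            "standard")) {
  fpr_convention <- match.arg(fpr_convention)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(prob)) == 1L) {
    warning("degenerate probabilities: returning threshold 0.5")
    return(list(prob_threshold = 0.5, fpr = NA_real_, fnr = NA_real_))
  }
  grid <- seq(0, 1, by = grid_step)
  rate <- function(num, den) if (den == 0) 0 else num / den
  best <- NULL
  for (th in grid) {
    pred <- as.integer(prob >= th)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
    fpr <- if (fpr_convention == "paper") rate(fp, fp + fn) else
      rate(fp, fp + tn)
    fnr <- rate(fn, tp + fn)
    d <- abs(fpr - fnr)
    if (is.null(best) || d < best$d - 1e-12) {
      best <- list(prob_threshold = th, fpr = fpr, fnr = fnr, d = d)
    }
  }
  best$d <- NULL
  best
}

#' Train a per-channel spindle classifier
#'
#' The current spindle detection method's second step, fit per channel:
#' derives the candidate threshold from the smallest manual-mark amplitude,
#' locates candidate epochs, extracts the 15 features, prunes collinear
#' features by VIF, selects a logistic model by bidirectional stepwise AIC,
#' optionally assesses selection stability by bootstrap, and sets the
#' probability cutoff by leave-one-out cross-validation equalising the
#' false-positive and false-negative rates.
#'
#' @param rec A \code{\link{recording}}.
#' @param channel Channel name.
#' @param marks Manual spindle marks for this channel (onset_s, offset_s).
#' @param mark_periods Intervals of exhaustively marked time.
#' @param n_boot Bootstrap replicates for the stability analysis (0 = skip).
#' @param fpr_convention Passed to
#'   \code{\link{choose_probability_threshold}}.
#' @param seed Seed for the bootstrap.
#' @return An object of class \code{spindle_classifier}.
#' @export
spindle_classifier <- function(rec, channel, marks, mark_periods,
                               n_boot = 0, fpr_convention = "paper",
                               seed = 1L) {
  stopifnot(inherits(rec, "ctc_recording"), channel %in% rec$channels)
  x <- rec$data[, channel]
  envs <- compute_envelopes(x, rec$rate_hz)
  thr <- candidate_threshold_from_marks(envs$amplitude, rec$rate_hz, marks,
                                        rec$t0_s)
  cands <- find_candidate_epochs(envs$edge, envs$amplitude, rec$rate_hz, thr,
                                 rec$t0_s)
  lab <- label_candidates(cands, marks, mark_periods)
  if (nrow(rec$exclusions)) {
    # excluded (artifact/epileptic) time was never marked: no labels there
    for (i in seq_len(nrow(rec$exclusions))) {
      lab[cands$onset_s <= rec$exclusions$offset_s[i] &
            cands$offset_s >= rec$exclusions$onset_s[i]] <- NA_integer_
    }
  }
  train <- which(!is.na(lab))
  if (length(unique(lab[train])) < 2) {
    stop("training data must contain both spindle and non-spindle candidates")
  }
  feats <- extract_features(cands[train, ], x, rec$rate_hz, rec$stages,
                            envs, rec$t0_s)
  surviving <- prune_collinear_vif(feats)
  sel <- stepwise_select_aic(feats[surviving], lab[train])
  boot_freq <- if (n_boot > 0) {
    bootstrap_stability(feats[surviving], lab[train], n_boot, seed)
  } else NULL
  loo <- loo_probabilities(feats[surviving], lab[train], sel$features)
  th <- choose_probability_threshold(loo, lab[train],
                                     fpr_convention = fpr_convention)
  structure(list(channel = channel, candidate_threshold = thr,
                 vif_surviving = surviving, selected_features = sel$features,
                 coefficients = sel$coef, ridged = sel$ridged,
                 prob_threshold = th$prob_threshold,
                 loo_fpr = th$fpr, loo_fnr = th$fnr,
                 bootstrap_selection_freq = boot_freq,
                 n_train = length(train), n_positive = sum(lab[train] == 1),
                 fpr_convention = fpr_convention),
            class = "spindle_classifier")
}

#' @export
print.spindle_classifier <- function(x, ...) {
  cat(sprintf("<spindle_classifier> channel %s\n", x$channel))
  cat(sprintf("  candidate threshold: %.3g; probability cutoff: %.3f\n",
              x$candidate_threshold, x$prob_threshold))
  cat("  features:", if (length(x$selected_features))
    paste(x$selected_features, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  trained on %d candidates (%d spindles)\n",
              x$n_train, x$n_positive))
  invisible(x)
}

#' @export
summary.spindle_classifier <- function(object, ...) {
  print(object)
  cat("  coefficients:\n")
  print(round(object$coefficients, 4))
  if (!is.null(object$bootstrap_selection_freq)) {
    cat("  bootstrap selection frequency:\n")
    print(round(object$bootstrap_selection_freq, 3))
  }
  cat(sprintf("  LOO rates at cutoff: FPR %.3f, FNR %.3f (%s convention)\n",
              object$loo_fpr, object$loo_fnr, object$fpr_convention))
  invisible(object)
}

#' @export
coef.spindle_classifier <- function(object, ...) object$coefficients

#' Predict spindle probabilities for candidate features
#'
#' @param object A \code{spindle_classifier}.
#' @param newdata Data frame of candidate features
#'   (\code{\link{extract_features}} columns).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.spindle_classifier <- function(object, newdata, ...) {
  co <- object$coefficients
  feats <- setdiff(names(co), "(Intercept)")
  eta <- co["(Intercept)"] +
    as.matrix(as.data.frame(newdata)[feats]) %*% co[feats]
  stats::plogis(drop(eta))
}

#' Apply a trained classifier to a channel
#'
#' Scores every candidate epoch of the channel, keeps candidates with
#' probability >= the classifier's cutoff, then removes events outside
#' N2/N3 or touching an exclusion interval, and finally applies artifact
#' rejection on epochs from -2 to +4 s around each spindle start.
#'
#' @param clf A \code{\link{spindle_classifier}}.
#' @param rec A \code{\link{recording}}.
#' @return Data frame of spindle events: channel, onset_s, offset_s,
#'   peak_amp, spindle_freq, class (\code{"slow"} for >10 and <= 12 Hz,
#'   \code{"fast"} for > 12 Hz), probability, method = "current".
#' @export
apply_classifier <- function(clf, rec) {
  stopifnot(inherits(clf, "spindle_classifier"),
            clf$channel %in% rec$channels)
  x <- rec$data[, clf$channel]
  envs <- compute_envelopes(x, rec$rate_hz)
  cands <- find_candidate_epochs(envs$edge, envs$amplitude, rec$rate_hz,
                                 clf$candidate_threshold, rec$t0_s)
  empty <- data.frame(channel = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), peak_amp = numeric(0),
                      spindle_freq = numeric(0), class = character(0),
                      probability = numeric(0), method = character(0))
  if (!nrow(cands)) return(empty)
  feats <- extract_features(cands, x, rec$rate_hz, rec$stages, envs, rec$t0_s)
  prob <- predict(clf, feats)
  keep <- prob >= clf$prob_threshold
  cands <- cands[keep, , drop = FALSE]
  feats <- feats[keep, , drop = FALSE]
  prob <- prob[keep]
  if (!nrow(cands)) return(empty)
  in_stage <- !is.na(stage_of_time(cands$onset_s, rec$stages)) &
    !is.na(stage_of_time(cands$offset_s, rec$stages))
  touches_excl <- rep(FALSE, nrow(cands))
  if (nrow(rec$exclusions)) {
    for (i in seq_len(nrow(rec$exclusions))) {
      touches_excl <- touches_excl |
        (cands$onset_s <= rec$exclusions$offset_s[i] &
           cands$offset_s >= rec$exclusions$onset_s[i])
    }
  }
  keep <- in_stage & !touches_excl
  ev <- data.frame(channel = clf$channel, onset_s = cands$onset_s[keep],
                   offset_s = cands$offset_s[keep],
                   peak_amp = cands$amp_env_peak[keep],
                   spindle_freq = feats$spindle_freq[keep],
                   probability = prob[keep], method = "current")
  ev$class <- ifelse(ev$spindle_freq <= 12, "slow", "fast")
  ev <- reject_artifact_events(ev, x, rec$rate_hz, epoch_s = c(-2, 4),
                               anchor = "onset_s", pool_anchors = cands$onset_s)
  ev[, c("channel", "onset_s", "offset_s", "peak_amp", "spindle_freq",
         "class", "probability", "method")]
}

#' Detect spindles on all channels with the envelope-threshold method
#'
#' Applies \code{\link{previous_method_detect}} per channel with the
#' region-appropriate threshold, restricts events to N2/N3 outside
#' exclusions, and applies the same post hoc artifact rejection as the
#' current method.
#'
#' @param rec A \code{\link{recording}}.
#' @return Data frame of spindle events (method = "previous").
#' @export
detect_spindles_threshold <- function(rec) {
  out <- list()
  for (j in seq_along(rec$channels)) {
    ev <- previous_method_detect(rec$data[, j], rec$rate_hz,
                                 rec$regions[j], rec$t0_s)
    if (!nrow(ev)) next
    keep <- !is.na(stage_of_time(ev$onset_s, rec$stages)) &
      !in_any_interval(ev$onset_s, rec$exclusions)
    ev <- ev[keep, , drop = FALSE]
    ev <- reject_artifact_events(ev, rec$data[, j], rec$rate_hz,
                                 epoch_s = c(-2, 4), anchor = "onset_s")
    if (!nrow(ev)) next
    ev$channel <- rec$channels[j]
    ev$class <- NA_character_
    ev$probability <- NA_real_
    out[[rec$channels[j]]] <- ev[, c("channel", "onset_s", "offset_s",
                                     "peak_amp", "spindle_freq", "class",
                                     "probability", "method")]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(channel = character(0), onset_s = numeric(0),
               offset_s = numeric(0), peak_amp = numeric(0),
               spindle_freq = numeric(0), class = character(0),
               probability = numeric(0), method = character(0))
  rownames(res) <- NULL
  res
}
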