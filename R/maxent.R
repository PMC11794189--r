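#' Sample background points from a raster stack
#'
#' Uniform sample of unmasked cell centers without replacement — the
#' "available environment" reference set of presence-background
#' modelling. If `n` exceeds the number of unmasked cells, all cells
#' are returned.
#'
#' @param stack a [raster_stack()].
#' @param n number of background points (default 10000, the
#'   conventional cap).
#' @param seed integer seed.
#' @return A tibble with `lon`, `lat` of sampled cell centers.
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  stopifnot(inherits(stack, "raster_stack"), n >= 1)
  cc <- as_tibble.raster_stack(stack)
  if (nrow(cc) == 0) stop("stack is fully masked", call. = FALSE)
  set.seed(as.integer(seed))
  k <- min(n, nrow(cc))
  idx <- sample.int(nrow(cc), k)
  cc[sort(idx), c("lon", "lat")]
}

# Per-feature-class regularization scale beta_fc(m): piecewise-linear
# interpolation in presence count m for L/Q/P, constant for hinges.
beta_fc_default <- function(class, m) {
  lqp <- stats::approx(x = c(10, 30, 100, 200), y = c(1.0, 0.6, 0.3, 0.15),
                       xout = min(max(m, 10), 200), rule = 2)$y
  ifelse(class == "H", 0.5, lqp)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit an L1-penalized maximum-entropy model
#'
#' Maximizes the penalized Gibbs log-likelihood
#' `l(beta) = mean_presence(eta) - log Z(beta) - sum_j lambda_j |beta_j|`
#' where `eta = X beta`, `Z = sum_background exp(eta)` and
#' `lambda_j = rm * beta_fc(m) * s_j / sqrt(m)` with `m` the presence
#' count and `s_j` the presence standard deviation of feature `j`.
#' Optimization is cyclic coordinate descent with soft-thresholded
#' Newton steps and backtracking, so the penalized objective is
#' non-decreasing across updates; it terminates when the relative
#' objective change over a full cycle drops below `tolerance` or at
#' `max_iterations` cycles.
#'
#' @param presence_features,background_features numeric feature matrices
#'   (rows = points) or lists from [build_features()].
#' @param rm regularization multiplier (> 0); larger values give
#'   sparser, smoother models.
#' @param max_iterations cap on coordinate-descent cycles.
#' @param tolerance relative objective-change stopping criterion.
#' @param beta_fc function `(class, m) -> scale` for the per-class
#'   regularization lookup; default [beta_fc_default].
#' @param max_step cap on a single coordinate update. Small steps make
#'   updates interleave across competing features, which keeps the
#'   per-feature gain attribution (the basis of
#'   [variable_contributions()]) close to symmetric for collinear
#'   variables; the objective optimum is unaffected.
#' @return An object of class `maxent_model`: coefficients, penalties,
#'   normalizer `log Z`, raw-distribution entropy `H_raw`, training
#'   gain, per-feature objective-gain increments, convergence info and
#'   (when built from [build_features()] output) the frozen feature
#'   spec.
#' @export
fit_maxent <- function(presence_features, background_features, rm = 1,
                       max_iterations = 500, tolerance = 1e-5,
                       beta_fc = beta_fc_default, max_step = 0.25) {
  spec <- NULL
  if (is.list(presence_features) && !is.null(presence_features$X)) {
    spec <- presence_features$spec
    presence_features <- presence_features$X
  }
  if (is.list(background_features) && !is.null(background_features$X))
    background_features <- background_features$X
  Xp <- as.matrix(presence_features)
  Xb <- as.matrix(background_features)
  stopifnot(nrow(Xp) >= 1, nrow(Xb) >= 2, ncol(Xp) == ncol(Xb), rm > 0)
  m <- nrow(Xp); nb <- nrow(Xb); J <- ncol(Xp)
  classes <- if (!is.null(spec)) spec$features$class
             else substr(colnames(Xp) %||% rep("L", J), 1, 1)
  classes[!classes %in% c("L", "Q", "H", "P")] <- "L"
  s_j <- apply(Xp, 2, stats::sd)
  if (m == 1) s_j[] <- 0
  lambda <- rm * beta_fc(classes, m) * s_j / sqrt(m)
  updatable <- s_j > 0
  fbar <- colMeans(Xp)

  beta <- numeric(J)
  eta_b <- numeric(nb)
  mean_eta_p <- 0
  logZ <- log(nb)
  pen_obj <- function(me, lz, b) me - lz - sum(lambda * abs(b))
  obj <- pen_obj(mean_eta_p, logZ, beta)
  obj_trace <- obj
  gain_inc <- numeric(J)
  converged <- FALSE
  iter <- 0

  while (iter < max_iterations) {
    iter <- iter + 1
    obj_prev <- obj
    for (j in which(updatable)) {
      xj <- Xb[, j]
      w <- exp(eta_b - logZ)
      Ef <- sum(w * xj)
      h <- sum(w * xj^2) - Ef^2
      g <- fbar[j] - Ef
      h <- max(h, 1e-8)
      target <- beta[j] + g / h
      prop <- sign(target) * max(abs(target) - lambda[j] / h, 0)
      d <- prop - beta[j]
      if (d == 0) next
      d <- sign(d) * min(abs(d), max_step)
      accepted <- FALSE
      for (half in 1:20) {
        eta_new <- eta_b + d * xj
        logZ_new <- log_sum_exp(eta_new)
        me_new <- mean_eta_p + d * fbar[j]
        b_new <- beta
        b_new[j] <- beta[j] + d
        obj_new <- pen_obj(me_new, logZ_new, b_new)
        if (obj_new > obj) {
          gain_inc[j] <- gain_inc[j] + (obj_new - obj)
          eta_b <- eta_new; logZ <- logZ_new
          mean_eta_p <- me_new; beta <- b_new; obj <- obj_new
          accepted <- TRUE
          break
        }
        d <- d / 2
      }
      if (!accepted) next
    }
    obj_trace <- c(obj_trace, obj)
    if (abs(obj - obj_prev) <= tolerance * (abs(obj_prev) + tolerance)) {
      converged <- TRUE
      break
    }
  }

  raw_b <- exp(eta_b - logZ)
  H_raw <- -sum(raw_b * log(pmax(raw_b, 1e-300)))
  structure(list(
    beta = stats::setNames(beta, colnames(Xp)),
    lambda = lambda, classes = classes, spec = spec,
    rm = rm, fc_set = if (!is.null(spec)) spec$fc_set else unique(classes),
    logZ = logZ, H_raw = H_raw,
    n_presence = m, n_background = nb,
    training_gain = mean_eta_p - logZ + log(nb),
    log_lik = m * (mean_eta_p - logZ),
    gain_increments = stats::setNames(gain_inc, colnames(Xp)),
    obj_trace = obj_trace, converged = converged, iterations = iter),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d feature(s), %d nonzero, rm = %.2g\n",
              length(x$beta), sum(abs(x$beta) > 1e-8), x$rm))
  cat(sprintf("  presences: %d, background: %d\n", x$n_presence,
              x$n_background))
  cat(sprintf("  training gain: %.4f, entropy: %.4f%s\n", x$training_gain,
              x$H_raw, if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

model_eta <- function(model, features) {
  if (is.data.frame(features)) {
    if (is.null(model$spec))
      stop("model carries no feature spec; supply a feature matrix",
           call. = FALSE)
    features <- build_features(features, spec = model$spec)$X
  } else if (is.list(features) && !is.null(features$X)) {
    features <- features$X
  }
  features <- as.matrix(features)
  if (ncol(features) != length(model$beta))
    stop("feature/coefficient length mismatch: ", ncol(features), " vs ",
         length(model$beta), call. = FALSE)
  drop(features %*% model$beta)
}

#' Predict from a maximum-entropy model
#'
#' `predict_raw()` returns the Gibbs density `exp(eta(x)) / Z` relative
#' to the model's background normalizer (the raw values sum to 1 over
#' the training background). `predict_cloglog()` returns the
#' complementary log-log transform
#' `1 - exp(-exp(H_raw) * raw(x))`, a strictly increasing map of raw
#' into `[0, 1]` using the raw distribution's entropy `H_raw`; a model
#' with uniform raw output gives `1 - exp(-1)` everywhere.
#'
#' @param model a `maxent_model`.
#' @param features a feature matrix conforming to the model's spec, a
#'   [build_features()] result, or a raw value table (expanded through
#'   the model's frozen spec).
#' @return Numeric vector: nonnegative raw densities, or cloglog values
#'   in `[0, 1]`.
#' @export
predict_raw <- function(model, features) {
  stopifnot(inherits(model, "maxent_model"))
  exp(model_eta(model, features) - model$logZ)
}

#' @rdname predict_raw
#' @export
predict_cloglog <- function(model, features) {
  1 - exp(-exp(model$H_raw) * predict_raw(model, features))
}

#' Presence-background AUC by rank statistic
#'
#' `AUC = P(score_presence > score_background) + 0.5 P(equal)`,
#' computed from the Wilcoxon rank sum; invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  stopifnot(np >= 1, nb >= 1)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}
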