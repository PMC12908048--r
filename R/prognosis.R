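# Prognostic modelling: univariate screening, logistic regression with a
# ridge fallback under separation, rank-based AUC, and bootstrap optimism
# correction of the apparent AUC (Harrell's internal-validation procedure).

# Maximum-likelihood logistic fit on a design matrix with intercept.
# Detects complete separation via fitted probabilities pinned to the labels.
logit_core <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  p_hat <- fit$fitted.values
  separated <- all(abs(y - p_hat) < 1e-7)
  list(coef = fit$coefficients, fitted = p_hat,
       converged = fit$converged, separated = separated)
}

# Ridge-penalised logistic regression by IRLS; penalty lambda on the
# sum-log-likelihood scale, intercept unpenalised.
ridge_logit_core <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, X * w) + pen, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(coef = beta, fitted = stats::plogis(drop(X %*% beta)),
       converged = TRUE, separated = FALSE)
}

logit_wald <- function(X, core) {
  w <- pmax(core$fitted * (1 - core$fitted), 1e-12)
  cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(se = rep(NA_real_, ncol(X)), p = rep(NA_real_, ncol(X))))
  }
  se <- sqrt(pmax(diag(cov), 0))
  z <- core$coef / se
  list(se = se, p = 2 * pnorm(-abs(z)))
}

build_design <- function(data, predictors) {
  n <- nrow(data)
  X <- matrix(1, n, 1)
  if (length(predictors)) {
    X <- cbind(X, vapply(predictors, function(v) as.numeric(data[[v]]),
                         numeric(n)))
  }
  colnames(X) <- c("(Intercept)", predictors)
  X
}

check_outcome <- function(y) {
  y <- as.numeric(y)
  assert_that(!anyNA(y) && all(y %in% c(0, 1)), "outcome must be binary 0/1")
  assert_that(length(unique(y)) == 2, "outcome has a single class")
  y
}

# single-covariate Wald p-values; separation => p 0 (flagged), zero-variance
# predictors skipped with a note
screen_core <- function(data, outcome, candidates, screen_alpha) {
  y <- check_outcome(data[[outcome]])
  purrr::map(candidates, function(v) {
    x <- as.numeric(data[[v]])
    if (anyNA(x)) {
      keep <- !is.na(x)
      x <- x[keep]
      yy <- y[keep]
    } else {
      yy <- y
    }
    if (var(x) == 0 || length(unique(yy)) < 2) {
      return(tibble(predictor = v, estimate = NA_real_, p_value = NA_real_,
                    selected = FALSE, note = "zero variance (skipped)"))
    }
    X <- cbind(1, x)
    core <- logit_core(X, yy)
    if (core$separated) {
      return(tibble(predictor = v, estimate = unname(core$coef[2]),
                    p_value = 0, selected = TRUE, note = "complete separation"))
    }
    p <- unname(logit_wald(X, core)$p[2])
    tibble(predictor = v, estimate = unname(core$coef[2]), p_value = p,
           selected = !is.na(p) && p < screen_alpha, note = NA_character_)
  }) |> list_rbind()
}

#' Univariate predictor screening for the prognostic model
#'
#' Fits a single-covariate logistic model per candidate and keeps predictors
#' whose Wald p-value is below `screen_alpha` (default 0.10, the
#' include-in-multivariable threshold), preserving the candidate order.
#' Zero-variance predictors are skipped with a note; completely separating
#' predictors are flagged and selected.
#'
#' @param data Data frame with the outcome and candidate columns.
#' @param outcome Name of the binary 0/1 outcome column.
#' @param candidates Character vector of candidate predictor names.
#' @param screen_alpha Selection threshold on the univariate p (default 0.10).
#' @return Tibble: `predictor`, `estimate`, `p_value`, `selected`, `note`.
#' @export
univariate_screen <- function(data, outcome, candidates, screen_alpha = 0.10) {
  data <- as_tibble(data)
  assert_that(outcome %in% names(data), "outcome column '%s' not found", outcome)
  assert_that(!(outcome %in% candidates), "outcome cannot be a candidate predictor")
  assert_that(all(candidates %in% names(data)), "candidate column '%s' not found",
              setdiff(candidates, names(data))[1])
  assert_that(screen_alpha > 0 && screen_alpha <= 1,
              "screen_alpha must be in (0, 1]")
  y <- check_outcome(data[[outcome]])
  assert_that(sum(y == 1) >= 10, "fewer than 10 events")
  screen_core(data, outcome, candidates, screen_alpha)
}

#' Multivariable logistic regression with a ridge fallback
#'
#' Maximum-likelihood logistic fit of a binary outcome on the given
#' predictors. Under complete separation, the fit falls back automatically to
#' ridge-penalised logistic regression with `lambda = 0.01 * n` (intercept
#' unpenalised) and the result is flagged `penalized = TRUE`.
#'
#' @inheritParams univariate_screen
#' @param predictors Character vector of predictor names (may be empty for an
#'   intercept-only model).
#' @param penalty `"none"` (default; ML with automatic ridge fallback) or
#'   `"ridge"` to force the penalised fit.
#' @param lambda Ridge penalty; defaults to `0.01 * n`.
#' @return Object of class `prognosis_fit` with a `coefficients` tibble
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`, `conf_low`,
#'   `conf_high`), flags `converged` / `penalized`, and enough state to
#'   [predict()] on new data.
#' @export
fit_logistic <- function(data, outcome, predictors, penalty = c("none", "ridge"),
                         lambda = NULL) {
  penalty <- match.arg(penalty)
  data <- as_tibble(data)
  y <- check_outcome(data[[outcome]])
  keep <- rep(TRUE, nrow(data))
  for (v in predictors) keep <- keep & !is.na(data[[v]])
  data <- data[keep, ]
  y <- y[keep]
  X <- build_design(data, predictors)
  lambda <- lambda %||% (0.01 * nrow(X))
  penalized <- penalty == "ridge"
  if (!penalized) {
    assert_that(nrow(X) > length(predictors) + 1,
                "need n > number of predictors + 1 for an unpenalised fit")
    core <- logit_core(X, y)
    if (core$separated || !core$converged || anyNA(core$coef)) {
      core <- ridge_logit_core(X, y, lambda)
      penalized <- TRUE
    }
  } else {
    core <- ridge_logit_core(X, y, lambda)
  }
  if (penalized) {
    coefs <- tibble(term = colnames(X), estimate = unname(core$coef),
                    std_error = NA_real_, statistic = NA_real_,
                    p_value = NA_real_, conf_low = NA_real_,
                    conf_high = NA_real_)
  } else {
    wd <- logit_wald(X, core)
    z975 <- qnorm(0.975)
    coefs <- tibble(term = colnames(X), estimate = unname(core$coef),
                    std_error = wd$se,
                    statistic = unname(core$coef) / wd$se,
                    p_value = wd$p,
                    conf_low = unname(core$coef) - z975 * wd$se,
                    conf_high = unname(core$coef) + z975 * wd$se)
  }
  structure(
    list(coefficients = coefs, outcome = outcome, predictors = predictors,
         converged = core$converged, penalized = penalized,
         lambda = if (penalized) lambda else NA_real_, n = nrow(X)),
    class = "prognosis_fit"
  )
}

#' @export
predict.prognosis_fit <- function(object, newdata, ...) {
  X <- build_design(as_tibble(newdata), object$predictors)
  drop(stats::plogis(X %*% object$coefficients$estimate))
}

#' @export
print.prognosis_fit <- function(x, ...) {
  cat("<prognosis_fit>", x$outcome, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
      if (x$penalized) sprintf(" [ridge, lambda = %.3g]", x$lambda) else "", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.prognosis_fit <- function(x, ...) x$coefficients

#' @export
glance.prognosis_fit <- function(x, ...) {
  tibble(n = x$n, n_predictors = length(x$predictors),
         converged = x$converged, penalized = x$penalized)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimator with mid-ranks for ties: the probability that a
#' random positive scores above a random negative (ties count one half).
#' Identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\]; 0.5 for uninformative (e.g., constant) scores.
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 1
#' @export
auc <- function(scores, labels) {
  labels <- check_outcome(labels)
  assert_that(length(scores) == length(labels) && !anyNA(scores),
              "scores and labels must match and be non-missing")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tibble(
    threshold = c(Inf, scores[ord]),
    tpr = c(0, cumsum(y) / sum(y)),
    fpr = c(0, cumsum(1 - y) / sum(1 - y))
  )
}

screen_and_fit <- function(data, outcome, candidates, screen_alpha) {
  sc <- screen_core(data, outcome, candidates, screen_alpha)
  sel <- sc$predictor[sc$selected]
  fit <- fit_logistic(data, outcome, sel)
  list(fit = fit, selected = sel, screen = sc)
}

# allocation-light kernels for the bootstrap loop (no NA support; the
# public entry points fall back to the tibble-based path when NAs exist)
boot_screen_idx <- function(M, y, screen_alpha) {
  keep <- integer(0)
  X <- cbind(1, 0)
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    if (var(x) == 0) next
    X <- cbind(1, x)
    core <- logit_core(X, y)
    if (core$separated) {
      keep <- c(keep, j)
    } else {
      p <- logit_wald(X, core)$p[2]
      if (!is.na(p) && p < screen_alpha) keep <- c(keep, j)
    }
  }
  keep
}

boot_fit_coef <- function(X, y) {
  core <- logit_core(X, y)
  if (core$separated || !core$converged || anyNA(core$coef)) {
    core <- ridge_logit_core(X, y, 0.01 * nrow(X))
  }
  core$coef
}

auc_fast <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap optimism-corrected AUC (internal validation)
#'
#' Harrell's procedure with the predictor screening repeated inside every
#' resample, so the optimism estimate covers the selection uncertainty as
#' well as the fitting: the apparent model is built by univariate screening
#' (p < `screen_alpha`) plus multivariable logistic fit on the full data; for
#' each of `n_boot` bootstrap resamples the screening and fit are redone on
#' the resample, the model's AUC is evaluated on the resample (`boot`) and on
#' the original data (`test`), and `optimism = mean(boot - test)`. The
#' corrected AUC is `apparent - optimism`, with a percentile confidence
#' interval over the per-replicate corrected values `apparent - optimism_b`.
#' Resamples missing one outcome class are redrawn (and counted). Fully
#' deterministic for a fixed seed.
#'
#' @inheritParams univariate_screen
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param conf_level Confidence level of the percentile interval (default 0.95).
#' @return Object of class `prognosis_result`: `selected`, `coefficients`
#'   (full-data fit), `apparent_auc`, `optimism`, `corrected_auc`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `n_redraws`, per-replicate
#'   `optimism_draws`, and ROC points of the apparent model.
#' @export
bootstrap_optimism <- function(data, outcome, candidates, screen_alpha = 0.10,
                               n_boot = 1000, seed = NULL, conf_level = 0.95) {
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  data <- as_tibble(data)
  y <- check_outcome(data[[outcome]])
  apparent <- screen_and_fit(data, outcome, candidates, screen_alpha)
  scores <- predict(apparent$fit, data)
  apparent_auc <- auc(scores, y)
  n <- nrow(data)
  M <- vapply(candidates, function(v) as.numeric(data[[v]]), numeric(n))
  fast <- !anyNA(M)
  res <- with_seed(seed, {
    n_redraws <- 0L
    opt <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (any(yb == 1) && any(yb == 0)) break
        n_redraws <- n_redraws + 1L
      }
      if (fast) {
        Mb <- M[idx, , drop = FALSE]
        sel <- boot_screen_idx(Mb, yb, screen_alpha)
        Xb <- cbind(1, Mb[, sel, drop = FALSE])
        beta <- boot_fit_coef(Xb, yb)
        boot_auc <- auc_fast(drop(Xb %*% beta), yb)
        test_auc <- auc_fast(drop(cbind(1, M[, sel, drop = FALSE]) %*% beta), y)
      } else {
        db <- data[idx, ]
        sf <- screen_and_fit(db, outcome, candidates, screen_alpha)
        boot_auc <- auc(predict(sf$fit, db), yb)
        test_auc <- auc(predict(sf$fit, data), y)
      }
      opt[b] <- boot_auc - test_auc
    }
    list(opt = opt, n_redraws = n_redraws)
  })
  optimism <- mean(res$opt)
  corrected <- apparent_auc - optimism
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(apparent_auc - res$opt, c(a, 1 - a)))
  structure(
    list(selected = apparent$selected, screen = apparent$screen,
         coefficients = apparent$fit$coefficients, fit = apparent$fit,
         apparent_auc = apparent_auc, optimism = optimism,
         corrected_auc = corrected, ci_low = ci[1], ci_high = ci[2],
         conf_level = conf_level, n_boot = n_boot, seed = seed,
         n_redraws = res$n_redraws, optimism_draws = res$opt,
         roc = roc_points(scores, y)),
    class = "prognosis_result"
  )
}

#' @export
print.prognosis_result <- function(x, ...) {
  cat("<prognosis_result>", length(x$selected), "selected predictor(s):",
      paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  apparent AUC %.3f, optimism %.3f, corrected AUC %.3f (%g%% CI %.3f-%.3f; %d resamples)\n",
              x$apparent_auc, x$optimism, x$corrected_auc,
              100 * x$conf_level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' @export
tidy.prognosis_result <- function(x, ...) x$coefficients

#' @export
glance.prognosis_result <- function(x, ...) {
  tibble(apparent_auc = x$apparent_auc, optimism = x$optimism,
         corrected_auc = x$corrected_auc, ci_low = x$ci_low,
         ci_high = x$ci_high, n_boot = x$n_boot,
         n_selected = length(x$selected), n_redraws = x$n_redraws)
}
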