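#' Fit an l2-penalized logistic mortality model
#'
#' Maximizes the penalized Bernoulli log-likelihood
#' `sum_i loglik_i - strength/2 * ||beta||^2` by Newton/IRLS iterations. The
#' penalty applies to the feature coefficients only, never the intercept
#' (matching the convention of common machine-learning implementations, whose
#' default corresponds to `strength = 1`). Deterministic given the data.
#'
#' @param x Numeric design matrix (rows = stays, columns = features), or a
#'   transformed cohort tibble (its [model_features()] columns are used).
#' @param y Binary outcome vector; both classes must be present.
#' @param strength Non-negative penalty strength (0 = unpenalized maximum
#'   likelihood).
#' @param preprocessor Optional `preprocessor_stats` the matrix was built
#'   with; stored for [predict_risk()].
#' @param max_iter,tol Newton iteration controls.
#' @return A `risk_model` object with `intercept`, `coefficients`,
#'   `regularization_strength`, and `preprocessor`.
#' @export
fit_risk_model <- function(x, y, strength = 1, preprocessor = NULL,
                           max_iter = 100L, tol = 1e-10) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  stopifnot(is.matrix(x), nrow(x) == length(y), strength >= 0)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("training outcomes contain a single class", call. = FALSE)
  }
  n <- nrow(x)
  p <- ncol(x)
  X <- cbind(`(intercept)` = 1, x)
  beta <- c(stats::qlogis(mean(y)), rep(0, p))
  pen <- diag(c(0, rep(strength, p)), p + 1)
  obj <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + strength / 2 * sum(b[-1]^2)
  }
  prev <- obj(beta)
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- as.numeric(crossprod(X, y - mu)) - c(0, strength * beta[-1])
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    # halve the step until the penalized objective improves
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      if (obj(cand) <= prev + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta_new <- beta + alpha * step
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    prev <- obj(beta)
    if (delta < tol) break
  }
  if (any(!is.finite(beta))) {
    stop("model fit produced non-finite coefficients", call. = FALSE)
  }
  structure(
    list(
      intercept = unname(beta[1]),
      coefficients = stats::setNames(beta[-1], colnames(x)),
      regularization_strength = strength,
      preprocessor = preprocessor,
      n_train = n,
      converged = delta < 1e-6
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> l2-penalized logistic regression\n")
  cat("  features:", length(x$coefficients),
      " strength:", x$regularization_strength,
      " n_train:", x$n_train, "\n")
  invisible(x)
}

#' Predict mortality risk
#'
#' Applies the model's frozen preprocessor (if any) and returns
#' `plogis(intercept + x %*% coefficients)` per row.
#'
#' @param model A `risk_model`.
#' @param table A cohort tibble (preprocessed through `model$preprocessor`
#'   when present) or a numeric matrix already on the model scale.
#' @return Numeric vector of risks in `(0, 1)`.
#' @export
predict_risk <- function(model, table) {
  stopifnot(inherits(model, "risk_model"))
  if (is.data.frame(table)) {
    if (!is.null(model$preprocessor)) {
      table <- transform_cohort(table, model$preprocessor)
    }
    x <- feature_matrix(table, names(model$coefficients))
  } else {
    x <- table
    if (ncol(x) != length(model$coefficients)) {
      stop("feature matrix does not match the model's coefficients",
           call. = FALSE)
    }
  }
  as.numeric(stats::plogis(model$intercept + x %*% model$coefficients))
}

#' Asymptotic standard errors of a fitted risk model
#'
#' Inverse observed Fisher information (including the penalty curvature) at
#' the fitted coefficients; used for coefficient-recovery checks.
#'
#' @param model A `risk_model`.
#' @param x The design matrix the model was fit on.
#' @return Named vector of standard errors (intercept first).
#' @export
risk_model_se <- function(model, x) {
  if (is.data.frame(x)) x <- feature_matrix(x, names(model$coefficients))
  X <- cbind(1, x)
  eta <- model$intercept + as.numeric(x %*% model$coefficients)
  mu <- stats::plogis(eta)
  pen <- diag(c(0, rep(model$regularization_strength, ncol(x))), ncol(X))
  info <- crossprod(X * (mu * (1 - mu)), X) + pen
  se <- sqrt(diag(solve(info)))
  stats::setNames(se, c("(intercept)", names(model$coefficients)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with one row per term (intercept included).
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    term = c("(intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$coefficients),
    regularization_strength = x$regularization_strength,
    n_train = x$n_train,
    converged = x$converged
  )
}
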