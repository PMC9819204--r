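#' @useDynLib mixbiome, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Draw random taxon subsets
#'
#' The random-subset variant of WQS estimates weights on many small random
#' subsets of the mixture components, which is what makes the method usable
#' when components (taxa) outnumber observations.
#'
#' @param p number of taxa in the mixture.
#' @param m subset size (1 <= m <= p).
#' @param B number of subsets.
#' @param seed integer seed; the draw is reproducible.
#' @return integer matrix, B x m; each row holds m distinct taxon indices.
#' @export
draw_random_subsets <- function(p, m, B, seed) {
  if (m < 1 || m > p) stop("subset size m must satisfy 1 <= m <= p")
  if (B < 1) stop("B must be >= 1")
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(B), function(b) sample.int(p, m), integer(m))
  # vapply returns a vector when m = 1 and an m x B matrix otherwise
  if (m == 1) matrix(draws, ncol = 1) else t(draws)
}

#' Signal-function value of a subset's t statistic
#'
#' Converts a subset fit's Wald t into the nonnegative averaging weight used
#' when pooling subset weights: `t2` (squared t, the conventional default),
#' `exp_t` (exp of |t|, a more severe emphasis), or `abs_t` (|t|, less
#' severe). `exp_t` clips |t| at 30 to avoid overflow (a warning reports
#' clipping).
#'
#' @param t numeric vector of t statistics (finite).
#' @param kind `"t2"`, `"exp_t"` or `"abs_t"`.
#' @return nonnegative numeric vector.
#' @export
signal_value <- function(t, kind = c("t2", "exp_t", "abs_t")) {
  kind <- match.arg(kind)
  if (any(!is.finite(t))) stop("t statistics must be finite")
  switch(kind,
    t2 = t^2,
    exp_t = {
      a <- abs(t)
      if (any(a > 30)) {
        warning(sum(a > 30), " t statistic(s) clipped at |t| = 30 for exp_t",
                call. = FALSE)
        a <- pmin(a, 30)
      }
      exp(a)
    },
    abs_t = abs(t))
}

#' Signal-weighted average of subset weights
#'
#' For each taxon, averages its estimated weight over the converged subsets
#' that contain it, using the signal function of each subset's t statistic
#' as the averaging weight; the resulting p-vector is renormalized to sum
#' to 1. Taxa that appear in no converged subset get weight 0 (with a
#' warning). With a constant signal this reduces to the plain per-taxon
#' mean, renormalized.
#'
#' @param fits list of subset fits from [estimate_subset_weights()].
#' @param p total number of taxa in the mixture.
#' @param kind signal function, see [signal_value()].
#' @return numeric p-vector on the simplex.
#' @export
signal_average <- function(fits, p, kind = c("t2", "exp_t", "abs_t")) {
  kind <- match.arg(kind)
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$t_stat),
                 logical(1))
  if (!any(conv)) stop("no converged subset fits to average")
  fits <- fits[conv]
  num <- numeric(p)
  den <- numeric(p)
  s <- signal_value(vapply(fits, `[[`, numeric(1), "t_stat"), kind)
  for (i in seq_along(fits)) {
    idx <- fits[[i]]$taxon_indices
    num[idx] <- num[idx] + s[i] * fits[[i]]$weights
    den[idx] <- den[idx] + s[i]
  }
  out <- numeric(p)
  seen <- den > 0
  if (!all(seen))
    warning(sum(!seen), " taxa appear in no converged subset; weight set to 0",
            call. = FALSE)
  out[seen] <- num[seen] / den[seen]
  out / sum(out)
}

#' Weighted quantile sum index
#'
#' The WQS index of each sample: the dot product of its quantile-score row
#' with the taxon weight vector. With scores in 0..L-1 and weights on the
#' simplex the index lies in \[0, L-1\].
#'
#' @param scores a `ranked_matrix` or an integer/numeric score matrix
#'   (samples x taxa).
#' @param weights numeric weight vector on the simplex, length = n taxa.
#' @return numeric per-sample index vector.
#' @export
build_index <- function(scores, weights) {
  sc <- if (inherits(scores, "ranked_matrix")) scores$scores else as.matrix(scores)
  if (ncol(sc) != length(weights))
    stop("dimension mismatch: ", ncol(sc), " taxa vs ", length(weights), " weights")
  drop(sc %*% weights)
}

## ---- subset-level constrained estimation ----------------------------------

# design matrix from a covariate data.frame (no intercept column)
.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(0, n, 0))
  if (is.data.frame(covariates)) {
    mm <- stats::model.matrix(~ ., data = covariates)
    X <- mm[, -1, drop = FALSE]
  } else {
    X <- as.matrix(covariates)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  X
}

.check_design_rank <- function(X) {
  M <- cbind(`(Intercept)` = 1, X)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    dropped <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

.dir_code <- function(direction) {
  switch(direction, positive = 1L, negative = -1L, unconstrained = 0L,
         stop("direction must be 'positive', 'negative' or 'unconstrained'"))
}

#' Estimate simplex-constrained weights on one taxon subset
#'
#' Maximizes the GLM likelihood of
#' \eqn{g(\mu) = \alpha + \beta_1 \sum_i w_i q_i + \delta Z}
#' jointly over the intercept, the index coefficient, covariate effects and
#' the weights, with the weights constrained to the simplex and optionally
#' the sign of \eqn{\beta_1} constrained. Internally the weights are
#' parameterized as a softmax of m-1 free reals and a sign-constrained
#' \eqn{\beta_1} as sign * exp(free real); optimization is quasi-Newton
#' (BFGS) with analytic gradients, an equal-weight start plus random
#' restarts. The returned t statistic is the Wald \eqn{\beta_1/SE} computed
#' from the observed information at the constrained optimum (weights held
#' fixed).
#'
#' @param scores numeric/integer score matrix restricted to the subset's
#'   taxa and the training samples (n x m).
#' @param outcome numeric outcome vector (0/1 for binomial).
#' @param covariates optional covariate data.frame or design matrix.
#' @param family `"binomial"` or `"gaussian"`.
#' @param direction `"positive"`, `"negative"` or `"unconstrained"`.
#' @param taxon_indices optional integer positions of these taxa in the full
#'   mixture (recorded in the fit for later averaging).
#' @param n_restarts total number of optimizer starts (1 equal-weight start
#'   plus `n_restarts - 1` random restarts; restarts draw from the current
#'   RNG stream).
#' @param maxit,reltol optimizer control.
#' @return a `subset_fit` list: `taxon_indices`, `weights` (simplex),
#'   `beta1`, `t_stat`, `alpha`, `delta`, `loglik`, `converged`.
#' @export
estimate_subset_weights <- function(scores, outcome, covariates = NULL,
                                    family = c("binomial", "gaussian"),
                                    direction = c("unconstrained", "positive",
                                                  "negative"),
                                    taxon_indices = seq_len(ncol(scores)),
                                    n_restarts = 3, maxit = 500,
                                    reltol = 1e-10) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  Q <- as.matrix(scores)
  storage.mode(Q) <- "double"
  y <- as.numeric(outcome)
  n <- length(y)
  if (nrow(Q) != n) stop("scores and outcome differ in length")
  if (anyNA(Q) || anyNA(y)) stop("missing data not allowed")
  if (length(unique(y)) < 2) stop("outcome is constant")
  X <- .covariate_matrix(covariates, n)
  .check_design_rank(X)
  m <- ncol(Q)
  k <- ncol(X)
  dir <- .dir_code(direction)
  fam <- if (family == "binomial") 0L else 1L

  # equal-weight start: ordinary GLM on the uniform index
  z0 <- rowMeans(Q)
  g0 <- stats::glm.fit(cbind(1, z0, X), y,
                       family = if (fam == 0L) stats::binomial() else stats::gaussian())
  cf <- unname(g0$coefficients)
  b_raw <- if (is.finite(cf[2])) cf[2] else 0
  b0 <- if (dir == 0L) b_raw else log(max(dir * b_raw, 0.05))
  start0 <- c(cf[1], b0, if (k) cf[3:(2 + k)] else numeric(0), rep(0, m - 1))
  start0[!is.finite(start0)] <- 0

  best <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    st <- start0
    if (r > 1) {  # random restart: jitter weights and the index coefficient
      if (m > 1) st[(2 + k + 1):length(st)] <- stats::rnorm(m - 1)
      st[2] <- st[2] + stats::rnorm(1, 0, 0.5)
    }
    opt <- try(stats::optim(st, fn = wqs_nll_cpp, gr = wqs_nll_grad_cpp,
                            Q = Q, X = X, y = y, dir = dir, family = fam,
                            method = "BFGS",
                            control = list(maxit = maxit, reltol = reltol)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  for (round in seq_len(3)) {
    # polish: a fresh BFGS from the optimum escapes stalls of the
    # quasi-Newton Hessian on the flat softmax surface
    if (is.null(best)) break
    polish <- try(stats::optim(best$par, fn = wqs_nll_cpp,
                               gr = wqs_nll_grad_cpp, Q = Q, X = X, y = y,
                               dir = dir, family = fam, method = "BFGS",
                               control = list(maxit = maxit, reltol = reltol)),
                  silent = TRUE)
    if (inherits(polish, "try-error") || polish$value > best$value - 1e-9) break
    best <- polish
  }
  if (is.null(best)) {
    return(structure(list(taxon_indices = taxon_indices,
                          weights = rep(1 / m, m), beta1 = NA_real_,
                          t_stat = NA_real_, alpha = NA_real_,
                          delta = rep(NA_real_, k), loglik = NA_real_,
                          converged = FALSE),
                     class = "subset_fit"))
  }
  par <- as.numeric(best$par)
  theta <- c(if (m > 1) par[(2 + k + 1):length(par)] else numeric(0), 0)
  theta <- theta - max(theta)
  w <- exp(theta) / sum(exp(theta))
  beta1 <- if (dir == 0L) par[2] else dir * exp(min(par[2], 50))
  alpha <- par[1]
  delta <- if (k) par[3:(2 + k)] else numeric(0)

  # Wald t from the observed information of (alpha, beta1, delta) at the
  # constrained optimum, weights fixed
  z <- drop(Q %*% w)
  M <- cbind(1, z, X)
  eta <- alpha + beta1 * z + if (k) drop(X %*% delta) else 0
  t_stat <- NA_real_
  se <- NA_real_
  if (fam == 0L) {
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(M * sqrt(wt))
  } else {
    sigma2 <- sum((y - eta)^2) / max(n - ncol(M), 1)
    info <- crossprod(M) / max(sigma2, 1e-12)
  }
  vc <- try(solve(info), silent = TRUE)
  if (!inherits(vc, "try-error") && vc[2, 2] > 0) {
    se <- sqrt(vc[2, 2])
    t_stat <- beta1 / se
  }
  structure(list(taxon_indices = taxon_indices, weights = as.numeric(w),
                 beta1 = beta1, t_stat = t_stat, alpha = alpha, delta = delta,
                 se_beta1 = se, loglik = -best$value,
                 converged = best$convergence == 0 && is.finite(t_stat)),
            class = "subset_fit")
}

## ---- validation fit --------------------------------------------------------

# Firth (Jeffreys-penalized) logistic IRLS; used only on separation
.firth_logistic <- function(M, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(M))
  for (it in seq_len(maxit)) {
    eta <- drop(M %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    WX <- M * W
    XtWX <- crossprod(M, WX)
    XtWXinv <- solve(XtWX)
    h <- rowSums((M %*% XtWXinv) * WX)        # hat diagonal
    score <- crossprod(M, y - mu + h * (0.5 - mu))
    step <- drop(XtWXinv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(M %*% beta)
  mu <- stats::plogis(eta)
  W <- pmax(mu * (1 - mu), 1e-10)
  vc <- solve(crossprod(M, M * W))
  list(coefficients = beta, se = sqrt(diag(vc)))
}

#' Unconstrained validation GLM of the WQS index
#'
#' Fits the ordinary (unconstrained) GLM of the outcome on the index plus
#' covariates on the validation samples. For the binomial family a detected
#' separation triggers a Jeffreys-penalized (Firth) refit, flagged with a
#' warning.
#'
#' @param index per-sample WQS index values (validation samples).
#' @param outcome outcome vector aligned with `index`.
#' @param covariates optional covariate data.frame or design matrix.
#' @param family `"binomial"` or `"gaussian"`.
#' @param conf_level confidence level for the Wald interval on the index
#'   coefficient.
#' @return list with `coefficients` (data.frame: term, estimate, se,
#'   statistic, p_value), `beta1`, `se_beta1`, `ci` (Wald), `odds_ratio` and
#'   `or_ci` (binomial only), `separation` flag.
#' @export
validate_index <- function(index, outcome, covariates = NULL,
                           family = c("binomial", "gaussian"),
                           conf_level = 0.95) {
  family <- match.arg(family)
  y <- as.numeric(outcome)
  n <- length(y)
  if (length(index) != n) stop("index and outcome differ in length")
  X <- .covariate_matrix(covariates, n)
  .check_design_rank(cbind(index = index, X))
  M <- cbind(`(Intercept)` = 1, index = index, X)
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(M, y, family = fam),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- fit$coefficients
  if (anyNA(est))
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(names(est)[is.na(est)], collapse = ", "))
  if (family == "binomial" && (separation || any(abs(est) > 15))) {
    separation <- TRUE
    warning("separation detected in validation fit; ",
            "reporting Jeffreys-penalized (Firth) coefficients", call. = FALSE)
    fr <- .firth_logistic(M, y)
    est <- fr$coefficients
    se <- fr$se
  } else {
    if (family == "binomial") {
      mu <- stats::plogis(drop(M %*% est))
      vc <- solve(crossprod(M, M * pmax(mu * (1 - mu), 1e-10)))
    } else {
      sigma2 <- sum(fit$residuals^2) / fit$df.residual
      vc <- solve(crossprod(M)) * sigma2
    }
    se <- sqrt(diag(vc))
  }
  stat <- est / se
  p <- if (family == "binomial") 2 * stats::pnorm(-abs(stat))
       else 2 * stats::pt(-abs(stat), df = n - ncol(M))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(est["index"] - zq * se[2], est["index"] + zq * se[2])
  names(ci) <- c("lower", "upper")
  out <- list(coefficients = data.frame(term = colnames(M), estimate = unname(est),
                                        se = unname(se), statistic = unname(stat),
                                        p_value = unname(p)),
              beta1 = unname(est["index"]), se_beta1 = unname(se[2]), ci = ci,
              family = family, separation = separation)
  if (family == "binomial") {
    out$odds_ratio <- exp(out$beta1)
    out$or_ci <- exp(ci)
  }
  out
}

#' Majority direction of the mixture association
#'
#' Given unconstrained subset fits, returns the majority sign of the
#' subset-level index coefficients, used to fix the directional constraint
#' before a constrained analysis. An exact tie returns `"negative"` with a
#' warning (documented default).
#'
#' @param fits list of subset fits from an unconstrained pass.
#' @return list with `direction` (`"positive"`/`"negative"`), `n_positive`,
#'   `n_negative`.
#' @export
determine_direction <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$beta1),
                 logical(1))
  if (!any(conv)) stop("no converged unconstrained fits")
  b <- vapply(fits[conv], `[[`, numeric(1), "beta1")
  n_pos <- sum(b > 0)
  n_neg <- sum(b < 0)
  if (n_pos == n_neg)
    warning("exact tie in coefficient signs; defaulting to 'negative'",
            call. = FALSE)
  list(direction = if (n_pos > n_neg) "positive" else "negative",
       n_positive = n_pos, n_negative = n_neg)
}

#' One full random-subset WQS pass
#'
#' Splits the samples into stratified training/validation partitions,
#' estimates simplex-constrained weights on `B` random subsets of size `m`
#' in the training partition, pools them with a signal-weighted average,
#' builds the WQS index on the validation partition and fits the
#' unconstrained validation GLM.
#'
#' @param ranked a `ranked_matrix` from [rank_table()] (full dataset).
#' @param outcome outcome vector aligned with the table's samples.
#' @param covariates optional covariate data.frame (factor/character columns
#'   are also used for stratifying the partition).
#' @param m subset size.
#' @param B number of random subsets.
#' @param signal signal function, see [signal_value()].
#' @param direction `"positive"`, `"negative"` or `"unconstrained"` (use
#'   [wqs_rsrh()] with `direction = "auto"` to fix the sign from an
#'   unconstrained pass).
#' @param family `"binomial"` or `"gaussian"`.
#' @param train_fraction fraction of samples in the training partition.
#' @param seed integer master seed for this pass (partition, subsets and
#'   optimizer restarts all derive from it).
#' @param n_restarts optimizer starts per subset fit.
#' @return an object of class `wqs_rs`: final weights, partition ids,
#'   validation GLM estimates, subset-level summaries.
#' @export
wqs_rs <- function(ranked, outcome, covariates = NULL, m = 30, B = 1000,
                   signal = c("t2", "exp_t", "abs_t"),
                   direction = c("positive", "negative", "unconstrained"),
                   family = c("binomial", "gaussian"),
                   train_fraction = 0.40, seed = 1, n_restarts = 3) {
  stopifnot(inherits(ranked, "ranked_matrix"))
  signal <- match.arg(signal)
  direction <- match.arg(direction)
  family <- match.arg(family)
  sc <- ranked$scores
  n <- nrow(sc)
  p <- ncol(sc)
  if (length(outcome) != n) stop("outcome length must match sample count")

  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  strata <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cat_cols <- vapply(covariates, function(x)
      is.factor(x) || is.character(x) || is.logical(x), logical(1))
    if (any(cat_cols)) strata <- covariates[, cat_cols, drop = FALSE]
  }
  part <- stratified_partition(outcome, strata, train_fraction, seed = seeds[1])
  tr <- part$train
  va <- part$validation

  subsets <- draw_random_subsets(p, m, B, seed = seeds[2])
  cov_tr <- if (!is.null(covariates)) covariates[tr, , drop = FALSE]
  cov_va <- if (!is.null(covariates)) covariates[va, , drop = FALSE]
  set.seed(seeds[3])  # restart jitter stream
  fits <- lapply(seq_len(B), function(b) {
    idx <- subsets[b, ]
    estimate_subset_weights(sc[tr, idx, drop = FALSE], outcome[tr],
                            covariates = cov_tr, family = family,
                            direction = direction, taxon_indices = idx,
                            n_restarts = n_restarts)
  })
  n_conv <- sum(vapply(fits, `[[`, logical(1), "converged"))
  warn <- character(0)
  if (n_conv < B / 2) {
    warn <- sprintf("only %d of %d subset fits converged", n_conv, B)
    warning(warn, call. = FALSE)
  }
  final_weights <- signal_average(fits, p, signal)
  names(final_weights) <- colnames(sc)

  index_va <- build_index(sc[va, , drop = FALSE], final_weights)
  glm_est <- validate_index(index_va, outcome[va], cov_va, family)

  structure(list(final_weights = final_weights,
                 train_ids = rownames(sc)[tr], validation_ids = rownames(sc)[va],
                 train_idx = tr, validation_idx = va,
                 direction = direction, signal = signal, family = family,
                 index_values = stats::setNames(index_va, rownames(sc)[va]),
                 glm_estimates = glm_est,
                 subset_beta1 = vapply(fits, `[[`, numeric(1), "beta1"),
                 subset_t = vapply(fits, `[[`, numeric(1), "t_stat"),
                 n_converged = n_conv, B = B, m = m,
                 warnings = warn, seed = seed),
            class = "wqs_rs")
}

#' @export
print.wqs_rs <- function(x, ...) {
  cat("wqs_rs: ", x$B, " random subsets of ", x$m, " taxa (",
      x$n_converged, " converged), direction ", x$direction,
      ", signal ", x$signal, "\n", sep = "")
  cat("  train/validation: ", length(x$train_ids), "/",
      length(x$validation_ids), " samples\n", sep = "")
  g <- x$glm_estimates
  cat(sprintf("  validation beta1 = %.4g (SE %.3g, 95%% CI %.4g to %.4g)\n",
              g$beta1, g$se_beta1, g$ci[1], g$ci[2]))
  if (!is.null(g$odds_ratio))
    cat(sprintf("  odds ratio = %.4g (95%% CI %.4g to %.4g)\n",
                g$odds_ratio, g$or_ci[1], g$or_ci[2]))
  invisible(x)
}
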