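#' @title Binary-trait regression models of leaf-mine presence on dominance
#' @name mine_models
#' @description
#' Three models of the probability that a plant taxon hosts leafminers
#' as a function of its total importance value (TIV):
#' an ordinary logistic GLM ([fit_glm_binary()]), a binary phylogenetic
#' generalized linear mixed model estimated by penalized
#' quasi-likelihood whose random effect has covariance s2 x V for the
#' Brownian tip covariance V ([fit_binary_pglmm()]), and a phylogenetic
#' logistic regression whose residual correlation decays with patristic
#' distance at Ornstein-Uhlenbeck rate alpha ([fit_phyloglm()]).
#' All fits return a `mine_fit` object with broom-style [tidy()] and
#' [glance()] methods.
NULL

check_binary_dataset <- function(data) {
  need <- c("taxon", "mined", "tiv")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apparency_schema_error")
  }
  if (!all(data$mined %in% c(0, 1))) {
    abort("mined must be 0/1", class = "apparency_validation_error")
  }
  if (length(unique(data$mined)) < 2) {
    abort("response is constant: need at least one host and one non-host",
          class = "apparency_validation_error")
  }
  if (anyDuplicated(data$taxon)) {
    abort("duplicated taxa in dataset", class = "apparency_validation_error")
  }
  invisible(data)
}

new_mine_fit <- function(model, est, se, p, signal = NA_real_,
                         p_signal = NA_real_, AIC = NA_real_,
                         converged = TRUE, n_iter = NA_integer_,
                         n = NA_integer_, extra = list()) {
  structure(
    c(list(model = model,
           intercept = unname(est[1]), B = unname(est[2]),
           se_intercept = unname(se[1]), se_B = unname(se[2]),
           p_intercept = unname(p[1]), p_B = unname(p[2]),
           signal = signal, p_signal = p_signal, AIC = AIC,
           converged = converged, n_iter = as.integer(n_iter), n = n),
      extra),
    class = "mine_fit")
}

wald_p <- function(est, se) 2 * pnorm(-abs(est / se))

#' Ordinary logistic regression of leaf-mine presence on TIV
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) with Wald
#' z p-values and AIC. Perfect separation is detected (any fitted
#' linear predictor exceeding 30 in magnitude) and raised as an error,
#' as is non-convergence.
#'
#' @param data Tibble with columns `taxon`, `mined` (0/1), `tiv`.
#' @return A `mine_fit` object.
#' @export
fit_glm_binary <- function(data) {
  check_binary_dataset(data)
  fit <- suppressWarnings(
    glm(mined ~ tiv, family = binomial(), data = data,
        control = list(maxit = 100))
  )
  if (!fit$converged) {
    abort(sprintf("logistic fit did not converge in 100 iterations (deviance %.4g)",
                  fit$deviance),
          class = "apparency_fit_error")
  }
  eta <- fit$linear.predictors
  if (any(abs(eta) > 30)) {
    abort("perfect or quasi-perfect separation detected (|linear predictor| > 30)",
          class = "apparency_separation_error")
  }
  est <- coef(fit)
  Vb <- vcov(fit)
  se <- setNames(rep(NA_real_, length(est)), names(est))
  se[rownames(Vb)] <- sqrt(diag(Vb)) # aliased terms (constant x) stay NA
  new_mine_fit("glm", est, se, wald_p(est, se),
               AIC = fit$aic, converged = TRUE, n_iter = fit$iter,
               n = nrow(data))
}

#' Binary phylogenetic GLMM by penalized quasi-likelihood
#'
#' Fits y_j ~ Bernoulli(logit^-1(intercept + B tiv_j + b_j)) with
#' b ~ N(0, s2 V), V the (preferably unit-height) Brownian tip
#' covariance. Estimation alternates (i) a working-variable GLS update
#' of the fixed and random effects given s2 with (ii) maximization of
#' the restricted working-model likelihood over s2 >= 0. Wald p-values
#' come from the GLS covariance of the fixed effects; p(s2) is a
#' likelihood-ratio comparison against the s2 = 0 fit referred to an
#' equal mixture of a point mass at zero and chi-square(1), the
#' standard test for a variance on its boundary. No AIC is reported
#' (the criterion is a quasi-likelihood).
#'
#' @param data Tibble with columns `taxon`, `mined` (0/1), `tiv`.
#' @param V Tip covariance matrix ordered as `data$taxon` (or with
#'   dimnames, in which case it is reordered).
#' @param s2_fixed Fix s2 at this value instead of estimating it (0
#'   reproduces the ordinary logistic fit).
#' @param s2_max Upper search bound for s2.
#' @param tol Relative convergence tolerance on all parameters.
#' @param maxit Maximum outer iterations.
#' @return A `mine_fit` object; `signal` holds the s2 estimate and
#'   `ranef` the fitted phylogenetic random effects.
#' @export
fit_binary_pglmm <- function(data, V, s2_fixed = NULL, s2_max = 10,
                             tol = 1e-6, maxit = 200) {
  check_binary_dataset(data)
  V <- align_V(V, data$taxon)
  ev_min <- min(eigen((V + t(V)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    abort(sprintf("V is not positive semi-definite (min eigenvalue %.3g)",
                  ev_min),
          class = "apparency_validation_error")
  }
  y <- data$mined
  X <- cbind(`(Intercept)` = 1, tiv = data$tiv)
  n <- length(y)

  fit0 <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  beta <- fit0$coefficients
  b <- rep(0, n)
  s2 <- if (is.null(s2_fixed)) 0.1 else s2_fixed
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    old <- c(beta, s2)
    st <- pql_inner(X, y, V, beta, b, s2)
    beta <- st$beta; b <- st$b
    if (is.null(s2_fixed)) {
      opt <- optimise(function(s) pql_reml(s, X, V, st$W, st$Z),
                      c(0, s2_max), maximum = TRUE, tol = 1e-8)
      s2 <- opt$maximum
      # the boundary value 0 may beat the interior optimum
      if (pql_reml(0, X, V, st$W, st$Z) >= opt$objective) s2 <- 0
    }
    delta <- max(abs(c(beta, s2) - old) / (abs(old) + 0.1))
    if (delta < tol) { converged <- TRUE; break }
    if (it >= maxit) break
  }
  st <- pql_inner(X, y, V, beta, b, s2)
  beta <- st$beta; b <- st$b
  covb <- solve(st$XtSiX)
  se <- sqrt(diag(covb))
  crit <- pql_reml(s2, X, V, st$W, st$Z)

  # boundary LR test of s2 = 0 against its own converged working model
  p_s2 <- NA_real_
  if (is.null(s2_fixed)) {
    null_fit <- fit_binary_pglmm(data, V, s2_fixed = 0, tol = tol,
                                 maxit = maxit)
    lr <- 2 * (crit - null_fit$crit)
    p_s2 <- 0.5 * pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    if (lr <= 0) p_s2 <- 1
  }

  new_mine_fit("pglmm", beta, se, wald_p(beta, se),
               signal = s2, p_signal = p_s2,
               converged = converged, n_iter = it, n = n,
               extra = list(ranef = setNames(as.numeric(b), data$taxon),
                            crit = crit, vcov = covb))
}

align_V <- function(V, taxa) {
  if (!is.null(dimnames(V)) && !is.null(rownames(V)) &&
      all(taxa %in% rownames(V))) {
    V <- V[taxa, taxa, drop = FALSE]
  }
  if (nrow(V) != length(taxa)) {
    abort(sprintf("V is %d x %d but the dataset has %d taxa",
                  nrow(V), ncol(V), length(taxa)),
          class = "apparency_validation_error")
  }
  unname(V)
}

# one block of working-variable GLS iterations at fixed s2
pql_inner <- function(X, y, V, beta, b, s2, tol = 1e-8, maxit = 50) {
  n <- length(y)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + b
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    Z <- eta + (y - mu) / w
    Sigma <- s2 * V + diag(1 / w, n)
    Si_X <- solve(Sigma, X)
    XtSiX <- crossprod(X, Si_X)
    beta_new <- drop(solve(XtSiX, crossprod(Si_X, Z)))
    r <- Z - drop(X %*% beta_new)
    b_new <- if (s2 > 0) drop(s2 * V %*% solve(Sigma, r)) else rep(0, n)
    step <- max(abs(c(beta_new - beta, b_new - b)))
    beta <- beta_new; b <- b_new
    if (step < tol) break
  }
  list(beta = beta, b = b, W = w, Z = Z, XtSiX = XtSiX)
}

# restricted working-model log-likelihood profiled over beta
pql_reml <- function(s2, X, V, W, Z) {
  n <- length(Z)
  Sigma <- s2 * V + diag(1 / W, n)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Si_X <- backsolve(ch, forwardsolve(t(ch), X))
  Si_Z <- backsolve(ch, forwardsolve(t(ch), Z))
  XtSiX <- crossprod(X, Si_X)
  beta <- solve(XtSiX, crossprod(X, Si_Z))
  r <- Z - drop(X %*% beta)
  Si_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (logdet + determinant(XtSiX, logarithm = TRUE)$modulus +
            sum(r * Si_r))
}

#' Phylogenetic logistic regression with an OU correlation parameter
#'
#' Logistic regression of leaf-mine presence on TIV whose residual
#' correlation between taxa i and j decays with their patristic
#' distance d_ij on the unit-height tree as rho exp(-alpha d_ij):
#' alpha is the Ornstein-Uhlenbeck rate (alpha near 0 means strong
#' phylogenetic signal, large alpha none) and rho the correlation
#' magnitude at zero distance, profiled out to absorb the attenuation
#' of latent correlation in binary responses. Coefficients solve
#' Firth-penalized generalized estimating equations at each alpha (the
#' penalty keeps estimates finite under separation and saturation);
#' alpha maximizes the penalized Gaussian working log-likelihood over a
#' 61-point log grid on \[1e-4, 1e3\] followed by golden-section
#' refinement. AIC = 2k - 2 penalized log-likelihood with k = 3
#' (intercept, slope, alpha).
#'
#' @param data Tibble with columns `taxon`, `mined` (0/1), `tiv`.
#' @param tree Dated [ape::phylo] tree whose tips match `data$taxon`.
#' @param alpha_bounds Search interval for alpha (tree height is
#'   standardized to 1).
#' @param n_grid Number of log-spaced grid points.
#' @param refine Golden-section refinement after the grid search.
#' @return A `mine_fit` object; `signal` holds the alpha estimate,
#'   `rho` the fitted correlation magnitude, and `at_bound` flags an
#'   alpha estimate stuck at a search bound.
#' @export
fit_phyloglm <- function(data, tree,
                         alpha_bounds = c(1e-4, 1e3), n_grid = 61,
                         refine = TRUE) {
  check_binary_dataset(data)
  mism <- c(setdiff(data$taxon, tree$tip.label),
            setdiff(tree$tip.label, data$taxon))
  if (length(mism) > 0) {
    abort(sprintf("taxa and tree tips differ: %s",
                  paste(sort(unique(mism)), collapse = ", ")),
          class = "apparency_validation_error")
  }
  Vh <- tip_covariance(tree, standardize = TRUE)[data$taxon, data$taxon]
  Dm <- outer(diag(Vh), diag(Vh), "+") - 2 * Vh # patristic distances
  y <- data$mined
  X <- cbind(`(Intercept)` = 1, tiv = data$tiv)
  n <- length(y)

  beta0 <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))$coefficients
  eval_alpha <- function(log_alpha, beta_start, rho_start = 0.5) {
    ou_profile_fit(X, y, exp(-exp(log_alpha) * Dm), beta_start, rho_start)
  }
  grid <- seq(log(alpha_bounds[1]), log(alpha_bounds[2]),
              length.out = n_grid)
  beta_ws <- beta0; rho_ws <- 0.5
  pll <- rep(NA_real_, n_grid)
  fits <- vector("list", n_grid)
  for (g in seq_along(grid)) {
    fits[[g]] <- eval_alpha(grid[g], beta_ws, rho_ws)
    beta_ws <- fits[[g]]$beta
    rho_ws <- max(fits[[g]]$rho, 0.05)
    pll[g] <- fits[[g]]$pll
  }
  g_best <- which.max(pll)
  la <- grid[g_best]
  fit <- fits[[g_best]]
  if (refine && g_best > 1 && g_best < n_grid) {
    gs <- golden_section(function(l) eval_alpha(l, fit$beta, max(fit$rho, 0.05))$pll,
                         grid[g_best - 1], grid[g_best + 1])
    if (gs$objective > pll[g_best]) {
      la <- gs$maximum
      fit <- eval_alpha(la, fit$beta, max(fit$rho, 0.05))
    }
  }
  alpha <- exp(la)
  at_bound <- g_best %in% c(1L, n_grid)
  se <- sqrt(diag(solve(fit$info)))
  new_mine_fit("phyloglm", fit$beta, se, wald_p(fit$beta, se),
               signal = alpha, AIC = 2 * 3 - 2 * fit$pll,
               converged = fit$converged, n_iter = fit$n_iter,
               n = n,
               extra = list(at_bound = at_bound, pll = fit$pll,
                            rho = fit$rho, vcov = solve(fit$info)))
}

# joint fit at one alpha: Firth GEE for beta under working correlation
# R = rho S + (1 - rho) I, with rho profiled on the Gaussian working
# likelihood via one eigendecomposition of S
ou_profile_fit <- function(X, y, S, beta_start, rho_start = 0.5,
                           n_cycles = 3) {
  n <- length(y)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  rho <- rho_start
  fit <- NULL
  for (cyc in seq_len(n_cycles)) {
    R <- rho * S + (1 - rho) * diag(n)
    fit <- firth_gee(X, y, R, beta_start)
    beta_start <- fit$beta
    mu <- plogis(drop(X %*% fit$beta))
    a <- sqrt(pmax(mu * (1 - mu), 1e-10))
    te <- drop(crossprod(es$vectors, (y - mu) / a))
    nll <- function(r) {
      dvec <- r * es$values + (1 - r)
      if (any(dvec <= 1e-12)) return(Inf)
      0.5 * (sum(log(dvec)) + sum(te^2 / dvec))
    }
    op <- optimise(nll, c(0, 0.999))
    rho_new <- if (nll(0) <= op$objective) 0 else op$minimum
    done <- abs(rho_new - rho) < 1e-4
    rho <- rho_new
    if (done) break
  }
  R <- rho * S + (1 - rho) * diag(n)
  fit <- firth_gee(X, y, R, fit$beta)
  mu <- plogis(drop(X %*% fit$beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  te <- drop(crossprod(es$vectors, (y - mu) / sqrt(w)))
  dvec <- rho * es$values + (1 - rho)
  ll <- -0.5 * (n * log(2 * pi) + sum(log(w)) + sum(log(dvec)) +
                  sum(te^2 / dvec))
  pll <- ll + 0.5 * determinant(fit$info, logarithm = TRUE)$modulus
  list(beta = fit$beta, info = fit$info, pll = as.numeric(pll),
       rho = rho, converged = fit$converged, n_iter = fit$n_iter)
}

# Firth-adjusted GEE fit of a logistic mean model under a fixed working
# correlation R; returns the penalized Gaussian working log-likelihood
firth_gee <- function(X, y, R, beta, tol = 1e-8, maxit = 100) {
  n <- length(y)
  Rch <- tryCatch(chol(R), error = function(e) chol(R + 1e-8 * diag(n)))
  Rinv <- chol2inv(Rch)
  score <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    a <- sqrt(w)
    # Vy^{-1} = diag(1/a) R^{-1} diag(1/a); score premultiplier X' W Vy^{-1}
    K <- t(X * a) %*% Rinv          # p x n, equals X' W^{1/2} R^{-1}
    info <- K %*% (X * a)           # X' W^{1/2} R^{-1} W^{1/2} X
    Xa <- X * a
    M <- crossprod(Xa)              # independence information for the penalty
    h <- rowSums(Xa * t(solve(M, t(Xa))))
    r_adj <- (y - mu + h * (0.5 - mu)) / a
    U <- drop(K %*% r_adj)
    list(U = U, info = info)
  }
  converged <- FALSE
  st <- score(beta)
  xscale <- pmax(apply(abs(X), 2, max), 1e-8)
  for (it in seq_len(maxit)) {
    delta <- drop(solve(st$info, st$U))
    # trust region: never move any linear-predictor scale by more than 5
    cap <- max(abs(delta) * xscale)
    if (cap > 5) delta <- delta * 5 / cap
    # step-halve on the adjusted-score norm so saturation cannot diverge
    step <- 1
    for (half in 1:20) {
      cand <- score(beta + step * delta)
      if (sum(cand$U^2) <= sum(st$U^2) || max(abs(step * delta)) < tol) break
      step <- step / 2
    }
    beta <- beta + step * delta
    st <- cand
    if (max(abs(step * delta * xscale)) < tol * max(xscale)) {
      converged <- TRUE; break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  a <- sqrt(w)
  e <- (y - mu) / a
  quad <- drop(crossprod(e, Rinv %*% e))
  logdetVy <- 2 * sum(log(diag(Rch))) + sum(log(w))
  K <- t(X * a) %*% Rinv
  info <- K %*% (X * a)
  ll <- -0.5 * (n * log(2 * pi) + logdetVy + quad)
  pll <- ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  list(beta = beta, info = info, pll = as.numeric(pll),
       converged = converged, n_iter = it)
}

golden_section <- function(f, lo, hi, tol = 1e-4, maxit = 60) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(maxit)) {
    if (hi - lo < tol) break
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    }
  }
  if (f1 >= f2) list(maximum = x1, objective = f1)
  else list(maximum = x2, objective = f2)
}

#' Fitted incidence probabilities along a TIV grid
#'
#' p(x) = logit^-1(intercept + B x), the fitted leaf-mine incidence
#' curve of any of the three models.
#'
#' @param fit A `mine_fit` object.
#' @param x_grid Numeric vector of TIV values.
#' @return A tibble with columns `tiv` and `p`.
#' @export
incidence_curve <- function(fit, x_grid) {
  stopifnot(inherits(fit, "mine_fit"))
  tibble(tiv = x_grid, p = plogis(fit$intercept + fit$B * x_grid))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.mine_fit <- function(x, ...) {
  cat(sprintf("<mine_fit: %s, n = %d>\n", x$model, x$n))
  cat(sprintf("  B = %.5g (p = %.3g), intercept = %.4g (p = %.3g)\n",
              x$B, x$p_B, x$intercept, x$p_intercept))
  if (x$model == "pglmm") {
    cat(sprintf("  s2 = %.4g (p = %.3g)\n", x$signal, x$p_signal))
  }
  if (x$model == "phyloglm") {
    cat(sprintf("  alpha = %.4g, AIC = %.4g\n", x$signal, x$AIC))
  }
  if (x$model == "glm") cat(sprintf("  AIC = %.4g\n", x$AIC))
  if (!x$converged) cat("  (not converged)\n")
  invisible(x)
}

#' Tidy a leaf-mine incidence model fit
#'
#' @param x A `mine_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.mine_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "tiv"),
         estimate = c(x$intercept, x$B),
         std.error = c(x$se_intercept, x$se_B),
         statistic = c(x$intercept / x$se_intercept, x$B / x$se_B),
         p.value = c(x$p_intercept, x$p_B))
}

#' One-row model summary of a leaf-mine incidence fit
#'
#' @param x A `mine_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: model, signal parameter (s2 or alpha) and
#'   its p-value where defined, AIC where defined, convergence.
#' @export
glance.mine_fit <- function(x, ...) {
  tibble(model = x$model, B = x$B, p_B = x$p_B,
         intercept = x$intercept, p_intercept = x$p_intercept,
         signal = x$signal, p_signal = x$p_signal, AIC = x$AIC,
         converged = x$converged, n_iter = x$n_iter, nobs = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
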