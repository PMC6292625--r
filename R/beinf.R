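# Zero-and-one-inflated beta distribution and its regression model.
#
# The response y in [0,1] follows a mixed discrete-continuous law: point
# masses P0 = nu/(1+nu+tau) at 0 and P1 = tau/(1+nu+tau) at 1, and with
# probability 1 - P0 - P1 a Beta(alpha, beta) draw on (0,1), where
# alpha = mu(1-sigma^2)/sigma^2 and beta = (1-mu)(1-sigma^2)/sigma^2.
# Regression puts a linear predictor on each of mu, sigma (logit link) and
# nu, tau (log link); maximum likelihood with analytic gradients.

#' Beta shape parameters from the (mu, sigma) parameterisation
#'
#' `alpha = mu (1 - sigma^2) / sigma^2`, `beta = (1 - mu)(1 - sigma^2) /
#' sigma^2`, so `alpha / (alpha + beta) = mu` and the interior variance is
#' `mu (1 - mu) sigma^2`.
#'
#' @param mu mean of the beta component, in (0,1).
#' @param sigma dispersion parameter, in (0,1).
#' @return list with `alpha`, `beta` (vectorised).
#' @export
beinfShape <- function(mu, sigma) {
  stopIfNot(all(mu > 0 & mu < 1), "mu must be in (0,1)")
  stopIfNot(all(sigma > 0 & sigma < 1), "sigma must be in (0,1)")
  phi <- (1 - sigma^2) / sigma^2
  list(alpha = mu * phi, beta = (1 - mu) * phi)
}

#' Endpoint probabilities from the inflation parameters
#'
#' `P0 = nu / (1 + nu + tau)`, `P1 = tau / (1 + nu + tau)`.
#'
#' @param nu,tau inflation odds (>= 0).
#' @return list with `p0`, `p1`.
#' @export
beinfProbs <- function(nu, tau) {
  stopIfNot(all(nu >= 0) && all(tau >= 0), "nu and tau must be >= 0")
  d <- 1 + nu + tau
  list(p0 = nu / d, p1 = tau / d)
}

#' Expectation of the inflated beta distribution
#'
#' `E(y) = (tau + mu) / (1 + nu + tau)`.
#'
#' @param mu beta-component mean in (0,1).
#' @param nu,tau inflation odds (>= 0).
#' @return numeric E(y) in (0,1).
#' @export
beinfExpectation <- function(mu, nu, tau) {
  stopIfNot(all(mu > 0 & mu < 1), "mu must be in (0,1)")
  stopIfNot(all(nu >= 0) && all(tau >= 0), "nu and tau must be >= 0")
  (tau + mu) / (1 + nu + tau)
}

#' Random draws from the inflated beta distribution
#'
#' @param n number of draws.
#' @param mu,sigma,nu,tau distribution parameters (recycled to length `n`).
#' @return numeric vector in \[0,1\].
#' @export
rbeinf <- function(n, mu, sigma, nu, tau = 0) {
  p <- beinfProbs(rep_len(nu, n), rep_len(tau, n))
  sh <- beinfShape(rep_len(mu, n), rep_len(sigma, n))
  y <- stats::rbeta(n, sh$alpha, sh$beta)
  u <- stats::runif(n)
  y[u < p$p0] <- 0
  y[u >= p$p0 & u < p$p0 + p$p1] <- 1
  y
}

#' Log-likelihood of the inflated beta model
#'
#' Sums, over observations, `log P0` where `y = 0`, `log P1` where `y = 1`,
#' and `log((1 - P0 - P1) * dbeta(y; alpha, beta))` for interior values.
#' The `"MIBR0"` family sets tau to 0 and refuses data containing `y = 1`.
#'
#' @param y responses in \[0,1\].
#' @param mu,sigma,nu,tau parameters, recycled to `length(y)`.
#' @param family `"MIBR"` or `"MIBR0"`.
#' @return total log-likelihood (scalar).
#' @export
beinfLoglik <- function(y, mu, sigma, nu, tau = 0, family = c("MIBR", "MIBR0")) {
  family <- match.arg(family)
  stopIfNot(all(y >= 0 & y <= 1), "y must be in [0,1]")
  if (family == "MIBR0") {
    stopIfNot(!any(y == 1), "MIBR0 cannot handle observations with y = 1")
    tau <- 0
  }
  n <- length(y)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  nu <- rep_len(nu, n); tau <- rep_len(tau, n)
  d <- 1 + nu + tau
  ll <- numeric(n)
  i0 <- y == 0; i1 <- y == 1; im <- !i0 & !i1
  ll[i0] <- log(nu[i0]) - log(d[i0])
  ll[i1] <- log(tau[i1]) - log(d[i1])
  if (any(im)) {
    sh <- beinfShape(mu[im], sigma[im])
    ll[im] <- -log(d[im]) +
      stats::dbeta(y[im], sh$alpha, sh$beta, log = TRUE)
  }
  sum(ll)
}

#' Decide between the MIBR and MIBR-0 family for a response
#'
#' With no or few (at most 3) observations equal to 1 the sample is too
#' small to model one-inflation, and the zero-inflated-only family is used.
#'
#' @param y responses in \[0,1\].
#' @param maxOnes threshold on the count of exact ones (default 3).
#' @return `"MIBR"` or `"MIBR0"`.
#' @export
chooseInflationFamily <- function(y, maxOnes = 3) {
  if (sum(y == 1) <= maxOnes) "MIBR0" else "MIBR"
}

# ---- fitting ----------------------------------------------------------

beinfParams <- function(family) {
  if (family == "MIBR0") c("mu", "sigma", "nu") else c("mu", "sigma", "nu", "tau")
}

# clamp link-scale values so plogis/exp stay in the open domain
clampEta <- function(eta) pmin(pmax(eta, -30), 30)

# negative log-likelihood and its analytic gradient in the packed
# coefficient vector
beinfObjective <- function(y, X, family) {
  pars <- beinfParams(family)
  k <- vapply(X[pars], ncol, 0L)
  idx <- split(seq_len(sum(k)), rep(pars, k))
  i0 <- y == 0; i1 <- y == 1; im <- !i0 & !i1
  ly <- lb <- numeric(length(y))
  ly[im] <- log(y[im]); lb[im] <- log1p(-y[im])
  unpack <- function(theta) {
    eta <- lapply(pars, function(p) clampEta(as.vector(X[[p]] %*% theta[idx[[p]]])))
    names(eta) <- pars
    list(mu = inv_logit(eta$mu), sigma = inv_logit(eta$sigma),
         nu = exp(eta$nu),
         tau = if (family == "MIBR") exp(eta$tau) else rep(0, length(y)))
  }
  negll <- function(theta) {
    p <- unpack(theta)
    mu <- pmin(pmax(p$mu, 1e-10), 1 - 1e-10)
    s <- pmin(pmax(p$sigma, 1e-10), 1 - 1e-10)
    ll <- beinfLoglik(y, mu, s, p$nu, p$tau, family)
    if (!is.finite(ll)) 1e10 else -ll
  }
  grad <- function(theta) {
    p <- unpack(theta)
    mu <- pmin(pmax(p$mu, 1e-10), 1 - 1e-10)
    s <- pmin(pmax(p$sigma, 1e-10), 1 - 1e-10)
    d <- 1 + p$nu + p$tau
    phi <- (1 - s^2) / s^2
    a <- mu * phi; b <- (1 - mu) * phi
    dmu <- dsig <- numeric(length(y))
    dg_a <- digamma(a[im]); dg_b <- digamma(b[im]); dg_f <- digamma(phi[im])
    # d ll / d eta_mu (interior only): phi*(ly - lb - psi(a) + psi(b)) * mu(1-mu)
    dmu[im] <- phi[im] * (ly[im] - lb[im] - dg_a + dg_b) * mu[im] * (1 - mu[im])
    # d ll / d eta_sigma via phi: dphi/ds = -2/s^3, ds/deta = s(1-s)
    dldphi <- mu[im] * ly[im] + (1 - mu[im]) * lb[im] -
      mu[im] * dg_a - (1 - mu[im]) * dg_b + dg_f
    dsig[im] <- dldphi * (-2 / s[im]^3) * s[im] * (1 - s[im])
    dnu <- as.numeric(i0) - p$nu / d
    g <- c(crossprod(X$mu, dmu), crossprod(X$sigma, dsig),
           crossprod(X$nu, dnu))
    if (family == "MIBR") {
      dtau <- as.numeric(i1) - p$tau / d
      g <- c(g, crossprod(X$tau, dtau))
    }
    -g
  }
  list(negll = negll, grad = grad, idx = idx, pars = pars, unpack = unpack)
}

#' Fit a zero-and-one-inflated beta regression by maximum likelihood
#'
#' Each distribution parameter gets its own model formula (right-hand side
#' only); mu and sigma use a logit link, nu and tau a log link. Starting
#' values come from sample moments (empirical endpoint frequencies, interior
#' mean and variance); optimisation is quasi-Newton (BFGS) on the joint
#' link-scale likelihood with analytic gradients, and standard errors come
#' from the observed information at the optimum.
#'
#' @param y responses in \[0,1\].
#' @param data data.frame holding the covariates.
#' @param mu,sigma,nu,tau one-sided formulas for each parameter's linear
#'   predictor (default intercept-only).
#' @param family `"MIBR"` or `"MIBR0"` (the latter drops tau and requires
#'   no `y = 1`); default chooses via [chooseInflationFamily()].
#' @param start optional named list of starting coefficient vectors.
#' @return An [InflatedBetaFit-class].
#' @export
fitBeinf <- function(y, data = NULL, mu = ~1, sigma = ~1, nu = ~1, tau = ~1,
                     family = NULL, start = NULL) {
  stopIfNot(all(y >= 0 & y <= 1), "y must be in [0,1]")
  if (is.null(family)) family <- chooseInflationFamily(y)
  if (family == "MIBR0" && any(y == 1))
    stop("MIBR0 requires data without y = 1", call. = FALSE)
  if (is.null(data)) data <- data.frame(row.names = seq_along(y))
  formulas <- list(mu = mu, sigma = sigma, nu = nu, tau = tau)
  pars <- beinfParams(family)
  formulas <- formulas[pars]
  X <- lapply(formulas, function(f) stats::model.matrix(f, data))
  stopIfNot(all(vapply(X, nrow, 0L) == length(y)),
            "covariate rows must match length(y)")
  obj <- beinfObjective(y, X, family)
  # moment-based starting values on intercepts, zero slopes
  p0 <- mean(y == 0); p1 <- mean(y == 1)
  pm <- max(1 - p0 - p1, 1e-3)
  yi <- y[y > 0 & y < 1]
  m <- if (length(yi)) mean(yi) else 0.5
  v <- if (length(yi) > 1) stats::var(yi) else 0.05
  s2 <- min(max(v / (m * (1 - m)), 0.01), 0.95)
  starts <- list(mu = logit(min(max(m, 0.01), 0.99)),
                 sigma = logit(sqrt(s2)),
                 nu = log(max(p0, 1e-3) / pm),
                 tau = log(max(p1, 1e-3) / pm))
  theta <- unlist(lapply(pars, function(p) {
    if (!is.null(start[[p]])) return(start[[p]])
    c(starts[[p]], rep(0, ncol(X[[p]]) - 1))
  }))
  opt <- stats::optim(theta, obj$negll, obj$grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  se_all <- suppressWarnings(sqrt(diag(vc)))
  coefs <- se <- list()
  for (p in pars) {
    cf <- opt$par[obj$idx[[p]]]
    names(cf) <- colnames(X[[p]])
    coefs[[p]] <- cf
    s <- se_all[obj$idx[[p]]]
    names(s) <- colnames(X[[p]])
    se[[p]] <- s
  }
  prm <- obj$unpack(opt$par)
  fitted <- beinfExpectation(pmin(pmax(prm$mu, 1e-10), 1 - 1e-10),
                             prm$nu, prm$tau)
  ll <- -opt$value
  fit <- new("InflatedBetaFit", family = family, coefficients = coefs,
             se = se, vcov = vc, loglik = ll,
             aic = -2 * ll + 2 * length(theta),
             converged = opt$convergence == 0, fitted = fitted, y = y,
             trace = character())
  attr(fit, "formulas") <- formulas
  if (!fit@converged)
    warning("inflated beta fit did not converge (optim code ",
            opt$convergence, ")")
  fit
}

#' Coefficient table of an inflated beta fit
#'
#' @param fit an [InflatedBetaFit-class].
#' @return data.frame with `parameter`, `term`, `estimate`, `se`, `z`, `p`.
#' @export
beinfCoefTable <- function(fit) {
  rows <- lapply(names(fit@coefficients), function(p) {
    est <- fit@coefficients[[p]]
    s <- fit@se[[p]]
    z <- est / s
    data.frame(parameter = p, term = names(est), estimate = unname(est),
               se = unname(s), z = unname(z),
               p = unname(2 * stats::pnorm(-abs(z))))
  })
  do.call(rbind, rows)
}

#' @describeIn fitBeinf predicted distribution parameters and expectation
#'   for new covariate values.
#' @param object an [InflatedBetaFit-class].
#' @param newdata data.frame of covariates.
#' @param ... unused.
#' @export
setMethod("predict", "InflatedBetaFit", function(object, newdata, ...) {
  formulas <- attr(object, "formulas")
  out <- data.frame(row.names = seq_len(nrow(newdata)))
  eta <- list()
  for (p in names(object@coefficients)) {
    M <- stats::model.matrix(formulas[[p]], newdata)
    eta[[p]] <- clampEta(as.vector(M %*% object@coefficients[[p]]))
  }
  out$mu <- inv_logit(eta$mu)
  out$sigma <- inv_logit(eta$sigma)
  out$nu <- exp(eta$nu)
  out$tau <- if (object@family == "MIBR") exp(eta$tau) else 0
  pr <- beinfProbs(out$nu, out$tau)
  out$p0 <- pr$p0; out$p1 <- pr$p1
  out$expectation <- beinfExpectation(pmin(pmax(out$mu, 1e-10), 1 - 1e-10),
                                      out$nu, out$tau)
  out
})

setMethod("show", "InflatedBetaFit", function(object) {
  cat(sprintf("%s fit: loglik %.3f, AIC %.2f, %sconverged\n", object@family,
              object@loglik, object@aic, if (object@converged) "" else "NOT "))
  print(beinfCoefTable(object), digits = 4)
  cat(sprintf("pseudo-R2 (cor^2 fitted vs observed): %.4f\n",
              pseudoR2(object@fitted, object@y)))
})
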