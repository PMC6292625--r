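# Regression model building: multiple linear regression for log-FA,
# inflated beta regression for contribution shares, with the screening,
# VIF-filtering, stepwise-AIC and simplification rules of the mapping
# procedure.

#' Multiple linear regression by ordinary least squares
#'
#' Thin wrapper around `lm()` that reports the fit statistics used in the
#' model tables (R-squared, adjusted R-squared, F statistic, per-coefficient
#' t and p) and fails loudly on rank deficiency, naming the collinear
#' columns.
#'
#' @param formula model formula (response already transformed upstream; FA
#'   enters as log(FA)).
#' @param data data.frame.
#' @return object of class `MlrFit`: list with `lm`, `r2`, `adj_r2`,
#'   `fstat`, `aic`, `coefficients` (summary table), `formula`.
#' @export
fitMlr <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)
  structure(list(lm = fit, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 fstat = unname(if (is.null(sm$fstatistic)) NA_real_
                                else sm$fstatistic[1]),
                 aic = stats::AIC(fit), coefficients = stats::coef(sm),
                 formula = formula),
            class = "MlrFit")
}

#' @export
print.MlrFit <- function(x, ...) {
  cat(sprintf("MLR fit: R2 %.4f (adj %.4f), F %.2f, AIC %.2f\n",
              x$r2, x$adj_r2, x$fstat, x$aic))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Squared correlation of fitted and observed values
#'
#' The fit statistic reported for the inflated beta models ("pseudo R2"):
#' the squared Pearson correlation between fitted expectations and observed
#' responses.
#'
#' @param fitted,observed numeric vectors of equal length.
#' @return squared correlation in \[0,1\]; `NA` with a warning when either
#'   vector is constant.
#' @export
pseudoR2 <- function(fitted, observed) {
  stopIfNot(length(fitted) == length(observed), "length mismatch")
  if (stats::sd(fitted) == 0 || stats::sd(observed) == 0) {
    warning("pseudo-R2 undefined for constant vectors")
    return(NA_real_)
  }
  stats::cor(fitted, observed)^2
}

#' Univariate covariate screening
#'
#' Fits one single-covariate model per candidate and keeps covariates whose
#' slope is significant at `alpha` (default 0.1). For inflated beta models
#' the default puts the slope on the mu predictor; `scope = "any"` puts the
#' covariate on every distribution parameter at once and screens on the
#' smallest slope p-value.
#'
#' @param y response (already log-transformed for MLR on FA).
#' @param covariates data.frame of candidate covariates (numeric columns).
#' @param family `"MLR"`, `"MIBR"` or `"MIBR0"`.
#' @param alpha significance gate (default 0.1); no multiplicity adjustment
#'   is applied, matching the procedure's raw gate.
#' @param scope `"mu"` or `"any"` (inflated beta families only).
#' @return data.frame with `covariate`, `p_value`, `kept`; failures are
#'   dropped with `p_value = NA`.
#' @export
univariateScreen <- function(y, covariates, family = c("MLR", "MIBR", "MIBR0"),
                             alpha = 0.1, scope = c("mu", "any")) {
  family <- match.arg(family)
  scope <- match.arg(scope)
  if (length(covariates) == 0)
    return(data.frame(covariate = character(), p_value = numeric(),
                      kept = logical()))
  out <- data.frame(covariate = names(covariates),
                    p_value = NA_real_, kept = FALSE)
  for (i in seq_along(covariates)) {
    d <- data.frame(x = covariates[[i]])
    p <- tryCatch({
      if (family == "MLR") {
        sm <- summary(stats::lm(y ~ x, data = d))
        sm$coefficients["x", "Pr(>|t|)"]
      } else {
        args <- list(y = y, data = d, mu = ~x, family = family)
        if (scope == "any") {
          args$sigma <- ~x; args$nu <- ~x
          if (family == "MIBR") args$tau <- ~x
        }
        fit <- suppressWarnings(do.call(fitBeinf, args))
        tab <- beinfCoefTable(fit)
        pv <- tab$p[tab$term == "x"]
        if (all(is.na(pv))) NA_real_ else min(pv, na.rm = TRUE)
      }
    }, error = function(e) NA_real_)
    out$p_value[i] <- p
    out$kept[i] <- isTRUE(p < alpha)
  }
  out
}

#' Variance-inflation-factor collinearity filter
#'
#' Computes the VIF of every covariate (1 / (1 - R2) of the regression of
#' that covariate on all others) and iteratively drops the covariate with
#' the highest VIF until all remaining values are below the threshold
#' (default 10).
#'
#' @param covariates data.frame of numeric covariates (>= 2 columns to do
#'   anything).
#' @param threshold VIF threshold (default 10).
#' @return list with `retained` (names), `vif` (final values), `dropped`
#'   (names in drop order).
#' @export
vifScreen <- function(covariates, threshold = 10) {
  vars <- names(covariates)
  dropped <- character()
  vifOf <- function(v, others) {
    if (length(others) == 0) return(1)
    r2 <- summary(stats::lm(stats::reformulate(others, v),
                            data = covariates))$r.squared
    1 / max(1 - r2, 1e-12)
  }
  repeat {
    if (length(vars) < 2) {
      vif <- stats::setNames(rep(1, length(vars)), vars)
      break
    }
    vif <- vapply(vars, function(v) vifOf(v, setdiff(vars, v)), 0)
    if (max(vif) < threshold) break
    worst <- vars[which.max(vif)]
    dropped <- c(dropped, worst)
    vars <- setdiff(vars, worst)
  }
  list(retained = vars, vif = vif, dropped = dropped)
}

#' Stepwise AIC model selection
#'
#' For MLR: forward selection with `stats::step()`. For the inflated beta
#' families: cycles over the distribution parameters (mu, sigma, nu, tau),
#' for each doing forward additions then backward eliminations of screened
#' covariates on that parameter's predictor, accepting only moves that
#' lower the AIC, until a full cycle changes nothing. Candidate fits that
#' fail are skipped and logged in the `skipped` attribute.
#'
#' @param y response vector.
#' @param covariates data.frame of screened covariates.
#' @param family `"MLR"`, `"MIBR"` or `"MIBR0"`.
#' @param maxCycles safety bound on parameter cycles.
#' @param init optional starting selection (named list of covariate names
#'   per distribution parameter), e.g. to extend a selected model with
#'   additional candidate covariates for a nested comparison.
#' @return An `MlrFit` or an [InflatedBetaFit-class] whose `trace` slot
#'   records the addition order (used by [simplifyBeinf()]).
#' @export
stepwiseSelect <- function(y, covariates, family = c("MLR", "MIBR", "MIBR0"),
                           maxCycles = 10, init = NULL) {
  family <- match.arg(family)
  covs <- names(covariates)
  stopIfNot(length(covs) >= 1, "screened covariate set is empty")
  if (family == "MLR") {
    d <- cbind(data.frame(.y = y), covariates)
    base <- stats::lm(.y ~ 1, data = d)
    sel <- stats::step(base, scope = list(
      lower = ~1, upper = stats::reformulate(covs)),
      direction = "forward", trace = 0)
    return(fitMlr(stats::formula(sel), d))
  }
  pars <- beinfParams(family)
  selected <- stats::setNames(rep(list(character()), length(pars)), pars)
  if (!is.null(init))
    for (p in intersect(names(init), pars))
      selected[[p]] <- intersect(init[[p]], covs)
  trace <- unlist(lapply(names(selected), function(p)
    if (length(selected[[p]])) paste0(p, ":", selected[[p]])))
  if (is.null(trace)) trace <- character()
  skipped <- character()
  mkFormula <- function(v) if (length(v) == 0) ~1 else stats::reformulate(v)
  refit <- function(sel) {
    args <- c(list(y = y, data = covariates, family = family),
              stats::setNames(lapply(sel, mkFormula), names(sel)))
    suppressWarnings(do.call(fitBeinf, args))
  }
  current <- refit(selected)
  for (cycle in seq_len(maxCycles)) {
    changed <- FALSE
    for (p in pars) {
      # forward: best single addition on this parameter
      repeat {
        cands <- setdiff(covs, selected[[p]])
        if (length(cands) == 0) break
        best <- NULL; bestAic <- current@aic - 1e-6
        for (cv in cands) {
          trial <- selected
          trial[[p]] <- c(trial[[p]], cv)
          f <- tryCatch(refit(trial), error = function(e) NULL)
          if (is.null(f)) { skipped <- c(skipped, paste0(p, ":", cv)); next }
          if (f@aic < bestAic) { best <- list(cov = cv, fit = f); bestAic <- f@aic }
        }
        if (is.null(best)) break
        selected[[p]] <- c(selected[[p]], best$cov)
        trace <- c(trace, paste0(p, ":", best$cov))
        current <- best$fit
        changed <- TRUE
      }
      # backward: best single removal on this parameter
      repeat {
        if (length(selected[[p]]) == 0) break
        best <- NULL; bestAic <- current@aic - 1e-6
        for (cv in selected[[p]]) {
          trial <- selected
          trial[[p]] <- setdiff(trial[[p]], cv)
          f <- tryCatch(refit(trial), error = function(e) NULL)
          if (is.null(f)) next
          if (f@aic < bestAic) { best <- list(cov = cv, fit = f); bestAic <- f@aic }
        }
        if (is.null(best)) break
        selected[[p]] <- setdiff(selected[[p]], best$cov)
        trace <- setdiff(trace, paste0(p, ":", best$cov))
        current <- best$fit
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current@trace <- trace
  attr(current, "selected") <- selected
  attr(current, "skipped") <- skipped
  current
}

#' Simplify a selected inflated beta model
#'
#' Guards against overfitting after stepwise selection: considers removing
#' the last coefficient added to any of the distribution parameters and
#' accepts the simplified model unless doing so worsens the AIC by more
#' than `aicRejectDiff` (default 10). By default the term is a removal
#' candidate when it is *not* significant (p >= `pThreshold`); the literal
#' variant (`pRule = "literal"`) instead removes it when p < `pThreshold`.
#'
#' @param fit an [InflatedBetaFit-class] from [stepwiseSelect()] (its
#'   `trace` slot identifies the last-added term).
#' @param y,covariates the data the model was fitted on.
#' @param pThreshold significance threshold (default 0.1).
#' @param pRule `"corrected"` (remove when p >= threshold) or `"literal"`.
#' @param aicRejectDiff reject the simplification when
#'   `AIC(simplified) - AIC(full) >` this value (default 10).
#' @return list with `model` (accepted fit) and `decision` (record of the
#'   candidate, p-value, AICs and outcome).
#' @export
simplifyBeinf <- function(fit, y, covariates, pThreshold = 0.1,
                          pRule = c("corrected", "literal"),
                          aicRejectDiff = 10) {
  pRule <- match.arg(pRule)
  decision <- list(candidate = NA_character_, p = NA_real_,
                   aic_full = fit@aic, aic_simplified = NA_real_,
                   outcome = "no removable coefficient")
  if (length(fit@trace) == 0)
    return(list(model = fit, decision = decision))
  last <- fit@trace[length(fit@trace)]
  parts <- strsplit(last, ":", fixed = TRUE)[[1]]
  par <- parts[1]; cov <- parts[2]
  tab <- beinfCoefTable(fit)
  p <- tab$p[tab$parameter == par & tab$term == cov]
  decision$candidate <- last
  decision$p <- p
  eligible <- if (pRule == "corrected") isTRUE(p >= pThreshold)
              else isTRUE(p < pThreshold)
  if (!eligible) {
    decision$outcome <- "kept (p rule not met)"
    return(list(model = fit, decision = decision))
  }
  selected <- attr(fit, "selected")
  selected[[par]] <- setdiff(selected[[par]], cov)
  mkFormula <- function(v) if (length(v) == 0) ~1 else stats::reformulate(v)
  args <- c(list(y = y, data = covariates, family = fit@family),
            stats::setNames(lapply(selected, mkFormula), names(selected)))
  simp <- suppressWarnings(do.call(fitBeinf, args))
  decision$aic_simplified <- simp@aic
  if (simp@aic - fit@aic > aicRejectDiff) {
    decision$outcome <- "rejected (AIC worsens by > threshold)"
    return(list(model = fit, decision = decision))
  }
  simp@trace <- setdiff(fit@trace, last)
  attr(simp, "selected") <- selected
  decision$outcome <- "simplified accepted"
  list(model = simp, decision = decision)
}

#' Predict a model over a covariate raster stack
#'
#' Evaluates a fitted model cell-wise on a [GridStack-class] whose layers
#' are named after the model covariates: E(y) for inflated beta fits, the
#' linear predictor (log scale for log-FA models) for MLR fits. Nodata
#' propagates.
#'
#' @param model an [InflatedBetaFit-class] or `MlrFit`.
#' @param stack a [GridStack-class] containing every selected covariate.
#' @return A [GridLayer-class] named `"prediction"`.
#' @export
predictSurface <- function(model, stack) {
  vals <- lapply(stack@layers, gridVector)
  newdata <- as.data.frame(vals)
  need <- if (is(model, "InflatedBetaFit"))
    unique(unlist(lapply(attr(model, "formulas"), all.vars)))
  else all.vars(stats::formula(model$lm))[-1]
  missing <- setdiff(need, names(newdata))
  stopIfNot(length(missing) == 0,
            paste("missing covariate layer(s):", paste(missing, collapse = ", ")))
  ok <- stats::complete.cases(newdata[, need, drop = FALSE])
  pred <- rep(NA_real_, nrow(newdata))
  if (any(ok)) {
    nd <- newdata[ok, , drop = FALSE]
    pred[ok] <- if (is(model, "InflatedBetaFit"))
      predict(model, nd)$expectation
    else as.vector(stats::predict(model$lm, nd))
  }
  gridFromVector(stack@layers[[1]], pred, name = "prediction")
}
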