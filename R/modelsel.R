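#' Printed GLS model-comparison table for the published amniote analysis
#'
#' Log-likelihoods and AIC values of the six candidate generalised-least-
#' squares models relating the shift-magnitude (delta2) series of the
#' Carboniferous-Triassic amniote supertree to origination, extinction
#' and mass-extinction series, as printed in the source study, together
#' with the published Akaike weights and random-forest scores. Used as a
#' fixed input for reproducing the weight computation; the underlying
#' amniote series themselves were not published in machine-readable form.
#'
#' @return \code{data.frame} with columns \code{model}, \code{loglik},
#'   \code{aic}, \code{weight}, \code{pct_mse}, \code{node_purity}.
#' @export
published_gls_table <- function() {
  data.frame(
    model = c("extinction", "origination", "mass_extinction",
              "origination+extinction", "origination+mass_extinction",
              "null"),
    loglik = c(36.99345, 35.62917, 34.98031, 35.69722, 33.81104, 36.86496),
    aic = c(-69.9869, -65.25833, -63.96063, -63.39445, -59.62208,
            -67.72992),
    weight = c(0.662553746, 0.062290971, 0.032556088, 0.024529433,
               0.003719877, 0.214349884),
    pct_mse = c(38.88489, -10.32131, 31.10235, NA, NA, NA),
    node_purity = c(5566.1174, 6401.3968, 774.6298, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Akaike weights from a set of AIC values
#'
#' \code{w_i = exp(-(AIC_i - AIC_min)/2) / sum_j exp(-(AIC_j - AIC_min)/2)};
#' invariant under adding a constant to all AICs.
#'
#' @param aics Numeric vector of finite AIC values (>= 1).
#' @return Vector of weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (!length(aics)) stop("empty AIC list")
  if (any(!is.finite(aics))) stop("non-finite AIC value")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit one GLS model of a time series with AR(1) errors
#'
#' Maximum-likelihood generalised least squares (so log-likelihoods are
#' comparable across fixed-effect structures) with an AR(1) correlation
#' on the residuals; set \code{ar1 = FALSE} for independent errors. The
#' parameter count k includes the intercept, slopes, the AR(1)
#' coefficient (when fitted) and the residual variance, and
#' \code{aic = 2k - 2 loglik}.
#'
#' @param y Response series (e.g. per-bin mean delta2).
#' @param X \code{data.frame} of predictor series (possibly 0 columns for
#'   the null/intercept-only model).
#' @param ar1 Fit an AR(1) error structure (default TRUE).
#' @param name Model label.
#' @return A \code{model_fit}: list with \code{name}, \code{loglik},
#'   \code{k}, \code{aic}, \code{coefficients}, \code{phi} and the
#'   underlying \code{gls} fit.
#' @export
gls_fit <- function(y, X, ar1 = TRUE, name = NULL) {
  stopifnot(is.numeric(y))
  X <- as.data.frame(X)
  if (length(y) < 5) stop("need >= 5 time points")
  if (ncol(X) > 0) {
    if (nrow(X) != length(y)) stop("predictor length mismatch")
    if (any(!is.finite(as.matrix(X)))) stop("non-finite predictor values")
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < ncol(X) + 1)
      stop("collinear predictors: ", paste(names(X), collapse = ", "))
  }
  dat <- cbind(data.frame(.y = y, .t = seq_along(y)), X)
  form <- if (ncol(X)) {
    stats::as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  } else .y ~ 1
  fit <- tryCatch({
    if (ar1) {
      nlme::gls(form, data = dat, method = "ML",
                correlation = nlme::corAR1(form = ~.t))
    } else {
      nlme::gls(form, data = dat, method = "ML")
    }
  }, error = function(e) stop("GLS did not converge for model '",
                              if (is.null(name)) deparse(form) else name,
                              "': ", conditionMessage(e)))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + 1L + as.integer(ar1)  # + sigma2 (+ phi)
  phi <- if (ar1) as.numeric(stats::coef(fit$modelStruct$corStruct,
                                         unconstrained = FALSE)) else NA_real_
  structure(list(name = if (is.null(name)) deparse(form) else name,
                 loglik = ll, k = k, aic = 2 * k - 2 * ll,
                 coefficients = stats::coef(fit), phi = phi, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit '", x$name, "': logLik = ", format(x$loglik, digits = 6),
      ", k = ", x$k, ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Compare candidate GLS models of the delta2 series
#'
#' Fits the six candidate models of the shift-magnitude series --
#' intercept-only null, extinction, origination, mass-extinction,
#' origination + extinction, origination + mass-extinction -- and
#' computes Akaike weights across exactly that set.
#'
#' @param delta2 Output of \code{\link{delta2_series}} (or a numeric
#'   vector of per-bin mean delta2).
#' @param rates A rate table with columns \code{orig_rate},
#'   \code{ext_rate} and \code{mass_ext} on the same bins.
#' @param ar1 Fit AR(1) errors (default TRUE).
#' @return \code{data.frame} with columns \code{model}, \code{loglik},
#'   \code{k}, \code{aic}, \code{weight}, sorted by decreasing weight.
#' @export
compare_models <- function(delta2, rates, ar1 = TRUE) {
  y <- if (is.data.frame(delta2)) delta2$mean_delta2 else delta2
  stopifnot(length(y) == nrow(rates))
  preds <- data.frame(origination = rates$orig_rate,
                      extinction = rates$ext_rate,
                      mass_extinction = rates$mass_ext)
  spec <- list(
    null = character(),
    extinction = "extinction",
    origination = "origination",
    mass_extinction = "mass_extinction",
    `origination+extinction` = c("origination", "extinction"),
    `origination+mass_extinction` = c("origination", "mass_extinction"))
  constant <- names(preds)[vapply(preds, function(p)
    stats::var(p) == 0, logical(1))]
  if (length(constant)) {
    drop <- vapply(spec, function(v) any(v %in% constant), logical(1))
    message("dropping model(s) with constant predictor(s) ",
            paste(constant, collapse = ", "), ": ",
            paste(names(spec)[drop], collapse = ", "))
    spec <- spec[!drop]
  }
  fits <- lapply(names(spec), function(nm)
    gls_fit(y, preds[spec[[nm]]], ar1 = ar1, name = nm))
  out <- data.frame(model = names(spec),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, `[[`, 0L, "k"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    stringsAsFactors = FALSE)
  out$weight <- akaike_weights(out$aic)
  out[order(-out$weight), , drop = FALSE]
}

#' Random-forest importance of rate predictors for the delta2 series
#'
#' Permutation importance (% increase in out-of-bag MSE), node-purity
#' importance and out-of-bag variance explained from a random-forest
#' regression of the shift series on the rate predictors; measures
#' absolute fit while guarding against overfitting.
#'
#' @param y Response series.
#' @param X \code{data.frame} of predictors.
#' @param n_trees Number of trees (>= 100; default 500).
#' @param seed RNG seed recorded in the output.
#' @return \code{data.frame} (one row per predictor) with \code{pct_mse}
#'   and \code{node_purity}; attributes \code{variance_explained} and
#'   \code{seed}.
#' @export
rf_importance <- function(y, X, n_trees = 500, seed = 1) {
  stopifnot(n_trees >= 100)
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (stats::var(y) == 0) stop("degenerate constant response")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  out <- data.frame(predictor = rownames(imp),
                    pct_mse = imp[, "%IncMSE"],
                    node_purity = imp[, "IncNodePurity"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "variance_explained") <- rf$rsq[length(rf$rsq)]
  attr(out, "seed") <- seed
  attr(out, "n_trees") <- n_trees
  out
}
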