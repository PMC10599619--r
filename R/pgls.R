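# Phylogenetic generalized least squares under the lambda-transformed
# Brownian covariance, and the 12-model suite regressing distance-to-centroid
# on species- and clade-level elaboration and innovation.

#' Fit a phylogenetic generalized least squares model
#'
#' GLS under the covariance `C(lambda)` obtained from the shared-path-length
#' matrix of the tree by multiplying its off-diagonal entries by `lambda`.
#' `lambda = 0` is ordinary least squares, `lambda = 1` the Brownian
#' expectation. The exact log-likelihood is reported with the ML rate
#' estimate; AIC counts every estimated parameter (coefficients, the rate,
#' and lambda when estimated).
#'
#' @param formula model formula; variables are looked up in `data`.
#' @param data data frame with rownames matching tip labels.
#' @param tree rooted `phylo`.
#' @param lambda `"fixed"` (use `lambda_value`) or `"estimated"` (profile ML
#'   on `[0, 1]`).
#' @param lambda_value the fixed lambda (default 1, Brownian motion).
#' @return object of class `phylo_gls` with the usual accessors:
#'   [coef()], [summary.phylo_gls()], [predict.phylo_gls()], [residuals()],
#'   [fitted()], [logLik()].
#' @examples
#' tr <- simulate_yule_tree(40, seed = 1)
#' d <- data.frame(x = rnorm(40), row.names = tr$tip.label)
#' d$y <- 2 * d$x + rnorm(40, sd = 0.1)
#' fit_pgls(y ~ x, d, tr)
#' @export
fit_pgls <- function(formula, data, tree, lambda = c("fixed", "estimated"),
                     lambda_value = 1) {
  lambda <- match.arg(lambda)
  stopifnot(inherits(tree, "phylo"), is.data.frame(data))
  miss <- setdiff(tree$tip.label, rownames(data))
  if (length(miss)) stop("data rows missing for tips: ", paste(miss, collapse = ", "))
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); q <- ncol(X)
  if (qr(X)$rank < q) {
    qr_ <- qr(X)
    bad <- colnames(X)[qr_$pivot[seq(qr_$rank + 1, q)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  A <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]

  fit_at <- function(lam) {
    C <- lam * A
    diag(C) <- diag(A)
    ch <- chol(C)
    yt <- backsolve(ch, y, transpose = TRUE)
    Xt <- backsolve(ch, X, transpose = TRUE)
    colnames(Xt) <- colnames(X)
    b <- stats::lm.fit(Xt, yt)
    rss <- sum(b$residuals^2)
    ldet <- 2 * sum(log(diag(ch)))
    s2_ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2_ml) + ldet + n)
    list(coef = b$coefficients, rss = rss, ll = ll, ch = ch, Xt = Xt, yt = yt,
         lambda = lam)
  }

  est_lambda <- lambda == "estimated"
  if (est_lambda) {
    opt <- stats::optimize(function(l) fit_at(l)$ll, c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    lls <- vapply(cand, function(l) fit_at(l)$ll, numeric(1))
    lam <- cand[which.max(lls)]
  } else lam <- lambda_value
  f <- fit_at(lam)

  s2 <- f$rss / (n - q)                       # unbiased, for SEs and t-tests
  XtXi <- chol2inv(qr.R(qr(f$Xt)))
  se <- stats::setNames(sqrt(diag(XtXi) * s2), names(f$coef))
  tval <- f$coef / se
  pval <- 2 * stats::pt(-abs(tval), df = n - q)

  # r2 against the GLS intercept-only model under the same covariance
  null_rss <- {
    ot <- backsolve(f$ch, rep(1, n), transpose = TRUE)
    mu <- sum(ot * f$yt) / sum(ot^2)
    sum((f$yt - mu * ot)^2)
  }
  r2 <- 1 - f$rss / null_rss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - q)

  p_count <- q + 1 + as.integer(est_lambda)   # coefficients + rate (+ lambda)
  aic <- 2 * p_count - 2 * f$ll

  out <- list(coefficients = f$coef, se = se, tvalue = tval, pvalue = pval,
              sigma2 = s2, logLik = f$ll, AIC = aic, adj_r2 = adj_r2,
              lambda = lam, lambda_mode = lambda, n = n, df.residual = n - q,
              n_par = p_count, formula = formula, tree_tips = tree$tip.label,
              fitted = drop(X %*% f$coef), residuals = y - drop(X %*% f$coef),
              call = match.call())
  class(out) <- "phylo_gls"
  out
}

#' @export
print.phylo_gls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  cat(sprintf("  lambda = %.3f (%s), n = %d, logLik = %.2f, AIC = %.2f, adj r2 = %.3f\n",
              x$lambda, x$lambda_mode, x$n, x$logLik, x$AIC, x$adj_r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Coefficient table for a phylogenetic GLS fit
#' @param object a `phylo_gls` fit.
#' @param ... unused.
#' @return the fit with a printed coefficient table (estimate, SE, t, p).
#' @export
summary.phylo_gls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tvalue, `Pr(>|t|)` = object$pvalue)
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.phylo_gls"
  out
}

#' @export
print.summary.phylo_gls <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.phylo_gls <- function(object, ...) object$coefficients

#' @export
residuals.phylo_gls <- function(object, ...) object$residuals

#' @export
fitted.phylo_gls <- function(object, ...) object$fitted

#' @export
logLik.phylo_gls <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = object$n, class = "logLik")
}

#' Predict from a phylogenetic GLS fit
#' @param object a `phylo_gls` fit.
#' @param newdata data frame of predictor values; the training fitted values
#'   when omitted.
#' @param ... unused.
#' @return numeric vector of linear predictions.
#' @export
predict.phylo_gls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  drop(X %*% object$coefficients)
}

# The 12 nested formulas of the model suite: the full two-way-interaction
# model, single-interaction removals, interaction-free multiple regressions,
# and single-predictor models.
table1_formulas <- function() {
  list(
    m1  = distance ~ elab_species + innov_species + elab_clade + innov_clade +
      elab_species:innov_clade + elab_species:elab_clade +
      innov_species:innov_clade + innov_species:elab_clade,
    m2  = distance ~ elab_species + innov_species + elab_clade + innov_clade +
      elab_species:innov_clade + innov_species:innov_clade +
      innov_species:elab_clade,
    m3  = distance ~ elab_species + innov_species + elab_clade + innov_clade +
      elab_species:innov_clade + elab_species:elab_clade +
      innov_species:innov_clade,
    m4  = distance ~ elab_species + innov_species + elab_clade + innov_clade +
      elab_species:elab_clade + innov_species:innov_clade +
      innov_species:elab_clade,
    m5  = distance ~ elab_species + innov_species + elab_clade + innov_clade +
      elab_species:innov_clade + elab_species:elab_clade +
      innov_species:elab_clade,
    m6  = distance ~ elab_species + innov_species + elab_clade + innov_clade,
    m7  = distance ~ elab_species + innov_species,
    m8  = distance ~ elab_clade + innov_clade,
    m9  = distance ~ elab_species,
    m10 = distance ~ innov_species,
    m11 = distance ~ elab_clade,
    m12 = distance ~ innov_clade
  )
}

#' Fit the 12-model elaboration/innovation PGLS suite
#'
#' Regresses distance-to-centroid on species- and clade-level elaboration and
#' innovation: the full two-way interaction model, its single-interaction
#' reductions, interaction-free multiple regressions, and the four
#' single-predictor models, all under a common lambda so AIC comparison is
#' meaningful. `lambda_mode = "fixed-min"` is a two-pass procedure: lambda is
#' estimated per model, the minimum taken, and every model refitted at it.
#'
#' @param data data frame with rownames matching tip labels and columns
#'   `distance`, `elab_species`, `innov_species`, `elab_clade`, `innov_clade`
#'   (clade-level scores broadcast to member species).
#' @param tree rooted `phylo`.
#' @param lambda_mode `"fixed-1"` (Brownian, default), `"fixed-min"`, or
#'   `"estimated"`.
#' @return object of class `pgls_suite`: data frame with one row per model
#'   (coefficient slots, ΔAIC relative to the best model, adjusted r²), with
#'   the fits in `attr(, "fits")`.
#' @export
table1_suite <- function(data, tree,
                         lambda_mode = c("fixed-1", "fixed-min", "estimated")) {
  lambda_mode <- match.arg(lambda_mode)
  need <- c("distance", "elab_species", "innov_species", "elab_clade",
            "innov_clade")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing predictor columns: ", paste(miss, collapse = ", "))
  fmls <- table1_formulas()

  fit_all <- function(mode, value = 1) {
    lapply(fmls, function(f)
      fit_pgls(f, data, tree, lambda = mode, lambda_value = value))
  }
  fits <- switch(lambda_mode,
    "fixed-1" = fit_all("fixed", 1),
    "estimated" = fit_all("estimated"),
    "fixed-min" = {
      first <- fit_all("estimated")
      lam_min <- min(vapply(first, function(f) f$lambda, numeric(1)))
      fit_all("fixed", lam_min)
    })

  slots <- c("elab_species", "innov_species", "elab_clade", "innov_clade",
             "elab_species:innov_clade", "elab_species:elab_clade",
             "innov_species:innov_clade", "innov_species:elab_clade")
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    cf <- coef(fits[[i]])
    row <- stats::setNames(rep(NA_real_, length(slots)), slots)
    row[intersect(names(cf), slots)] <- cf[intersect(names(cf), slots)]
    data.frame(model = names(fits)[i], t(row), check.names = FALSE,
               delta_AIC = aic[i] - min(aic),
               adj_r2 = fits[[i]]$adj_r2, lambda = fits[[i]]$lambda,
               row.names = NULL)
  }))
  attr(tab, "fits") <- fits
  class(tab) <- c("pgls_suite", "data.frame")
  tab
}

#' @export
print.pgls_suite <- function(x, digits = 3, ...) {
  fits <- attr(x, "fits")
  cat("PGLS model suite (common lambda =",
      format(x$lambda[1], digits = 3), ")\n")
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  slots <- setdiff(names(x), c("model", "delta_AIC", "adj_r2", "lambda"))
  disp <- x["model"]
  for (sl in slots) {
    col <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
      cf <- coef(fits[[i]]); pv <- fits[[i]]$pvalue
      col[i] <- if (sl %in% names(cf))
        paste0(format(round(cf[sl], digits)), stars(pv[sl])) else ""
    }
    disp[[sl]] <- col
  }
  disp$dAIC <- format(round(x$delta_AIC, 2))
  disp$adj_r2 <- format(round(x$adj_r2, 2))
  print(disp, row.names = FALSE)
  invisible(x)
}
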