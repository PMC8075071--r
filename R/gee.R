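#' Generalized estimating equations for clustered count data
#'
#' Fits a marginal log-linear count model by generalized estimating
#' equations (GEE): Fisher scoring on the estimating equations
#' \eqn{\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0} with
#' \eqn{\mu_{ij} = \exp(x_{ij}'\beta + o_{ij})}, a working correlation
#' matrix shared across clusters, and the robust (sandwich) covariance
#' estimator, so inference is valid even when the working correlation is
#' misspecified. The variance function is \eqn{v(\mu)=\mu} for the Poisson
#' family and \eqn{v(\mu)=\mu+\mu^2/\theta} for the negative binomial
#' family (with \eqn{\theta} estimated once by [MASS::glm.nb] on the
#' pooled data).
#'
#' With two repeated measures per cluster — e.g. a pre and a post period
#' per patient — the exchangeable structure estimates a single
#' within-patient correlation; with an independence structure the point
#' estimates coincide with an ordinary Poisson GLM (only the standard
#' errors differ).
#'
#' @param formula Model formula for the count outcome; use
#'   \code{offset(log(exposure))} terms or the \code{offset} argument to
#'   model rates.
#' @param data Data frame with one row per observation.
#' @param id Cluster identifier: a vector, or the (quoted or unquoted)
#'   name of a column of \code{data}.
#' @param family \code{"poisson"} or \code{"negative_binomial"}.
#' @param corstr Working correlation: \code{"exchangeable"} (default) or
#'   \code{"independence"}.
#' @param offset Optional numeric offset vector on the log scale (an
#'   alternative to an \code{offset()} term in the formula).
#' @param maxit,tol Fisher-scoring iteration cap and convergence tolerance
#'   on the maximum absolute coefficient change.
#' @return An object of class \code{gee_fit} with components
#'   \code{coefficients}, \code{vcov} (robust), \code{naive_vcov},
#'   \code{alpha} (estimated working correlation), \code{phi} (Pearson
#'   dispersion), \code{theta} (NB size, or \code{NA}), \code{n_clusters},
#'   \code{fitted.values}, \code{residuals} (Pearson), \code{converged},
#'   \code{family}, \code{corstr}, \code{call}. Supported methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{confint}, \code{predict}, \code{residuals}, \code{fitted}.
#' @export
#' @examples
#' d <- data.frame(y = c(2, 1, 3, 0, 4, 2), t = rep(0:1, 3),
#'                 days = rep(365, 6), id = rep(1:3, each = 2))
#' fit <- gee_count(y ~ t + offset(log(days)), d, id = id)
#' exp(coef(fit)["t"])  # post/pre rate ratio
gee_count <- function(formula, data, id,
                      family = c("poisson", "negative_binomial"),
                      corstr = c("exchangeable", "independence"),
                      offset = NULL, maxit = 50L, tol = 1e-10) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  cl <- match.call()

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- rep(0, length(y))
  if (!is.null(offset)) off <- off + offset

  id_expr <- substitute(id)
  idv <- if (is.character(id_expr) || (is.name(id_expr) &&
             as.character(id_expr) %in% names(data))) {
    data[[as.character(id_expr)]]
  } else id
  kept <- attr(mf, "na.action")
  if (!is.null(kept)) idv <- idv[-kept]
  if (length(idv) != length(y)) stop("'id' must match the rows of 'data'")
  clusters <- split(seq_along(y), idv)
  n_clus <- length(clusters)
  if (n_clus < 2) stop("GEE needs at least 2 clusters, got ", n_clus)

  theta <- NA_real_
  if (family == "negative_binomial") {
    nb <- suppressWarnings(MASS::glm.nb(y ~ X - 1 + offset(off)))
    theta <- nb$theta
  }
  varfun <- function(mu) if (family == "poisson") mu else mu + mu^2 / theta

  # initialise at the independence (GLM) solution
  beta <- stats::glm.fit(X, y, offset = off,
                         family = stats::poisson())$coefficients
  p <- length(beta)
  alpha <- 0
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    v <- varfun(mu)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in clusters) {
        m <- length(ix)
        if (m > 1) {
          rc <- r[ix]
          num <- num + (sum(rc)^2 - sum(rc^2)) / 2
          den <- den + m * (m - 1) / 2
        }
      }
      alpha <- if (den > 0) num / (den * phi) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    U <- numeric(p); H <- matrix(0, p, p)
    for (ix in clusters) {
      m <- length(ix)
      Ai <- sqrt(v[ix])
      Di <- (mu[ix] * X[ix, , drop = FALSE])
      Ri <- if (corstr == "exchangeable" && m > 1) {
        matrix(alpha, m, m) + diag(1 - alpha, m)
      } else diag(1, m)
      Vi_inv <- solve(Ri * tcrossprod(Ai)) / phi
      U <- U + crossprod(Di, Vi_inv %*% (y[ix] - mu[ix]))
      H <- H + crossprod(Di, Vi_inv %*% Di)
    }
    delta <- solve(H, U)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("GEE did not converge in ", maxit, " iterations ",
         "(last max coefficient change ", signif(max(abs(delta)), 3),
         "); check for separation or degenerate exposures")
  }

  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  v <- varfun(mu)
  r <- (y - mu) / sqrt(v)
  phi <- sum(r^2) / (length(y) - p)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in clusters) {
    m <- length(ix)
    Ai <- sqrt(v[ix])
    Di <- (mu[ix] * X[ix, , drop = FALSE])
    Ri <- if (corstr == "exchangeable" && m > 1) {
      matrix(alpha, m, m) + diag(1 - alpha, m)
    } else diag(1, m)
    Vi_inv <- solve(Ri * tcrossprod(Ai)) / phi
    si <- crossprod(Di, Vi_inv %*% (y[ix] - mu[ix]))
    B <- B + crossprod(Di, Vi_inv %*% Di)
    M <- M + tcrossprod(si)
  }
  B_inv <- solve(B)
  robust <- B_inv %*% M %*% B_inv
  robust <- (robust + t(robust)) / 2
  # a zero score (e.g. perfectly symmetric data) can leave the diagonal
  # at -epsilon; clamp so downstream sqrt is defined
  diag(robust) <- pmax(diag(robust), 0)
  dimnames(robust) <- list(colnames(X), colnames(X))
  naive <- B_inv
  dimnames(naive) <- dimnames(robust)

  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = robust, naive_vcov = naive, alpha = alpha, phi = phi,
                 theta = theta, n_clusters = n_clus, n_obs = length(y),
                 fitted.values = mu, residuals = r, linear.predictors = eta,
                 offset = off, y = y, X = X,
                 converged = converged, iterations = iter,
                 family = family, corstr = corstr,
                 formula = formula, call = cl),
            class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
fitted.gee_fit <- function(object, ...) object$fitted.values

#' @export
residuals.gee_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (type == "pearson") object$residuals else object$y - object$fitted.values
}

#' @export
predict.gee_fit <- function(object, newdata = NULL,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    object$linear.predictors
  } else {
    mf <- stats::model.frame(stats::delete.response(stats::terms(object$formula)),
                             newdata)
    off <- stats::model.offset(mf)
    drop(stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                             mf) %*% object$coefficients) +
      if (is.null(off)) 0 else off
  }
  if (type == "link") eta else exp(eta)
}

#' @export
confint.gee_fit <- function(object, parm, level = 0.95, ...) {
  cf <- stats::coef(object)
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.gee_fit <- function(x, digits = 4, ...) {
  cat("Count GEE (", x$family, " family, ", x$corstr,
      " working correlation)\n", sep = "")
  cat("Clusters:", x$n_clusters, " Observations:", x$n_obs, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, alpha = object$alpha, phi = object$phi,
              theta = object$theta, family = object$family,
              corstr = object$corstr, n_clusters = object$n_clusters,
              n_obs = object$n_obs, call = object$call)
  class(out) <- "summary.gee_fit"
  out
}

#' @export
print.summary.gee_fit <- function(x, digits = 4, ...) {
  cat("Count GEE (", x$family, " family, ", x$corstr,
      " working correlation)\n", sep = "")
  cat("Clusters:", x$n_clusters, " Observations:", x$n_obs, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nScale (Pearson dispersion):", round(x$phi, digits))
  if (x$corstr == "exchangeable") {
    cat("  Working correlation:", round(x$alpha, digits))
  }
  if (!is.na(x$theta)) cat("  NB size:", round(x$theta, digits))
  cat("\n")
  invisible(x)
}

#' Choose between a Poisson and a negative binomial count model
#'
#' Fits a Poisson log-linear model for the outcome (intervention indicator
#' plus log-exposure offset) and computes the Pearson dispersion
#' statistic, chi-squared over residual degrees of freedom. Equidispersed
#' (Poisson-like) data give values near 1; values above the threshold
#' indicate overdispersion and select the negative binomial family.
#'
#' @param table Patient-period table from [build_period_table()].
#' @param outcome \code{"exacerbations"} or \code{"hosp_days"}.
#' @param threshold Dispersion above which the negative binomial family is
#'   selected (default 1.5).
#' @return \code{"poisson"} or \code{"negative_binomial"}, with the
#'   dispersion statistic in attribute \code{"dispersion"}.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 50, seed = 3), daily = FALSE)
#' tab <- build_period_table(sim$cohort, sim$events)
#' select_family(tab, "exacerbations")
select_family <- function(table, outcome = c("exacerbations", "hosp_days"),
                          threshold = 1.5) {
  outcome <- match.arg(outcome)
  y <- outcome_vector(table, outcome)
  if (length(unique(table$patient_id)) < 2) {
    stop("family selection needs at least 2 patients")
  }
  if (all(y == 0)) {
    stop("all '", outcome, "' counts are zero: no rate model is identifiable; ",
         "report descriptive statistics only")
  }
  fit <- stats::glm(y ~ table$intervention + offset(log(table$exposure_days)),
                    family = stats::poisson())
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  structure(if (disp > threshold) "negative_binomial" else "poisson",
            dispersion = disp)
}

model_terms <- list(
  `1` = "intervention",
  `2` = c("intervention", "sex", "age"),
  `3` = c("intervention", "sex", "age", "gold"),
  `4` = c("intervention", "sex", "age", "gold", "ics_use")
)

outcome_vector <- function(table, outcome) {
  switch(outcome, exacerbations = table$n_exacerbations,
         hosp_days = table$n_hosp_days,
         stop("unknown outcome: ", outcome))
}

#' Pre-post incidence rate ratio from a Poisson GEE
#'
#' Estimates the post-versus-pre incidence rate ratio (IRR) of an outcome
#' count with a log-linear GEE: the intervention indicator (0 = pre,
#' 1 = post) is the exposure of interest, the log of the period length
#' enters as an offset, and clustering by patient is handled by the
#' working correlation plus robust standard errors. Four nested
#' covariate sets mirror a staged confounder adjustment: model 1 is crude;
#' model 2 adds sex and age; model 3 adds GOLD category (patients with a
#' missing GOLD category are excluded); model 4 adds inhaled
#' corticosteroid use.
#'
#' @param table Patient-period table from [build_period_table()] (two rows
#'   per patient).
#' @param outcome \code{"exacerbations"} (total exacerbation count) or
#'   \code{"hosp_days"} (days admitted to hospital).
#' @param model_id 1-4, the adjustment set (see Details).
#' @param family Count family; \code{NULL} (default) picks it with
#'   [select_family()].
#' @param corstr Working correlation passed to [gee_count()].
#' @return An object of classes \code{irr_fit} and \code{gee_fit}; in
#'   addition to the [gee_count()] components it carries
#'   \code{outcome_name}, \code{model_id}, \code{irr}, \code{ci_low},
#'   \code{ci_high} (Wald 95% CI on the IRR scale), \code{robust_se} (of
#'   the log IRR) and \code{n_patients}.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 60, seed = 5), daily = FALSE)
#' tab <- build_period_table(sim$cohort, sim$events)
#' fit_irr(tab, "exacerbations", model_id = 1)
fit_irr <- function(table, outcome = c("exacerbations", "hosp_days"),
                    model_id = 1, family = NULL,
                    corstr = c("exchangeable", "independence")) {
  outcome <- match.arg(outcome)
  corstr <- match.arg(corstr)
  model_id <- as.character(model_id)
  if (!model_id %in% names(model_terms)) {
    stop("model_id must be 1, 2, 3 or 4")
  }
  if (model_id %in% c("3", "4")) {
    table <- table[!is.na(table$gold) & table$gold != "missing", , drop = FALSE]
  }
  if (length(unique(table$patient_id)) < 2) {
    stop("fewer than 2 patients with complete data for model ", model_id)
  }
  if (is.null(family)) family <- as.character(select_family(table, outcome))
  table$.y <- outcome_vector(table, outcome)
  rhs <- paste(c(model_terms[[model_id]], "offset(log(exposure_days))"),
               collapse = " + ")
  fit <- gee_count(stats::as.formula(paste(".y ~", rhs)), data = table,
                   id = table$patient_id, family = family, corstr = corstr)
  b <- fit$coefficients[["intervention"]]
  se <- sqrt(fit$vcov["intervention", "intervention"])
  fit$outcome_name <- outcome
  fit$model_id <- as.integer(model_id)
  fit$robust_se <- se
  fit$irr <- exp(b)
  fit$ci_low <- exp(b - 1.96 * se)
  fit$ci_high <- exp(b + 1.96 * se)
  fit$n_patients <- length(unique(table$patient_id))
  class(fit) <- c("irr_fit", class(fit))
  fit
}

#' @export
print.irr_fit <- function(x, digits = 3, ...) {
  cat("Pre-post IRR, outcome '", x$outcome_name, "', model ", x$model_id,
      " (", x$family, " GEE, ", x$corstr, ")\n", sep = "")
  cat(sprintf("IRR %.*f (95%% CI %.*f-%.*f), %d patients\n",
              digits, x$irr, digits, x$ci_low, digits, x$ci_high,
              x$n_patients))
  invisible(x)
}

#' Trend of repeated CCQ health-status scores over time
#'
#' Fits a marginal linear model of the CCQ score on time with clustering
#' by patient: ordinary least squares point estimates with a
#' cluster-robust (sandwich) standard error, i.e. an identity-link GEE
#' with independence working correlation. The slope is reported per 30
#' days.
#'
#' @param ccq_long Data frame with columns \code{patient_id}, \code{day},
#'   \code{ccq} (rows with missing CCQ are dropped).
#' @return A list with \code{slope} (CCQ points per 30 days), \code{se},
#'   \code{p_value} (two-sided Wald) and \code{n_patients}.
#' @export
ccq_trend <- function(ccq_long) {
  d <- ccq_long[!is.na(ccq_long$ccq), , drop = FALSE]
  tab <- table(d$patient_id)
  if (length(tab) < 2 || sum(tab >= 2) < 2) {
    stop("CCQ trend needs at least 2 observations for at least 2 patients")
  }
  if (stats::var(d$ccq) == 0) {
    warning("all CCQ scores identical: slope is 0 with degenerate variance")
    return(list(slope = 0, se = NA_real_, p_value = NA_real_,
                n_patients = length(tab)))
  }
  d$month <- d$day / 30
  fit <- stats::lm(ccq ~ month, data = d)
  X <- stats::model.matrix(fit)
  r <- stats::residuals(fit)
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (ix in split(seq_len(nrow(d)), d$patient_id)) {
    s <- crossprod(X[ix, , drop = FALSE], r[ix])
    meat <- meat + tcrossprod(s)
  }
  V <- bread %*% meat %*% bread
  slope <- stats::coef(fit)[["month"]]
  se <- sqrt(V[2, 2])
  list(slope = slope, se = se,
       p_value = 2 * stats::pnorm(-abs(slope / se)),
       n_patients = length(tab))
}
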