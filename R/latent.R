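#' Latent-dependent covariates from gender identity and natal sex
#'
#' The model terms that depend on the (possibly unobserved) natal sex of a
#' non-binary athlete: `nb_predictor` is +1 for natal-male non-binary
#' athletes, -1 for natal-female non-binary athletes and 0 otherwise;
#' `is_nbm` and `is_nbf` indicate natal-male non-binary and natal-female
#' non-binary respectively; `is_nb` = `is_nbm + is_nbf` indicates any
#' non-binary athlete. Athletes not registered non-binary get all zeros.
#'
#' @param gender_id Character vector in `{male, female, non-binary}`.
#' @param natal_sex Character vector in `{male, female}`.
#' @return Data frame with columns `nb_predictor`, `is_nbm`, `is_nbf`,
#'   `is_nb`.
#' @export
#' @examples
#' latent_covariates("non-binary", "male")    # +1, 1, 0, 1
#' latent_covariates("non-binary", "female")  # -1, 0, 1, 1
latent_covariates <- function(gender_id, natal_sex) {
  if (!all(gender_id %in% c("male", "female", "non-binary"))) {
    stop("invalid gender_id", call. = FALSE)
  }
  if (!all(natal_sex %in% c("male", "female"))) {
    stop("invalid natal_sex", call. = FALSE)
  }
  nb <- gender_id == "non-binary"
  m <- natal_sex == "male"
  data.frame(nb_predictor = ifelse(nb, ifelse(m, 1, -1), 0),
             is_nbm = as.numeric(nb & m),
             is_nbf = as.numeric(nb & !m),
             is_nb = as.numeric(nb))
}

#' Specification of the four log-time models
#'
#' All four models share event fixed effects and linear plus quadratic age
#' terms centred at 40. They differ in the sex/gender term and the
#' non-binary term:
#' \describe{
#'   \item{1}{`event + natal_sex + (age-40) + (age-40)^2 + nb_predictor`}
#'   \item{2}{`event + gender_id + (age-40) + (age-40)^2 + nb_predictor`}
#'   \item{3}{`event + natal_sex + (age-40) + (age-40)^2 + is_nbm + is_nbf`}
#'   \item{4}{`event + natal_sex + (age-40) + (age-40)^2 + is_nb`}
#' }
#' `natal_sex` (models 1, 3, 4) and `nb_predictor`, `is_nbm`, `is_nbf` are
#' functions of the latent natal sex; `gender_id` and `is_nb` are observed.
#'
#' @param model_id Integer 1-4.
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_id) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:4) stop("model_id must be 1, 2, 3 or 4", call. = FALSE)
  structure(list(
    model_id = model_id,
    sex_term = if (model_id == 2L) "gender_id" else "natal_sex",
    extra_terms = switch(model_id, "nb_predictor", "nb_predictor",
                         c("is_nbm", "is_nbf"), "is_nb")
  ), class = "model_spec")
}

# Design matrices for the two latent completions. Returns X_M and X_F, the
# design with every athlete's natal sex set to male resp. female; rows are
# later mixed with weights prob_male and 1 - prob_male.
.latent_design <- function(data, spec) {
  stopifnot(all(c("event", "age", "gender_id", "time_seconds", "prob_male")
                %in% names(data)))
  if (any(is.na(data$prob_male))) {
    stop("every record needs an assigned prob_male; drop unassigned records first",
         call. = FALSE)
  }
  ev <- factor(data$event)
  base <- if (nlevels(ev) >= 2L) {
    stats::model.matrix(~ ev)
  } else {
    matrix(1, nrow = nrow(data), dimnames = list(NULL, "(Intercept)"))
  }
  colnames(base) <- sub("^ev", "event:", colnames(base))
  age_c <- data$age - 40
  nb <- as.numeric(data$gender_id == "non-binary")

  obs <- cbind(base, age_c = age_c, age_c2 = age_c^2)
  if (spec$sex_term == "gender_id") {
    obs <- cbind(obs,
                 gender_female = as.numeric(data$gender_id == "female"),
                 gender_nonbinary = nb)
  }

  sex_cols <- function(sex) {
    f <- as.numeric(sex == "female")
    cols <- NULL
    if (spec$sex_term == "natal_sex") cols <- cbind(natal_female = rep(f, nrow(data)))
    lat <- latent_covariates(data$gender_id,
                             rep(sex, nrow(data)))
    cbind(cols, as.matrix(lat[, spec$extra_terms, drop = FALSE]))
  }
  X_M <- cbind(obs, sex_cols("male"))
  X_F <- cbind(obs, sex_cols("female"))
  list(X_M = X_M, X_F = X_F,
       y = log(data$time_seconds), p = data$prob_male)
}

# EM for a linear model with a latent binary covariate. Each record i with
# prob_male p_i contributes the two-component marginal likelihood
#   p_i N(y_i; x_i(M) beta, s2) + (1 - p_i) N(y_i; x_i(F) beta, s2);
# records with degenerate p_i collapse to a single Gaussian term, so with no
# uncertain records the fit is exactly ordinary least squares. The E-step
# computes posterior male responsibilities; the M-step is weighted least
# squares on the two completion rows with a single shared sigma.
.latent_em <- function(X_M, X_F, y, p, tol = 1e-10, max_iter = 500L,
                       on_nonconv = c("error", "keep")) {
  on_nonconv <- match.arg(on_nonconv)
  n <- length(y)
  k <- ncol(X_M)
  cert <- p == 0 | p == 1
  Xc <- X_M
  i0 <- which(p == 0)
  if (length(i0)) Xc[i0, ] <- X_F[i0, , drop = FALSE]
  Xcert <- Xc[cert, , drop = FALSE]
  ycert <- y[cert]
  Ac <- crossprod(Xcert)
  bc <- crossprod(Xcert, ycert)
  un <- which(!cert)
  XMu <- X_M[un, , drop = FALSE]
  XFu <- X_F[un, , drop = FALSE]
  yu <- y[un]
  pu <- p[un]
  lpu <- log(pu)
  lqu <- log1p(-pu)

  mstep <- function(rM) {
    A <- Ac
    b <- bc
    if (length(un)) {
      A <- A + crossprod(XMu, rM * XMu) + crossprod(XFu, (1 - rM) * XFu)
      b <- b + crossprod(XMu, rM * yu) + crossprod(XFu, (1 - rM) * yu)
    }
    beta <- tryCatch(solve(A, b),
                     error = function(e) stop("singular design matrix",
                                              call. = FALSE))
    rc <- ycert - Xcert %*% beta
    ss <- sum(rc^2)
    if (length(un)) {
      rmu <- yu - XMu %*% beta
      rfu <- yu - XFu %*% beta
      ss <- ss + sum(rM * rmu^2 + (1 - rM) * rfu^2)
    }
    list(beta = drop(beta), sig2 = ss / n)
  }

  est <- mstep(if (length(un)) pu else numeric(0))
  ll_prev <- -Inf
  ll <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sd_ <- sqrt(est$sig2)
    llc <- sum(stats::dnorm(ycert, Xcert %*% est$beta, sd_, log = TRUE))
    if (length(un)) {
      dM <- stats::dnorm(yu, XMu %*% est$beta, sd_, log = TRUE) + lpu
      dF <- stats::dnorm(yu, XFu %*% est$beta, sd_, log = TRUE) + lqu
      mx <- pmax(dM, dF)
      lse <- mx + log(exp(dM - mx) + exp(dF - mx))
      ll <- llc + sum(lse)
      rM <- exp(dM - lse)
    } else {
      ll <- llc
      rM <- numeric(0)
    }
    trace[iter] <- ll
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    est <- mstep(rM)
  }
  if (!converged && on_nonconv == "error") {
    stop("EM did not converge within ", max_iter, " iterations", call. = FALSE)
  }
  list(beta = est$beta, sig2 = est$sig2, loglik = ll, iterations = iter,
       converged = converged, loglik_trace = trace)
}

#' Fit a log-time linear model with latent natal sex
#'
#' Maximizes, by EM, the marginal likelihood of a Gaussian linear model for
#' log finish time in which each record's natal sex is a latent binary
#' variable with known probability `prob_male`, and the natal-sex and
#' non-binary covariates are evaluated under both completions. Records with
#' `prob_male` 0 or 1 contribute a single Gaussian component, so when every
#' probability is degenerate the estimator reduces exactly to ordinary least
#' squares on the completed data. A single residual SD is shared across
#' components. Columns that are identically zero under both completions
#' (e.g. non-binary indicators when no athlete registered non-binary) are
#' dropped with a warning and reported in `dropped_terms`.
#'
#' @param data Cross-race data frame with `event`, `age`, `gender_id`,
#'   `time_seconds` and `prob_male` (no `NA`s) columns.
#' @param spec A [model_spec()] (or a model id 1-4).
#' @param tol Convergence tolerance on successive marginal log-likelihoods.
#' @param max_iter Maximum EM iterations; exceeding it is an error.
#' @return A `latent_fit`: list with `coefficients`, `residual_sd`,
#'   `loglik`, `loglik_trace`, `n_obs`, `iterations`, `converged`, `spec`,
#'   `dropped_terms`, and the design kept for reuse by
#'   [monte_carlo_pvalues()] and [residual_qq()].
#' @export
fit_latent_model <- function(data, spec, tol = 1e-10, max_iter = 500L) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  des <- .latent_design(data, spec)
  zero <- apply(des$X_M == 0, 2, all) & apply(des$X_F == 0, 2, all)
  dropped <- colnames(des$X_M)[zero]
  if (length(dropped)) {
    warning("structurally zero term(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    des$X_M <- des$X_M[, !zero, drop = FALSE]
    des$X_F <- des$X_F[, !zero, drop = FALSE]
  }
  em <- .latent_em(des$X_M, des$X_F, des$y, des$p, tol = tol,
                   max_iter = max_iter, on_nonconv = "error")
  coefs <- em$beta
  names(coefs) <- colnames(des$X_M)
  structure(list(
    coefficients = coefs,
    residual_sd = sqrt(em$sig2),
    loglik = em$loglik,
    loglik_trace = em$loglik_trace,
    n_obs = length(des$y),
    iterations = em$iterations,
    converged = em$converged,
    spec = spec,
    dropped_terms = dropped,
    design = des,
    tol = tol, max_iter = max_iter
  ), class = "latent_fit")
}

#' @export
print.latent_fit <- function(x, ...) {
  cat(sprintf("Latent natal-sex linear model (model %d), n = %d\n",
              x$spec$model_id, x$n_obs))
  cat(sprintf("  residual SD %.5f, log-likelihood %.3f (%d EM iterations)\n",
              x$residual_sd, x$loglik, x$iterations))
  nonev <- !grepl("^event:|^\\(Intercept\\)", names(x$coefficients))
  print(round(x$coefficients[nonev], 5))
  invisible(x)
}

#' Parametric-bootstrap Monte Carlo p-values for one coefficient
#'
#' Simulates the sampling distribution of the coefficient estimate under the
#' null that `term`'s coefficient is zero. The null parameter vector is the
#' fitted one with `term` zeroed; each simulation draws every athlete's
#' natal sex from their (fixed, observed) `prob_male`, generates log times
#' from the corresponding completion row plus Gaussian noise at the fitted
#' residual SD, refits the latent model, and records the term's estimate.
#' P-values use the add-one estimator `(r + 1) / (n_sims + 1)`, which cannot
#' be zero. The one-tailed p counts exceedances in the alternative's
#' direction: the observed estimate's sign by default, or a pre-registered
#' `"positive"`/`"negative"` direction.
#'
#' @param fit A [fit_latent_model()] result.
#' @param term Coefficient name present in the fit.
#' @param n_sims Number of simulations (>= 1).
#' @param seed RNG seed; same seed and inputs give identical p-values.
#' @param direction `"observed"`, `"positive"` or `"negative"`.
#' @return List with `term`, `estimate`, `p_one_tailed`, `p_two_tailed`,
#'   `n_sims`, `direction`, `n_nonconverged` (simulated refits that hit the
#'   iteration cap; their final iterate is used).
#' @export
monte_carlo_pvalues <- function(fit, term, n_sims = 1000L, seed = 1L,
                                direction = c("observed", "positive", "negative")) {
  stopifnot(inherits(fit, "latent_fit"))
  direction <- match.arg(direction)
  if (!term %in% names(fit$coefficients)) {
    stop("term '", term, "' is not in the fitted model", call. = FALSE)
  }
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)

  des <- fit$design
  beta0 <- fit$coefficients
  beta0[term] <- 0
  muM <- drop(des$X_M %*% beta0)
  muF <- drop(des$X_F %*% beta0)
  sd0 <- fit$residual_sd
  n <- length(des$y)
  j <- match(term, names(fit$coefficients))

  set.seed(as.integer(seed))
  bstar <- numeric(n_sims)
  nonconv <- 0L
  for (s in seq_len(n_sims)) {
    male <- stats::runif(n) < des$p
    ystar <- ifelse(male, muM, muF) + stats::rnorm(n, 0, sd0)
    em <- .latent_em(des$X_M, des$X_F, ystar, des$p, tol = 1e-8,
                     max_iter = fit$max_iter, on_nonconv = "keep")
    if (!em$converged) nonconv <- nonconv + 1L
    bstar[s] <- em$beta[j]
  }
  bhat <- fit$coefficients[[term]]
  p_two <- (sum(abs(bstar) >= abs(bhat)) + 1) / (n_sims + 1)
  dir_sign <- switch(direction,
                     observed = if (bhat >= 0) 1 else -1,
                     positive = 1, negative = -1)
  p_one <- (sum(dir_sign * bstar >= dir_sign * bhat) + 1) / (n_sims + 1)
  list(term = term, estimate = bhat, p_one_tailed = p_one, p_two_tailed = p_two,
       n_sims = n_sims, direction = direction, n_nonconverged = nonconv)
}

#' Convert a log-time coefficient to a percentage effect
#'
#' `100 * (exp(coefficient) - 1)`: the multiplicative change in race time
#' implied by a unit change in the covariate.
#'
#' @param coefficient Numeric vector of log-time coefficients.
#' @return Percentage effect sizes.
#' @export
#' @examples
#' effect_size_pct(0.12221)  # ~13.00
effect_size_pct <- function(coefficient) {
  100 * (exp(coefficient) - 1)
}

#' Significance stars for a two-tailed p-value
#'
#' `***` < 0.001, `**` < 0.01, `*` < 0.05, `(.)` < 0.10, otherwise empty.
#'
#' @param p Numeric vector of two-tailed p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.10, "(.)", ""))))
}

#' Normal Q-Q data for the residuals of a latent fit
#'
#' Residuals are computed with natal sex at its known value; by default the
#' data are restricted to athletes whose sex is known (`prob_male` 0 or 1),
#' matching the usual residual diagnostic for this model class. With
#' `known_sex_only = FALSE`, uncertain records use their posterior-mode
#' completion. Ordered residuals are paired with standard normal quantiles
#' at `(i - 0.5) / n`.
#'
#' @param fit A [fit_latent_model()] result.
#' @param known_sex_only Restrict to records with degenerate `prob_male`.
#' @return Data frame with columns `theoretical_quantile`,
#'   `ordered_residual`.
#' @export
residual_qq <- function(fit, known_sex_only = TRUE) {
  stopifnot(inherits(fit, "latent_fit"))
  des <- fit$design
  beta <- fit$coefficients
  resM <- des$y - drop(des$X_M %*% beta)
  resF <- des$y - drop(des$X_F %*% beta)
  male <- des$p > 0.5
  r <- ifelse(male, resM, resF)
  if (known_sex_only) r <- r[des$p == 0 | des$p == 1]
  n <- length(r)
  if (n == 0L) {
    return(data.frame(theoretical_quantile = numeric(0),
                      ordered_residual = numeric(0)))
  }
  data.frame(theoretical_quantile = stats::qnorm((seq_len(n) - 0.5) / n),
             ordered_residual = sort(r))
}

#' Tabulate a latent fit in the published-report layout
#'
#' One row per non-event coefficient with its percentage effect size, the
#' Monte Carlo one- and two-tailed p-values (where supplied) and
#' significance stars derived from the two-tailed p.
#'
#' @param fit A [fit_latent_model()] result.
#' @param pvalues Optional named list of [monte_carlo_pvalues()] results,
#'   keyed by term.
#' @param include_events Include intercept and event coefficients (no
#'   p-values are attached to them); default `FALSE`.
#' @return Data frame with columns `Parameter`, `Coefficient`,
#'   `Effect_size_pct`, `P_one_tailed`, `P_two_tailed`, `Stars`.
#' @export
fit_table <- function(fit, pvalues = NULL, include_events = FALSE) {
  stopifnot(inherits(fit, "latent_fit"))
  terms <- names(fit$coefficients)
  if (!include_events) {
    terms <- terms[!grepl("^event:|^\\(Intercept\\)", terms)]
  }
  p1 <- p2 <- rep(NA_real_, length(terms))
  if (!is.null(pvalues)) {
    for (i in seq_along(terms)) {
      pv <- pvalues[[terms[i]]]
      if (!is.null(pv)) {
        p1[i] <- pv$p_one_tailed
        p2[i] <- pv$p_two_tailed
      }
    }
  }
  data.frame(
    Parameter = terms,
    Coefficient = unname(fit$coefficients[terms]),
    Effect_size_pct = effect_size_pct(unname(fit$coefficients[terms])),
    P_one_tailed = p1,
    P_two_tailed = p2,
    Stars = ifelse(is.na(p2), "", significance_stars(p2)),
    stringsAsFactors = FALSE
  )
}
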