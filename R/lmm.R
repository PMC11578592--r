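#' @keywords internal
"_PACKAGE"

#' Z-score a numeric vector (population SD)
#'
#' Centres to mean 0 and scales to SD 1 using the population formula
#' (divide by n). Fixed-effect estimates are invariant to the n vs n-1
#' convention because outcome and predictors share it; the population
#' formula gives exactly +/-1 for balanced binary factors.
#'
#' @param x numeric vector with no NAs.
#' @return numeric vector, mean 0, SD 1.
#' @export
zscore <- function(x) {
  if (anyNA(x)) stop("zscore: NA values in input")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zscore: zero-variance input")
  (x - mean(x)) / s
}

## Map a 2-level column (numeric, character or factor) to 0/1.
code_binary <- function(x, name = deparse(substitute(x))) {
  u <- sort(unique(x))
  if (length(u) != 2L) {
    stop(sprintf("factor '%s' must have exactly 2 levels, found %d",
                 name, length(u)))
  }
  as.numeric(x == u[2L])
}

#' Build a z-scored factorial design matrix
#'
#' Each factor is coded 0/1, z-scored across the analysed trials, and
#' interaction columns are formed as products of the z-scored parents
#' (they are not re-z-scored). Optional continuous covariates are
#' z-scored and appended after the factorial terms.
#'
#' @param data data.frame holding the factor and covariate columns.
#' @param factors character vector of factor column names; all main
#'   effects and interactions up to the full order are generated.
#' @param covariates character vector of numeric covariate columns.
#' @return numeric matrix with an `(Intercept)` column first; term names
#'   use `:` for interactions.
#' @export
zscore_design <- function(data, factors, covariates = character()) {
  stopifnot(is.data.frame(data), length(factors) >= 1L)
  zcols <- lapply(factors, function(f) {
    x <- data[[f]]
    if (is.null(x)) stop(sprintf("column '%s' not found", f))
    if (!is.numeric(x) || !all(x %in% c(0, 1))) x <- code_binary(x, f)
    zscore(x)
  })
  names(zcols) <- factors
  terms <- list()
  for (k in seq_along(factors)) {
    for (idx in utils::combn(length(factors), k, simplify = FALSE)) {
      nm <- paste(factors[idx], collapse = ":")
      terms[[nm]] <- Reduce(`*`, zcols[idx])
    }
  }
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stop(sprintf("covariate '%s' not found", cv))
    terms[[cv]] <- zscore(as.numeric(x))
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, terms))
  colnames(X) <- c("(Intercept)", names(terms))
  X
}

#' Random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits `y = X b + u[group] + e`, `u ~ N(0, tau2)`, `e ~ N(0, sigma2)` by
#' ML. The fixed effects and residual variance are profiled out
#' analytically, leaving a one-dimensional optimisation over the variance
#' ratio `lambda = tau2/sigma2`; each objective evaluation costs
#' O(G p^2) after one O(N p) pass, which makes refits cheap enough to sit
#' inside permutation loops. Estimates agree with `lme4::lmer(REML =
#' FALSE)` (checked in the test suite).
#'
#' @param y numeric outcome vector.
#' @param X design matrix (include the intercept column yourself).
#' @param group grouping vector (participant ids).
#' @return list with `beta`, `se`, `t`, `df` (n - p), `p`, `ci_low`,
#'   `ci_high`, `sigma2`, `tau2`, `lambda`, `logLik`, `n`, `n_groups`,
#'   `converged`.
#' @export
fit_ranint_ml <- function(y, X, group) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  N <- length(y)
  p <- ncol(X)
  if (nrow(X) != N) stop("nrow(X) != length(y)")
  g <- as.integer(factor(group))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)
  S <- rowsum(X, g, reorder = TRUE)           # G x p group sums of X
  tg <- drop(rowsum(y, g, reorder = TRUE))    # group sums of y
  ng <- as.numeric(tabulate(g))
  G <- length(ng)

  solve_at <- function(lam) {
    w <- lam / (1 + lam * ng)
    A <- XtX - crossprod(S * sqrt(w))
    b <- Xty - drop(crossprod(S, w * tg))
    q <- yty - sum(w * tg^2)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    rss <- max(q - sum(b * beta), .Machine$double.eps)
    sigma2 <- rss / N
    dev <- N * log(2 * pi * sigma2) + sum(log1p(lam * ng)) + N
    list(lam = lam, beta = beta, sigma2 = sigma2, chol = ch, dev = dev)
  }

  obj <- function(u) {
    f <- solve_at(exp(u))
    if (is.null(f)) Inf else f$dev
  }
  opt <- stats::optimize(obj, interval = c(-14, 12), tol = 1e-8)
  cand <- solve_at(exp(opt$minimum))
  bnd <- solve_at(0)
  fit <- if (!is.null(bnd) && (is.null(cand) || bnd$dev <= cand$dev)) bnd else cand
  if (is.null(fit)) stop("fit_ranint_ml: singular design")

  Ainv <- chol2inv(fit$chol)
  se <- sqrt(pmax(diag(Ainv), 0) * fit$sigma2)
  beta <- drop(fit$beta)
  names(beta) <- names(se) <- colnames(X)
  df <- N - p
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  list(beta = beta, se = se, t = tval, df = df, p = pval,
       ci_low = beta - crit * se, ci_high = beta + crit * se,
       sigma2 = fit$sigma2, tau2 = fit$lam * fit$sigma2, lambda = fit$lam,
       logLik = -fit$dev / 2, n = N, n_groups = G,
       converged = is.finite(fit$dev))
}

## lme4 route for the same model; used as reference engine.
fit_ranint_lmer <- function(y, X, group) {
  dat <- as.data.frame(X[, colnames(X) != "(Intercept)", drop = FALSE])
  cn <- colnames(dat)
  safe <- make.names(cn)
  colnames(dat) <- safe
  dat$.y <- y
  dat$.g <- factor(group)
  form <- stats::as.formula(
    paste(".y ~ 1 +", paste(safe, collapse = " + "), "+ (1 | .g)"))
  m <- lme4::lmer(form, data = dat, REML = FALSE,
                  control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  N <- length(y)
  p <- length(fe)
  df <- N - p
  tval <- fe / se
  crit <- stats::qt(0.975, df)
  vc <- lme4::VarCorr(m)
  names(fe) <- names(se) <- colnames(X)
  list(beta = fe, se = se, t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df),
       ci_low = fe - crit * se, ci_high = fe + crit * se,
       sigma2 = attr(vc, "sc")^2, tau2 = as.numeric(vc$.g),
       lambda = as.numeric(vc$.g) / attr(vc, "sc")^2,
       logLik = as.numeric(stats::logLik(m)), n = N,
       n_groups = nlevels(dat$.g), converged = TRUE)
}

fit_to_table <- function(fit) {
  data.frame(term = names(fit$beta), beta = unname(fit$beta),
             ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
             se = unname(fit$se), t = unname(fit$t), df = fit$df,
             p = unname(fit$p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit a single-trial factorial mixed-effects model
#'
#' The workhorse model of the pipeline:
#' `outcome ~ 1 + f1 * f2 * ... + (1 | participant)`, with every factor,
#' the optional covariates, and the outcome z-scored across the analysed
#' trials so the reported coefficients are standardized. Estimation is by
#' maximum likelihood; degrees of freedom are reported as n - k.
#'
#' @param data trial-level data.frame.
#' @param outcome name of the outcome column.
#' @param factors factor column names (default the experiment's
#'   incentive, distractor, drug design).
#' @param covariates optional numeric covariate columns (z-scored,
#'   appended after the factorial terms).
#' @param group grouping column for the random intercept.
#' @param transform `"identity"` or `"log"` (applied before z-scoring;
#'   reaction times are analysed on the log scale).
#' @param include optional logical column name or vector selecting trials.
#' @param engine `"profile"` for the built-in profiled-ML solver,
#'   `"lmer"` for lme4.
#' @return data.frame (class `strm_fit`) with columns term, beta, ci_low,
#'   ci_high, se, t, df, p; attributes `n_trials`, `n_participants`,
#'   `outcome`, `engine`, `fit`.
#' @export
fit_single_trial_model <- function(data, outcome,
                                   factors = c("incentive", "distractor", "thp"),
                                   covariates = character(),
                                   group = "participant",
                                   transform = c("identity", "log"),
                                   include = NULL,
                                   engine = c("profile", "lmer")) {
  transform <- match.arg(transform)
  engine <- match.arg(engine)
  keep <- rep(TRUE, nrow(data))
  if (!is.null(include)) {
    keep <- if (is.character(include)) data[[include]] %in% TRUE else include %in% TRUE
  }
  need <- c(outcome, factors, covariates, group)
  keep <- keep & stats::complete.cases(data[, need, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires positive outcome values")
    y <- log(y)
  }
  y <- zscore(y)
  X <- zscore_design(d, factors, covariates)
  fit <- switch(engine,
                profile = fit_ranint_ml(y, X, d[[group]]),
                lmer = fit_ranint_lmer(y, X, d[[group]]))
  out <- fit_to_table(fit)
  attr(out, "n_trials") <- nrow(d)
  attr(out, "n_participants") <- length(unique(d[[group]]))
  attr(out, "outcome") <- outcome
  attr(out, "engine") <- engine
  attr(out, "fit") <- fit
  class(out) <- c("strm_fit", "data.frame")
  out
}

#' @method print strm_fit
#' @export
print.strm_fit <- function(x, ...) {
  cat(sprintf("Single-trial mixed model: %s (%d trials, %d participants, %s)\n",
              attr(x, "outcome"), attr(x, "n_trials"),
              attr(x, "n_participants"), attr(x, "engine")))
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Regress ERP window means on behavioural measures
#'
#' Fits `ERP ~ 1 + behaviour + incentive*distractor*thp +
#' (1 | participant)` for every ERP x behaviour pair and applies a
#' Bonferroni threshold of alpha / (number of models) to the behaviour
#' term.
#'
#' @param data trial-level data.frame with ERP and behaviour columns.
#' @param erps ERP window-mean column names.
#' @param behaviours behavioural outcome column names.
#' @param factors,group as in [fit_single_trial_model()].
#' @param extra_covariates optional further behavioural covariates added
#'   to every model (control analyses).
#' @param alpha family-wise alpha before correction.
#' @param engine model engine.
#' @return data.frame with one row per ERP x behaviour model: the
#'   behaviour-term estimate, raw p, Bonferroni-corrected threshold and
#'   significance flag; attribute `fits` keeps the full tables.
#' @export
fit_erp_behaviour_models <- function(data,
                                     erps = c("pre_preparation", "p3a", "cnv"),
                                     behaviours = c("residual_velocity",
                                                    "log_rt", "pull_deg"),
                                     factors = c("incentive", "distractor", "thp"),
                                     group = "participant",
                                     extra_covariates = character(),
                                     alpha = 0.05,
                                     engine = c("profile", "lmer")) {
  engine <- match.arg(engine)
  m <- length(erps) * length(behaviours)
  alpha_corr <- alpha / m
  rows <- list()
  fits <- list()
  for (e in erps) {
    for (b in behaviours) {
      need <- c(e, b, factors, group)
      ok <- stats::complete.cases(data[, need, drop = FALSE])
      if (!any(ok)) {
        message(sprintf("skipping %s ~ %s: no complete trials", e, b))
        next
      }
      f <- fit_single_trial_model(data[ok, , drop = FALSE], outcome = e,
                                  factors = factors,
                                  covariates = c(b, extra_covariates),
                                  group = group, engine = engine)
      row <- f[f$term == b, , drop = FALSE]
      rows[[paste(e, b, sep = "~")]] <- data.frame(
        erp = e, behaviour = b, beta = row$beta, ci_low = row$ci_low,
        ci_high = row$ci_high, se = row$se, t = row$t, df = row$df,
        p = row$p, alpha_corrected = alpha_corr,
        significant = row$p < alpha_corr, stringsAsFactors = FALSE)
      fits[[paste(e, b, sep = "~")]] <- f
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  attr(out, "n_comparisons") <- m
  out
}
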