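## Baron-Kenny-style mediation and mediated moderation for single-trial
## random-intercept models, with a permutation null for the change in
## the absolute standardized treatment coefficient. Negative delta =
## mediation (the mediator reduces the treatment effect).

## z-score treatment/moderator/mediator/outcome on the analysed subset;
## all mediation-family models are fitted on the identical trials
prepare_mediation_data <- function(data, cols, group) {
  ok <- stats::complete.cases(data[, c(cols, group), drop = FALSE])
  d <- data[ok, , drop = FALSE]
  z <- lapply(cols, function(cn) {
    x <- d[[cn]]
    if (!is.numeric(x)) x <- code_binary(x, cn)
    x <- as.numeric(x)
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s   # constant -> 0s
  })
  names(z) <- cols
  list(d = d, z = z, g = d[[group]], n = nrow(d))
}

shuffle_within <- function(g) {
  idx <- seq_along(g)
  for (lev in unique(g)) {
    sel <- which(g == lev)
    if (length(sel) > 1) idx[sel] <- sel[sample.int(length(sel))]
  }
  idx
}

#' Permutation-based mediation test
#'
#' Four-step mediation for a treatment -> mediator -> outcome pathway
#' with random participant intercepts, all variables z-scored:
#' model 1 `Y ~ 1 + X`, model 2 `M ~ 1 + X`, model 3
#' `Y ~ 1 + X + M (+ X:M)`. Mediation is the change in the absolute
#' standardized treatment coefficient, `delta = |b_direct| - |b_total|`
#' (negative = mediation). Its null distribution is built by shuffling
#' the mediator across trials within each participant and refitting
#' model 3; the one-tailed p is the proportion of the null with an equal
#' or more negative change (add-one smoothing). The p-value is withheld
#' (NA) unless steps 1-3 are significant at `alpha`.
#'
#' @param data trial table.
#' @param treatment,mediator,outcome column names.
#' @param group random-intercept grouping column.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param include_interaction include the `X:M` term in model 3.
#' @param within `"participant"` shuffles the mediator across all of a
#'   participant's trials; `"cell"` additionally preserves the
#'   participant x condition cell.
#' @param cell_factors cell-defining columns for `within = "cell"`.
#' @param alpha step-precondition significance level.
#' @return list of class `MediationResult`: step coefficient tables,
#'   `beta_total`, `beta_a` (plus `beta_a_raw` on the mediator's
#'   physical scale), `beta_b`, `beta_direct`, `delta` (= |direct| -
#'   |total|), `null` (permutation deltas), `p` (one-tailed, NA when the
#'   step preconditions fail), `assumptions`, `n`, `n_perm`, `seed`.
#' @export
mediation_test <- function(data, treatment = "incentive",
                           mediator = "cnv", outcome = "log_rt",
                           group = "participant", n_perm = 2500,
                           seed = 1, include_interaction = TRUE,
                           within = c("participant", "cell"),
                           cell_factors = c("incentive", "distractor", "thp"),
                           alpha = 0.05) {
  within <- match.arg(within)
  pd <- prepare_mediation_data(data, c(treatment, mediator, outcome), group)
  X <- pd$z[[treatment]]
  M <- pd$z[[mediator]]
  Y <- pd$z[[outcome]]
  g <- pd$g
  one <- rep(1, pd$n)

  fit1 <- fit_ranint_ml(Y, cbind(`(Intercept)` = one, X = X), g)
  if (all(M == 0)) {
    # degenerate: a constant mediator cannot change the treatment effect
    return(structure(list(
      model1 = fit_to_table(fit1), model2 = NULL, model3 = NULL,
      beta_total = fit1$beta[["X"]], beta_a = 0, beta_a_raw = 0,
      beta_b = 0, beta_direct = fit1$beta[["X"]], delta = 0,
      null = numeric(0), p = NA_real_,
      assumptions = c(treatment_outcome = fit1$p[["X"]] < alpha,
                      treatment_mediator = FALSE, mediator_outcome = FALSE),
      n = pd$n, n_perm = 0L, seed = seed, treatment = treatment,
      mediator = mediator, outcome = outcome),
      class = "MediationResult"))
  }
  fit2 <- fit_ranint_ml(M, cbind(`(Intercept)` = one, X = X), g)
  m3 <- function(Mv) {
    D <- cbind(`(Intercept)` = one, X = X, M = Mv)
    if (include_interaction) D <- cbind(D, `X:M` = X * Mv)
    fit_ranint_ml(Y, D, g)
  }
  fit3 <- m3(M)
  ## mediator -> treatment coefficient on the mediator's physical scale
  mraw <- as.numeric(pd$d[[mediator]])
  a_raw <- fit_ranint_ml(mraw - mean(mraw),
                         cbind(`(Intercept)` = one, X = X), g)$beta[["X"]]

  beta_total <- fit1$beta[["X"]]
  beta_direct <- fit3$beta[["X"]]
  delta <- abs(beta_direct) - abs(beta_total)
  assumptions <- c(treatment_outcome = fit1$p[["X"]] < alpha,
                   treatment_mediator = fit2$p[["X"]] < alpha,
                   mediator_outcome = fit3$p[["M"]] < alpha)

  cellg <- if (within == "cell") {
    interaction(pd$d[, unique(c(group, cell_factors))], drop = TRUE)
  } else g
  set.seed(seed %% 2147483629L)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    null[i] <- abs(m3(M[shuffle_within(cellg)])$beta[["X"]]) -
      abs(beta_total)
  }
  p <- if (all(assumptions)) (1 + sum(null <= delta)) / (n_perm + 1)
  else NA_real_

  structure(list(
    model1 = fit_to_table(fit1), model2 = fit_to_table(fit2),
    model3 = fit_to_table(fit3),
    beta_total = beta_total, beta_a = fit2$beta[["X"]],
    beta_a_raw = a_raw, beta_b = fit3$beta[["M"]],
    beta_direct = beta_direct, delta = delta, null = null, p = p,
    assumptions = assumptions, n = pd$n, n_perm = n_perm, seed = seed,
    treatment = treatment, mediator = mediator, outcome = outcome),
    class = "MediationResult")
}

#' @method print MediationResult
#' @export
print.MediationResult <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s (n = %d)\n", x$treatment,
              x$mediator, x$outcome, x$n))
  cat(sprintf("  total %.4f | a %.4f (raw %.4f) | b %.4f | direct %.4f\n",
              x$beta_total, x$beta_a, x$beta_a_raw, x$beta_b, x$beta_direct))
  cat(sprintf("  delta|beta| = %+.4f; one-tailed p = %s (%d permutations)\n",
              x$delta, ifelse(is.na(x$p), "withheld (assumptions)",
                              format.pval(x$p, digits = 4)), x$n_perm))
  if (!all(x$assumptions))
    cat("  failed steps:", paste(names(which(!x$assumptions)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Permutation-based mediated moderation test
#'
#' Tests whether a mediator accounts for how a moderator changes the
#' treatment effect: model 5 `Y ~ 1 + X + W + X:W`, model 6
#' `M ~ 1 + X + W + X:W`, model 7 `Y ~ 1 + X + W + X:W + M + M:W`.
#' The statistic is the change in the absolute `X:W` coefficient between
#' models 7 and 5; its null is built by shuffling the mediator within
#' participants and refitting model 7 (one-tailed, equal or more
#' negative). The p-value is withheld unless the two moderation steps
#' (the `X:W` terms of models 5 and 6) are significant at `alpha`; the
#' `M:W` coefficient of model 7 is reported in its table.
#'
#' @inheritParams mediation_test
#' @param moderator moderator column (the drug factor).
#' @return list of class `MediatedModerationResult`.
#' @export
mediated_moderation_test <- function(data, treatment = "incentive",
                                     moderator = "thp", mediator = "cnv",
                                     outcome = "log_rt",
                                     group = "participant", n_perm = 2500,
                                     seed = 1,
                                     within = c("participant", "cell"),
                                     cell_factors = c("incentive",
                                                      "distractor", "thp"),
                                     alpha = 0.05) {
  within <- match.arg(within)
  pd <- prepare_mediation_data(
    data, c(treatment, moderator, mediator, outcome), group)
  X <- pd$z[[treatment]]
  W <- pd$z[[moderator]]
  M <- pd$z[[mediator]]
  Y <- pd$z[[outcome]]
  g <- pd$g
  one <- rep(1, pd$n)

  fit5 <- fit_ranint_ml(Y, cbind(`(Intercept)` = one, X = X, W = W,
                                 `X:W` = X * W), g)
  fit6 <- fit_ranint_ml(M, cbind(`(Intercept)` = one, X = X, W = W,
                                 `X:W` = X * W), g)
  m7 <- function(Mv) {
    fit_ranint_ml(Y, cbind(`(Intercept)` = one, X = X, W = W,
                           `X:W` = X * W, M = Mv, `M:W` = Mv * W), g)
  }
  fit7 <- m7(M)

  b5 <- fit5$beta[["X:W"]]
  b7 <- fit7$beta[["X:W"]]
  delta <- abs(b7) - abs(b5)
  ## the gates are the moderation steps (5 and 6); the reduction itself
  ## (step 7) is the measured statistic, so it does not gate the p-value
  assumptions <- c(interaction_outcome = fit5$p[["X:W"]] < alpha,
                   interaction_mediator = fit6$p[["X:W"]] < alpha)

  cellg <- if (within == "cell") {
    interaction(pd$d[, unique(c(group, cell_factors))], drop = TRUE)
  } else g
  set.seed(seed %% 2147483629L)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    null[i] <- abs(m7(M[shuffle_within(cellg)])$beta[["X:W"]]) - abs(b5)
  }
  p <- if (all(assumptions)) (1 + sum(null <= delta)) / (n_perm + 1)
  else NA_real_

  structure(list(
    model5 = fit_to_table(fit5), model6 = fit_to_table(fit6),
    model7 = fit_to_table(fit7),
    beta_int_outcome = b5, beta_int_mediator = fit6$beta[["X:W"]],
    beta_int_direct = b7, delta = delta, null = null, p = p,
    assumptions = assumptions, n = pd$n, n_perm = n_perm, seed = seed,
    treatment = treatment, moderator = moderator, mediator = mediator,
    outcome = outcome),
    class = "MediatedModerationResult")
}

#' @method print MediatedModerationResult
#' @export
print.MediatedModerationResult <- function(x, ...) {
  cat(sprintf("Mediated moderation: (%s x %s) via %s -> %s (n = %d)\n",
              x$treatment, x$moderator, x$mediator, x$outcome, x$n))
  cat(sprintf("  X:W on outcome %.4f | X:W on mediator %.4f | with mediator %.4f\n",
              x$beta_int_outcome, x$beta_int_mediator, x$beta_int_direct))
  cat(sprintf("  delta|beta| = %+.4f; one-tailed p = %s (%d permutations)\n",
              x$delta, ifelse(is.na(x$p), "withheld (assumptions)",
                              format.pval(x$p, digits = 4)), x$n_perm))
  invisible(x)
}
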