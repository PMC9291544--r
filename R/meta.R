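#' Multilevel random-effects meta-analysis of coral effect sizes
#'
#' Pools effect sizes with known sampling variances under the model
#' `y_j = mu + u_study(j) + w_genus(j) + e_j`, with
#' `e_j ~ N(0, v_j)` (known), `u ~ N(0, sigma2_study)` and
#' `w ~ N(0, sigma2_genus)` as crossed random intercepts. Variance components
#' are estimated by REML (non-negative), the pooled mean by generalized least
#' squares at the REML variances, and inference is Wald-type (z), so an
#' estimate is significant when its CI excludes zero. Fitting is delegated to
#' [metafor::rma.mv()]; the returned object wraps the fit with the effect
#' table and pipeline metadata.
#'
#' A random factor with fewer than two observed levels is dropped (with a
#' message): its variance component is not identifiable, and the fit then
#' reduces to the corresponding single-factor (or fixed-effect) model.
#'
#' @param effects A `coral_effects` data frame (see [effect_sizes()]) holding
#'   one stratum (one `kind`); columns `value`, `variance`, `study_id`,
#'   `genus` are required.
#' @param random Character vector of grouping columns entering as random
#'   intercepts (default study and genus).
#' @param structure `"crossed"` (parallel intercepts, the default) or
#'   `"nested"` (study within genus).
#' @param fixed_sigma2 Optional numeric vector fixing the variance components
#'   (in the order of `random`) instead of estimating them; `c(0, 0)` yields
#'   the closed-form inverse-variance fixed-effect mean.
#' @param alpha Significance level for CIs and the significance flag.
#' @param method Variance-component estimator, `"REML"` (default) or `"ML"`.
#' @return An object of class `coral_meta` with components `estimate`, `se`,
#'   `zval`, `p_value`, `ci_low`, `ci_high`, `sigma2` (named), `k`,
#'   `significant`, `kind`, `attribute`, `context`, `effects`, and `fit` (the
#'   underlying `rma.mv` object). Methods: `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `logLik`, `residuals`, `plot`, `predict`.
#' @seealso [leave_one_study_out()], [funnel_data()], [predict.coral_meta()]
#' @export
#' @examples
#' eff <- data.frame(value = c(0.5, 1.0), variance = c(0.1, 0.2),
#'                   study_id = c("a", "b"), genus = c("g1", "g2"),
#'                   kind = "arrhenius_E", attribute = "survival",
#'                   context = "single_driver")
#' coral_meta(eff, fixed_sigma2 = c(0, 0))$estimate # 2/3
coral_meta <- function(effects, random = c("study_id", "genus"),
                       structure = c("crossed", "nested"),
                       fixed_sigma2 = NULL, alpha = 0.05, method = "REML") {
  structure <- match.arg(structure)
  effects <- as.data.frame(effects)
  need <- c("value", "variance", random)
  missing_cols <- setdiff(need, names(effects))
  if (length(missing_cols)) {
    .fail("effects table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(effects) < 2) {
    .fail("at least 2 effect sizes are required (k = ", nrow(effects), ")")
  }
  if (any(!is.finite(effects$variance) | effects$variance <= 0)) {
    .fail("all sampling variances must be finite and > 0")
  }
  if ("kind" %in% names(effects) && length(unique(effects$kind)) > 1) {
    .fail("effects mix kinds ", paste(unique(effects$kind), collapse = ", "),
          "; fit one stratum at a time (see coral_meta_by)")
  }

  keep <- random[vapply(random, function(f) {
    length(unique(effects[[f]])) >= 2L
  }, logical(1))]
  dropped <- setdiff(random, keep)
  if (length(dropped)) {
    message("dropping random factor(s) with a single level: ",
            paste(dropped, collapse = ", "))
    if (!is.null(fixed_sigma2)) fixed_sigma2 <- fixed_sigma2[match(keep, random)]
  }

  dat <- effects
  for (f in keep) dat[[f]] <- factor(dat[[f]])
  rand <- if (structure == "crossed" || length(keep) < 2) {
    lapply(keep, function(f) stats::as.formula(paste0("~ 1 | ", f)))
  } else {
    ## nested: studies within genus (inner factor last in the / notation)
    list(stats::as.formula(paste0("~ 1 | ", keep[2], "/", keep[1])))
  }
  args <- list(yi = dat$value, V = dat$variance, data = dat,
               method = method, test = "z", sparse = FALSE)
  if (length(rand)) args$random <- rand
  if (!is.null(fixed_sigma2) && length(fixed_sigma2)) args$sigma2 <- fixed_sigma2
  fit <- tryCatch(do.call(metafor::rma.mv, args), error = function(e) {
    .fail("meta-analysis failed to converge: ", conditionMessage(e))
  })

  sigma2 <- rep(0, length(random))
  names(sigma2) <- paste0("sigma2_", random)
  if (length(keep)) {
    est <- fit$sigma2
    if (structure == "crossed" || length(keep) < 2) {
      sigma2[paste0("sigma2_", keep)] <- est
    } else {
      ## nested parameterisation: outer factor then inner interaction
      sigma2[paste0("sigma2_", keep[2])] <- est[1]
      sigma2[paste0("sigma2_", keep[1])] <- est[2]
    }
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  estimate <- unname(coef(fit))
  se <- unname(fit$se)
  out <- list(
    estimate = estimate, se = se, zval = estimate / se,
    p_value = unname(fit$pval),
    ci_low = estimate - zcrit * se, ci_high = estimate + zcrit * se,
    sigma2 = sigma2, k = fit$k,
    significant = unname(fit$pval) < alpha,
    alpha = alpha, method = method, structure = structure,
    random = random, random_used = keep,
    kind = if ("kind" %in% names(effects)) unique(effects$kind) else NA_character_,
    attribute = if ("attribute" %in% names(effects) &&
                    length(unique(effects$attribute)) == 1)
      unique(effects$attribute) else NA_character_,
    context = if ("context" %in% names(effects) &&
                  length(unique(effects$context)) == 1)
      unique(effects$context) else NA_character_,
    effects = effects, fit = fit, call = match.call())
  class(out) <- "coral_meta"
  out
}

#' @export
print.coral_meta <- function(x, digits = 4, ...) {
  unit <- if (identical(x$kind, "arrhenius_E")) " eV"
  else if (identical(x$kind, "lnrr_co2")) " per +100 uatm" else ""
  cat("Multilevel random-effects meta-analysis (", x$method, ")\n", sep = "")
  if (!is.na(x$attribute)) cat("  attribute: ", x$attribute,
                               "  context: ", x$context, "\n", sep = "")
  cat("  k = ", x$k, " effect sizes\n", sep = "")
  cat(sprintf("  pooled estimate: %.*f%s (SE %.*f), %d%% CI [%.*f, %.*f]\n",
              digits, x$estimate, unit, digits, x$se,
              round(100 * (1 - x$alpha)), digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  z = %.*f, p = %.3g%s\n", digits, x$zval, x$p_value,
              if (x$significant) " (*)" else ""))
  cat("  variance components: ",
      paste(sprintf("%s = %.*f", names(x$sigma2), digits, x$sigma2),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.coral_meta <- function(object, ...) {
  object$table <- data.frame(
    estimate = object$estimate, se = object$se, zval = object$zval,
    p_value = object$p_value, ci_low = object$ci_low, ci_high = object$ci_high,
    k = object$k, row.names = "pooled")
  class(object) <- c("summary.coral_meta", "coral_meta")
  object
}

#' @export
print.summary.coral_meta <- function(x, ...) {
  print.coral_meta(x, ...)
  cat("\n")
  print(x$table)
  invisible(x)
}

#' @export
coef.coral_meta <- function(object, ...) c(estimate = object$estimate)

#' @export
vcov.coral_meta <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("estimate", "estimate"))
}

#' @export
confint.coral_meta <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$estimate - z * object$se, object$estimate + z * object$se),
         1, 2, dimnames = list("estimate", c("lower", "upper")))
}

#' @export
logLik.coral_meta <- function(object, ...) stats::logLik(object$fit)

#' @export
residuals.coral_meta <- function(object, ...) {
  object$effects$value - object$estimate
}

#' Forest or funnel plot of a fitted meta-analysis
#'
#' @param x A `coral_meta` object.
#' @param type `"forest"` or `"funnel"` (drawn by the corresponding
#'   'metafor' functions).
#' @param ... Passed to [metafor::forest()] / [metafor::funnel()].
#' @return The value of the underlying plotting call, invisibly.
#' @export
plot.coral_meta <- function(x, type = c("forest", "funnel"), ...) {
  type <- match.arg(type)
  if (type == "forest") {
    invisible(metafor::forest(x$fit, ...))
  } else {
    invisible(metafor::funnel(x$fit, ...))
  }
}

#' Fit one meta-analysis per attribute x kind x context stratum
#'
#' @param effects A `coral_effects` table possibly mixing strata.
#' @param by Stratifying columns.
#' @param min_k Strata with fewer effect sizes are skipped with a warning.
#' @param ... Passed to [coral_meta()].
#' @return A named list of `coral_meta` fits (names `attribute.kind.context`).
#' @seealso [meta_table()]
#' @export
coral_meta_by <- function(effects, by = c("attribute", "kind", "context"),
                          min_k = 2, ...) {
  effects <- as.data.frame(effects)
  key <- interaction(effects[by], drop = TRUE, sep = ".")
  fits <- list()
  for (lev in levels(key)) {
    sub <- effects[key == lev, , drop = FALSE]
    if (nrow(sub) < min_k) {
      warning("skipping stratum ", lev, ": only ", nrow(sub),
              " effect size(s)", call. = FALSE)
      next
    }
    fits[[lev]] <- coral_meta(sub, ...)
  }
  fits
}

#' Tidy table of pooled estimates
#'
#' @param fits A list of `coral_meta` objects (e.g. from [coral_meta_by()]).
#' @return A data frame with one row per fit: labels, pooled estimate, SE,
#'   CI, p, variance components and k.
#' @export
meta_table <- function(fits) {
  if (inherits(fits, "coral_meta")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    data.frame(attribute = f$attribute, kind = f$kind, context = f$context,
               estimate = f$estimate, se = f$se, ci_low = f$ci_low,
               ci_high = f$ci_high, p_value = f$p_value,
               significant = f$significant,
               sigma2_study = unname(f$sigma2["sigma2_study_id"]),
               sigma2_genus = unname(f$sigma2["sigma2_genus"]),
               k = f$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-study-out sensitivity reruns
#'
#' Refits the meta-analysis with each study removed in turn and flags reruns
#' whose significance verdict differs from the full fit — the standard check
#' that no single publication drives the pooled conclusion.
#'
#' @param fit A `coral_meta` object fitted to effects with a `study_id`
#'   column.
#' @return A data frame with one row per held-out study: `study_id`, `k`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value`, `significant`,
#'   `verdict_changed`.
#' @export
leave_one_study_out <- function(fit) {
  stopifnot(inherits(fit, "coral_meta"))
  effects <- fit$effects
  studies <- unique(effects$study_id)
  if (length(studies) < 3) {
    .fail("leave-one-study-out needs at least 3 distinct studies")
  }
  rows <- lapply(studies, function(s) {
    sub <- effects[effects$study_id != s, , drop = FALSE]
    f <- coral_meta(sub, random = fit$random, structure = fit$structure,
                    alpha = fit$alpha, method = fit$method)
    data.frame(study_id = s, k = f$k, estimate = f$estimate, se = f$se,
               ci_low = f$ci_low, ci_high = f$ci_high, p_value = f$p_value,
               significant = f$significant,
               verdict_changed = f$significant != fit$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Funnel-plot coordinates with a coverage flag
#'
#' Exports, per effect size, its value and standard error plus a flag for
#' whether it falls inside the 95% funnel around the pooled estimate, with
#' total variance `v_j + sigma2_study + sigma2_genus`.
#'
#' @param fit A `coral_meta` object.
#' @param z Normal quantile defining the funnel (1.96 for 95%).
#' @return A data frame with `value`, `se`, `inside_funnel` and the labels.
#' @export
funnel_data <- function(fit, z = 1.96) {
  stopifnot(inherits(fit, "coral_meta"))
  eff <- fit$effects
  tot <- eff$variance + sum(fit$sigma2)
  data.frame(
    study_id = eff$study_id, genus = eff$genus,
    value = eff$value, se = sqrt(eff$variance),
    inside_funnel = abs(eff$value - fit$estimate) <= z * sqrt(tot),
    stringsAsFactors = FALSE)
}

#' Restricted log-likelihood of the two-factor meta-analysis model
#'
#' Evaluates the REML objective of the crossed random-intercept model at
#' given variance components, independently of any fitting routine: with
#' `V = diag(v) + s_study Z_s Z_s' + s_genus Z_g Z_g'` and `X = 1`,
#' `ll = -0.5 [ (k-1) log(2 pi) - log|X'X| + log|V| + log|X' V^-1 X| +
#' r' V^-1 r ]` where `r` are the GLS residuals (the `log|X'X|` term follows
#' the common REML convention, so the value matches `logLik` on the fitted
#' model exactly, not just up to a constant). Useful as a grid-search oracle
#' for the optimizer and for profile diagnostics.
#'
#' @param sigma2_study,sigma2_genus Non-negative variance components.
#' @param value,variance Effect sizes and their known sampling variances.
#' @param study,genus Grouping labels (any vectors coercible to factor).
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(sigma2_study, sigma2_genus, value, variance,
                        study, genus) {
  stopifnot(sigma2_study >= 0, sigma2_genus >= 0,
            length(value) == length(variance))
  k <- length(value)
  Zs <- stats::model.matrix(~ 0 + factor(study))
  Zg <- stats::model.matrix(~ 0 + factor(genus))
  V <- diag(variance, k) + sigma2_study * tcrossprod(Zs) +
    sigma2_genus * tcrossprod(Zg)
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, k)))
  xtvx <- sum(Vi1)                      # X'V^-1 X with X = 1
  mu <- sum(Vi1 * value) / xtvx
  r <- value - mu
  Vir <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * ((k - 1) * log(2 * pi) - log(k) + logdetV + log(xtvx) + sum(r * Vir))
}

#' REML profile grid for a fitted meta-analysis
#'
#' Evaluates [reml_loglik()] on a grid of variance components around the
#' fitted optimum (0 to `mult` times each estimate, floored at `floor_to`
#' when an estimate is zero).
#'
#' @param fit A `coral_meta` object.
#' @param grid_size Points per axis.
#' @param mult Upper limit as a multiple of each fitted component.
#' @param floor_to Upper limit used when a fitted component is 0.
#' @return A data frame `sigma2_study`, `sigma2_genus`, `loglik`.
#' @export
reml_profile <- function(fit, grid_size = 50, mult = 5, floor_to = 0.05) {
  stopifnot(inherits(fit, "coral_meta"))
  eff <- fit$effects
  s_hat <- unname(fit$sigma2["sigma2_study_id"])
  g_hat <- unname(fit$sigma2["sigma2_genus"])
  s_grid <- seq(0, max(mult * s_hat, floor_to), length.out = grid_size)
  g_grid <- seq(0, max(mult * g_hat, floor_to), length.out = grid_size)
  grid <- expand.grid(sigma2_study = s_grid, sigma2_genus = g_grid)
  grid$loglik <- mapply(function(s, g) {
    reml_loglik(s, g, eff$value, eff$variance, eff$study_id, eff$genus)
  }, grid$sigma2_study, grid$sigma2_genus)
  grid
}
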