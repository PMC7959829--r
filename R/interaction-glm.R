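# Age x efficiency interaction model. For a behavior score beh and a
# network efficiency value E (global, or one parcel's nodal/local
# efficiency), fit by ordinary least squares:
#
#   beh = a1*age + a2*E + a3*sex + a4*edu + a5*ICV + a6*morph
#         + beta*(age x E) + intercept + error
#
# where morph is the whole-cortex covariate matched to the network measure
# (total volume / total area / mean thickness). The interaction
# coefficient beta tests whether the efficiency-behavior association
# changes with age. Continuous variables are z-scored by default, so
# coefficients are standardized; the interaction is the product of
# standardized age and standardized E.

MODEL_TERMS <- c("age", "E", "sex", "edu", "icv", "morph", "age:E")

# Build the (optionally standardized) model frame. Returns the frame, the
# scaling used, and the raw columns for plotting.
build_model_frame <- function(data, behavior, efficiency, morph = "morph_global",
                              standardize = c("all", "predictors", "none")) {
  standardize <- match.arg(standardize)
  cols <- c(behavior, efficiency, "age", "sex", "education", "icv", morph)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop(sprintf("cohort data is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw <- data.frame(beh = data[[behavior]], age = data[["age"]],
                    E = data[[efficiency]], sex = data[["sex"]],
                    edu = data[["education"]], icv = data[["icv"]],
                    morph = data[[morph]])
  if (anyNA(raw)) {
    stop("model columns contain missing values; subset to complete cases first",
         call. = FALSE)
  }
  if (nrow(raw) < length(MODEL_TERMS) + 3L) {
    stop(sprintf("need at least %d complete observations, got %d",
                 length(MODEL_TERMS) + 3L, nrow(raw)), call. = FALSE)
  }
  if (length(unique(raw$sex)) > 2L) {
    stop("'sex' must be a binary code", call. = FALSE)
  }
  d <- raw
  continuous <- c("age", "E", "edu", "icv", "morph")
  if (standardize == "all") continuous <- c("beh", continuous)
  center <- numeric(0); scale <- numeric(0)
  if (standardize != "none") {
    for (v in continuous) {
      s <- stats::sd(d[[v]])
      if (!is.finite(s) || s == 0) {
        stop(sprintf("column '%s' has zero variance; cannot standardize",
                     switch(v, beh = behavior, E = efficiency, edu = "education",
                            morph = morph, v)), call. = FALSE)
      }
      center[v] <- mean(d[[v]]); scale[v] <- s
      d[[v]] <- (d[[v]] - center[v]) / s
    }
  }
  list(frame = d, raw = raw, standardize = standardize,
       center = center, scale = scale)
}

#' Fit the age-by-efficiency interaction model
#'
#' Ordinary least squares of a behavior score on age, network efficiency,
#' sex, education, intracranial volume, the global morphometry covariate
#' and the age-by-efficiency interaction. By default all continuous
#' variables (including the behavior) are z-scored before fitting, so the
#' reported interaction coefficient is standardized; the interaction term
#' is the product of standardized age and standardized efficiency.
#'
#' @param data Cohort data.frame with columns `age` (years), `sex` (0/1),
#'   `education` (years), `icv` (mm^3), the `morph` column, plus the
#'   behavior and efficiency columns.
#' @param behavior Name of the behavior score column.
#' @param efficiency Name of the efficiency column (e.g. `"e_glob"`).
#' @param morph Name of the whole-cortex morphometry covariate column
#'   matched to the network measure (default `"morph_global"`).
#' @param standardize `"all"` (default: z-score behavior and continuous
#'   predictors), `"predictors"` (leave the behavior on its raw scale) or
#'   `"none"` (raw-scale fit).
#' @return An object of class `interaction_fit` with components `lm` (the
#'   underlying [stats::lm] fit), `coefficients`, `interaction` (list with
#'   `beta`, `t`, `p`), `n`, and metadata. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `simulate`, `plot`.
#' @examples
#' set.seed(7)
#' n <- 80
#' d <- data.frame(age = runif(n, 18, 64), sex = rep(0:1, length.out = n),
#'                 education = rnorm(n, 15, 3), icv = rnorm(n, 1.45e6, 1e5),
#'                 morph_global = rnorm(n, 9e4, 5e3), e_glob = rnorm(n))
#' za <- scale(d$age)[, 1]; zE <- scale(d$e_glob)[, 1]
#' d$score <- 0.3 * za + 0.2 * zE - 0.4 * za * zE + rnorm(n, 0, 0.6)
#' fit <- interaction_glm(d, "score", "e_glob")
#' fit
#' coef(fit)
#' @export
interaction_glm <- function(data, behavior, efficiency, morph = "morph_global",
                            standardize = c("all", "predictors", "none")) {
  mf <- build_model_frame(data, behavior, efficiency, morph, standardize)
  fit <- stats::lm(beh ~ age + E + sex + edu + icv + morph + age:E,
                   data = mf$frame)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ct <- summary(fit)$coefficients
  structure(list(
    lm = fit,
    coefficients = stats::coef(fit),
    interaction = list(beta = ct["age:E", "Estimate"],
                       t = ct["age:E", "t value"],
                       p = ct["age:E", "Pr(>|t|)"]),
    n = nrow(mf$frame),
    behavior = behavior, efficiency = efficiency, morph = morph,
    standardize = mf$standardize, center = mf$center, scale = mf$scale,
    raw = mf$raw,
    call = match.call()
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Age x efficiency interaction model (%s ~ %s), n = %d\n",
              x$behavior, x$efficiency, x$n))
  cat(sprintf("  interaction beta = %.4f, t = %.3f, p = %.4g\n",
              x$interaction$beta, x$interaction$t, x$interaction$p))
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) object$coefficients

#' @export
summary.interaction_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.interaction_fit")
}

#' @export
print.summary.interaction_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  standardization: %s; adjusted R^2 = %.3f\n\n",
              x$fit$standardize, x$lm_summary$adj.r.squared))
  stats::printCoefmat(x$lm_summary$coefficients, signif.stars = FALSE)
  invisible(x)
}

#' @export
residuals.interaction_fit <- function(object, ...) stats::residuals(object$lm, ...)

#' @export
simulate.interaction_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)
}

#' Predict behavior for new subjects
#'
#' New data are transformed with the scaling stored in the fit; when the
#' behavior was standardized at fit time, predictions are returned on the
#' raw behavior scale.
#'
#' @param object An `interaction_fit`.
#' @param newdata Optional data.frame with the same columns as the fit.
#' @param ... Passed to [stats::predict.lm].
#' @export
predict.interaction_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    pred <- stats::predict(object$lm, ...)
  } else {
    nd <- data.frame(age = newdata[["age"]], E = newdata[[object$efficiency]],
                     sex = newdata[["sex"]], edu = newdata[["education"]],
                     icv = newdata[["icv"]], morph = newdata[[object$morph]])
    for (v in intersect(names(object$center), names(nd))) {
      nd[[v]] <- (nd[[v]] - object$center[[v]]) / object$scale[[v]]
    }
    pred <- stats::predict(object$lm, newdata = nd, ...)
  }
  if (object$standardize == "all" && is.numeric(pred)) {
    pred <- pred * object$scale[["beh"]] + object$center[["beh"]]
  }
  pred
}

#' Age-group scatter of the efficiency-behavior association
#'
#' Plots raw behavior against raw efficiency, split into two age groups at
#' `age_split`, with a least-squares line per group (solid where the
#' within-group association is significant at `alpha`, dashed otherwise).
#' This is the standard way to visualize an interaction: the two slopes
#' differ when beta is nonzero.
#'
#' @param x An `interaction_fit`.
#' @param age_split Age boundary between the two groups (default 35
#'   years, the young-adult / middle-aged boundary).
#' @param alpha Significance level for solid-vs-dashed lines.
#' @param ... Passed to [graphics::plot].
#' @export
plot.interaction_fit <- function(x, age_split = 35, alpha = 0.05, ...) {
  raw <- x$raw
  grp <- raw$age >= age_split
  cols <- c("#2166AC", "#B2182B")
  graphics::plot(raw$E, raw$beh, col = cols[grp + 1L], pch = 19,
                 xlab = x$efficiency, ylab = x$behavior, ...)
  for (g in c(FALSE, TRUE)) {
    sub <- raw[grp == g, ]
    if (nrow(sub) < 3L || stats::sd(sub$E) == 0) next
    fit <- stats::lm(beh ~ E, data = sub)
    p <- summary(fit)$coefficients["E", "Pr(>|t|)"]
    graphics::abline(fit, col = cols[g + 1L], lwd = 2,
                     lty = if (p < alpha) 1 else 2)
  }
  graphics::legend("topright", bty = "n", pch = 19, col = cols,
                   legend = c(sprintf("age < %g", age_split),
                              sprintf("age >= %g", age_split)))
  invisible(x)
}

# Fast OLS path used by leave-one-out folds and Monte-Carlo loops: returns
# the interaction coefficient's estimate and two-sided p, or signals
# rank-deficiency. X must carry the intercept; `term` indexes the
# interaction column.
ols_term_test <- function(X, y, term) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  # qr() may pivot columns; map back to original order
  piv <- qx$pivot
  se <- sqrt(sigma2 * diag(xtx_inv))[order(piv)]
  tval <- cf / se
  list(beta = cf[[term]], t = tval[[term]],
       p = 2 * stats::pt(-abs(tval[[term]]), df), df = df)
}

fold_interaction_p <- function(data, behavior, efficiency, morph, standardize) {
  mf <- build_model_frame(data, behavior, efficiency, morph, standardize)
  d <- mf$frame
  X <- cbind(1, d$age, d$E, d$sex, d$edu, d$icv, d$morph, d$age * d$E)
  ols_term_test(X, d$beh, term = 8L)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment of a family of p-values; tests with adjusted
#' q-value below `q_threshold` form the significant set. Used across the
#' 32 parcels of a nodal/local efficiency family (q < 0.05 by default).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (may be named).
#' @param q_threshold Significance threshold on the adjusted values.
#' @return Object of class `fdr_result`: list with `p`, `q`, logical
#'   `significant`, and `q_threshold`.
#' @export
fdr_bh <- function(p, q_threshold = 0.05) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0 | p > 1))) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  structure(list(p = p, q = q, significant = q < q_threshold,
                 q_threshold = q_threshold),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("BH-FDR over %d test(s): %d significant at q < %g\n",
              length(x$p), sum(x$significant), x$q_threshold))
  invisible(x)
}

#' Leave-one-out reproducibility of the interaction
#'
#' Refits the interaction model once per subject with that subject
#' removed, and reports the percentage of folds in which the interaction
#' coefficient stays significant (two-sided p below `alpha`,
#' uncorrected). Rank-deficient folds are flagged and excluded from both
#' numerator and denominator with a warning.
#'
#' @inheritParams interaction_glm
#' @param alpha Per-fold significance level on the interaction.
#' @return Object of class `loo_result`: list with `reproducibility_pct`,
#'   `n_folds` (= n), `n_used`, `fold_p`, `flagged` (indices of excluded
#'   folds) and `alpha`.
#' @export
loo_reproducibility <- function(data, behavior, efficiency, alpha = 0.05,
                                morph = "morph_global",
                                standardize = c("all", "predictors", "none")) {
  standardize <- match.arg(standardize)
  n <- nrow(data)
  fold_p <- rep(NA_real_, n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch(fold_interaction_p(data[-i, , drop = FALSE], behavior,
                                       efficiency, morph, standardize),
                    error = function(e) NULL)
    if (is.null(res)) flagged <- c(flagged, i) else fold_p[i] <- res$p
  }
  if (length(flagged)) {
    warning(sprintf("%d leave-one-out fold(s) were rank-deficient and excluded",
                    length(flagged)), call. = FALSE)
  }
  n_used <- n - length(flagged)
  pct <- if (n_used > 0) 100 * sum(fold_p < alpha, na.rm = TRUE) / n_used else NA_real_
  structure(list(reproducibility_pct = pct, n_folds = n, n_used = n_used,
                 fold_p = fold_p, flagged = flagged, alpha = alpha),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out reproducibility: %.2f%% (%d folds, %d used, alpha = %g)\n",
              x$reproducibility_pct, x$n_folds, x$n_used, x$alpha))
  invisible(x)
}

#' Scan all efficiency metrics and behaviors for age interactions
#'
#' Fits the interaction model for every (efficiency metric, behavior)
#' combination in a cohort table: global efficiency (`e_glob`), and
#' per-parcel nodal (`e_nodal_<parcel>`) and local (`e_local_<parcel>`)
#' efficiency. FDR is applied per family: across parcels within each
#' (metric, behavior) for nodal/local, and across behaviors for global
#' efficiency. Leave-one-out reproducibility is computed for FDR-
#' significant rows (default), all rows, or skipped.
#'
#' @param cohort Cohort data.frame containing covariates, behaviors and
#'   efficiency columns (see [simulate_cohort()] / [run_pipeline()]).
#' @param behaviors Character vector of behavior column names.
#' @param measure Network measure tag carried into the output.
#' @param q_threshold FDR threshold (default 0.05).
#' @param loo `"significant"`, `"all"` or `"none"`.
#' @param loo_alpha Per-fold significance level.
#' @inheritParams interaction_glm
#' @return A data.frame with one row per test: `measure`, `metric`,
#'   `parcel`, `behavior`, `beta`, `t`, `p`, `q`, `significant`,
#'   `reproducibility_pct`, `n`.
#' @export
efficiency_interaction_scan <- function(cohort, behaviors,
                                        measure = NA_character_,
                                        q_threshold = 0.05,
                                        loo = c("significant", "all", "none"),
                                        loo_alpha = 0.05,
                                        morph = "morph_global",
                                        standardize = "all") {
  loo <- match.arg(loo)
  nodal_cols <- grep("^e_nodal_", names(cohort), value = TRUE)
  local_cols <- grep("^e_local_", names(cohort), value = TRUE)
  eff_sets <- list(global = if ("e_glob" %in% names(cohort)) "e_glob" else character(0),
                   nodal = nodal_cols, local = local_cols)
  model_cols <- c("age", "sex", "education", "icv", morph)

  # A single untestable column (e.g. a parcel whose local efficiency is
  # constant across subjects) yields an NA row instead of aborting the scan.
  fit_one <- function(beh, eff) {
    sub <- cohort[stats::complete.cases(cohort[, c(model_cols, beh, eff)]), ,
                  drop = FALSE]
    fit <- tryCatch(interaction_glm(sub, beh, eff, morph = morph,
                                    standardize = standardize),
                    error = function(e) {
                      warning(sprintf("test (%s, %s) skipped: %s", beh, eff,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) {
      return(data.frame(beta = NA_real_, t = NA_real_, p = NA_real_,
                        n = nrow(sub), stringsAsFactors = FALSE))
    }
    data.frame(beta = fit$interaction$beta, t = fit$interaction$t,
               p = fit$interaction$p, n = fit$n, stringsAsFactors = FALSE)
  }

  apply_fdr <- function(fam) {
    fam$q <- NA_real_
    fam$significant <- FALSE
    ok <- is.finite(fam$p)
    if (any(ok)) {
      fdr <- fdr_bh(fam$p[ok], q_threshold)
      fam$q[ok] <- fdr$q
      fam$significant[ok] <- fdr$significant
    }
    fam
  }

  rows <- list()
  for (metric in names(eff_sets)) {
    cols <- eff_sets[[metric]]
    if (!length(cols)) next
    if (metric == "global") {
      # family: behaviors within the measure
      fam <- do.call(rbind, lapply(behaviors, function(b) {
        cbind(data.frame(measure = measure, metric = metric, parcel = "global",
                         behavior = b, stringsAsFactors = FALSE),
              fit_one(b, "e_glob"))
      }))
      fam <- apply_fdr(fam)
      fam$eff_col <- "e_glob"
      rows[[length(rows) + 1L]] <- fam
    } else {
      parcels <- sub(sprintf("^e_%s_", metric), "", cols)
      for (b in behaviors) {
        # family: the parcels within (measure, metric, behavior)
        fam <- do.call(rbind, lapply(seq_along(cols), function(k) {
          cbind(data.frame(measure = measure, metric = metric,
                           parcel = parcels[k], behavior = b,
                           stringsAsFactors = FALSE),
                fit_one(b, cols[k]))
        }))
        fam <- apply_fdr(fam)
        fam$eff_col <- cols
        rows[[length(rows) + 1L]] <- fam
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$reproducibility_pct <- NA_real_
  if (loo != "none") {
    todo <- if (loo == "all") seq_len(nrow(out)) else which(out$significant)
    for (r in todo) {
      beh <- out$behavior[r]; eff <- out$eff_col[r]
      sub <- cohort[stats::complete.cases(cohort[, c(model_cols, beh, eff)]), ,
                    drop = FALSE]
      out$reproducibility_pct[r] <-
        loo_reproducibility(sub, beh, eff, alpha = loo_alpha, morph = morph,
                            standardize = standardize)$reproducibility_pct
    }
  }
  out$eff_col <- NULL
  out[, c("measure", "metric", "parcel", "behavior", "beta", "t", "p", "q",
          "significant", "reproducibility_pct", "n")]
}
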