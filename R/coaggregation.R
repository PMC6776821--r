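# Familial coaggregation: logistic odds ratios of one disorder in
# relatives of probands with the other disorder, with cluster-robust
# (sandwich) standard errors for the familial dependence.

#' Logistic regression with cluster-robust variance
#'
#' Maximum-likelihood logistic fit (via [stats::glm()]) with both the
#' model-based and the cluster-robust sandwich covariance; the sandwich
#' stacks score contributions by `clusters` and reduces to the
#' heteroskedasticity-robust estimator when every cluster is a singleton.
#' Complete or quasi-complete separation is detected (any fitted
#' probability within 1e-8 of 0/1) and flagged rather than silently
#' reported.
#'
#' @param outcome binary 0/1 vector.
#' @param exposure binary 0/1 vector.
#' @param covariates optional numeric matrix/data.frame of adjusters.
#' @param clusters optional cluster id vector (default: one cluster per
#'   observation).
#' @return a `logistic_fit`: list with `coef`, `vcov_model`,
#'   `vcov_sandwich`, `or` (exposure OR with 95% CI and p from the
#'   sandwich SE), `separation`, `n`, `n_clusters`, `glm`.
#' @examples
#' y <- rep(c(1, 0, 1, 0), c(10, 90, 5, 95))
#' x <- rep(c(1, 1, 0, 0), c(10, 90, 5, 95))
#' fit_logistic(y, x)$or  # cross-product ratio 2.111
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         clusters = NULL) {
  if (!all(outcome %in% 0:1) || !all(exposure %in% 0:1))
    stopf("outcome and exposure must be binary 0/1")
  df <- data.frame(.y = outcome, exposure = exposure)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) length(unique(v)) > 1L, TRUE)
    df <- cbind(df, covariates[keep])
  }
  if (is.null(clusters)) clusters <- seq_along(outcome)
  if (length(clusters) != length(outcome))
    stopf("clusters must cover all rows")
  if (sum(exposure == 1) == 0L || sum(exposure == 0) == 0L)
    stopf("empty exposure stratum")
  fit <- glm(.y ~ ., data = df, family = binomial())
  mu <- fitted(fit)
  # fitted probabilities at the 0/1 boundary, or a diverging exposure
  # log-odds, indicate (quasi-)separation / empty event cells
  sep <- any(mu < 1e-8 | mu > 1 - 1e-8) ||
    abs(coef(fit)[["exposure"]]) > 8
  Vs <- sandwich::vcovCL(fit, cluster = clusters)
  b <- coef(fit)
  se <- sqrt(diag(Vs))
  i <- "exposure"
  or <- c(or = exp(b[[i]]),
          ci_low = exp(b[[i]] - 1.96 * se[[i]]),
          ci_high = exp(b[[i]] + 1.96 * se[[i]]),
          p = 2 * pnorm(-abs(b[[i]] / se[[i]])))
  structure(list(coef = b, vcov_model = vcov(fit), vcov_sandwich = Vs,
                 se_sandwich = se, or = or, separation = sep,
                 n = length(outcome),
                 n_clusters = length(unique(clusters)), glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: n=%d, clusters=%d%s\n", x$n, x$n_clusters,
              if (x$separation) " [SEPARATION FLAGGED]" else ""))
  cat(sprintf("  exposure OR %.3f (95%% CI %.3f, %.3f), p=%.3g\n",
              x$or[["or"]], x$or[["ci_low"]], x$or[["ci_high"]],
              x$or[["p"]]))
  invisible(x)
}

#' Cross-relative coaggregation odds ratio
#'
#' Regression of the relative's disorder on the index person's disorder
#' over double-entered relative pairs (both orientations), adjusted for
#' both members' birth years (centered) and sexes, with the sandwich
#' variance clustered on family id.  Optionally further adjusted for the
#' relative's own index-disorder status as a sensitivity analysis.
#'
#' @param ped pedigree/phenotype table.
#' @param pairs an [enumerate_pairs()] result.
#' @param index_trait column name of the index (exposure) diagnosis.
#' @param relative_trait column name of the outcome diagnosis in the
#'   relative.
#' @param adjust_relative_index also adjust for the relative's own
#'   `index_trait`.
#' @return a `logistic_fit` with extra fields `class_label` and `n_pairs`.
#' @export
coaggregation_or <- function(ped, pairs, index_trait, relative_trait,
                             adjust_relative_index = FALSE) {
  ii <- match(pairs$i, ped$iid)
  jj <- match(pairs$j, ped$iid)
  idx <- c(ii, jj); rel <- c(jj, ii)      # double entry
  df <- data.frame(
    outcome = ped[[relative_trait]][rel],
    exposure = ped[[index_trait]][idx],
    by_index = ped$birth_year[idx],
    by_rel = ped$birth_year[rel],
    sex_index = as.integer(ped$sex[idx] == "M"),
    sex_rel = as.integer(ped$sex[rel] == "M"),
    fid = rep(pairs$fid, 2),
    rel_index_dx = ped[[index_trait]][rel])
  df <- df[complete.cases(df[c("outcome", "exposure")]), , drop = FALSE]
  df$by_index <- df$by_index - mean(df$by_index)
  df$by_rel <- df$by_rel - mean(df$by_rel)
  covs <- df[c("by_index", "by_rel", "sex_index", "sex_rel")]
  if (adjust_relative_index) covs$rel_index_dx <- df$rel_index_dx
  fit <- fit_logistic(df$outcome, df$exposure, covariates = covs,
                      clusters = df$fid)
  fit$class_label <- attr(pairs, "class_label")
  fit$n_pairs <- nrow(pairs)
  fit
}

#' Summary table of coaggregation fits ordered by relatedness
#'
#' @param fits named list of `logistic_fit` objects; names are taken as
#'   `"<class>:<trait>"` labels when the fits lack `class_label`.
#' @return data.frame with class, trait, OR, CI bounds, p, n_pairs,
#'   separation flag, ordered full siblings first, cousins last.
#' @export
forest_table <- function(fits) {
  if (!length(fits)) stopf("need at least one fit")
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    lab <- f$class_label %||% names(fits)[k] %||% as.character(k)
    data.frame(class = lab,
               trait = f$trait %||% NA_character_,
               or = f$or[["or"]], ci_low = f$or[["ci_low"]],
               ci_high = f$or[["ci_high"]], p = f$or[["p"]],
               n_pairs = f$n_pairs %||% NA_integer_,
               separation = f$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- c("full_sister", "full_sibling", "maternal_half_sister",
           "maternal_half_sibling", "paternal_half_sibling", "cousin")
  out <- out[order(match(out$class, ord, nomatch = length(ord) + 1L)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
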