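# Cross-validated regression of proteome mass allocation on transcriptome
# module activity. Three candidate families — linear, exponential
# (3-parameter, with offset), and continuous two-segment broken line —
# compete by leave-one-out MAE; the winner is refit on all conditions and
# labelled strong when its adjusted R^2 reaches 0.3.

#' Proteome mass fraction allocated to a module's genes, per condition
#'
#' Sums raw-scale mass fractions over the module's proteome-covered genes
#' in each sample, then averages replicates within each condition.
#'
#' @param members character vector of the module's gene identifiers.
#' @param fractions proteins x samples matrix of mass fractions.
#' @param metadata sample metadata (`sample_id`, `condition_id`).
#' @return named numeric vector of per-condition mass fractions, or NULL
#'   (with a message) when no module gene is covered by the proteome.
#' @export
module_mass_fraction <- function(members, fractions, metadata) {
  covered <- intersect(members, rownames(fractions))
  if (!length(covered)) {
    message("module has no proteome-covered genes; skipped")
    return(NULL)
  }
  per_sample <- colSums(fractions[covered, , drop = FALSE])
  m <- condition_average(matrix(per_sample, nrow = 1,
                                dimnames = list(NULL, names(per_sample))),
                         metadata)
  stats::setNames(m[1, ], colnames(m))
}

fit_linear_family <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(family = "linear", n_par = 2L,
       parameters = c(intercept = unname(cf[1]), slope = unname(cf[2])),
       predict = function(newx) unname(cf[1] + cf[2] * newx))
}

fit_exponential_family <- function(x, y) {
  rng <- diff(range(y))
  if (rng == 0) stop("constant response")
  eps <- 1e-3 * rng
  starts <- list()
  # log-linear initialization, increasing and mirrored decreasing branches
  z <- log(y - min(y) + eps)
  cf <- stats::coef(stats::lm(z ~ x))
  starts[[1]] <- list(c = min(y) - eps, a = exp(unname(cf[1])),
                      b = unname(cf[2]))
  z2 <- log(max(y) - y + eps)
  cf2 <- stats::coef(stats::lm(z2 ~ x))
  starts[[2]] <- list(c = max(y) + eps, a = -exp(unname(cf2[1])),
                      b = unname(cf2[2]))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c + a * exp(b * x), start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit) ^ 2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("exponential fit did not converge")
  cf <- stats::coef(best$fit)
  list(family = "exponential", n_par = 3L,
       parameters = c(offset = unname(cf["c"]), scale = unname(cf["a"]),
                      rate = unname(cf["b"])),
       predict = function(newx) unname(cf["c"] + cf["a"] * exp(cf["b"] * newx)))
}

fit_broken_line_family <- function(x, y) {
  xs <- sort(unique(x))
  # candidate breakpoints: observed x with at least 2 points strictly
  # either side, keeping both segments identifiable
  cand <- xs[vapply(xs, function(b) sum(x < b) >= 2 && sum(x > b) >= 2, TRUE)]
  if (!length(cand)) stop("too few distinct x values for a broken line")
  best <- NULL
  for (b in cand) {
    X <- cbind(1, x, pmax(x - b, 0))
    f <- stats::.lm.fit(X, y)
    sse <- sum(f$residuals ^ 2)
    if (is.null(best) || sse < best$sse) {
      best <- list(b = b, coef = f$coefficients, sse = sse)
    }
  }
  cf <- best$coef
  bp <- best$b
  list(family = "broken_line", n_par = 4L,
       parameters = c(breakpoint = bp, intercept = unname(cf[1]),
                      slope_left = unname(cf[2]),
                      slope_right = unname(cf[2] + cf[3])),
       predict = function(newx) {
         unname(cf[1] + cf[2] * newx + cf[3] * pmax(newx - bp, 0))
       })
}

family_fitters <- list(linear = fit_linear_family,
                       exponential = fit_exponential_family,
                       broken_line = fit_broken_line_family)

#' Fit one regression family to an activity/mass-fraction series
#'
#' Linear by ordinary least squares; exponential `y = c + a exp(b x)` by
#' nonlinear least squares initialized from a log-linear fit; broken line
#' as a continuous two-segment piecewise linear model with the breakpoint
#' chosen by exhaustive search over interior observed x values.
#'
#' @param x numeric activity series (per condition).
#' @param y numeric mass-fraction series, same length.
#' @param family one of "linear", "exponential", "broken_line".
#' @return list with `family`, `parameters`, `n_par`, `predict` (function
#'   of new x), `fitted`, and in-sample `r2`.
#' @export
fit_family <- function(x, y, family = c("linear", "exponential",
                                        "broken_line")) {
  family <- match.arg(family)
  n_min <- if (family == "broken_line") 8L else 6L
  if (length(x) < n_min) stop(family, " fit needs at least ", n_min, " points")
  stopifnot(length(x) == length(y))
  out <- family_fitters[[family]](x, y)
  out$fitted <- out$predict(x)
  sst <- sum((y - mean(y)) ^ 2)
  out$r2 <- if (sst == 0) NA_real_ else 1 - sum((y - out$fitted) ^ 2) / sst
  out
}

#' Normalized cross-validation errors
#'
#' Elementwise `|y_pred - y_test| / y_avg`, the scale-free error used to
#' compare held-out predictions across modules of different size.
#'
#' @param y_pred,y_test numeric vectors of predictions and held-out truths.
#' @param y_avg positive scalar, the mean of the observed response.
#' @return numeric vector of normalized absolute errors.
#' @export
normalized_cv_error <- function(y_pred, y_test, y_avg) {
  if (!is.finite(y_avg) || y_avg <= 0) stop("y_avg must be positive")
  abs(y_pred - y_test) / y_avg
}

loocv_family <- function(x, y, family) {
  n <- length(x)
  preds <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_family(x[-i], y[-i], family), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    preds[i] <- fit$predict(x[i])
  }
  preds
}

#' Select an allocation model by leave-one-out cross-validation
#'
#' Each candidate family is scored by the mean absolute error of its
#' leave-one-out predictions; the lowest-MAE family wins, with ties going
#' to the simpler family (linear, then exponential, then broken line).
#' Under the default `rule = "one_se"` a tie is read statistically: the
#' simplest family whose MAE lies within one standard error of the best
#' family's MAE is selected, which keeps sampling noise in the
#' cross-validation errors from promoting a needlessly complex family.
#' `rule = "min"` takes the literal minimizer. The winner is refit on all
#' conditions and labelled `strong` when its adjusted R^2 (with 2/3/4
#' parameters for linear/exponential/broken line) reaches `r2_min`.
#'
#' @param x numeric activity series (replicate-averaged per condition).
#' @param y numeric mass-fraction series, same length.
#' @param families candidate families to consider.
#' @param r2_min adjusted R^2 threshold for the `strong` label (default 0.3).
#' @param rule `"one_se"` (simplest family within one standard error of
#'   the best MAE) or `"min"` (exact minimizer).
#' @param name optional module name carried into the result.
#' @return object of class `allocation_fit` with the chosen `family`,
#'   `parameters`, `loocv_mae` (per family), `normalized_errors`, `r2`,
#'   `adjusted_r2`, `strength`, and the data.
#' @export
select_model_loocv <- function(x, y,
                               families = c("linear", "exponential",
                                            "broken_line"),
                               r2_min = 0.3, rule = c("one_se", "min"),
                               name = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(x) == length(y), length(x) >= 6L)
  n <- length(x)
  maes <- stats::setNames(rep(NA_real_, length(families)), families)
  preds <- list()
  for (fam in families) {
    if (fam == "broken_line" && n < 8L) next
    p <- loocv_family(x, y, fam)
    if (is.null(p)) {
      message(fam, " family excluded: cross-validation fit failed")
      next
    }
    preds[[fam]] <- p
    maes[fam] <- mean(abs(p - y))
  }
  if (all(is.na(maes))) stop("no candidate family could be fit")
  # order of `families` encodes simplicity; which.min takes the first
  # minimum, so exact ties resolve to the simpler family
  best <- names(maes)[which.min(maes)]
  chosen <- if (rule == "one_se") {
    err_best <- abs(preds[[best]] - y)
    margin <- stats::sd(err_best) / sqrt(n)
    ok <- !is.na(maes) & maes <= maes[best] + margin
    names(maes)[which(ok)[1]]
  } else best
  final <- fit_family(x, y, chosen)
  p <- final$n_par
  adj_r2 <- 1 - (1 - final$r2) * (n - 1) / (n - p - 1)
  structure(list(
    name = name, family = chosen, parameters = final$parameters,
    loocv_mae = maes, loocv_predictions = preds[[chosen]],
    normalized_errors = normalized_cv_error(preds[[chosen]], y, mean(y)),
    r2 = final$r2, adjusted_r2 = adj_r2,
    strength = if (adj_r2 >= r2_min) "strong" else "weak",
    r2_min = r2_min, x = x, y = y, fitted = final$fitted,
    predict_fun = final$predict, n_par = p), class = "allocation_fit")
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat(sprintf("allocation fit%s: %s (%s)\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$family, x$strength))
  cat(sprintf("  adjusted R^2 = %.3f (threshold %.2f), LOOCV MAE = %.3g on n = %d conditions\n",
              x$adjusted_r2, x$r2_min, x$loocv_mae[x$family], length(x$x)))
  invisible(x)
}

#' @export
summary.allocation_fit <- function(object, ...) {
  cat(sprintf("Allocation regression%s\n",
              if (is.null(object$name)) "" else paste0(" for ", object$name)))
  cat(sprintf("  selected family: %s (LOOCV MAE per family below)\n",
              object$family))
  print(signif(object$loocv_mae, 4))
  cat("  parameters:\n")
  print(signif(object$parameters, 6))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f -> %s\n",
              object$r2, object$adjusted_r2, object$strength))
  cat(sprintf("  median normalized CV error = %.4f\n",
              stats::median(object$normalized_errors)))
  invisible(object)
}

#' @export
coef.allocation_fit <- function(object, ...) object$parameters

#' @export
predict.allocation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.list(newdata)) newdata <- newdata$x
  object$predict_fun(as.numeric(newdata))
}

#' @export
residuals.allocation_fit <- function(object, ...) object$y - object$fitted

#' @export
fitted.allocation_fit <- function(object, ...) object$fitted

#' @export
plot.allocation_fit <- function(x, ...) {
  ord <- order(x$x)
  graphics::plot(x$x, x$y, xlab = "module activity",
                 ylab = "proteome mass fraction",
                 main = sprintf("%s (%s, adj. R^2 = %.2f)",
                                if (is.null(x$name)) "module" else x$name,
                                x$family, x$adjusted_r2), ...)
  graphics::lines(x$x[ord], x$fitted[ord], col = "firebrick", lwd = 2)
  invisible(x)
}

#' Robustness sweep over held-out test fractions
#'
#' For each holdout fraction and repeat, splits the conditions at random
#' (test size rounded half up), selects a model by LOOCV on the training
#' split, and evaluates the final model on the held-out split.
#'
#' @param x,y activity and mass-fraction series.
#' @param fractions holdout fractions (default 0.10 to 0.30 by 0.05).
#' @param n_repeats random splits per fraction.
#' @param seed master seed; per-(fraction, repeat) seeds derive from it.
#' @param max_resample retries for degenerate splits (constant training x).
#' @return data.frame with one row per (fraction, repeat): chosen family,
#'   test MAE, test adjusted R^2.
#' @export
holdout_sweep <- function(x, y, fractions = seq(0.10, 0.30, by = 0.05),
                          n_repeats = 10L, seed = 1L, max_resample = 10L) {
  n <- length(x)
  out <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_test <- floor(n * f + 0.5)  # round half up
    stopifnot(n_test >= 1L, n - n_test >= 8L)
    for (r in seq_len(n_repeats)) {
      set.seed((seed * 1000L + fi * 100L + r) %% .Machine$integer.max)
      for (try in seq_len(max_resample)) {
        test_idx <- sample.int(n, n_test)
        if (length(unique(x[-test_idx])) > 3L) break
      }
      fit <- select_model_loocv(x[-test_idx], y[-test_idx])
      pred <- predict(fit, x[test_idx])
      yt <- y[test_idx]
      sst <- sum((yt - mean(yt)) ^ 2)
      r2 <- if (sst == 0) NA_real_ else 1 - sum((yt - pred) ^ 2) / sst
      adj <- 1 - (1 - r2) * (n_test - 1) / (n_test - fit$n_par - 1)
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, repeat_index = r, n_test = n_test,
        family = fit$family, test_mae = mean(abs(pred - yt)),
        test_adjusted_r2 = adj)
    }
  }
  do.call(rbind, out)
}

#' Fit allocation regressions for every eligible transcriptome module
#'
#' Uncharacterized, genomic, and technical modules are ignored; each
#' remaining module's replicate-averaged activity is regressed on the
#' proteome mass fraction of its covered genes via [select_model_loocv()].
#'
#' @param imodulons_t `imodulon_set` of the transcriptome decomposition.
#' @param A_t transcriptome activity matrix (components x samples).
#' @param fractions proteome mass-fraction matrix (proteins x samples).
#' @param metadata_t,metadata_p sample metadata for the two layers.
#' @param r2_min adjusted R^2 threshold for `strong`.
#' @return list of class `allocation_set` of `allocation_fit` objects,
#'   named by module.
#' @export
fit_allocation <- function(imodulons_t, A_t, fractions, metadata_t,
                           metadata_p, r2_min = 0.3) {
  skip <- c("uncharacterized", "genomic", "technical/single-gene")
  fits <- list()
  act <- condition_average(A_t, metadata_t)
  for (im in imodulons_t) {
    if (im$category %in% skip) next
    y <- module_mass_fraction(im$members, fractions, metadata_p)
    if (is.null(y)) next
    conds <- intersect(colnames(act), names(y))
    if (length(conds) < 8L) next
    x <- act[im$component_index, conds]
    fit <- tryCatch(
      select_model_loocv(x, y[conds], r2_min = r2_min, name = im$name),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit$members <- im$members
      fits[[im$name]] <- fit
    }
  }
  structure(fits, class = "allocation_set")
}

#' @export
print.allocation_set <- function(x, ...) {
  cat(sprintf("allocation fits for %d modules (%d strong, %d weak)\n",
              length(x),
              sum(vapply(x, `[[`, "", "strength") == "strong"),
              sum(vapply(x, `[[`, "", "strength") == "weak")))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.allocation_set <- function(x, ...) {
  data.frame(
    module = vapply(x, function(f) if (is.null(f$name)) NA_character_ else f$name, ""),
    family = vapply(x, `[[`, "", "family"),
    adjusted_r2 = vapply(x, `[[`, 0, "adjusted_r2"),
    loocv_mae = vapply(x, function(f) f$loocv_mae[f$family], 0),
    strength = vapply(x, `[[`, "", "strength"),
    n_members = vapply(x, function(f) length(f$members), 0L),
    row.names = NULL)
}

#' Sequential proteome allocation summary across module groups
#'
#' Assigns each proteome-covered gene to exactly one group: strong modules
#' first (descending adjusted R^2, ties to the larger module), then weak
#' modules, then the remaining genes split into invariant (mass-fraction
#' CV at or below `cv_cutoff`) and other. Reports, per module and per
#' residual group, the gene count, the mean across samples of the group's
#' summed mass fraction, and the CV of that sum.
#'
#' @param fits an `allocation_set` (fits carry their module member sets).
#' @param fractions proteome mass-fraction matrix.
#' @param cv_cutoff invariance cutoff on per-gene CV (default 1, inclusive).
#' @return data.frame of class `allocation_summary` with columns `group`,
#'   `name`, `gene_count`, `mean_mass_share`, `cv_of_share`. Shares sum
#'   to 1 over all rows.
#' @export
summarize_allocation <- function(fits, fractions, cv_cutoff = 1.0) {
  fractions <- as.matrix(fractions)
  remaining <- rownames(fractions)
  tab <- as.data.frame(fits)
  ord <- order(tab$strength != "strong", -tab$adjusted_r2, -tab$n_members)
  rows <- list()
  share_row <- function(group, name, genes) {
    if (!length(genes)) {
      return(data.frame(group = group, name = name, gene_count = 0L,
                        mean_mass_share = 0, cv_of_share = NA_real_))
    }
    s <- colSums(fractions[genes, , drop = FALSE])
    data.frame(group = group, name = name, gene_count = length(genes),
               mean_mass_share = mean(s),
               cv_of_share = stats::sd(s) / mean(s))
  }
  for (i in ord) {
    fit <- fits[[i]]
    genes <- intersect(fit$members, remaining)
    rows[[length(rows) + 1L]] <- share_row(fit$strength, tab$module[i], genes)
    remaining <- setdiff(remaining, genes)
  }
  mu <- rowMeans(fractions[remaining, , drop = FALSE])
  cv <- apply(fractions[remaining, , drop = FALSE], 1, stats::sd) / mu
  invariant <- remaining[!is.na(cv) & cv <= cv_cutoff]
  other <- setdiff(remaining, invariant)
  rows[[length(rows) + 1L]] <- share_row("invariant", "invariant", invariant)
  rows[[length(rows) + 1L]] <- share_row("other", "other", other)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("allocation_summary", "data.frame")
  out
}
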