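# The pairwise-additive diploid model: predict biallelic (diploid) function
# from two haploid allele scores, d = a + b*x_j + c*x_k with x_j <= x_k.
# This is the package's central fitted object.

#' Order two allele scores as (minimum, maximum)
#'
#' The diploid model is parameterized on the lower-growth allele `x_j` and
#' the higher-growth allele `x_k`; homozygotes have `x_j == x_k`. Vectorized
#' and symmetric in argument order.
#'
#' @param score1,score2 Finite numeric haploid scores (wild type = 1,
#'   null = 0).
#' @return List with components `x_j` (pairwise minimum) and `x_k` (maximum).
#' @export
order_alleles <- function(score1, score2) {
  if (any(!is.finite(score1)) || any(!is.finite(score2))) stop("non-finite allele score")
  list(x_j = pmin(score1, score2), x_k = pmax(score1, score2))
}

#' Fit the pairwise-additive diploid growth model
#'
#' Ordinary least squares fit of observed diploid growth on the ordered
#' haploid scores of the two alleles, `d = a + b*x_j + c*x_k`. Fitted to the
#' experimental diploid panel of the PSAT1 assay this model carries
#' coefficients near a = 0.05, b = 0.28, c = 0.73 and explains ~97% of the
#' variance; the small intercept reflects a consistent growth increase of
#' diploids over haploids and b < c reflects incomplete dominance of the
#' higher-growing allele.
#'
#' @param pairs Data frame with observed diploid growth `d` and either
#'   ordered scores `x_j`, `x_k` or raw `score1`, `score2` (ordered
#'   internally).
#' @param model `"full"` (default), `"mean"` (constrains b = c: growth
#'   predicted from the allele mean), or `"dominant"` (constrains b = 0:
#'   complete dominance of the higher-growing allele).
#' @return Object of class `diploid_fit`: coefficients `(a, b, c)`,
#'   `r.squared`, `sigma`, residuals, fitted values, `n`, the constraint
#'   name, and the underlying `lm`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `fitted`, `simulate`, `plot`.
#' @examples
#' pairs <- data.frame(score1 = runif(10), score2 = runif(10))
#' pairs$d <- 0.05 + 0.28 * pmin(pairs$score1, pairs$score2) +
#'   0.73 * pmax(pairs$score1, pairs$score2)
#' coef(fit_diploid_growth(pairs))
#' @export
fit_diploid_growth <- function(pairs, model = c("full", "mean", "dominant")) {
  model <- match.arg(model)
  pairs <- as.data.frame(pairs)
  if (!all(c("x_j", "x_k") %in% names(pairs))) {
    xs <- order_alleles(pairs$score1, pairs$score2)
    pairs$x_j <- xs$x_j
    pairs$x_k <- xs$x_k
  }
  stopifnot("d" %in% names(pairs))
  if (nrow(pairs) < 4) stop("need at least 4 allele pairs to fit")
  form <- switch(model,
                 full = d ~ x_j + x_k,
                 mean = d ~ I(x_j + x_k),
                 dominant = d ~ x_k)
  lmfit <- stats::lm(form, data = pairs)
  if (any(is.na(stats::coef(lmfit)))) {
    stop("collinear design (e.g. all homozygotes); consider the 'mean' model")
  }
  cf <- stats::coef(lmfit)
  co <- switch(model,
               full = c(a = unname(cf[1]), b = unname(cf["x_j"]), c = unname(cf["x_k"])),
               mean = c(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[2])),
               dominant = c(a = unname(cf[1]), b = 0, c = unname(cf["x_k"])))
  structure(list(coefficients = co,
                 r.squared = suppressWarnings(summary(lmfit)$r.squared),
                 sigma = stats::sigma(lmfit),
                 residuals = stats::residuals(lmfit),
                 fitted.values = stats::fitted(lmfit),
                 n = nrow(pairs), model = model, lm = lmfit,
                 data = pairs, call = match.call()),
            class = "diploid_fit")
}

#' @export
print.diploid_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise-additive diploid model (%s), n = %d pairs\n", x$model, x$n))
  cat(sprintf("  d = %.*f + %.*f * x_j + %.*f * x_k\n",
              digits, x$coefficients["a"], digits, x$coefficients["b"],
              digits, x$coefficients["c"]))
  cat(sprintf("  R-squared = %.3f, residual SD = %.4f\n", x$r.squared, x$sigma))
  invisible(x)
}

#' @export
coef.diploid_fit <- function(object, ...) object$coefficients

#' @export
residuals.diploid_fit <- function(object, ...) object$residuals

#' @export
fitted.diploid_fit <- function(object, ...) object$fitted.values

#' @export
summary.diploid_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat(sprintf("Pairwise-additive diploid model (%s)\n", object$model))
  print(s$coefficients)
  cat(sprintf("R-squared %.4f, adj. %.4f, residual SD %.4f on %d pairs\n",
              s$r.squared, s$adj.r.squared, stats::sigma(object$lm), object$n))
  invisible(s)
}

#' Predict diploid growth for new allele pairs
#'
#' @param object A `diploid_fit`.
#' @param newdata Data frame with `score1`/`score2` (any order; ordered
#'   internally) or pre-ordered `x_j`/`x_k`. Omitted: fitted values.
#' @param ... Unused.
#' @return Numeric predicted diploid growth (not clamped; the homozygous
#'   wild-type prediction exceeds 1 by construction).
#' @export
predict.diploid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.data.frame(newdata)
  if (!all(c("x_j", "x_k") %in% names(newdata))) {
    xs <- order_alleles(newdata$score1, newdata$score2)
    newdata$x_j <- xs$x_j
    newdata$x_k <- xs$x_k
  }
  co <- object$coefficients
  co[["a"]] + co[["b"]] * newdata$x_j + co[["c"]] * newdata$x_k
}

#' @export
simulate.diploid_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.diploid_fit <- function(x, boundary = NULL, ...) {
  graphics::plot(x$fitted.values, x$data$d,
                 xlab = "Predicted diploid growth", ylab = "Observed diploid growth",
                 main = sprintf("Pairwise-additive model (R² = %.2f)", x$r.squared), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  if (!is.null(boundary)) graphics::abline(v = boundary, lty = 3, col = "purple")
  invisible(x)
}

#' Compare nested diploid models with an F test
#'
#' Standard nested-model ANOVA between the full pairwise model and a
#' constrained alternative (`mean`: b = c, or `dominant`: b = 0), each with
#' one constrained degree of freedom.
#'
#' @param full,restricted `diploid_fit` objects fitted to the same data.
#' @return One-row data frame `F`, `df1`, `df2`, `p.value`, `rss_full`,
#'   `rss_restricted`.
#' @export
compare_diploid_models <- function(full, restricted) {
  stopifnot(inherits(full, "diploid_fit"), inherits(restricted, "diploid_fit"))
  if (full$n != restricted$n ||
      !isTRUE(all.equal(full$data$d, restricted$data$d))) {
    stop("models must be fitted to the same data")
  }
  rss_f <- sum(full$residuals^2)
  rss_r <- sum(restricted$residuals^2)
  df_f <- full$lm$df.residual
  df_r <- restricted$lm$df.residual
  df1 <- df_r - df_f
  if (df1 < 0) stop("models are not nested (restricted model has more parameters)")
  if (df1 == 0) {
    return(data.frame(F = 0, df1 = 0, df2 = df_f, p.value = 1,
                      rss_full = rss_f, rss_restricted = rss_r))
  }
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df_f)
  data.frame(F = Fstat, df1 = df1, df2 = df_f,
             p.value = stats::pf(Fstat, df1, df_f, lower.tail = FALSE),
             rss_full = rss_f, rss_restricted = rss_r)
}

#' Leave-one-out cross validation of the diploid model
#'
#' Refits the model on every leave-one-out subset and predicts the held-out
#' pair; reports RMSE and MAE of the held-out predictions. Folds whose
#' remainder is collinear are skipped with a warning.
#'
#' @param pairs Data frame as for [fit_diploid_growth()] (n >= 5).
#' @param model Model variant passed through.
#' @return List `rmse`, `mae`, `predictions` (held-out), `n_folds`.
#' @export
loocv_diploid <- function(pairs, model = "full") {
  pairs <- as.data.frame(pairs)
  if (!all(c("x_j", "x_k") %in% names(pairs))) {
    xs <- order_alleles(pairs$score1, pairs$score2)
    pairs$x_j <- xs$x_j
    pairs$x_k <- xs$x_k
  }
  n <- nrow(pairs)
  if (n < 5) stop("need at least 5 pairs for leave-one-out validation")
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(fit_diploid_growth(pairs[-i, , drop = FALSE], model = model),
                      error = function(e) NULL)
    if (is.null(fit_i)) {
      warning("fold ", i, " skipped: collinear remainder")
      next
    }
    pred[i] <- predict(fit_i, pairs[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  err <- pred[ok] - pairs$d[ok]
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       predictions = pred, n_folds = sum(ok))
}

#' Logistic patient/carrier classifier on predicted diploid growth
#'
#' Fits `log(p / (1 - p)) = g + h * y_p` by maximum likelihood, where the
#' positive class is the high-growth (carrier) label, and reports the
#' p = 0.5 decision boundary `-g/h` on the predicted-growth scale. Under
#' complete separation the boundary is reported as the midpoint between the
#' two classes with a separation flag.
#'
#' @param predicted Numeric predicted diploid growth per genotype.
#' @param label Character/factor with exactly the classes `"patient"` and
#'   `"carrier"` (patients grow less).
#' @return List of class `logistic_boundary`: `g`, `h`, `boundary`,
#'   `separation`, `misclassified` (genotype indices on the wrong side of
#'   the boundary), `fit` (the `glm`, absent under separation).
#' @export
fit_logistic_boundary <- function(predicted, label) {
  lab <- as.character(label)
  keep <- lab %in% c("patient", "carrier")
  y <- predicted[keep]
  lab <- lab[keep]
  if (length(unique(lab)) < 2) stop("both patient and carrier classes required")
  z <- as.integer(lab == "carrier")
  sep <- max(y[z == 0]) < min(y[z == 1])
  if (sep) {
    boundary <- (max(y[z == 0]) + min(y[z == 1])) / 2
    res <- list(g = NA_real_, h = NA_real_, boundary = boundary,
                separation = TRUE)
  } else {
    fit <- suppressWarnings(stats::glm(z ~ y, family = stats::binomial()))
    g <- unname(stats::coef(fit)[1])
    h <- unname(stats::coef(fit)[2])
    if (abs(h) < .Machine$double.eps) stop("degenerate logistic fit: zero slope")
    res <- list(g = g, h = h, boundary = -g / h, separation = FALSE, fit = fit)
  }
  wrong <- which((z == 1 & y < res$boundary) | (z == 0 & y >= res$boundary))
  res$misclassified <- which(keep)[wrong]
  res$n <- length(y)
  class(res) <- "logistic_boundary"
  res
}

#' @export
print.logistic_boundary <- function(x, ...) {
  if (x$separation) {
    cat(sprintf("Logistic boundary (complete separation): %.3f [midpoint], n = %d\n",
                x$boundary, x$n))
  } else {
    cat(sprintf("Logistic boundary: logit(p) = %.1f + %.1f * y_p; p = 0.5 at %.3f, n = %d\n",
                x$g, x$h, x$boundary, x$n))
  }
  if (length(x$misclassified)) {
    cat("  misclassified genotypes:", paste(x$misclassified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted diploid growth over all unordered allele pairs
#'
#' Scans all `n(n+1)/2` unordered pairs (with repetition) of a haploid score
#' vector — typically the variant scores plus wild type (1) and null (0) —
#' through a fitted pairwise model, accumulating a binned histogram and the
#' count of genotypes strictly below a classification boundary, in chunks of
#' rows so memory stays linear in `n`. Predictions themselves are returned
#' only when `keep_predictions = TRUE` (small n).
#'
#' @param scores Numeric haploid allele scores.
#' @param fit A `diploid_fit`.
#' @param boundary Classification boundary on predicted growth (optional).
#' @param binwidth Histogram bin width (default 0.01, i.e. 1% growth bins).
#' @param keep_predictions Return the full prediction matrix rows (default
#'   FALSE).
#' @return List `n_alleles`, `n_pairs`, `below_boundary` (strict `<`),
#'   `histogram` (data frame `bin_lo`, `bin_hi`, `count`), and optionally
#'   `predictions` (data frame `i`, `j`, `pred`).
#' @export
predict_all_pairs <- function(scores, fit, boundary = NULL, binwidth = 0.01,
                              keep_predictions = FALSE) {
  stopifnot(inherits(fit, "diploid_fit"))
  x <- as.numeric(scores)
  n <- length(x)
  co <- fit$coefficients
  lo_all <- co[["a"]] + (co[["b"]] + co[["c"]]) * min(x)
  hi_all <- co[["a"]] + (co[["b"]] + co[["c"]]) * max(x)
  edges <- seq(floor(min(lo_all, hi_all) / binwidth) * binwidth,
               ceiling(max(lo_all, hi_all) / binwidth) * binwidth + binwidth,
               by = binwidth)
  counts <- integer(length(edges) - 1L)
  below <- 0
  preds <- if (keep_predictions) vector("list", n) else NULL
  for (i in seq_len(n)) {
    xi <- x[i]
    xj <- x[i:n]
    pred <- co[["a"]] + co[["b"]] * pmin(xi, xj) + co[["c"]] * pmax(xi, xj)
    if (!is.null(boundary)) below <- below + sum(pred < boundary)
    bin <- findInterval(pred, edges, all.inside = TRUE)
    tb <- tabulate(bin, length(counts))
    counts <- counts + tb
    if (keep_predictions) preds[[i]] <- data.frame(i = i, j = i:n, pred = pred)
  }
  out <- list(n_alleles = n, n_pairs = n * (n + 1) / 2,
              below_boundary = if (is.null(boundary)) NA_integer_ else below,
              boundary = boundary,
              histogram = data.frame(bin_lo = edges[-length(edges)],
                                     bin_hi = edges[-1], count = counts))
  if (keep_predictions) out$predictions <- do.call(rbind, preds)
  out
}
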