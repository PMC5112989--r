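# Temperature-correcting GLMs, partial-residual OTU classification,
# correlation-matrix PCA and the rank-sum test used to compare OTUs.

#' Test for a temperature-by-taxon interaction (ANCOVA)
#'
#' Fits a two-slope linear model `value ~ temperature * otu` and returns the
#' F test of the interaction term. A non-significant interaction licenses
#' the common-slope temperature-correction model.
#'
#' @param values Numeric response.
#' @param temperatures Perch temperatures in degrees Celsius.
#' @param otu_labels Factor or character with exactly two levels, at least
#'   three observations each.
#' @return List with `f_statistic`, `p_value`, `df`.
#' @export
ancova_interaction <- function(values, temperatures, otu_labels) {
  otu <- factor(otu_labels)
  if (nlevels(otu) != 2L || any(table(otu) < 3L))
    stop("two OTU groups with at least 3 observations each are required")
  fit <- stats::lm(values ~ temperatures * otu)
  an <- stats::anova(fit)
  i <- grep(":", rownames(an))
  list(f_statistic = an[i, "F value"], p_value = an[i, "Pr(>F)"],
       df = c(an[i, "Df"], an[nrow(an), "Df"]))
}

#' Fit the temperature-correction model for one song variable
#'
#' Fits `variable = a + b * temperature + c * OTU` with the OTU pair coded
#' 0/1 (reference OTU = 0): ordinary least squares for Gaussian variables,
#' a log-link Poisson GLM for counts, or a logit-link binomial GLM for
#' per-individual success fractions (supply `sizes` as the denominators).
#'
#' @param values Numeric response (successes for the binomial family).
#' @param temperatures Perch temperatures in degrees Celsius.
#' @param otu_labels Two-level factor or character; the first level (or
#'   `reference`) is coded 0.
#' @param family One of `"gaussian_identity"`, `"poisson_log"`,
#'   `"binomial_logit"`.
#' @param variable_name Label stored with the fit.
#' @param sizes Binomial denominators (per-individual group counts).
#' @param reference OTU label to code as 0.
#' @return An object of class `glm_fit` with coefficients `a`, `b`, `c`,
#'   their standard errors, Wald t/z statistics and p-values.
#' @export
fit_temperature_glm <- function(values, temperatures, otu_labels,
                                family = c("gaussian_identity",
                                           "poisson_log",
                                           "binomial_logit"),
                                variable_name = "variable", sizes = NULL,
                                reference = NULL) {
  family <- match.arg(family)
  otu <- factor(otu_labels)
  if (nlevels(otu) != 2L)
    stop("exactly two OTU labels are required")
  if (!is.null(reference)) otu <- stats::relevel(otu, reference)
  code <- as.numeric(otu) - 1
  n <- length(values)
  if (n < 3L) stop("at least 3 individuals are required")
  if (stats::var(temperatures) == 0)
    stop("temperature has no variance; slope b is inestimable")

  fit <- switch(family,
    gaussian_identity = stats::lm(values ~ temperatures + code),
    poisson_log = stats::glm(values ~ temperatures + code,
                             family = stats::poisson()),
    binomial_logit = {
      if (is.null(sizes)) stop("binomial family needs 'sizes' denominators")
      stats::glm(cbind(values, sizes - values) ~ temperatures + code,
                 family = stats::binomial())
    })
  if (inherits(fit, "glm") && !fit$converged)
    stop("GLM did not converge (possible separation); family = ", family)
  sm <- summary(fit)
  co <- sm$coefficients
  if (nrow(co) < 3L || any(is.na(stats::coef(fit))))
    stop("collinear design; coefficients inestimable")
  structure(list(
    variable_name = variable_name, family = family,
    a = co[1, 1], b = co[2, 1], c = co[3, 1],
    se_b = co[2, 2], se_c = co[3, 2],
    t_or_z_temp = co[2, 3], p_temp = co[2, 4],
    t_or_z_otu = co[3, 3], p_otu = co[3, 4],
    n = n, reference = levels(otu)[1], contrast = levels(otu)[2],
    model = fit), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s (%s), n = %d, %s = 0 / %s = 1\n",
              x$variable_name, x$family, x$n, x$reference, x$contrast))
  cat(sprintf("  a = %.4g, b = %.4g (p = %.3g), c = %.4g (p = %.3g)\n",
              x$a, x$b, x$p_temp, x$c, x$p_otu))
  invisible(x)
}

#' Simulate individuals from a fitted temperature-correction model
#'
#' Draws temperatures uniformly over `temp_range`, codes a balanced OTU
#' pair 0/1, and simulates responses from `a + b * temperature + c * OTU`
#' under the given family (Gaussian noise `sd`, Poisson counts from the
#' log-mean, or binomial successes from the logit).
#'
#' @param a,b,c Generating coefficients.
#' @param family Model family as in [fit_temperature_glm()].
#' @param n Number of individuals (even).
#' @param temp_range Temperature range in degrees Celsius.
#' @param sd Gaussian residual SD.
#' @param sizes Binomial denominators (recycled).
#' @param seed Integer seed.
#' @return Data.frame with `value`, `temperature`, `otu`, and `size` for
#'   the binomial family.
#' @export
simulate_glm_data <- function(a, b, c, family = "gaussian_identity",
                              n = 200L, temp_range = c(17, 33), sd = 0,
                              sizes = 20L, seed = 1L) {
  with_seed(seed, {
    temps <- stats::runif(n, temp_range[1], temp_range[2])
    code <- rep(c(0, 1), length.out = n)
    eta <- a + b * temps + c * code
    out <- data.frame(
      temperature = temps,
      otu = ifelse(code == 0, "ref", "contrast"),
      stringsAsFactors = FALSE)
    if (family == "gaussian_identity") {
      out$value <- eta + stats::rnorm(n, 0, sd)
    } else if (family == "poisson_log") {
      out$value <- stats::rpois(n, exp(eta))
    } else if (family == "binomial_logit") {
      out$size <- rep_len(sizes, n)
      out$value <- stats::rbinom(n, out$size, stats::plogis(eta))
    } else stop("unknown family: ", family)
    out
  })
}

#' Classify individuals by temperature-corrected partial residuals
#'
#' Removes the fitted temperature effect from each individual's value
#' (partial residual = transformed value minus `b * temperature`, on the
#' model's link scale) and compares it with the observed min-max interval
#' ("variance") of the two reference OTUs. Reference-OTU individuals lying
#' inside the opposite OTU's interval are scored as overlap (failures);
#' individuals of any further OTU are assigned to whichever interval
#' contains them (`reference`, `contrast`, `overlap` when inside both,
#' nearest interval when inside neither).
#'
#' @param fit A `glm_fit` for the reference OTU pair.
#' @param values,temperatures,otu_labels Data for all individuals to score
#'   (may include OTUs beyond the fitted pair).
#' @param interval How the reference variance is summarized: observed range
#'   (default) or mean +/- k SD.
#' @param k SD multiplier for `interval = "sd"`.
#' @return An object of class `residual_classification`: a data.frame with
#'   `otu`, `partial_residual`, `label`, plus the two intervals as an
#'   attribute.
#' @export
classify_by_partial_residuals <- function(fit, values, temperatures,
                                          otu_labels,
                                          interval = c("range", "sd"),
                                          k = 2) {
  stopifnot(inherits(fit, "glm_fit"))
  interval <- match.arg(interval)
  link <- switch(fit$family,
    gaussian_identity = function(y) y,
    poisson_log = function(y) log(pmax(y, 0.5)),
    binomial_logit = function(y) stats::qlogis(pmin(pmax(y, 0.02), 0.98)))
  pr <- link(values) - fit$b * temperatures
  ref <- otu_labels == fit$reference
  con <- otu_labels == fit$contrast
  if (!any(ref) || !any(con)) stop("empty reference group")
  iv <- function(x) {
    if (interval == "range") range(x)
    else mean(x) + c(-k, k) * stats::sd(x)
  }
  ref_iv <- iv(pr[ref]); con_iv <- iv(pr[con])
  inside <- function(x, ivl) x >= ivl[1] & x <= ivl[2]
  in_ref <- inside(pr, ref_iv); in_con <- inside(pr, con_iv)
  label <- ifelse(in_ref & in_con, "overlap",
           ifelse(in_ref, "reference",
           ifelse(in_con, "contrast",
             ifelse(pmin(abs(pr - ref_iv[1]), abs(pr - ref_iv[2])) <=
                      pmin(abs(pr - con_iv[1]), abs(pr - con_iv[2])),
                    "reference", "contrast"))))
  out <- data.frame(otu = as.character(otu_labels), partial_residual = pr,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "intervals") <- list(reference = ref_iv, contrast = con_iv,
                                 reference_otu = fit$reference,
                                 contrast_otu = fit$contrast)
  class(out) <- c("residual_classification", "data.frame")
  out
}

#' Correlation-matrix principal component analysis
#'
#' PCA on features standardized to unit variance (`prcomp` with
#' `scale. = TRUE`), with a deterministic sign convention: the
#' largest-magnitude element of every loading vector is positive.
#'
#' @param feature_matrix Numeric matrix or data.frame, individuals in rows
#'   (>= 3), features in columns; no missing values, no zero-variance
#'   feature.
#' @return A list of class `pca_result` with `loadings`, `scores` and
#'   `explained` (variance fractions).
#' @export
pca_correlation <- function(feature_matrix) {
  X <- as.matrix(feature_matrix)
  if (nrow(X) < 3L) stop("at least 3 individuals are required")
  if (anyNA(X)) stop("missing values in the feature matrix")
  if (any(apply(X, 2, stats::sd) == 0))
    stop("zero-variance feature; correlation PCA undefined")
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(loadings = pr$rotation, scores = pr$x,
                 explained = pr$sdev^2 / sum(pr$sdev^2)),
            class = "pca_result")
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with the convention that `W` counts pairs with
#' `x_i > y_j` plus half of the ties (the Mann-Whitney U of the first
#' sample). The p-value is exact for samples of at most 20 without ties and
#' a tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `W` and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 20 && n2 <= 20) {
    if (W > n1 * n2 / 2) {
      p <- stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- stats::pwilcox(W, n1, n2)
    }
    p <- min(1, 2 * p)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(W = W, p_value = p)
}
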