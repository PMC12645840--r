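#' @importFrom stats glm binomial quasibinomial residuals df.residual coef
#'   vcov model.matrix as.formula plogis pt pnorm qt qnorm terms delete.response
#' @importFrom lme4 glmer glmerControl fixef nobars
NULL

#' Fit a binomial-family model of mutation frequency
#'
#' Models per-observation mutation proportions (mutation count out of
#' sequenced bases) on the logit scale as a function of fixed and optional
#' random effects.  Without random effects a GLM is fitted; the Pearson
#' dispersion phi = X2/(n - p) decides the family: quasibinomial when
#' phi > 1, plain binomial otherwise (the coefficient estimates are
#' identical; only standard errors scale).  With random effects a binomial
#' GLMM with random intercepts is fitted by Laplace-approximated maximum
#' likelihood.  Because mutation frequencies are tiny, the logit link is
#' effectively a log link and exponentiated contrasts approximate fold
#' changes.
#'
#' @param data `data.frame` (or [MFResult-class]) with one row per
#'   observation.
#' @param fixed character vector of fixed-effect terms (columns of `data`);
#'   may include interactions like `"dose:target"`.
#' @param random optional character vector of random-intercept grouping
#'   columns.
#' @param count,depth names of the mutation-count and depth columns
#'   (defaults `sum_min`, `group_depth`).
#' @return a [ModelFit-class].
#' @export
fitMFModel <- function(data, fixed, random = NULL,
                       count = "sum_min", depth = "group_depth") {
  if (methods::is(data, "MFResult")) data <- mfData(data)
  data <- as.data.frame(data)
  need <- c(count, depth, fixed, random)
  need <- unique(unlist(strsplit(need, "[:*]")))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("column(s) absent: ", paste(miss, collapse = ", "))
  if (any(data[[depth]] <= 0, na.rm = TRUE)) {
    stop("all depths must be positive")
  }
  if (all(data[[count]] == 0)) stop("no mutations observed; nothing to fit")
  # effects enter as factors: the model estimates a mean per level
  for (v in unique(unlist(strsplit(c(fixed, random), "[:*]")))) {
    data[[v]] <- factor(data[[v]])
  }
  # constant fixed factors carry no information; drop to the intercept
  keep <- vapply(fixed, function(tm) {
    vs <- unlist(strsplit(tm, "[:*]"))
    all(vapply(vs, function(v) nlevels(data[[v]]) > 1L, logical(1)))
  }, logical(1))
  fixed_terms <- if (any(keep)) fixed[keep] else "1"
  data$.y <- cbind(data[[count]], data[[depth]] - data[[count]])

  if (is.null(random) || length(random) == 0L) {
    fml <- stats::as.formula(paste(".y ~",
                                   paste(fixed_terms, collapse = " + ")))
    fit <- stats::glm(fml, family = stats::binomial(), data = data)
    if (fit$rank < ncol(stats::model.matrix(fit))) {
      aliased <- names(which(is.na(stats::coef(fit))))
      stop("non-estimable design; aliased term(s): ",
           paste(aliased, collapse = ", "))
    }
    phi <- sum(stats::residuals(fit, type = "pearson")^2) /
      stats::df.residual(fit)
    family <- if (phi > 1) "quasibinomial" else "binomial"
    if (family == "quasibinomial") {
      fit <- stats::glm(fml, family = stats::quasibinomial(), data = data)
    }
    random <- character(0)
  } else {
    fml <- stats::as.formula(paste(
      ".y ~", paste(fixed_terms, collapse = " + "), "+",
      paste(sprintf("(1 | %s)", random), collapse = " + ")))
    fit <- lme4::glmer(fml, family = stats::binomial(), data = data,
                       control = lme4::glmerControl(
                         check.conv.singular = "ignore"))
    phi <- sum(stats::residuals(fit, type = "pearson")^2) /
      stats::df.residual(fit)
    family <- "binomial"
  }
  lev <- .levelEstimates(fit, data, fixed)
  methods::new("ModelFit", fit = fit, family = family,
               dispersion = phi, fixed = fixed, random = random,
               levelEstimates = lev, data = data)
}

.fit_coef <- function(fit) {
  if (methods::is(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
}

.fit_vcov <- function(fit) as.matrix(stats::vcov(fit))

.levelEstimates <- function(fit, data, fixed) {
  vars <- unique(unlist(strsplit(fixed, "[:*]")))
  nd <- unique(data[, vars, drop = FALSE])
  nd <- nd[do.call(order, nd), , drop = FALSE]
  rownames(nd) <- NULL
  tt <- if (methods::is(fit, "merMod")) {
    stats::delete.response(stats::terms(lme4::nobars(stats::formula(fit))))
  } else {
    stats::delete.response(stats::terms(fit))
  }
  X <- stats::model.matrix(tt, nd)
  beta <- .fit_coef(fit)
  V <- .fit_vcov(fit)
  eta <- drop(X %*% beta)
  se_eta <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  mu <- stats::plogis(eta)
  nd$estimate <- mu
  nd$se <- mu * (1 - mu) * se_eta  # delta method on the logistic scale
  nd$lower <- stats::plogis(eta - 1.96 * se_eta)
  nd$upper <- stats::plogis(eta + 1.96 * se_eta)
  nd
}

#' Per-level mean estimates from a fitted model
#'
#' Mean mutation frequency for each level combination of the fixed effects,
#' back-transformed from the logit scale with delta-method standard errors.
#' At typical ECS mutation frequencies the logistic and exponential
#' back-transforms agree to numerical precision.
#'
#' @param fit a [ModelFit-class].
#' @return `data.frame` of level combinations with `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
estimateLevels <- function(fit) {
  stopifnot(methods::is(fit, "ModelFit"))
  fit@levelEstimates
}

#' Estimate linear combinations of model coefficients
#'
#' For each supplied contrast vector c, computes theta = c' beta with
#' variance c' V c, the approximate fold change exp(theta) with
#' delta-method standard error exp(theta) * se(theta), a Wald test
#' (t with residual degrees of freedom for GLMs, z for GLMMs) and Sidak-
#' adjusted p-values across the supplied set of comparisons.
#'
#' @param fit a [ModelFit-class].
#' @param contrasts a named list of numeric contrast vectors, or a matrix
#'   with one contrast per row, each of length `length(coef)`.
#' @param conf_level confidence level for the fold-change interval.
#' @return `data.frame` with `theta`, `se_theta`, `fold_change`, `se_fold`,
#'   `lower`, `upper`, `statistic`, `p_value`, `p_adjust`.
#' @export
estimateContrast <- function(fit, contrasts, conf_level = 0.95) {
  stopifnot(methods::is(fit, "ModelFit"))
  beta <- .fit_coef(fit@fit)
  V <- .fit_vcov(fit@fit)
  if (is.numeric(contrasts) && is.null(dim(contrasts))) {
    contrasts <- matrix(contrasts, nrow = 1)
  }
  if (is.list(contrasts)) {
    contrasts <- do.call(rbind, contrasts)
  }
  if (ncol(contrasts) != length(beta)) {
    stop("contrast length ", ncol(contrasts),
         " does not match number of coefficients ", length(beta))
  }
  theta <- drop(contrasts %*% beta)
  se <- sqrt(pmax(rowSums((contrasts %*% V) * contrasts), 0))
  stat <- ifelse(se > 0, theta / se, 0)
  is_glmm <- methods::is(fit@fit, "merMod")
  if (is_glmm) {
    p <- 2 * stats::pnorm(-abs(stat))
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  } else {
    dfres <- stats::df.residual(fit@fit)
    p <- 2 * stats::pt(-abs(stat), df = dfres)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df = dfres)
  }
  p[se == 0] <- 1
  out <- data.frame(
    contrast = if (!is.null(rownames(contrasts))) rownames(contrasts) else
      paste0("contrast_", seq_len(nrow(contrasts))),
    theta = theta, se_theta = se,
    fold_change = exp(theta), se_fold = exp(theta) * se,
    lower = exp(theta - crit * se), upper = exp(theta + crit * se),
    statistic = stat, p_value = p,
    p_adjust = sidakAdjust(p),
    row.names = NULL
  )
  out
}

#' Contrasts of each level of a factor against a control level
#'
#' Convenience builder producing one contrast row per non-control level of
#' a fixed-effect factor, on the coefficient scale of the fitted model
#' (treatment coding), suitable for [estimateContrast()].
#'
#' @param fit a [ModelFit-class].
#' @param factor_name name of the fixed-effect factor.
#' @param control control level; defaults to the factor's reference level.
#' @return named contrast matrix, one row per comparison.
#' @export
contrastsVsControl <- function(fit, factor_name, control = NULL) {
  stopifnot(methods::is(fit, "ModelFit"))
  beta <- .fit_coef(fit@fit)
  levs <- levels(fit@data[[factor_name]])
  if (is.null(control)) control <- levs[1L]
  others <- setdiff(levs, control)
  cn <- names(beta)
  rows <- lapply(others, function(lv) {
    v <- numeric(length(beta))
    nm_lv <- paste0(factor_name, lv)
    nm_ctl <- paste0(factor_name, control)
    if (!nm_lv %in% cn && !nm_ctl %in% cn) {
      stop("cannot build contrast for level ", lv)
    }
    if (nm_lv %in% cn) v[cn == nm_lv] <- 1
    if (nm_ctl %in% cn) v[cn == nm_ctl] <- -1
    v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste(others, "vs", control)
  m
}

#' Sidak multiple-comparison adjustment
#'
#' Family-wise adjustment `p_adj = 1 - (1 - p)^m` over `m` comparisons,
#' clamped to `[0, 1]`.  With a single comparison the p-value is unchanged.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values.
#' @examples
#' sidakAdjust(0.01, m = 3)  # 0.029701
#' @export
sidakAdjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Pearson-residual diagnostics for a mutation-frequency model
#'
#' Returns the data behind the automatically generated model diagnostics: a
#' histogram and a normal Q-Q layout of Pearson residuals.
#'
#' @param fit a [ModelFit-class].
#' @return `data.frame` with `residual`, `theoretical` (normal quantiles in
#'   residual rank order).
#' @export
modelDiagnostics <- function(fit) {
  stopifnot(methods::is(fit, "ModelFit"))
  r <- stats::residuals(fit@fit, type = "pearson")
  n <- length(r)
  qq <- stats::qnorm(stats::ppoints(n))[order(order(r))]
  data.frame(residual = as.numeric(r), theoretical = qq)
}
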