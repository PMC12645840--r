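#' @importFrom stats optim uniroot rnorm pnorm qnorm quantile median sd
NULL

.DR_FAMILIES <- c("exponential", "hill", "inv_exponential", "lognormal")

# Four-parameter continuous dose-response forms on the natural scale, the
# standard PROAST/EFSA families for increasing continuous endpoints:
#   exponential:     y = a (c - (c-1) exp(-b x^d))
#   hill:            y = a (1 + (c-1) x^d / (b^d + x^d))
#   inv exponential: y = a (1 + (c-1) exp(-b x^-d))
#   log-normal:      y = a (1 + (c-1) Phi(d log(x/b)))
# All satisfy f(0) = a and f(inf) = a c, with a > 0 the control response,
# c >= 1 the maximum fold change, b > 0 the dose scale and d > 0 the shape.
.drCurve <- function(family, x, a, b, c_, d) {
  switch(family,
    exponential = a * (c_ - (c_ - 1) * exp(-b * x^d)),
    hill = a * (1 + (c_ - 1) * x^d / (b^d + x^d)),
    inv_exponential = {
      y <- ifelse(x <= 0, a, a * (1 + (c_ - 1) * exp(-b * x^(-d))))
      y
    },
    lognormal = {
      y <- ifelse(x <= 0, a,
                  a * (1 + (c_ - 1) * stats::pnorm(d * log(x / b))))
      y
    },
    stop("unknown dose-response family: ", family)
  )
}

.unpack <- function(par) {
  list(a = exp(par[1L]), b = exp(par[2L]),
       c_ = 1 + exp(par[3L]), d = exp(par[4L]))
}

#' Fit one continuous dose-response family
#'
#' Maximum-likelihood fit of one of the four continuous families
#' (exponential, Hill, inverse exponential, log-normal) to individual
#' responses, assuming normal errors on the log-transformed response.
#' Parameters are constrained to a monotone non-decreasing curve (a, b,
#' d > 0; c >= 1) via an unconstrained log reparameterization.  The error
#' SD is profiled out.  AIC counts the four curve parameters plus the
#' error SD.
#'
#' @param doses numeric vector of doses (>= 0; at least 3 distinct values).
#' @param responses positive numeric responses (e.g. per-sample MF_Min).
#' @param family one of `"exponential"`, `"hill"`, `"inv_exponential"`,
#'   `"lognormal"`.
#' @param start optional named vector (a, b, c, d) used as the single
#'   starting point (e.g. to warm-start bootstrap refits); by default a
#'   small grid of data-driven starts is tried.
#' @return list with `family`, `par` (a, b, c, d), `sigma` (log-scale
#'   residual SD), `logLik`, `AIC`, `converged`.
#' @export
fitDoseResponse <- function(doses, responses, family, start = NULL) {
  family <- match.arg(family, .DR_FAMILIES)
  if (any(responses <= 0)) {
    stop("responses must be positive for log transformation")
  }
  if (length(unique(doses)) < 3L) stop("need at least 3 distinct doses")
  n <- length(responses)
  ly <- log(responses)

  sse_fn <- function(par) {
    p <- .unpack(par)
    mu <- .drCurve(family, doses, p$a, p$b, p$c_, p$d)
    if (any(!is.finite(mu)) || any(mu <= 0)) return(1e10)
    sum((ly - log(mu))^2)
  }

  ctrl0 <- mean(responses[doses == min(doses)])
  top <- max(mean(responses[doses == max(doses)]), ctrl0 * 1.0001)
  dmax <- max(doses[doses > 0])
  starts <- list(
    c(log(ctrl0), log(1 / dmax), log(max(top / ctrl0 - 1, 1e-3)), 0),
    c(log(ctrl0), log(2 / dmax), log(max(2 * (top / ctrl0 - 1), 1e-3)),
      log(2)),
    c(log(ctrl0), log(0.2 / dmax), log(max(top / ctrl0 - 1, 1e-3)),
      log(0.5))
  )
  if (family %in% c("hill", "lognormal", "inv_exponential")) {
    # b is a dose-scale parameter for these families
    starts <- lapply(starts, function(s) {
      s[2L] <- log(dmax / 2)
      s
    })
  }
  if (!is.null(start)) {
    starts <- list(c(log(start[["a"]]), log(start[["b"]]),
                     log(max(start[["c"]] - 1, 1e-6)), log(start[["d"]])))
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, sse_fn, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(list(family = family, converged = FALSE))
  }
  p <- .unpack(best$par)
  sse <- best$value
  sigma2 <- max(sse / n, 1e-300)
  # log-normal errors: include the Jacobian of the log transform
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - sum(ly)
  list(family = family, par = c(a = p$a, b = p$b, c = p$c_, d = p$d),
       sigma = sqrt(sigma2), logLik = ll, AIC = -2 * ll + 2 * 5,
       converged = best$convergence == 0 || sse < 1e-12)
}

#' Benchmark dose of a fitted dose-response curve
#'
#' The BMD is the smallest dose at which the fitted curve reaches the
#' benchmark response: `f(0) * (1 + bmr)` for a relative-increase BMR, or
#' `f(0) * exp(sd0)` for a one-control-SD BMR on the log scale.  Solved in
#' closed form for each family where available, otherwise by bracketed
#' root finding; `NA` when the curve never reaches the target (e.g. a flat
#' fit).
#'
#' @param fit a fit from [fitDoseResponse()].
#' @param bmr benchmark response, a relative increase fraction (e.g. 0.5
#'   for a 50% increase over control).
#' @param type `"relative"` or `"sd"`; for `"sd"`, `sd0` must be given.
#' @param sd0 control standard deviation on the log scale (type `"sd"`).
#' @param dose_max upper end of the searched dose range (defaults to 10x
#'   the fitted scale); the target must be reached within it.
#' @return the BMD (numeric), or `NA` with a `reason` attribute.
#' @export
computeBmd <- function(fit, bmr, type = c("relative", "sd"), sd0 = NULL,
                       dose_max = NULL) {
  type <- match.arg(type)
  if (isFALSE(fit$converged)) {
    out <- NA_real_
    attr(out, "reason") <- "fit did not converge"
    return(out)
  }
  a <- fit$par[["a"]]; b <- fit$par[["b"]]
  c_ <- fit$par[["c"]]; d <- fit$par[["d"]]
  if (bmr == 0 && type == "relative") return(0)
  # target expressed as a fold change over the control response
  fold <- if (type == "relative") 1 + bmr else {
    if (is.null(sd0)) stop("sd0 required for type = 'sd'")
    exp(sd0)
  }
  B <- fold - 1
  if (c_ - 1 <= B) {
    out <- NA_real_
    attr(out, "reason") <- "response never reaches the benchmark response"
    return(out)
  }
  bmd <- switch(fit$family,
    exponential = (-log((c_ - 1 - B) / (c_ - 1)) / b)^(1 / d),
    hill = b * (B / (c_ - 1 - B))^(1 / d),
    inv_exponential = (b / log((c_ - 1) / B))^(1 / d),
    lognormal = b * exp(stats::qnorm(B / (c_ - 1)) / d)
  )
  if (!is.finite(bmd) || bmd < 0) {
    # fall back to bracketed root finding on the fitted curve
    target <- a * fold
    upper <- if (is.null(dose_max)) 10 * b else dose_max
    g <- function(x) .drCurve(fit$family, x, a, b, c_, d) - target
    if (g(upper) < 0) {
      out <- NA_real_
      attr(out, "reason") <- "target not reached within the dose range"
      return(out)
    }
    bmd <- stats::uniroot(g, c(0, upper), tol = 1e-10)$root
  }
  unname(bmd)
}

#' Model-averaged benchmark dose by bootstrap
#'
#' Fits all four continuous dose-response families to log-transformed
#' individual responses, computes Akaike weights from the per-family AICs,
#' and bootstraps the BMD: each replicate draws a generating family with
#' probability equal to its weight, simulates new responses parametrically
#' from that family's fit (normal noise on the log scale at the fitted
#' residual SD), refits all families to the replicate, recomputes the
#' replicate's Akaike weights, draws a family from them and records its
#' BMD.  The model-averaged BMD is the median of the bootstrap draws;
#' BMDL and BMDU are the 5th and 95th percentiles (a 90% interval).  The
#' whole procedure is reproducible from `seed`.
#'
#' @inheritParams fitDoseResponse
#' @param bmr relative-increase benchmark response (default 0.5, a 50%
#'   increase in mutation frequency over control).
#' @param type `"relative"` or `"sd"` (see [computeBmd()]).
#' @param n_boot number of bootstrap replicates (>= 200 recommended).
#' @param seed integer seed.
#' @return a [BmdResult-class].
#' @export
bmdModelAverage <- function(doses, responses, bmr = 0.5,
                            type = c("relative", "sd"),
                            n_boot = 200, seed = 1) {
  type <- match.arg(type)
  seed <- as.integer(seed)
  set.seed(seed)
  sd0 <- stats::sd(log(responses[doses == min(doses)]))
  fits <- lapply(.DR_FAMILIES, function(f)
    tryCatch(fitDoseResponse(doses, responses, f),
             error = function(e) list(family = f, converged = FALSE)))
  names(fits) <- .DR_FAMILIES
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("all dose-response families failed to fit")
  aic <- vapply(fits[ok], function(f) f$AIC, numeric(1))
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)

  draw_bmd <- function(fit_list, weights) {
    fam <- sample(names(weights), 1L, prob = weights)
    computeBmd(fit_list[[fam]], bmr, type = type, sd0 = sd0)
  }
  draws <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    gen <- sample(names(w), 1L, prob = w)
    gf <- fits[[gen]]
    mu <- .drCurve(gf$family, doses, gf$par[["a"]], gf$par[["b"]],
                   gf$par[["c"]], gf$par[["d"]])
    yb <- exp(log(mu) + stats::rnorm(length(doses), 0, gf$sigma))
    # warm-start every family from its full-data fit
    bfits <- lapply(.DR_FAMILIES, function(f)
      tryCatch(fitDoseResponse(doses, yb, f,
                               start = if (isTRUE(fits[[f]]$converged))
                                 fits[[f]]$par else NULL),
               error = function(e) list(family = f, converged = FALSE)))
    names(bfits) <- .DR_FAMILIES
    bok <- vapply(bfits, function(f) isTRUE(f$converged), logical(1))
    if (!any(bok)) next
    baic <- vapply(bfits[bok], function(f) f$AIC, numeric(1))
    bw <- exp(-(baic - min(baic)) / 2)
    bw <- bw / sum(bw)
    draws[i] <- draw_bmd(bfits, bw)
  }
  failed <- sum(is.na(draws))
  if (failed > 0.2 * n_boot) {
    warning(failed, " of ", n_boot, " bootstrap replicates failed to ",
            "produce a BMD")
  }
  good <- draws[!is.na(draws)]
  if (!length(good)) stop("no bootstrap replicate produced a BMD")
  full_w <- stats::setNames(numeric(length(.DR_FAMILIES)), .DR_FAMILIES)
  full_w[names(w)] <- w
  methods::new("BmdResult",
    fits = fits, aic = aic, weights = full_w,
    draws = draws,
    bmd = stats::median(good),
    bmdl = unname(stats::quantile(good, 0.05)),
    bmdu = unname(stats::quantile(good, 0.95)),
    bmr = list(value = bmr, type = type, sd0 = sd0),
    seed = seed, nBoot = as.integer(n_boot),
    nFailed = as.integer(failed))
}
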