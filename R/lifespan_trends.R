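#' Multiplicative zero replacement for compositions
#'
#' Replaces zero proportions by a small positive value `delta` and rescales
#' the non-zero parts multiplicatively so each composition still sums to 1;
#' ratios between non-zero parts are preserved. By default `delta` is half
#' the smallest non-zero proportion observed in the input.
#'
#' @param compositions numeric vector (one composition) or matrix/data.frame
#'   (one composition per row), each row summing to 1.
#' @param delta replacement value for zeros; default
#'   `0.5 * min(x[x > 0])` over the whole input.
#' @return Same shape as the input, strictly positive, rows summing to 1.
#' @export
impute_zero_proportions <- function(compositions, delta = NULL) {
  vec <- is.null(dim(compositions))
  x <- if (vec) matrix(compositions, nrow = 1) else as.matrix(compositions)
  if (any(x < 0)) stop("proportions must be nonnegative")
  sums <- rowSums(x)
  if (any(abs(sums - 1) > 1e-8))
    stop("each composition must sum to 1")
  if (any(rowSums(x > 0) == 0)) stop("all-zero composition")
  if (is.null(delta)) {
    nz <- x[x > 0]
    delta <- 0.5 * min(nz)
  }
  if (delta <= 0) stop("delta must be > 0")
  out <- x
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (!any(z)) next
    if (delta * sum(z) >= 1)
      stop("delta too large for the number of zeros")
    out[i, z] <- delta
    out[i, !z] <- x[i, !z] * (1 - delta * sum(z))
  }
  if (vec) out[1, ] else out
}

#' Log-odds transform of a proportion
#'
#' `log(x / (1 - x))`: removes the 0/1 boundaries of percentage-based role
#' proportions so they can be modelled on an unbounded scale. Requires
#' strictly interior values; impute zeros first
#' (see [impute_zero_proportions()]).
#'
#' @param x proportions strictly in (0, 1).
#' @return Unbounded real values.
#' @seealso [inv_logodds()]
#' @export
logodds <- function(x) {
  if (any(x <= 0 | x >= 1))
    stop("log-odds requires values strictly in (0, 1); impute zeros first")
  log(x / (1 - x))
}

#' Inverse log-odds
#'
#' @param y real values on the log-odds scale.
#' @return Proportions in (0, 1); `inv_logodds(logodds(x)) == x`.
#' @export
inv_logodds <- function(y) 1 / (1 + exp(-y))

# Extract the smooth-term row (F, edf, p) from a mgcv summary.
.smooth_stats <- function(sm, which = 1) {
  st <- sm$s.table
  list(f = unname(st[which, "F"]),
       edf = unname(st[which, "edf"]),
       p = unname(st[which, "p-value"]))
}

#' Fit a smooth age trend with covariate adjustment
#'
#' Penalized cubic regression spline of a response (log-odds role proportion
#' or efficiency balance) on age, with linear adjustment for mean functional
#' connectivity, sex and total intracranial volume. The spline uses a small
#' basis (`knots`, default 3) to keep the fit near-linear unless the data
#' demand curvature; smoothing is selected by REML. Alongside the smooth's
#' F-test, a companion linear fit provides the slope `b` with a 95% CI, and
#' partial eta-squared is derived from that fit's F statistic.
#'
#' @param response numeric response vector.
#' @param age ages in years.
#' @param covariates data.frame of linear confounds (e.g. columns `mean_fc`,
#'   `sex`, `tiv`); may be NULL for an unadjusted fit.
#' @param knots spline basis dimension (default 3).
#' @return Object of class `trend_fit`: the fitted `gam` plus `f_stat`,
#'   `edf`, `p_value`, `b`, `ci_low`, `ci_high`, `partial_eta_sq`.
#' @export
fit_age_trend <- function(response, age, covariates = NULL, knots = 3) {
  n <- length(response)
  if (n < 30) stop("need at least 30 observations for a stable smooth")
  if (length(age) != n) stop("age length mismatch")
  if (stats::sd(response) == 0) stop("constant response")
  dat <- data.frame(.y = response, age = age)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariate length mismatch")
    if (anyNA(covariates)) stop("covariates must be complete")
    dat <- cbind(dat, covariates)
    cov_terms <- names(covariates)
  }
  rhs <- paste(c(sprintf("s(age, k = %d, bs = \"cr\")", knots), cov_terms),
               collapse = " + ")
  fit <- mgcv::gam(stats::as.formula(paste(".y ~", rhs)), data = dat,
                   method = "REML")
  sm <- .smooth_stats(summary(fit))
  # companion linear fit for slope, CI and effect size
  lin_rhs <- paste(c("age", cov_terms), collapse = " + ")
  lfit <- stats::lm(stats::as.formula(paste(".y ~", lin_rhs)), data = dat)
  b <- stats::coef(lfit)[["age"]]
  ci <- stats::confint(lfit, "age", level = 0.95)
  tval <- summary(lfit)$coefficients["age", "t value"]
  df_res <- lfit$df.residual
  eta <- tval^2 / (tval^2 + df_res)
  structure(
    list(model = fit, linear_model = lfit, response = deparse(substitute(response)),
         f_stat = sm$f, edf = sm$edf, p_value = sm$p,
         b = b, ci_low = ci[1], ci_high = ci[2], partial_eta_sq = eta,
         knots = knots, n = n),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> F=%.2f, edf=%.2f, p=%.3g | b=%.3f [%.3f, %.3f], eta2p=%.3f (n=%d)\n",
    x$f_stat, x$edf, x$p_value, x$b, x$ci_low, x$ci_high,
    x$partial_eta_sq, x$n))
  invisible(x)
}

#' Factor-smooth age trends with FDR correction
#'
#' Fits one age smooth per factor level (e.g. per subsystem-by-role series)
#' in a single model — `y ~ group + s(age, by = group)` with shared linear
#' covariate adjustment — and Benjamini-Hochberg-corrects the per-level
#' smooth p-values within the family.
#'
#' @param data long data.frame with columns `value`, `age`, `group`
#'   (factor), plus any covariate columns named in `covariates`.
#' @param covariates character vector of covariate column names (default
#'   none).
#' @param knots spline basis dimension per smooth (default 3).
#' @return data.frame: `group`, `f_stat`, `edf`, `p_value`, `q_value`
#'   (BH within the family), plus the fitted model as attribute `"model"`.
#' @export
fit_factor_smooths <- function(data, covariates = character(0), knots = 3) {
  need <- c("value", "age", "group")
  if (!all(need %in% names(data)))
    stop("data must have columns value, age, group")
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2) stop("need at least 2 factor levels")
  rhs <- paste(c("group",
                 sprintf("s(age, by = group, k = %d, bs = \"cr\")", knots),
                 covariates), collapse = " + ")
  fit <- mgcv::gam(stats::as.formula(paste("value ~", rhs)), data = data,
                   method = "REML")
  st <- summary(fit)$s.table
  groups <- levels(data$group)
  # rows of s.table follow the level order of the by-factor
  out <- data.frame(
    group = groups,
    f_stat = unname(st[, "F"]),
    edf = unname(st[, "edf"]),
    p_value = unname(st[, "p-value"]),
    row.names = NULL
  )
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "model") <- fit
  out
}

#' Scan a fitted smooth for significant curvature
#'
#' Evaluates the finite-difference second derivative of the fitted age smooth
#' on a grid and flags grid ages where a simulation band (from `B` draws of
#' the smooth's coefficient posterior) excludes zero; contiguous flagged ages
#' are merged into intervals. An effectively linear smooth (edf close to 1)
#' returns no intervals.
#'
#' @param fit `trend_fit` from [fit_age_trend()].
#' @param age_grid ages at which to evaluate curvature (default: 100 points
#'   over the observed age range).
#' @param B posterior draws for the band (default 500).
#' @param level band coverage (default 0.95).
#' @param edf_min smooths with edf below this are treated as linear
#'   (default 1.1).
#' @return data.frame of intervals (`age_lo`, `age_hi`); zero rows when no
#'   significant curvature. The full grid scan is attached as attribute
#'   `"scan"` (`age`, `d2`, `lo`, `hi`, `significant`).
#' @export
inflection_scan <- function(fit, age_grid = NULL, B = 500, level = 0.95,
                            edf_min = 1.1) {
  if (!inherits(fit, "trend_fit")) stop("fit must be a trend_fit")
  model <- fit$model
  ages <- model$model$age
  if (is.null(age_grid))
    age_grid <- seq(min(ages), max(ages), length.out = 100)
  empty <- data.frame(age_lo = numeric(0), age_hi = numeric(0))
  if (fit$edf < edf_min) return(empty)
  # covariates pinned at reference values; only the smooth varies with age
  newdat <- data.frame(age = age_grid)
  for (v in setdiff(names(model$model), c(".y", "age"))) {
    col <- model$model[[v]]
    newdat[[v]] <- if (is.numeric(col)) mean(col) else col[1]
  }
  Xp <- stats::predict(model, newdata = newdat, type = "lpmatrix")
  h <- diff(age_grid[1:2])
  m <- length(age_grid)
  # central second-difference operator on the grid
  D2 <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) D2[i, i:(i + 2)] <- c(1, -2, 1) / h^2
  curv_X <- D2 %*% Xp
  beta <- stats::coef(model)
  Vb <- stats::vcov(model)
  draws <- mgcv::rmvn(B, beta, Vb)
  curv_draws <- curv_X %*% t(draws)       # (m-2) x B
  alpha <- (1 - level) / 2
  lo <- apply(curv_draws, 1, stats::quantile, probs = alpha)
  hi <- apply(curv_draws, 1, stats::quantile, probs = 1 - alpha)
  d2 <- as.numeric(curv_X %*% beta)
  sig <- lo > 0 | hi < 0
  mid_ages <- age_grid[2:(m - 1)]
  scan <- data.frame(age = mid_ages, d2 = d2, lo = lo, hi = hi,
                     significant = sig)
  if (!any(sig)) {
    attr(empty, "scan") <- scan
    return(empty)
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(age_lo = mid_ages[starts[keep]],
                    age_hi = mid_ages[ends[keep]])
  attr(out, "scan") <- scan
  out
}
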