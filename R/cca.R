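#' Prepare the cognitive score matrix
#'
#' Applies the participant-level rules for the brain-cognition analysis:
#' subjects with more than `max_missing` missing task scores are excluded
#' (and logged); remaining missing values are imputed with the median of the
#' subject's age decile (deciles of the retained sample); finally every task
#' column is z-scored.
#'
#' @param scores data.frame with `subject_id` plus one column per task
#'   (NA = missing).
#' @param ages per-subject ages, same order as `scores` rows.
#' @param max_missing exclusion threshold on missing scores (default 3:
#'   subjects with more than 3 missing are dropped).
#' @return list: `matrix` (subjects x tasks, z-scored), `subject_id`,
#'   `ages` (retained), `excluded` (data.frame log), `n_imputed`.
#' @export
prepare_cognitive <- function(scores, ages, max_missing = 3) {
  if (!"subject_id" %in% names(scores))
    stop("scores must have a subject_id column")
  task_cols <- setdiff(names(scores), "subject_id")
  if (length(task_cols) == 0) stop("no task columns")
  m <- as.matrix(scores[, task_cols])
  storage.mode(m) <- "double"
  if (any(colSums(!is.na(m)) == 0))
    stop("task column(s) entirely missing")
  if (nrow(m) != length(ages)) stop("ages do not match subjects")
  n_miss <- rowSums(is.na(m))
  drop <- n_miss > max_missing
  excluded <- data.frame(subject_id = scores$subject_id[drop],
                         n_missing = n_miss[drop])
  m <- m[!drop, , drop = FALSE]
  keep_ages <- ages[!drop]
  # age deciles of the retained sample
  qs <- stats::quantile(keep_ages, probs = seq(0, 1, 0.1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  decile <- cut(keep_ages, breaks = unique(qs), include.lowest = TRUE)
  n_imputed <- 0L
  for (j in seq_len(ncol(m))) {
    miss <- which(is.na(m[, j]))
    for (i in miss) {
      med <- stats::median(m[decile == decile[i], j], na.rm = TRUE)
      if (is.na(med)) med <- stats::median(m[, j], na.rm = TRUE)
      m[i, j] <- med
      n_imputed <- n_imputed + 1L
    }
  }
  z <- scale(m)
  list(matrix = z[, , drop = FALSE],
       subject_id = scores$subject_id[!drop],
       ages = keep_ages, excluded = excluded, n_imputed = n_imputed)
}

#' Orthogonal midlife age contrasts
#'
#' Two contrast columns capturing nonlinear midlife effects:
#' contrast 1 codes 56-60 > 45-50 + 51-55 (+2 / -1 / -1, 0 elsewhere);
#' contrast 2 codes 51-55 > 45-50 (+1 / -1, 0 elsewhere). Columns are
#' mean-centered; with balanced bins they are mutually orthogonal
#' (Helmert-type coding on the three midlife bins).
#'
#' @param ages ages in years.
#' @return n x 2 matrix with columns `contrast1`, `contrast2` (centered).
#' @export
build_age_contrasts <- function(ages) {
  b45 <- ages >= 45 & ages <= 50
  b51 <- ages >= 51 & ages <= 55
  b56 <- ages >= 56 & ages <= 60
  if (!any(b45) || !any(b51) || !any(b56))
    stop("degenerate contrasts: one or more midlife age bins (45-50, 51-55, 56-60) is empty")
  c1 <- 2 * b56 - 1 * b45 - 1 * b51
  c2 <- 1 * b51 - 1 * b45
  out <- cbind(contrast1 = c1 - mean(c1), contrast2 = c2 - mean(c2))
  out
}

#' Residualize a table on confounds
#'
#' Replaces every column by the residuals of an ordinary least-squares fit on
#' the confounds (plus intercept), removing linear confound contributions
#' before multivariate analysis.
#'
#' @param matrix subjects x variables numeric matrix or data.frame.
#' @param confounds subjects x confounds numeric matrix/data.frame
#'   (e.g. mean FC, sex, TIV), complete.
#' @return Matrix of residuals, same shape and dimnames as the input.
#' @export
residualize_confounds <- function(matrix, confounds) {
  m <- as.matrix(matrix)
  cf <- as.matrix(confounds)
  storage.mode(cf) <- "double"
  if (nrow(cf) != nrow(m)) stop("confounds do not match subjects")
  if (anyNA(cf)) stop("confounds must be complete")
  design <- cbind(1, cf)
  if (qr(design)$rank < ncol(design)) stop("collinear confounds")
  fit <- stats::lm.fit(design, m)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(m)
  res
}

# Inverse symmetric square root of a covariance matrix; refuses near-singular.
.isqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values))
    stop("rank-deficient input set")
  e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
}

#' Canonical correlation analysis
#'
#' Finds linear combinations (variates) of a brain variable set `X` and a
#' cognitive set `Y` that maximize their mutual correlation, via the SVD of
#' the whitened cross-covariance. Produces `min(pX, pY)` canonical functions
#' with nonincreasing canonical correlations, Wilks lambda statistics with
#' Bartlett chi-square p-values, canonical weights and variates, structure
#' coefficients (correlations of each variable with its own set's variate)
#' and cross-correlations (brain variables vs cognitive variates). Each
#' function is sign-oriented so its largest-|r| cognitive variable has a
#' positive structure coefficient.
#'
#' Inputs should already be confound-residualized; columns are z-scored
#' internally.
#'
#' @param X subjects x pX brain matrix.
#' @param Y subjects x pY cognitive matrix.
#' @return Object of class `cca_model`: `rc` (canonical correlations),
#'   `wilks`, `chisq`, `df`, `p_values`, `x_weights`, `y_weights`,
#'   `x_variates`, `y_variates`, `structure_x`, `structure_y`, `cross`
#'   (pX x k brain-variable vs cognitive-variate correlations), `n`.
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y have different numbers of subjects")
  px <- ncol(X); py <- ncol(Y)
  if (n <= max(px, py) + 1) stop("too few subjects for the number of variables")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%02d", seq_len(px))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%02d", seq_len(py))
  Xs <- scale(X); Ys <- scale(Y)
  if (anyNA(Xs) || anyNA(Ys)) stop("constant or missing columns")
  k <- min(px, py)
  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  Wxh <- .isqrt(Sxx); Wyh <- .isqrt(Syy)
  sv <- svd(Wxh %*% Sxy %*% Wyh)
  rc <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  wx <- Wxh %*% sv$u[, seq_len(k), drop = FALSE]
  wy <- Wyh %*% sv$v[, seq_len(k), drop = FALSE]
  U <- Xs %*% wx
  V <- Ys %*% wy
  # sign convention: largest-|r| cognitive variable gets positive r
  ry <- stats::cor(Ys, V)
  for (j in seq_len(k)) {
    lead <- which.max(abs(ry[, j]))
    if (ry[lead, j] < 0) {
      wx[, j] <- -wx[, j]; wy[, j] <- -wy[, j]
      U[, j] <- -U[, j]; V[, j] <- -V[, j]
    }
  }
  structure_x <- stats::cor(Xs, U)
  structure_y <- stats::cor(Ys, V)
  cross <- stats::cor(Xs, V)
  wilks <- rev(cumprod(rev(1 - rc^2)))
  ks <- seq_len(k)
  chisq <- -(n - 1 - (px + py + 1) / 2) * log(wilks)
  df <- (px - ks + 1) * (py - ks + 1)
  p_values <- stats::pchisq(chisq, df, lower.tail = FALSE)
  dimnames(wx) <- list(colnames(X), paste0("cf", ks))
  dimnames(wy) <- list(colnames(Y), paste0("cf", ks))
  colnames(U) <- colnames(V) <- paste0("cf", ks)
  colnames(structure_x) <- colnames(structure_y) <- colnames(cross) <-
    paste0("cf", ks)
  structure(
    list(rc = rc, wilks = wilks, chisq = chisq, df = df, p_values = p_values,
         x_weights = wx, y_weights = wy, x_variates = U, y_variates = V,
         structure_x = structure_x, structure_y = structure_y, cross = cross,
         n = n, px = px, py = py,
         x_center = attr(Xs, "scaled:center"),
         x_scale = attr(Xs, "scaled:scale"),
         y_center = attr(Ys, "scaled:center"),
         y_scale = attr(Ys, "scaled:scale")),
    class = "cca_model"
  )
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> %d functions (n=%d, pX=%d, pY=%d)\n",
              length(x$rc), x$n, x$px, x$py))
  for (j in seq_along(x$rc))
    cat(sprintf("  cf%d: Rc=%.3f, Wilks=%.3f, p=%.3g\n",
                j, x$rc[j], x$wilks[j], x$p_values[j]))
  invisible(x)
}

#' Structure coefficients and cross-correlations
#'
#' Recomputes, from a fitted model and the raw input tables, the correlation
#' of every variable with its own set's variate and the cross-correlation of
#' each brain variable with the cognitive variates. Matches the matrices
#' stored in the model; exposed as a function so the coefficients can be
#' recomputed on held-out or transformed data.
#'
#' @param model `cca_model`.
#' @param X,Y the matrices to correlate against the model's variates
#'   (columns matching the fitted sets).
#' @return list: `structure_x`, `structure_y`, `cross`.
#' @export
structure_and_cross <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xs <- scale(X, center = model$x_center, scale = model$x_scale)
  Ys <- scale(Y, center = model$y_center, scale = model$y_scale)
  U <- Xs %*% model$x_weights
  V <- Ys %*% model$y_weights
  list(structure_x = stats::cor(X, U),
       structure_y = stats::cor(Y, V),
       cross = stats::cor(X, V))
}

#' Mechanism difference scores
#'
#' A neural mechanism is expressed as the difference between the structure
#' coefficients of its two brain variables (e.g. a provincial-to-connector
#' reconfiguration scores `r_connector - r_provincial`), per canonical
#' function; the analogous difference of cross-correlations is reported
#' alongside.
#'
#' @param model `cca_model`.
#' @param mechanism_pairs named list of character pairs
#'   `c(variable_a, variable_b)` (score = r_a - r_b), names = mechanism
#'   labels; variables must be columns of the fitted X set.
#' @return data.frame: `mechanism`, `canonical_function`, `score`
#'   (structure-coefficient difference), `cross_score` (cross-correlation
#'   difference).
#' @export
mechanism_scores <- function(model, mechanism_pairs) {
  sx <- model$structure_x
  cx <- model$cross
  out <- do.call(rbind, lapply(names(mechanism_pairs), function(nm) {
    pair <- mechanism_pairs[[nm]]
    if (!all(pair %in% rownames(sx)))
      stop(sprintf("unknown variable(s) in mechanism '%s'", nm))
    data.frame(
      mechanism = nm,
      canonical_function = colnames(sx),
      score = sx[pair[1], ] - sx[pair[2], ],
      cross_score = cx[pair[1], ] - cx[pair[2], ],
      row.names = NULL
    )
  }))
  out
}

#' Cross-validated and bootstrap robustness of a CCA
#'
#' Ten-fold cross-validation (weights fit on the training folds, canonical
#' correlations evaluated on the held-out fold, sign-aligned to the
#' full-sample weights) and nonparametric bootstrap percentile intervals for
#' the canonical correlations and structure coefficients, with variate signs
#' aligned across resamples.
#'
#' @param X,Y the two variable sets (as in [fit_cca()]).
#' @param folds number of cross-validation folds (default 10).
#' @param boots bootstrap resamples (default 1000; 0 skips the bootstrap).
#' @param seed integer seed.
#' @return list: `cv` (data.frame of out-of-fold correlations per function
#'   and fold), `cv_mean` (per function), `boot_rc` (boots x k draws),
#'   `rc_ci` (2.5/97.5 percentile intervals), `structure_y_ci` (array
#'   variable x function x bound).
#' @export
validate_cca <- function(X, Y, folds = 10, boots = 1000, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2 * folds) stop("folds too small for the sample")
  ref <- fit_cca(X, Y)
  k <- length(ref$rc)
  .with_seed(seed, function() {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    cv <- do.call(rbind, lapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_cca(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
      # align fold weights to full-sample reference
      sgn <- sign(colSums(fit$x_weights * ref$x_weights))
      sgn[sgn == 0] <- 1
      Xs <- scale(X[!tr, , drop = FALSE], fit$x_center, fit$x_scale)
      Ys <- scale(Y[!tr, , drop = FALSE], fit$y_center, fit$y_scale)
      U <- Xs %*% sweep(fit$x_weights, 2, sgn, "*")
      V <- Ys %*% sweep(fit$y_weights, 2, sgn, "*")
      data.frame(fold = f, canonical_function = seq_len(k),
                 oof_cor = vapply(seq_len(k), function(j)
                   stats::cor(U[, j], V[, j]), numeric(1)))
    }))
    cv_mean <- tapply(cv$oof_cor, cv$canonical_function, mean)
    if (boots == 0)
      return(list(cv = cv, cv_mean = as.numeric(cv_mean),
                  boot_rc = NULL, rc_ci = NULL, structure_y_ci = NULL))
    boot_rc <- matrix(NA_real_, boots, k)
    boot_sy <- array(NA_real_, c(ncol(Y), k, boots))
    for (b in seq_len(boots)) {
      idx <- sample(n, replace = TRUE)
      fit <- try(fit_cca(X[idx, , drop = FALSE], Y[idx, , drop = FALSE]),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      sgn <- sign(colSums(fit$y_weights * ref$y_weights))
      sgn[sgn == 0] <- 1
      boot_rc[b, ] <- fit$rc
      boot_sy[, , b] <- sweep(fit$structure_y, 2, sgn, "*")
    }
    ok <- !is.na(boot_rc[, 1])
    rc_ci <- t(apply(boot_rc[ok, , drop = FALSE], 2, stats::quantile,
                     probs = c(0.025, 0.975)))
    sy_ci <- apply(boot_sy[, , ok, drop = FALSE], c(1, 2), stats::quantile,
                   probs = c(0.025, 0.975))
    list(cv = cv, cv_mean = as.numeric(cv_mean),
         boot_rc = boot_rc[ok, , drop = FALSE],
         rc_ci = rc_ci, structure_y_ci = sy_ci)
  })
}
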