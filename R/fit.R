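#' Model configuration for the penalized regional fit
#'
#' @param error_p0,error_p1 read-level error probabilities: an unmethylated
#'   (resp. methylated) cytosine read is observed methylated with
#'   probability `error_p0` (resp. `error_p1`). Defaults 0 and 1 switch the
#'   error layer off. Require `0 <= error_p0 < error_p1 <= 1`.
#' @param max_iter maximum IRLS iterations per smoothing value.
#' @param tol relative coefficient-change convergence tolerance.
#' @param smoothing `"reml"` (default: choose the smoothing multiplier on
#'   `lambda_grid` by restricted maximum likelihood of the converged
#'   working model — the low-variance choice, used for inference),
#'   `"gcv"` (generalized cross-validation of the Pearson statistic) or
#'   `"fixed"` (use `lambda` as given).
#' @param variance `"betabinom"` (default): after a first quasi-binomial
#'   pass, estimate the intra-CpG read correlation rho from the
#'   depth-dependence of the Pearson residuals and refit with effective
#'   denominators `n / (1 + (n - 1) rho)`, so over-dispersion that grows
#'   with read depth is weighted correctly; `"quasibinomial"`: constant
#'   multiplicative dispersion only (the classical quasi-binomial GLM,
#'   whose point estimates coincide with binomial IRLS).
#' @param lambda fixed smoothing multiplier when `smoothing = "fixed"`
#'   (0 = unpenalized).
#' @param lambda_grid candidate multipliers for GCV, on the scale of the
#'   penalty after normalization against the information matrix.
#' @param ci_level default pointwise confidence level.
#' @return list of class `model_config`.
#' @export
model_config <- function(error_p0 = 0, error_p1 = 1, max_iter = 200L,
                         tol = 1e-8, smoothing = c("reml", "gcv", "fixed"),
                         lambda = 1,
                         lambda_grid = 10^seq(-4, 3, length.out = 8),
                         variance = c("betabinom", "quasibinomial"),
                         ci_level = 0.95) {
  smoothing <- match.arg(smoothing)
  variance <- match.arg(variance)
  stopifnot(error_p0 >= 0, error_p0 < error_p1, error_p1 <= 1, tol > 0,
            max_iter >= 1L, ci_level > 0, ci_level < 1, all(lambda >= 0))
  structure(list(error_p0 = error_p0, error_p1 = error_p1,
                 max_iter = as.integer(max_iter), tol = tol,
                 smoothing = smoothing, lambda = lambda,
                 lambda_grid = lambda_grid, variance = variance,
                 ci_level = ci_level),
            class = "model_config")
}

# One penalized IRLS run at a fixed penalty matrix S.
# Returns coefficients, weights and the converged working quantities.
irls_fit <- function(X, y, n, S, p0, p1, beta, max_iter, tol) {
  span <- p1 - p0
  eps <- 1e-10
  boundary <- FALSE
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    q <- stats::plogis(eta)
    mu <- p0 + span * q
    mu <- pmin(pmax(mu, eps), 1 - eps)
    dmu <- pmax(span * q * (1 - q), eps)
    w <- n * dmu^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / dmu
    XtWX <- crossprod(X, X * w)
    rhs <- crossprod(X, w * z)
    A <- XtWX + S
    diag(A) <- diag(A) + 1e-9 * mean(diag(XtWX))
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) stop("singular penalized information matrix")
    beta_new <- drop(backsolve(ch, forwardsolve(t(ch), rhs)))
    delta <- max(abs(beta_new - beta)) / (max(abs(beta_new)) + 1e-8)
    beta <- beta_new
    if (delta < tol) { conv <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  q <- stats::plogis(eta)
  mu <- pmin(pmax(p0 + span * q, eps), 1 - eps)
  if (any(abs(eta) > 12)) boundary <- TRUE
  dmu <- pmax(span * q * (1 - q), eps)
  w <- n * dmu^2 / (mu * (1 - mu))
  XtWX <- crossprod(X, X * w)
  pearson <- sum(n * (y - mu)^2 / (mu * (1 - mu)))
  list(beta = beta, mu = mu, eta = eta, w = w, XtWX = XtWX,
       pearson = pearson, converged = conv, boundary = boundary, iters = it)
}

#' Fit the penalized smooth-curve regional model
#'
#' Models per-read methylation within one CpG region: for sample i at CpG
#' position t, `logit pi(i,t) = beta0(t) + D_i beta1(t) + age_i beta2(t)`
#' with each curve a penalized B-spline in t, and the observed success
#' probability `pi* = pi * error_p1 + (1 - pi) * error_p0`. The penalized
#' binomial working likelihood is maximized by IRLS; over-dispersion phi is
#' estimated from the Pearson statistic over residual degrees of freedom;
#' the smoothing multiplier is chosen by GCV unless fixed. Missing
#' sample x CpG records (total 0 or `NA`) contribute nothing.
#'
#' @param meth,total integer matrices, CpG (rows, ordered by position) by
#'   sample (columns); `total = 0` or `NA` marks a missing record.
#' @param design data.frame aligned to the columns of `meth`: `disease`
#'   (0/1), optional `age` (years; centered internally at the sample mean).
#' @param basis a [build_basis()] result evaluated at the region's CpG
#'   positions (rows of `meth`).
#' @param config a [model_config()].
#' @param region_id optional label carried into the output.
#' @return object of class `region_fit`: curve estimates and pointwise
#'   standard errors per CpG (`curves`), dispersion `phi`, effective
#'   degrees of freedom per curve (`edf`), the chosen smoothing multiplier,
#'   the region-level p-value for the disease curve, and convergence flags.
#' @export
fit_region <- function(meth, total, design, basis, config = model_config(),
                       region_id = NA_character_) {
  stopifnot(inherits(basis, "region_basis"), inherits(config, "model_config"))
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (!all(dim(meth) == dim(total))) stop("meth/total dimension mismatch")
  if (nrow(meth) != nrow(basis$B)) stop("basis not aligned to region CpGs")
  if (nrow(design) != ncol(meth)) stop("design not aligned to samples")
  if (any(!is.finite(meth[!is.na(total) & total > 0])))
    stop("non-finite methylated counts")
  D <- as.numeric(design$disease)
  if (any(is.na(D)) || !all(D %in% c(0, 1))) stop("design$disease must be 0/1")
  has_age <- "age" %in% names(design) && !is.null(design$age)
  age_center <- if (has_age) mean(design$age) else 0
  agec <- if (has_age) design$age - age_center else NULL

  obs <- which(!is.na(total) & total > 0)
  if (length(obs) < 2L) stop("no usable observations in region")
  t_idx <- row(total)[obs]; i_idx <- col(total)[obs]
  y <- meth[obs] / total[obs]
  n <- as.numeric(total[obs])
  Bt <- basis$B[t_idx, , drop = FALSE]
  K <- basis$df
  X <- if (has_age) cbind(Bt, D[i_idx] * Bt, agec[i_idx] * Bt)
       else cbind(Bt, D[i_idx] * Bt)
  ncurve <- if (has_age) 3L else 2L
  blocks <- split(seq_len(ncurve * K), rep(seq_len(ncurve), each = K))

  # normalize the penalty against the initial information scale so the
  # smoothing multiplier grid is problem-size invariant
  pbar <- sum(meth[obs]) / sum(n)
  beta0 <- numeric(ncurve * K)
  beta0[blocks[[1]]] <- stats::qlogis(min(max(pbar, 0.02), 0.98))
  w0 <- n * 0.25
  info_scale <- sum(colSums(Bt^2 * w0)) / K
  P_norm <- if (sum(abs(basis$P)) > 0)
    basis$P * (info_scale / (sum(diag(basis$P)) / K)) else basis$P
  S_of <- function(lam) {
    lam <- rep_len(lam, ncurve)
    S <- matrix(0, ncurve * K, ncurve * K)
    for (j in seq_len(ncurve)) S[blocks[[j]], blocks[[j]]] <- lam[j] * P_norm
    S
  }

  n_obs <- length(y)
  pen_eig <- eigen(P_norm, symmetric = TRUE, only.values = TRUE)$values
  pen_keep <- pen_eig > max(pen_eig[1], 0) * 1e-10
  pen_rank <- sum(pen_keep)
  pen_logdet <- sum(log(pen_eig[pen_keep]))
  eval_lambda <- function(lam, n_fit, beta_ws) {
    S <- S_of(lam)
    f <- irls_fit(X, y, n_fit, S, config$error_p0, config$error_p1,
                  beta_ws, config$max_iter, config$tol)
    A <- f$XtWX + S
    diag(A) <- diag(A) + 1e-9 * mean(diag(f$XtWX))
    ch <- chol(A)
    M <- chol2inv(ch)
    edf_i <- rowSums(M * f$XtWX)
    edf_tot <- sum(edf_i)
    score <- if (config$smoothing == "reml" && pen_rank > 0) {
      # restricted likelihood of the converged Gaussian working model,
      # dispersion profiled out; the weighted working RSS is the Pearson
      # statistic
      lamv <- rep_len(lam, ncurve)
      rss_pen <- f$pearson + drop(crossprod(f$beta, S %*% f$beta))
      mp <- ncurve * K - ncurve * pen_rank
      logdet_a <- 2 * sum(log(diag(ch)))
      logdet_s <- sum(pen_rank * log(lamv) + pen_logdet)
      (n_obs - mp) / 2 * log(rss_pen / (n_obs - mp)) +
        (logdet_a - logdet_s) / 2
    } else {
      n_obs * f$pearson / (n_obs - edf_tot)^2
    }
    list(f = f, M = M, edf_i = edf_i, edf_tot = edf_tot, lam = lam,
         gcv = score)
  }
  # Smoothing search: a shared multiplier over the grid first, then a
  # separate 1-D refinement of the disease-curve multiplier. The nuisance
  # curves (baseline, age) typically want much heavier smoothing than the
  # disease curve, so a purely shared multiplier would oversmooth the curve
  # that carries the inference.
  run_grid <- function(n_fit, refine = TRUE) {
    if (config$smoothing == "fixed")
      return(list(best = eval_lambda(config$lambda, n_fit, beta0)))
    best <- NULL; wiggly <- NULL
    beta_ws <- beta0
    for (lam in sort(config$lambda_grid)) {
      cand <- eval_lambda(lam, n_fit, beta_ws)
      beta_ws <- cand$f$beta
      if (is.null(wiggly)) wiggly <- cand
      if (is.null(best) || cand$gcv < best$gcv) best <- cand
    }
    if (refine && ncurve >= 2L) {
      shared <- best$lam[1]
      beta_ws <- best$f$beta
      for (lam1 in sort(config$lambda_grid)) {
        if (lam1 == shared) next
        lv <- rep(shared, ncurve); lv[2] <- lam1
        cand <- eval_lambda(lv, n_fit, beta_ws)
        beta_ws <- cand$f$beta
        if (cand$gcv < best$gcv) best <- cand
      }
    }
    list(best = best, wiggly = wiggly)
  }

  rho_hat <- 0
  n_fit <- n
  if (config$variance == "betabinom" && config$smoothing != "fixed") {
    # moment estimate of the intra-CpG read correlation from the
    # depth-dependence of the Pearson residuals of the least-smoothed grid
    # fit (so curve lack-of-fit under heavy smoothing cannot masquerade as
    # over-dispersion), then reweight with beta-binomial effective
    # denominators for the full smoothing search
    ref <- eval_lambda(min(config$lambda_grid), n, beta0)
    r2 <- n * (y - ref$f$mu)^2 / (ref$f$mu * (1 - ref$f$mu))
    rho_hat <- (sum(r2) - (n_obs - ref$edf_tot)) / sum(pmax(n - 1, 0))
    rho_hat <- min(max(rho_hat, 0), 0.95)
    if (rho_hat > 1e-4) n_fit <- n / (1 + (n - 1) * rho_hat)
  }
  best <- run_grid(n_fit)$best
  f <- best$f; M <- best$M; best_lam <- best$lam; best_gcv <- best$gcv
  phi <- best$f$pearson / max(n_obs - best$edf_tot, 1)
  Vb <- phi * M
  edf <- vapply(blocks, function(b) sum(best$edf_i[b]), numeric(1))
  names(edf) <- c("beta0", "beta1", "beta2")[seq_len(ncurve)]

  B <- basis$B
  curves <- data.table::data.table(pos = basis$positions)
  for (j in seq_len(ncurve)) {
    b <- blocks[[j]]
    est <- drop(B %*% f$beta[b])
    se <- sqrt(pmax(rowSums((B %*% Vb[b, b, drop = FALSE]) * B), 0))
    nm <- c("beta0", "beta1", "beta2")[j]
    curves[[nm]] <- est
    curves[[paste0("se_", nm)]] <- se
  }

  fit <- structure(list(region_id = region_id, positions = basis$positions,
                        curves = curves, coef = f$beta, Vb = Vb, M = M,
                        XtWX = f$XtWX, blocks = blocks, phi = phi,
                        rho = rho_hat, edf = edf,
                        lambda = best_lam, gcv = best_gcv,
                        converged = f$converged, boundary = f$boundary,
                        has_age = has_age, age_center = age_center,
                        n_obs = n_obs, basis = basis, config = config),
                   class = "region_fit")
  fit$region_pvalue <- tryCatch(region_test(fit), error = function(e) NA_real_)
  fit
}

#' @export
print.region_fit <- function(x, ...) {
  cat("Regional penalized smooth fit",
      if (!is.na(x$region_id)) paste0(" [", x$region_id, "]"), "\n", sep = "")
  cat(sprintf("  CpGs: %d   observations: %d   dispersion phi: %.3f\n",
              length(x$positions), x$n_obs, x$phi))
  cat(sprintf("  edf: %s   lambda: %s   converged: %s\n",
              paste(sprintf("%s=%.2f", names(x$edf), x$edf), collapse = " "),
              paste(signif(x$lambda, 3), collapse = "/"), x$converged))
  cat(sprintf("  region p-value (disease curve): %.3g\n", x$region_pvalue))
  invisible(x)
}

#' Region-level test of the disease effect curve
#'
#' Tests H0: beta1(t) = 0 across the region with a Wald quadratic form on
#' the disease-curve spline coefficients, using their Bayesian covariance
#' (dispersion-scaled). The covariance is eigen-truncated at rank equal to
#' the rounded effective degrees of freedom of the disease curve and the
#' statistic referred to a chi-square with that rank.
#'
#' @param fit a [fit_region()] result.
#' @return the region p-value in `[0, 1]`.
#' @export
region_test <- function(fit) {
  stopifnot(inherits(fit, "region_fit"))
  if (!fit$converged) stop("fit did not converge; p-value withheld")
  b <- fit$blocks[[2]]
  b1 <- fit$coef[b]
  V1 <- fit$Vb[b, b, drop = FALSE]
  edf1 <- fit$edf[["beta1"]]
  e <- eigen((V1 + t(V1)) / 2, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-10)
  r <- max(1L, min(as.integer(round(edf1)), pos))
  u <- drop(crossprod(e$vectors[, seq_len(r), drop = FALSE], b1))
  stat <- sum(u^2 / e$values[seq_len(r)])
  stats::pchisq(stat, df = r, lower.tail = FALSE)
}

#' Pointwise confidence intervals for the disease effect curve
#'
#' Normal-theory intervals `estimate +/- z * SE` on the logit scale.
#'
#' @param fit a [fit_region()] result.
#' @param ci_level confidence level in (0, 1).
#' @return `data.table` with `pos`, `est`, `se`, `lo`, `hi`.
#' @export
pointwise_intervals <- function(fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "region_fit"))
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1) stop("invalid confidence level")
  z <- stats::qnorm((1 + ci_level) / 2)
  data.table::data.table(pos = fit$positions,
                         est = fit$curves$beta1, se = fit$curves$se_beta1,
                         lo = fit$curves$beta1 - z * fit$curves$se_beta1,
                         hi = fit$curves$beta1 + z * fit$curves$se_beta1)
}

#' Model-derived group methylation proportions
#'
#' Evaluates the fitted linear predictor at a case profile and a control
#' profile (age fixed, by default at the sample mean age used for
#' centering) and inverts the logit, giving per-CpG model-derived
#' methylation proportions per group, their averages over a CpG subset, and
#' the control-minus-case gap in percentage points.
#'
#' @param fit a [fit_region()] result.
#' @param subset_pos CpG positions to average over (default: whole region).
#' @param age evaluation age in years (default: the centering age).
#' @return list with `per_cpg` (`data.table`: `pos`, `p_case`,
#'   `p_control`), `case_avg`, `control_avg`, and `gap_pp` =
#'   `100 * (control_avg - case_avg)`.
#' @export
fitted_group_proportions <- function(fit, subset_pos = NULL, age = NULL) {
  stopifnot(inherits(fit, "region_fit"))
  pos <- fit$positions
  keep <- if (is.null(subset_pos)) rep(TRUE, length(pos))
          else pos %in% subset_pos
  if (!any(keep)) stop("empty CpG subset")
  agec <- if (is.null(age)) 0 else age - fit$age_center
  eta_ctl <- fit$curves$beta0 +
    if (fit$has_age) agec * fit$curves$beta2 else 0
  eta_case <- eta_ctl + fit$curves$beta1
  p_ctl <- stats::plogis(eta_ctl); p_case <- stats::plogis(eta_case)
  case_avg <- mean(p_case[keep]); control_avg <- mean(p_ctl[keep])
  list(per_cpg = data.table::data.table(pos = pos, p_case = p_case,
                                        p_control = p_ctl)[keep],
       case_avg = case_avg, control_avg = control_avg,
       gap_pp = proportion_gap_pp(case_avg, control_avg))
}

#' Percentage-point gap between group methylation averages
#'
#' The reporting convention for group differences: how much lower (positive
#' values) the case average is than the control average, in percentage
#' points.
#'
#' @param case_avg,control_avg group-average methylation proportions.
#' @return `100 * (control_avg - case_avg)`.
#' @export
proportion_gap_pp <- function(case_avg, control_avg) {
  100 * (control_avg - case_avg)
}

#' Bonferroni-corrected per-region significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_regions number of regions tested (>= 1).
#' @return `alpha / n_regions`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_regions) {
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 1)
    stop("n_regions must be a positive count")
  alpha / n_regions
}
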