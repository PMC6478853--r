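#' Standardize continuous predictors and encode factors for modelling
#'
#' Continuous predictors (latitude and log10 sampling-unit size) are centred
#' and scaled to unit sample (n-1) standard deviation. The quadratic
#' latitude term is the square of the standardized latitude (not itself
#' re-standardized, so the linear/quadratic pair stays interpretable).
#' Vegetation is coded against reference level `closed`, realm against
#' `Afrotropical`.
#'
#' @param data Data frame with columns `latitude`, `size` and optionally
#'   `vegetation`, `realm`.
#' @param abs_latitude Use `abs(latitude)` instead of signed latitude.
#' @param log_size Apply `log10` to `size` before standardizing (sizes span
#'   orders of magnitude, from under a square metre to over a square
#'   kilometre).
#' @return List with `data` (adds `lat_std`, `lat2`, `size_std`; factors
#'   releveled) and `scaling` (means/sds for back-transformation).
#' @export
standardize_predictors <- function(data, abs_latitude = FALSE, log_size = TRUE) {
  lat <- if (abs_latitude) abs(data$latitude) else data$latitude
  size <- data$size
  if (log_size) {
    if (any(size <= 0)) stop("sampling-unit sizes must be positive", call. = FALSE)
    size <- log10(size)
  }
  sc <- list(
    lat_mean = mean(lat), lat_sd = stats::sd(lat),
    size_mean = mean(size), size_sd = stats::sd(size),
    abs_latitude = abs_latitude, log_size = log_size
  )
  if (sc$lat_sd == 0) stop("zero-variance predictor: latitude", call. = FALSE)
  if (sc$size_sd == 0) stop("zero-variance predictor: size", call. = FALSE)
  data$lat_std <- (lat - sc$lat_mean) / sc$lat_sd
  data$lat2 <- data$lat_std^2
  data$size_std <- (size - sc$size_mean) / sc$size_sd
  if (!is.null(data$vegetation))
    data$vegetation <- factor(data$vegetation, levels = VEGETATION_CLASSES)
  if (!is.null(data$realm))
    data$realm <- factor(data$realm, levels = REALMS)
  list(data = data, scaling = sc)
}

#' Gaussian marginal log-likelihood of the study-grouped mixed model
#'
#' The model is `y = X beta + b_study + e` with
#' `V_g = sigma2_study * J + sigma2_resid * R_g` within study `g`, where `J`
#' is all-ones and `R_g[i,j] = exp(-d_ij / rho)` under the exponential
#' spatial correlation (identity when `rho` is `NULL`). The REML variant
#' adds the `-0.5 log|X' V^-1 X|` correction and drops the fixed-effect
#' dimensions from the `2*pi` constant.
#'
#' @param y Response vector.
#' @param X Design matrix (`n x p`).
#' @param groups Grouping factor (study ids).
#' @param params List with `beta`, `sigma2_study` (>= 0), `sigma2_resid`
#'   (> 0) and optionally `rho` (> 0, spatial range in the units of
#'   `coords` distances).
#' @param coords Optional two-column matrix of coordinates; required when
#'   `rho` is supplied. With `coord_type = "geo"` columns are (lon, lat) in
#'   degrees and distances are great-circle km; with `"euclidean"` plain
#'   Euclidean distance is used.
#' @param reml Evaluate the REML criterion instead of ML.
#' @param coord_type `"geo"` or `"euclidean"`.
#' @return Log-likelihood (numeric scalar).
#' @export
lmm_loglik <- function(y, X, groups, params, coords = NULL, reml = FALSE,
                       coord_type = c("geo", "euclidean")) {
  coord_type <- match.arg(coord_type)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(groups) == n)
  beta <- params$beta
  s2s <- params$sigma2_study; s2e <- params$sigma2_resid
  rho <- params$rho
  if (is.na(s2s) || s2s < 0) stop("sigma2_study must be >= 0", call. = FALSE)
  if (is.na(s2e) || s2e <= 0) stop("sigma2_resid must be > 0", call. = FALSE)
  if (!is.null(rho) && rho <= 0) stop("rho must be > 0", call. = FALSE)
  groups <- as.factor(groups)
  r <- y - X %*% beta

  logdet <- 0; quad <- 0; XtVX <- matrix(0, p, p)
  for (g in levels(groups)) {
    i <- which(groups == g)
    m <- length(i)
    R <- if (is.null(rho)) diag(m) else
      exp(-group_dist(coords[i, , drop = FALSE], coord_type) / rho)
    V <- s2s * matrix(1, m, m) + s2e * R
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular within-group covariance", call. = FALSE))
    logdet <- logdet + 2 * sum(log(diag(ch)))
    ri <- backsolve(ch, forwardsolve(t(ch), r[i]))
    quad <- quad + sum(r[i] * ri)
    Xi <- X[i, , drop = FALSE]
    XiV <- backsolve(ch, forwardsolve(t(ch), Xi))
    XtVX <- XtVX + crossprod(Xi, XiV)
  }
  if (!reml) {
    -0.5 * (n * log(2 * pi) + logdet + quad)
  } else {
    -0.5 * ((n - p) * log(2 * pi) + logdet + quad +
              determinant(XtVX, logarithm = TRUE)$modulus[1])
  }
}

# Within-group distance matrix: great-circle km from (lon, lat) degrees, or
# plain Euclidean distance on planar coordinates.
group_dist <- function(xy, coord_type) {
  if (is.null(xy)) stop("coords required for spatial correlation", call. = FALSE)
  if (coord_type == "geo") {
    geosphere::distm(xy, fun = geosphere::distHaversine) / 1000
  } else as.matrix(stats::dist(xy))
}

#' Fit the study-grouped linear mixed model
#'
#' Maximizes the marginal (ML) or restricted (REML) likelihood of the model
#' described in [lmm_loglik()]. `beta` and the residual variance are
#' profiled out analytically; the optimizer works on the log of the
#' variance ratio `sigma2_study / sigma2_resid` (and log `rho` when spatial
#' correlation is on), from several starting points to guard against local
#' optima.
#'
#' @inheritParams lmm_loglik
#' @param spatial Include the exponential spatial correlation.
#' @param n_starts Number of optimizer starts (default 3).
#' @return An object of class `lmm_fit`: coefficient estimates and
#'   covariance, variance components, `rho`, log-likelihood, parameter count
#'   `k`, `n`, convergence flag, and the data needed for downstream
#'   summaries.
#' @export
fit_lmm <- function(y, X, groups, coords = NULL, spatial = FALSE,
                    reml = FALSE, coord_type = c("geo", "euclidean"),
                    n_starts = 3L) {
  coord_type <- match.arg(coord_type)
  X <- as.matrix(X)
  n <- length(y); p <- qr(X)$rank
  if (p < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  if (n <= ncol(X)) stop("need n > number of fixed effects", call. = FALSE)
  groups <- droplevels(as.factor(groups))
  idx <- split(seq_len(n), groups)

  Dlist <- NULL
  if (spatial) {
    if (is.null(coords)) stop("spatial fit requires coords", call. = FALSE)
    Dlist <- lapply(idx, function(i) group_dist(coords[i, , drop = FALSE], coord_type))
    dbar <- mean(unlist(lapply(Dlist, function(d) d[upper.tri(d)])), na.rm = TRUE)
    if (!is.finite(dbar) || dbar <= 0) dbar <- 1
  }

  # Profiled criterion at theta = (log gamma [, log rho]).
  profile_fit <- function(theta) {
    gamma <- exp(theta[1])
    rho <- if (spatial) exp(theta[2]) else NULL
    logdetW <- 0
    XtWX <- matrix(0, ncol(X), ncol(X)); XtWy <- numeric(ncol(X))
    sol <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[[k]]; m <- length(i)
      R <- if (is.null(rho)) diag(m) else exp(-Dlist[[k]] / rho)
      W <- gamma * matrix(1, m, m) + R
      ch <- tryCatch(chol(W), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      logdetW <- logdetW + 2 * sum(log(diag(ch)))
      Xi <- X[i, , drop = FALSE]
      WinvX <- backsolve(ch, forwardsolve(t(ch), Xi))
      Winvy <- backsolve(ch, forwardsolve(t(ch), y[i]))
      XtWX <- XtWX + crossprod(Xi, WinvX)
      XtWy <- XtWy + crossprod(Xi, Winvy)
      sol[[k]] <- list(ch = ch, i = i)
    }
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    rss <- 0
    for (k in seq_along(idx)) {
      i <- sol[[k]]$i; ch <- sol[[k]]$ch
      ri <- y[i] - X[i, , drop = FALSE] %*% beta
      wr <- backsolve(ch, forwardsolve(t(ch), ri))
      rss <- rss + sum(ri * wr)
    }
    if (!reml) {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi) + logdetW + n * log(s2) + n)
    } else {
      np <- n - ncol(X)
      s2 <- rss / np
      # log|X'V^-1 X| = log|X'W^-1 X| - p log s2; the p log s2 term is folded
      # into the (n-p) log s2 below
      ll <- -0.5 * (np * log(2 * pi) + logdetW + np * log(s2) +
                      determinant(XtWX, logarithm = TRUE)$modulus[1] + np)
    }
    list(ll = ll, beta = drop(beta), s2 = s2, XtWX = XtWX, gamma = gamma, rho = rho)
  }
  obj <- function(theta) {
    f <- profile_fit(theta)
    if (is.null(f) || !is.finite(f$ll)) 1e10 else -f$ll
  }

  starts <- if (spatial) {
    gs <- c(-2, 0, 2); rs <- log(dbar) + c(-1.5, 0, 1.5)
    mapply(function(a, b) c(a, b), gs[seq_len(n_starts)], rs[seq_len(n_starts)],
           SIMPLIFY = FALSE)
  } else as.list(c(-2, 0, 2)[seq_len(n_starts)])

  best <- NULL; best_conv <- FALSE
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = rep(-20, length(st)), upper = rep(20, length(st))),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-10) {
      best <- o
      best_conv <- o$convergence == 0
    }
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  f <- profile_fit(best$par)
  s2e <- f$s2
  s2s <- f$gamma * s2e
  vcov_beta <- s2e * solve(f$XtWX)
  n_groups <- length(idx)
  k_par <- ncol(X) + 2L + if (spatial) 1L else 0L
  fit <- list(
    beta = stats::setNames(f$beta, colnames(X)),
    se = stats::setNames(sqrt(diag(vcov_beta)), colnames(X)),
    vcov_beta = vcov_beta,
    sigma2_study = s2s, sigma2_resid = s2e,
    rho = if (spatial) f$rho else NULL,
    logLik = f$ll, k = k_par, n = n, p = ncol(X),
    n_groups = n_groups,
    df_resid = n - ncol(X) - n_groups + 1L,
    method = if (reml) "REML" else "ML",
    spatial = spatial,
    converged = best_conv,
    X = X, y = y, groups = groups, coords = coords, coord_type = coord_type,
    assign = attr(X, "assign"), term_labels = attr(X, "term_labels")
  )
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s)%s: n = %d, groups = %d\n",
              x$method, if (x$spatial) " + exponential spatial correlation" else "",
              x$n, x$n_groups))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  cat(sprintf("sigma2_study = %.4f, sigma2_resid = %.4f%s, logLik = %.3f\n",
              x$sigma2_study, x$sigma2_resid,
              if (x$spatial) sprintf(", rho = %.2f", x$rho) else "", x$logLik))
  invisible(x)
}

#' Akaike information criterion with small-sample correction
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. The parameter count `k`
#' includes the fixed coefficients, both variance components, and the
#' spatial range when present.
#'
#' @param fit An `lmm_fit`, or a numeric log-likelihood (then supply `k`
#'   and `n`).
#' @param k,n Parameter count and sample size (taken from the fit when
#'   omitted).
#' @return AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "lmm_fit")) {
    ll <- fit$logLik; k <- fit$k; n <- fit$n
  } else ll <- fit
  if (is.null(k) || is.null(n)) stop("k and n required", call. = FALSE)
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc with Akaike weights
#'
#' @param fits Named list of ML `lmm_fit` objects on the same data.
#' @return Data frame sorted by AICc with `logLik`, `k`, `AICc`, `dAICc`,
#'   `weight` (non-converged fits get `NA` weight and are excluded from the
#'   normalization).
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits have different sample sizes; not comparable", call. = FALSE)
  tab <- data.frame(
    model = names(fits),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = ns,
    AICc = vapply(fits, aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  ok <- tab$converged
  tab$dAICc <- tab$AICc - min(tab$AICc[ok])
  w <- exp(-tab$dAICc / 2)
  w[!ok] <- NA
  tab$weight <- w / sum(w, na.rm = TRUE)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-components decomposition: with `s2_f` the variance of the
#' fixed-effect predictor `X beta`, marginal R2 is
#' `s2_f / (s2_f + s2_study + s2_resid)` and conditional R2 is
#' `(s2_f + s2_study) / (s2_f + s2_study + s2_resid)`.
#'
#' @param fit An `lmm_fit`.
#' @return List with `R2_marginal`, `R2_conditional`.
#' @export
r2_marginal_conditional <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  s2f <- stats::var(drop(fit$X %*% fit$beta))
  tot <- s2f + fit$sigma2_study + fit$sigma2_resid
  if (tot == 0) return(list(R2_marginal = NA_real_, R2_conditional = NA_real_))
  list(R2_marginal = s2f / tot,
       R2_conditional = (s2f + fit$sigma2_study) / tot)
}

#' Marginal Wald tests of the fixed-effect terms
#'
#' Each term is tested with all other fixed effects present: multi-level
#' factors get a joint Wald F over their coefficients, single-coefficient
#' terms a Wald t. The denominator degrees of freedom follow the grouped
#' convention `n - rank(X) - n_groups + 1` (declared, configurable via
#' `df_resid`).
#'
#' @param fit An `lmm_fit` (REML fit of the selected model).
#' @param df_resid Override the denominator degrees of freedom.
#' @return Data frame: `term`, `df_num`, `df_den`, `F`, `p`, plus
#'   coefficient-level `t` statistics in the attribute `"coefficients"`.
#' @export
marginal_tests <- function(fit, df_resid = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  asgn <- fit$assign
  labels <- fit$term_labels
  if (is.null(asgn) || is.null(labels))
    stop("fit lacks term structure; build X with model.matrix and keep the ",
         "'assign'/'term_labels' attributes", call. = FALSE)
  dfd <- if (is.null(df_resid)) fit$df_resid else df_resid
  terms_ids <- sort(unique(asgn[asgn > 0]))
  rows <- lapply(terms_ids, function(t_id) {
    sel <- which(asgn == t_id)
    b <- fit$beta[sel]
    Vb <- fit$vcov_beta[sel, sel, drop = FALSE]
    q <- length(sel)
    Fstat <- drop(crossprod(b, solve(Vb, b))) / q
    data.frame(term = labels[t_id], df_num = q, df_den = dfd, F = Fstat,
               p = stats::pf(Fstat, q, dfd, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tvals <- fit$beta / fit$se
  attr(out, "coefficients") <- data.frame(
    coefficient = names(fit$beta), estimate = fit$beta, se = fit$se,
    t = tvals, p = 2 * stats::pt(abs(tvals), dfd, lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

# Build the design matrix for one candidate formula, keeping term metadata.
build_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  attr(X, "term_labels") <- attr(stats::terms(formula), "term.labels")
  X
}

#' Fit and rank the candidate model set for one response
#'
#' The candidate set holds latitude, latitude-squared and sampling-unit size
#' in every model and varies the categorical predictors: \{none, realm,
#' vegetation, realm + vegetation\} (no interactions). All candidates are
#' fitted by ML and ranked by AICc; the top model is refitted by REML for
#' coefficient reporting, marginal Wald tests and R-squared.
#'
#' @param data Data frame holding the response column, `latitude`, `size`,
#'   `vegetation`, `realm`, `study_id`, and `longitude` when
#'   `spatial = TRUE`.
#' @param response Column name, e.g. `"ses_mpd"` or `"ses_mntd"`.
#' @param spatial Add the exponential spatial correlation.
#' @param abs_latitude Model `abs(latitude)` instead of signed latitude.
#' @param coord_type Passed to [fit_lmm()].
#' @return List: `ranking` (AICc table), `fits` (ML fits), `top_name`,
#'   `top_fit` (REML refit), `tests` (marginal Wald tests), `r2`,
#'   `curves` (predicted fixed-effect SES over a latitude grid per
#'   vegetation class), `n_dropped` (rows lost to missing values),
#'   `scaling`.
#' @export
run_candidate_set <- function(data, response, spatial = FALSE,
                              abs_latitude = FALSE,
                              coord_type = c("geo", "euclidean")) {
  coord_type <- match.arg(coord_type)
  need <- c(response, "latitude", "size", "vegetation", "realm", "study_id")
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "),
         call. = FALSE)
  ok <- stats::complete.cases(data[, need])
  n_dropped <- sum(!ok)
  data <- data[ok, , drop = FALSE]
  std <- standardize_predictors(data, abs_latitude = abs_latitude)
  d <- std$data
  d$.y <- d[[response]]

  specs <- list(
    "latitude + latitude2 + size" = .y ~ lat_std + lat2 + size_std,
    "latitude + latitude2 + size + realm" = .y ~ lat_std + lat2 + size_std + realm,
    "latitude + latitude2 + size + vegetation" = .y ~ lat_std + lat2 + size_std + vegetation,
    "latitude + latitude2 + size + realm + vegetation" =
      .y ~ lat_std + lat2 + size_std + realm + vegetation
  )
  # drop factor terms with a single observed level (degenerate designs)
  usable <- vapply(specs, function(f) {
    v <- all.vars(f)[-1]
    all(vapply(v, function(nm) !is.factor(d[[nm]]) ||
                 nlevels(droplevels(d[[nm]])) > 1, logical(1)))
  }, logical(1))
  specs <- specs[usable]
  d <- droplevels(d)

  coords <- if (spatial) as.matrix(d[, c("longitude", "latitude")]) else NULL
  designs <- lapply(specs, build_design, data = d)
  # a candidate is only usable when AICc is defined: n > k + 1
  k_extra <- 2L + if (spatial) 1L else 0L
  supported <- vapply(designs, function(X)
    nrow(X) > ncol(X) + k_extra + 1L, logical(1))
  if (!any(supported))
    stop("sample too small for any candidate model", call. = FALSE)
  if (any(!supported))
    warning("candidate model(s) dropped (n too small for AICc): ",
            paste(names(specs)[!supported], collapse = "; "), call. = FALSE)
  specs <- specs[supported]; designs <- designs[supported]
  fits <- lapply(designs, function(X) {
    fit_lmm(d$.y, X, d$study_id, coords = coords, spatial = spatial,
            reml = FALSE, coord_type = coord_type)
  })
  ranking <- rank_models(fits)
  top_name <- ranking$model[1]
  X_top <- build_design(specs[[top_name]], d)
  top_fit <- fit_lmm(d$.y, X_top, d$study_id, coords = coords,
                     spatial = spatial, reml = TRUE, coord_type = coord_type)
  tests <- marginal_tests(top_fit)
  r2 <- r2_marginal_conditional(top_fit)
  curves <- prediction_curves(top_fit, d, std$scaling)
  list(ranking = ranking, fits = fits, top_name = top_name, top_fit = top_fit,
       tests = tests, r2 = r2, curves = curves, n_dropped = n_dropped,
       scaling = std$scaling)
}

# Predicted fixed-effect SES on a latitude grid, one curve per vegetation
# class present in the fit, other predictors at reference/mean values.
prediction_curves <- function(fit, d, scaling, n_grid = 100L) {
  has_veg <- any(grepl("^vegetation", names(fit$beta)))
  veg_levels <- if (has_veg) levels(droplevels(d$vegetation)) else "all"
  lat_grid <- seq(min(d$lat_std), max(d$lat_std), length.out = n_grid)
  rows <- list()
  for (v in veg_levels) {
    Xg <- matrix(0, n_grid, length(fit$beta),
                 dimnames = list(NULL, names(fit$beta)))
    Xg[, "(Intercept)"] <- 1
    Xg[, "lat_std"] <- lat_grid
    Xg[, "lat2"] <- lat_grid^2
    if (has_veg && v != veg_levels[1]) {
      col <- paste0("vegetation", v)
      if (col %in% colnames(Xg)) Xg[, col] <- 1
    }
    rows[[v]] <- data.frame(
      vegetation = v,
      latitude = lat_grid * scaling$lat_sd + scaling$lat_mean,
      predicted = drop(Xg %*% fit$beta),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
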