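# Segmented (piecewise-linear) regression with estimated break-points.
#
# Model: y = Z gamma + b1 * x + sum_k d_k * (x - psi_k)+ + e, where x is the
# segmented covariate (age in days), Z holds the intercept and categorical
# dummies (breed category, calendar month, year), and psi_1 < ... < psi_K
# are break-points estimated by iterative linearization: each iteration
# adds, for every current psi_k, the hinge term (x - psi_k)+ and the
# indicator term -1{x > psi_k}; the ratio of the indicator coefficient to
# the hinge coefficient is the first-order update to psi_k. On
# non-convergence (or on request) a profile grid search over psi on a
# 1-day lattice minimising the residual sum of squares is used instead.

seg_design <- function(x, psi, Z) {
  U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
  cbind(Z, x, U)
}

seg_rss <- function(y, x, psi, Z) {
  f <- stats::.lm.fit(seg_design(x, psi, Z), y)
  sum(f$residuals^2)
}

seg_ols <- function(y, x, psi, Z) {
  X <- seg_design(x, psi, Z)
  f <- stats::lm.fit(X, y)
  if (f$rank < ncol(X))
    stop_config("singular design: collinear covariates or empty segment")
  f
}

# candidate break lattice leaving at least min_seg_obs observations outside
# the extreme breaks
seg_lattice <- function(x, step, min_seg_obs) {
  xs <- sort(x)
  lo <- xs[min_seg_obs]
  hi <- xs[length(xs) - min_seg_obs + 1L]
  if (hi - lo < 2 * step) return(numeric(0))
  seq(ceiling(lo + step), floor(hi - step), by = step)
}

seg_valid_psi <- function(x, psi, min_seg_obs, min_gap = 1) {
  if (!length(psi)) return(TRUE)
  if (is.unsorted(psi, strictly = TRUE)) return(FALSE)
  if (length(psi) > 1L && any(diff(psi) < min_gap)) return(FALSE)
  all(tabulate(findInterval(x, psi) + 1L,
               nbins = length(psi) + 1L) >= min_seg_obs)
}

# exhaustive / coordinate-refined grid search over break positions
seg_grid_core <- function(y, x, Z, K, step = 1, min_seg_obs = 5L,
                          budget = 3e5) {
  lat <- seg_lattice(x, step, min_seg_obs)
  if (length(lat) < K) stop_config("too few distinct ages for %d breaks", K)
  n_comb <- choose(length(lat), K)
  best <- NULL
  eval_psi <- function(psi) {
    if (!seg_valid_psi(x, psi, min_seg_obs, min_gap = step)) return(Inf)
    seg_rss(y, x, psi, Z)
  }
  if (n_comb <= budget && K <= 2) {
    if (K == 1L) {
      rss <- vapply(lat, function(p) eval_psi(p), 0)
      best <- lat[which.min(rss)]
    } else {
      best_rss <- Inf
      for (i in seq_along(lat)) {
        p1 <- lat[i]
        for (p2 in lat[lat > p1]) {
          r <- eval_psi(c(p1, p2))
          if (r < best_rss) { best_rss <- r; best <- c(p1, p2) }
        }
      }
    }
  } else {
    # coarse lattice then per-coordinate refinement at the fine step
    coarse_target <- 1.5e4
    coarse_step <- step *
      max(2, ceiling((length(lat) / (factorial(K) * coarse_target)^(1 / K))))
    clat <- seg_lattice(x, coarse_step, min_seg_obs)
    combs <- utils::combn(clat, K)
    rss <- apply(combs, 2L, eval_psi)
    best <- combs[, which.min(rss)]
    for (pass in 1:3) {
      for (k in seq_len(K)) {
        cand <- seq(best[k] - coarse_step, best[k] + coarse_step, by = step)
        r <- vapply(cand, function(p) {
          psi <- best; psi[k] <- p
          if (is.unsorted(psi, strictly = TRUE)) return(Inf)
          eval_psi(psi)
        }, 0)
        best[k] <- cand[which.min(r)]
      }
    }
  }
  psi <- sort(best)
  list(psi = psi, rss = seg_rss(y, x, psi, Z))
}

# one iterative-linearization run from a given start; the raw update can
# oscillate around the optimum, so each step is halved until the residual
# sum of squares does not increase (monotone descent)
seg_iterate <- function(y, x, Z, psi, tol, max_iter, min_seg_obs) {
  n <- length(y)
  K <- length(psi)
  rng <- range(x)
  if (!seg_valid_psi(x, psi, min_seg_obs)) return(NULL)
  cur_rss <- seg_rss(y, x, psi, Z)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
    V <- vapply(psi, function(p) -as.numeric(x > p), numeric(n))
    X <- cbind(Z, x, U, V)
    f <- stats::lm.fit(X, y)
    cf <- f$coefficients
    if (anyNA(cf)) return(NULL)
    d <- cf[ncol(Z) + 1L + seq_len(K)]
    g <- cf[ncol(Z) + 1L + K + seq_len(K)]
    if (any(abs(d) < 1e-12)) return(NULL)
    step <- g / d
    if (any(!is.finite(step))) return(NULL)
    h <- 1
    accepted <- FALSE
    for (half in 1:10) {
      cand <- sort(psi + h * step)
      if (all(cand > rng[1]) && all(cand < rng[2]) &&
          seg_valid_psi(x, cand, min_seg_obs)) {
        cand_rss <- seg_rss(y, x, cand, Z)
        if (cand_rss <= cur_rss + 1e-10) {
          rel <- max(abs(cand - psi) / pmax(abs(psi), 1))
          psi <- cand
          cur_rss <- cand_rss
          accepted <- TRUE
          break
        }
      }
      h <- h / 2
    }
    if (!accepted) { converged <- it > 1L; break }  # stalled at optimum
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) return(NULL)
  list(psi = psi, rss = cur_rss, iterations = it, converged = TRUE)
}

seg_fit_core <- function(y, x, Z, K, init_psi = NULL, tol = 1e-4,
                         max_iter = 50L, fallback = "grid_search",
                         grid_step = 1, min_seg_obs = 5L) {
  if (is.null(init_psi))
    init_psi <- stats::quantile(x, seq_len(K) / (K + 1), names = FALSE)
  res <- seg_iterate(y, x, Z, init_psi, tol, max_iter, min_seg_obs)
  method <- "iterative"
  if (is.null(res)) {
    if (fallback == "fail")
      stop_config("segmented fit did not converge for K = %d", K)
    g <- seg_grid_core(y, x, Z, K, step = grid_step,
                       min_seg_obs = min_seg_obs)
    # polish the grid optimum with the iterative scheme when it cooperates
    pol <- seg_iterate(y, x, Z, g$psi, tol, max_iter, min_seg_obs)
    if (!is.null(pol) && pol$rss <= g$rss) {
      res <- pol
      method <- "iterative_from_grid"
    } else {
      res <- list(psi = g$psi, rss = g$rss, iterations = 0L,
                  converged = TRUE)
      method <- "grid_search"
    }
  }
  res$method <- method
  res
}

#' Fit a segmented regression with estimated break-points
#'
#' Fits a continuous piecewise-linear regression of the response on a
#' segmented numeric covariate (typically age in days) with additive
#' categorical covariates, estimating the break-point positions by
#' iterative linearization with a residual-sum-of-squares grid search as
#' fallback.
#'
#' @param formula e.g. `liveweight ~ age_days + breed_category + month +
#'   year`. The first (or `seg`-named) right-hand-side variable is the
#'   segmented covariate; all other terms are treated as unordered factors.
#' @param data data.frame.
#' @param K number of break-points (1-3).
#' @param seg name of the segmented covariate; default the first
#'   right-hand-side numeric term.
#' @param init_psi optional starting break-points; default the
#'   `k/(K+1)` quantiles of the segmented covariate.
#' @param tol convergence threshold on the maximum relative break-point
#'   change per iteration.
#' @param max_iter maximum linearization iterations before fallback.
#' @param fallback `"grid_search"` (profile search on a `grid_step` lattice)
#'   or `"fail"`.
#' @param grid_step lattice spacing (days) for the fallback search.
#' @param min_seg_obs minimum observations required in every segment.
#' @return an object of class `segfit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' d <- data.frame(age = 1:200)
#' d$y <- piecewise_mean(d$age, 10, c(1, 0.2), 100) + rnorm(200, 0, 2)
#' f <- segfit(y ~ age, d, K = 1)
#' f$psi
#' @export
segfit <- function(formula, data, K = 1L, seg = NULL, init_psi = NULL,
                   tol = 1e-4, max_iter = 50L,
                   fallback = c("grid_search", "fail"), grid_step = 1,
                   min_seg_obs = 5L) {
  fallback <- match.arg(fallback)
  if (K < 1 || K > 3) stop_config("K must be 1, 2 or 3")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  terms_obj <- attr(mf, "terms")
  labs <- attr(terms_obj, "term.labels")
  if (!length(labs)) stop_config("formula needs at least the segmented term")
  if (is.null(seg)) seg <- labs[1L]
  if (!seg %in% labs) stop_config("segmented variable %s not in formula", seg)
  x <- mf[[seg]]
  if (!is.numeric(x)) stop_config("segmented variable must be numeric")
  covs <- setdiff(labs, seg)
  xlevels <- list()
  if (length(covs)) {
    fcts <- lapply(covs, function(v) factor(mf[[v]]))
    names(fcts) <- covs
    xlevels <- lapply(fcts, levels)
    # constant covariates carry no contrast; they are absorbed by the
    # intercept but keep their level recorded for prediction
    multi <- vapply(fcts, function(f) nlevels(f) >= 2L, TRUE)
    Z <- if (any(multi))
      stats::model.matrix(~ ., data = as.data.frame(fcts[multi]))
    else
      matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  } else {
    Z <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  n <- length(y)
  n_par <- ncol(Z) + 1L + 2L * K
  if (n <= n_par + 10L)
    stop_config("need more than %d observations for K = %d", n_par + 10L, K)
  core <- seg_fit_core(y, x, Z, K, init_psi, tol, max_iter, fallback,
                       grid_step, min_seg_obs)
  ols <- seg_ols(y, x, core$psi, Z)
  cf <- ols$coefficients
  names(cf) <- c(colnames(Z), seg, paste0("delta", seq_len(K)))
  rss <- sum(ols$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = cf, psi = unname(core$psi), K = K,
    response = deparse(formula[[2L]]), seg = seg, xlevels = xlevels,
    r.squared = 1 - rss / tss, sigma = sqrt(rss / (n - length(cf))),
    rss = rss, n = n, fitted.values = unname(ols$fitted.values),
    residuals = unname(ols$residuals), converged = core$converged,
    iterations = core$iterations, method = core$method,
    x_range = range(x), call = match.call(), model = mf),
    class = "segfit")
}

#' @export
print.segfit <- function(x, ...) {
  cat(sprintf("Segmented regression: %s ~ %s, K = %d (%s)\n",
              x$response, x$seg, x$K, x$method))
  cat(sprintf("  break-points: %s\n",
              paste(round(x$psi, 1), collapse = ", ")))
  cat(sprintf("  n = %d, R-squared = %.4f, sigma = %.2f\n",
              x$n, x$r.squared, x$sigma))
  invisible(x)
}

#' @export
summary.segfit <- function(object, ...) {
  sl <- slope_profile(object)
  structure(list(fit = object, slopes = sl), class = "summary.segfit")
}

#' @export
print.summary.segfit <- function(x, ...) {
  print(x$fit)
  cat("Per-segment slopes:\n")
  print(x$slopes)
  cat("Coefficients:\n")
  print(round(x$fit$coefficients, 4))
  invisible(x)
}

#' Per-segment slopes of a segmented fit
#'
#' @param fit a [segfit()] object.
#' @return data.frame with segment bounds and slope (baseline slope plus
#'   accumulated slope changes).
#' @export
slope_profile <- function(fit) {
  b1 <- fit$coefficients[[fit$seg]]
  deltas <- fit$coefficients[paste0("delta", seq_len(fit$K))]
  slopes <- b1 + cumsum(c(0, deltas))
  data.frame(segment = seq_len(fit$K + 1L),
             from = c(fit$x_range[1], fit$psi),
             to = c(fit$psi, fit$x_range[2]),
             slope = unname(slopes))
}

#' @export
coef.segfit <- function(object, ...) object$coefficients

#' @export
fitted.segfit <- function(object, ...) object$fitted.values

#' @export
residuals.segfit <- function(object, ...) object$residuals

#' Predict from a segmented fit
#'
#' Piecewise-linear and continuous in the segmented covariate; additive
#' categorical offsets. Factor levels unseen at fit time (e.g. calendar
#' months or years absent from the training data) are resolved to the
#' reference level with a warning.
#'
#' @param object a [segfit()].
#' @param newdata data.frame with the segmented covariate and the fitted
#'   categorical covariates.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.segfit <- function(object, newdata, ...) {
  x <- newdata[[object$seg]]
  if (is.null(x)) stop_config("newdata lacks %s", object$seg)
  if (any(x < 0)) stop_config("negative %s in newdata", object$seg)
  cf <- object$coefficients
  pred <- rep(cf[["(Intercept)"]], length(x))
  unseen <- character(0)
  for (v in names(object$xlevels)) {
    lev <- object$xlevels[[v]]
    val <- as.character(newdata[[v]])
    if (is.null(newdata[[v]]))
      stop_config("newdata lacks covariate %s", v)
    bad <- !val %in% lev
    if (any(bad)) {
      unseen <- c(unseen, paste0(v, "=", unique(val[bad])))
      val[bad] <- lev[1L]  # reference level
    }
    nm <- paste0(v, val)
    off <- ifelse(val == lev[1L], 0, cf[nm])
    pred <- pred + off
  }
  if (length(unseen))
    warning("unseen levels resolved to reference: ",
            paste(unique(unseen), collapse = ", "), call. = FALSE)
  pred <- pred + cf[[object$seg]] * x
  for (k in seq_len(object$K))
    pred <- pred + cf[[paste0("delta", k)]] * pmax(x - object$psi[k], 0)
  unname(pred)
}

#' @export
simulate.segfit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  mu <- if (is.null(newdata)) object$fitted.values
        else predict(object, newdata)
  run <- function() mu + stats::rnorm(length(mu), 0, object$sigma)
  if (!is.null(seed)) with_seed(seed, replicate(nsim, run(), simplify = FALSE))
  else replicate(nsim, run(), simplify = FALSE)
}

#' @export
plot.segfit <- function(x, ..., n_grid = 200L) {
  mf <- x$model
  xs <- mf[[x$seg]]
  y <- stats::model.response(mf)
  graphics::plot(xs, y, pch = 16, cex = 0.4, col = "grey60",
                 xlab = x$seg, ylab = x$response,
                 main = sprintf("Segmented fit (K = %d)", x$K), ...)
  grid_x <- seq(x$x_range[1], x$x_range[2], length.out = n_grid)
  nd <- data.frame(grid_x)
  names(nd) <- x$seg
  for (v in names(x$xlevels)) nd[[v]] <- x$xlevels[[v]][1L]
  graphics::lines(grid_x, predict(x, nd), col = "firebrick", lwd = 2)
  graphics::abline(v = x$psi, lty = 2, col = "steelblue")
  invisible(x)
}

#' Stratified sample of slaughter records by animal class
#'
#' Draws exactly `per_class_n` records per animal class, without
#' replacement, reproducibly under a seed. The class sizes must allow it.
#'
#' @param records cleaned slaughter-record data.frame with `animal_class`.
#' @param per_class_n records per class.
#' @param seed integer seed.
#' @param class_col name of the class column.
#' @return data.frame with `per_class_n * nlevels` rows.
#' @export
stratified_sample <- function(records, per_class_n, seed = 1L,
                              class_col = "animal_class") {
  cls <- records[[class_col]]
  sizes <- table(cls)
  short <- names(sizes)[sizes < per_class_n]
  if (length(short))
    stop_config("insufficient records in class(es): %s",
                paste(short, collapse = ", "))
  with_seed(seed, {
    idx <- unlist(lapply(names(sizes), function(cl) {
      pool <- which(cls == cl)
      pool[sample.int(length(pool), per_class_n)]
    }), use.names = FALSE)
    out <- records[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Select the number of break-points by incremental R-squared
#'
#' Fits K = 1, 2, ..., `kmax` break-points and returns the smallest K
#' beyond which the R-squared improvement falls below
#' `delta_r2_threshold` (or `kmax` when every increment helps at least that
#' much). To keep R-squared non-decreasing in K, each K+1 candidate is also
#' started from the K-break solution augmented with the best additional
#' lattice break, and the better of the two runs is kept.
#'
#' @inheritParams segfit
#' @param kmax largest K considered (<= 3).
#' @param delta_r2_threshold minimum R-squared gain counted as a real
#'   improvement; gains below it are "minor".
#' @return the selected `segfit`, with all candidate fits in
#'   `$candidates` and the R-squared sequence in `$selection`.
#' @export
select_breakpoint_count <- function(formula, data, kmax = 3L,
                                    delta_r2_threshold = 0.01, seg = NULL,
                                    ...) {
  if (kmax > 3L) stop_config("kmax must be <= 3")
  fits <- list()
  for (K in seq_len(kmax)) {
    cand <- tryCatch(segfit(formula, data, K = K, seg = seg, ...),
                     error = function(e) {
                       warning(sprintf("K = %d fit failed: %s", K,
                                       conditionMessage(e)), call. = FALSE)
                       NULL
                     })
    prev <- if (K > 1L) fits[[as.character(K - 1L)]] else NULL
    if (!is.null(prev) &&
        (is.null(cand) || cand$r.squared < prev$r.squared)) {
      aug <- tryCatch(
        segfit(formula, data, K = K, seg = seg,
               init_psi = augment_psi(prev), ...),
        error = function(e) NULL)
      if (!is.null(aug) &&
          (is.null(cand) || aug$r.squared > cand$r.squared))
        cand <- aug
    }
    if (!is.null(cand)) fits[[as.character(K)]] <- cand
  }
  if (!length(fits)) stop_config("every candidate break-point count failed")
  ks <- as.integer(names(fits))
  r2 <- vapply(fits, function(f) f$r.squared, 0)
  sel <- ks[length(ks)]
  for (i in seq_along(ks)[-length(ks)]) {
    if (r2[i + 1L] - r2[i] < delta_r2_threshold) { sel <- ks[i]; break }
  }
  out <- fits[[as.character(sel)]]
  out$candidates <- fits
  out$selection <- data.frame(K = ks, r_squared = unname(r2))
  out
}

# best single additional break (RSS-profiled on a lattice) appended to an
# existing fit's break set, as a K+1 starting point
augment_psi <- function(fit) {
  mf <- fit$model
  y <- stats::model.response(mf)
  x <- mf[[fit$seg]]
  covs <- names(fit$xlevels)
  fcts <- lapply(covs, function(v) factor(mf[[v]], levels = fit$xlevels[[v]]))
  names(fcts) <- covs
  fcts <- fcts[vapply(fcts, function(f) nlevels(f) >= 2L, TRUE)]
  Z <- if (length(fcts))
    stats::model.matrix(~ ., data = as.data.frame(fcts))
  else matrix(1, nrow = length(y))
  lat <- seg_lattice(x, step = max(1, diff(range(x)) / 200), min_seg_obs = 5L)
  lat <- lat[!lat %in% fit$psi]
  rss <- vapply(lat, function(p) {
    psi <- sort(c(fit$psi, p))
    if (!seg_valid_psi(x, psi, 5L)) return(Inf)
    seg_rss(y, x, psi, Z)
  }, 0)
  sort(c(fit$psi, lat[which.min(rss)]))
}
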