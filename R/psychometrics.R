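# 2IFC response aggregation and cumulative-normal psychometric fitting.

#' Aggregate 2IFC trials into per-disparity response proportions
#'
#' Pools trials over blocks and over leftward/rightward translation
#' directions, and counts "stereo deeper" responses per
#' (condition, stimulus, disparity level) cell. Each psychometric function
#' is identified by `condition_id` together with the nominal
#' `dtheta_deg_s`/`dalpha_deg_s` stimulus values (several stimuli share a
#' motion/pursuit ratio, so the rates themselves are the key).
#'
#' @param trials A data.frame of trial records (the dialect written by
#'   [write_trials()]), or a `session_dataset` from [read_trials()].
#'   Required columns: `condition_id`, `f_cm`, `dtheta_deg_s`,
#'   `dalpha_deg_s`, `disparity_arcmin`, `response_stereo_deeper`.
#' @param by_observer If TRUE, keep observers separate (adds an
#'   `observer_id` column to the keys).
#' @return A data.frame of class `"response_table"` with one row per cell:
#'   keys, `n_trials`, `n_deeper`, `proportion`.
#' @export
aggregate_trials <- function(trials, by_observer = FALSE) {
  if (inherits(trials, "session_dataset")) trials <- trials$trials
  stopifnot(is.data.frame(trials))
  req <- c("condition_id", "f_cm", "dtheta_deg_s", "dalpha_deg_s",
           "disparity_arcmin", "response_stereo_deeper")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop("trials are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("no trials to aggregate", call. = FALSE)
  f_per_cond <- tapply(trials$f_cm, trials$condition_id,
                       function(x) length(unique(x)))
  if (any(f_per_cond > 1L)) {
    stop("condition(s) with mixed viewing distances: ",
         paste(names(f_per_cond)[f_per_cond > 1L], collapse = ", "),
         call. = FALSE)
  }
  keys <- c(if (by_observer) "observer_id", "condition_id", "f_cm",
            "dtheta_deg_s", "dalpha_deg_s", "disparity_arcmin")
  if (by_observer && !"observer_id" %in% names(trials)) {
    stop("trials are missing columns: observer_id", call. = FALSE)
  }
  kdf <- trials[keys]
  key <- do.call(paste, c(kdf, sep = "\r"))
  first <- !duplicated(key)
  out <- kdf[first, , drop = FALSE]
  resp <- as.logical(trials$response_stereo_deeper)
  if (any(is.na(resp))) {
    stop("response_stereo_deeper contains values not coercible to logical",
         call. = FALSE)
  }
  n <- tapply(resp, key, length)
  k <- tapply(resp, key, sum)
  ukey <- key[first]
  out$n_trials <- as.integer(n[ukey])
  out$n_deeper <- as.integer(k[ukey])
  out$proportion <- out$n_deeper / out$n_trials
  ord <- order(out$condition_id,
               if (by_observer) out$observer_id else out$condition_id,
               out$dalpha_deg_s, out$dtheta_deg_s, out$disparity_arcmin,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

#' Fit a cumulative-normal psychometric function
#'
#' Least-squares fit of \eqn{\Phi((\delta - PSE)/\sigma)} to response
#' proportions over disparity levels. The PSE is the 50% point of the
#' fitted function (the disparity judged perceptually equal to the
#' comparison stimulus); `sigma` is the spread, interpretable as a
#' discrimination threshold in disparity units.
#'
#' The default criterion is unweighted nonlinear least squares on the
#' proportions. `method = "probit"` instead fits a binomial GLM with a
#' probit link to the raw counts (requires `n_trials`) and converts the
#' linear coefficients to (PSE, sigma); it is a robustness option, not the
#' default estimator.
#'
#' Data that never cross 0.5, or that are flat, cannot anchor a PSE within
#' the tested range: the fit is returned with `converged = FALSE` and/or
#' `extrapolated = TRUE`.
#'
#' @param disparity Numeric vector of disparity levels (arcmin), or a
#'   `response_table` holding a single psychometric function (columns
#'   `disparity_arcmin`, `proportion`, `n_trials`).
#' @param proportion Proportion of "deeper" responses at each level.
#' @param n_trials Optional trial counts per level (needed for probit).
#' @param method `"ls"` (default) or `"probit"`.
#' @return An object of class `"psychometric_fit"`: `pse`, `sigma` (both
#'   arcmin), `n_levels`, `converged`, `extrapolated`, `residual_sse`,
#'   `method`.
#' @examples
#' p <- pnorm((1:9 - 5.8) / 1.08)
#' fit_cumulative_normal(1:9, p)
#' @export
fit_cumulative_normal <- function(disparity, proportion = NULL,
                                  n_trials = NULL,
                                  method = c("ls", "probit")) {
  method <- match.arg(method)
  if (is.data.frame(disparity)) {
    tab <- disparity
    disparity <- tab$disparity_arcmin
    proportion <- tab$proportion
    if (is.null(n_trials)) n_trials <- tab$n_trials
  }
  stopifnot(is.numeric(disparity), is.numeric(proportion),
            length(disparity) == length(proportion))
  ok <- is.finite(disparity) & is.finite(proportion)
  x <- disparity[ok]
  p <- proportion[ok]
  n <- if (!is.null(n_trials)) n_trials[ok]
  if (length(x) < 3L) {
    stop("need at least 3 disparity levels to fit a psychometric function",
         call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("proportions must be in [0, 1]", call. = FALSE)
  o <- order(x)
  x <- x[o]
  p <- p[o]
  if (!is.null(n)) n <- n[o]

  res <- list(pse = NA_real_, sigma = NA_real_, n_levels = length(x),
              converged = FALSE, extrapolated = TRUE,
              residual_sse = NA_real_, method = method,
              disparity = x, proportion = p)
  class(res) <- "psychometric_fit"

  if (diff(range(p)) < sqrt(.Machine$double.eps)) {
    return(res)  # flat data: no information about the PSE
  }
  crosses <- min(p) <= 0.5 && max(p) >= 0.5

  if (method == "probit") {
    if (is.null(n)) {
      stop("method = \"probit\" needs per-level trial counts 'n_trials'",
           call. = FALSE)
    }
    k <- round(p * n)
    gfit <- suppressWarnings(
      stats::glm(cbind(k, n - k) ~ x, family = stats::binomial("probit")))
    b <- stats::coef(gfit)
    if (!all(is.finite(b)) || b[2] <= 0) return(res)
    res$pse <- unname(-b[1] / b[2])
    res$sigma <- unname(1 / b[2])
    res$residual_sse <- sum((p - stats::pnorm((x - res$pse) / res$sigma))^2)
    res$converged <- gfit$converged && crosses
    res$extrapolated <- !crosses || res$pse < min(x) || res$pse > max(x)
    return(res)
  }

  # initial values: interpolate the first 0.5 crossing, quartile spread
  mu0 <- {
    above <- which(p >= 0.5)
    below <- which(p < 0.5)
    if (length(above) && length(below) && min(above) > 1L &&
        p[min(above)] > p[min(above) - 1L]) {
      j <- min(above)
      x[j - 1L] + (0.5 - p[j - 1L]) / (p[j] - p[j - 1L]) * (x[j] - x[j - 1L])
    } else if (length(above)) {
      x[min(above)]
    } else {
      mean(range(x))
    }
  }
  s0 <- diff(range(x)) / 4
  obj <- function(par) {
    mu <- par[1]
    s <- exp(par[2])
    sum((p - stats::pnorm((x - mu) / s))^2)
  }
  opt <- stats::optim(c(mu0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt2 <- tryCatch(
    stats::optim(opt$par, obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500)),
    error = function(e) opt)
  if (opt2$value <= opt$value) opt <- opt2

  res$pse <- opt$par[1]
  res$sigma <- exp(opt$par[2])
  res$residual_sse <- opt$value
  res$converged <- crosses && is.finite(opt$value)
  res$extrapolated <- !crosses || res$pse < min(x) || res$pse > max(x)
  res
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Cumulative-normal psychometric fit (", x$method, ")\n", sep = "")
  cat(sprintf("  PSE = %.4g arcmin, sigma = %.4g arcmin over %d levels\n",
              x$pse, x$sigma, x$n_levels))
  cat(sprintf("  converged: %s%s, residual SSE = %.3g\n",
              x$converged,
              if (isTRUE(x$extrapolated)) " (PSE extrapolated)" else "",
              x$residual_sse))
  invisible(x)
}

#' Perceived depth implied by a psychometric PSE
#'
#' Converts the PSE of a depth-matching psychometric function to the
#' perceived depth of the matched stimulus via the distance-square law:
#' the motion-parallax stimulus is perceived as deep as the disparity
#' stimulus at the PSE, so `d_mp = f^2 * pse / i`.
#'
#' @param fit A converged [fit_cumulative_normal()] result.
#' @param f Viewing distance of the disparity comparison stimulus, cm.
#' @param i Inter-ocular distance, cm.
#' @return Perceived depth `d_mp`, cm.
#' @export
pse_to_depth <- function(fit, f, i = 6.5) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$converged)) {
    stop("psychometric fit did not converge; no depth estimate", call. = FALSE)
  }
  disparity_to_depth(fit$pse, f = f, i = i)
}

#' Depth discrimination threshold implied by a psychometric spread
#'
#' Applies the distance-square law to the fitted `sigma`, giving the
#' disparity spread of the psychometric function as a depth increment in
#' cm.
#'
#' @inheritParams pse_to_depth
#' @return Depth threshold, cm.
#' @export
sigma_to_depth_threshold <- function(fit, f, i = 6.5) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$converged)) {
    stop("psychometric fit did not converge; no threshold estimate",
         call. = FALSE)
  }
  disparity_to_depth(fit$sigma, f = f, i = i)
}

#' Fit psychometric functions for every stimulus in a session
#'
#' Convenience wrapper: aggregates trials ([aggregate_trials()]) and fits
#' one cumulative normal per (condition, stimulus) cell, optionally per
#' observer. Rows of the result carry the stimulus keys plus the fitted
#' PSE/sigma and convergence flags; converged fits also get the implied
#' perceived depth `d_mp` (cm) via [pse_to_depth()].
#'
#' @param trials Trial records (see [aggregate_trials()]).
#' @param by_observer Fit per observer (TRUE) or on pooled proportions.
#' @param i Inter-ocular distance, cm, for the depth conversion.
#' @param method Passed to [fit_cumulative_normal()].
#' @return A data.frame with one row per psychometric function.
#' @export
fit_session <- function(trials, by_observer = FALSE, i = 6.5,
                        method = c("ls", "probit")) {
  method <- match.arg(method)
  tab <- aggregate_trials(trials, by_observer = by_observer)
  keys <- c(if (by_observer) "observer_id", "condition_id", "f_cm",
            "dtheta_deg_s", "dalpha_deg_s")
  kdf <- tab[keys]
  # NA-safe composite key (control trials have NA rates)
  key <- do.call(paste, c(kdf, sep = "\r"))
  pieces <- split(seq_len(nrow(tab)), key)
  rows <- lapply(pieces, function(idx) {
    sub <- tab[idx, , drop = FALSE]
    fit <- fit_cumulative_normal(sub$disparity_arcmin, sub$proportion,
                                 n_trials = sub$n_trials, method = method)
    out <- sub[1L, keys, drop = FALSE]
    out$n_levels <- fit$n_levels
    out$n_trials <- sum(sub$n_trials)
    out$pse <- fit$pse
    out$sigma <- fit$sigma
    out$converged <- fit$converged
    out$extrapolated <- fit$extrapolated
    out$d_mp <- if (isTRUE(fit$converged)) {
      pse_to_depth(fit, f = out$f_cm, i = i)
    } else {
      NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  ord <- order(res$condition_id,
               if (by_observer) res$observer_id else res$condition_id,
               res$dalpha_deg_s, res$dtheta_deg_s, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
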