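# Log-space least-squares plane fit recovering the power-law transducer
# parameters of the empirical motion/pursuit ratio.

.match_cols <- function(matches) {
  th <- if ("dtheta_deg_s" %in% names(matches)) matches$dtheta_deg_s else matches$dtheta
  al <- if ("dalpha_deg_s" %in% names(matches)) matches$dalpha_deg_s else matches$dalpha
  f <- if ("f_cm" %in% names(matches)) matches$f_cm else matches$f
  if (is.null(th) || is.null(al) || is.null(f) || is.null(matches$d_mp)) {
    stop("matches need columns d_mp, dtheta(_deg_s), dalpha(_deg_s), f(_cm)",
         call. = FALSE)
  }
  data.frame(d_mp = matches$d_mp, dtheta = th, dalpha = al, f = f)
}

#' Fit the empirical motion/pursuit ratio in log space
#'
#' Unweighted ordinary least squares of `ln(d_mp / f)` on
#' `[1, ln(dtheta), ln(dalpha)]` (natural logs throughout). On the
#' power-law model `d_mp = k f dtheta^r / dalpha^e` this plane is exact,
#' and the coefficients export to a [transducer_model()] as
#' `r = coef(ln dtheta)`, `e = -coef(ln dalpha)`, `k = exp(intercept)`.
#'
#' Points with non-positive or non-finite `d_mp` cannot enter the log fit;
#' they are dropped with a warning and counted in `n_excluded`.
#'
#' @param matches A data.frame of depth matches: columns `d_mp` (cm, > 0),
#'   `dtheta`/`dtheta_deg_s`, `dalpha`/`dalpha_deg_s` (deg/s), `f`/`f_cm`
#'   (cm). Needs at least 4 points spanning at least 2 distinct `dtheta`
#'   and 2 distinct `dalpha` values, and a full-rank log design.
#' @param weights Optional per-point weights (e.g. inverse squared SEs);
#'   the default NULL is the plain unweighted fit.
#' @param angle_unit Unit tag recorded on the exported model.
#' @return An object of class `"plane_fit"`: `intercept`,
#'   `coef_log_dtheta`, `coef_log_dalpha`, `r_squared`, `residuals`,
#'   `fitted`, `n_points`, `n_excluded`, and `model`, the exported
#'   [transducer_model()].
#' @examples
#' g <- expand.grid(dtheta = c(0.2, 0.5, 1.2), dalpha = c(1.1, 4.95, 11.57))
#' g$f <- 36
#' g$d_mp <- empirical_depth(g)
#' fit_empirical_mpr(g)
#' @export
fit_empirical_mpr <- function(matches, weights = NULL, angle_unit = "degree") {
  m <- .match_cols(matches)
  keep <- is.finite(m$d_mp) & m$d_mp > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    warning(sprintf("excluded %d point(s) with non-positive d_mp from log fit",
                    n_excluded), call. = FALSE)
    m <- m[keep, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (nrow(m) < 4L) {
    stop("need at least 4 usable depth matches", call. = FALSE)
  }
  if (length(unique(m$dtheta)) < 2L || length(unique(m$dalpha)) < 2L) {
    stop("need at least 2 distinct dtheta and 2 distinct dalpha values",
         call. = FALSE)
  }
  .check_pos(m$dtheta, "dtheta")
  .check_pos(m$dalpha, "dalpha")
  .check_pos(m$f, "f")
  df <- data.frame(y = log(m$d_mp / m$f),
                   lth = log(m$dtheta), lal = log(m$dalpha))
  X <- cbind(1, df$lth, df$lal)
  if (qr(X)$rank < 3L) {
    stop("rank-deficient log design: ln(dtheta) and ln(dalpha) are collinear",
         call. = FALSE)
  }
  fit <- if (is.null(weights)) {
    stats::lm(y ~ lth + lal, data = df)
  } else {
    stats::lm(y ~ lth + lal, data = df, weights = weights)
  }
  b <- stats::coef(fit)
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  sse <- sum(w * stats::residuals(fit)^2)
  sst <- sum(w * (df$y - stats::weighted.mean(df$y, w))^2)
  out <- list(
    intercept = unname(b[1]),
    coef_log_dtheta = unname(b[2]),
    coef_log_dalpha = unname(b[3]),
    r_squared = 1 - sse / sst,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    n_points = nrow(m),
    n_excluded = n_excluded,
    weighted = !is.null(weights),
    model = transducer_model(r = unname(b[2]), e = -unname(b[3]),
                             k = exp(unname(b[1])), angle_unit = angle_unit))
  class(out) <- "plane_fit"
  out
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("Log-space plane fit of the empirical motion/pursuit ratio\n")
  cat(sprintf("  ln(d/f) = %.4g + %.4g ln(dtheta) %+.4g ln(dalpha)   (natural logs)\n",
              x$intercept, x$coef_log_dtheta, x$coef_log_dalpha))
  cat(sprintf("  r^2 = %.4g on %d points (%d excluded)%s\n",
              x$r_squared, x$n_points, x$n_excluded,
              if (isTRUE(x$weighted)) ", weighted" else ""))
  cat(sprintf("  exported model: r = %.4g, e = %.4g, k = %.4g (%s-based)\n",
              x$model$r, x$model$e, x$model$k, x$model$angle_unit))
  invisible(x)
}

#' Refit after correcting for a hypothesised stereo depth distortion
#'
#' Multiplies every depth match by [johnston_ratio()] at its viewing
#' distance -- undoing a hypothetical linear failure of stereo depth
#' constancy in the comparison stimuli -- and refits the log-space plane.
#' A distance-independent scaling (`b = 0`) only shifts the intercept
#' (rescales `k`); a distance-dependent scaling also moves the exponents.
#'
#' @inheritParams fit_empirical_mpr
#' @param js A [johnston_scaling()].
#' @return A `"plane_fit"` (with `adjusted = TRUE`) whose `model` is the
#'   adjusted transducer model.
#' @export
johnston_adjust_and_refit <- function(matches, js = johnston_scaling(),
                                      weights = NULL, angle_unit = "degree") {
  m <- .match_cols(matches)
  scale <- johnston_ratio(m$f, js)
  m$d_mp <- m$d_mp * scale
  out <- fit_empirical_mpr(m, weights = weights, angle_unit = angle_unit)
  out$adjusted <- TRUE
  out$scaling <- js
  out
}

#' Tabulate empirical vs geometric depth predictions over a grid
#'
#' Evaluates the transducer model and the first-order geometric prediction
#' ([approx_depth()]) on a stimulus grid, together with their ratio, the
#' foreshortening factor (fraction of geometric depth actually perceived).
#'
#' @param model A [transducer_model()].
#' @param grid A data.frame with columns `dtheta`/`dtheta_deg_s`,
#'   `dalpha`/`dalpha_deg_s`, `f`/`f_cm` (positive rates, ratios < 1).
#' @return The grid with added columns `d_empirical`, `d_geometric` (cm)
#'   and `foreshortening` (= empirical / geometric).
#' @export
predict_depth_surface <- function(model = transducer_model(), grid) {
  stopifnot(inherits(model, "transducer_model"), is.data.frame(grid))
  out <- grid
  out$d_empirical <- empirical_depth(grid, model = model)
  out$d_geometric <- approx_depth(grid)
  out$foreshortening <- out$d_empirical / out$d_geometric
  out
}
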