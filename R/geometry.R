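# Closed-form depth laws and unit conversions.
#
# Unit conventions used throughout the package:
#   viewing distance f ......... cm
#   dtheta, dalpha ............. deg/s (unless a transducer model says radian)
#   binocular disparity delta .. arcmin
#   depth ...................... cm

ARCMIN_PER_RAD <- 60 * 180 / pi
DEG_PER_RAD <- 180 / pi

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and >= 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Motion-parallax stimulus condition
#'
#' Bundles the physical parameters of one motion-parallax stimulus: the
#' viewing distance `f` (cm), the peak retinal image speed `dtheta` (deg/s)
#' of the non-fixated surface, the compensatory eye-rotation (pursuit) speed
#' `dalpha` (deg/s), whether the observer's head is stationary or
#' translating, and the direction of stimulus/head translation.
#'
#' The motion/pursuit ratio `dtheta/dalpha` must lie in `[0, 1)`; ratios at
#' or above 1 have no depth interpretation under the motion/pursuit law.
#'
#' @param f Viewing distance, cm (> 0).
#' @param dtheta Peak retinal image speed, deg/s (>= 0).
#' @param dalpha Pursuit speed, deg/s (> 0).
#' @param head_state `"stationary"` or `"translating"`.
#' @param direction `"left"` or `"right"`.
#' @return An object of class `"stimulus_condition"`.
#' @examples
#' stimulus_condition(f = 36, dtheta = 1.2375, dalpha = 4.95)
#' @export
stimulus_condition <- function(f, dtheta, dalpha,
                               head_state = c("stationary", "translating"),
                               direction = c("left", "right")) {
  head_state <- match.arg(head_state)
  direction <- match.arg(direction)
  .check_pos(f, "f")
  .check_pos(dalpha, "dalpha")
  .check_nonneg(dtheta, "dtheta")
  if (any(dtheta / dalpha >= 1)) {
    stop("motion/pursuit ratio dtheta/dalpha must be < 1", call. = FALSE)
  }
  structure(
    list(f = f, dtheta = dtheta, dalpha = dalpha,
         head_state = head_state, direction = direction),
    class = "stimulus_condition"
  )
}

#' @export
print.stimulus_condition <- function(x, ...) {
  cat(sprintf(
    "Motion-parallax stimulus: f = %g cm, dtheta = %g deg/s, dalpha = %g deg/s\n",
    x$f, x$dtheta, x$dalpha))
  cat(sprintf("  M/PR = %.4g, head %s, %sward translation\n",
              x$dtheta / x$dalpha, x$head_state, x$direction))
  invisible(x)
}

#' Binocular disparity stimulus
#'
#' @param delta Peak binocular disparity, arcmin (>= 0).
#' @param f Viewing distance, cm (> 0).
#' @param i Inter-ocular distance, cm (> 0). Defaults to the standard adult
#'   6.5 cm.
#' @return An object of class `"disparity_stimulus"`.
#' @export
disparity_stimulus <- function(delta, f, i = 6.5) {
  .check_nonneg(delta, "delta")
  .check_pos(f, "f")
  .check_pos(i, "i")
  structure(list(delta = delta, f = f, i = i), class = "disparity_stimulus")
}

#' Power-law transducer model (empirical motion/pursuit ratio)
#'
#' Parameters of the empirical motion/pursuit ratio
#' \deqn{d_{mp} = k \, f \, d\theta^{r} / d\alpha^{e},}
#' where `r` is the retinal-motion exponent, `e` the pursuit exponent and
#' `k` a unit-dependent scaling constant. The exponents are dimensionless
#' and independent of the angular unit; `k` is tied to the unit in which the
#' rates are expressed, so the unit is carried with the model. Defaults are
#' the values estimated from the head-stationary depth-matching data
#' (r = 0.416, e = 0.192, k = 0.0313 with rates in deg/s).
#'
#' @param r Retinal-motion exponent.
#' @param e Pursuit exponent.
#' @param k Scaling constant (> 0).
#' @param angle_unit Unit of the rates `k` was estimated with.
#' @return An object of class `"transducer_model"`.
#' @seealso [empirical_depth()], [rescale_model()], [fit_empirical_mpr()]
#' @examples
#' transducer_model()                       # head-stationary estimates
#' transducer_model(0.428, 0.148, 0.0444)   # stereo-distortion adjusted
#' @export
transducer_model <- function(r = 0.416, e = 0.192, k = 0.0313,
                             angle_unit = "degree") {
  if (!is.numeric(r) || !is.finite(r) || !is.numeric(e) || !is.finite(e)) {
    stop("exponents 'r' and 'e' must be finite", call. = FALSE)
  }
  .check_pos(k, "k")
  stopifnot(is.character(angle_unit), length(angle_unit) == 1L)
  structure(list(r = r, e = e, k = k, angle_unit = angle_unit),
            class = "transducer_model")
}

#' @export
print.transducer_model <- function(x, ...) {
  cat("Empirical motion/pursuit transducer model\n")
  cat(sprintf("  d_mp = k * f * dtheta^r / dalpha^e\n"))
  cat(sprintf("  r = %.4g (retinal motion), e = %.4g (pursuit), k = %.4g\n",
              x$r, x$e, x$k))
  cat(sprintf("  rates in %s/s; k is %s-based\n", x$angle_unit, x$angle_unit))
  invisible(x)
}

#' Linear stereo depth-constancy scaling
#'
#' Perceived/veridical stereo depth ratio as a linear function of viewing
#' distance, `a - b * f`. The defaults (a = 2.015, b = 0.011 per cm) are a
#' least-squares extrapolation of classic stereo depth-constancy failure
#' data to near viewing distances; they are used as a hypothetical
#' worst-case distortion of the binocular comparison stimulus.
#'
#' @param a Intercept (dimensionless).
#' @param b Slope, 1/cm.
#' @return An object of class `"johnston_scaling"`.
#' @seealso [johnston_ratio()], [johnston_adjust_and_refit()]
#' @export
johnston_scaling <- function(a = 2.015, b = 0.011) {
  stopifnot(is.numeric(a), is.finite(a), is.numeric(b), is.finite(b))
  structure(list(a = a, b = b), class = "johnston_scaling")
}

#' @export
print.johnston_scaling <- function(x, ...) {
  cat(sprintf("Stereo depth scaling: d(perceived)/d(veridical) = %g - %g * f\n",
              x$a, x$b))
  invisible(x)
}

# Resolve (dtheta, dalpha, f) from either a stimulus_condition / data.frame
# or bare numeric arguments.
.resolve_cond <- function(cond, dtheta, dalpha, f) {
  if (!is.null(cond)) {
    if (inherits(cond, "stimulus_condition")) {
      return(list(dtheta = cond$dtheta, dalpha = cond$dalpha, f = cond$f))
    }
    if (is.data.frame(cond)) {
      th <- if ("dtheta_deg_s" %in% names(cond)) cond$dtheta_deg_s else cond$dtheta
      al <- if ("dalpha_deg_s" %in% names(cond)) cond$dalpha_deg_s else cond$dalpha
      fv <- if ("f_cm" %in% names(cond)) cond$f_cm else cond$f
      if (is.null(th) || is.null(al) || is.null(fv)) {
        stop("data.frame condition needs dtheta, dalpha and f columns",
             call. = FALSE)
      }
      return(list(dtheta = th, dalpha = al, f = fv))
    }
    stop("'cond' must be a stimulus_condition or a data.frame", call. = FALSE)
  }
  list(dtheta = dtheta, dalpha = dalpha, f = f)
}

#' Exact relative depth from the motion/pursuit law
#'
#' The exact geometric relation between the retinal image speed of a
#' non-fixated point, the pursuit speed maintaining fixation, and relative
#' depth:
#' \deqn{d/f = \frac{d\theta}{d\alpha}\,\frac{1}{1 - d\theta/d\alpha}.}
#' The result is dimensionless relative depth `d/f`; multiply by the viewing
#' distance to obtain depth in cm. Defined only for motion/pursuit ratios
#' below 1.
#'
#' @param dtheta Retinal image speed (same angular unit as `dalpha`, per
#'   unit time; the ratio is what matters).
#' @param dalpha Pursuit speed (> 0).
#' @return Relative depth `d/f`, dimensionless. Vectorised.
#' @examples
#' exact_relative_depth(0.25, 1)       # 1/3
#' exact_relative_depth(0.25, 1) * 36  # 12 cm at f = 36 cm
#' @export
exact_relative_depth <- function(dtheta, dalpha) {
  .check_pos(dalpha, "dalpha")
  .check_nonneg(dtheta, "dtheta")
  ratio <- dtheta / dalpha
  if (any(ratio >= 1)) {
    stop("motion/pursuit ratio >= 1: depth is geometrically undefined",
         call. = FALSE)
  }
  ratio / (1 - ratio)
}

#' Approximate (first-order) motion-parallax depth
#'
#' The motion/pursuit ratio approximation `d = (dtheta/dalpha) * f`, the
#' first-order version of [exact_relative_depth()]. For the small ratios
#' used in depth-matching experiments (<= 0.25) the two agree closely; this
#' approximation is the conventional "geometric prediction" against which
#' perceived depth is compared.
#'
#' @param cond Optional [stimulus_condition()] or data.frame with columns
#'   `dtheta`/`dtheta_deg_s`, `dalpha`/`dalpha_deg_s`, `f`/`f_cm`.
#' @param dtheta,dalpha,f Used when `cond` is NULL.
#' @return Depth in cm.
#' @examples
#' approx_depth(dtheta = 0.25, dalpha = 1, f = 36)  # 9 cm
#' @export
approx_depth <- function(cond = NULL, dtheta = NULL, dalpha = NULL, f = NULL) {
  a <- .resolve_cond(cond, dtheta, dalpha, f)
  .check_pos(a$dalpha, "dalpha")
  .check_pos(a$f, "f")
  .check_nonneg(a$dtheta, "dtheta")
  ratio <- a$dtheta / a$dalpha
  if (any(ratio >= 1)) {
    stop("motion/pursuit ratio >= 1: depth is geometrically undefined",
         call. = FALSE)
  }
  ratio * a$f
}

#' Depth from binocular disparity (distance-square law)
#'
#' Converts peak binocular disparity to depth with the small-angle
#' distance-square law `d = f^2 * delta / i`, with `delta` supplied in
#' arcmin and converted to radians internally.
#'
#' @param delta Peak disparity, arcmin (>= 0), or a [disparity_stimulus()]
#'   (in which case `f` and `i` are taken from it).
#' @param f Viewing distance, cm.
#' @param i Inter-ocular distance, cm.
#' @return Depth, cm. Vectorised over `delta`.
#' @examples
#' disparity_to_depth(23.3, f = 36)  # 1.351 cm
#' disparity_to_depth(4.66, f = 72)  # 1.081 cm
#' @export
disparity_to_depth <- function(delta, f = NULL, i = 6.5) {
  if (inherits(delta, "disparity_stimulus")) {
    f <- delta$f
    i <- delta$i
    delta <- delta$delta
  }
  .check_nonneg(delta, "delta")
  .check_pos(f, "f")
  .check_pos(i, "i")
  f^2 * (delta / ARCMIN_PER_RAD) / i
}

#' Disparity equivalent to a given depth
#'
#' Inverse of [disparity_to_depth()]: `delta = d * i / f^2`, returned in
#' arcmin.
#'
#' @param depth Depth, cm (>= 0).
#' @param f Viewing distance, cm.
#' @param i Inter-ocular distance, cm.
#' @return Disparity, arcmin.
#' @export
depth_to_disparity <- function(depth, f, i = 6.5) {
  .check_nonneg(depth, "depth")
  .check_pos(f, "f")
  .check_pos(i, "i")
  depth * i / f^2 * ARCMIN_PER_RAD
}

#' Perceived depth under the empirical motion/pursuit ratio
#'
#' Evaluates the power-law transducer model
#' `d_mp = k * f * dtheta^r / dalpha^e`. The rates must be expressed in the
#' model's `angle_unit` (deg/s for the default model).
#'
#' @param cond Optional [stimulus_condition()] or data.frame (see
#'   [approx_depth()]). A [transducer_model()] passed here is understood as
#'   `model` for convenience.
#' @param model A [transducer_model()].
#' @param dtheta,dalpha,f Used when `cond` is NULL; both rates must be > 0.
#' @return Perceived depth `d_mp`, cm.
#' @examples
#' empirical_depth(dtheta = 1, dalpha = 1, f = 36)  # k * f = 1.1268 cm
#' empirical_depth(transducer_model(), dtheta = 0.5, dalpha = 4.95, f = 36)
#' @export
empirical_depth <- function(cond = NULL, model = transducer_model(),
                            dtheta = NULL, dalpha = NULL, f = NULL) {
  if (inherits(cond, "transducer_model")) {
    model <- cond
    cond <- NULL
  }
  stopifnot(inherits(model, "transducer_model"))
  a <- .resolve_cond(cond, dtheta, dalpha, f)
  .check_pos(a$dtheta, "dtheta")
  .check_pos(a$dalpha, "dalpha")
  .check_pos(a$f, "f")
  model$k * a$f * a$dtheta^model$r / a$dalpha^model$e
}

#' Rescale a transducer model to a different angular unit
#'
#' Changing the unit of the rates by a factor `c` (for example
#' `c = pi/180` for deg/s to rad/s) leaves the exponents untouched and
#' rescales the constant as `k' = k / c^(r - e)`, so that
#' [empirical_depth()] is invariant when the rates are converted
#' consistently.
#'
#' @param model A [transducer_model()].
#' @param c Multiplicative unit-conversion factor applied to the rates
#'   (> 0).
#' @param angle_unit Optional unit label for the result; guessed for the
#'   degree/radian conversions.
#' @return A rescaled [transducer_model()].
#' @examples
#' rescale_model(transducer_model(), pi / 180)  # k ~ 0.0775, radian-based
#' @export
rescale_model <- function(model, c, angle_unit = NULL) {
  stopifnot(inherits(model, "transducer_model"))
  .check_pos(c, "c")
  stopifnot(length(c) == 1L)
  if (is.null(angle_unit)) {
    angle_unit <-
      if (isTRUE(all.equal(c, pi / 180)) && model$angle_unit == "degree") {
        "radian"
      } else if (isTRUE(all.equal(c, 180 / pi)) && model$angle_unit == "radian") {
        "degree"
      } else if (isTRUE(all.equal(c, 1))) {
        model$angle_unit
      } else {
        sprintf("%s*%g", model$angle_unit, c)
      }
  }
  transducer_model(r = model$r, e = model$e,
                   k = model$k / c^(model$r - model$e),
                   angle_unit = angle_unit)
}

#' Perceived/veridical stereo depth ratio at a viewing distance
#'
#' Evaluates the linear depth-constancy scaling `a - b * f` of a
#' [johnston_scaling()] object. Values are only meaningful within the
#' calibrated range of distances; the caller interprets ratios <= 0.
#'
#' @param f Viewing distance, cm (> 0). Vectorised.
#' @param js A [johnston_scaling()].
#' @return Dimensionless ratio of perceived to veridical depth.
#' @examples
#' johnston_ratio(36)  # 1.619
#' johnston_ratio(72)  # 1.223
#' @export
johnston_ratio <- function(f, js = johnston_scaling()) {
  stopifnot(inherits(js, "johnston_scaling"))
  .check_pos(f, "f")
  js$a - js$b * f
}

#' Eye-rotation rate compensating a lateral head translation
#'
#' Small-angle conversion of a lateral head (or stimulus) translation speed
#' into the compensatory eye-rotation rate needed to maintain fixation at
#' distance `f`: `dalpha = (v / f) * 180 / pi` deg/s.
#'
#' @param v Translation speed, cm/s (>= 0).
#' @param f Viewing distance, cm (> 0).
#' @return Eye-rotation rate, deg/s.
#' @examples
#' head_speed_to_pursuit_rate(11.0, 36)  # 17.5 deg/s
#' @export
head_speed_to_pursuit_rate <- function(v, f) {
  .check_nonneg(v, "v")
  .check_pos(f, "f")
  (v / f) * DEG_PER_RAD
}

#' Visual angle subtended by screen pixels
#'
#' Small-angle conversion of a pixel count into arcmin given the monitor
#' pixel pitch and viewing distance.
#'
#' @param n_pixels Number of pixels (>= 0).
#' @param pitch Pixel pitch, mm/pixel (> 0). Default 0.244 mm.
#' @param f Viewing distance, cm (> 0).
#' @return Visual angle, arcmin.
#' @examples
#' pixel_to_angle(1, f = 36)  # 2.33 arcmin
#' @export
pixel_to_angle <- function(n_pixels, pitch = 0.244, f = NULL) {
  .check_nonneg(n_pixels, "n_pixels")
  .check_pos(pitch, "pitch")
  .check_pos(f, "f")
  (n_pixels * pitch / 10 / f) * ARCMIN_PER_RAD
}

#' Pursuit share of a compensatory eye movement
#'
#' Percentage of the total compensatory eye-movement speed accounted for by
#' a pursuit-equivalent speed, `100 * pursuit_equiv / total`.
#'
#' @param pursuit_equiv Pursuit-equivalent speed, deg/s.
#' @param total Total compensatory eye speed, deg/s (> 0).
#' @return Percentage.
#' @examples
#' pursuit_fraction(6.6, 17.5)  # ~38 %
#' @export
pursuit_fraction <- function(pursuit_equiv, total) {
  .check_pos(total, "total")
  .check_nonneg(pursuit_equiv, "pursuit_equiv")
  100 * pursuit_equiv / total
}
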