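# Session I/O, outlier exclusion and the end-to-end
# simulate -> fit -> report pipeline.

TRIAL_COLUMNS <- c("observer_id", "condition_id", "f_cm", "dtheta_deg_s",
                   "dalpha_deg_s", "head_state", "direction",
                   "head_speed_cm_s", "disparity_pixels", "disparity_arcmin",
                   "response_stereo_deeper", "block")

#' Write a trial table to CSV
#'
#' Writes trials in the package's CSV dialect: optional `# key: value`
#' provenance comment lines (seed, configuration stamps), a header row, and
#' one row per trial. Numeric fields are written with 17 significant
#' digits so that [read_trials()] round-trips them bit-exactly.
#'
#' @param trials Trial data.frame (columns of `TRIAL_COLUMNS`) or a
#'   `session_dataset`.
#' @param path Output file path.
#' @param provenance Named list written as header comments (a
#'   `session_dataset`'s own provenance is used when `provenance` is
#'   empty).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, provenance = list()) {
  if (inherits(trials, "session_dataset")) {
    if (!length(provenance)) provenance <- trials$provenance
    trials <- trials$trials
  }
  stopifnot(is.data.frame(trials))
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss)) {
    stop("trials are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- trials[TRIAL_COLUMNS]
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "NA",
                         format(df[[nm]], digits = 17, trim = TRUE,
                                scientific = FALSE))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, function(v) paste(format(v), collapse = " "),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads the dialect written by [write_trials()], parses `# key: value`
#' provenance comments, and validates every row; validation failures name
#' the offending file line.
#'
#' @param path CSV file path.
#' @return A list of class `"session_dataset"`: `trials` (data.frame) and
#'   `provenance` (named list of header-comment values).
#' @export
read_trials <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  prov <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) prov[[trimws(m[2])]] <- trimws(m[3])
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 1L) stop("no header row in ", path, call. = FALSE)
  if (length(body_idx) < 2L) {
    stop("empty trial file: ", path, " has a header but no trial rows",
         call. = FALSE)
  }
  df <- utils::read.csv(text = lines[body_idx], stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss)) {
    stop("trial file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data_lines <- body_idx[-1L]  # file line number of each data row
  bad <- function(rows, why) {
    stop(sprintf("invalid trial rows (%s) at line(s) %s of %s", why,
                 paste(utils::head(data_lines[rows], 5L), collapse = ", "),
                 path), call. = FALSE)
  }
  if (!all(df$head_state %in% c("stationary", "translating"))) {
    bad(which(!df$head_state %in% c("stationary", "translating")),
        "unknown head_state")
  }
  if (!all(df$direction %in% c("left", "right"))) {
    bad(which(!df$direction %in% c("left", "right")), "unknown direction")
  }
  num_ok <- function(x) is.numeric(x) | is.logical(x)
  for (nm in c("f_cm", "dtheta_deg_s", "dalpha_deg_s", "head_speed_cm_s",
               "disparity_pixels", "disparity_arcmin")) {
    if (!num_ok(df[[nm]])) bad(which(is.na(suppressWarnings(as.numeric(df[[nm]])))),
                               paste("non-numeric", nm))
  }
  if (any(!is.finite(df$f_cm) | df$f_cm <= 0)) {
    bad(which(!is.finite(df$f_cm) | df$f_cm <= 0), "non-positive f_cm")
  }
  rate_bad <- (!is.na(df$dtheta_deg_s) & df$dtheta_deg_s < 0) |
    (!is.na(df$dalpha_deg_s) & df$dalpha_deg_s <= 0)
  if (any(rate_bad)) bad(which(rate_bad), "negative or zero rates")
  if (any(!is.na(df$disparity_arcmin) & df$disparity_arcmin < 0)) {
    bad(which(df$disparity_arcmin < 0), "negative disparity")
  }
  resp <- df$response_stereo_deeper
  if (!is.logical(resp)) resp <- as.logical(resp)
  if (any(is.na(resp))) bad(which(is.na(resp)), "non-logical response")
  df$response_stereo_deeper <- resp
  hs_missing <- df$head_state == "translating" & is.na(df$head_speed_cm_s)
  if (any(hs_missing)) bad(which(hs_missing),
                           "translating trial without head_speed_cm_s")
  structure(list(trials = df, provenance = prov), class = "session_dataset")
}

#' @export
print.session_dataset <- function(x, ...) {
  cat(sprintf("2IFC session dataset: %d trials, %d observer(s), %d condition(s)\n",
              nrow(x$trials), length(unique(x$trials$observer_id)),
              length(unique(x$trials$condition_id))))
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(sprintf("%s=%s", names(x$provenance), unlist(x$provenance)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exclude observers whose PSEs are outliers relative to the group
#'
#' Flags, for each observer and each (condition, stimulus) cell, whether
#' the observer's PSE lies strictly more than `sd_threshold` standard
#' deviations from the group of the *other* observers (leave-one-out mean
#' and SD, so one aberrant observer cannot mask itself by inflating the
#' group SD). An observer is excluded when the fraction of its flagged
#' cells strictly exceeds `fraction` (default: a majority). With fewer
#' than 3 observers no filtering is attempted.
#'
#' @param per_observer_pses Data.frame of per-observer fits (e.g. from
#'   [fit_session()] with `by_observer = TRUE`): columns `observer_id`,
#'   `condition_id`, `dtheta_deg_s`, `dalpha_deg_s`, `pse`.
#' @param sd_threshold Flagging threshold in SD units (strict inequality).
#' @param fraction Minimum flagged-cell fraction for exclusion (strict
#'   inequality).
#' @return A list of class `"outlier_report"`: `kept` (filtered table),
#'   `excluded_observers`, `report` (per-observer cell counts, flagged
#'   fraction and decision).
#' @export
exclude_outlier_observers <- function(per_observer_pses, sd_threshold = 3,
                                      fraction = 0.5) {
  df <- per_observer_pses
  req <- c("observer_id", "condition_id", "dtheta_deg_s", "dalpha_deg_s", "pse")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("per-observer PSE table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[is.finite(df$pse), , drop = FALSE]
  obs <- unique(df$observer_id)
  if (length(obs) < 3L) {
    warning("fewer than 3 observers: outlier filtering skipped", call. = FALSE)
    rep <- data.frame(observer_id = obs, n_cells = NA_integer_,
                      n_flagged = NA_integer_, fraction_flagged = NA_real_,
                      excluded = FALSE)
    return(structure(list(kept = per_observer_pses,
                          excluded_observers = character(0), report = rep),
                     class = "outlier_report"))
  }
  cell <- paste(df$condition_id, df$dtheta_deg_s, df$dalpha_deg_s, sep = "\r")
  rep_rows <- lapply(obs, function(o) {
    mine <- df$observer_id == o
    n_flag <- 0L
    n_cell <- 0L
    for (cl in unique(cell[mine])) {
      x_self <- df$pse[mine & cell == cl]
      x_rest <- df$pse[!mine & cell == cl]
      if (length(x_rest) < 2L) next
      s <- stats::sd(x_rest)
      if (!is.finite(s) || s == 0) next
      n_cell <- n_cell + 1L
      if (any(abs(x_self - mean(x_rest)) / s > sd_threshold)) {
        n_flag <- n_flag + 1L
      }
    }
    data.frame(observer_id = o, n_cells = n_cell, n_flagged = n_flag,
               fraction_flagged = if (n_cell > 0L) n_flag / n_cell else NA_real_)
  })
  rep <- do.call(rbind, rep_rows)
  rep$excluded <- !is.na(rep$fraction_flagged) & rep$fraction_flagged > fraction
  excl <- rep$observer_id[rep$excluded]
  kept <- per_observer_pses[!per_observer_pses$observer_id %in% excl, ,
                            drop = FALSE]
  structure(list(kept = kept, excluded_observers = excl, report = rep),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier screening: %d of %d observer(s) excluded",
              length(x$excluded_observers), nrow(x$report)))
  if (length(x$excluded_observers)) {
    cat(" (", paste(x$excluded_observers, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Normalized depth-constancy matches from control trials
#'
#' For each control condition, fits a psychometric function to the pooled
#' proportions of "variable deeper" responses over the variable disparity
#' levels, converts the PSE to depth at the variable stimulus's viewing
#' distance, and normalizes by the depth of the fixed standard. A value of
#' 1 is perfect depth constancy.
#'
#' @param control_trials Output of [simulate_depth_constancy_control()]
#'   (or equivalent real data with the same columns).
#' @param i Inter-ocular distance, cm.
#' @param design Control design table; defaults to the attribute attached
#'   by the simulator, falling back to [control_design()].
#' @return A data.frame with one row per control condition: PSE and sigma
#'   (arcmin), matched depth and fixed depth (cm), `normalized_match`, and
#'   the sigma-implied depth threshold (cm).
#' @export
analyze_depth_constancy <- function(control_trials, i = 6.5, design = NULL) {
  if (is.null(design)) design <- attr(control_trials, "control_design")
  if (is.null(design)) design <- control_design()
  rows <- lapply(seq_len(nrow(design)), function(ci) {
    des <- design[ci, ]
    sub <- control_trials[control_trials$condition_id == des$condition_id, ,
                          drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    agg <- aggregate_trials(sub)
    fit <- fit_cumulative_normal(agg$disparity_arcmin, agg$proportion,
                                 n_trials = agg$n_trials)
    d_fix <- disparity_to_depth(des$disparity_fixed_arcmin,
                                f = des$f_fixed_cm, i = i)
    conv <- isTRUE(fit$converged)
    d_var <- if (conv) pse_to_depth(fit, f = des$f_variable_cm, i = i) else NA_real_
    data.frame(condition_id = des$condition_id,
               f_fixed_cm = des$f_fixed_cm,
               f_variable_cm = des$f_variable_cm,
               pse_arcmin = fit$pse, sigma_arcmin = fit$sigma,
               converged = conv,
               depth_fixed_cm = d_fix, depth_matched_cm = d_var,
               normalized_match = d_var / d_fix,
               depth_threshold_cm = if (conv) {
                 sigma_to_depth_threshold(fit, f = des$f_variable_cm, i = i)
               } else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Equivalent head-stationary pursuit speed implied by a depth match under a
# transducer model: invert d = k f ratio^r dalpha^(r-e).
.equivalent_pursuit <- function(d_mp, ratio, f, model) {
  if (abs(model$r - model$e) < 1e-8) return(rep(NA_real_, length(d_mp)))
  (d_mp / (model$k * f * ratio^model$r))^(1 / (model$r - model$e))
}

#' Run the full simulate / fit / report pipeline
#'
#' End-to-end analysis on synthetic (or supplied) 2IFC data:
#' \enumerate{
#'   \item simulate head-stationary, head-translating and depth-constancy
#'     control sessions (skipped when `trials` is supplied);
#'   \item fit per-observer psychometric functions and screen outlier
#'     observers ([exclude_outlier_observers()]);
#'   \item fit group psychometric functions on the pooled proportions of
#'     the retained observers and convert PSEs to depth matches;
#'   \item fit the log-space transducer plane on the head-stationary depth
#'     matches ([fit_empirical_mpr()]) and the stereo-distortion-adjusted
#'     refit ([johnston_adjust_and_refit()]);
#'   \item analyse the head-translating conditions: mean head speed, total
#'     compensatory eye speed, the equivalent head-stationary pursuit
#'     speed implied by the fitted model, and its percentage of the total
#'     ([pursuit_fraction()]);
#'   \item compute normalized depth-constancy matches
#'     ([analyze_depth_constancy()]).
#' }
#' The run is deterministic given (`config`, `seed`).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for all randomness.
#' @param trials Optional pre-existing experimental trials (data.frame or
#'   `session_dataset`); when given, only analysis is performed and the
#'   control analysis is skipped unless `control_trials` is also given.
#' @param control_trials Optional control-condition trials.
#' @param i Inter-ocular distance used in depth conversions, cm.
#' @return An object of class `"mpr_report"`; see [print.mpr_report()].
#' @export
run_full_pipeline <- function(config = simulation_config(), seed = 1L,
                              trials = NULL, control_trials = NULL, i = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(i)) i <- config$i_cm
  set.seed(seed)
  grid <- build_stimulus_grid(config)
  simulated <- is.null(trials)
  if (simulated) {
    trials <- rbind(simulate_trials(grid, config),
                    simulate_head_translation_session(grid, config))
    control_trials <- simulate_depth_constancy_control(config)
  } else if (inherits(trials, "session_dataset")) {
    trials <- trials$trials
  }

  per_obs <- fit_session(trials, by_observer = TRUE, i = i)
  screening <- exclude_outlier_observers(per_obs[per_obs$converged, ,
                                                 drop = FALSE])
  kept_trials <- trials[!trials$observer_id %in% screening$excluded_observers, ,
                        drop = FALSE]

  group <- fit_session(kept_trials, by_observer = FALSE, i = i)
  kept_obs <- screening$kept
  # per-stimulus average of individual estimates, with SE across observers
  cell <- paste(group$condition_id, group$dtheta_deg_s, group$dalpha_deg_s,
                sep = "\r")
  ocell <- paste(kept_obs$condition_id, kept_obs$dtheta_deg_s,
                 kept_obs$dalpha_deg_s, sep = "\r")
  group$d_mp_indiv_mean <- vapply(cell, function(cl) {
    v <- kept_obs$d_mp[ocell == cl & is.finite(kept_obs$d_mp)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  group$d_mp_se <- vapply(cell, function(cl) {
    v <- kept_obs$d_mp[ocell == cl & is.finite(kept_obs$d_mp)]
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  group$ratio <- group$dtheta_deg_s / group$dalpha_deg_s
  group$head_state <- ifelse(
    group$condition_id %in% grid$condition_id,
    grid$head_state[match(group$condition_id, grid$condition_id)],
    "stationary")

  stationary <- group[group$head_state == "stationary" & group$converged, ,
                      drop = FALSE]
  n_unconverged <- sum(!group$converged)
  plane <- fit_empirical_mpr(stationary)
  adjusted <- johnston_adjust_and_refit(stationary)

  translating <- group[group$head_state == "translating" & group$converged, ,
                       drop = FALSE]
  trans_summary <- NULL
  if (nrow(translating)) {
    tcond <- unique(translating$condition_id)
    trans_summary <- do.call(rbind, lapply(tcond, function(cid) {
      sub <- translating[translating$condition_id == cid, , drop = FALSE]
      tt <- trials[trials$condition_id == cid, , drop = FALSE]
      v_mean <- mean(tt$head_speed_cm_s, na.rm = TRUE)
      f <- sub$f_cm[1]
      total <- head_speed_to_pursuit_rate(v_mean, f)
      equiv <- .equivalent_pursuit(sub$d_mp, sub$ratio, f, plane$model)
      data.frame(condition_id = cid, f_cm = f,
                 head_speed_cm_s = v_mean,
                 total_dalpha_deg_s = total,
                 equivalent_dalpha_deg_s = mean(equiv, na.rm = TRUE),
                 pursuit_fraction_pct = pursuit_fraction(
                   mean(equiv, na.rm = TRUE), total))
    }))
    rownames(trans_summary) <- NULL
  }

  control <- if (!is.null(control_trials)) {
    analyze_depth_constancy(control_trials, i = i)
  }

  out <- list(config = config, seed = seed, simulated = simulated,
              grid = grid, i_cm = i,
              n_trials = nrow(trials),
              per_observer = per_obs,
              screening = screening,
              depth_matches = group,
              n_unconverged = n_unconverged,
              plane_fit = plane,
              adjusted_fit = adjusted,
              translating = trans_summary,
              control = control)
  class(out) <- "mpr_report"
  out
}

#' Print a pipeline report
#'
#' One section per pipeline stage, with counts and units (depths in cm,
#' rates in deg/s, disparities in arcmin, natural logs in the plane fit;
#' the angular-unit basis of the scaling constant `k` is stated).
#'
#' @param x An `"mpr_report"`.
#' @param ... Unused.
#' @export
print.mpr_report <- function(x, ...) {
  cat("== Motion-parallax depth pipeline report ==\n")
  cat(sprintf("seed %d | %s trials: %d | observers kept: %d of %d\n",
              x$seed, if (x$simulated) "simulated" else "supplied",
              x$n_trials,
              nrow(x$screening$report) - length(x$screening$excluded_observers),
              nrow(x$screening$report)))
  cat(sprintf("psychometric functions: %d (group), %d unconverged\n",
              nrow(x$depth_matches), x$n_unconverged))
  cat("units: depth cm, rates deg/s, disparity arcmin, natural logs\n\n")
  cat("-- head-stationary transducer plane --\n")
  print(x$plane_fit)
  cat("\n-- stereo-distortion adjusted refit --\n")
  print(x$adjusted_fit)
  if (!is.null(x$translating)) {
    cat("\n-- head-translating pursuit decomposition --\n")
    print(format(x$translating, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$control)) {
    cat("\n-- depth-constancy control --\n")
    print(format(x$control[c("condition_id", "pse_arcmin", "sigma_arcmin",
                             "normalized_match", "depth_threshold_cm")],
                 digits = 4), row.names = FALSE)
  }
  invisible(x)
}
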