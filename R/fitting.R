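## Bounded multi-start nonlinear least squares for the 4-parameter (randomized)
## and 5-parameter (ordered/skipped) models, fitted to repetition-averaged
## cell means as in the experimental analysis.

# box bounds for (range, slope, x_offset, y_offset, reuse)
.par_lower <- c(range = 0, slope = 0, x_offset = 0, y_offset = -180, reuse = 0)
.par_upper <- c(range = 360, slope = 200, x_offset = 10, y_offset = 180, reuse = 1)

# deterministic jitter table for the 4 extra starts: multiplicative on
# range/slope, additive on x_offset (drawers), y_offset (deg), reuse replaced
.start_jitter <- rbind(
  c(0.5, 1.5,  0.8,  -5, 0.05),
  c(1.5, 0.6, -0.8,   5, 0.50),
  c(0.8, 2.0,  0.4,  10, 0.00),
  c(1.2, 0.5, -0.4, -10, 0.35))

#' Average raw trials into a direction-by-drawer profile
#'
#' Collapses repetitions: each (direction, drawer) cell becomes the mean of
#' its repetitions, the profile the fitting functions consume.  Randomized
#' trials (direction `"none"`) yield one cell per drawer.
#'
#' @param trials A trial table (see [read_trials]) restricted to one
#'   participant and one task.
#' @return A data.frame with columns `direction`, `drawer`, `angle` sorted by
#'   direction then drawer.
#' @export
average_profile <- function(trials) {
  stopifnot(all(c("direction", "drawer", "angle_deg") %in% names(trials)))
  agg <- stats::aggregate(angle_deg ~ direction + drawer, data = trials, FUN = mean)
  names(agg)[names(agg) == "angle_deg"] <- "angle"
  agg[order(agg$direction, agg$drawer), c("direction", "drawer", "angle"),
      drop = FALSE]
}

# heuristic starting values from observed cell means (collapsed over direction)
.start_values <- function(drawer, angle, with_reuse) {
  ord <- order(drawer)
  d <- drawer[ord]; a <- angle[ord]
  rng <- max(a) - min(a)
  y0 <- (max(a) + min(a)) / 2
  # drawer where the observations cross the midpoint, linearly interpolated
  x0 <- mean(range(d))
  s <- sign(a - y0)
  cross <- which(s[-1] != s[-length(s)])
  if (length(cross)) {
    i <- cross[1]
    if (a[i + 1] != a[i])
      x0 <- d[i] + (y0 - a[i]) * (d[i + 1] - d[i]) / (a[i + 1] - a[i])
  }
  slope0 <- max(abs(diff(a)) / diff(d))
  p <- c(range = max(rng, 1e-3), slope = max(slope0, 1e-3),
         x_offset = x0, y_offset = y0)
  if (with_reuse) p <- c(p, reuse = 0.2)
  p
}

.clamp_par <- function(p) {
  k <- names(p)
  pmin(pmax(p, .par_lower[k]), .par_upper[k])
}

# model predictions for a cell-mean profile given a parameter vector
.predict_profile <- function(par, profile) {
  sp <- sigmoid_params(par[["range"]], par[["slope"]],
                       par[["x_offset"]], par[["y_offset"]])
  if (is.na(match("reuse", names(par))) || all(profile$direction == "none"))
    return(optimal_angle(sp, profile$drawer))
  model <- reuse_model(sp, par[["reuse"]])
  pred <- numeric(nrow(profile))
  for (dir in unique(profile$direction)) {
    idx <- which(profile$direction == dir)
    dset <- profile$drawer[idx]
    ord <- if (dir == "descending") order(dset, decreasing = TRUE) else order(dset)
    sim <- simulate_sequence(model, sequence_spec(dset[ord],
      direction = if (dir == "descending") "descending" else "ascending"))
    pred[idx[ord]] <- sim
  }
  pred
}

.fit_multistart <- function(profile, with_reuse) {
  obs <- profile$angle
  # collapse over direction for start heuristics
  coll <- stats::aggregate(angle ~ drawer, data = profile, FUN = mean)
  base <- .start_values(coll$drawer, coll$angle, with_reuse)
  starts <- list(.clamp_par(base))
  for (j in seq_len(nrow(.start_jitter))) {
    p <- base
    p[["range"]] <- base[["range"]] * .start_jitter[j, 1]
    p[["slope"]] <- base[["slope"]] * .start_jitter[j, 2]
    p[["x_offset"]] <- base[["x_offset"]] + .start_jitter[j, 3]
    p[["y_offset"]] <- base[["y_offset"]] + .start_jitter[j, 4]
    if (with_reuse) p[["reuse"]] <- .start_jitter[j, 5]
    starts[[j + 1]] <- .clamp_par(p)
  }
  resid_fn <- function(par) {
    names(par) <- names(base)
    obs - .predict_profile(par, profile)
  }
  k <- names(base)
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = unname(.par_lower[k]), upper = unname(.par_upper[k]),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxfev = 2000, maxiter = 500)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)  # strict improvement; ties keep first
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  best$n_starts <- length(starts)
  best
}

.make_fit_result <- function(par, profile, converged, n_starts, degenerate = FALSE) {
  pred <- .predict_profile(par, profile)
  gof <- goodness_of_fit(profile$angle, pred)
  z <- standardized_residuals(profile$angle, pred)
  sp <- sigmoid_params(par[["range"]], par[["slope"]],
                       par[["x_offset"]], par[["y_offset"]])
  reuse <- if ("reuse" %in% names(par)) par[["reuse"]] else 0
  structure(list(
    params = reuse_model(sp, reuse),
    profile = profile,
    fitted = pred,
    captured_variance_pct = gof$captured_variance_pct,
    rmse = gof$rmse,
    standardized_residuals = z,
    converged = converged,
    n_starts_used = n_starts,
    degenerate = degenerate),
    class = "hyst_fit")
}

#' @export
print.hyst_fit <- function(x, ...) {
  cat("Sequential posture selection model fit\n")
  print(x$params)
  cat(sprintf("  captured variance %.1f %%, RMSE %.2f deg, %d cells\n",
              x$captured_variance_pct, x$rmse, nrow(x$profile)))
  if (x$degenerate) cat("  (degenerate fit: flat data, range pinned to 0)\n")
  invisible(x)
}

#' Fit the 4-parameter sigmoid model to a randomized-task profile
#'
#' Estimates range, slope, x-offset and y-offset by bounded multi-start
#' Levenberg-Marquardt least squares on repetition-averaged cell means; the
#' reuse fraction is fixed at 0 because randomized sequences are assumed
#' unaffected by the previous posture.
#'
#' @param profile A profile data.frame (see [average_profile]) with one cell
#'   per drawer; a bare data.frame with `drawer` and `angle` columns is
#'   accepted.
#' @return A `hyst_fit` object: fitted [reuse_model] parameters (reuse = 0),
#'   captured variance (%), RMSE (deg), standardized residuals, convergence
#'   flag and number of starts.
#' @export
fit_sigmoid <- function(profile) {
  if (!"direction" %in% names(profile)) profile$direction <- "none"
  stopifnot(all(c("drawer", "angle") %in% names(profile)))
  if (length(unique(profile$drawer)) < 5)
    stop("at least 5 distinct drawers are required for a 4-parameter fit",
         call. = FALSE)
  profile <- profile[order(profile$drawer), , drop = FALSE]
  if (stats::sd(profile$angle) == 0) {
    warning("degenerate fit: all angles identical; range pinned to 0, ",
            "slope and x-offset are not identifiable", call. = FALSE)
    par <- c(range = 0, slope = 0, x_offset = mean(range(profile$drawer)),
             y_offset = profile$angle[1])
    return(.make_fit_result(par, profile, converged = TRUE, n_starts = 0,
                            degenerate = TRUE))
  }
  best <- .fit_multistart(profile, with_reuse = FALSE)
  par <- best$fit$par; names(par) <- c("range", "slope", "x_offset", "y_offset")
  .make_fit_result(par, profile, converged = best$fit$info %in% 1:4,
                   n_starts = best$n_starts)
}

#' Fit the full 5-parameter reuse model to an ordered/skipped profile
#'
#' Estimates the four sigmoid parameters and the reuse fraction jointly from
#' a profile containing both ascending and descending cells.  Reuse is
#' box-bounded to [0, 1] (0 is the model's stated lower bound; 1, total
#' persistence, is the physical cap).
#'
#' @param profile Profile data.frame with `direction` in
#'   `{"ascending","descending"}`, `drawer`, `angle`; at least 6 cells.
#' @return A `hyst_fit` object (see [fit_sigmoid]).
#' @export
fit_reuse_model <- function(profile) {
  stopifnot(all(c("direction", "drawer", "angle") %in% names(profile)))
  dirs <- unique(profile$direction)
  if (!all(c("ascending", "descending") %in% dirs))
    stop("both ascending and descending cells are required for a ",
         "5-parameter fit", call. = FALSE)
  if (nrow(profile) < 6)
    stop("at least 6 cells are required for a 5-parameter fit", call. = FALSE)
  profile <- profile[order(profile$direction, profile$drawer), , drop = FALSE]
  best <- .fit_multistart(profile, with_reuse = TRUE)
  par <- best$fit$par
  names(par) <- c("range", "slope", "x_offset", "y_offset", "reuse")
  .make_fit_result(par, profile, converged = best$fit$info %in% 1:4,
                   n_starts = best$n_starts)
}

#' Captured variance and RMSE of a prediction
#'
#' Captured variance is `100 * (1 - SS_residual / SS_total)` with the total
#' sum of squares taken about the observed grand mean; RMSE is the root mean
#' squared cell residual.  A perfect prediction captures exactly 100%.  For
#' constant observations the captured variance is undefined and returned as
#' `NA` with a warning (the RMSE is still valid).
#'
#' @param observed,predicted Matching numeric vectors of cell angles.
#' @return List with `captured_variance_pct` and `rmse`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("captured variance undefined: observations are constant",
            call. = FALSE)
    return(list(captured_variance_pct = NA_real_, rmse = rmse))
  }
  list(captured_variance_pct = 100 * (1 - sum(res^2) / ss_tot), rmse = rmse)
}

#' Standardized residuals of a fit
#'
#' Residuals centered on their mean and scaled by their sample (n-1) standard
#' deviation; inspected for heteroscedasticity, outliers and structure.  For
#' a perfect fit (zero residual variance) all-zero residuals are returned,
#' flagged with the attribute `zero_variance`.
#'
#' @param observed,predicted Matching numeric vectors with at least 2 cells.
#' @return Numeric vector with mean 0 and SD 1 (or all zeros, flagged).
#' @export
standardized_residuals <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  r <- observed - predicted
  s <- stats::sd(r)
  if (s == 0) {
    z <- rep(0, length(r))
    attr(z, "zero_variance") <- TRUE
    return(z)
  }
  z <- (r - mean(r)) / s
  attr(z, "zero_variance") <- FALSE
  z
}
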