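#' Sigmoid optimal grasp-angle parameters
#'
#' Constructs the four parameters of the sigmoid optimal pro/supination angle
#' function.  The optimal grasp angle for a drawer at height coordinate d is
#'
#'   y_offset + (range/2) * tanh((2 * slope / range) * (d - x_offset))
#'
#' so that `range` is the full asymptotic span of the curve (lowest to highest
#' drawer), `slope` is the literal steepest derivative in degrees per drawer
#' (attained at the inflection), `x_offset` is the drawer coordinate of the
#' inflection and `y_offset` the angle there.
#'
#' @param range Asymptotic span in degrees, >= 0.
#' @param slope Steepest derivative in degrees per drawer, >= 0.
#' @param x_offset Inflection position in drawer units, in [0, 10].
#' @param y_offset Angle at the inflection in degrees, in [-180, 180].
#' @return An object of class `sigmoid_params`.
#' @examples
#' sp <- sigmoid_params(range = 133.3, slope = 39.4, x_offset = 4.4, y_offset = 17.2)
#' optimal_angle(sp, 4.4)  # returns the y-offset at the inflection
#' @export
sigmoid_params <- function(range, slope, x_offset, y_offset) {
  vals <- c(range = range, slope = slope, x_offset = x_offset, y_offset = y_offset)
  if (!all(is.finite(vals)))
    stop("sigmoid parameters must be finite numbers", call. = FALSE)
  if (range < 0) stop("'range' must be >= 0", call. = FALSE)
  if (slope < 0) stop("'slope' must be >= 0", call. = FALSE)
  if (x_offset < 0 || x_offset > 10)
    stop("'x_offset' must lie in [0, 10]", call. = FALSE)
  if (y_offset < -180 || y_offset > 180)
    stop("'y_offset' must lie in [-180, 180]", call. = FALSE)
  structure(list(range = range, slope = slope,
                 x_offset = x_offset, y_offset = y_offset),
            class = "sigmoid_params")
}

#' Five-parameter reuse model
#'
#' Bundles a sigmoid optimal-angle curve with the fixed fraction of motor plan
#' reuse applied between subsequent drawers.  The reuse fraction is stored in
#' [0, 1]; human-facing reports multiply by 100 (percent).
#'
#' @param sigmoid A [sigmoid_params] object (or the four parameters passed via
#'   `...` to `sigmoid_params`).
#' @param reuse Fraction of the previous motor plan reused, in [0, 1].
#' @return An object of class `reuse_model`.
#' @export
reuse_model <- function(sigmoid, reuse) {
  if (!inherits(sigmoid, "sigmoid_params"))
    stop("'sigmoid' must be a sigmoid_params object", call. = FALSE)
  if (!is.finite(reuse) || reuse < 0 || reuse > 1)
    stop("'reuse' must be a fraction in [0, 1]", call. = FALSE)
  structure(list(sigmoid = sigmoid, reuse = reuse), class = "reuse_model")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat("Sigmoid optimal grasp-angle function\n")
  cat(sprintf("  range    %8.2f deg\n  slope    %8.2f deg/drawer\n", x$range, x$slope))
  cat(sprintf("  x-offset %8.2f drawers\n  y-offset %8.2f deg\n", x$x_offset, x$y_offset))
  invisible(x)
}

#' @export
print.reuse_model <- function(x, ...) {
  print(x$sigmoid)
  cat(sprintf("  reuse    %8.1f %%\n", 100 * x$reuse))
  invisible(x)
}

#' Optimal grasp angle for a drawer
#'
#' Evaluates the sigmoid optimal-angle function.  The `range = 0` limit is the
#' flat curve: the function returns `y_offset` for every drawer.
#'
#' @param params A [sigmoid_params] object.
#' @param drawer Drawer coordinate(s); real-valued, drawers are printed 1..9
#'   on the apparatus.
#' @return Angle(s) in degrees, vectorised over `drawer`.
#' @export
optimal_angle <- function(params, drawer) {
  if (!inherits(params, "sigmoid_params"))
    stop("'params' must be a sigmoid_params object", call. = FALSE)
  if (!all(is.finite(drawer)))
    stop("'drawer' must be finite", call. = FALSE)
  if (params$range == 0) return(rep(params$y_offset, length(drawer)))
  params$y_offset + (params$range / 2) *
    tanh((2 * params$slope / params$range) * (drawer - params$x_offset))
}

#' Blend a previous posture with the optimal posture
#'
#' The core motor-plan reuse rule: the next grasp angle is a weighted average
#' of the previous grasp angle (weight `reuse`) and the optimal angle for the
#' upcoming drawer (weight `1 - reuse`).  For example a previous posture of
#' 74.0 deg blended with an optimal posture of 40.0 deg at 30% reuse gives
#' 0.30 * 74.0 + 0.70 * 40.0 = 50.2 deg.
#'
#' @param previous_angle Previous grasp angle in degrees.
#' @param optimal Optimal grasp angle for the next drawer in degrees.
#' @param reuse Reuse fraction in [0, 1].
#' @return Blended angle in degrees.
#' @examples
#' blend(74.0, 40.0, 0.30)  # 50.2
#' @export
blend <- function(previous_angle, optimal, reuse) {
  if (!all(is.finite(c(previous_angle, optimal, reuse))))
    stop("inputs to blend() must be finite", call. = FALSE)
  if (any(reuse < 0 | reuse > 1))
    stop("'reuse' must lie in [0, 1]", call. = FALSE)
  reuse * previous_angle + (1 - reuse) * optimal
}

#' Sequence specification
#'
#' An ordered list of drawers to visit.  `ascending`/`descending` directions
#' must be strictly monotone; `custom` allows any order (used for randomized
#' sequences).
#'
#' @param drawers Integer drawer numbers, each in 1..9.
#' @param direction One of `"ascending"`, `"descending"`, `"custom"`.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(drawers, direction = c("custom", "ascending", "descending")) {
  direction <- match.arg(direction)
  if (length(drawers) == 0) stop("'drawers' must be non-empty", call. = FALSE)
  if (!all(drawers == as.integer(drawers)) || any(drawers < 1 | drawers > 9))
    stop("'drawers' must be integers in 1..9", call. = FALSE)
  if (direction == "ascending" && any(diff(drawers) <= 0))
    stop("ascending sequences must be strictly increasing", call. = FALSE)
  if (direction == "descending" && any(diff(drawers) >= 0))
    stop("descending sequences must be strictly decreasing", call. = FALSE)
  structure(list(drawers = as.integer(drawers), direction = direction),
            class = "sequence_spec")
}

#' Task specification
#'
#' The three task designs of the drawer experiment: `randomized` (pseudo-random
#' permutations of drawers 1..9), `ordered` (ascending/descending passes over
#' 1..9), and `skipped` (ordered passes over drawers 1, 3, 5, 7, 9 only).
#'
#' @param name One of `"randomized"`, `"ordered"`, `"skipped"`.
#' @param drawer_set Drawers used by the task; defaults follow the design.
#' @param n_repetitions Repetitions per condition (default 4).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(name = c("randomized", "ordered", "skipped"),
                      drawer_set = NULL, n_repetitions = 4L) {
  name <- match.arg(name)
  if (is.null(drawer_set))
    drawer_set <- switch(name,
                         randomized = 1:9,
                         ordered = 1:9,
                         skipped = c(1L, 3L, 5L, 7L, 9L))
  if (name == "ordered" && !identical(as.integer(drawer_set), 1:9))
    stop("ordered task uses drawers 1..9", call. = FALSE)
  if (name == "skipped" && !identical(as.integer(drawer_set), c(1L, 3L, 5L, 7L, 9L)))
    stop("skipped task uses drawers 1, 3, 5, 7, 9", call. = FALSE)
  if (n_repetitions < 1) stop("'n_repetitions' must be >= 1", call. = FALSE)
  structure(list(name = name, drawer_set = sort(as.integer(drawer_set)),
                 n_repetitions = as.integer(n_repetitions)),
            class = "task_spec")
}

#' Simulate one sequence of grasp angles
#'
#' Trial 1 adopts the optimal angle for its drawer (a sequence starts from a
#' resting posture, so there is no previous plan to reuse); from trial 2 on,
#' each angle is the reuse blend of the previous angle with the optimal angle
#' of the current drawer.
#'
#' @param model A [reuse_model] object.
#' @param seq A [sequence_spec] object, or a bare vector of drawers.
#' @param first_trial How trial 1 is seeded: `"optimal"` (default) or a
#'   numeric starting angle in degrees.
#' @return Numeric vector of simulated angles, one per trial.
#' @export
simulate_sequence <- function(model, seq, first_trial = "optimal") {
  if (!inherits(model, "reuse_model"))
    stop("'model' must be a reuse_model object", call. = FALSE)
  if (!inherits(seq, "sequence_spec")) seq <- sequence_spec(seq)
  d <- seq$drawers
  opt <- optimal_angle(model$sigmoid, d)
  a <- numeric(length(d))
  a[1] <- if (identical(first_trial, "optimal")) opt[1] else as.numeric(first_trial)
  if (length(d) > 1)
    for (i in 2:length(d))
      a[i] <- blend(a[i - 1], opt[i], model$reuse)
  a
}

#' Predict direction-by-drawer profiles and the hysteresis effect for a task
#'
#' Simulates one ascending and one descending pass over the task's drawer set
#' and summarises the motor hysteresis effect as the mean over drawers of
#' (descending angle - ascending angle).  With zero reuse the two passes are
#' identical and the effect is exactly 0; with positive slope and reuse the
#' effect is non-negative (descending sequences stay more pronated).
#'
#' @param model A [reuse_model] object.
#' @param task A [task_spec] for an `ordered` or `skipped` task (the
#'   randomized task has no direction structure).
#' @return A list with `profile` (data.frame: direction, drawer, angle),
#'   `per_drawer_effect` (named by drawer) and `mean_effect` (degrees).
#' @export
predict_task <- function(model, task) {
  if (!inherits(task, "task_spec"))
    stop("'task' must be a task_spec object", call. = FALSE)
  if (task$name == "randomized")
    stop("randomized task has no direction structure to predict", call. = FALSE)
  dset <- task$drawer_set
  asc <- simulate_sequence(model, sequence_spec(dset, "ascending"))
  desc <- simulate_sequence(model, sequence_spec(rev(dset), "descending"))
  desc <- desc[match(dset, rev(dset))]          # align to ascending drawer order
  eff <- desc - asc
  names(eff) <- dset
  profile <- data.frame(
    direction = rep(c("ascending", "descending"), each = length(dset)),
    drawer = rep(dset, 2L),
    angle = c(asc, desc),
    stringsAsFactors = FALSE)
  list(profile = profile, per_drawer_effect = eff, mean_effect = mean(eff))
}

#' Cost-optimization curves for the reuse fraction
#'
#' Illustrative power-function costs: the cognitive cost of planning decreases
#' with the reuse fraction u as `w_c * (1 - u)^p`, the mechanical cost of
#' execution increases as `w_m * u^p`; the optimal reuse minimises their sum.
#' Increasing the mechanical weight relative to the cognitive weight shifts
#' the optimum towards lower reuse.
#'
#' @param reuse_grid Grid of reuse fractions in [0, 1].
#' @param cognitive_weight,mechanical_weight Non-negative weights, not both 0.
#' @param exponent Power p > 1 (convexity requires it).
#' @return A list with `cognitive`, `mechanical`, `total` cost vectors and
#'   `argmin_reuse`, the grid point minimising total cost.
#' @export
cost_curves <- function(reuse_grid, cognitive_weight, mechanical_weight,
                        exponent = 2) {
  if (exponent <= 1) stop("'exponent' must be > 1", call. = FALSE)
  if (cognitive_weight < 0 || mechanical_weight < 0)
    stop("weights must be >= 0", call. = FALSE)
  if (cognitive_weight == 0 && mechanical_weight == 0)
    stop("at least one weight must be positive", call. = FALSE)
  if (any(reuse_grid < 0 | reuse_grid > 1))
    stop("'reuse_grid' must lie in [0, 1]", call. = FALSE)
  cog <- cognitive_weight * (1 - reuse_grid)^exponent
  mech <- mechanical_weight * reuse_grid^exponent
  tot <- cog + mech
  list(cognitive = cog, mechanical = mech, total = tot,
       argmin_reuse = reuse_grid[which.min(tot)])
}
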