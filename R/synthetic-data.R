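## Synthetic cohorts shaped like the drawer experiment, with known ground
## truth, so fitting and decomposition are testable without any real data.

# evaluate expr under a fixed seed, then restore the caller's RNG state
.local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# one draw from a Gaussian truncated to [lo, hi] by rejection
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Configuration of a synthetic cohort
#'
#' Population means and SDs of the five model parameters default to the
#' ordered-task cohort values (range 131.9 +/- 29.9 deg, slope 41.2 +/- 20.3
#' deg/drawer, x-offset 4.4 +/- 0.6 drawers, y-offset 16.5 +/- 15.2 deg,
#' reuse 15.6 +/- 13.0 %).  Per-participant parameters are drawn from
#' Gaussians truncated to the parameter bounds.  Each trial receives
#' independent Gaussian noise of SD `trial_noise_sd`.
#'
#' @param n_participants Cohort size (default 31).
#' @param param_means,param_sds Named numeric vectors with entries `range`,
#'   `slope`, `x_offset`, `y_offset`, `reuse` (reuse as a fraction).
#' @param trial_noise_sd Trial noise SD in degrees (default 4).
#' @param n_repetitions Repetitions per condition (default 4).
#' @param tasks Subset of `c("randomized", "ordered", "skipped")`.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 31L,
                          param_means = c(range = 131.9, slope = 41.2,
                                          x_offset = 4.4, y_offset = 16.5,
                                          reuse = 0.156),
                          param_sds = c(range = 29.9, slope = 20.3,
                                        x_offset = 0.6, y_offset = 15.2,
                                        reuse = 0.130),
                          trial_noise_sd = 4,
                          n_repetitions = 4L,
                          tasks = c("randomized", "ordered", "skipped"),
                          master_seed = 1L) {
  keys <- c("range", "slope", "x_offset", "y_offset", "reuse")
  stopifnot(n_participants >= 1, trial_noise_sd >= 0, n_repetitions >= 1,
            all(keys %in% names(param_means)), all(keys %in% names(param_sds)),
            all(param_sds[keys] >= 0))
  tasks <- match.arg(tasks, several.ok = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 param_means = param_means[keys], param_sds = param_sds[keys],
                 trial_noise_sd = trial_noise_sd,
                 n_repetitions = as.integer(n_repetitions),
                 tasks = tasks, master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

# draw one participant's true parameters, truncated to the type bounds
.draw_params <- function(config) {
  mu <- config$param_means; sd <- config$param_sds
  sp <- sigmoid_params(
    range = .rtruncnorm1(mu[["range"]], sd[["range"]], 0, 360),
    slope = .rtruncnorm1(mu[["slope"]], sd[["slope"]], 0, 200),
    x_offset = .rtruncnorm1(mu[["x_offset"]], sd[["x_offset"]], 0, 10),
    y_offset = .rtruncnorm1(mu[["y_offset"]], sd[["y_offset"]], -180, 180))
  reuse_model(sp, .rtruncnorm1(mu[["reuse"]], sd[["reuse"]], 0, 1))
}

# simulate the trial rows for one task of one participant
.task_trials <- function(model, task_name, n_rep, noise_sd, participant_id) {
  rows <- list()
  seq_idx <- 0L
  if (task_name == "randomized") {
    flat <- reuse_model(model$sigmoid, 0)   # randomized postures are optimal
    for (r in seq_len(n_rep)) {
      seq_idx <- seq_idx + 1L
      d <- sample(1:9)
      ang <- simulate_sequence(flat, sequence_spec(d)) +
        stats::rnorm(length(d), 0, noise_sd)
      rows[[seq_idx]] <- data.frame(
        participant_id = participant_id, task = task_name,
        sequence_index = seq_idx, direction = "none",
        trial_index = seq_along(d), drawer = d, angle_deg = ang,
        stringsAsFactors = FALSE)
    }
  } else {
    dset <- if (task_name == "ordered") 1:9 else c(1L, 3L, 5L, 7L, 9L)
    for (dir in c("ascending", "descending")) {
      d <- if (dir == "ascending") dset else rev(dset)
      for (r in seq_len(n_rep)) {
        seq_idx <- seq_idx + 1L
        ang <- simulate_sequence(model, sequence_spec(d, dir)) +
          stats::rnorm(length(d), 0, noise_sd)
        rows[[seq_idx]] <- data.frame(
          participant_id = participant_id, task = task_name,
          sequence_index = seq_idx, direction = dir,
          trial_index = seq_along(d), drawer = d, angle_deg = ang,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate one synthetic participant
#'
#' Draws true model parameters from the configured population and simulates
#' every configured task: randomized sequences are permutations of drawers
#' 1..9 simulated with reuse forced to 0 (randomized postures are assumed
#' optimal), ordered/skipped tasks get `n_repetitions` ascending and
#' descending passes each, every pass simulated independently from a resting
#' start.  Gaussian trial noise is added per trial.  Fully reproducible from
#' the seed.
#'
#' @param config A [cohort_config].
#' @param participant_seed Integer seed for this participant.
#' @param participant_id Identifier string (default derived from the seed).
#' @return List with `params` (true [reuse_model]) and `trials` (trial table).
#' @export
generate_participant <- function(config, participant_seed,
                                 participant_id = sprintf("P%d", participant_seed)) {
  stopifnot(inherits(config, "cohort_config"))
  .local_seed(participant_seed, {
    model <- .draw_params(config)
    trials <- do.call(rbind, lapply(config$tasks, function(tk)
      .task_trials(model, tk, config$n_repetitions, config$trial_noise_sd,
                   participant_id)))
    list(params = model, trials = trials)
  })
}

#' Generate a full synthetic cohort
#'
#' Maps [generate_participant] over per-participant seeds derived
#' deterministically from the master seed.
#'
#' @param config A [cohort_config].
#' @return An object of class `synthetic_cohort`: `truth` (data.frame of true
#'   parameters per participant, reuse as a fraction) and `trials` (the
#'   combined trial table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  seeds <- .local_seed(config$master_seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("P%02d", seq_len(n))
  truth <- vector("list", n)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_participant(config, seeds[i], ids[i])
    p <- g$params
    truth[[i]] <- data.frame(
      participant_id = ids[i], range = p$sigmoid$range, slope = p$sigmoid$slope,
      x_offset = p$sigmoid$x_offset, y_offset = p$sigmoid$y_offset,
      reuse = p$reuse, stringsAsFactors = FALSE)
    trials[[i]] <- g$trials
  }
  structure(list(config = config,
                 truth = do.call(rbind, truth),
                 trials = do.call(rbind, trials)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, tasks {%s}, %d trials\n",
              x$config$n_participants, paste(x$config$tasks, collapse = ", "),
              nrow(x$trials)))
  invisible(x)
}

#' Model parameters of a fit as a named vector
#'
#' @param object A `hyst_fit` object.
#' @param ... Unused.
#' @return Named vector `range`, `slope`, `x_offset`, `y_offset`, `reuse`.
#' @export
coef.hyst_fit <- function(object, ...) {
  p <- object$params
  c(range = p$sigmoid$range, slope = p$sigmoid$slope,
    x_offset = p$sigmoid$x_offset, y_offset = p$sigmoid$y_offset,
    reuse = p$reuse)
}

#' Parameter-recovery report
#'
#' Compares fitted parameters against known ground truth: per-parameter bias
#' (mean fitted - true), RMSE and mean absolute error.
#'
#' @param truth Data.frame of true parameters (columns `range`, `slope`,
#'   `x_offset`, `y_offset`, `reuse`), one row per participant.
#' @param fits A list of `hyst_fit` objects, or a data.frame with the same
#'   parameter columns, aligned with `truth`.
#' @return Data.frame with rows per parameter and columns `bias`, `rmse`,
#'   `mae`.
#' @export
recovery_report <- function(truth, fits) {
  keys <- c("range", "slope", "x_offset", "y_offset", "reuse")
  if (is.list(fits) && !is.data.frame(fits))
    fits <- as.data.frame(do.call(rbind, lapply(fits, coef)))
  stopifnot(nrow(truth) == nrow(fits), all(keys %in% names(truth)),
            all(keys %in% names(fits)))
  out <- do.call(rbind, lapply(keys, function(k) {
    e <- fits[[k]] - truth[[k]]
    data.frame(parameter = k, bias = mean(e), rmse = sqrt(mean(e^2)),
               mae = mean(abs(e)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
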