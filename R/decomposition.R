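## Per-participant factorial sum-of-squares decomposition of balanced 2 x D
## direction-by-drawer cell-mean profiles, hysteresis-specific variance
## capture, and the hysteresis-vs-noise participant split.

# coerce a 2xD profile (matrix with rownames ascending/descending, or a
# profile data.frame) to a 2xD matrix, ascending row first
.as_profile_matrix <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 2) stop("profile must have exactly 2 directions", call. = FALSE)
    if (ncol(x) < 2) stop("profile must have at least 2 drawers", call. = FALSE)
    if (anyNA(x)) stop("incomplete design: missing cell", call. = FALSE)
    return(x)
  }
  stopifnot(all(c("direction", "drawer", "angle") %in% names(x)))
  dirs <- sort(unique(x$direction))
  if (length(dirs) != 2) stop("profile must have exactly 2 directions", call. = FALSE)
  drawers <- sort(unique(x$drawer))
  m <- matrix(NA_real_, 2, length(drawers),
              dimnames = list(dirs, drawers))
  for (i in seq_len(nrow(x)))
    m[x$direction[i], as.character(x$drawer[i])] <- x$angle[i]
  if (anyNA(m)) stop("incomplete design: missing cell", call. = FALSE)
  m
}

#' Factorial sum-of-squares decomposition of a direction-by-drawer profile
#'
#' Partitions a balanced 2 x D table of cell means into sequence (direction),
#' drawer, and sequence-by-drawer interaction components about the grand
#' mean.  The components are additive: `ss_total = ss_sequence + ss_drawer +
#' ss_interaction`.
#'
#' @param profile A 2 x D numeric matrix (rows = directions, columns =
#'   drawers) or a profile data.frame with `direction`, `drawer`, `angle`.
#' @return An object of class `factorial_ss` with fields `ss_total`,
#'   `ss_sequence`, `ss_drawer`, `ss_interaction` (squared degrees).
#' @export
factorial_ss <- function(profile) {
  m <- .as_profile_matrix(profile)
  g <- mean(m)
  ss_total <- sum((m - g)^2)
  ss_sequence <- ncol(m) * sum((rowMeans(m) - g)^2)
  ss_drawer <- nrow(m) * sum((colMeans(m) - g)^2)
  structure(list(ss_total = ss_total,
                 ss_sequence = ss_sequence,
                 ss_drawer = ss_drawer,
                 ss_interaction = ss_total - ss_sequence - ss_drawer),
            class = "factorial_ss")
}

#' @export
print.factorial_ss <- function(x, ...) {
  cat("Factorial SS decomposition (deg^2)\n")
  cat(sprintf("  sequence    %10.3f\n  drawer      %10.3f\n", x$ss_sequence, x$ss_drawer))
  cat(sprintf("  interaction %10.3f\n  total       %10.3f\n", x$ss_interaction, x$ss_total))
  invisible(x)
}

#' Per-drawer and mean hysteresis effect of a profile
#'
#' The hysteresis effect at each drawer is the descending minus the ascending
#' cell mean; positive values mean the descending pass stays more pronated.
#' The summary effect is the mean over drawers.
#'
#' @param profile As in [factorial_ss]; directions must be identifiable as
#'   ascending/descending (matrix rows are taken in alphabetical order, i.e.
#'   ascending first).
#' @return List with `per_drawer_effect` (named by drawer) and `mean_effect`
#'   in degrees.
#' @export
hysteresis_effect <- function(profile) {
  m <- .as_profile_matrix(profile)
  rn <- rownames(m)
  if (!is.null(rn) && all(c("ascending", "descending") %in% rn)) {
    eff <- m["descending", ] - m["ascending", ]
  } else {
    eff <- m[2, ] - m[1, ]
  }
  list(per_drawer_effect = eff, mean_effect = mean(eff))
}

#' Fraction of hysteresis-specific variance captured by a model
#'
#' The total variance of an ordered profile is dominated by the drawer main
#' effect; this statistic isolates the two components affected by hysteresis
#' (sequence and sequence x drawer).  The residual profile
#' (observed - predicted) is decomposed with [factorial_ss] and the captured
#' fraction is
#'
#'   100 * (1 - (ss_sequence_res + ss_interaction_res) /
#'              (ss_sequence_obs + ss_interaction_obs))
#'
#' which is 100 for a perfect fit, ~0 for a direction-symmetric model, and
#' may be negative when the model worsens those components (reported as-is).
#'
#' @param observed,predicted Matching 2 x D profiles.
#' @return Captured hysteresis variance in percent.
#' @export
captured_hysteresis_variance <- function(observed, predicted) {
  mo <- .as_profile_matrix(observed)
  mp <- .as_profile_matrix(predicted)
  stopifnot(identical(dim(mo), dim(mp)))
  sso <- factorial_ss(mo)
  denom <- sso$ss_sequence + sso$ss_interaction
  if (denom == 0)
    stop("observed profile has zero hysteresis variance; captured fraction ",
         "is undefined", call. = FALSE)
  ssr <- factorial_ss(mo - mp)
  100 * (1 - (ssr$ss_sequence + ssr$ss_interaction) / denom)
}

#' Split participants into hysteresis and noise groups
#'
#' Participants are ranked by the ratio of their sequence SS to their
#' sequence-by-drawer interaction SS: a large ratio means the direction
#' difference is a coherent shift (true hysteresis), a small ratio means the
#' direction-dependent variance is mostly unstructured noise.  The top half
#' is labeled `"hysteresis"`, the bottom half `"noise"`; for odd N the median
#' participant is `"excluded"`.  A ratio with zero interaction SS and
#' positive sequence SS is treated as infinite; a participant with both SS
#' zero has an undefined ratio and is excluded with a warning.
#'
#' @param ss_sequence,ss_interaction Numeric vectors, one entry per
#'   participant (N >= 2).
#' @return Character vector of labels in input order.
#' @export
classify_participants <- function(ss_sequence, ss_interaction) {
  stopifnot(length(ss_sequence) == length(ss_interaction))
  n <- length(ss_sequence)
  if (n < 2) stop("at least 2 participants are required", call. = FALSE)
  ratio <- ifelse(ss_interaction == 0,
                  ifelse(ss_sequence > 0, Inf, NA_real_),
                  ss_sequence / ss_interaction)
  labels <- rep(NA_character_, n)
  undef <- is.na(ratio)
  if (any(undef)) {
    warning(sum(undef), " participant(s) with zero sequence and interaction ",
            "SS: ratio undefined, labeled 'excluded'", call. = FALSE)
    labels[undef] <- "excluded"
  }
  ok <- which(!undef)
  m <- length(ok)
  if (m > 0) {
    rk <- rank(-ratio[ok], ties.method = "first")  # 1 = largest ratio
    half <- m %/% 2
    lab <- rep("excluded", m)
    lab[rk <= half] <- "hysteresis"
    lab[rk > m - half] <- "noise"
    labels[ok] <- lab
  }
  labels
}
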