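# Independent oracles, coded from definitions and kept separate from the
# package implementation.

# scalar sigmoid via the exponential definition of tanh (not the tanh()
# builtin used by the package)
oracle_sigmoid <- function(range, slope, x_offset, y_offset, d) {
  if (range == 0) return(y_offset)
  t <- (2 * slope / range) * (d - x_offset)
  y_offset + (range / 2) * (exp(t) - exp(-t)) / (exp(t) + exp(-t))
}

# naive step-by-step sequence recursion
oracle_sequence <- function(range, slope, x_offset, y_offset, reuse, drawers) {
  a <- numeric(length(drawers))
  for (i in seq_along(drawers)) {
    opt <- oracle_sigmoid(range, slope, x_offset, y_offset, drawers[i])
    a[i] <- if (i == 1) opt else reuse * a[i - 1] + (1 - reuse) * opt
  }
  a
}

# definitional balanced two-way decomposition via cell effects
oracle_two_way_ss <- function(m) {
  g <- mean(m)
  alpha <- rowMeans(m) - g
  beta <- colMeans(m) - g
  gamma <- sweep(sweep(m - g, 1, alpha), 2, beta)
  list(ss_sequence = ncol(m) * sum(alpha^2),
       ss_drawer = nrow(m) * sum(beta^2),
       ss_interaction = sum(gamma^2),
       ss_total = sum((m - g)^2))
}

# stationary point of w_c*(1-u)^p + w_m*u^p by bisection on the derivative
oracle_cost_argmin <- function(w_c, w_m, p, tol = 1e-10) {
  f <- function(u) w_m * u^(p - 1) - w_c * (1 - u)^(p - 1)
  lo <- 1e-12; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# sigmoid constructed so that optimal(6) = 74.0 and optimal(5) = 40.0
# (the drawer #6 -> #5 demonstration): symmetric about x = 5.5, y = 57,
# span 100, tanh(2*slope/range * 0.5) = 34/50 => slope = range * atanh(0.34)
demo_sigmoid <- function() {
  sigmoid_params(range = 100, slope = 100 * atanh(0.34),
                 x_offset = 5.5, y_offset = 57)
}

# random balanced 2 x D profile matrix
rand_profile_matrix <- function(D = 9, sd = 20) {
  matrix(rnorm(2 * D, 30, sd), nrow = 2,
         dimnames = list(c("ascending", "descending"), seq_len(D)))
}

# noiseless ordered cell-mean profile from a parameter vector
noiseless_profile <- function(range, slope, x_offset, y_offset, reuse,
                              task = "ordered") {
  m <- reuse_model(sigmoid_params(range, slope, x_offset, y_offset), reuse)
  predict_task(m, task_spec(task))$profile
}
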