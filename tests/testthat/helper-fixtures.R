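## shared fixtures, built in code at test time

## two-group tibble in the cohort layout used by the stats layer
two_groups <- function(x, y, groups = c("control", "mtbi")) {
  tibble::tibble(
    group = rep(groups, c(length(x), length(y))),
    visit = 1L,
    value = c(x, y)
  )
}

## independent Mann-Whitney oracle: U by direct pair counting, two-sided p
## by exhaustive enumeration of all assignments of the pooled sample
mw_oracle <- function(x, y) {
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
  list(u = u, p = p)
}

## deterministic random BOLD image: positive signal, no structure
random_bold <- function(dims = c(6, 6, 4), n_t = 60, tr_s = 2, seed = 11) {
  set.seed(seed)
  arr <- array(800 + rnorm(prod(dims) * n_t, sd = 30), c(dims, n_t))
  bold_image(arr, voxel_size_mm = c(3.6, 3.6, 3), tr_s = tr_s)
}

default_regressor <- function(n_volumes = 255, tr_s = 2) {
  build_protocol_waveform(hypercapnia_protocol(), tr_s = tr_s, n_volumes = n_volumes)
}

## closed-form per-voxel OLS oracle (independent of fit_matrix): slope in
## %/mmHg with S0 over `baseline_idx`, Pearson r via cor()
ols_oracle <- function(ts, x, baseline_idx) {
  b <- sum((x - mean(x)) * (ts - mean(ts))) / sum((x - mean(x))^2)
  s0 <- mean(ts[baseline_idx])
  c(slope = 100 * b / s0, r = stats::cor(ts, x))
}
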