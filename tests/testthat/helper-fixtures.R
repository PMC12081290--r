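# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small except where a check is explicitly about scale.

fix <- local({
  design <- maze_design()
  trials <- simulate_session(design, seed = 101)
  list(design = design, trials = trials)
})

# An epoch_matrix whose values are a deterministic function of the trial
# labels (plus optional iid noise); used to construct noiseless single-factor
# units and controlled inputs without going through spike simulation.
synthetic_em <- function(fun, maze_id = 1, trials = fix$trials,
                         design = fix$design, unit_id = "syn",
                         noise_sd = 0) {
  zero <- numeric(0)
  em <- epoch_matrix(zero, trials, maze_id, design, unit_id, smooth = FALSE)
  lab <- em$labels
  v <- matrix(0, nrow(lab), 9L, dimnames = list(NULL, colnames(em$values)))
  for (i in seq_len(nrow(lab)))
    v[i, ] <- fun(epoch = colnames(v), position = lab$position[i],
                  rewarded = lab$rewarded[i], subsequence = lab$subsequence[i])
  if (noise_sd > 0) v <- v + matrix(rnorm(length(v), sd = noise_sd), nrow(v))
  em$values <- v
  em
}

# Profile pair with an exact target Pearson correlation.
profiles_with_r <- function(r, n = 72, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))
  x <- as.vector(scale(x)); z <- as.vector(scale(z))
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}

expect_multiset_equal <- function(a, b) expect_equal(sort(a), sort(b))
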