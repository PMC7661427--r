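# Heavy Monte Carlo results shared across acceptance tests, computed once
# per test run. Scale: 100 replicates, 100 bootstrap draws per cell.

.acc_cache <- new.env(parent = emptyenv())

acc_grid <- function() {
  if (is.null(.acc_cache$grid))
    .acc_cache$grid <- grid_study(sds = c(5, 7), replicates = 100, seed = 1)
  .acc_cache$grid
}

acc_boot <- function() {
  if (is.null(.acc_cache$boot))
    .acc_cache$boot <- bootstrap_comparison(
      config = mixture_config(sds = 7),
      replicates = 100, n_boot = 100, seed = 1,
      gamma = gamma_spec("absolute", 5), delta = 5)
  .acc_cache$boot
}
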