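# Shared fixtures: tiny hand-built bursts and small simulated ensembles.

toy_burst <- function(id = "b1", donor, acceptor, bg_d = 0, bg_a = 0,
                      condition = "TOY", bin_width = 1)
  binned_burst(id, donor, acceptor, bg_d, bg_a,
               condition = condition, bin_width = bin_width)

# Three short bursts with nonzero background, irregular lengths.
toy_set <- function() {
  burst_set(list(
    toy_burst("t1", donor = c(15, 12, 18, 10, 14, 16),
              acceptor = c(25, 30, 22, 28, 26, 24), bg_d = 10, bg_a = 20),
    toy_burst("t2", donor = c(20, 11, 13, 17), acceptor = c(21, 27, 29, 23),
              bg_d = 10, bg_a = 20),
    toy_burst("t3", donor = c(14, 15, 13, 16, 12, 18, 11, 19),
              acceptor = c(24, 26, 23, 27, 25, 22, 28, 21),
              bg_d = 10, bg_a = 20)))
}

# Deterministic RNG sandbox: every test that draws random numbers goes
# through this so suite order never changes results.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

quick_config <- function(...) {
  defaults <- list(duration_model = list(kind = "uniform", min = 100, max = 300),
                   n_bursts = 50)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
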