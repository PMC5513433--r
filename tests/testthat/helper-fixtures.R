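# small in-code fixtures shared across test files

# a site table built by hand (0-based half-open coordinates)
manual_sites <- function(start, end, tf = "a", strand = "+",
                         score = 0, s_max = 0) {
  tibble::tibble(site_id = seq_along(start), tf = rep_len(tf, length(start)),
                 start = start, end = end,
                 strand = rep_len(strand, length(start)),
                 score = rep_len(score, length(start)),
                 footprint = end - start,
                 s_max = rep_len(s_max, length(start)))
}

# single-TF parameter set with permissive defaults
simple_params <- function(role = "activator", E_A = 1, E_Q = 0, E_C = 0,
                          A = 1, lambda = 1, coactivated_by = NULL,
                          global = global_params(), config = model_config()) {
  param_set(tf_params("a", role, coactivated_by = coactivated_by, A = A,
                      lambda = lambda, E_A = E_A, E_Q = E_Q, E_C = E_C),
            global, config)
}

# random occupancy instance for oracle-equivalence checks
random_occupancy_instance <- function(n, P = 2, span = 300) {
  starts <- sort(sample(0:span, n))
  fp <- sample(5:12, n, replace = TRUE)
  sites <- manual_sites(starts, starts + fp,
                        tf = sample(c("coopX", "other"), n, replace = TRUE))
  w <- matrix(exp(stats::runif(n * P, -4, 4)), n, P)
  if (stats::runif(1) < 0.3) w[sample(length(w), 1)] <- 0
  coop <- coop_spec("coopX", omega = exp(stats::runif(1, 0, log(1000))),
                    d_omega = sample(0:80, 1))
  list(sites = sites, w = w, coop = coop)
}

# benchmark bundle cached per test run
benchmark_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_benchmark(seed = 1)
    cache
  }
})
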