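# one shared warm-start chain (standing -> straight -> curved) computed
# lazily and cached across acceptance tests; problem sizes follow the
# packaged study conditions (N = 50 nodes, 12 synthetic cycles, seed 1)

chain_cache <- new.env(parent = emptyenv())

chain_settings <- function() {
  solver_settings(max_inner = 40, max_outer = 5)
}

chain_ref <- function() {
  if (is.null(chain_cache$ref)) {
    m <- runner_model()
    chain_cache$ref <- cycles_to_reference(
      synth_reference(m, speed = 4.0, n_cycles = 12, seed = 1), N = 50)
  }
  chain_cache$ref
}

chain_standing <- function() {
  if (is.null(chain_cache$stand)) {
    chain_cache$stand <- standing_task(runner_model(), n_starts = 5,
                                       seed = 1)
  }
  chain_cache$stand
}

chain_straight <- function() {
  if (is.null(chain_cache$straight)) {
    chain_cache$straight <- straight_running_task(
      runner_model(), chain_ref(), v_x = 4.0, v_z = 0.0,
      init = chain_standing(), settings = chain_settings())
  }
  chain_cache$straight
}

chain_curved <- function() {
  if (is.null(chain_cache$curved)) {
    chain_cache$curved <- curved_running_task(
      runner_model(), chain_ref(), v_norm = 2.7, r = 3.7,
      init = chain_straight(), settings = chain_settings())
  }
  chain_cache$curved
}

chain_straight_n25 <- function() {
  if (is.null(chain_cache$straight25)) {
    chain_cache$straight25 <- straight_running_task(
      runner_model(), chain_ref(), v_x = 4.0, v_z = 0.0,
      init = chain_standing(), N = 25, settings = chain_settings())
  }
  chain_cache$straight25
}
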