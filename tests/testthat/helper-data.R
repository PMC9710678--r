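# Shared small fixtures, built in code.

default_scales <- seqppi::load_default_scale_set()

# tiny labelled dataset with a planted signal, cached per (n, seed)
tiny_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_pos = 30L, n_neg = 30L, seed = 7L, ...) {
    key <- paste(n_pos, n_neg, seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- seqppi::generate_pair_dataset(
        seqppi::synthetic_config(n_pos = n_pos, n_neg = n_neg, seed = seed,
                                 ...))
    cache[[key]]
  }
})

# small fast forest for plumbing tests
tiny_rf <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      d <- tiny_dataset()
      model <<- seqppi::train_rf(
        d$pairs, d$sequences, default_scales,
        seqppi::rf_config(n_trees = 25L, seed = 3L))
    }
    model
  }
})
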