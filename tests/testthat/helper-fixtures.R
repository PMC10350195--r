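# Shared fixtures: everything is generated programmatically at test time.

# small synthetic corpus with configurable noise
tiny_corpus <- function(n, seed, ...) {
  generate_corpus(corpus_config(n_reports = n, seed = seed, ...))
}

# noise-free ("separable") generation settings: no negation, misspelling,
# abbreviation or grade-in-subtype collisions
clean_settings <- list(negation_rate = 0, misspelling_rate = 0,
                       abbreviation_rate = 0, collision_rate = 0)

clean_corpus <- function(n, seed) {
  do.call(corpus_config, c(list(n_reports = n, seed = seed), clean_settings))
}

# fast training config for unit tests
fast_config <- function(...) {
  args <- utils::modifyList(
    list(batch_size = 8L, learning_rate = 2e-3, max_epochs = 8L,
         patience = 8L, d_model = 32L, d_ff = 64L),
    list(...))
  do.call(train_config, args)
}
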