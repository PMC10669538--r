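# Shared test fixtures. The fixture autoencoder is trained once per test run
# (seeded, deterministic) and cached for every test that needs real weights.

.fixture_env <- new.env(parent = emptyenv())

# study conditions for the integration tests: single-organ 128x128 phantoms
test_phantom_config <- function() {
  phantom_config(size = c(128L, 128L), organ_means = 0.7,
                 radius_frac = c(0.15, 0.25))
}

test_phantom <- function(seed) generate_phantom(test_phantom_config(), seed = seed)

mask_center <- function(mask) {
  ctr <- round(colMeans(which(mask, arr.ind = TRUE)))
  c(ctr[[1]], ctr[[2]])
}

fixture_weights <- function() {
  if (!is.null(.fixture_env$weights)) return(.fixture_env$weights)
  corpus <- generate_texture_corpus(56, size = c(128L, 128L), seed = 0)
  w <- train_fixture_autoencoder(corpus[seq_len(48)], seed = 0,
                                 holdout = corpus[49:56])
  path <- file.path(tempdir(), "clickseg-fixture-weights.json")
  ae_save_weights(w, path)
  .fixture_env$weights <- w
  .fixture_env$path <- path
  w
}

fixture_weights_path <- function() {
  fixture_weights()
  .fixture_env$path
}
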