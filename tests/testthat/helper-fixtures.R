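## Shared in-code fixtures. Everything is generated programmatically; no
## binary data ships with the tests.

## a small hand-built spectrum
toy_spectrum <- function(id = "s1", ionmode = "positive",
                         inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                         smiles = "CCO",
                         mz = c(50, 120.5, 200, 310.2, 400, 512.3),
                         intensity = c(10, 100, 55, 7, 30, 2)) {
  ms_spectrum(mz, intensity,
              list(identifier = id, ionmode = ionmode, inchikey = inchikey,
                   smiles = smiles, precursor_mz = max(mz) + 1))
}

## small synthetic library shared by generator/model/ensemble tests;
## memoized per session because several files use it
small_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_clusters = 8, members_per_cluster = 4,
                              spectra_per_compound = 3, seed = 11)
      comps <- generate_compounds(cfg)
      spectra <- generate_spectra(comps, cfg)
      prep <- preprocess_spectra(select_annotated_positive(spectra),
                                 n_bins_total = 400)
      labels <- build_label_matrix(fingerprints = synthetic_fingerprints(comps))
      cache <<- list(cfg = cfg, compounds = comps, spectra = spectra,
                     binned = prep$binned, scheme = prep$scheme,
                     labels = labels,
                     keys = vapply(comps, function(cp) cp$key, ""))
    }
    cache
  }
})

pool_by_keys <- function(binned, keys) {
  Filter(function(b) b$compound_key %in% keys, binned)
}

## a tiny trained model on the small library; memoized (trains in seconds)
small_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lib <- small_library()
      split <- split_by_compound(lib$keys, 6, 6, seed = 21)
      cfg <- model_config(input_dim = length(lib$scheme$known_bins),
                          hidden_dims = c(32, 32), embedding_dim = 16,
                          learning_rate = 0.005, max_epochs = 30,
                          early_stop_patience = 30, seed = 21)
      m <- build_model(cfg, lib$scheme)
      m <- train_model(m, pool_by_keys(lib$binned, split$train),
                       pool_by_keys(lib$binned, split$val), lib$labels)
      cache <<- list(model = m, split = split, lib = lib)
    }
    cache
  }
})

## brute-force set-based similarity oracles (independent of the matrix
## implementation in the package)
oracle_tanimoto <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  u <- length(union(A, B))
  if (u == 0) 0 else length(intersect(A, B)) / u
}

oracle_dice <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  if (length(A) + length(B) == 0) 0 else
    2 * length(intersect(A, B)) / (length(A) + length(B))
}
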