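# Shared substituent sets and cached force-field builds.  Building the full
# methyl-substituted isomer families is moderately expensive, so each family
# is built once per test run and reused.

me_set <- function(n) substituent_set("C", n)

.build_cache <- new.env(parent = emptyenv())

cached_batches <- function(n_methyl, n_conf = 1) {
  key <- paste0("me", n_methyl, "_", n_conf)
  if (is.null(.build_cache[[key]])) {
    .build_cache[[key]] <- build_isomers(me_set(n_methyl), n_conf = n_conf,
                                         keep = 1, seed = 42)
  }
  .build_cache[[key]]
}

# random barcode sampler for property tests
random_barcodes <- function(n, counts = c(1, 1), seed = 7) {
  bv_fixture("barcodes", seed = seed, n = n, counts = counts)
}
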