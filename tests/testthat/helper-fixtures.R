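# Shared fixtures built in code: tiny transcript models and footprints.

options(riboscape.verbose = FALSE)

# one transcript: utr5 [0,20), cds [20,80), utr3 [80,100)
tiny_model <- function() {
  cds <- paste0("ATG", strrep("GCT", 18L), "TAA")   # 60 nt
  transcript_models(data.frame(
    transcript_id = "tx1", gene_id = "g1",
    sequence = paste0(strrep("C", 20L), cds, strrep("A", 20L)),
    cds_start = 20L, cds_end = 80L, stringsAsFactors = FALSE))
}

# footprints placed at given 5' positions on tx1
tiny_footprints <- function(pos, len = 28L, sample_id = "s1") {
  as_fp <- data.frame(sample_id = sample_id, transcript_id = "tx1",
                      five_prime_pos = as.integer(pos),
                      read_length = as.integer(len),
                      stringsAsFactors = FALSE)
  riboscape:::as_footprints(as_fp)
}

# deterministic offsets object: 12 nt for every length
flat_offsets <- function(lengths = 20:40, offset = 12L) {
  off <- setNames(rep(as.integer(offset), length(lengths)), lengths)
  attr(off, "default") <- as.integer(offset)
  off
}

# a small but non-trivial simulated study, cached per session
small_study <- local({
  cache <- NULL
  function(n_genes = 300L, seed = 42L, ...) {
    key <- paste(n_genes, seed, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$study)
    st <- simulate_study(sim_config(n_genes = n_genes, seed = seed, ...))
    cache <<- list(key = key, study = st)
    st
  }
})
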