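# Small deterministic fixtures built in code.

# A genome string with the Nt.BspQ1 motif planted at known positions over a
# motif-free background (background alphabet {A,T} only, so the GC-containing
# motif cannot arise by chance).
planted_genome <- function(positions, length = 50000, motif = "GCTCTTC",
                           seed = 1, id = paste0("planted_", seed)) {
  set.seed(seed)
  bases <- sample(c("A", "T"), length, replace = TRUE)
  mot <- strsplit(motif, "")[[1]]
  for (p in positions) bases[(p + 1):(p + nchar(motif))] <- mot
  sequence_record(id, paste(bases, collapse = ""))
}

# Naive double-strand sliding-window motif scan (independent oracle):
# compares every length-m window against the motif and its reverse
# complement via vectorized substring extraction.
naive_scan <- function(seq_string, motif) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  m <- nchar(motif)
  starts <- seq_len(nchar(seq_string) - m + 1)
  windows <- substring(seq_string, starts, starts + m - 1)
  hits <- starts[windows == motif | windows == rc(motif)]
  sort(unique(hits)) - 1
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random valid molecule set for round-trip tests.
random_bnx <- function(n_mol, seed = 1) {
  set.seed(seed)
  mols <- lapply(seq_len(n_mol), function(k) {
    len <- round(runif(1, 1e5, 3e5), 1)
    nl <- rpois(1, 15)
    labs <- round(sort(runif(nl, 0, len)), 1)
    label_map(sprintf("mol_%04d", k), len, labs, source = "simulation")
  })
  bnx_dataset(mols, header = c(run = "test", bpp = "500"))
}

zero_noise <- noise_model_none()
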