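test_that("find_motif_sites reports pooled double-strand hits, 0-based", {
  expect_equal(find_motif_sites(sequence_record("x", "GCTCTTC"), "GCTCTTC"), 0)
  # reverse-complement occurrence reported at its forward-strand position
  expect_equal(find_motif_sites(sequence_record("x", "GAAGAGC"), "GCTCTTC"), 0)
  expect_equal(find_motif_sites(sequence_record("x", "TTGCTCTTCTT"), "GCTCTTC"), 2)
  expect_error(find_motif_sites(sequence_record("x", "ACGT"), "GCNCTTC"),
               "only A, C, G, T")
})

test_that("motif windows containing N never match", {
  expect_length(find_motif_sites(sequence_record("x", "GCTNTTC"), "GCTCTTC"), 0)
  s <- paste0("GCTCTTC", "N", "GCTCTTC")
  expect_equal(find_motif_sites(sequence_record("x", s), "GCTCTTC"), c(0, 8))
})

test_that("find_motif_sites equals the naive double-strand scan oracle", {
  set.seed(11)
  for (k in 1:25) {
    s <- random_dna(2000, gc = runif(1, 0.3, 0.6))
    expect_equal(find_motif_sites(sequence_record("r", s), "GCTCTTC"),
                 naive_scan(s, "GCTCTTC"))
  }
  # short motif with overlapping and palindromic-adjacent hits
  for (k in 1:10) {
    s <- random_dna(500, gc = 0.5)
    expect_equal(find_motif_sites(sequence_record("r", s), "GCGC"),
                 naive_scan(s, "GCGC"))
  }
})

test_that("nick_density follows the per-100-kb definition", {
  expect_equal(nick_density(137, 1e6), 13.7)
  expect_equal(nick_density(0, 5e5), 0)
  expect_error(nick_density(10, 0), "> 0")
})

test_that("apply_resolution merges sub-resolution chains at midpoints", {
  expect_equal(apply_resolution(c(1000, 2000), 500), c(1000, 2000))
  expect_equal(apply_resolution(c(1000, 1400), 500), 1200)
  # gap of exactly the resolution is NOT merged (strict comparison)
  expect_equal(apply_resolution(c(1000, 1400, 1900), 500), c(1200, 1900))
  expect_equal(apply_resolution(numeric(0), 500), numeric(0))
  # chain of three collapses to the midpoint of its extremes
  expect_equal(apply_resolution(c(100, 450, 800), 500), 450)
})

test_that("apply_resolution is idempotent with all gaps >= resolution", {
  set.seed(21)
  for (k in 1:20) {
    pos <- sort(runif(60, 0, 1e5))
    out <- apply_resolution(pos, 500)
    expect_true(all(diff(out) >= 500))
    expect_equal(apply_resolution(out, 500), out)
    expect_true(length(out) <= length(pos))
  }
})

test_that("digest_sequences counts planted motifs and pools aggregates", {
  gen0 <- sequence_record("empty", paste(rep("AT", 2500), collapse = ""))
  dig0 <- digest_sequences(list(gen0))
  expect_length(dig0$maps$maps[[1]]$labels, 0)
  expect_equal(dig0$aggregate$label_density, 0)

  pos <- seq(1000, 46000, by = 3000)  # 16 well-spaced sites in 50 kb
  gen <- planted_genome(pos)
  dig <- digest_sequences(list(gen))
  expect_equal(dig$maps$maps[[1]]$labels, pos)
  expect_equal(dig$aggregate$nick_density, 16 / 5e4 * 1e5)
  expect_true(dig$aggregate$label_density <= dig$aggregate$nick_density)
})

test_that("aggregate density is additive over records", {
  genA <- planted_genome(c(1000, 9000, 20000), seed = 2)
  genB <- planted_genome(c(4000, 30000), seed = 3)
  both <- digest_sequences(list(genA, genB))
  cat_seq <- sequence_record("cat", paste0(genA$sequence, genB$sequence))
  # no boundary-spanning motifs: background is AT-only
  dig_cat <- digest_sequences(list(cat_seq))
  expect_equal(both$aggregate$nick_density, dig_cat$aggregate$nick_density)
})

test_that("enzyme_report selects the density closest to the target", {
  single <- enzyme_report(list(planted_genome(c(1000, 9000))),
                          catalog = c(Nt.BspQ1 = "GCTCTTC"))
  expect_equal(single$selected, "Nt.BspQ1")

  # two motifs planted at ~8 and ~25 per 100 kb in one 100-kb genome
  set.seed(5)
  bases <- sample(c("A", "T"), 1e5, replace = TRUE)
  plant <- function(bases, motif, n, offset) {
    pos <- offset + round(seq(0, 99000 - offset, length.out = n))
    for (p in pos) bases[(p + 1):(p + nchar(motif))] <- strsplit(motif, "")[[1]]
    bases
  }
  bases <- plant(bases, "GCTCTTC", 8, 0)
  bases <- plant(bases, "GCAATGC", 25, 500)
  gen <- sequence_record("two_enzyme", paste(bases, collapse = ""))
  rep2 <- enzyme_report(list(gen),
                        catalog = c(sparse = "GCTCTTC", dense = "GCAATGC"),
                        target_density = 10)
  expect_equal(rep2$selected, "sparse")
  expect_true(all(rep2$table$label_density <= rep2$table$nick_density))
})

test_that("fluctuation_band applies the symmetric fractional rule", {
  band <- fluctuation_band(11.0)
  expect_equal(unname(band["lo"]), 9.35)
  expect_equal(unname(band["hi"]), 12.65)
  expect_equal(unname(fluctuation_band(0)), c(0, 0))
  expect_error(fluctuation_band(-1), ">= 0")
})
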