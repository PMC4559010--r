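# Shared fixture: an irregular but comfortably spaced label pattern.
ref_map <- label_map("ref", 200000,
                     c(6000, 18000, 27000, 52000, 71000, 90000, 118000,
                       131000, 158000, 176000, 193000),
                     source = "digest")

test_that("self-alignment pairs every label with ratio exactly 1", {
  q <- label_map("q", ref_map$length, ref_map$labels, source = "digest")
  a <- align_maps(q, ref_map)
  expect_s3_class(a, "map_alignment")
  expect_equal(a$orientation, "+")
  expect_equal(nrow(a$pairs), length(ref_map$labels))
  expect_equal(a$mapping_length_ratio, 1.0)
  expect_true(a$thorough)
  expect_equal(a$n_query_unmatched, 0)
})

test_that("a mirror-image query aligns in reverse orientation, ratio 1", {
  q <- label_map("mirror", ref_map$length,
                 rev(ref_map$length - ref_map$labels), source = "digest")
  a <- align_maps(q, ref_map)
  expect_equal(a$orientation, "-")
  expect_equal(nrow(a$pairs), length(ref_map$labels))
  expect_equal(a$mapping_length_ratio, 1.0)
})

test_that("DP alignment equals exhaustive enumeration on small instances", {
  set.seed(17)
  p <- align_params()
  for (k in 1:60) {
    nq <- sample(2:6, 1); nr <- sample(2:6, 1)
    q <- label_map("q", 60000, sort(runif(nq, 0, 60000)))
    r <- label_map("r", 80000, sort(runif(nr, 0, 80000)))
    bf <- brute_force_align(q, r, p)
    dp <- opmapr:::cpp_align_both(q$labels, r$labels, q$length,
                                  opmapr:::scoring_list(p))
    expect_equal(dp$score, bf$score, tolerance = 1e-9)
  }
})

test_that("brute-force oracle handles its own documented cases", {
  p <- align_params()
  q <- label_map("q", 30000, c(5000, 15000, 25000))
  r <- label_map("r", 30000, c(5000, 15000, 25000))
  bf <- brute_force_align(q, r, p)
  expect_equal(bf$pairs[, 1], 1:3)
  expect_equal(bf$pairs[, 2], 1:3)
  expect_equal(bf$score, 3 * p$match_bonus)
  big <- label_map("big", 1e5, seq(1000, 99000, length.out = 12))
  expect_error(brute_force_align(big, r, p), "size bound")
})

test_that("mapping length ratio follows the half-flanking-gap rule", {
  # query matching ref labels 1..6 plus one distant unmatched decoy label;
  # the aligned span runs from the molecule start (every left label matched)
  # to halfway between the last matched label and the decoy
  decoy <- 195000
  q <- label_map("partial", 200000, c(ref_map$labels[1:6], decoy),
                 source = "digest")
  a <- align_maps(q, ref_map)
  expect_equal(nrow(a$pairs), 6)
  last <- ref_map$labels[6]
  expected <- (last + (decoy - last) / 2) / 200000
  expect_equal(a$mapping_length_ratio, expected)
  expect_false(a$thorough)
  expect_equal(mapping_length_ratio(a, 200000), a$mapping_length_ratio)
})

test_that("batch_align retains only queries with at least 7 labels", {
  set.seed(23)
  qs <- c(
    lapply(1:3, function(k)
      label_map(paste0("small_", k), 60000, sort(runif(5, 0, 60000)))),
    lapply(1:7, function(k) {
      n <- sample(8:11, 1)
      label_map(paste0("big_", k), 150000, sort(runif(n, 0, 150000)) )
    }))
  ba <- batch_align(cmap_dataset(qs), cmap_dataset(list(ref_map)))
  expect_equal(ba$summary$n_queries, 10)
  expect_equal(ba$summary$n_retained, 7)
})

test_that("aligning a map set to itself is 100% thorough", {
  set.seed(29)
  maps <- lapply(1:5, function(k) {
    n <- sample(8:14, 1)
    labs <- sort(runif(n, 0, 2e5))
    labs <- labs[c(TRUE, diff(labs) > 2000)]
    label_map(paste0("m", k), 2e5, labs, source = "assembly")
  })
  ds <- cmap_dataset(maps)
  ba <- batch_align(ds, ds)
  expect_equal(ba$summary$frac_thorough, 1.0)
  expect_true(all(ba$table$ratio == 1.0))
})

test_that("estimators recover truth on a noise-free simulation", {
  g <- simulate_genome(1e6, target_label_density = 11, seed = 50)
  ds <- generate_dataset(g$record, depth = 8, noise = noise_model_none(),
                         seed = 51)
  dig <- label_map("genome", g$record$length, ds$digest$labels)
  p <- align_params()
  alns <- Filter(Negate(is.null),
                 lapply(ds$bnx$molecules, function(m)
                   align_maps(m, dig, p, enforce_min_sites = TRUE)))
  expect_gt(length(alns), 10)
  expect_equal(estimate_fp_rate(alns, p), 0)
  expect_equal(estimate_bpp(alns), 500, tolerance = 1e-6)
  expect_true(all(vapply(alns, function(a) a$mapping_length_ratio, 1) == 1))
})

test_that("estimate_bpp tracks a planted molecule stretch", {
  g <- simulate_genome(1.5e6, target_label_density = 11, seed = 52)
  p <- align_params()
  dig <- digest_sequences(list(g$record))$maps$maps[[1]]
  ref <- label_map("genome", g$record$length, dig$labels)
  for (stretch in c(1.008, 0.99)) {
    nm <- noise_model(stretch_mean = stretch)
    ds <- generate_dataset(g$record, depth = 30, noise = nm, seed = 53)
    alns <- Filter(Negate(is.null),
                   lapply(ds$bnx$molecules, function(m)
                     align_maps(m, ref, p, enforce_min_sites = TRUE)))
    expect_gt(length(alns), 200)
    expect_lt(abs(estimate_bpp(alns) - 500 * stretch), 2.5)
  }
})

test_that("overlap distance is symmetric and zero for identical molecules", {
  set.seed(61)
  ap <- assembly_params()
  mols <- lapply(1:6, function(k) {
    labs <- sort(runif(12, 0, 1.8e5))
    labs <- labs[c(TRUE, diff(labs) > 600)]
    label_map(paste0("m", k), 1.8e5, labs, source = "simulation")
  })
  expect_equal(mol_distance(mols[[1]], mols[[1]], ap), 0)
  for (k in 2:6) {
    d1 <- mol_distance(mols[[1]], mols[[k]], ap)
    d2 <- mol_distance(mols[[k]], mols[[1]], ap)
    expect_equal(d1, d2)
  }
  tiny <- label_map("tiny", 1e5, 50000)
  expect_true(attr(mol_distance(tiny, mols[[1]], ap), "degenerate"))
})
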