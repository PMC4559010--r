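# Fixture: a 1.2-Mb genome, its digest, and molecule makers.
asm_genome <- simulate_genome(1.2e6, target_label_density = 11, seed = 101)
asm_digest <- digest_sequences(list(asm_genome$record))$maps$maps[[1]]

# a window whose true sites are all comfortably resolvable (>= 1.6 kb apart):
# site pairs below twice the kernel bandwidth fuse to their midpoint by
# construction, so exact-recovery checks need well-spaced truth
clean_window_start <- local({
  labs <- asm_digest$labels
  for (s in seq(0, asm_digest$length - 2e5, by = 1e4)) {
    w <- labs[labs >= s & labs < s + 2e5]
    if (length(w) >= 12 && all(diff(w) >= 1600)) return(s)
  }
  stop("fixture genome has no well-spaced window")
})

cut_molecule <- function(s, e, id, flip = FALSE, noise = noise_model_none()) {
  lab <- asm_digest$labels[asm_digest$labels >= s & asm_digest$labels < e] - s
  if (flip) lab <- rev((e - s) - lab)
  corrupt_molecule(lab, e - s, noise, id = id)$molecule
}

region_molecules <- function(lo, hi, depth, tag, noise = noise_model(),
                             seed = 1) {
  set.seed(seed)
  iv <- sample_molecule_intervals(hi - lo, depth, molecule_length_model())
  lapply(seq_len(nrow(iv)), function(k)
    cut_molecule(iv$start[k] + lo, iv$end[k] + lo,
                 sprintf("%s%03d", tag, k), noise = noise))
}

test_that("clustering groups tilings and discards tiny clusters", {
  set.seed(3)
  mols <- lapply(1:5, function(k) cut_molecule(0, 2e5, paste0("c", k)))
  D <- distance_matrix(mols)
  expect_true(all(D[upper.tri(D)] == 0))
  cl <- cluster_molecules(D, assembly_params())
  expect_length(cl$clusters, 1)
  expect_length(cl$clusters[[1]], 5)

  # a cut of 0 over distinct molecules isolates everything
  distinct <- lapply(1:4, function(k)
    cut_molecule((k - 1) * 3e5, (k - 1) * 3e5 + 2e5, paste0("d", k)))
  D2 <- distance_matrix(distinct)
  cl2 <- cluster_molecules(D2, assembly_params(cluster_cut = 0,
                                               min_molecules_per_map = 2))
  expect_length(cl2$clusters, 0)
  expect_length(cl2$discarded, 4)
})

test_that("well-separated regions give two pure clusters", {
  # noise-free molecules: exact gap patterns leave no coincidental chains,
  # so the overlap graph separates the two loci perfectly
  mols_a <- region_molecules(0, 5e5, 10, "A", noise = noise_model_none(),
                             seed = 11)
  mols_b <- region_molecules(7e5, 1.2e6, 10, "B", noise = noise_model_none(),
                             seed = 12)
  G <- overlap_graph(c(mols_a, mols_b), assembly_params())
  cl <- cluster_molecules(G$dist, assembly_params())
  expect_length(cl$clusters, 2)
  n_a <- length(mols_a)
  purity <- vapply(cl$clusters, function(ix)
    max(mean(ix <= n_a), mean(ix > n_a)), numeric(1))
  expect_equal(purity, c(1, 1))
})

test_that("noisy molecules from separate regions assemble into pure maps", {
  # at realistic error rates, label-pattern coincidences occasionally link
  # molecules across loci; the corroborated layout confines them, so the
  # separation guarantee lives at the map level
  mols_a <- region_molecules(0, 5e5, 16, "A", seed = 13)
  mols_b <- region_molecules(7e5, 1.2e6, 16, "B", seed = 14)
  asm <- assemble(bnx_dataset(c(mols_a, mols_b)), assembly_params())
  expect_gte(length(asm$maps), 2)
  pl <- asm$placements
  purity <- vapply(split(pl$molecule, pl$map), function(idv) {
    isA <- startsWith(idv, "A")
    max(mean(isA), 1 - mean(isA))
  }, numeric(1))
  expect_true(all(purity >= 0.95))
})

test_that("noise-free copies anchor at their exact true offsets", {
  starts <- c(0, 30000, 60000, 90000, 120000)
  mols <- lapply(seq_along(starts), function(k)
    cut_molecule(starts[k], starts[k] + 2e5, sprintf("m%d", k)))
  anc <- anchor_cluster(mols, assembly_params())
  expect_length(anc$layouts, 1)
  pl <- anc$layouts[[1]]$placements
  expect_equal(nrow(pl), 5)
  pl <- pl[order(pl$index), ]
  expect_equal(pl$offset - pl$offset[1], starts)
  expect_true(all(pl$orientation == "+"))
})

test_that("a reversed molecule is placed with reverse orientation", {
  mols <- list(cut_molecule(0, 2.2e5, "fwd1"),
               cut_molecule(20000, 2.4e5, "rev1", flip = TRUE),
               cut_molecule(40000, 2.6e5, "fwd2"))
  anc <- anchor_cluster(mols, assembly_params())
  pl <- anc$layouts[[1]]$placements
  expect_equal(nrow(pl), 3)
  expect_equal(pl$orientation[pl$id == "rev1"], "-")
  expect_equal(pl$orientation[pl$id == "fwd1"], "+")
})

test_that("consensus of exact copies reproduces the labels exactly", {
  one <- cut_molecule(clean_window_start, clean_window_start + 2e5, "solo")
  anc1 <- list(placements = data.frame(
    id = "solo", index = 1L, offset = 0, orientation = "+",
    length = one$length, n_labels = length(one$labels),
    stringsAsFactors = FALSE),
    layout_labels = list(one$labels))
  cons1 <- call_consensus(anc1, assembly_params(), id = "m1")
  expect_equal(cons1$map$labels, one$labels)

  mols <- lapply(1:10, function(k)
    cut_molecule(clean_window_start, clean_window_start + 2e5, paste0("c", k)))
  anc <- anchor_cluster(mols, assembly_params())
  cons <- call_consensus(anc$layouts[[1]], assembly_params(), id = "m2")
  expect_equal(cons$map$labels, one$labels)
  expect_true(all(cons$map$support == 10))
})

test_that("consensus from noisy copies recovers every true label", {
  nm <- noise_model(fp_rate = 1.5, fn_prob = 0.15, sizing_sd_scale = 5,
                    stretch_mean = 1, stretch_sd = 0.005)
  set.seed(33)
  lo <- clean_window_start; hi <- clean_window_start + 2e5
  mols <- lapply(1:50, function(k)
    cut_molecule(lo, hi, sprintf("n%02d", k), noise = nm))
  truth <- asm_digest$labels[asm_digest$labels >= lo & asm_digest$labels < hi] - lo
  anc <- anchor_cluster(mols, assembly_params())
  cons <- call_consensus(anc$layouts[[1]], assembly_params(), id = "m")
  # the map's coordinate origin is the noisy layout minimum; estimate the
  # frame shift from nearest-label deltas before measuring per-label error
  shift <- median(vapply(truth, function(x)
    cons$map$labels[which.min(abs(cons$map$labels - x))] - x, numeric(1)))
  found <- vapply(truth + shift, function(x)
    min(abs(cons$map$labels - x)), numeric(1))
  expect_true(all(found <= 1500))
  # spurious labels never clear the support threshold
  spur <- vapply(cons$map$labels, function(x)
    min(abs(truth + shift - x)), numeric(1))
  expect_true(all(spur <= 1500))
  expect_true(all(diff(cons$map$labels) >= 500))
})

test_that("assemble handles empty input and filters short molecules", {
  empty <- assemble(bnx_dataset(), assembly_params())
  expect_length(empty$maps, 0)
  short <- bnx_dataset(list(label_map("s", 5e4, c(1e4, 3e4),
                                      source = "simulation")))
  asm <- assemble(short, assembly_params())
  expect_length(asm$maps, 0)
  expect_equal(asm$set_aside, "s")
})

test_that("zero-noise round trip recovers the genome map", {
  ds <- generate_dataset(asm_genome$record, depth = 40,
                         noise = noise_model_none(), seed = 120)
  asm <- assemble(ds$bnx, assembly_params())
  expect_gte(length(asm$maps), 1)
  lens <- vapply(asm$maps$maps, function(m) m$length, numeric(1))
  expect_lt(abs(sum(lens) - 1.2e6) / 1.2e6, 0.05)
  ev <- evaluate_assembly(asm, ds$truth, ds$digest, tol = 500)
  # true-site pairs below twice the kernel bandwidth fuse to midpoints, so
  # a few labels sit just beyond the one-pixel tolerance even without noise
  expect_gte(ev$frac_recovered, 0.95)
  expect_equal(ev$n_spurious, 0L)
  # deterministic CMAP bytes
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_cmap(asm$maps, p1)
  write_cmap(assemble(ds$bnx, assembly_params())$maps, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("consensus label gaps always respect the optical resolution", {
  ds <- generate_dataset(asm_genome$record, depth = 30, seed = 130)
  asm <- assemble(ds$bnx, assembly_params())
  for (m in asm$maps$maps) {
    if (length(m$labels) > 1) expect_true(all(diff(m$labels) >= 500))
  }
})

test_that("depth titration improves contiguity with coverage", {
  g <- simulate_genome(2e6, target_label_density = 11, seed = 140)
  ds <- generate_dataset(g$record, depth = 42, seed = 141)
  tt <- depth_titration(ds$bnx, genome_size = 2e6, depths = c(10, 40),
                        seeds = c(1, 2), params = assembly_params())
  expect_equal(nrow(tt), 4)
  for (s in c(1, 2)) {
    lo <- tt[tt$depth == 10 & tt$seed == s, ]
    hi <- tt[tt$depth == 40 & tt$seed == s, ]
    expect_gte(hi$n50, lo$n50)
  }
  expect_error(depth_titration(ds$bnx, 2e6, depths = 100),
               "exceeds")
})
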