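#' Assembly parameters
#'
#' Knobs of the consensus-map assembler. Molecules shorter than
#' `min_mol_len` are excluded up front. Pairwise overlap distances gate on
#' a minimum matched-site chain (`min_pairs`): single inter-label gaps
#' separate overlap from coincidence only weakly, so chain length is the
#' discriminating signal. Clustering is agglomerative on the distance
#' matrix; the default single linkage reads clusters as connected
#' components of the molecule overlap graph, the natural grouping for
#' molecules that tile a region while sharing only partial intervals. For
#' large inputs the pairwise stage runs on the `max_scaffold_molecules`
#' longest molecules and the remainder are recruited against the
#' provisional consensus maps.
#'
#' @param min_mol_len Minimum molecule length, bp (default 100,000).
#' @param linkage Hierarchical linkage: `"single"` (default), `"average"`
#'   or `"complete"`.
#' @param cluster_cut Distance cut height in `[0, 1]` (default 0.9).
#' @param kde_bandwidth Gaussian kernel bandwidth for consensus label
#'   density, bp (default 500).
#' @param min_peak_support_frac Fraction of local molecule coverage that
#'   must support a peak (default 0.25).
#' @param min_molecules_per_map Smallest retained cluster (default 3).
#' @param min_pairs Minimum matched sites for a usable pairwise overlap
#'   (default 8).
#' @param max_scaffold_molecules Size cap for the all-pairs stage
#'   (default 1500).
#' @param confirm_edges Apply the overlap-graph edge filters (per-molecule
#'   placement disambiguation, optionally preceded by a mutual
#'   nearest-neighbour prune; default `TRUE`, see [overlap_graph()]).
#' @param mutual_k Optional sparsifier: edges must rank within each
#'   endpoint's `mutual_k` strongest overlaps (default `Inf`, disabled —
#'   partial genuine overlaps rank poorly and over-pruning starves the
#'   layout).
#' @param confirm_offset_tol Offset agreement tolerance for confirmation,
#'   bp (default 5000).
#' @param shared_site_rate Expected mutually observable label sites per bp
#'   of genuine molecule overlap (default 7e-5: an 11-per-100-kb site
#'   density seen by both molecules at 15% label loss each, discounted for
#'   chain trimming by the local aligner), used to predict whether an
#'   implied overlap should have been detected.
#' @param drop_expected_overlaps Reject a rival placement group once the
#'   expected number of missed overlap detections it implies reaches this
#'   value (default 3).
#' @param min_support_ratio During layout growth, the fraction of the
#'   model-expected overlap detections a placement must actually hold as
#'   edges to the placed molecules it lands on (default 0.3).
#' @param refine_rounds Consensus refinement iterations: every molecule is
#'   re-placed directly against its map's consensus and the consensus is
#'   re-called, collapsing progressive-layout chain noise (default 1).
#' @param min_relative_depth Maps whose mean molecule depth falls below
#'   this fraction of the deepest map are dropped as reject-pool residue
#'   (default 0.2).
#' @param align An `align_params` for the pairwise overlap aligner; the
#'   default tightens `max_skip` to 2 — molecule-to-molecule overlaps
#'   rarely need three consecutive skips on a side, and the tighter bound
#'   both curbs coincidental chains and halves the all-pairs cost.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(min_mol_len = 1e5,
                            linkage = c("single", "average", "complete"),
                            cluster_cut = 0.9, kde_bandwidth = 500,
                            min_peak_support_frac = 0.25,
                            min_molecules_per_map = 3L, min_pairs = 8L,
                            max_scaffold_molecules = 1500L,
                            confirm_edges = TRUE, mutual_k = Inf,
                            confirm_offset_tol = 5000,
                            shared_site_rate = 7e-5,
                            drop_expected_overlaps = 3,
                            min_support_ratio = 0.3,
                            refine_rounds = 1L,
                            min_relative_depth = 0.2,
                            align = align_params(max_skip = 2L)) {
  linkage <- match.arg(linkage)
  if (cluster_cut < 0 || cluster_cut > 1) stop("cluster_cut must be in [0, 1]")
  if (min_peak_support_frac < 0 || min_peak_support_frac > 1)
    stop("min_peak_support_frac must be in [0, 1]")
  structure(list(min_mol_len = min_mol_len, linkage = linkage,
                 cluster_cut = cluster_cut, kde_bandwidth = kde_bandwidth,
                 min_peak_support_frac = min_peak_support_frac,
                 min_molecules_per_map = as.integer(min_molecules_per_map),
                 min_pairs = as.integer(min_pairs),
                 max_scaffold_molecules = as.integer(max_scaffold_molecules),
                 confirm_edges = isTRUE(confirm_edges),
                 mutual_k = mutual_k,
                 confirm_offset_tol = confirm_offset_tol,
                 shared_site_rate = shared_site_rate,
                 drop_expected_overlaps = drop_expected_overlaps,
                 min_support_ratio = min_support_ratio,
                 refine_rounds = as.integer(refine_rounds),
                 min_relative_depth = min_relative_depth,
                 align = align),
            class = "assembly_params")
}

#' Overlap distance between two molecules
#'
#' `1 - S / (match_bonus * min(n_A, n_B))` where `S` is the best overlap
#' alignment score over both orientations, clamped to `[0, 1]`. Pairs whose
#' best chain matches fewer than `min_pairs` sites — and molecules with
#' fewer than two labels — get the maximal distance 1 (flagged via the
#' `"degenerate"` attribute in the two-label case).
#'
#' @param mol_a,mol_b `label_map` objects.
#' @param params An `assembly_params`.
#' @return Distance in `[0, 1]`.
#' @export
mol_distance <- function(mol_a, mol_b, params = assembly_params()) {
  if (length(mol_a$labels) < 2 || length(mol_b$labels) < 2)
    return(structure(1, degenerate = TRUE))
  G <- cpp_overlap_graph(list(mol_a$labels, mol_b$labels),
                         c(mol_a$length, mol_b$length),
                         scoring_list(params$align), params$min_pairs)
  G$dist[1, 2]
}

#' Pairwise overlap distance matrix
#'
#' @param molecules List of `label_map` objects.
#' @param params An `assembly_params`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(molecules, params = assembly_params()) {
  overlap_graph(molecules, params, confirm = FALSE)$dist
}

#' Molecule overlap graph with placement disambiguation
#'
#' Computes all pairwise overlap alignments, recording for each qualifying
#' pair the placement transform `x_j = a + b * x_i` (`b = +/-1`) of one
#' molecule into the other's coordinate frame. With `confirm = TRUE`
#' (the assembler's default path) each molecule's edges are grouped into
#' mutually consistent placements — neighbour pairs whose transforms
#' compose within `confirm_offset_tol` — and rival groups are rejected
#' when they imply overlaps with the molecule's main placement group that
#' the detection model says should have been observed but were not, or
#' that directly contradict it. A molecule occupies one locus, so this
#' removes most coincidental pattern-match edges that would otherwise fuse
#' unrelated loci under single linkage.
#'
#' @param molecules List of `label_map` objects.
#' @param params An `assembly_params`.
#' @param confirm Apply the edge filters.
#' @return List: `dist` (symmetric matrix, rejected or non-qualifying
#'   pairs at 1), `a`, `b` (transform matrices, `NA` where no edge), and
#'   `lens` (molecule lengths).
#' @export
overlap_graph <- function(molecules, params = assembly_params(),
                          confirm = params$confirm_edges) {
  labs <- lapply(molecules, function(m) m$labels)
  lens <- vapply(molecules, function(m) m$length, numeric(1))
  G <- cpp_overlap_graph(labs, lens, scoring_list(params$align),
                         params$min_pairs)
  ids <- vapply(molecules, function(m) m$id, character(1))
  dimnames(G$dist) <- list(ids, ids)
  G$lens <- lens
  if (confirm && nrow(G$dist) > 2) G <- confirm_overlap_edges(G, params)
  G
}

# Edge filtering: per-molecule placement disambiguation.
#
# A molecule occupies one genomic locus, so all of its genuine overlap
# edges describe one coherent placement; a coincidental pattern match
# describes a different, incompatible one. For each molecule the edges are
# grouped into mutually compatible placements and only the group with the
# most total support is kept. Two edges (i,j) and (i,k) are compatible
# when j and k are themselves adjacent with a transform that composes to
# the direct one (within confirm_offset_tol), or when the intervals of i
# they claim barely overlap (below the detectable-overlap span), so that
# their silence about each other is expected. Adjacent-but-inconsistent
# and overlapping-but-unacquainted pairs conflict. An edge survives only
# if both endpoints keep it. An optional mutual k-nearest-neighbour prune
# (mutual_k) sparsifies the graph first.
confirm_overlap_edges <- function(G, params) {
  A <- G$a; B <- G$b; D <- G$dist
  n <- nrow(D)
  adj <- !is.na(B)
  k_mut <- params$mutual_k
  if (is.finite(k_mut) && k_mut >= 1) {
    keep_rank <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (!length(nb)) next
      d <- D[i, nb]
      thr <- sort(d)[min(k_mut, length(d))]
      keep_rank[i, nb[d <= thr + 1e-12]] <- TRUE
    }
    mutual <- keep_rank & t(keep_rank)
    kill <- adj & !mutual
    D[kill] <- 1; A[kill] <- NA_real_; B[kill] <- NA_real_
    adj <- adj & mutual
  }

  lens <- G$lens
  tol <- params$confirm_offset_tol
  shared_rate <- params$shared_site_rate
  e_drop <- params$drop_expected_overlaps
  mp <- params$min_pairs
  keep <- adj
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    m <- length(nb)
    if (m < 2) next
    # interval of molecule i claimed by each neighbour, in i's frame
    a_i <- A[i, nb]; b_i <- B[i, nb]
    lo <- ifelse(b_i > 0, -a_i, a_i - lens[nb])
    hi <- ifelse(b_i > 0, lens[nb] - a_i, a_i)
    lo <- pmax(lo, 0); hi <- pmin(hi, lens[i])
    ov <- pmax(outer(hi, hi, pmin) - outer(lo, lo, pmax), 0)
    adj_nb <- adj[nb, nb, drop = FALSE]
    a_nb <- A[nb, nb, drop = FALSE]; b_nb <- B[nb, nb, drop = FALSE]
    # transform agreement for adjacent neighbour pairs: T_jk o T_ij vs T_ik
    b_comp <- b_nb * matrix(b_i, m, m)
    a_comp <- a_nb + b_nb * matrix(a_i, m, m)
    consistent <- adj_nb & (b_comp == matrix(b_i, m, m, byrow = TRUE)) &
      (abs(a_comp - matrix(a_i, m, m, byrow = TRUE)) <= tol)
    consistent <- consistent | t(consistent)
    diag(consistent) <- TRUE
    # placement groups: components linked by consistent neighbour pairs
    comp <- seq_len(m)
    repeat {
      M <- matrix(comp, m, m, byrow = TRUE)
      M[!consistent] <- NA_integer_
      new <- as.integer(pmin(apply(M, 1, min, na.rm = TRUE), comp))
      if (identical(new, comp)) break
      comp <- new
    }
    w <- vapply(split(1 - D[i, nb], comp), sum, numeric(1))
    best <- as.integer(names(w)[order(-w, as.integer(names(w)))[1]])
    main <- comp == best
    if (all(main)) next
    # a rival group is rejected when its claims imply overlaps with the
    # main group that should have been detected but were not, or directly
    # contradict it
    for (cid in unique(comp[!main])) {
      mem <- comp == cid
      ov_cross <- ov[mem, main, drop = FALSE]
      adj_cross <- adj_nb[mem, main, drop = FALSE]
      e_missing <- sum(ppois(mp - 1, shared_rate * ov_cross[!adj_cross],
                             lower.tail = FALSE))
      n_contra <- sum(adj_cross & !consistent[mem, main, drop = FALSE])
      if (e_missing >= e_drop || n_contra >= 3)
        keep[i, nb[mem]] <- FALSE
    }
  }
  kill <- adj & !(keep & t(keep))
  D[kill] <- 1; A[kill] <- NA_real_; B[kill] <- NA_real_
  list(dist = D, a = A, b = B, lens = lens)
}

#' Cluster molecules on a distance matrix
#'
#' Agglomerative hierarchical clustering with the configured linkage, cut
#' at `cluster_cut`; clusters smaller than `min_molecules_per_map` are
#' discarded. Retained clusters are ordered by size (descending), ties by
#' smallest member index.
#'
#' @param D Square symmetric distance matrix.
#' @param params An `assembly_params`.
#' @return List: `clusters` (list of integer index vectors) and
#'   `discarded` (integer vector of indices in no retained cluster).
#' @export
cluster_molecules <- function(D, params = assembly_params()) {
  n <- nrow(D)
  if (n == 0) return(list(clusters = list(), discarded = integer(0)))
  memb <- if (n == 1) 1L else {
    hc <- hclust(as.dist(D), method = params$linkage)
    cutree(hc, h = params$cluster_cut)
  }
  cl <- split(seq_len(n), memb)
  keep <- vapply(cl, length, integer(1)) >= params$min_molecules_per_map
  clusters <- unname(cl[keep])
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]
  list(clusters = clusters,
       discarded = sort(unlist(unname(cl[!keep]), use.names = FALSE)))
}

# Align a molecule against reference labels already in layout coordinates;
# returns placement (offset, orientation, layout labels) or NULL.
place_against <- function(mol, ref_labels, params) {
  if (length(mol$labels) < 2 || length(ref_labels) < 2) return(NULL)
  res <- cpp_align_both(mol$labels, ref_labels, mol$length,
                        scoring_list(params$align))
  if (length(res$qi) < params$min_pairs) return(NULL)
  qpos <- norm_positions(mol$labels, mol$length, res$orientation)
  offset <- median(ref_labels[res$ri] - qpos[res$qi])
  list(offset = offset, orientation = res$orientation,
       layout_labels = qpos + offset, score = res$score,
       n_pairs = length(res$qi))
}

# Joint offset estimation on a layout: weighted least squares over the
# pairwise edge constraints o_j - o_i = c_e implied by the overlap-graph
# transforms and the assigned orientations, with iterative trimming of
# outlier edges. Solved per connected component with the first member of
# each component pinned at its progressive-layout offset (the gauge).
sync_offsets <- function(rows, placements, G, params) {
  n <- length(rows)
  o0 <- placements$offset
  B <- G$b[rows, rows, drop = FALSE]
  A <- G$a[rows, rows, drop = FALSE]
  Dm <- G$dist[rows, rows, drop = FALSE]
  L <- placements$length
  sgn <- placements$orientation
  e <- which(!is.na(B) & upper.tri(B), arr.ind = TRUE)
  if (nrow(e) < 2) return(o0)
  i <- e[, 1]; j <- e[, 2]
  b <- B[e]; a <- A[e]
  same <- sgn[i] == sgn[j]
  ok <- ifelse(same, b == 1, b == -1)
  c_e <- ifelse(sgn[i] == "+" & sgn[j] == "+", -a,
         ifelse(sgn[i] == "+" & sgn[j] == "-", a - L[j],
         ifelse(sgn[i] == "-" & sgn[j] == "+", L[i] - a,
                L[i] - L[j] + a)))
  w <- (1 - Dm[e])
  i <- i[ok]; j <- j[ok]; c_e <- c_e[ok]; w <- w[ok]
  if (length(i) < 2) return(o0)
  # drop edges wildly inconsistent with the progressive layout up front
  sane <- abs(o0[j] - o0[i] - c_e) < 10 * params$confirm_offset_tol
  i <- i[sane]; j <- j[sane]; c_e <- c_e[sane]; w <- w[sane]
  if (length(i) < 2) return(o0)

  solve_once <- function(i, j, c_e, w) {
    # union-find components over the current edge set
    comp <- seq_len(n)
    find <- function(x) {
      while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }
      x
    }
    for (ee in seq_along(i)) {
      r1 <- find(i[ee]); r2 <- find(j[ee])
      if (r1 != r2) comp[r1] <- r2
    }
    comp <- vapply(seq_len(n), find, integer(1))
    Wm <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(w, 2),
                               dims = c(n, n))
    Lap <- Matrix::Diagonal(x = Matrix::rowSums(Wm)) - Wm
    rhs <- numeric(n)
    tmp <- rowsum(c(-w * c_e, w * c_e), group = c(i, j))
    rhs[as.integer(rownames(tmp))] <- tmp[, 1]
    # pin the first node of every component at its current offset
    pins <- vapply(split(seq_len(n), comp), min, integer(1))
    for (pp in pins) {
      Lap[pp, ] <- 0; Lap[pp, pp] <- 1; rhs[pp] <- o0[pp]
    }
    tryCatch(as.numeric(Matrix::solve(Lap, rhs)),
             error = function(err) NULL)
  }

  o <- o0
  for (iter in 1:3) {
    sol <- solve_once(i, j, c_e, w)
    if (is.null(sol) || anyNA(sol)) return(o)
    o <- sol
    resid <- o[j] - o[i] - c_e
    bad <- abs(resid) > 2 * params$confirm_offset_tol
    if (!any(bad)) break
    i <- i[!bad]; j <- j[!bad]; c_e <- c_e[!bad]; w <- w[!bad]
    if (length(i) < 2) break
  }
  o
}

#' Lay out a cluster of molecules on shared axes
#'
#' Progressive, corroborated layout. The longest unassigned molecule
#' (ties by id) seeds a coordinate frame; remaining molecules join
#' best-first — at each step the unplaced molecule closest (by overlap
#' distance) to the placed set is aligned against its nearest placed
#' neighbours and placed at the median matched offset, in the orientation
#' the aligner selects. Once three molecules are placed, every further
#' placement must be corroborated: a second, independent placed neighbour
#' with an overlap edge to the candidate must agree on its position within
#' `confirm_offset_tol`. A coincidental pattern match proposes a position
#' no independent neighbour agrees with, so chimeric joins stall instead
#' of growing; when growth stalls, the layout is closed and the next seed
#' starts a new one. Layouts smaller than `min_molecules_per_map` are
#' dissolved (their molecules may join later layouts).
#'
#' @param molecules List of `label_map` objects (one cluster).
#' @param params An `assembly_params`.
#' @param D Optional precomputed (confirmed) distance matrix for the
#'   cluster.
#' @return List: `layouts` — one entry per layout, each with `placements`
#'   (data.frame: id, index, offset, orientation, length, n_labels) and
#'   `layout_labels` (list, per placement) — and `set_aside` (indices in
#'   no layout).
#' @export
anchor_cluster <- function(molecules, params = assembly_params(), D = NULL) {
  n <- length(molecules)
  if (n == 0) return(list(layouts = list(), set_aside = integer(0)))
  if (is.null(D)) D <- overlap_graph(molecules, params)$dist
  lens <- vapply(molecules, function(m) m$length, numeric(1))
  ids <- vapply(molecules, function(m) m$id, character(1))
  tol <- params$confirm_offset_tol

  unassigned <- rep(TRUE, n)
  seed_barred <- rep(FALSE, n)
  layouts <- list()

  while (sum(unassigned) >= max(params$min_molecules_per_map, 1)) {
    seedable <- which(unassigned & !seed_barred)
    if (!length(seedable)) break
    seed <- seedable[order(-lens[seedable], ids[seedable])[1]]

    placed <- rep(FALSE, n)
    offset <- rep(NA_real_, n); orient <- rep(NA_character_, n)
    layout <- vector("list", n)
    placed[seed] <- TRUE
    offset[seed] <- 0; orient[seed] <- "+"
    layout[[seed]] <- molecules[[seed]]$labels
    best_d <- D[, seed]
    deferred <- rep(FALSE, n)  # failed once; retried after any new placement

    repeat {
      cand <- which(unassigned & !placed & !deferred)
      cand <- cand[is.finite(best_d[cand]) & best_d[cand] <= params$cluster_cut]
      if (!length(cand)) break
      k <- cand[order(best_d[cand], -lens[cand], ids[cand])[1]]
      partners <- which(placed & D[, k] <= params$cluster_cut)
      partners <- partners[order(D[partners, k])]
      pl <- NULL
      for (p in head(partners, 3L)) {
        pl <- place_against(molecules[[k]], layout[[p]], params)
        if (!is.null(pl)) { partners <- partners[partners != p]; break }
      }
      ok <- !is.null(pl)
      if (ok && sum(placed) >= 3) {
        ok <- FALSE
        for (q in head(partners, 5L)) {
          pl2 <- place_against(molecules[[k]], layout[[q]], params)
          if (!is.null(pl2) && pl2$orientation == pl$orientation &&
              abs(pl2$offset - pl$offset) <= tol) { ok <- TRUE; break }
        }
      }
      # support veto: landing amid placed coverage, the candidate must hold
      # edges to about as many of those molecules as the detection model
      # expects; a molecule following a coincidental bridgehead overlaps
      # many placed molecules it has never aligned to
      if (ok && sum(placed) >= 5) {
        pidx <- which(placed)
        ov <- pmin(offset[pidx] + lens[pidx], pl$offset + lens[k]) -
          pmax(offset[pidx], pl$offset)
        ov <- pmax(ov, 0)
        p_det <- ppois(params$min_pairs - 1, params$shared_site_rate * ov,
                       lower.tail = FALSE)
        expected <- sum(p_det)
        observed <- sum(D[pidx, k] <= params$cluster_cut & ov > 0)
        if (expected >= 4 && observed < params$min_support_ratio * expected)
          ok <- FALSE
      }
      if (!ok) { deferred[k] <- TRUE; next }
      placed[k] <- TRUE
      offset[k] <- pl$offset; orient[k] <- pl$orientation
      layout[[k]] <- pl$layout_labels
      best_d <- pmin(best_d, D[, k])
      deferred[] <- FALSE
    }

    idx <- which(placed)
    if (length(idx) >= params$min_molecules_per_map) {
      layouts[[length(layouts) + 1L]] <- list(
        placements = data.frame(
          id = ids[idx], index = idx, offset = offset[idx],
          orientation = orient[idx], length = lens[idx],
          n_labels = vapply(molecules[idx], function(m) length(m$labels),
                            integer(1)),
          stringsAsFactors = FALSE),
        layout_labels = layout[idx])
      unassigned[idx] <- FALSE
    } else {
      seed_barred[seed] <- TRUE   # reseed elsewhere; molecules stay available
    }
  }
  list(layouts = layouts, set_aside = which(unassigned))
}

#' Call a consensus map from anchored molecules
#'
#' Pools anchored label positions, fits a Gaussian kernel density
#' (bandwidth `kde_bandwidth`), and calls local maxima as consensus labels.
#' A peak must be supported by at least `min_peak_support_frac` of the
#' molecules covering its position (each supporting molecule contributes a
#' label within two bandwidths, the width label clouds reach once
#' accumulated sizing error is in play); peak positions are refined to the
#' median of the labels within one bandwidth of the density maximum;
#' peaks closer than the optical resolution merge,
#' keeping the better-supported one. Map coordinates are shifted so the
#' layout starts at zero.
#'
#' @param anchored Result of [anchor_cluster()].
#' @param params An `assembly_params`.
#' @param id Map id.
#' @return List: `map` (a `label_map` with per-label `support`),
#'   `mean_depth`, and `shift` (layout coordinate of map position 0).
#' @export
call_consensus <- function(anchored, params = assembly_params(), id = "map_1") {
  pl <- anchored$placements
  if (is.null(pl) || !nrow(pl)) stop("no anchored molecules")
  spans_lo <- pl$offset
  spans_hi <- pl$offset + pl$length
  # trim to two-molecule coverage: a map end carried by a single molecule
  # is that molecule's private opinion, not consensus
  if (nrow(pl) >= 2) {
    lo <- sort(spans_lo)[2]; hi <- sort(spans_hi, decreasing = TRUE)[2]
    if (hi <= lo) { lo <- min(spans_lo); hi <- max(spans_hi) }
  } else {
    lo <- min(spans_lo); hi <- max(spans_hi)
  }
  all_lab <- unlist(anchored$layout_labels, use.names = FALSE)
  mol_of <- rep.int(seq_len(nrow(pl)),
                    vapply(anchored$layout_labels, length, integer(1)))
  ord <- order(all_lab)
  all_lab <- all_lab[ord]; mol_of <- mol_of[ord]

  bw <- params$kde_bandwidth
  ngrid <- 2^max(9, ceiling(log2((hi - lo) / 50)))
  den <- density(all_lab, bw = bw, from = lo, to = hi, n = ngrid)
  y <- den$y
  pk <- which(y > head(c(-Inf, y), -1) & y >= c(y[-1], -Inf))
  pk_x <- den$x[pk]

  pos <- numeric(0); sup <- integer(0)
  win <- 2 * bw   # support window: label clouds widen with sizing error
  for (x in pk_x) {
    i1 <- findInterval(x - win, all_lab) + 1L
    i2 <- findInterval(x + win, all_lab)
    if (i2 < i1) next
    mols <- unique(mol_of[i1:i2])
    coverage <- sum(spans_lo <= x & spans_hi >= x)
    if (length(mols) >= max(1, params$min_peak_support_frac * coverage)) {
      j1 <- findInterval(x - bw, all_lab) + 1L   # position from the core
      j2 <- findInterval(x + bw, all_lab)
      core <- if (j2 >= j1) all_lab[j1:j2] else all_lab[i1:i2]
      pos <- c(pos, median(core))
      sup <- c(sup, length(mols))
    }
  }
  # merge peaks below the optical resolution, better-supported first
  res_bp <- params$align$resolution_bp
  keep <- rep(TRUE, length(pos))
  for (i in order(-sup, pos)) {
    if (!keep[i]) next
    close_by <- which(keep & abs(pos - pos[i]) < res_bp)
    keep[setdiff(close_by, i)] <- FALSE
  }
  pos <- pos[keep]; sup <- sup[keep]
  ord <- order(pos)
  pos <- pos[ord]; sup <- sup[ord]
  inside <- pos >= lo & pos <= hi
  pos <- pos[inside]; sup <- sup[inside]
  pos <- pmin(pmax(pos - lo, 0), hi - lo)

  map <- label_map(id, hi - lo, pos, source = "assembly",
                   support = as.integer(sup))
  list(map = map, mean_depth = sum(pl$length) / (hi - lo), shift = lo)
}

#' Assemble consensus genome maps from molecules
#'
#' The full assembler: filter molecules (length, at least two labels),
#' compute pairwise overlap distances on the scaffold set (the longest
#' `max_scaffold_molecules` molecules), cluster, lay out each retained
#' cluster progressively, then recruit any remaining molecules against the
#' provisional consensus maps and recall the consensus with everything
#' placed. Deterministic given the input order and parameters.
#'
#' @param dataset A `bnx_dataset`.
#' @param params An `assembly_params`.
#' @return An object of class `map_assembly`: `maps` (a `cmap_dataset`),
#'   `placements` (data.frame: molecule id, map id, offset in map
#'   coordinates, orientation), `mean_depths`, `set_aside` (molecule ids
#'   not placed), and `n_input`.
#' @export
assemble <- function(dataset, params = assembly_params()) {
  mols <- dataset$molecules
  keep <- vapply(mols, function(m) m$length >= params$min_mol_len &&
                   length(m$labels) >= 2, logical(1))
  aside_ids <- vapply(mols[!keep], function(m) m$id, character(1))
  mols <- mols[keep]
  if (!length(mols))
    return(structure(list(maps = cmap_dataset(), placements = NULL,
                          mean_depths = numeric(0), set_aside = aside_ids,
                          n_input = length(dataset$molecules)),
                     class = "map_assembly"))

  lens <- vapply(mols, function(m) m$length, numeric(1))
  ids <- vapply(mols, function(m) m$id, character(1))
  scaf <- order(-lens, ids)[seq_len(min(length(mols), params$max_scaffold_molecules))]
  scaf <- sort(scaf)
  rest <- setdiff(seq_along(mols), scaf)

  G <- overlap_graph(mols[scaf], params)
  D <- G$dist
  cl <- cluster_molecules(D, params)
  aside_ids <- c(aside_ids, ids[scaf[cl$discarded]])

  maps <- list(); placements <- list(); depths <- numeric(0)
  anchors <- list()
  for (ci in seq_along(cl$clusters)) {
    idx <- cl$clusters[[ci]]
    anc <- anchor_cluster(mols[scaf[idx]], params, D = D[idx, idx, drop = FALSE])
    if (length(anc$set_aside))
      aside_ids <- c(aside_ids, ids[scaf[idx[anc$set_aside]]])
    for (lay in anc$layouts) {
      lay$placements$index <- scaf[idx[lay$placements$index]]
      anchors[[length(anchors) + 1L]] <- lay
    }
  }

  # globally synchronize scaffold offsets: progressive growth accumulates
  # drift and leaves seams where growth fronts meet; solving all offsets
  # jointly from the pairwise edge transforms removes the seams
  for (ci in seq_along(anchors)) {
    a <- anchors[[ci]]
    rows <- match(a$placements$index, scaf)
    if (anyNA(rows) || nrow(a$placements) < 3) next
    o_new <- sync_offsets(rows, a$placements, G, params)
    a$placements$offset <- o_new
    a$layout_labels <- lapply(seq_len(nrow(a$placements)), function(r) {
      k <- a$placements$index[r]
      norm_positions(mols[[k]]$labels, lens[k], a$placements$orientation[r]) +
        a$placements$offset[r]
    })
    anchors[[ci]] <- a
  }

  # dissolve redundant layouts: when a smaller layout's provisional
  # consensus aligns onto a larger one, the two describe the same locus
  # (growth stalled and reseeded over covered ground); its molecules are
  # demoted to the recruitment pool and re-placed against the retained map
  if (length(anchors) > 1) {
    sizes <- vapply(anchors, function(a) nrow(a$placements), integer(1))
    ord <- order(-sizes)
    retained <- list(); retained_cons <- list()
    for (ci in ord) {
      cons <- call_consensus(anchors[[ci]], params, id = "prov")
      redundant <- FALSE
      for (rc in retained_cons) {
        a <- align_maps(cons$map, rc$map, params$align)
        if (!is.null(a) && nrow(a$pairs) >= params$min_pairs &&
            a$mapping_length_ratio >= 0.3) { redundant <- TRUE; break }
      }
      if (redundant) {
        rest <- c(rest, anchors[[ci]]$placements$index)
      } else {
        retained[[length(retained) + 1L]] <- anchors[[ci]]
        retained_cons[[length(retained_cons) + 1L]] <- cons
      }
    }
    anchors <- retained
    rest <- sort(rest)
  }

  # recruit molecules outside the scaffold set against provisional consensi
  if (length(rest) && length(anchors)) {
    prov <- lapply(seq_along(anchors), function(ci)
      call_consensus(anchors[[ci]], params, id = sprintf("prov_%d", ci)))
    sl <- scoring_list(params$align)
    rest_labs <- lapply(mols[rest], function(m) m$labels)
    by_map <- lapply(prov, function(pv)
      cpp_place_batch(rest_labs, lens[rest], pv$map$labels + pv$shift, sl,
                      params$min_pairs))
    sc <- vapply(by_map, function(z) {
      s <- z$score; s[is.na(z$offset)] <- -Inf; s
    }, numeric(length(rest)))
    sc <- matrix(sc, nrow = length(rest))
    best_ci <- max.col(sc, ties.method = "first")
    placeable <- is.finite(sc[cbind(seq_along(rest), best_ci)])
    aside_ids <- c(aside_ids, ids[rest[!placeable]])
    for (r in which(placeable)) {
      k <- rest[r]; ci <- best_ci[r]
      z <- by_map[[ci]]
      qpos <- norm_positions(mols[[k]]$labels, lens[k], z$orientation[r])
      a <- anchors[[ci]]
      a$placements <- rbind(a$placements, data.frame(
        id = ids[k], index = k, offset = z$offset[r],
        orientation = z$orientation[r], length = lens[k],
        n_labels = length(mols[[k]]$labels), stringsAsFactors = FALSE))
      a$layout_labels <- c(a$layout_labels, list(qpos + z$offset[r]))
      anchors[[ci]] <- a
    }
  }

  # consensus refinement: offsets estimated along the progressive layout
  # accumulate chain noise; re-placing every molecule directly against the
  # first-pass consensus collapses that scatter to single-alignment error,
  # and the consensus is then re-called from the tightened layout
  sl <- scoring_list(params$align)
  for (round in seq_len(params$refine_rounds)) {
    for (ci in seq_along(anchors)) {
      a <- anchors[[ci]]
      cons0 <- call_consensus(a, params, id = "refine")
      ref_labels <- cons0$map$labels + cons0$shift
      labs <- lapply(a$placements$index, function(k) mols[[k]]$labels)
      z <- cpp_place_batch(labs, a$placements$length, ref_labels, sl,
                           params$min_pairs)
      upd <- !is.na(z$offset)   # failures keep their progressive placement
      a$placements$offset[upd] <- z$offset[upd]
      a$placements$orientation[upd] <- z$orientation[upd]
      a$layout_labels <- lapply(seq_len(nrow(a$placements)), function(r) {
        k <- a$placements$index[r]
        norm_positions(mols[[k]]$labels, lens[k], a$placements$orientation[r]) +
          a$placements$offset[r]
      })
      anchors[[ci]] <- a
    }
    anchors <- anchors[vapply(anchors, function(a)
      nrow(a$placements) >= params$min_molecules_per_map, logical(1))]
  }

  cons_all <- lapply(seq_along(anchors), function(ci)
    call_consensus(anchors[[ci]], params, id = sprintf("tmp_%d", ci)))
  dep_all <- vapply(cons_all, function(z) z$mean_depth, numeric(1))
  # drop sparse residue maps: layouts assembled from the reject pool carry a
  # small fraction of the coverage the surrounding assembly achieves
  keep_map <- dep_all >= params$min_relative_depth * max(dep_all, 0)
  for (ci in which(!keep_map))
    aside_ids <- c(aside_ids, anchors[[ci]]$placements$id)
  anchors <- anchors[keep_map]
  cons_all <- cons_all[keep_map]

  for (ci in seq_along(anchors)) {
    id <- sprintf("map_%03d", ci)
    cons <- cons_all[[ci]]
    cons$map$id <- id
    maps[[length(maps) + 1L]] <- cons$map
    depths <- c(depths, cons$mean_depth)
    pl <- anchors[[ci]]$placements
    placements[[length(placements) + 1L]] <- data.frame(
      molecule = pl$id, map = id, offset = pl$offset - cons$shift,
      orientation = pl$orientation, stringsAsFactors = FALSE)
  }

  structure(list(
    maps = cmap_dataset(maps, header = c(
      n_molecules = as.character(length(dataset$molecules)),
      min_mol_len = as.character(params$min_mol_len))),
    placements = if (length(placements)) do.call(rbind, placements) else NULL,
    mean_depths = depths,
    set_aside = unname(aside_ids),
    n_input = length(dataset$molecules)),
    class = "map_assembly")
}

#' @export
print.map_assembly <- function(x, ...) {
  lens <- map_lengths(x$maps)
  cat(sprintf("<map_assembly> %d maps, %.2f Mb total, N50 %.0f kb; %d/%d molecules placed\n",
              length(x$maps), sum(lens) / 1e6,
              if (length(lens)) n50(lens) / 1e3 else 0,
              if (!is.null(x$placements)) nrow(x$placements) else 0, x$n_input))
  invisible(x)
}

#' Depth titration of the assembly
#'
#' Re-assembles length-matched random subsets of the molecules at each
#' requested depth and records map N50 and map count, charting how molecule
#' coverage drives assembly contiguity.
#'
#' @param dataset A `bnx_dataset`.
#' @param genome_size Genome size in bp (converts depth to total length).
#' @param depths Numeric vector of target fold-coverages.
#' @param seeds Integer vector of subsampling seeds (one replicate per
#'   seed).
#' @param params An `assembly_params`.
#' @return A data.frame: depth, seed, n_maps, total_length, n50.
#' @export
depth_titration <- function(dataset, genome_size, depths, seeds = 1L,
                            params = assembly_params()) {
  total <- sum(vapply(dataset$molecules, function(m) m$length, numeric(1)))
  if (max(depths) * genome_size > total)
    stop("requested depth exceeds the dataset's total molecule length")
  rows <- list()
  for (seed in seeds) {
    for (d in depths) {
      set.seed(seed)
      ord <- sample.int(length(dataset$molecules))
      lens <- vapply(dataset$molecules[ord], function(m) m$length, numeric(1))
      take <- ord[cumsum(lens) <= d * genome_size |
                    seq_along(ord) == 1L]
      sub <- bnx_dataset(dataset$molecules[sort(take)], dataset$header)
      asm <- assemble(sub, params)
      ml <- map_lengths(asm$maps)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, seed = seed, n_maps = length(ml),
        total_length = sum(ml),
        n50 = if (length(ml)) n50(ml) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate an assembly against simulation truth
#'
#' Uses the truth table to predict, for every true digest label covered by
#' placed molecules, where the label should sit in map coordinates (median
#' over covering molecules of the composed strand/orientation transform),
#' then scores consensus sensitivity (true labels with a consensus label
#' within `tol`) and precision (consensus labels near a predicted true
#' label), plus the spurious-consensus-label rate per 100 kb.
#'
#' @param assembly A `map_assembly`.
#' @param truth Truth data.frame from [generate_dataset()].
#' @param digest The true genome `label_map`.
#' @param tol Matching tolerance in bp (default 1500).
#' @return List: `n_true_covered`, `frac_recovered`, `n_consensus`,
#'   `n_spurious`, `spurious_per_100kb`, `max_abs_error` (largest
#'   recovered-label discrepancy), `total_length`.
#' @export
evaluate_assembly <- function(assembly, truth, digest, tol = 1500) {
  stopifnot(inherits(assembly, "map_assembly"))
  pl <- assembly$placements
  if (is.null(pl) || !nrow(pl))
    return(list(n_true_covered = 0L, frac_recovered = NA_real_,
                n_consensus = 0L, n_spurious = 0L,
                spurious_per_100kb = NA_real_, max_abs_error = NA_real_,
                total_length = 0))
  tr <- truth[match(pl$molecule, truth$id), ]
  n_cov <- 0L; n_rec <- 0L; errs <- numeric(0)
  n_cons <- 0L; n_spur <- 0L; tot_len <- 0
  for (map in assembly$maps$maps) {
    sel <- which(pl$map == map$id)
    if (!length(sel)) next
    tot_len <- tot_len + map$length
    n_cons <- n_cons + length(map$labels)
    cons <- map$labels
    # predicted map-frame position of each covered true label
    preds <- rep(NA_real_, length(digest$labels))
    cnt <- integer(length(digest$labels))
    acc <- vector("list", length(digest$labels))
    for (s in sel) {
      st <- tr$start[s]; en <- tr$end[s]
      cov_idx <- which(digest$labels >= st & digest$labels < en)
      if (!length(cov_idx)) next
      g <- digest$labels[cov_idx]
      x <- if (tr$strand[s] == "+") g - st else (en - st) - (g - st)
      x <- x * tr$stretch[s]   # observed molecule coordinates are stretched
      Lobs <- tr$obs_length[s]
      y <- if (pl$orientation[s] == "+") pl$offset[s] + x else
        pl$offset[s] + (Lobs - x)
      for (j in seq_along(cov_idx)) {
        ci <- cov_idx[j]
        acc[[ci]] <- c(acc[[ci]], y[j])
        cnt[ci] <- cnt[ci] + 1L
      }
    }
    covered <- which(cnt >= 2)   # consensus is defined at >= 2-molecule coverage
    pred_pos <- vapply(covered, function(ci) median(acc[[ci]]), numeric(1))
    n_cov <- n_cov + length(covered)
    if (length(covered) && length(cons)) {
      derr <- vapply(pred_pos, function(p) min(abs(cons - p)), numeric(1))
      n_rec <- n_rec + sum(derr <= tol)
      errs <- c(errs, derr[derr <= tol])
      dc <- vapply(cons, function(cp) min(abs(pred_pos - cp)), numeric(1))
      n_spur <- n_spur + sum(dc > tol)
    } else n_spur <- n_spur + length(cons)
  }
  list(n_true_covered = n_cov,
       frac_recovered = if (n_cov) n_rec / n_cov else NA_real_,
       n_consensus = n_cons, n_spurious = n_spur,
       spurious_per_100kb = if (tot_len > 0) n_spur / tot_len * 1e5 else NA_real_,
       max_abs_error = if (length(errs)) max(errs) else NA_real_,
       total_length = tot_len)
}
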