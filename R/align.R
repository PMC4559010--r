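#' Alignment scoring parameters
#'
#' The scoring model makes the platform's error rates meaningful as
#' penalties. Matching two consecutive label pairs scores a Gaussian sizing
#' term `-(dr - dq)^2 / (2 * (s0^2 * dr + sd0^2))` plus a match bonus;
#' skipping a reference label (a site missing from the query) costs
#' `-log(fn_prob)`; skipping a query label (a spurious site) costs
#' `-log(fp_penalty_rate / ref_label_density)`, the log-odds that an
#' observed label is spurious rather than genuine. Alignment is local and both
#' query orientations are tried; `max_skip` bounds the labels skipped
#' between consecutive matches on either side and is part of the scoring
#' model (the brute-force oracle applies the same bound).
#'
#' @param fp_penalty_rate Expected false labels per 100 kb (default 1.5).
#' @param fn_penalty_prob Missed-label probability (default 0.15).
#' @param sizing_sd_scale `s0`, bp^0.5 (default 5).
#' @param sizing_sd0 Additive sd floor in bp absorbing pixel quantization
#'   and resolution-merge shifts (default 250).
#' @param ref_label_density Nominal genuine-label density per 100 kb used
#'   in the spurious-label log-odds (default 10).
#' @param match_bonus Reward per matched pair (default 3).
#' @param max_skip Max consecutive skipped labels per side (default 4).
#' @param min_query_sites Minimum query labels for [batch_align()]'s
#'   retention filter; "more than 6 sites" read strictly (default 7).
#' @param min_score Acceptance threshold for [align_maps()] (default 9,
#'   i.e. at least three clean matches).
#' @param resolution_bp Optical resolution, bp (default 500).
#' @return An object of class `align_params`.
#' @export
align_params <- function(fp_penalty_rate = 1.5, fn_penalty_prob = 0.15,
                         sizing_sd_scale = 5, sizing_sd0 = 250,
                         ref_label_density = 10, match_bonus = 3,
                         max_skip = 4L, min_query_sites = 7L, min_score = 9,
                         resolution_bp = 500) {
  if (fp_penalty_rate < 0 || fn_penalty_prob < 0 || fn_penalty_prob > 1 ||
      sizing_sd_scale < 0 || sizing_sd0 < 0 || max_skip < 0 ||
      ref_label_density <= 0)
    stop("invalid alignment parameters")
  structure(list(fp_penalty_rate = fp_penalty_rate,
                 fn_penalty_prob = fn_penalty_prob,
                 sizing_sd_scale = sizing_sd_scale, sizing_sd0 = sizing_sd0,
                 ref_label_density = ref_label_density,
                 match_bonus = match_bonus, max_skip = as.integer(max_skip),
                 min_query_sites = as.integer(min_query_sites),
                 min_score = min_score, resolution_bp = resolution_bp),
            class = "align_params")
}

# penalty list consumed by the C++ core
scoring_list <- function(p) {
  fp_pen <- if (p$fp_penalty_rate > 0)
    -log(p$fp_penalty_rate / p$ref_label_density) else Inf
  fn_pen <- if (p$fn_penalty_prob > 0) -log(p$fn_penalty_prob) else Inf
  list(s0 = p$sizing_sd_scale, var0 = p$sizing_sd0^2,
       match_bonus = p$match_bonus, fp_pen = max(fp_pen, 0),
       fn_pen = max(fn_pen, 0), max_skip = p$max_skip)
}

# positions of a query in its orientation-normalized frame
norm_positions <- function(labels, len, orientation) {
  if (orientation == "+") labels else rev(len - labels)
}

# aligned query span under the pinned rule: the matched span plus half of
# each flanking gap to the nearest unmatched label; a side with no
# unmatched label beyond the terminal match extends to the molecule end.
aligned_query_span <- function(qpos, qi, qlen) {
  i1 <- qi[1]; im <- qi[length(qi)]
  left <- if (i1 > 1) qpos[i1] - (qpos[i1] - qpos[i1 - 1]) / 2 else 0
  right <- if (im < length(qpos)) qpos[im] + (qpos[im + 1] - qpos[im]) / 2 else qlen
  c(left, right)
}

build_alignment <- function(query, ref, res, params) {
  qi <- res$qi; ri <- res$ri
  qpos <- norm_positions(query$labels, query$length, res$orientation)
  rpos <- ref$labels
  pairs <- data.frame(qi = qi, ri = ri, qpos = qpos[qi], rpos = rpos[ri])
  span <- aligned_query_span(qpos, qi, query$length)
  ratio <- min(max((span[2] - span[1]) / query$length, 0), 1)
  structure(list(
    query_id = query$id, ref_id = ref$id, orientation = res$orientation,
    pairs = pairs, score = res$score, confidence = res$confidence,
    query_span = span[2] - span[1],
    ref_span = rpos[ri[length(ri)]] - rpos[ri[1]],
    query_length = query$length,
    query_labels = qpos, ref_labels = rpos,
    mapping_length_ratio = ratio, thorough = ratio >= 0.95,
    n_query_unmatched = length(qpos) - length(qi),
    n_ref_unmatched = (ri[length(ri)] - ri[1] + 1) - length(ri)),
    class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf("<map_alignment> %s -> %s (%s): %d pairs, score %.2f, ratio %.3f%s\n",
              x$query_id, x$ref_id, x$orientation, nrow(x$pairs), x$score,
              x$mapping_length_ratio, if (x$thorough) " [thorough]" else ""))
  invisible(x)
}

#' Align a query label map to a reference map
#'
#' Dynamic-programming local alignment of two ordered label maps under the
#' FP/FN-aware scoring of [align_params()]. Both query orientations are
#' evaluated (forward preferred on ties); the highest-scoring chain is
#' returned if it reaches `min_score`, else `NULL`. Matched pair indices
#' are reported in the orientation-normalized query frame (ascending in
#' both indices). Confidence is the score margin over the best alignment
#' that is disjoint in query labels, floored at zero.
#'
#' @param query,ref `label_map` objects.
#' @param params An `align_params` object.
#' @param enforce_min_sites Apply the `min_query_sites` retention filter
#'   (default `FALSE`; [batch_align()] applies it).
#' @return A `map_alignment` or `NULL`.
#' @export
align_maps <- function(query, ref, params = align_params(),
                       enforce_min_sites = FALSE) {
  if (enforce_min_sites && length(query$labels) < params$min_query_sites)
    return(NULL)
  if (!length(query$labels) || !length(ref$labels)) return(NULL)
  sl <- scoring_list(params)
  res <- cpp_align_both(query$labels, ref$labels, query$length, sl)
  if (res$score < params$min_score || !length(res$qi)) return(NULL)

  # best query-disjoint alignment for the confidence margin
  qpos <- norm_positions(query$labels, query$length, res$orientation)
  i1 <- res$qi[1]; im <- res$qi[length(res$qi)]
  second <- 0
  if (i1 > 1) {
    left <- cpp_align_both(qpos[seq_len(i1 - 1)], ref$labels, query$length, sl)
    second <- max(second, left$score)
  }
  if (im < length(qpos)) {
    right <- cpp_align_both(qpos[seq(im + 1, length(qpos))], ref$labels,
                            query$length, sl)
    second <- max(second, right$score)
  }
  res$confidence <- max(res$score - max(second, 0), 0)
  build_alignment(query, ref, res, params)
}

#' Brute-force alignment oracle
#'
#' Exhaustively enumerates every monotone index pairing of query and
#' reference labels (both query orientations, respecting the same
#' `max_skip` bound as the DP) under the identical scoring function, and
#' returns the best score. Intended as an independent test oracle for small
#' instances.
#'
#' @param query,ref `label_map` objects with at most `max_labels` labels.
#' @param params An `align_params`.
#' @param max_labels Size guard (default 8).
#' @return List: `score`, `orientation`, `pairs` (matrix of matched index
#'   pairs in the normalized frame; empty pairing scores 0).
#' @export
brute_force_align <- function(query, ref, params = align_params(),
                              max_labels = 8L) {
  nq <- length(query$labels); nr <- length(ref$labels)
  if (nq > max_labels || nr > max_labels)
    stop("brute_force_align: size bound exceeded")
  sl <- scoring_list(params)
  best <- list(score = 0, orientation = "+",
               pairs = matrix(integer(0), ncol = 2))
  for (orient in c("+", "-")) {
    qpos <- norm_positions(query$labels, query$length, orient)
    rpos <- ref$labels
    chains <- function(i, j, sc, chain) {
      if (sc > best$score + 1e-12) {
        best <<- list(score = sc, orientation = orient,
                      pairs = matrix(chain, ncol = 2, byrow = TRUE))
      }
      for (di in seq_len(min(sl$max_skip + 1L, nq - i))) {
        for (dj in seq_len(min(sl$max_skip + 1L, nr - j))) {
          ii <- i + di; jj <- j + dj
          trans <- -(rpos[jj] - rpos[j] - (qpos[ii] - qpos[i]))^2 /
            (2 * (sl$s0^2 * (rpos[jj] - rpos[j]) + sl$var0)) -
            sl$fp_pen * (di - 1) - sl$fn_pen * (dj - 1)
          chains(ii, jj, sc + sl$match_bonus + trans, c(chain, ii, jj))
        }
      }
    }
    for (i in seq_len(nq)) for (j in seq_len(nr))
      chains(i, j, sl$match_bonus, c(i, j))
  }
  best
}

#' Mapping length ratio
#'
#' The aligned query span divided by the query's total length, clamped to
#' `[0, 1]`. The span runs between the terminal matched labels extended by
#' half of each flanking gap to the nearest unmatched label; when every
#' label on a side is matched the span extends to the molecule end, so
#' self-alignment gives exactly 1. A ratio of at least 0.95 defines a
#' thorough alignment (the flanks before the first and after the last
#' nicking site carry no label information, hence the threshold below 1).
#'
#' @param alignment A `map_alignment`.
#' @param query_total_length Total query length, bp (defaults to the length
#'   recorded in the alignment).
#' @return Ratio in `[0, 1]`.
#' @export
mapping_length_ratio <- function(alignment, query_total_length = NULL) {
  if (is.null(alignment) || !nrow(alignment$pairs)) stop("empty alignment")
  if (is.null(query_total_length)) query_total_length <- alignment$query_length
  min(max(alignment$query_span / query_total_length, 0), 1)
}

#' Align many queries against a map set
#'
#' Retains queries with at least `min_query_sites` labels, aligns each to
#' every reference, and keeps only its highest-confidence alignment. The
#' summary reports the fraction of aligned queries with mapping length
#' ratio at least 0.7, 0.8 and 0.95 (thorough).
#'
#' @param queries,refs `cmap_dataset` objects.
#' @param params An `align_params`.
#' @return List: `alignments` (named by query id), `summary` (list with
#'   `n_queries`, `n_retained`, `n_aligned`, `frac_ge_0.7`, `frac_ge_0.8`,
#'   `frac_thorough`), and `table` (one row per aligned query).
#' @export
batch_align <- function(queries, refs, params = align_params()) {
  alns <- list()
  n_retained <- 0L
  for (q in queries$maps) {
    if (length(q$labels) < params$min_query_sites) next
    n_retained <- n_retained + 1L
    best <- NULL
    for (r in refs$maps) {
      a <- align_maps(q, r, params)
      if (!is.null(a) &&
          (is.null(best) || a$confidence > best$confidence + 1e-9 ||
           (abs(a$confidence - best$confidence) <= 1e-9 && a$score > best$score)))
        best <- a
    }
    if (!is.null(best)) alns[[q$id]] <- best
  }
  ratios <- vapply(alns, function(a) a$mapping_length_ratio, numeric(1))
  tab <- if (length(alns)) data.frame(
    query = vapply(alns, function(a) a$query_id, character(1)),
    ref = vapply(alns, function(a) a$ref_id, character(1)),
    orientation = vapply(alns, function(a) a$orientation, character(1)),
    n_pairs = vapply(alns, function(a) nrow(a$pairs), integer(1)),
    score = vapply(alns, function(a) a$score, numeric(1)),
    confidence = vapply(alns, function(a) a$confidence, numeric(1)),
    ratio = unname(ratios),
    thorough = vapply(alns, function(a) a$thorough, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE) else NULL
  list(alignments = alns,
       summary = list(
         n_queries = length(queries$maps), n_retained = n_retained,
         n_aligned = length(alns),
         frac_ge_0.7 = if (length(alns)) mean(ratios >= 0.7) else NA_real_,
         frac_ge_0.8 = if (length(alns)) mean(ratios >= 0.8) else NA_real_,
         frac_thorough = if (length(alns)) mean(ratios >= 0.95) else NA_real_),
       table = tab)
}

#' Estimate the false-positive label rate from alignments
#'
#' Reconstructs the rate of spurious molecule labels from reference
#' alignments. Inside each aligned span, every unmatched query label is
#' projected into reference coordinates by linear interpolation between
#' the bracketing matched pairs and classified as a mismatch when no
#' reference label lies within a noise-scaled tolerance
#' (`3 * sqrt(s0^2 * g / 4 + sd0^2)` for a bracket gap `g`). The raw
#' mismatch rate is then divided by two detection efficiencies estimated
#' from the data themselves: the chance that a uniformly placed spurious
#' label escapes the classification window around reference labels, and
#' the chance that it escapes fusion (within the optical resolution) with
#' an observed label. Both are censoring corrections, not fitted
#' constants.
#'
#' @param alignments List of `map_alignment` objects.
#' @param params The `align_params` supplying the sizing-noise scale and
#'   the optical resolution.
#' @return Estimated false labels per 100 kb, or `NA` when no usable
#'   alignment is given.
#' @export
estimate_fp_rate <- function(alignments, params = align_params()) {
  alignments <- alignments[!vapply(alignments, is.null, logical(1))]
  if (!length(alignments)) return(NA_real_)
  s0 <- params$sizing_sd_scale; var0 <- params$sizing_sd0^2
  mism <- 0; span_sum <- 0; tol_sum <- 0; tol_n <- 0
  nref_span <- 0; ref_span_sum <- 0; nq_span <- 0
  for (a in alignments) {
    qi <- a$pairs$qi; ri <- a$pairs$ri
    if (length(qi) < 2) next
    ql <- a$query_labels; rl <- a$ref_labels
    qp <- a$pairs$qpos; rp <- a$pairs$rpos
    span <- qp[length(qp)] - qp[1]
    span_sum <- span_sum + span
    nq_span <- nq_span + (qi[length(qi)] - qi[1] + 1)
    nref_span <- nref_span + (ri[length(ri)] - ri[1] + 1)
    ref_span_sum <- ref_span_sum + (rp[length(rp)] - rp[1])
    inside <- setdiff(seq(qi[1], qi[length(qi)]), qi)
    for (u in inside) {
      k <- findInterval(u, qi)          # bracketing matched pairs k, k+1
      g <- rp[k + 1] - rp[k]
      f <- (ql[u] - qp[k]) / (qp[k + 1] - qp[k])
      pred <- rp[k] + f * g
      tol <- 3 * sqrt(s0^2 * g / 4 + var0)
      tol_sum <- tol_sum + tol; tol_n <- tol_n + 1
      if (min(abs(rl - pred)) > tol) mism <- mism + 1
    }
  }
  if (span_sum <= 0) return(NA_real_)
  d_ref <- nref_span / ref_span_sum           # reference label density in spans
  d_q <- nq_span / span_sum                   # observed query label density
  mean_tol <- if (tol_n) tol_sum / tol_n else 3 * params$sizing_sd0
  eff_class <- max(1 - 2 * mean_tol * d_ref, 0.25)
  eff_merge <- max(1 - 2 * params$resolution_bp * d_q, 0.25)
  mism / span_sum / (eff_class * eff_merge) * 1e5
}

#' Estimate the effective bases-per-pixel scale
#'
#' Regresses matched query gaps on matched reference gaps (least squares
#' through the origin, pooled over alignments); the slope times the nominal
#' pixel size is the effective bp-per-pixel scale. A systematic molecule
#' stretch of 0.8% over a 500-bp nominal pixel reads out as ~504 bp/pixel.
#'
#' @param alignments List of `map_alignment` objects with >= 2 matched
#'   pairs each.
#' @param nominal_bpp Nominal pixel size in bp (default 500).
#' @return Effective bp per pixel, or `NA` if no usable gap is available.
#' @export
estimate_bpp <- function(alignments, nominal_bpp = 500) {
  alignments <- alignments[!vapply(alignments, is.null, logical(1))]
  num <- 0; den <- 0
  for (a in alignments) {
    if (nrow(a$pairs) < 2) next
    dq <- diff(a$pairs$qpos); dr <- diff(a$pairs$rpos)
    num <- num + sum(dq * dr); den <- den + sum(dr * dr)
  }
  if (den <= 0) return(NA_real_)
  nominal_bpp * num / den
}
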