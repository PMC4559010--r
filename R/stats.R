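#' N50 of a set of lengths
#'
#' The smallest length L such that elements of length at least L sum to at
#' least half the total (descending sort, cumulative). Order-invariant.
#'
#' @param lengths Non-empty numeric vector of positive lengths.
#' @return The N50 in the same units.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50 of an empty set is undefined")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Summary table of length sets
#'
#' One row per named dataset with count, total length, N50, min and max —
#' the basic statistics reported for raw molecules and assembled maps.
#'
#' @param datasets Named list; each element a numeric vector of lengths, a
#'   `bnx_dataset` or a `cmap_dataset`.
#' @return A data.frame with columns label, number, total_length, n50,
#'   min, max (NA statistics for empty sets).
#' @export
summary_table <- function(datasets) {
  rows <- lapply(names(datasets), function(nm) {
    x <- datasets[[nm]]
    lens <- if (inherits(x, "bnx_dataset") || inherits(x, "cmap_dataset"))
      map_lengths(x) else as.numeric(x)
    if (!length(lens))
      data.frame(label = nm, number = 0L, total_length = 0,
                 n50 = NA_real_, min = NA_real_, max = NA_real_,
                 stringsAsFactors = FALSE)
    else
      data.frame(label = nm, number = length(lens), total_length = sum(lens),
                 n50 = n50(lens), min = min(lens), max = max(lens),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Length histogram with an accumulating tail bin
#'
#' Right-open bins `[left, right)` of width `bin_width`; everything at or
#' above `tail_accumulate_at` lands in a single open-ended final bin.
#'
#' @param lengths Numeric lengths.
#' @param bin_width Bin width in bp (default 50,000).
#' @param tail_accumulate_at Threshold of the open final bin; `Inf`
#'   disables accumulation.
#' @return A data.frame: bin_start, bin_end, count, total_length.
#' @export
length_histogram <- function(lengths, bin_width = 5e4,
                             tail_accumulate_at = Inf) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!length(lengths))
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0), total_length = numeric(0)))
  idx <- floor(lengths / bin_width)
  cap <- floor(tail_accumulate_at / bin_width)
  idx[idx >= cap] <- cap
  bins <- seq(min(idx), max(idx))
  data.frame(
    bin_start = bins * bin_width,
    bin_end = ifelse(bins >= cap, Inf, (bins + 1) * bin_width),
    count = vapply(bins, function(b) sum(idx == b), integer(1)),
    total_length = vapply(bins, function(b) sum(lengths[idx == b]), numeric(1)))
}

#' Per-molecule label densities and the pooled overall density
#'
#' Per molecule, labels per 100 kb of molecule length; overall density
#' pools total labels over total length (not the mean of per-molecule
#' densities). Quartiles per length bin give the boxplot view of density
#' stability across molecule sizes.
#'
#' @param dataset A `bnx_dataset` (or list of `label_map`s).
#' @param bin_width Length-bin width for the quartile table (default 50 kb).
#' @return List: `per_molecule` (data.frame id, length, n_labels, density),
#'   `overall` (pooled density per 100 kb), `mean_per_molecule`, and
#'   `by_length_bin` (data.frame of quartiles per bin).
#' @export
label_density_stats <- function(dataset, bin_width = 5e4) {
  mols <- if (inherits(dataset, "bnx_dataset")) dataset$molecules else dataset
  lens <- vapply(mols, function(m) m$length, numeric(1))
  nl <- vapply(mols, function(m) length(m$labels), integer(1))
  if (any(lens <= 0)) stop("molecule lengths must be > 0")
  dens <- nl / lens * 1e5
  per <- data.frame(id = vapply(mols, function(m) m$id, character(1)),
                    length = lens, n_labels = nl, density = dens,
                    stringsAsFactors = FALSE)
  bins <- floor(lens / bin_width)
  qs <- lapply(sort(unique(bins)), function(b) {
    d <- dens[bins == b]
    data.frame(bin_start = b * bin_width, bin_end = (b + 1) * bin_width,
               n = length(d), q1 = quantile(d, 0.25, names = FALSE),
               median = median(d), q3 = quantile(d, 0.75, names = FALSE))
  })
  list(per_molecule = per,
       overall = sum(nl) / sum(lens) * 1e5,
       mean_per_molecule = mean(dens),
       by_length_bin = do.call(rbind, qs))
}

#' Molecule counts and depth against length thresholds
#'
#' For each length threshold: how many molecules survive and what fold
#' coverage of the genome they still represent.
#'
#' @param dataset A `bnx_dataset`.
#' @param thresholds Numeric vector of length thresholds in bp.
#' @param genome_size Genome size in bp (> 0).
#' @return A data.frame: threshold, n_molecules, total_length, depth.
#' @export
depth_threshold_table <- function(dataset, thresholds, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  lens <- map_lengths(dataset)
  rows <- lapply(thresholds, function(t) {
    sel <- lens >= t
    data.frame(threshold = t, n_molecules = sum(sel),
               total_length = sum(lens[sel]),
               depth = sum(lens[sel]) / genome_size)
  })
  do.call(rbind, rows)
}

#' Fold coverage
#'
#' @param total_molecule_length Summed molecule length, bp.
#' @param genome_size Genome size, bp (> 0).
#' @return Fold coverage (ratio).
#' @export
coverage_fold <- function(total_molecule_length, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  total_molecule_length / genome_size
}
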