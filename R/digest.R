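#' Digestion parameters
#'
#' Parameters for in-silico nicking-endonuclease digestion. The default
#' motif is the Nt.BspQ1 recognition site `GCTCTTC`; `resolution_bp` is the
#' optical resolution below which adjacent nicking sites cannot be told
#' apart and are merged into a single label.
#'
#' @param motif Recognition motif over `{A,C,G,T}`, length >= 4.
#' @param resolution_bp Merge distance in bp (default 500).
#' @param density_window Window for density reporting, bp (fixed 100 kb).
#' @return An object of class `digest_params`.
#' @export
digest_params <- function(motif = "GCTCTTC", resolution_bp = 500,
                          density_window = 1e5) {
  motif <- toupper(motif)
  if (nchar(motif) < 4) stop("motif must be at least 4 bp")
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  if (resolution_bp < 0) stop("resolution_bp must be >= 0")
  structure(list(motif = motif, resolution_bp = resolution_bp,
                 density_window = density_window),
            class = "digest_params")
}

#' Find nicking-site motif occurrences on both strands
#'
#' Nickases cut a single strand, but the resulting label is visible on the
#' molecule regardless of which strand carries the site, so forward-strand
#' matches of the motif and matches of its reverse complement are pooled.
#' Positions are 0-based coordinates of the leftmost base of the occurrence
#' on the forward strand; windows containing `N` never match.
#'
#' @param seq A `sequence_record` (or plain DNA string).
#' @param motif Recognition motif over `{A,C,G,T}`.
#' @return Sorted, deduplicated numeric vector of 0-based positions.
#' @export
find_motif_sites <- function(seq, motif) {
  if (grepl("[^ACGT]", toupper(motif))) stop("motif must contain only A, C, G, T")
  s <- if (inherits(seq, "sequence_record")) seq$sequence else toupper(seq)
  subject <- Biostrings::DNAString(s)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(toupper(motif)),
                                  subject, fixed = TRUE)
  rcm <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(motif)))
  rev <- Biostrings::matchPattern(rcm, subject, fixed = TRUE)
  sort(unique(c(Biostrings::start(fwd), Biostrings::start(rev)))) - 1
}

#' Nick or label density per 100 kb
#'
#' @param n_sites Number of sites.
#' @param length_bp Sequence length in bp (> 0).
#' @param window Density window (default 100 kb).
#' @return Sites per `window` bp.
#' @export
nick_density <- function(n_sites, length_bp, window = 1e5) {
  if (length_bp <= 0) stop("length_bp must be > 0")
  n_sites / length_bp * window
}

#' Merge nicking sites below the optical resolution
#'
#' Maximal chains of consecutive positions whose successive gaps are all
#' strictly below `resolution_bp` collapse to a single label at the midpoint
#' of the chain's extremes. Output gaps are therefore all `>= resolution_bp`
#' and the operation is idempotent.
#'
#' @param positions Ascending numeric positions.
#' @param resolution_bp Merge distance (strict `<` comparison).
#' @return Ascending merged label positions.
#' @export
apply_resolution <- function(positions, resolution_bp) {
  if (!length(positions)) return(numeric(0))
  if (is.unsorted(positions)) stop("positions must be ascending")
  if (resolution_bp <= 0) return(as.numeric(positions))
  gaps <- diff(positions)
  chain <- cumsum(c(0L, as.integer(!(gaps < resolution_bp))))
  first <- positions[!duplicated(chain)]
  last <- positions[!duplicated(chain, fromLast = TRUE)]
  (first + last) / 2
}

#' Digest sequences into label maps
#'
#' Scans each record for the motif on both strands, applies the resolution
#' merge, and reports per-sequence and aggregate nick/label densities.
#' Aggregate densities pool summed counts over summed lengths, not the mean
#' of per-record densities.
#'
#' @param records List of `sequence_record` objects.
#' @param params A `digest_params` object.
#' @return A list: `maps` (a `cmap_dataset` with one `label_map` per
#'   record), `per_sequence` (data.frame of id, length, nicks, labels,
#'   nick/label density) and `aggregate` (list with pooled densities, `NULL`
#'   for empty input).
#' @export
digest_sequences <- function(records, params = digest_params()) {
  if (inherits(records, "sequence_record")) records <- list(records)
  maps <- vector("list", length(records))
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    nicks <- find_motif_sites(rec, params$motif)
    labels <- apply_resolution(nicks, params$resolution_bp)
    maps[[i]] <- label_map(rec$id, rec$length, labels, source = "digest")
    rows[[i]] <- data.frame(
      id = rec$id, length = rec$length,
      n_nicks = length(nicks), n_labels = length(labels),
      nick_density = nick_density(length(nicks), rec$length, params$density_window),
      label_density = nick_density(length(labels), rec$length, params$density_window),
      stringsAsFactors = FALSE)
  }
  per_seq <- do.call(rbind, rows)
  aggregate <- NULL
  if (length(records)) {
    tot_len <- sum(per_seq$length)
    aggregate <- list(
      length = tot_len,
      n_nicks = sum(per_seq$n_nicks), n_labels = sum(per_seq$n_labels),
      nick_density = nick_density(sum(per_seq$n_nicks), tot_len, params$density_window),
      label_density = nick_density(sum(per_seq$n_labels), tot_len, params$density_window))
  }
  list(maps = cmap_dataset(maps,
                           header = c(motif = params$motif,
                                      resolution_bp = as.character(params$resolution_bp))),
       per_sequence = per_seq, aggregate = aggregate)
}

#' Enzyme-selection report
#'
#' Computes nick and label densities for each candidate enzyme motif on the
#' given sequences and selects the enzyme whose label density is closest to
#' the target (ties go to the first listed). The platform's optimum is about
#' 10 labels per 100 kb: too sparse gives uninformative patterns, too dense
#' exceeds the labelling resolution.
#'
#' @param records List of `sequence_record` objects.
#' @param catalog Named character vector, enzyme name -> motif. Only the
#'   Nt.BspQ1 motif ships as a default; other enzymes' motifs must be
#'   supplied by the caller.
#' @param target_density Target label density per 100 kb (default 10).
#' @param resolution_bp Optical resolution for the label merge.
#' @return A list: `table` (data.frame with enzyme, motif, nick_density,
#'   label_density) and `selected` (enzyme name).
#' @export
enzyme_report <- function(records, catalog = c(Nt.BspQ1 = "GCTCTTC"),
                          target_density = 10, resolution_bp = 500) {
  if (!length(catalog)) stop("at least one enzyme required")
  rows <- lapply(seq_along(catalog), function(k) {
    dig <- digest_sequences(records, digest_params(catalog[[k]], resolution_bp))
    data.frame(enzyme = names(catalog)[k], motif = catalog[[k]],
               nick_density = dig$aggregate$nick_density,
               label_density = dig$aggregate$label_density,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sel <- which.min(abs(tab$label_density - target_density))
  list(table = tab, selected = tab$enzyme[sel])
}

#' Expected label-density fluctuation band
#'
#' Empirically, genome-wide average label density fluctuates by a fixed
#' fraction around a pilot in-silico estimate; the band brackets what the
#' instrument should observe if the enzyme choice is sound.
#'
#' @param density Pilot label density estimate (per 100 kb).
#' @param frac Fractional fluctuation (default 0.15).
#' @return Numeric `c(lo, hi)` = `density * (1 -/+ frac)`.
#' @export
fluctuation_band <- function(density, frac = 0.15) {
  if (density < 0) stop("density must be >= 0")
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  c(lo = density * (1 - frac), hi = density * (1 + frac))
}
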