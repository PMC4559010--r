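#' Ordered label maps
#'
#' A label map is the basic object of optical mapping: an ordered set of
#' label positions (bp) on a sequence, molecule or consensus map, together
#' with the total length. Positions are 0-based bp coordinates within the
#' map; writers convert to the 1-based site indices of the on-disk formats.
#'
#' @param id Character scalar identifier.
#' @param length Total length in bp (> 0).
#' @param labels Numeric vector of ascending label positions in `[0, length]`.
#' @param source One of `"digest"`, `"simulation"`, `"assembly"`.
#' @param support Optional integer vector (one per label) of supporting
#'   molecule counts, used for consensus maps.
#' @return An object of class `label_map`.
#' @examples
#' label_map("m1", 50000, c(1000, 20000, 41000))
#' @export
label_map <- function(id, length, labels = numeric(0),
                      source = c("digest", "simulation", "assembly"),
                      support = NULL) {
  source <- match.arg(source)
  labels <- as.numeric(labels)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.numeric(length) || length <= 0)
    stop("label map '", id, "': length must be > 0")
  if (is.unsorted(labels))
    stop("label map '", id, "': labels must be ascending")
  if (base::length(labels) && (labels[1L] < 0 || labels[base::length(labels)] > length))
    stop("label map '", id, "': labels outside [0, length]")
  if (!is.null(support) && base::length(support) != base::length(labels))
    stop("label map '", id, "': support must have one entry per label")
  structure(list(id = id, length = as.numeric(length), labels = labels,
                 source = source, support = support),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %.0f bp, %d labels (%s)\n",
              x$id, x$length, length(x$labels), x$source))
  invisible(x)
}

n_labels <- function(map) length(map$labels)

#' Molecule container (BNX-style dataset)
#'
#' An ordered collection of observed molecules. Each molecule is a
#' `label_map` (observed length and observed label positions); simulation
#' truth, when present, travels separately (see [generate_dataset()]).
#'
#' @param molecules List of `label_map` objects with unique ids.
#' @param header Named character vector of header metadata, preserved
#'   verbatim on round trip.
#' @return An object of class `bnx_dataset`.
#' @export
bnx_dataset <- function(molecules = list(), header = character(0)) {
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids in BNX dataset")
  structure(list(molecules = molecules, header = header), class = "bnx_dataset")
}

#' @export
print.bnx_dataset <- function(x, ...) {
  tl <- sum(vapply(x$molecules, function(m) m$length, numeric(1)))
  cat(sprintf("<bnx_dataset> %d molecules, %.2f Mb total\n",
              length(x$molecules), tl / 1e6))
  invisible(x)
}

#' @export
length.bnx_dataset <- function(x) length(x$molecules)

#' Map container (CMAP-style dataset)
#'
#' @param maps List of `label_map` objects (digested sequences or consensus
#'   maps) with unique ids.
#' @param header Named character vector of header metadata.
#' @return An object of class `cmap_dataset`.
#' @export
cmap_dataset <- function(maps = list(), header = character(0)) {
  ids <- vapply(maps, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate map ids in CMAP dataset")
  structure(list(maps = maps, header = header), class = "cmap_dataset")
}

#' @export
print.cmap_dataset <- function(x, ...) {
  tl <- sum(vapply(x$maps, function(m) m$length, numeric(1)))
  cat(sprintf("<cmap_dataset> %d maps, %.2f Mb total\n",
              length(x$maps), tl / 1e6))
  invisible(x)
}

#' @export
length.cmap_dataset <- function(x) length(x$maps)

map_lengths <- function(x) {
  items <- if (inherits(x, "bnx_dataset")) x$molecules else x$maps
  vapply(items, function(m) m$length, numeric(1))
}
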