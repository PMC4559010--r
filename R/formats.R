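#' Read sequences from a FASTA file
#'
#' Reads DNA sequences, removing line wrapping and normalizing case to
#' uppercase. Characters outside `{A,C,G,T,N}` are rejected unless
#' `map_ambiguous_to_n = TRUE`, in which case IUPAC ambiguity codes are
#' mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @param map_ambiguous_to_n Map non-ACGTN letters to `N` instead of failing.
#' @return A list of `sequence_record` objects: `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path, map_ambiguous_to_n = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    s <- toupper(as.character(set[[i]]))
    if (nchar(s) == 0)
      stop("FASTA record '", ids[i], "': empty sequence")
    if (grepl("[^ACGTN]", s)) {
      if (map_ambiguous_to_n) s <- gsub("[^ACGTN]", "N", s)
      else stop("FASTA record '", ids[i], "': non-ACGTN characters")
    }
    sequence_record(ids[i], s)
  })
}

#' Construct a sequence record
#'
#' @param id Record identifier.
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("record '", id, "': empty sequence")
  if (grepl("[^ACGTN]", sequence)) stop("record '", id, "': non-ACGTN characters")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s: %d bp\n", x$id, x$length))
  invisible(x)
}

#' Write sequence records to FASTA
#'
#' @param records List of `sequence_record` objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")  # binary mode keeps writers byte-deterministic
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    starts <- seq(1L, rec$length, by = width)
    writeLines(substring(rec$sequence, starts,
                         pmin(starts + width - 1L, rec$length)), con)
  }
  invisible(path)
}

fmt_pos <- function(x) sprintf("%.1f", x)

write_header_lines <- function(header, con, prefix) {
  if (length(header)) {
    keys <- names(header)
    writeLines(sprintf("%s\t%s\t%s", prefix, keys, unname(header)), con)
  }
}

parse_header_lines <- function(lines, prefix) {
  hl <- lines[startsWith(lines, prefix)]
  if (!length(hl)) return(character(0))
  parts <- strsplit(hl, "\t", fixed = TRUE)
  vals <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", character(1))
  names(vals) <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  vals
}

#' Write molecules to a BNX-style file
#'
#' Emits a minimal, documented subset of the BNX molecule format: `#K`
#' header lines (key/value, preserved verbatim on round trip), then per
#' molecule a `0` line (id, length) followed by a `1` line with the label
#' positions. Positions are written in bp with one decimal; the writer is
#' byte-deterministic for identical input.
#'
#' @param dataset A `bnx_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bnx <- function(dataset, path) {
  stopifnot(inherits(dataset, "bnx_dataset"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# BNX-style molecule file (minimal dialect)", con)
  write_header_lines(dataset$header, con, "#K")
  for (m in dataset$molecules) {
    if (is.unsorted(m$labels)) stop("molecule '", m$id, "': unsorted labels on write")
    writeLines(paste("0", m$id, fmt_pos(m$length), sep = "\t"), con)
    writeLines(paste(c("1", fmt_pos(m$labels)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BNX-style molecule file
#'
#' @param path Path written by [write_bnx()] (or following the same layout).
#' @return A `bnx_dataset`.
#' @export
read_bnx <- function(path) {
  if (!file.exists(path)) stop("BNX file not found: ", path)
  lines <- readLines(path)
  header <- parse_header_lines(lines, "#K")
  body <- lines[!startsWith(lines, "#")]
  mols <- list()
  i <- 1L
  while (i <= length(body)) {
    f0 <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (f0[1] != "0" || length(f0) < 3)
      stop("malformed BNX molecule line ", i, ": ", body[i])
    id <- f0[2]; len <- as.numeric(f0[3])
    labels <- numeric(0)
    if (i + 1L <= length(body)) {
      f1 <- strsplit(body[i + 1L], "\t", fixed = TRUE)[[1]]
      if (f1[1] != "1") stop("molecule '", id, "': missing label line")
      if (length(f1) > 1) labels <- as.numeric(f1[-1])
    } else stop("molecule '", id, "': missing label line")
    if (length(labels) && labels[length(labels)] > len + 1e-6)
      stop("molecule '", id, "': label position exceeds molecule length")
    mols[[length(mols) + 1L]] <- label_map(id, len, labels, source = "simulation")
    i <- i + 2L
  }
  bnx_dataset(mols, header)
}

#' Write maps to a CMAP-style file
#'
#' Emits a minimal long-format CMAP-style table: one row per label site with
#' columns `CMapId`, `ContigLength`, `NumSites`, `SiteID` (1-based),
#' `LabelChannel`, `Position`, `Coverage`, plus the conventional channel-0
#' sentinel row at the contig end. `#K` header lines carry metadata.
#'
#' @param dataset A `cmap_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(dataset, path) {
  stopifnot(inherits(dataset, "cmap_dataset"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# CMAP-style map file (minimal dialect)", con)
  write_header_lines(dataset$header, con, "#K")
  writeLines("#h\tCMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition\tCoverage", con)
  for (m in dataset$maps) {
    if (is.unsorted(m$labels)) stop("map '", m$id, "': unsorted labels on write")
    n <- length(m$labels)
    cov <- if (!is.null(m$support)) m$support else rep(1L, n)
    if (n > 0)
      writeLines(sprintf("%s\t%s\t%d\t%d\t1\t%s\t%d",
                         m$id, fmt_pos(m$length), n, seq_len(n),
                         fmt_pos(m$labels), as.integer(cov)), con)
    writeLines(sprintf("%s\t%s\t%d\t%d\t0\t%s\t0",
                       m$id, fmt_pos(m$length), n, n + 1L, fmt_pos(m$length)), con)
  }
  invisible(path)
}

#' Read a CMAP-style map file
#'
#' @param path Path written by [write_cmap()] (or following the same layout).
#' @param source Source tag to attach to the maps.
#' @return A `cmap_dataset`.
#' @export
read_cmap <- function(path, source = "assembly") {
  if (!file.exists(path)) stop("CMAP file not found: ", path)
  lines <- readLines(path)
  header <- parse_header_lines(lines, "#K")
  body <- lines[!startsWith(lines, "#")]
  maps <- list()
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ok <- vapply(parts, length, integer(1)) == 7L
    if (!all(ok)) stop("malformed CMAP row: ", body[which(!ok)[1]])
    tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(tab) <- c("id", "len", "nsites", "site", "channel", "pos", "cov")
    for (id in unique(tab$id)) {
      sub <- tab[tab$id == id, , drop = FALSE]
      len <- as.numeric(sub$len[1])
      lab <- sub[sub$channel == "1", , drop = FALSE]
      pos <- as.numeric(lab$pos)
      if (length(pos) && max(pos) > len + 1e-6)
        stop("map '", id, "': label position exceeds map length")
      sup <- if (nrow(lab)) as.integer(lab$cov) else NULL
      maps[[length(maps) + 1L]] <-
        label_map(id, len, pos, source = source, support = sup)
    }
  }
  cmap_dataset(maps, header)
}
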