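#' Molecule error model
#'
#' Error parameters of nanochannel optical mapping as seen at the molecule
#' level: spurious (false-positive) labels arriving at a fixed rate per
#' 100 kb, per-site label loss (false negatives), local sizing noise whose
#' sd grows with the square root of the inter-label gap, a per-molecule
#' multiplicative stretch, camera pixel quantization, and the optical
#' resolution below which neighbouring labels fuse.
#'
#' @param fp_rate False labels per 100 kb (default 1.5).
#' @param fn_prob Per-true-label miss probability (default 0.15).
#' @param sizing_sd_scale Coefficient `s0` (bp^0.5): gap noise sd =
#'   `s0 * sqrt(gap)` (default 5).
#' @param stretch_mean Mean per-molecule stretch factor (default 1.008,
#'   i.e. an effective scale of ~504 bp per 500-bp pixel).
#' @param stretch_sd Sd of the per-molecule stretch factor (default 0.01).
#' @param bpp Bases per pixel for position quantization; 0 disables
#'   quantization (default 500).
#' @param resolution_bp Label fusion distance in bp (default 500).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(fp_rate = 1.5, fn_prob = 0.15, sizing_sd_scale = 5,
                        stretch_mean = 1.008, stretch_sd = 0.01,
                        bpp = 500, resolution_bp = 500) {
  if (fp_rate < 0 || sizing_sd_scale < 0 || stretch_sd < 0 || bpp < 0 ||
      resolution_bp < 0 || stretch_mean <= 0)
    stop("noise model parameters must be non-negative (stretch_mean > 0)")
  if (fn_prob < 0 || fn_prob > 1) stop("fn_prob must be in [0, 1]")
  structure(list(fp_rate = fp_rate, fn_prob = fn_prob,
                 sizing_sd_scale = sizing_sd_scale,
                 stretch_mean = stretch_mean, stretch_sd = stretch_sd,
                 bpp = bpp, resolution_bp = resolution_bp),
            class = "noise_model")
}

#' Noise-free error model
#'
#' Convenience constructor: no FP/FN labels, no sizing noise, unit stretch,
#' quantization off. Useful for round-trip checks.
#' @return A `noise_model` with all error sources disabled.
#' @export
noise_model_none <- function() {
  noise_model(fp_rate = 0, fn_prob = 0, sizing_sd_scale = 0,
              stretch_mean = 1, stretch_sd = 0, bpp = 0)
}

#' Molecule length model
#'
#' Molecule lengths follow a log-normal law truncated at the instrument's
#' minimum reported length. Given the truncation point, the target N50 and
#' the target median of retained molecules, the log-normal parameters are
#' calibrated by root finding against the closed-form truncated partial
#' expectation, so simulated sets reproduce the target N50. Defaults mirror
#' a typical nanochannel run: molecules >= 100 kb with N50 about 176 kb and
#' roughly half of all molecules between 100 and 150 kb.
#'
#' @param min_len Minimum molecule length, bp (default 100,000).
#' @param target_n50 Target N50 of sampled lengths, bp (default 176,000).
#' @param target_median Target median length, bp (default 150,000).
#' @param meanlog,sdlog Log-normal parameters; calibrated automatically
#'   when `NULL`.
#' @return An object of class `molecule_length_model`.
#' @export
molecule_length_model <- function(min_len = 1e5, target_n50 = 176e3,
                                  target_median = 150e3,
                                  meanlog = NULL, sdlog = NULL) {
  if (min_len <= 0) stop("min_len must be > 0")
  if (is.null(meanlog) || is.null(sdlog)) {
    if (target_n50 <= target_median || target_median <= min_len)
      stop("need min_len < target_median < target_n50 for calibration")
    cal <- calibrate_lnorm_truncated(min_len, target_median, target_n50)
    meanlog <- cal$meanlog; sdlog <- cal$sdlog
  }
  structure(list(min_len = min_len, target_n50 = target_n50,
                 target_median = target_median,
                 meanlog = meanlog, sdlog = sdlog),
            class = "molecule_length_model")
}

# Closed-form N50 of a lognormal truncated below at t: the length L solving
# E[X 1(X>=L)] = 0.5 E[X 1(X>=t)], using
# E[X 1(X>=a)] = exp(mu + s^2/2) * pnorm((mu + s^2 - log a)/s).
lnorm_trunc_n50 <- function(meanlog, sdlog, t) {
  z <- (meanlog + sdlog^2 - log(t)) / sdlog
  exp(meanlog + sdlog^2 - sdlog * qnorm(0.5 * pnorm(z)))
}

lnorm_trunc_median <- function(meanlog, sdlog, t) {
  pt <- pnorm((log(t) - meanlog) / sdlog)
  exp(meanlog + sdlog * qnorm((1 + pt) / 2))
}

calibrate_lnorm_truncated <- function(t, med, n50) {
  # inner solve parametrized by pt = P(X < t) for numerical stability;
  # mu = log(t) - s * qnorm(pt), median condition in pt
  mu_for <- function(s) {
    g <- function(pt) log(t) - s * qnorm(pt) + s * qnorm((1 + pt) / 2) - log(med)
    if (g(1e-12) <= 0) return(log(med))  # truncation negligible at this s
    pt <- uniroot(g, lower = 1e-12, upper = 1 - 1e-9, tol = 1e-12)$root
    log(t) - s * qnorm(pt)
  }
  s <- uniroot(function(s) lnorm_trunc_n50(mu_for(s), s, t) - n50,
               lower = 0.05, upper = 3, tol = 1e-9)$root
  list(meanlog = mu_for(s), sdlog = s)
}

r_trunc_lnorm <- function(n, meanlog, sdlog, min_len) {
  p0 <- plnorm(min_len, meanlog, sdlog)
  qlnorm(runif(n, p0, 1), meanlog, sdlog)
}

#' Simulate a genome with a target label density
#'
#' Generates an i.i.d. background sequence at the requested GC content and
#' plants additional motif copies (forward or reverse complement, equal
#' odds) at Poisson spacings tuned so that the post-resolution label
#' density approximates `target_label_density`, accounting for both the
#' expected background motif rate and the expected loss to the resolution
#' merge. A rescan after planting reports the realized densities.
#'
#' @param length Genome length in bp.
#' @param gc GC content in (0, 1) (default 0.4).
#' @param target_label_density Target post-resolution labels per 100 kb.
#' @param seed Optional RNG seed.
#' @param params A `digest_params` (motif and resolution).
#' @param id Record id.
#' @return List: `record` (a `sequence_record`), `n_planted`, and realized
#'   `nick_density` / `label_density` from the rescan.
#' @export
simulate_genome <- function(length, gc = 0.4, target_label_density = 11,
                            seed = NULL, params = digest_params(),
                            id = "synth_genome") {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(probs), length, replace = TRUE, prob = probs)

  motif <- strsplit(params$motif, "")[[1]]
  m <- length(motif)
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[motif])
  # expected background occurrence rate per bp, both strands
  p1 <- prod(probs[motif]); p2 <- prod(probs[rc])
  bg_rate <- p1 + p2
  target_rate <- target_label_density / 1e5
  # post-merge density of a Poisson(lambda) site process is lambda*exp(-lambda*res)
  res <- params$resolution_bp
  max_rate <- if (res > 0) exp(-1) / res else Inf
  n_planted <- 0L
  if (target_rate > 0) {
    if (target_rate >= max_rate) {
      warning("target label density unachievable at this resolution; planting maximum")
      lambda_tot <- 1 / res
    } else if (res > 0) {
      lambda_tot <- uniroot(function(l) l * exp(-l * res) - target_rate,
                            lower = target_rate, upper = 1 / res, tol = 1e-14)$root
    } else lambda_tot <- target_rate
    lambda_plant <- lambda_tot - bg_rate
    if (lambda_plant < 0) {
      warning("background motif rate exceeds target density; planting none")
      lambda_plant <- 0
    }
    n_planted <- rpois(1, lambda_plant * max(0, length - m + 1))
    if (n_planted > 0) {
      pos <- sort(sample.int(length - m + 1L, n_planted))
      pos <- pos[c(TRUE, diff(pos) >= m)]  # avoid overlapping plants
      flip <- runif(length(pos)) < 0.5
      for (k in seq_along(pos)) {
        ins <- if (flip[k]) rc else motif
        bases[pos[k]:(pos[k] + m - 1L)] <- ins
      }
      n_planted <- length(pos)
    }
  }
  rec <- sequence_record(id, paste(bases, collapse = ""))
  dig <- digest_sequences(list(rec), params)
  list(record = rec, n_planted = n_planted,
       nick_density = dig$aggregate$nick_density,
       label_density = dig$aggregate$label_density)
}

#' Sample molecule intervals to a target depth
#'
#' Draws molecule lengths from the truncated log-normal law and uniform
#' start positions; sampling stops once the summed interval length reaches
#' `depth * genome_length`.
#'
#' @param genome_length Genome length, bp (must exceed the model minimum).
#' @param depth Target fold-coverage (> 0).
#' @param model A `molecule_length_model`.
#' @param seed Optional RNG seed.
#' @return A data.frame with columns `start`, `end` (0-based, end
#'   exclusive).
#' @export
sample_molecule_intervals <- function(genome_length, depth,
                                      model = molecule_length_model(),
                                      seed = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  if (genome_length < model$min_len)
    stop("genome shorter than the minimum molecule length")
  if (!is.null(seed)) set.seed(seed)
  target <- depth * genome_length
  starts <- numeric(0); ends <- numeric(0); total <- 0
  while (total < target) {
    k <- max(16L, ceiling((target - total) / model$target_median))
    lens <- pmin(r_trunc_lnorm(k, model$meanlog, model$sdlog, model$min_len),
                 genome_length)
    st <- floor(runif(k, 0, genome_length - lens + 1))
    keep <- cumsum(lens) <= (target - total)
    if (!any(keep)) keep[1] <- TRUE          # always take at least one
    last <- max(which(keep))
    if (last < k && total + sum(lens[seq_len(last)]) < target) last <- last + 1L
    idx <- seq_len(last)
    starts <- c(starts, st[idx]); ends <- c(ends, st[idx] + floor(lens[idx]))
    total <- total + sum(floor(lens[idx]))
  }
  data.frame(start = starts, end = ends)
}

#' Corrupt a molecule's true labels under the error model
#'
#' Applies the error pipeline in order: (1) drop each true label with
#' probability `fn_prob`; (2) add Poisson-distributed false labels uniform
#' on the molecule; (3) perturb every inter-label gap (including the two
#' terminal flanks) with Gaussian noise of sd `s0 * sqrt(gap)` and
#' re-accumulate positions; (4) apply the per-molecule stretch factor to
#' positions and length; (5) quantize to the pixel grid; (6) merge labels
#' below the optical resolution. Truth correspondence is recorded before
#' the merge.
#'
#' @param true_labels Ascending true label positions within the interval.
#' @param interval_length Interval length, bp.
#' @param noise A `noise_model`.
#' @param seed Optional RNG seed.
#' @param id Molecule id.
#' @return List: `molecule` (a `label_map`) and `truth` (list with
#'   `n_true`, `n_kept`, `n_fp`, pre-merge `origin` indices — `NA` for
#'   false labels — and the applied `stretch`).
#' @export
corrupt_molecule <- function(true_labels, interval_length,
                             noise = noise_model(), seed = NULL,
                             id = "mol") {
  if (!is.null(seed)) set.seed(seed)
  if (length(true_labels) &&
      (is.unsorted(true_labels) || true_labels[1] < 0 ||
       true_labels[length(true_labels)] > interval_length))
    stop("true_labels must be ascending within [0, interval_length]")
  n_true <- length(true_labels)
  kept <- if (n_true) which(runif(n_true) >= noise$fn_prob) else integer(0)
  pos <- true_labels[kept]
  origin <- kept
  n_fp <- rpois(1, noise$fp_rate * interval_length / 1e5)
  if (n_fp > 0) {
    pos <- c(pos, runif(n_fp, 0, interval_length))
    origin <- c(origin, rep(NA_integer_, n_fp))
  }
  ord <- order(pos)
  pos <- pos[ord]; origin <- origin[ord]

  len <- interval_length
  if (noise$sizing_sd_scale > 0 && length(pos)) {
    gaps <- diff(c(0, pos, len))
    gaps <- pmax(gaps + rnorm(length(gaps),
                              sd = noise$sizing_sd_scale * sqrt(pmax(gaps, 1))), 1)
    acc <- cumsum(gaps)
    pos <- acc[seq_along(pos)]
    len <- acc[length(acc)]
  }
  stretch <- if (noise$stretch_sd > 0 || noise$stretch_mean != 1)
    rnorm(1, noise$stretch_mean, noise$stretch_sd) else 1
  pos <- pos * stretch; len <- len * stretch
  if (noise$bpp > 0) {
    pos <- round(pos / noise$bpp) * noise$bpp
    len <- max(round(len / noise$bpp) * noise$bpp, max(pos, 0))
  }
  pos <- pmin(pmax(pos, 0), len)
  merged <- apply_resolution(pos, noise$resolution_bp)
  list(molecule = label_map(id, len, merged, source = "simulation"),
       truth = list(n_true = n_true, n_kept = length(kept), n_fp = n_fp,
                    origin = origin, pre_merge = pos, stretch = stretch))
}

#' Generate a simulated molecule dataset with truth
#'
#' Digests the genome, samples molecule intervals to the requested depth,
#' mirrors each molecule with probability 1/2 (nanochannel molecules carry
#' no orientation), and corrupts each under the error model. A single RNG
#' stream seeded once drives every stage, so identical seeds give
#' byte-identical BNX output.
#'
#' @param genome A `sequence_record` (or the list returned by
#'   [simulate_genome()]).
#' @param depth Target fold-coverage.
#' @param params A `digest_params`.
#' @param length_model A `molecule_length_model`.
#' @param noise A `noise_model`.
#' @param seed RNG seed (required for reproducibility).
#' @return List: `bnx` (a `bnx_dataset`), `truth` (data.frame: id,
#'   genome_id, start, end, strand, n_true, n_kept, n_fp, obs_length,
#'   stretch), and `digest` (the genome's true `label_map`).
#' @export
generate_dataset <- function(genome, depth, params = digest_params(),
                             length_model = molecule_length_model(),
                             noise = noise_model(), seed = 1L) {
  if (is.list(genome) && !inherits(genome, "sequence_record") &&
      !is.null(genome$record))
    genome <- genome$record
  stopifnot(inherits(genome, "sequence_record"))
  set.seed(seed)
  dig <- digest_sequences(list(genome), params)
  true_map <- dig$maps$maps[[1]]
  iv <- sample_molecule_intervals(genome$length, depth, length_model, seed = NULL)
  n <- nrow(iv)
  strands <- ifelse(runif(n) < 0.5, "+", "-")
  mols <- vector("list", n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    s <- iv$start[k]; e <- iv$end[k]; L <- e - s
    lab <- true_map$labels[true_map$labels >= s & true_map$labels < e] - s
    if (strands[k] == "-") lab <- rev(L - lab)
    id <- sprintf("mol_%06d", k)
    cm <- corrupt_molecule(lab, L, noise, seed = NULL, id = id)
    mols[[k]] <- cm$molecule
    rows[[k]] <- data.frame(
      id = id, genome_id = genome$id, start = s, end = e,
      strand = strands[k], n_true = cm$truth$n_true,
      n_kept = cm$truth$n_kept, n_fp = cm$truth$n_fp,
      obs_length = cm$molecule$length, stretch = cm$truth$stretch,
      stringsAsFactors = FALSE)
  }
  header <- c(seed = as.character(seed), depth = as.character(depth),
              bpp = as.character(noise$bpp),
              min_len = as.character(length_model$min_len))
  list(bnx = bnx_dataset(mols, header), truth = do.call(rbind, rows),
       digest = true_map)
}

#' Estimate realized FP and FN rates from simulation truth
#'
#' @param dataset A `bnx_dataset` from [generate_dataset()].
#' @param truth The matching truth data.frame.
#' @return List: `fp_hat` (false labels per 100 kb of molecule length) and
#'   `fn_hat` (fraction of true labels dropped).
#' @export
validate_rates <- function(dataset, truth) {
  if (is.null(truth) || !nrow(truth)) stop("truth table required")
  total_len <- sum(vapply(dataset$molecules, function(m) m$length, numeric(1)))
  list(fp_hat = sum(truth$n_fp) / total_len * 1e5,
       fn_hat = sum(truth$n_true - truth$n_kept) / sum(truth$n_true))
}
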