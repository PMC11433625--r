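## Synthetic data: genomes with planted primer sites and restriction sites,
## gel calibration datasets, and noise-corrupted measured profiles. Truth is
## exact by construction (rejection sampling keeps cores free of accidental
## sites), so the whole pipeline can be exercised against known answers.

#' Specification of a synthetic genome set
#'
#' Each synthetic genome is `pad + forward primer + core + revcomp(reverse
#' primer) + pad`; restriction sites are planted into the core at known
#' offsets and the core is otherwise kept free of the planted enzymes'
#' sites, so amplicon and fragment lengths are known analytically. Some
#' genomes are emitted as the reverse complement and some primer copies
#' carry substitutions, exercising the extraction fallbacks. A fraction of
#' species copy another species' amplicon verbatim (multi-species identical
#' barcodes, as real ITS databases contain).
#'
#' @param n_species number of species.
#' @param core_length_range inter-primer core length range in nt
#'   (default 200-1000, spanning the typical ITS barcode range).
#' @param planted_enzymes list of `list(enzyme = <enzyme>, n_sites = <int>)`
#'   entries; `n_sites` sites of each enzyme are planted per amplicon.
#' @param pad_length_range genomic padding outside the amplicon.
#' @param duplicate_fraction fraction of species sharing another species'
#'   amplicon sequence (default 0.1).
#' @param primer_mismatch_range range of substitutions planted into the
#'   forward-primer copy (default 0-2; 2 substitutions require the relaxed
#'   extraction pass).
#' @param revcomp_fraction fraction of genomes emitted reverse-complemented
#'   (default 0.5).
#' @param seed RNG seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_species, core_length_range = c(200, 1000),
                       planted_enzymes = list(
                         list(enzyme = enzyme("HaeIII", "GGCC", 2), n_sites = 2),
                         list(enzyme = enzyme("HinfI", "GANTC", 1), n_sites = 1)),
                       pad_length_range = c(20, 60),
                       duplicate_fraction = 0.1,
                       primer_mismatch_range = c(0, 2),
                       revcomp_fraction = 0.5,
                       seed = 1L) {
  stopifnot(n_species >= 1, all(core_length_range > 0),
            core_length_range[1] <= core_length_range[2],
            all(pad_length_range >= 0),
            duplicate_fraction >= 0, duplicate_fraction < 1,
            revcomp_fraction >= 0, revcomp_fraction <= 1,
            all(primer_mismatch_range >= 0))
  structure(list(n_species = as.integer(n_species),
                 core_length_range = as.integer(core_length_range),
                 planted_enzymes = planted_enzymes,
                 pad_length_range = as.integer(pad_length_range),
                 duplicate_fraction = duplicate_fraction,
                 primer_mismatch_range = as.integer(primer_mismatch_range),
                 revcomp_fraction = revcomp_fraction,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Gel measurement noise specification
#'
#' Parameters of the size-measurement error model used to corrupt true
#' fragment sizes: `measured = beta0 + beta1 * true + e`, with
#' `sd(e) = sigma * |mu|^delta` and AR(1) correlation `phi` across bands of
#' one lane (migration order). Fragments shorter than `dropout_below` are
#' invisible on the gel and are dropped.
#'
#' @param beta0,beta1 calibration line (nt; dimensionless slope).
#' @param sigma residual scale at size 1 (nt).
#' @param delta variance power exponent.
#' @param phi within-lane AR(1) coefficient.
#' @param dropout_below detection limit in nt (default 100).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(beta0 = 2, beta1 = 0.97, sigma = 1.5, delta = 0.6,
                       phi = 0.4, dropout_below = 100) {
  stopifnot(abs(phi) < 1, sigma >= 0, beta1 > 0)
  structure(list(beta0 = beta0, beta1 = beta1, sigma = sigma, delta = delta,
                 phi = phi, dropout_below = dropout_below),
            class = "noise_spec")
}

## overlap-aware fixed-string occurrence scan (independent of the regex
## machinery in cut_positions); returns 0-based starts
.site_occurrences <- function(seq, site) {
  n <- nchar(seq); out <- integer()
  for (ex in expand_iupac(site)) {
    sl <- nchar(ex)
    if (sl > n) next
    starts <- which(substring(seq, 1:(n - sl + 1L), sl:n) == ex)
    out <- c(out, starts - 1L)
  }
  sort(unique(out))
}

## sample one element safely (length-1 x is returned as-is, avoiding R's
## sample(n, 1) scalar surprise)
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## standardized AR(1) innovations of length k (unit marginal variance)
.ar1_unit <- function(k, phi) {
  z <- stats::rnorm(k)
  if (k == 0L) return(numeric())
  u <- numeric(k)
  u[1] <- z[1]
  if (k > 1L) for (i in 2:k) u[i] <- phi * u[i - 1] + sqrt(1 - phi^2) * z[i]
  u
}

## mutate k positions of a primer copy to bases outside the primer's
## IUPAC set at those positions
.mutate_primer <- function(primer, k) {
  if (k == 0L) return(primer)
  chars <- strsplit(primer, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    allowed <- strsplit(.IUPAC[[chars[p]]], "")[[1]]
    chars[p] <- .sample1(setdiff(c("A", "C", "G", "T"), allowed))
  }
  paste(chars, collapse = "")
}

#' Generate synthetic genomes with exact truth
#'
#' @param spec a [synth_spec()].
#' @param primers the [primer_pair()] planted into each genome.
#' @param max_tries rejection-sampling attempts per species before the
#'   planting is declared infeasible.
#' @return list with `sequences` (named character vector, names
#'   `"<species>|g1"`), and `truth`: per-species lists with `species`,
#'   `amplicon` (forward-oriented string), `amplicon_length`, `n_mismatch`,
#'   `revcomp`, `duplicate_of` and `fragments` (named list: enzyme ->
#'   integer fragment lengths, descending).
#' @export
synth_genomes <- function(spec, primers = its_primers(), max_tries = 500L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_species
  labels <- sprintf("sp%03d", seq_len(n))
  enz_list <- lapply(spec$planted_enzymes, `[[`, "enzyme")
  n_sites <- vapply(spec$planted_enzymes, `[[`, numeric(1), "n_sites")
  fwd <- primers$forward
  rev_rc <- revcomp(primers$reverse)

  make_one <- function() {
    for (try in seq_len(max_tries)) {
      L <- .sample1(spec$core_length_range[1]:spec$core_length_range[2])
      core <- random_dna(L)
      ## plant sites at non-overlapping offsets
      placements <- list()
      taken <- integer()
      ok <- TRUE
      for (j in seq_along(enz_list)) {
        sl <- nchar(enz_list[[j]]$site)
        starts <- integer()
        for (s in seq_len(n_sites[j])) {
          cand <- setdiff(seq_len(L - sl + 1L),
                          unlist(lapply(taken, function(t)
                            (t - sl + 1L):(t + sl - 1L))))
          if (!length(cand)) { ok <- FALSE; break }
          pos <- .sample1(cand)
          starts <- c(starts, pos)
          taken <- c(taken, pos:(pos + sl - 1L))
          ex <- expand_iupac(enz_list[[j]]$site)
          pick <- .sample1(ex)
          substr(core, pos, pos + sl - 1L) <- pick
        }
        if (!ok) break
        placements[[j]] <- sort(starts)
      }
      if (!ok) next

      k_mm <- .sample1(spec$primer_mismatch_range[1]:
                        spec$primer_mismatch_range[2])
      fwd_copy <- .mutate_primer(fwd, k_mm)
      amplicon <- paste0(fwd_copy, core, rev_rc)

      ## verify: occurrences over the whole amplicon are exactly the planted
      ## ones (insertions or primer copies may create accidental sites)
      good <- TRUE
      frag_truth <- list()
      for (j in seq_along(enz_list)) {
        e <- enz_list[[j]]
        occ <- .site_occurrences(amplicon, e$site)
        planted <- placements[[j]] - 1L + nchar(fwd_copy)
        if (!identical(occ, as.integer(sort(planted)))) { good <- FALSE; break }
        cuts <- sort(planted + e$cut_offset)
        cuts <- cuts[cuts > 0L & cuts < nchar(amplicon)]
        frag_truth[[e$name]] <- sort(diff(c(0L, cuts, nchar(amplicon))),
                                     decreasing = TRUE)
      }
      if (!good) next
      return(list(amplicon = amplicon, n_mismatch = k_mm,
                  fragments = frag_truth))
    }
    stop("infeasible planting: could not place ",
         sum(n_sites), " site(s) in a clean core after ", max_tries,
         " attempts")
  }

  truth <- vector("list", n)
  names(truth) <- labels
  for (i in seq_len(n)) {
    t1 <- make_one()
    truth[[i]] <- list(species = labels[i], amplicon = t1$amplicon,
                       amplicon_length = nchar(t1$amplicon),
                       n_mismatch = t1$n_mismatch, revcomp = FALSE,
                       duplicate_of = NA_character_,
                       fragments = t1$fragments)
  }

  ## duplicates: overwrite the amplicon of selected species with a copy
  n_dup <- round(spec$duplicate_fraction * n)
  if (n_dup > 0 && n >= 2) {
    dup_idx <- if (n == 2L) 2L else sample(2:n, min(n_dup, n - 1))
    for (i in dup_idx) {
      src <- .sample1(setdiff(seq_len(i - 1), dup_idx))
      truth[[i]]$amplicon <- truth[[src]]$amplicon
      truth[[i]]$amplicon_length <- truth[[src]]$amplicon_length
      truth[[i]]$n_mismatch <- truth[[src]]$n_mismatch
      truth[[i]]$fragments <- truth[[src]]$fragments
      truth[[i]]$duplicate_of <- truth[[src]]$species
    }
  }

  sequences <- character(n)
  for (i in seq_len(n)) {
    pad1 <- random_dna(.sample1(spec$pad_length_range[1]:
                                   spec$pad_length_range[2]))
    pad2 <- random_dna(.sample1(spec$pad_length_range[1]:
                                   spec$pad_length_range[2]))
    g <- paste0(pad1, truth[[i]]$amplicon, pad2)
    if (stats::runif(1) < spec$revcomp_fraction) {
      g <- revcomp(g)
      truth[[i]]$revcomp <- TRUE
    }
    sequences[i] <- g
  }
  names(sequences) <- paste0(labels, "|g1")
  list(sequences = sequences, truth = truth)
}

#' Write synthetic genomes to FASTA
#'
#' @param genomes result of [synth_genomes()].
#' @param path output FASTA path.
#' @return `path` invisibly.
#' @export
write_synth_fasta <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Simulate a gel calibration dataset
#'
#' Expected sizes are drawn per lane, ordered by descending size (migration
#' order) and measured through the noise model: heteroscedastic
#' (power-of-mean) errors with AR(1) correlation along the lane.
#'
#' @param noise a [noise_spec()].
#' @param n_lanes,fragments_per_lane dataset shape.
#' @param seed RNG seed.
#' @param size_range range of expected sizes (nt).
#' @return data frame with columns `expected`, `measured`, `lane_id`,
#'   `rank`.
#' @export
synth_calibration <- function(noise = noise_spec(), n_lanes = 40,
                              fragments_per_lane = 8, seed = 1L,
                              size_range = c(100, 1000)) {
  stopifnot(inherits(noise, "noise_spec"))
  set.seed(seed)
  rows <- lapply(seq_len(n_lanes), function(l) {
    expected <- sort(sample(size_range[1]:size_range[2], fragments_per_lane),
                     decreasing = TRUE)
    mu <- noise$beta0 + noise$beta1 * expected
    u <- .ar1_unit(fragments_per_lane, noise$phi)
    measured <- mu + noise$sigma * abs(mu)^noise$delta * u
    data.frame(expected = expected, measured = pmax(measured, 1),
               lane_id = sprintf("lane%03d", l),
               rank = seq_len(fragments_per_lane))
  })
  do.call(rbind, rows)
}

#' Corrupt a true fragment profile with gel noise
#'
#' Fragments below the detection limit are dropped; the survivors are
#' measured through the noise model with AR(1) correlation along their
#' migration order (descending size).
#'
#' @param true_profile a `fragment_profile` or numeric vector of true
#'   fragment lengths.
#' @param noise a [noise_spec()].
#' @param seed optional RNG seed.
#' @param enzyme_name carried into the result when `true_profile` is a bare
#'   vector.
#' @return a [measured_profile()].
#' @export
simulate_measured_profile <- function(true_profile, noise = noise_spec(),
                                      seed = NULL, enzyme_name = NA_character_) {
  if (inherits(true_profile, "fragment_profile")) {
    enzyme_name <- true_profile$enzyme
    true_profile <- true_profile$fragments
  }
  if (!is.null(seed)) set.seed(seed)
  frags <- sort(filter_detectable(true_profile, noise$dropout_below),
                decreasing = TRUE)
  if (!length(frags))
    return(suppressWarnings(measured_profile(enzyme_name, numeric(),
                                             noise$dropout_below)))
  mu <- noise$beta0 + noise$beta1 * frags
  u <- .ar1_unit(length(frags), noise$phi)
  measured <- pmax(mu + noise$sigma * abs(mu)^noise$delta * u, 1)
  measured_profile(enzyme_name, measured,
                   min_detectable = noise$dropout_below)
}
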