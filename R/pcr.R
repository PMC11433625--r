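## In-silico PCR: degenerate primer matching and amplicon extraction.
##
## The ITS1-5.8S-ITS2 region is delimited by the universal fungal primers
## ITS1/ITS4; we look for the forward primer and, downstream of it, the
## reverse complement of the reverse primer, and return the convergent span.

#' Primer pair constructor
#'
#' Both primers are given 5'->3' as on the order sheet. The default pair is
#' the universal fungal ITS pair amplifying the ITS1-5.8S-ITS2 region.
#'
#' @param forward,reverse primer sequences (IUPAC codes allowed).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  check_iupac(forward)
  check_iupac(reverse)
  structure(list(forward = toupper(forward), reverse = toupper(reverse)),
            class = "primer_pair")
}

#' @rdname primer_pair
#' @export
its_primers <- function() {
  primer_pair(forward = "TCCGTAGGTGAACCTGCGG",
              reverse = "TCCTCCGCTTATTGATATGC")
}

#' In-silico PCR parameters
#'
#' @param max_error_rate allowed mismatch fraction of the matched primer
#'   length on the first pass (default 0.10, i.e. floor(0.1 * 19) = 1
#'   mismatch for a 19-nt primer).
#' @param relaxed_error_rate mismatch fraction used when the first pass finds
#'   nothing (default 0.20).
#' @param min_overlap minimum number of primer bases that must align when a
#'   primer hangs off a sequence end (default 18 nt).
#' @param min_amplicon_len shortest span accepted as a genuine amplicon
#'   (default 200 nt); shorter spans trigger the fallback passes.
#' @param include_primers_in_length if `TRUE` (default) the reported amplicon
#'   length covers both primer binding sites, matching what a gel measures.
#' @param max_passes number of (error-rate) passes attempted per strand.
#' @return an object of class `pcr_params`.
#' @export
pcr_params <- function(max_error_rate = 0.10, relaxed_error_rate = 0.20,
                       min_overlap = 18L, min_amplicon_len = 200L,
                       include_primers_in_length = TRUE, max_passes = 2L) {
  stopifnot(max_error_rate >= 0, max_error_rate < 0.5,
            relaxed_error_rate >= 0, relaxed_error_rate < 0.5,
            min_overlap >= 1, min_amplicon_len > 0, max_passes >= 1)
  structure(list(max_error_rate = max_error_rate,
                 relaxed_error_rate = relaxed_error_rate,
                 min_overlap = as.integer(min_overlap),
                 min_amplicon_len = as.integer(min_amplicon_len),
                 include_primers_in_length = isTRUE(include_primers_in_length),
                 max_passes = as.integer(max_passes)),
            class = "pcr_params")
}

#' Find degenerate primer matches in a sequence
#'
#' Scans for occurrences of `primer` in `seq` allowing substitutions only
#' (no indels): a window matches when its mismatch count does not exceed
#' `floor(error_rate * matched_length)`. Full-length internal windows are
#' scanned, plus partial windows hanging off either sequence end with at
#' least `params$min_overlap` aligned bases. Ambiguity codes in the primer
#' match set-wise; non-ACGT letters in the subject never match.
#'
#' @param seq subject DNA string.
#' @param primer primer DNA string (IUPAC allowed).
#' @param params a [pcr_params()] object.
#' @param error_rate mismatch fraction; defaults to `params$max_error_rate`.
#' @return data frame with columns `start`, `end` (0-based, half-open),
#'   `n_errors`, `length`, sorted by `start`.
#' @export
find_primer_matches <- function(seq, primer, params = pcr_params(),
                                error_rate = params$max_error_rate) {
  check_iupac(seq)
  check_iupac(primer)
  s <- seq_mask(seq, concrete_only = TRUE)
  p <- seq_mask(primer)
  n <- length(s); m <- length(p)
  hits <- list()

  ## full-length internal windows
  nw <- n - m + 1L
  if (nw >= 1L) {
    mism <- integer(nw)
    for (j in seq_len(m))
      mism <- mism + as.integer(bitwAnd(s[j:(j + nw - 1L)], p[j]) == 0L)
    allowed <- floor(error_rate * m)
    k <- which(mism <= allowed)
    if (length(k))
      hits[[length(hits) + 1L]] <- data.frame(
        start = k - 1L, end = k - 1L + m, n_errors = mism[k], length = m)
  }

  ## partial windows at the ends (primer hanging off the edge)
  ov_max <- min(m - 1L, n)
  if (params$min_overlap <= ov_max) {
    for (L in params$min_overlap:ov_max) {
      allowed <- floor(error_rate * L)
      ## primer 3' suffix aligned to the sequence start
      e1 <- sum(bitwAnd(s[seq_len(L)], p[(m - L + 1L):m]) == 0L)
      if (e1 <= allowed)
        hits[[length(hits) + 1L]] <- data.frame(
          start = 0L, end = L, n_errors = as.integer(e1), length = L)
      ## primer 5' prefix aligned to the sequence end
      e2 <- sum(bitwAnd(s[(n - L + 1L):n], p[seq_len(L)]) == 0L)
      if (e2 <= allowed)
        hits[[length(hits) + 1L]] <- data.frame(
          start = n - L, end = n, n_errors = as.integer(e2), length = L)
    }
  }

  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      n_errors = integer(), length = integer()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, -out$length, out$n_errors), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## one extraction attempt on a fixed strand at a fixed error rate
.extract_once <- function(seq, primers, params, error_rate) {
  fwd <- find_primer_matches(seq, primers$forward, params, error_rate)
  rev <- find_primer_matches(seq, revcomp(primers$reverse), params, error_rate)
  if (!nrow(fwd) || !nrow(rev)) return(NULL)
  spans <- list()
  for (i in seq_len(nrow(fwd))) {
    dn <- rev[rev$start >= fwd$end[i], , drop = FALSE]
    if (!nrow(dn)) next
    for (j in seq_len(nrow(dn))) {
      spans[[length(spans) + 1L]] <- c(start = fwd$start[i], end = dn$end[j],
                                       fwd_len = fwd$length[i],
                                       rev_len = dn$length[j])
    }
  }
  if (!length(spans)) return(NULL)
  spans <- do.call(rbind, spans)
  spans <- spans[spans[, "end"] - spans[, "start"] >= params$min_amplicon_len,
                 , drop = FALSE]
  if (!nrow(spans)) return(NULL)
  lens <- spans[, "end"] - spans[, "start"]
  if (length(unique(lens)) > 1L)
    warning("multiple convergent primer pairings with distinct spans (",
            paste(sort(unique(lens)), collapse = ", "),
            " nt); keeping the 5'-most innermost", call. = FALSE)
  spans[1L, ]
}

#' Extract the amplicon a primer pair would produce
#'
#' Emulates a PCR on one template: finds a forward-primer site and, downstream
#' of it, the reverse complement of the reverse primer, and returns the
#' convergent span. If no span of at least `min_amplicon_len` is found, the
#' scan is retried at the relaxed error rate, then on the reverse complement
#' of the template (re-orienting the result forward), then relaxed on that
#' strand. Flags record which fallback fired.
#'
#' @param seq template DNA string.
#' @param primers a [primer_pair()].
#' @param params a [pcr_params()].
#' @param species_label,seq_id labels carried into the record.
#' @return an `amplicon_record` (list with `species_label`, `seq_id`,
#'   `sequence`, `length`, `extraction_flags`) or `NULL` when every pass
#'   fails.
#' @export
extract_amplicon <- function(seq, primers = its_primers(),
                             params = pcr_params(),
                             species_label = NA_character_,
                             seq_id = NA_character_) {
  check_iupac(seq)
  seq <- toupper(seq)
  passes <- list(
    list(s = seq,          rate = params$max_error_rate,     flags = character()),
    list(s = seq,          rate = params$relaxed_error_rate, flags = "relaxed_error"),
    list(s = revcomp(seq), rate = params$max_error_rate,     flags = "reverse_complemented"),
    list(s = revcomp(seq), rate = params$relaxed_error_rate,
         flags = c("relaxed_error", "reverse_complemented"))
  )
  for (p in passes) {
    hit <- .extract_once(p$s, primers, params, p$rate)
    if (is.null(hit)) next
    span_seq <- substr(p$s, hit[["start"]] + 1L, hit[["end"]])
    len <- if (params$include_primers_in_length) nchar(span_seq)
           else nchar(span_seq) - hit[["fwd_len"]] - hit[["rev_len"]]
    return(structure(list(species_label = species_label, seq_id = seq_id,
                          sequence = span_seq, length = as.integer(len),
                          extraction_flags = p$flags),
                     class = "amplicon_record"))
  }
  NULL
}

#' @export
print.amplicon_record <- function(x, ...) {
  cat("<amplicon_record> ", x$species_label,
      if (!is.na(x$seq_id)) paste0(" [", x$seq_id, "]"), "\n",
      "  length: ", x$length, " nt",
      if (length(x$extraction_flags))
        paste0("  flags: ", paste(x$extraction_flags, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}
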