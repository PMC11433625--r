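# Shared fixtures and independent oracles for the suite.

# a small, fairly discriminative panel of 4-cutters
toy_panel <- function() {
  list(enzyme("HaeIII", "GGCC", 2), enzyme("HinfI", "GANTC", 1),
       enzyme("AluI", "AGCT", 2), enzyme("TaqI", "TCGA", 1),
       enzyme("RsaI", "GTAC", 2), enzyme("MseI", "TTAA", 1))
}

# zero-noise calibration model: permissive ranges collapse to points
identity_model <- function(min_detectable = 0) {
  structure(list(kind = "lm", beta0 = 0, beta1 = 1, sigma = 0, delta = 0,
                 phi = 0, level = 0.95, min_detectable = min_detectable,
                 loglik = NA_real_, n = 0L, converged = TRUE),
            class = "calibration_model")
}

# oracle: exhaustive sliding-window Hamming scan for full-length primer
# occurrences (substitutions only; IUPAC sets in the primer)
oracle_primer_scan <- function(seq, primer, max_err) {
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(primer), "")[[1]]
  sets <- rflpid:::.IUPAC
  m <- length(pc)
  out <- integer()
  for (s in seq_len(length(sc) - m + 1L)) {
    err <- 0L
    for (j in seq_len(m)) {
      sj <- sc[s + j - 1L]
      ok <- sj %in% strsplit(sets[[pc[j]]], "")[[1]]
      if (!ok) err <- err + 1L
    }
    if (err <= max_err) out <- c(out, s - 1L)
  }
  out
}

# oracle: naive digestion by scanning every IUPAC expansion with a
# character-by-character window comparison
oracle_digest <- function(seq, enz) {
  seq <- toupper(seq)
  n <- nchar(seq)
  cuts <- integer()
  for (ex in expand_iupac(enz$site)) {
    sl <- nchar(ex)
    if (sl > n) next
    for (s in seq_len(n - sl + 1L))
      if (substr(seq, s, s + sl - 1L) == ex)
        cuts <- c(cuts, s - 1L + enz$cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < n]
  sort(diff(c(0L, cuts, n)), decreasing = TRUE)
}

# oracle: maximum bipartite matching by brute force over all injections
oracle_match <- function(ranges, refs) {
  nq <- nrow(ranges)
  nr <- length(refs)
  compat <- function(i, j) refs[j] >= ranges[i, 1] && refs[j] <= ranges[i, 2]
  best <- 0L
  assign_next <- function(i, used, size) {
    if (size + (nq - i + 1L) <= best) return()
    if (i > nq) { best <<- max(best, size); return() }
    assign_next(i + 1L, used, size)  # leave query i unmatched
    for (j in seq_len(nr)) if (!used[j] && compat(i, j)) {
      used[j] <- TRUE
      assign_next(i + 1L, used, size + 1L)
      used[j] <- FALSE
    }
  }
  assign_next(1L, logical(nr), 0L)
  best
}

# random concrete enzyme with a short (possibly ambiguous) site
random_enzyme <- function() {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "N")
  len <- sample(3:5, 1)
  site <- paste(sample(codes, len, replace = TRUE,
                       prob = c(rep(0.2, 4), rep(0.05, 5))), collapse = "")
  enzyme(paste0("rnd", sample(1e6, 1)), site, sample(0:len, 1))
}
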