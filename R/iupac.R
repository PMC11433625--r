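## IUPAC nucleotide code utilities shared by the PCR and restriction modules.

.IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

## bitmask per base: A=1, C=2, G=4, T=8; a degenerate code is the union of its bases
.IUPAC_MASK <- vapply(.IUPAC, function(s) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[strsplit(s, "")[[1]]])
}, integer(1))

.COMPLEMENT_FROM <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
.COMPLEMENT_TO <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Validate a nucleotide string against the IUPAC alphabet
#'
#' @param x character string.
#' @param allow_ambiguous if `FALSE`, only A/C/G/T are accepted.
#' @return `TRUE` invisibly; throws an error for an invalid alphabet.
#' @keywords internal
check_iupac <- function(x, allow_ambiguous = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop("sequence must be a single non-empty character string")
  chars <- unique(strsplit(toupper(x), "")[[1]])
  allowed <- if (allow_ambiguous) names(.IUPAC) else c("A", "C", "G", "T")
  bad <- setdiff(chars, allowed)
  if (length(bad))
    stop("invalid nucleotide code(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Reverse complement of a (possibly IUPAC-ambiguous) DNA string
#'
#' Ambiguity codes are complemented set-wise (R <-> Y, K <-> M, ...).
#'
#' @param x character string of IUPAC nucleotide codes.
#' @return the reverse complement, same case as input.
#' @examples
#' revcomp("ACGTN")   # "NACGT"
#' revcomp("GANTC")   # "GANTC" (HinfI site is its own reverse complement)
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr(.COMPLEMENT_FROM, .COMPLEMENT_TO, s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand an IUPAC-ambiguous site to all concrete sequences
#'
#' A recognition site containing degenerate codes stands for the set of all
#' concrete A/C/G/T strings obtained by substituting each code with every base
#' it denotes; the cardinality is the product of the per-position degeneracies.
#'
#' @param site IUPAC string.
#' @return character vector of concrete DNA strings, all of length
#'   `nchar(site)`, in lexicographic order.
#' @examples
#' expand_iupac("GGCC")
#' expand_iupac("RGCY")  # 4 strings
#' @export
expand_iupac <- function(site) {
  check_iupac(site)
  sets <- lapply(strsplit(toupper(site), "")[[1]],
                 function(ch) strsplit(.IUPAC[[ch]], "")[[1]])
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  sort(out)
}

## regex character-class form of a site; non-ACGT subject letters can never
## match because classes only ever contain concrete bases
iupac_to_regex <- function(site) {
  check_iupac(site)
  paste(vapply(strsplit(toupper(site), "")[[1]], function(ch) {
    bases <- .IUPAC[[ch]]
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1)), collapse = "")
}

## integer bitmasks for a sequence; letters outside the IUPAC alphabet get 0
## (never match anything). strict masks keep only concrete bases: ambiguous
## letters in a *subject* sequence never count as a primer/site match.
seq_mask <- function(x, concrete_only = FALSE) {
  chars <- strsplit(toupper(x), "")[[1]]
  m <- unname(.IUPAC_MASK[chars])
  m[is.na(m)] <- 0L
  if (concrete_only)
    m[!chars %in% c("A", "C", "G", "T")] <- 0L
  m
}

## uniform random A/C/G/T string (helper for the synthetic module)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
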