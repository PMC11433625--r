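## Restriction enzymes and in-silico digestion.

#' Restriction enzyme constructor
#'
#' @param name enzyme name; a name like `"CfoI/HhaI/HinP1I"` denotes a group
#'   of site-isoschizomers reported as one entry.
#' @param site IUPAC recognition site, length >= 2.
#' @param cut_offset cut position measured from the site start: the cut falls
#'   between positions `cut_offset - 1` and `cut_offset` of the top strand.
#'   Must lie inside or at either boundary of the site (enzymes cutting at a
#'   distance from their site are not modelled).
#' @param group optional group label; defaults to `name` when it contains
#'   `"/"`.
#' @return an object of class `enzyme`.
#' @examples
#' enzyme("HaeIII", "GGCC", 2)
#' @export
enzyme <- function(name, site, cut_offset, group = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_iupac(site)
  site <- toupper(site)
  if (nchar(site) < 2L) stop("recognition site must be at least 2 nt")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop("cut offset must lie within the recognition site (0..",
         nchar(site), ")")
  if (is.null(group) && grepl("/", name, fixed = TRUE)) group <- name
  structure(list(name = name, site = site, cut_offset = cut_offset,
                 group = group),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat("<enzyme> ", x$name, ": ",
      substr(x$site, 1, x$cut_offset), "^",
      substr(x$site, x$cut_offset + 1, nchar(x$site)),
      if (!is.null(x$group)) paste0("  (group: ", x$group, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Parse a tab-delimited enzyme table
#'
#' Each non-comment line reads `name<TAB>site`, where `^` in the site marks
#' the cut position (e.g. `HaeIII<TAB>GG^CC`). Lines starting with `#` and
#' blank lines are skipped. Duplicate names are rejected; names containing
#' `/` are recorded as site-isoschizomer groups.
#'
#' @param text character vector of lines, or a length-1 string with embedded
#'   newlines.
#' @return list of [enzyme()] objects.
#' @seealso [read_enzyme_file()]
#' @export
parse_enzyme_table <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text)) & !grepl("^\\s*#", text)]
  out <- vector("list", length(text))
  for (i in seq_along(text)) {
    parts <- strsplit(text[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("line ", i, ": expected 'name<TAB>site', got: ", text[i])
    name <- trimws(parts[1]); site <- trimws(parts[2])
    caret <- regexpr("^", site, fixed = TRUE)
    if (caret < 0L)
      stop("line ", i, " (", name, "): site has no '^' cut marker")
    bare <- sub("^", "", site, fixed = TRUE)
    if (grepl("^", bare, fixed = TRUE))
      stop("line ", i, " (", name, "): more than one '^' in site")
    e <- tryCatch(enzyme(name, bare, caret - 1L),
                  error = function(err)
                    stop("line ", i, " (", name, "): ",
                         conditionMessage(err), call. = FALSE))
    out[[i]] <- e
  }
  nms <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate enzyme name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(out) <- nms
  out
}

#' @param path path to an enzyme table file.
#' @rdname parse_enzyme_table
#' @export
read_enzyme_file <- function(path) {
  parse_enzyme_table(readLines(path, warn = FALSE))
}

#' Top-strand cut coordinates of an enzyme in a sequence
#'
#' Every occurrence of the (IUPAC-expanded) recognition site is found,
#' overlapping occurrences included; an occurrence starting at 0-based `s`
#' contributes the cut coordinate `s + cut_offset`. Coordinates are
#' deduplicated and only cuts strictly inside the sequence are kept (a cut at
#' 0 or at the full length produces no new fragment). Positions of the
#' subject containing non-ACGT letters never match; a warning is emitted when
#' such letters are present.
#'
#' @param seq concrete amplicon DNA string.
#' @param enz an [enzyme()].
#' @return sorted integer vector of cut coordinates.
#' @examples
#' cut_positions("AAAAGGCCAAAA", enzyme("HaeIII", "GGCC", 2))  # 6
#' @export
cut_positions <- function(seq, enz) {
  check_iupac(seq)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    warning("sequence contains ambiguous bases; they never match a site",
            call. = FALSE)
  ## lookahead regex finds overlapping occurrences
  pat <- paste0("(?=", iupac_to_regex(enz$site), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] < 0L) return(integer())
  starts <- as.integer(m) - 1L
  cuts <- sort(unique(starts + enz$cut_offset))
  cuts[cuts > 0L & cuts < nchar(seq)]
}

#' Digest an amplicon with one enzyme
#'
#' Fragments are the consecutive differences of `c(0, cuts, length)`; their
#' sum always equals the amplicon length. Only top-strand coordinates are
#' modelled: the few-nt 5'/3' overhang asymmetry of sticky ends is far below
#' gel resolution.
#'
#' @param amplicon an `amplicon_record`, or a plain DNA string.
#' @param enz an [enzyme()].
#' @return a `fragment_profile`: list with `enzyme`, `fragments` (integer
#'   vector sorted descending) and `amplicon_length`.
#' @export
digest <- function(amplicon, enz) {
  seq <- if (inherits(amplicon, "amplicon_record")) amplicon$sequence
         else amplicon
  cuts <- cut_positions(seq, enz)
  frags <- diff(c(0L, cuts, nchar(seq)))
  fragment_profile(enz$name, frags, nchar(seq))
}

#' @param enzyme_name name of the enzyme that produced the fragments.
#' @param fragments integer vector of fragment lengths.
#' @param amplicon_length total length; must equal `sum(fragments)`.
#' @rdname digest
#' @export
fragment_profile <- function(enzyme_name, fragments, amplicon_length) {
  fragments <- as.integer(fragments)
  amplicon_length <- as.integer(amplicon_length)
  stopifnot(all(fragments >= 1L), sum(fragments) == amplicon_length)
  structure(list(enzyme = enzyme_name,
                 fragments = sort(fragments, decreasing = TRUE),
                 amplicon_length = amplicon_length),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat("<fragment_profile> ", x$enzyme, " on ", x$amplicon_length, " nt: ",
      paste(x$fragments, collapse = ";"), "\n", sep = "")
  invisible(x)
}

#' Collapse site-isoschizomers to one profile per recognition site
#'
#' Enzymes sharing a recognition sequence but cutting at different offsets
#' shift fragment boundaries by at most a few nt -- below gel resolution.
#' This helper merges such enzymes into a single entry named
#' `"A/B/..."` keeping the first member's cut offset.
#'
#' @param enzymes list of [enzyme()] objects.
#' @return list of enzymes with one entry per distinct site.
#' @export
collapse_isoschizomers <- function(enzymes) {
  sites <- vapply(enzymes, `[[`, character(1), "site")
  out <- lapply(split(seq_along(enzymes), sites), function(idx) {
    members <- enzymes[idx]
    if (length(members) == 1L) return(members[[1]])
    nm <- paste(vapply(members, `[[`, character(1), "name"), collapse = "/")
    enzyme(nm, members[[1]]$site, members[[1]]$cut_offset, group = nm)
  })
  out <- unname(out)
  names(out) <- vapply(out, `[[`, character(1), "name")
  out[order(names(out))]
}
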