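## The species x enzyme restriction-profile database: build, deduplicate,
## serialize, load, summarize.

#' Build a restriction-profile database from FASTA sequences
#'
#' For every species, the amplicon the primer pair would produce is extracted
#' ([extract_amplicon()]) and digested in silico with every enzyme of the
#' panel. Species whose templates yield no amplicon are listed in a skip
#' report; enzymes whose site occurs in no amplicon are dropped from the
#' panel with a notice (they carry no information for this database).
#' Species sharing a byte-identical amplicon sequence are collected into
#' duplicate groups: no enzyme can ever distinguish them.
#'
#' @param fasta path to a (multi-)FASTA file, a `Biostrings::DNAStringSet`,
#'   or a named character vector of sequences. Record names are parsed as
#'   `"species_label<sep>seq_id"`; the id part is optional.
#' @param enzymes list of [enzyme()] objects (the candidate panel).
#' @param primers a [primer_pair()].
#' @param pcr a [pcr_params()].
#' @param label_sep separator between species label and sequence id in the
#'   FASTA headers (default `"|"`).
#' @return an object of class `profile_db`: list with `records` (per-species
#'   lists: `species_label`, `taxonomy`, `amplicon`, `profiles`),
#'   `duplicate_groups`, `enzymes` (retained panel), `dropped_enzymes`,
#'   `skipped` (data frame), `params`.
#' @export
build_profile_db <- function(fasta, enzymes, primers = its_primers(),
                             pcr = pcr_params(), label_sep = "|") {
  seqs <- .load_sequences(fasta)
  if (!length(seqs)) stop("no sequences found in input")
  labels <- vapply(strsplit(names(seqs), label_sep, fixed = TRUE),
                   `[[`, character(1), 1L)
  ids <- vapply(strsplit(names(seqs), label_sep, fixed = TRUE), function(p)
    if (length(p) > 1L) paste(p[-1L], collapse = label_sep) else NA_character_,
    character(1))

  records <- list()
  skipped <- list()
  for (i in seq_along(seqs)) {
    lab <- labels[i]
    if (!is.null(records[[lab]])) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(species = lab, seq_id = ids[i],
                   reason = "species already represented")
      next
    }
    amp <- extract_amplicon(seqs[[i]], primers, pcr,
                            species_label = lab, seq_id = ids[i])
    if (is.null(amp)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(species = lab, seq_id = ids[i],
                   reason = "no amplicon (all extraction passes failed)")
      next
    }
    records[[lab]] <- list(species_label = lab, taxonomy = NULL,
                           amplicon = amp, profiles = NULL)
  }
  if (!length(records))
    stop("no species yielded an amplicon; nothing to build")

  ## digest, then drop enzymes with zero sites across all amplicons
  panel <- enzymes
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  cut_any <- setNames(logical(length(panel)), names(panel))
  for (lab in names(records)) {
    profs <- lapply(panel, function(e) digest(records[[lab]]$amplicon, e))
    names(profs) <- names(panel)
    records[[lab]]$profiles <- profs
    cut_any <- cut_any | vapply(profs, function(p)
      length(p$fragments) > 1L, logical(1))
  }
  dropped <- names(panel)[!cut_any]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " enzyme(s) with no site in any amplicon: ",
            paste(dropped, collapse = ", "))
    panel <- panel[cut_any]
    for (lab in names(records))
      records[[lab]]$profiles <- records[[lab]]$profiles[names(panel)]
  }

  dup <- dedupe_sequences(records)
  ## identical sequences must give identical profiles under every enzyme
  for (grp in dup) {
    ref <- records[[grp[1]]]$profiles
    for (other in grp[-1])
      stopifnot(identical(
        lapply(records[[other]]$profiles, `[[`, "fragments"),
        lapply(ref, `[[`, "fragments")))
  }

  structure(list(
    records = records,
    duplicate_groups = dup,
    enzymes = panel,
    dropped_enzymes = dropped,
    skipped = if (length(skipped)) do.call(rbind, skipped)
              else data.frame(species = character(), seq_id = character(),
                              reason = character()),
    params = list(primers = primers, pcr = pcr)
  ), class = "profile_db")
}

.load_sequences <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) {
    setNames(as.character(fasta), names(fasta))
  } else if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    setNames(as.character(x), names(x))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else {
    stop("fasta must be a file path, a DNAStringSet, ",
         "or a named character vector")
  }
}

#' @export
print.profile_db <- function(x, ...) {
  cat("<profile_db> ", length(x$records), " species x ",
      length(x$enzymes), " enzymes\n", sep = "")
  if (length(x$duplicate_groups))
    cat("  duplicate sequence groups: ", length(x$duplicate_groups), "\n",
        sep = "")
  if (nrow(x$skipped))
    cat("  skipped inputs: ", nrow(x$skipped), "\n", sep = "")
  invisible(x)
}

#' Group species by identical amplicon sequence
#'
#' @param records a `profile_db`, its `records` list, or a named character
#'   vector of sequences.
#' @return list of character vectors (species labels), one per group of two
#'   or more species sharing an identical amplicon sequence; singletons are
#'   omitted. Groups are sorted by their first label for determinism.
#' @export
dedupe_sequences <- function(records) {
  if (inherits(records, "profile_db")) records <- records$records
  seqs <- if (is.character(records)) records
          else vapply(records, function(r) r$amplicon$sequence, character(1))
  groups <- split(names(seqs), seqs)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  groups <- lapply(groups, sort)
  groups <- unname(groups[order(vapply(groups, `[[`, character(1), 1L))])
  groups
}

#' Serialize / load a profile database
#'
#' The database is written as a TSV (one row per species x enzyme:
#' `species, amplicon_length, enzyme, fragments` with fragments `;`-joined
#' in descending order) plus a JSON sidecar (`<path>.json`) holding the
#' enzyme panel, extraction parameters, amplicon sequences, flags, duplicate
#' groups and the skip report. The round trip `read_db(write_db(db, p))`
#' restores every field.
#'
#' @param db a `profile_db`.
#' @param path output TSV path.
#' @return `write_db` returns `path` invisibly; `read_db` returns the
#'   restored `profile_db`.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "profile_db"))
  rows <- do.call(rbind, lapply(db$records, function(r) {
    data.frame(species = r$species_label,
               amplicon_length = r$amplicon$length,
               enzyme = names(r$profiles),
               fragments = vapply(r$profiles, function(p)
                 paste(p$fragments, collapse = ";"), character(1)))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rflpid profile-db format v1", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    format = "rflpid-db-sidecar-v1",
    enzymes = lapply(unname(db$enzymes), function(e)
      list(name = e$name, site = e$site, cut_offset = e$cut_offset,
           group = e$group)),
    dropped_enzymes = as.list(db$dropped_enzymes),
    duplicate_groups = lapply(db$duplicate_groups, as.list),
    skipped = db$skipped,
    params = list(
      forward = db$params$primers$forward,
      reverse = db$params$primers$reverse,
      pcr = unclass(db$params$pcr)),
    amplicons = lapply(db$records, function(r)
      list(seq_id = r$amplicon$seq_id, sequence = r$amplicon$sequence,
           length = r$amplicon$length,
           flags = as.list(r$amplicon$extraction_flags)))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_db
#' @export
read_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "# rflpid profile-db format v1"))
    stop("unrecognized or missing format header in ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar file ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = FALSE)
  if (!identical(side$format, "rflpid-db-sidecar-v1"))
    stop("sidecar version mismatch in ", side_path)

  tab <- tryCatch(
    utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                      colClasses = c("character", "integer", "character",
                                     "character")),
    error = function(e) stop("malformed database table: ",
                             conditionMessage(e), call. = FALSE))

  enzymes <- lapply(side$enzymes, function(e)
    enzyme(e$name, e$site, e$cut_offset,
           group = if (is.null(e$group)) NULL else e$group))
  names(enzymes) <- vapply(enzymes, `[[`, character(1), "name")

  records <- list()
  for (lab in names(side$amplicons)) {
    a <- side$amplicons[[lab]]
    rows <- tab[tab$species == lab, , drop = FALSE]
    if (!nrow(rows)) stop("species ", lab, " present in sidecar but not in ",
                          path)
    profs <- lapply(seq_len(nrow(rows)), function(i) {
      frs <- as.integer(strsplit(rows$fragments[i], ";", fixed = TRUE)[[1]])
      if (anyNA(frs) || sum(frs) != rows$amplicon_length[i])
        stop("malformed fragment row ", i, " for species ", lab)
      fragment_profile(rows$enzyme[i], frs, rows$amplicon_length[i])
    })
    names(profs) <- rows$enzyme
    amp <- structure(list(
      species_label = lab,
      seq_id = if (is.null(a$seq_id)) NA_character_ else a$seq_id,
      sequence = a$sequence, length = as.integer(a$length),
      extraction_flags = as.character(unlist(a$flags))),
      class = "amplicon_record")
    records[[lab]] <- list(species_label = lab, taxonomy = NULL,
                           amplicon = amp, profiles = profs[names(enzymes)])
  }

  skipped <- as.data.frame(lapply(side$skipped, unlist),
                           stringsAsFactors = FALSE)
  if (!nrow(skipped))
    skipped <- data.frame(species = character(), seq_id = character(),
                          reason = character())
  pcr_side <- side$params$pcr
  structure(list(
    records = records,
    duplicate_groups = lapply(side$duplicate_groups,
                              function(g) as.character(unlist(g))),
    enzymes = enzymes,
    dropped_enzymes = as.character(unlist(side$dropped_enzymes)),
    skipped = skipped,
    params = list(primers = primer_pair(side$params$forward,
                                        side$params$reverse),
                  pcr = pcr_params(pcr_side$max_error_rate,
                                   pcr_side$relaxed_error_rate,
                                   pcr_side$min_overlap,
                                   pcr_side$min_amplicon_len,
                                   pcr_side$include_primers_in_length,
                                   pcr_side$max_passes))
  ), class = "profile_db")
}

#' Amplicon-length summary over unique sequences
#'
#' Duplicate-sequence species are counted once (one representative per
#' duplicate group), mirroring a summary over unique amplicon sequences.
#'
#' @param db a `profile_db`.
#' @return list with `n_unique_lengths`, `median`, and `min`/`max` each a
#'   list of `length` and `species` (the label attaining it; first
#'   alphabetically on ties).
#' @export
length_summary <- function(db) {
  stopifnot(inherits(db, "profile_db"), length(db$records) > 0L)
  drop <- unlist(lapply(db$duplicate_groups, function(g) sort(g)[-1L]))
  keep <- setdiff(names(db$records), drop)
  lens <- vapply(db$records[keep], function(r) r$amplicon$length, integer(1))
  lens <- lens[order(names(lens))]
  list(
    n_unique_lengths = length(unique(lens)),
    median = stats::median(lens),
    min = list(length = min(lens),
               species = names(lens)[which.min(lens)]),
    max = list(length = max(lens),
               species = names(lens)[which.max(lens)])
  )
}

#' Species labels of a database
#' @param db a `profile_db`.
#' @return character vector of species labels.
#' @export
db_species <- function(db) names(db$records)
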