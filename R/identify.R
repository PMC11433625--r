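## Progressive species identification from measured PCR-RFLP profiles, and
## the pruned search over enzyme combinations.

#' A measured restriction profile
#'
#' Fragment lengths estimated from a gel for one enzyme. Fragments below the
#' detection limit are removed; a profile left empty after filtering is
#' uninformative (a warning is emitted and downstream stages skip it).
#'
#' @param enzyme_name enzyme that produced the fragments.
#' @param fragments numeric vector of measured fragment lengths (nt).
#' @param min_detectable detection limit applied on construction.
#' @return an object of class `measured_profile`.
#' @export
measured_profile <- function(enzyme_name, fragments, min_detectable = 100) {
  kept <- filter_detectable(fragments, min_detectable)
  if (!length(kept))
    warning("profile for ", enzyme_name,
            " has no fragment above the detection limit; it is uninformative",
            call. = FALSE)
  structure(list(enzyme = enzyme_name, fragments = sort(kept,
                                                        decreasing = TRUE)),
            class = "measured_profile")
}

## Kuhn's augmenting-path maximum bipartite matching.
## adj: list over left vertices of integer vectors of compatible right
## vertices. Returns the matching size.
.max_bipartite_matching <- function(adj, n_right) {
  match_r <- integer(n_right)
  size <- 0L
  for (u in seq_along(adj)) {
    seen <- logical(n_right)
    augment <- function(u) {
      for (v in adj[[u]]) {
        if (!seen[v]) {
          seen[v] <<- TRUE
          if (match_r[v] == 0L || augment(match_r[v])) {
            match_r[v] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (augment(u)) size <- size + 1L
  }
  size
}

## ranges: 2-column matrix of permissive intervals for the query fragments
.match_score <- function(ranges, ref_fragments) {
  if (!nrow(ranges) || !length(ref_fragments)) return(0L)
  adj <- lapply(seq_len(nrow(ranges)), function(i)
    which(ref_fragments >= ranges[i, 1] & ref_fragments <= ranges[i, 2]))
  .max_bipartite_matching(adj, length(ref_fragments))
}

#' Match a measured profile against a reference profile
#'
#' The score is the size of a maximum one-to-one matching between measured
#' and reference fragments, where a pair is compatible when the reference
#' length lies in the permissive range of the measured length under the
#' calibration model. Reference fragments left unmatched do not penalize
#' the score (faint bands are routinely missed on gels); set
#' `penalize_unmatched_reference = TRUE` to subtract them.
#'
#' @param query a [measured_profile()] (or numeric vector of measured
#'   lengths).
#' @param reference a `fragment_profile` (or numeric vector); filtered to
#'   the model's detection limit before matching.
#' @param model a `calibration_model`.
#' @param penalize_unmatched_reference alternative containment-style score.
#' @return integer match score.
#' @export
match_profile <- function(query, reference, model,
                          penalize_unmatched_reference = FALSE) {
  q <- if (inherits(query, "measured_profile")) query$fragments else query
  r <- if (inherits(reference, "fragment_profile")) reference$fragments
       else reference
  q <- filter_detectable(q, model$min_detectable)
  r <- filter_detectable(r, model$min_detectable)
  if (!length(q) || !length(r))
    return(if (penalize_unmatched_reference) -length(r) else 0L)
  ranges <- permissive_range(model, q)
  if (is.null(dim(ranges))) ranges <- matrix(ranges, nrow = 1L)
  s <- .match_score(ranges, r)
  if (penalize_unmatched_reference) s - (length(r) - s) else s
}

#' Progressive identification of a species from measured data
#'
#' Stage 0 keeps the species whose in-silico amplicon length falls in the
#' permissive range of the measured amplicon length. Each following stage
#' takes one measured enzyme profile, scores it against the surviving
#' species' reference profiles ([match_profile()]) and keeps the species
#' attaining the maximum score (ties keep all tied species). Candidate sets
#' never grow; an empty stage ends the run with an empty final set (no
#' backtracking).
#'
#' @param db a `profile_db`.
#' @param measured_amplicon measured amplicon length (nt).
#' @param queries list of [measured_profile()] objects, in selection order.
#' @param model a `calibration_model`.
#' @param truth optional true species label; fills `identified`/`precision`.
#' @param penalize_unmatched_reference passed to [match_profile()].
#' @return an `identification_result`: list with `stages` (each:
#'   `stage`, `candidates`, `scores`), `final_candidates`, and when `truth`
#'   is given, `truth`, `identified` and `precision`
#'   (`length(final) - 1`, `NA` unless the truth is in the final set).
#' @export
identify_species <- function(db, measured_amplicon, queries, model,
                             truth = NULL,
                             penalize_unmatched_reference = FALSE) {
  stopifnot(inherits(db, "profile_db"))
  q_enzymes <- vapply(queries, `[[`, character(1), "enzyme")
  missing <- setdiff(q_enzymes, names(db$enzymes))
  if (length(missing))
    stop("query enzyme(s) absent from the database panel: ",
         paste(missing, collapse = ", "))

  lens <- vapply(db$records, function(r) r$amplicon$length, numeric(1))
  rng <- permissive_range(model, measured_amplicon)
  survivors <- names(lens)[lens >= rng[1] & lens <= rng[2]]
  stages <- list(list(stage = "amplicon_length", candidates = survivors,
                      scores = NULL))

  for (qp in queries) {
    if (!length(survivors)) break
    if (!length(qp$fragments)) {
      warning("skipping uninformative profile for ", qp$enzyme,
              call. = FALSE)
      next
    }
    ranges <- permissive_range(model, qp$fragments)
    if (is.null(dim(ranges))) ranges <- matrix(ranges, nrow = 1L)
    scores <- vapply(survivors, function(sp) {
      ref <- filter_detectable(db$records[[sp]]$profiles[[qp$enzyme]]$fragments,
                               model$min_detectable)
      s <- .match_score(ranges, ref)
      if (penalize_unmatched_reference) s - (length(ref) - s) else s
    }, numeric(1))
    survivors <- survivors[scores == max(scores)]
    stages[[length(stages) + 1L]] <-
      list(stage = qp$enzyme, candidates = survivors,
           scores = scores[scores == max(scores)])
  }

  res <- list(stages = stages, final_candidates = survivors)
  if (!is.null(truth)) {
    res$truth <- truth
    res$identified <- truth %in% survivors
    res$precision <- if (res$identified) length(survivors) - 1L else NA_integer_
  }
  structure(res, class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result> ", length(x$stages), " stage(s)\n", sep = "")
  for (st in x$stages)
    cat("  ", st$stage, ": ", length(st$candidates), " candidate(s)\n",
        sep = "")
  cat("  final:", if (length(x$final_candidates))
    paste(utils::head(x$final_candidates, 8), collapse = ", ")
    else "(none)", "\n")
  if (!is.null(x$identified))
    cat("  identified:", x$identified,
        if (!is.na(x$precision)) paste0(" (precision ", x$precision, ")"),
        "\n")
  invisible(x)
}

#' Evaluate identification over a truth-labelled query set
#'
#' @param db a `profile_db`.
#' @param query_set list of queries, each a list with `truth`,
#'   `measured_amplicon` and `profiles` (list of [measured_profile()]).
#' @param model a `calibration_model`.
#' @return list with `per_query` (data frame: `truth`, `identified`,
#'   `precision`, `n_final`) and `summary` (`pct_identified`,
#'   `precision_min`, `precision_median`, `precision_max` over identified
#'   queries).
#' @export
evaluate_identification <- function(db, query_set, model) {
  rows <- lapply(query_set, function(q) {
    r <- identify_species(db, q$measured_amplicon, q$profiles, model,
                          truth = q$truth)
    data.frame(truth = q$truth, identified = r$identified,
               precision = r$precision,
               n_final = length(r$final_candidates))
  })
  per_query <- do.call(rbind, rows)
  prec <- per_query$precision[per_query$identified]
  list(per_query = per_query,
       summary = list(
         pct_identified = 100 * mean(per_query$identified),
         precision_min = if (length(prec)) min(prec) else NA,
         precision_median = if (length(prec)) stats::median(prec) else NA,
         precision_max = if (length(prec)) max(prec) else NA))
}

#' Configuration for the enzyme-combination search
#'
#' Testing every ordered 5-tuple of a large panel is intractable
#' ([count_ordered_selections()]), so the search prunes: the first-stage
#' panel keeps enzymes that alone identify every sampled species with fewer
#' than `max_coselected_single` co-selected species (capped at
#' `first_stage_panel_size` by precision); the later-stage panel keeps
#' enzymes that, in some pair, improve the median co-selection count by at
#' least `min_precision_improvement` over the better single enzyme (capped
#' at `later_stage_panel_size`).
#'
#' @param max_coselected_single single-enzyme co-selection ceiling
#'   (default 50).
#' @param min_precision_improvement required relative improvement
#'   (default 0.25).
#' @param first_stage_panel_size cap for first-stage enzymes (default 80).
#' @param later_stage_panel_size cap for later-stage enzymes (default 22).
#' @param n_query_species number of species sampled as queries
#'   (default 100).
#' @param seed RNG seed for the query sample.
#' @return an object of class `combo_config`.
#' @export
combo_config <- function(max_coselected_single = 50,
                         min_precision_improvement = 0.25,
                         first_stage_panel_size = 80,
                         later_stage_panel_size = 22,
                         n_query_species = 100, seed = 1L) {
  stopifnot(max_coselected_single > 0, first_stage_panel_size > 0,
            later_stage_panel_size > 0, n_query_species > 0,
            min_precision_improvement >= 0)
  structure(list(max_coselected_single = max_coselected_single,
                 min_precision_improvement = min_precision_improvement,
                 first_stage_panel_size = first_stage_panel_size,
                 later_stage_panel_size = later_stage_panel_size,
                 n_query_species = n_query_species, seed = as.integer(seed)),
            class = "combo_config")
}

## run one ordered tuple over the query species; queries are the species'
## own in-silico profiles (exact values), uncertainty enters through the
## calibration model's permissive ranges
.eval_tuple <- function(db, model, tuple, query_species) {
  res <- lapply(query_species, function(sp) {
    rec <- db$records[[sp]]
    profs <- lapply(tuple, function(e)
      suppressWarnings(measured_profile(e, rec$profiles[[e]]$fragments,
                                        model$min_detectable)))
    suppressWarnings(identify_species(db, rec$amplicon$length, profs, model,
                                      truth = sp))
  })
  identified <- vapply(res, `[[`, logical(1), "identified")
  cosel <- vapply(res, function(r)
    if (r$identified) length(r$final_candidates) - 1 else NA_real_,
    numeric(1))
  precise <- sum(identified & cosel == 0, na.rm = TRUE)
  list(pct_identified = 100 * mean(identified),
       median_coselected = if (any(identified))
         stats::median(cosel[identified]) else NA_real_,
       n_precise = as.integer(precise))
}

#' Search enzyme combinations for precise identification
#'
#' Runs the progressive identification over every ordered enzyme tuple of
#' the (optionally pruned) search space on a seeded sample of query species,
#' recording the identification percentage, the median number of co-selected
#' species, and the number of precise (single-species) identifications.
#'
#' @param db a `profile_db`.
#' @param model a `calibration_model`.
#' @param ks tuple sizes to test (subset of 2:5).
#' @param config a [combo_config()].
#' @param prune if `FALSE`, every ordered tuple over the whole panel is
#'   enumerated (small panels only).
#' @return list with `results` (data frame: `tuple`, `k`, `pct_identified`,
#'   `median_coselected`, `n_precise`, sorted by `n_precise` desc),
#'   `first_stage_panel`, `later_stage_panel`, `query_species`,
#'   `single_stats`, and `reason` when the pruned space is empty.
#' @export
search_combinations <- function(db, model, ks = 2:5,
                                config = combo_config(), prune = TRUE) {
  stopifnot(all(ks >= 2), all(ks <= 5))
  panel <- names(db$enzymes)
  species <- db_species(db)
  set.seed(config$seed)
  query_species <- sort(sample(species,
                               min(config$n_query_species, length(species))))

  ## single-enzyme baseline
  single <- lapply(panel, function(e) .eval_tuple(db, model, e, query_species))
  names(single) <- panel
  single_df <- data.frame(
    enzyme = panel,
    pct_identified = vapply(single, `[[`, numeric(1), "pct_identified"),
    median_coselected = vapply(single, `[[`, numeric(1),
                               "median_coselected"),
    n_precise = vapply(single, `[[`, integer(1), "n_precise"))

  if (prune) {
    ok <- single_df$pct_identified == 100 &
      !is.na(single_df$median_coselected) &
      single_df$median_coselected < config$max_coselected_single
    first_panel <- single_df$enzyme[ok]
    first_panel <- first_panel[order(single_df$median_coselected[ok],
                                     first_panel)]
    first_panel <- utils::head(first_panel, config$first_stage_panel_size)
    if (!length(first_panel))
      return(list(results = .empty_combo_results(),
                  first_stage_panel = character(),
                  later_stage_panel = character(),
                  query_species = query_species, single_stats = single_df,
                  reason = "no enzyme meets the single-enzyme criteria"))

    ## pairwise improvement screen for later-stage enzymes
    best_imp <- setNames(rep(-Inf, length(panel)), panel)
    for (e1 in first_panel) for (e2 in setdiff(panel, e1)) {
      pr <- .eval_tuple(db, model, c(e1, e2), query_species)
      singles <- c(single[[e1]]$median_coselected,
                   single[[e2]]$median_coselected)
      base <- suppressWarnings(min(singles, na.rm = TRUE))
      if (!is.finite(base) || is.na(pr$median_coselected)) next
      imp <- if (base > 0) (base - pr$median_coselected) / base
             else as.numeric(pr$median_coselected == 0)
      best_imp[e2] <- max(best_imp[e2], imp)
    }
    later_panel <- names(best_imp)[best_imp >=
                                     config$min_precision_improvement]
    later_panel <- later_panel[order(-best_imp[later_panel], later_panel)]
    later_panel <- utils::head(later_panel, config$later_stage_panel_size)
    if (!length(later_panel))
      return(list(results = .empty_combo_results(),
                  first_stage_panel = first_panel,
                  later_stage_panel = character(),
                  query_species = query_species, single_stats = single_df,
                  reason = "no enzyme meets the pairwise improvement criterion"))
  } else {
    first_panel <- panel
    later_panel <- panel
  }

  tuples <- list()
  for (k in sort(ks)) {
    for (e1 in first_panel) {
      rest <- setdiff(later_panel, e1)
      if (length(rest) < k - 1L) next
      for (combo in .ordered_tuples(rest, k - 1L))
        tuples[[length(tuples) + 1L]] <- c(e1, combo)
    }
  }
  if (!length(tuples))
    return(list(results = .empty_combo_results(),
                first_stage_panel = first_panel,
                later_stage_panel = later_panel,
                query_species = query_species, single_stats = single_df,
                reason = "pruned search space is empty"))

  rows <- lapply(tuples, function(tp) {
    ev <- .eval_tuple(db, model, tp, query_species)
    data.frame(tuple = paste(tp, collapse = "+"), k = length(tp),
               pct_identified = ev$pct_identified,
               median_coselected = ev$median_coselected,
               n_precise = ev$n_precise)
  })
  results <- do.call(rbind, rows)
  results <- results[order(-results$n_precise, -results$pct_identified,
                           results$median_coselected, results$tuple), ,
                     drop = FALSE]
  rownames(results) <- NULL
  list(results = results, first_stage_panel = first_panel,
       later_stage_panel = later_panel, query_species = query_species,
       single_stats = single_df, reason = NULL)
}

.empty_combo_results <- function() {
  data.frame(tuple = character(), k = integer(), pct_identified = numeric(),
             median_coselected = numeric(), n_precise = integer())
}

## all ordered j-tuples of distinct elements of x
.ordered_tuples <- function(x, j) {
  if (j == 0L) return(list(character()))
  out <- list()
  for (i in seq_along(x))
    for (rest in .ordered_tuples(x[-i], j - 1L))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Enzyme frequency among combinations
#'
#' For each enzyme, the percentage of combinations (optionally only those
#' achieving at least one precise identification) whose tuple contains it.
#' Over a set of k-tuples the percentages sum to k * 100.
#'
#' @param combo_results the `results` data frame of
#'   [search_combinations()], or the full returned list.
#' @param precise_only restrict to combinations with `n_precise > 0`.
#' @return data frame with `enzyme` and `pct`, sorted by `pct` desc.
#' @export
enzyme_frequency <- function(combo_results, precise_only = TRUE) {
  if (is.list(combo_results) && !is.data.frame(combo_results))
    combo_results <- combo_results$results
  rows <- combo_results
  if (precise_only) rows <- rows[rows$n_precise > 0, , drop = FALSE]
  if (!nrow(rows))
    return(data.frame(enzyme = character(), pct = numeric()))
  members <- strsplit(rows$tuple, "+", fixed = TRUE)
  all_enz <- sort(unique(unlist(members)))
  pct <- vapply(all_enz, function(e)
    100 * mean(vapply(members, function(m) e %in% m, logical(1))),
    numeric(1))
  out <- data.frame(enzyme = all_enz, pct = unname(pct))
  out[order(-out$pct, out$enzyme), , drop = FALSE]
}
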