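## Discriminative power of enzymes, singly and in combination, and the
## indistinguishability network of species no single enzyme can resolve.

#' Canonical profile key for an enzyme tuple
#'
#' Two species are indistinguishable under a tuple of enzymes exactly when
#' their keys are equal: the key encodes, per enzyme in order, the multiset
#' of fragment lengths (sorted descending). Keys of `(E1, E2)` and
#' `(E2, E1)` are distinct strings but induce the same partition of species.
#'
#' @param db a `profile_db`.
#' @param enzymes character vector of enzyme names (order matters for the
#'   key string, not for the induced partition).
#' @return named character vector, one key per species.
#' @export
profile_key <- function(db, enzymes) {
  stopifnot(inherits(db, "profile_db"), length(enzymes) >= 1L)
  missing <- setdiff(enzymes, names(db$enzymes))
  if (length(missing))
    stop("enzyme(s) not in panel: ", paste(missing, collapse = ", "))
  vapply(db$records, function(r) {
    paste(vapply(enzymes, function(e)
      paste0(e, ":", paste(r$profiles[[e]]$fragments, collapse = ";")),
      character(1)), collapse = "|")
  }, character(1))
}

.stats_from_keys <- function(keys, enzymes) {
  tab <- table(keys)
  n_ident <- sum(tab == 1L)
  structure(list(
    enzymes = enzymes,
    n_species = length(keys),
    n_profiles = length(tab),
    n_identifiable = n_ident,
    fraction_identifiable = n_ident / length(keys)
  ), class = "enzyme_stats")
}

#' @export
print.enzyme_stats <- function(x, ...) {
  cat("<enzyme_stats> ", paste(x$enzymes, collapse = "+"), ": ",
      x$n_profiles, " profiles, ", x$n_identifiable, "/", x$n_species,
      " identifiable (", sprintf("%.2f%%", 100 * x$fraction_identifiable),
      ")\n", sep = "")
  invisible(x)
}

#' Discrimination statistics for a single enzyme
#'
#' `n_profiles` counts distinct restriction profiles over the database;
#' `n_identifiable` counts species whose profile is shared with no other
#' species (singleton profile classes) -- species in a duplicate-sequence
#' group can never be singletons.
#'
#' @param db a `profile_db`.
#' @param enzyme_name one enzyme name from the panel.
#' @return an `enzyme_stats` object.
#' @export
enzyme_stats <- function(db, enzyme_name) {
  stopifnot(length(enzyme_name) == 1L)
  .stats_from_keys(profile_key(db, enzyme_name), enzyme_name)
}

#' Discrimination statistics for an ordered enzyme tuple
#'
#' The joint profile refines every member's partition, so
#' `n_identifiable(tuple) >= max` over the members.
#'
#' @param db a `profile_db`.
#' @param enzymes 2 to 5 distinct enzyme names.
#' @return an `enzyme_stats` object.
#' @export
combined_stats <- function(db, enzymes) {
  if (length(enzymes) < 2L || length(enzymes) > 5L)
    stop("combined_stats takes 2 to 5 enzymes")
  if (anyDuplicated(enzymes))
    stop("repeated enzyme in tuple: ",
         paste(unique(enzymes[duplicated(enzymes)]), collapse = ", "))
  .stats_from_keys(profile_key(db, enzymes), enzymes)
}

#' Rank the panel by single-enzyme discriminative power
#'
#' @param db a `profile_db`.
#' @return data frame with columns `enzyme`, `n_profiles`, `n_identifiable`,
#'   `fraction_identifiable`, sorted by `n_identifiable` (desc), then
#'   `n_profiles` (desc), then name.
#' @export
rank_enzymes <- function(db) {
  rows <- lapply(names(db$enzymes), function(e) {
    st <- enzyme_stats(db, e)
    data.frame(enzyme = e, n_profiles = st$n_profiles,
               n_identifiable = st$n_identifiable,
               fraction_identifiable = st$fraction_identifiable)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_identifiable, -out$n_profiles, out$enzyme), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Indistinguishability network of never-identifiable species
#'
#' Nodes are the species that no single panel enzyme identifies uniquely
#' (their profile class is non-singleton under every enzyme). An edge joins
#' two nodes whose profiles are identical under at least one enzyme; its
#' weight is the percentage of panel enzymes under which the two profiles
#' are identical. Species sharing an identical amplicon sequence form
#' 100%-weight cliques.
#'
#' @param db a `profile_db`.
#' @param restrict_to_unidentifiable if `FALSE`, all species sharing a
#'   profile under at least one enzyme become nodes (per-enzyme collision
#'   view), not only the never-identifiable ones.
#' @return list with `nodes`, `edges` (data frame `from`, `to`, `weight`,
#'   `n_enzymes_identical`), and `components` (list of character vectors).
#' @export
indistinguishability_graph <- function(db, restrict_to_unidentifiable = TRUE) {
  panel <- names(db$enzymes)
  stopifnot(length(panel) >= 1L)
  keys <- lapply(panel, function(e) profile_key(db, e))
  names(keys) <- panel
  species <- db_species(db)

  singleton <- sapply(keys, function(k) {
    tab <- table(k)
    tab[k] == 1L
  })  # species x enzyme matrix
  if (is.null(dim(singleton)))
    singleton <- matrix(singleton, nrow = length(species),
                        dimnames = list(species, panel))
  rownames(singleton) <- species

  nodes <- if (restrict_to_unidentifiable)
    species[rowSums(singleton) == 0L] else species[rowSums(!singleton) > 0L]

  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), n_enzymes_identical = integer())
  if (length(nodes) >= 2L) {
    pairs <- utils::combn(sort(nodes), 2L)
    n_id <- apply(pairs, 2L, function(p) {
      sum(vapply(panel, function(e)
        keys[[e]][p[1]] == keys[[e]][p[2]], logical(1)))
    })
    keep <- n_id >= 1L
    edges <- data.frame(from = pairs[1L, keep], to = pairs[2L, keep],
                        weight = 100 * n_id[keep] / length(panel),
                        n_enzymes_identical = as.integer(n_id[keep]))
  }

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  components <- unname(split(names(comp$membership), comp$membership))
  components <- components[order(-vapply(components, length, integer(1)),
                                 vapply(components, `[[`, character(1), 1L))]
  list(nodes = nodes, edges = edges, components = components)
}

#' Number of ordered enzyme selections
#'
#' Counts ordered k-tuples of distinct enzymes drawn from a panel of `n`
#' (falling factorial n * (n-1) * ... * (n-k+1)): the size of the search
#' space an exhaustive combination test would face.
#'
#' @param n panel size.
#' @param k tuple length.
#' @return the exact count as a double (exact while below 2^53).
#' @examples
#' count_ordered_selections(143, 5)  # > 55 billion
#' @export
count_ordered_selections <- function(n, k) {
  stopifnot(n >= 1, k >= 1, k <= n)
  prod(seq(n, by = -1, length.out = k))
}
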