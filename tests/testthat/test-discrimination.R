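# a hand-built database with controlled profiles over four species:
#   E1 merges {A,B}; C and D are singletons under it
#   E2 merges {A,D} and {B,C}
#   E3 is uninformative (everyone identical)
# so A and B are never identifiable by any single enzyme, while C and D are.
handmade_db <- function() {
  mk <- function(lab, seq) {
    amp <- structure(list(species_label = lab, seq_id = NA_character_,
                          sequence = seq, length = nchar(seq),
                          extraction_flags = character()),
                     class = "amplicon_record")
    list(species_label = lab, taxonomy = NULL, amplicon = amp,
         profiles = NULL)
  }
  profs <- function(...) {
    fr <- list(...)
    setNames(lapply(fr, function(f) fragment_profile(f$e, f$fr, sum(f$fr))),
             vapply(fr, `[[`, character(1), "e"))
  }
  recs <- list(
    A = mk("A", strrep("A", 300)),
    B = mk("B", strrep("C", 300)),
    C = mk("C", strrep("G", 300)),
    D = mk("D", strrep("T", 300)))
  recs$A$profiles <- profs(list(e = "E1", fr = c(100, 200)),
                           list(e = "E2", fr = c(150, 150)),
                           list(e = "E3", fr = 300))
  recs$B$profiles <- profs(list(e = "E1", fr = c(200, 100)),
                           list(e = "E2", fr = c(120, 180)),
                           list(e = "E3", fr = 300))
  recs$C$profiles <- profs(list(e = "E1", fr = 300),
                           list(e = "E2", fr = c(180, 120)),
                           list(e = "E3", fr = 300))
  recs$D$profiles <- profs(list(e = "E1", fr = c(150, 150)),
                           list(e = "E2", fr = c(150, 150)),
                           list(e = "E3", fr = 300))
  structure(list(records = recs, duplicate_groups = list(),
                 enzymes = setNames(list(enzyme("E1", "GGCC", 2),
                                         enzyme("E2", "AGCT", 2),
                                         enzyme("E3", "TTAA", 1)),
                                    c("E1", "E2", "E3")),
                 dropped_enzymes = character(),
                 skipped = data.frame(),
                 params = list(primers = its_primers(), pcr = pcr_params())),
            class = "profile_db")
}

random_db <- function(n, seed, panel = toy_panel()) {
  sp <- synth_spec(n_species = n, duplicate_fraction = 0,
                   primer_mismatch_range = c(0, 0), revcomp_fraction = 0,
                   seed = seed)
  build_profile_db(synth_genomes(sp)$sequences, panel)
}

# group-by partition oracle on raw fragment multisets
oracle_partition <- function(db, enzymes) {
  keys <- vapply(db$records, function(r)
    paste(vapply(enzymes, function(e)
      paste(sort(r$profiles[[e]]$fragments), collapse = ","), character(1)),
      collapse = " / "), character(1))
  split(names(keys), keys)
}

test_that("profile keys implement multiset semantics", {
  db <- handmade_db()
  k <- profile_key(db, "E1")
  expect_identical(unname(k["A"]), unname(k["B"]))  # [100,200] == [200,100]
  expect_false(k[["A"]] == k[["C"]])  # [100,200] vs [300]: count matters
  k2 <- profile_key(db, "E2")
  expect_length(unique(k2), 2L)       # {A,D} and {B,C}
  expect_error(profile_key(db, "E9"), "not in panel")
})

test_that("single-enzyme stats count singleton profile classes", {
  db <- handmade_db()
  s1 <- enzyme_stats(db, "E1")
  expect_equal(s1$n_profiles, 3L)       # {A,B}, {C}, {D}
  expect_equal(s1$n_identifiable, 2L)   # C and D
  s3 <- enzyme_stats(db, "E3")
  expect_equal(s3$n_profiles, 1L)
  expect_equal(s3$n_identifiable, 0L)
  s2 <- enzyme_stats(db, "E2")
  expect_equal(s2$n_profiles, 2L)       # {A,D}, {B,C}
  expect_equal(s2$n_identifiable, 0L)
})

test_that("combined stats refine and match the brute-force oracle", {
  db <- handmade_db()
  cmb <- combined_stats(db, c("E1", "E2"))
  expect_equal(cmb$n_identifiable, 4L)
  expect_error(combined_stats(db, c("E1", "E1")), "repeated")
  expect_error(combined_stats(db, "E1"), "2 to 5")

  rdb <- random_db(25, seed = 40)
  panel <- names(rdb$enzymes)
  for (pair in utils::combn(panel, 2, simplify = FALSE)) {
    st <- combined_stats(rdb, pair)
    parts <- oracle_partition(rdb, pair)
    expect_equal(st$n_profiles, length(parts))
    expect_equal(st$n_identifiable,
                 sum(lengths(parts) == 1L))
    singles <- vapply(pair, function(e)
      enzyme_stats(rdb, e)$n_identifiable, integer(1))
    expect_gte(st$n_identifiable, max(singles))  # partition refinement
    # order of the tuple changes the key string, not the partition
    rev_parts <- oracle_partition(rdb, rev(pair))
    expect_setequal(
      unname(vapply(parts, paste, character(1), collapse = ",")),
      unname(vapply(rev_parts, paste, character(1), collapse = ",")))
  }
})

test_that("enzyme ranking is a deterministic total order", {
  db <- handmade_db()
  rk <- rank_enzymes(db)
  expect_identical(rk$enzyme, c("E1", "E2", "E3"))
  rdb <- random_db(20, seed = 41)
  rk2 <- rank_enzymes(rdb)
  expect_true(all(diff(rk2$n_identifiable) <= 0))
  recompute <- vapply(rk2$enzyme, function(e)
    enzyme_stats(rdb, e)$n_identifiable, integer(1))
  expect_identical(unname(recompute), rk2$n_identifiable)
})

test_that("indistinguishability graph has the defined nodes, weights and cliques", {
  db <- handmade_db()
  g <- indistinguishability_graph(db)
  # A and B are never singletons under any enzyme; C and D each are (E1)
  expect_setequal(g$nodes, c("A", "B"))
  expect_equal(nrow(g$edges), 1L)
  # A,B identical under E1 and E3 (2 of 3 panel enzymes), distinct under E2
  expect_equal(g$edges$weight, 100 * 2 / 3)

  # duplicate-sequence species appear as a 100%-weight clique
  sp <- synth_spec(n_species = 8, duplicate_fraction = 0.25,
                   primer_mismatch_range = c(0, 0), revcomp_fraction = 0,
                   seed = 42)
  dbd <- build_profile_db(synth_genomes(sp)$sequences, toy_panel())
  gg <- indistinguishability_graph(dbd)
  for (grp in dbd$duplicate_groups) {
    expect_true(all(grp %in% gg$nodes))
    for (pr in utils::combn(sort(grp), 2, simplify = FALSE)) {
      w <- gg$edges$weight[gg$edges$from == pr[1] & gg$edges$to == pr[2]]
      expect_equal(w, 100)
    }
  }
  # components agree with an independent union-find over the edge list
  parent <- setNames(gg$nodes, gg$nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(gg$edges)))
    parent[[find(gg$edges$from[i])]] <- find(gg$edges$to[i])
  oracle_comp <- split(gg$nodes, vapply(gg$nodes, find, character(1)))
  expect_setequal(
    unname(vapply(gg$components, function(cp) paste(sort(cp), collapse = ","),
                  character(1))),
    unname(vapply(oracle_comp, function(cp) paste(sort(cp), collapse = ","),
                  character(1))))
})

test_that("a fully discriminable database yields an empty graph", {
  rdb <- random_db(10, seed = 43)
  rk <- rank_enzymes(rdb)
  expect_equal(max(rk$n_identifiable), 10L)  # one enzyme resolves everything
  g <- indistinguishability_graph(rdb)
  expect_length(g$nodes, 0L)
  expect_equal(nrow(g$edges), 0L)
})

test_that("ordered-selection counts are exact falling factorials", {
  expect_equal(count_ordered_selections(5, 2), 20)
  expect_equal(count_ordered_selections(8, 3), 8 * 7 * 6)
  expect_equal(count_ordered_selections(143, 1), 143)
})
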