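noisy_model <- function(sigma = 1.5, delta = 0.6, phi = 0,
                        min_detectable = 100, beta0 = 2, beta1 = 0.97) {
  structure(list(kind = "varpow", beta0 = beta0, beta1 = beta1, sigma = sigma,
                 delta = delta, phi = phi, level = 0.95,
                 min_detectable = min_detectable, loglik = NA_real_, n = 0L,
                 converged = TRUE), class = "calibration_model")
}

small_db <- function(n = 20, seed = 60, panel = toy_panel()) {
  sp <- synth_spec(n_species = n, duplicate_fraction = 0,
                   primer_mismatch_range = c(0, 0), revcomp_fraction = 0,
                   seed = seed)
  build_profile_db(synth_genomes(sp)$sequences, panel)
}

test_that("profile match scores agree with a brute-force assignment oracle", {
  set.seed(61)
  m <- noisy_model()
  for (rep in 1:40) {
    q <- sort(runif(sample(3:6, 1), 110, 900), decreasing = TRUE)
    r <- sort(sample(110:900, sample(3:6, 1)), decreasing = TRUE)
    ranges <- permissive_range(m, q)
    got <- match_profile(q, r, m)
    expect_equal(got, oracle_match(ranges, r))
  }
})

test_that("identical profiles under a zero-noise model match fully; disjoint ones score zero", {
  id <- structure(list(kind = "lm", beta0 = 0, beta1 = 1, sigma = 0,
                       delta = 0, phi = 0, level = 0.95, min_detectable = 0,
                       loglik = NA_real_, n = 0L, converged = TRUE),
                  class = "calibration_model")
  expect_equal(match_profile(c(300, 200, 150), c(150, 200, 300), id), 3L)
  expect_equal(match_profile(c(300, 200), c(700, 650), noisy_model()), 0L)
  # penalty mode subtracts unmatched reference fragments
  expect_equal(match_profile(c(300, 200), c(300, 200, 500), id,
                             penalize_unmatched_reference = TRUE), 1L)
})

test_that("noiseless self-queries identify the true species with shrinking candidate sets", {
  db <- small_db(20)
  id <- identity_model()
  for (sp in db_species(db)[c(1, 7, 13)]) {
    rec <- db$records[[sp]]
    profs <- lapply(names(db$enzymes)[1:2], function(e)
      suppressWarnings(measured_profile(e, rec$profiles[[e]]$fragments,
                                        min_detectable = 0)))
    r2 <- identify_species(db, rec$amplicon$length, profs, id, truth = sp)
    expect_true(r2$identified)
    sizes <- vapply(r2$stages, function(s) length(s$candidates), integer(1))
    expect_true(all(diff(sizes) <= 0))  # monotone refinement
    # one-enzyme prefix cannot be tighter than the two-enzyme run
    r1 <- identify_species(db, rec$amplicon$length, profs[1], id, truth = sp)
    expect_lte(length(r2$final_candidates), length(r1$final_candidates))
  }
})

test_that("querying an enzyme absent from the panel errors", {
  db <- small_db(5, seed = 62)
  q <- suppressWarnings(measured_profile("NoSuchEnzyme", c(300, 200)))
  expect_error(identify_species(db, 500, list(q), identity_model()),
               "absent from the database panel")
})

test_that("evaluation aggregates match an independent tally", {
  db <- small_db(15, seed = 63)
  m <- noisy_model()
  set.seed(64)
  queries <- lapply(db_species(db)[1:10], function(sp) {
    rec <- db$records[[sp]]
    profs <- lapply(names(db$enzymes)[1:2], function(e)
      simulate_measured_profile(rec$profiles[[e]],
                                noise_spec(phi = 0), enzyme_name = e))
    list(truth = sp, measured_amplicon = rec$amplicon$length,
         profiles = profs)
  })
  ev <- evaluate_identification(db, queries, m)
  expect_equal(nrow(ev$per_query), 10L)
  expect_equal(ev$summary$pct_identified,
               100 * mean(ev$per_query$identified))
  prec <- ev$per_query$precision[ev$per_query$identified]
  expect_equal(ev$summary$precision_median, median(prec))
  # precision is |final| - 1 whenever the truth is in the final set
  expect_true(all(ev$per_query$n_final[ev$per_query$identified] - 1L ==
                    prec))
})

test_that("a planted perfectly-resolving pair wins the combination search", {
  db <- small_db(12, seed = 65)
  # unbiased calibration with narrow bands: in-silico self-queries stay
  # inside their own permissive ranges
  m <- noisy_model(sigma = 0.2, delta = 0.3, beta0 = 0, beta1 = 1)
  res <- search_combinations(db, m, ks = 2,
                             config = combo_config(n_query_species = 8,
                                                   seed = 66),
                             prune = FALSE)
  expect_gt(nrow(res$results), 0)
  top <- res$results[1, ]
  expect_equal(top$pct_identified, 100)
  # both orders of every pair are enumerated
  tuples <- res$results$tuple
  parts <- strsplit(tuples, "+", fixed = TRUE)
  rev_tuples <- vapply(parts, function(p) paste(rev(p), collapse = "+"),
                       character(1))
  expect_true(all(rev_tuples %in% tuples))
})

test_that("pruned search results are a subset of the exhaustive search and agree on survivors", {
  db <- small_db(12, seed = 67, panel = toy_panel()[1:4])
  m <- noisy_model(sigma = 0.5, delta = 0.4, beta0 = 0, beta1 = 1)
  cfg <- combo_config(max_coselected_single = 8, n_query_species = 8,
                      seed = 68)
  pruned <- search_combinations(db, m, ks = 2, config = cfg, prune = TRUE)
  full <- search_combinations(db, m, ks = 2, config = cfg, prune = FALSE)
  if (nrow(pruned$results)) {
    expect_true(all(pruned$results$tuple %in% full$results$tuple))
    merged <- merge(pruned$results, full$results, by = "tuple")
    expect_equal(merged$pct_identified.x, merged$pct_identified.y)
    expect_equal(merged$n_precise.x, merged$n_precise.y)
    expect_equal(merged$median_coselected.x, merged$median_coselected.y)
  } else {
    expect_match(pruned$reason, ".")
  }
})

test_that("enzyme frequencies recount the combination table", {
  res <- data.frame(tuple = c("A+B", "A+C", "B+C"), k = 2,
                    pct_identified = 100, median_coselected = 0,
                    n_precise = c(3L, 2L, 0L))
  fr <- enzyme_frequency(res, precise_only = TRUE)
  expect_equal(fr$pct[fr$enzyme == "A"], 100)
  expect_equal(fr$pct[fr$enzyme == "B"], 50)
  expect_equal(sum(fr$pct), 2 * 100)  # k * 100 over a k-tuple set
  fr_all <- enzyme_frequency(res, precise_only = FALSE)
  expect_equal(fr_all$pct, c(200 / 3, 200 / 3, 200 / 3),
               tolerance = 1e-10, ignore_attr = TRUE)
})
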