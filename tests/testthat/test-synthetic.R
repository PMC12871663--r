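small_spec <- function(seed = 17, ...) {
  array_spec(n_dimers = 30, te_islands = tibble::tibble(
    after_dimer = 15, length = 600
  ), proximal_length = 200, distal_length = 400, seed = seed, ...)
}

test_that("a mutation-free array is a perfect dimer ladder", {
  spec <- small_spec(mutation_rate = 0, truncation_prob = 0)
  sim <- gen_array(spec)
  expect_equal(sim$truth$total_repeats, 60)
  expect_equal(sim$truth$repeat_left, 30)
  expect_equal(sim$truth$repeat_right, 30)
  expect_equal(sim$truth$repeat_variant, 0)
  expect_equal(sim$truth$te_island, 1)
  expect_equal(count_copies(sim$array), sim$truth)
  # sequence length equals the annotation span
  expect_equal(nchar(sim$sequence), max(sim$array$end))
})

test_that("generation is a pure function of the spec and seed", {
  a <- gen_array(small_spec())
  b <- gen_array(small_spec())
  expect_identical(a$sequence, b$sequence)
  expect_identical(as.data.frame(a$array), as.data.frame(b$array))
  c <- gen_array(small_spec(seed = 18))
  expect_false(identical(a$sequence, c$sequence))
})

test_that("rule-based classification of truth hits reproduces generator labels", {
  spec <- small_spec(mutation_rate = 0.15, truncation_prob = 0.1)
  sim <- gen_array(spec)
  cls <- classify_units(sim$hits, consensus_length = spec$unit_length)
  truth <- sim$array[sim$array$family %in% c("L-Rsp", "R-Rsp"), ]
  expect_equal(nrow(cls), nrow(truth))
  expect_equal(cls$unit_class, truth$unit_class)
  expect_gt(sum(cls$unit_class == "repeat-variant"), 0)
  expect_gt(sum(cls$unit_class == "repeat-truncated"), 0)
  expect_equal(count_copies(sat_array(cls, contig = "x"))$total_repeats,
               sim$truth$total_repeats)
})

test_that("planted guide sites are recovered exactly", {
  withr::with_seed(31, {
    g <- guide_spec("g1", random_dna(20))
    sim <- gen_array(small_spec(mutation_rate = 0.02, truncation_prob = 0),
                     plant_guide = g, plant_at = c(3, 11, 24))
    hits <- find_target_sites(sim$sequence, g)
    expect_equal(hits$position, sim$planted_sites$position)
    expect_equal(hits$cut_position, sim$planted_sites$cut_position)
    expect_true(all(hits$strand == "+"))
  })
})

test_that("editing a planted array removes the sites inside the deleted span", {
  withr::with_seed(32, {
    g <- guide_spec("g1", random_dna(20))
    sim <- gen_array(small_spec(mutation_rate = 0, truncation_prob = 0),
                     plant_guide = g, plant_at = c(5, 10, 20))
    sites <- find_target_sites(sim$sequence, g)
    out <- simulate_editing(sim$array, sites,
                            edit_model(1, "outermost-join"), 1, seed = 1)
    expect_equal(out$event_class, "deletion")
    # reconstruct the edited sequence from the deleted coordinates and verify
    # by an independent search that no site survives in the deleted span
    a <- min(sites$cut_position)
    b <- max(sites$cut_position)
    edited <- paste0(substr(sim$sequence, 1, a),
                     substr(sim$sequence, b + 1, nchar(sim$sequence)))
    sv <- site_survival(sites, edited, g)
    # precise religation of two cuts through identical protospacers can
    # reconstitute one site at the junction, but none survive inside the span
    remaining <- find_target_sites(edited, g)
    expect_lte(sv$remaining, 1)
    expect_true(all(remaining$cut_position == a))
    expect_equal(out$surviving_sites, 0)
    expect_lt(out$copy_total, sim$truth$total_repeats)
  })
})

test_that("variant-table generation respects tract truth when noiseless", {
  spec <- tract_spec(
    contig_length = 5e5,
    tracts = tibble::tibble(end = c(2e5, 5e5),
                            state = c("reference", "alternate")),
    sites_per_kb = 0.5, depth_mean = 200, depth_dispersion = 50,
    error_rate = 0.01, noise = 0, seed = 7
  )
  sim <- gen_variant_table(spec)
  st <- site_states(sim$variants)
  classified <- st[st$state != "uncertain", ]
  expect_equal(classified$state, classified$true_state)
  expect_equal(sim$truth_breakpoints, 2e5)

  single <- gen_variant_table(tract_spec(
    contig_length = 1e5,
    tracts = tibble::tibble(end = 1e5, state = "reference"), seed = 8
  ))
  expect_length(single$truth_breakpoints, 0)
})

test_that("cross-count generation hits its binomial anchors", {
  null <- gen_cross_counts(0.5, 1, n_offspring = 500, n_crosses = 200,
                           seed = 5)
  males <- null[null$parent_sex == "male", ]
  expect_equal(mean(males$n_sd / (males$n_sd + males$n_plus)), 0.5,
               tolerance = 0.01)

  perfect <- gen_cross_counts(1, 0.8, n_offspring = 100, n_crosses = 20,
                              seed = 6)
  pm <- perfect[perfect$parent_sex == "male", ]
  expect_true(all(pm$n_sd == 100))

  a <- gen_cross_counts(0.7, 0.9, 100, 10, seed = 9)
  b <- gen_cross_counts(0.7, 0.9, 100, 10, seed = 9)
  expect_identical(a, b)
})

test_that("FASTA and cross tables round-trip through their writers", {
  withr::with_seed(41, {
    seq <- random_dna(500)
    fa <- withr::local_tempfile(fileext = ".fa")
    write_fasta(seq, fa, name = "toy")
    back <- read_fasta(fa)
    expect_equal(unname(back), seq)
    expect_equal(names(back), "toy")

    crosses <- gen_cross_counts(0.8, 1, 100, 5, seed = 2)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    readr::write_tsv(crosses, tsv)
    expect_equal(as.data.frame(read_crosses_tsv(tsv)),
                 as.data.frame(crosses))
  })
})
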