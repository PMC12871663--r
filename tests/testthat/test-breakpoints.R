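make_records <- function(qual, depth) {
  tibble::tibble(
    contig = "c", pos = seq_along(qual) * 100, qual = qual,
    ref_depth = pmax(0, depth - 5), alt_depth = pmin(5, depth),
    total_depth = depth
  )
}

test_that("quality and depth-quantile filters follow the stated rules", {
  rec <- make_records(qual = c(29, 31, 50, 50, 50),
                      depth = c(30, 30, 10, 20, 50))
  out <- filter_variants(rec)
  expect_false(29 %in% out$qual)  # QUAL must exceed 30
  expect_true(31 %in% out$qual)

  # depths {10,20,30,40,50}: interpolated q25 = 20, q75 = 40, inclusive
  rec2 <- make_records(qual = rep(60, 5), depth = c(10, 20, 30, 40, 50))
  out2 <- filter_variants(rec2)
  expect_setequal(out2$total_depth, c(20, 30, 40))
  expect_equal(attr(out2, "depth_band"), c(20, 40))

  # degenerate depth distribution: everything passes the depth filter
  rec3 <- make_records(qual = rep(60, 4), depth = rep(33, 4))
  expect_equal(nrow(filter_variants(rec3)), 4)

  expect_warning(filter_variants(rec[0, ]), "no variant")
})

test_that("filtering is idempotent once the depth band is frozen", {
  withr::with_seed(2, {
    rec <- make_records(qual = runif(50, 20, 80),
                        depth = rpois(50, 40))
    once <- filter_variants(rec)
    band <- attr(once, "depth_band")
    twice <- filter_variants(once, depth_quantiles = c(0, 1))
    twice <- twice[twice$total_depth >= band[1] &
                     twice$total_depth <= band[2], ]
    attr(twice, "depth_band") <- attr(once, "depth_band") <- NULL
    expect_equal(as.data.frame(twice), as.data.frame(once))
    expect_true(nrow(once) <= nrow(rec))
  })
})

test_that("AD ratio arithmetic and boundaries", {
  expect_equal(ad_ratio(1, 9), 0.9)
  expect_equal(ad_ratio(50, 50), 0.5)
  expect_equal(ad_ratio(0, 37), 1)
  expect_true(is.na(ad_ratio(0, 0)))
})

test_that("genotype states partition [0,1] with the stated bands", {
  expect_equal(classify_state(c(0.9, 0.1, 0.5)),
               c("alternate", "reference", "heterozygous"))
  expect_equal(classify_state(0.2), "uncertain")
  expect_equal(classify_state(0.7), "heterozygous")
  expect_equal(classify_state(0.70001), "uncertain")
  expect_equal(classify_state(NA_real_), "uncertain")
  expect_error(classify_state(1.2), "0, 1")

  grid <- seq(0, 1, by = 0.001)
  states <- classify_state(grid)
  expect_true(all(states %in%
                    c("alternate", "reference", "heterozygous", "uncertain")))
  expect_equal(length(states), length(grid))
})

test_that("window summaries count states and report alternate frequency", {
  st <- tibble::tibble(
    contig = "c",
    pos = c(1:100, 50001:50100),
    ref_depth = c(rep(0, 100), rep(50, 50), rep(5, 50)),
    alt_depth = c(rep(50, 100), rep(50, 50), rep(95, 50))
  ) |> site_states()
  w <- window_states(st, window_size = 50000, contig_length = 100000)
  expect_equal(nrow(w), 2)
  expect_equal(w$alternate_frequency[1], 1)    # 100 alternate sites
  expect_equal(w$alternate_frequency[2], 0.5)  # 50 het + 50 alt
  expect_equal(w$mean_dose, c(1, 0.75))
  expect_false(any(w$empty))
  expect_error(window_states(st, window_size = 0), "positive")
})

test_that("depth-summed window frequency is available behind the flag", {
  st <- tibble::tibble(
    contig = "c", pos = c(100, 200),
    ref_depth = c(10, 90), alt_depth = c(90, 10)
  ) |> site_states()
  w <- window_states(st, window_size = 1000, contig_length = 1000,
                     freq_method = "depth")
  expect_equal(w$alternate_frequency, 0.5)
})

test_that("a clean state step yields one breakpoint bracketing the transition", {
  w <- 50000
  st <- tibble::tibble(
    contig = "c",
    pos = c(seq(1000, 10 * w - 1000, by = 2000),
            seq(10 * w + 1000, 20 * w - 1000, by = 2000)),
    ref_depth = 50, alt_depth = 0
  )
  st$alt_depth[st$pos > 10 * w] <- 50
  st$ref_depth[st$pos > 10 * w] <- 0
  states <- site_states(st)
  wins <- window_states(states, w, contig_length = 20 * w)
  bp <- call_breakpoints(wins, states = states)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$left_state, "reference")
  expect_equal(bp$right_state, "alternate")
  expect_lte(bp$start, 10 * w)
  expect_gte(bp$end, 10 * w - w)
  expect_lte(bp$end - bp$start, 2 * w)

  # a uniform heterozygous chromosome has no transitions
  het <- st
  het$ref_depth <- 25
  het$alt_depth <- 25
  hw <- window_states(site_states(het), w, contig_length = 20 * w)
  expect_equal(nrow(call_breakpoints(hw)), 0)

  expect_warning(call_breakpoints(wins[1:3, ]), "too few")
})

test_that("breakpoints are recovered on noisy synthetic recombinants", {
  w <- 50000
  for (seed in 1:5) {
    spec <- tract_spec(
      contig_length = 2e6,
      tracts = tibble::tibble(end = c(1.02e6, 2e6),
                              state = c("reference", "alternate")),
      sites_per_kb = 1, noise = 0.05, seed = seed
    )
    sim <- gen_variant_table(spec)
    states <- site_states(filter_variants(sim$variants))
    wins <- window_states(states, w, contig_length = 2e6)
    bp <- call_breakpoints(wins, states = states)
    expect_equal(nrow(bp), 1)
    expect_gte(sim$truth_breakpoints, bp$start - w)
    expect_lte(sim$truth_breakpoints, bp$end + w)
  }
})

test_that("variant tables round-trip through the VCF writer and reader", {
  spec <- tract_spec(
    contig_length = 1e5,
    tracts = tibble::tibble(end = 1e5, state = "heterozygous"),
    sites_per_kb = 0.5, seed = 3
  )
  sim <- gen_variant_table(spec)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(sim$variants, path)
  back <- read_variants_vcf(path)
  expect_equal(back$pos, sim$variants$pos)
  expect_equal(back$ref_depth, sim$variants$ref_depth)
  expect_equal(back$alt_depth, sim$variants$alt_depth)
  expect_equal(back$total_depth, sim$variants$total_depth)
  expect_equal(back$qual, sim$variants$qual, tolerance = 0.01)
  expect_equal(back$gt, sim$variants$gt)
  expect_equal(attr(back, "n_multiallelic"), 0)
})
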