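fx <- but2_fixtures()

test_that("bundled fixtures carry the canonical primers and gene model", {
  expect_equal(unname(fx$primers["BuT2_F"]), "CAGTGCTGCCAACAWTTYGT")
  expect_equal(unname(fx$primers["BuT2_R"]), "CASTGCTGCCAATTTAGCYA")
  expect_equal(unname(fx$primers["BuT2C_F"]), "AGACYTCGGGRACAGTTTTGC")
  expect_equal(unname(fx$primers["BuT2C_R"]), "AGCATTAATGCYAARCTTTC")
  expect_equal(sum(fx$exons$end - fx$exons$start + 1L), 1932L)
  expect_equal(fx$element_len, 2775L)
  expect_equal(fx$tir_len, 12L)
  expect_equal(fx$tsd_len, 8L)
  expect_equal(fx$tss, 325L)
})

test_that("random_genome is seed-deterministic with calibrated GC", {
  expect_identical(random_genome(5000, 0.4, seed = 61),
                   random_genome(5000, 0.4, seed = 61))
  expect_equal(random_genome(0, 0.5), "")
  g <- random_genome(100000, 0.5, seed = 62)
  expect_equal(gc_content(g), 0.5, tolerance = 0.02)
})

test_that("make_element has exact primer-compatible inverted termini and coding capacity", {
  el <- make_element(sim_config(seed = 63), seed = 63)
  expect_equal(nchar(el), 2775L)
  tir <- detect_tir(el, 12, max_mismatch = 0)
  expect_equal(tir$mismatches, 0L)
  f_hits <- scan_primer(el, fx$primers["BuT2_F"], max_mismatch = 0)
  expect_true(any(f_hits$orientation == "forward" & f_hits$start == 1L))
  r_hits <- scan_primer(el, fx$primers["BuT2_R"], max_mismatch = 0)
  expect_true(any(r_hits$orientation == "reverse" &
                  r_hits$end == nchar(el)))
  expect_gt(nrow(find_orfs(el, min_aa = 100)), 0L)
  # non-canonical lengths still produce a structured element
  el2 <- make_element(sim_config(seed = 63, element_len = 1500), seed = 64)
  expect_equal(nchar(el2), 1500L)
  expect_false(is.null(detect_tir(el2, 12, 0)))
})

test_that("derive_mite keeps both TIRs and loses coding capacity", {
  el <- make_element(sim_config(seed = 65), seed = 65)
  mite <- derive_mite(el, 350, 350)
  expect_equal(nchar(mite), 700L)
  tir <- detect_tir(mite, 12, max_mismatch = 0)
  expect_equal(tir$mismatches, 0L)
  expect_equal(nrow(find_orfs(mite, min_aa = 100)), 0L)
  expect_error(derive_mite(el, 5, 350), "breakpoints")
  expect_error(derive_mite(el, 2000, 1000), "breakpoints")
})

test_that("plant_copies duplicates each target site and keeps truth consistent", {
  set.seed(66)
  cfg <- sim_config(seed = 66, genome_len = 30000, n_complete = 2,
                    n_mite = 3)
  sim <- simulate_host_genome(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 5L)
  # non-overlapping, in bounds
  tr <- tr[order(tr$start), ]
  expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
  expect_true(all(tr$start > fx$tsd_len & tr$end + fx$tsd_len <=
                    nchar(sim$genome)))
  for (i in seq_len(nrow(tr))) {
    # both flanks equal the recorded TSD
    left <- substr(sim$genome, tr$start[i] - 8, tr$start[i] - 1)
    right <- substr(sim$genome, tr$end[i] + 1, tr$end[i] + 8)
    expect_equal(left, tr$tsd[i])
    expect_equal(right, tr$tsd[i])
    # the copy itself is the planted sequence
    planted <- if (tr$klass[i] == "complete") sim$element else sim$mite
    expect_equal(substr(sim$genome, tr$start[i], tr$end[i]),
                 as.vector(planted))
  }
  # TSDs of distinct copies differ
  expect_equal(anyDuplicated(tr$tsd), 0L)
  # too few distinct target sites for the requested insertions
  expect_error(plant_copies(random_genome(50, 0.5, 1),
                            setNames(rep(strrep("ACGT", 100), 5),
                                     paste0("c", 1:5)),
                            sim_config(seed = 1)), "too small")
})

test_that("planted copies are recovered end to end with exact structure", {
  cfg <- sim_config(seed = 67, genome_len = 25000, n_complete = 1, n_mite = 2)
  sim <- simulate_host_genome(cfg)
  ann <- annotate_genome(c(g = sim$genome), fx$primers["BuT2_F"],
                         fx$primers["BuT2_R"], max_mismatch = 3,
                         min_len = 400, max_len = 5000)
  tr <- sim$truth[order(sim$truth$start), ]
  expect_equal(ann$start, tr$start)
  expect_equal(ann$end, tr$end)
  expect_equal(ann$klass, tr$klass)
  expect_true(all(ann$tir_mismatches == 0L))
  expect_equal(ann$tsd_left, tr$tsd)
})

test_that("TIR detection degrades monotonically with terminal decay", {
  found_at <- function(rate) {
    hits <- 0L
    for (s in 1:30) {
      cfg <- sim_config(seed = 700 + s, genome_len = 6000, n_complete = 0,
                        n_mite = 1, terminal_mut_rate = rate)
      sim <- simulate_host_genome(cfg)
      copy <- substr(sim$genome, sim$truth$start, sim$truth$end)
      if (!is.null(detect_tir(copy, 12, max_mismatch = 2))) hits <- hits + 1L
    }
    hits
  }
  n0 <- found_at(0); n2 <- found_at(0.2); n5 <- found_at(0.5)
  expect_equal(n0, 30L)
  expect_gte(n0, n2)
  expect_gte(n2, n5)
})

test_that("evolve_pair hits its target divergence", {
  anc <- random_genome(4000, 0.5, seed = 68)
  same <- evolve_pair(anc, 0, seed = 68)
  expect_identical(same[1], anc)
  expect_identical(same[2], anc)
  expect_error(evolve_pair(anc, 0.8), "0.75")

  set.seed(69)
  ps <- vapply(1:150, function(i) {
    pair <- evolve_pair(anc, 0.2)
    p_distance(pair[1], pair[2])
  }, 0)
  expect_equal(mean(ps), 0.2, tolerance = 0.01)

  # realized variance shrinks with sequence length
  v_at <- function(L) {
    a <- random_genome(L, 0.5)
    stats::var(vapply(1:40, function(i) {
      pair <- evolve_pair(a, 0.2); p_distance(pair[1], pair[2])
    }, 0))
  }
  expect_gt(v_at(1000), v_at(10000))
})

test_that("make_scenario enforces mode constraints and is reproducible", {
  expect_error(make_scenario("VT", d_gene = 0.2, d_te = 0.1), "VT scenario")
  expect_error(make_scenario("HT", d_gene = 0.1, d_te = 0.2), "HT scenario")
  s1 <- make_scenario("HT", d_gene = 0.2, d_te = 0.02, seed = 70)
  s2 <- make_scenario("HT", d_gene = 0.2, d_te = 0.02, seed = 70)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "mode"), "HT")
  expect_equal(nchar(s1$te_a), 1000L)
  expect_equal(nchar(s1$gene_a), 5000L)
})
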