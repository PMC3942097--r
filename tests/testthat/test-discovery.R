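fx <- but2_fixtures()

test_that("in-silico PCR query is forward primer + revcomp(reverse primer)", {
  q <- build_ispcr_query(fx$primers["BuT2_F"], fx$primers["BuT2_R"])
  expect_equal(nchar(q), 40L)
  expect_equal(q, paste0("CAGTGCTGCCAACAWTTYGT",
                         oracle_revcomp("CASTGCTGCCAATTTAGCYA")))
  expect_equal(build_ispcr_query("A", "T"), "AA")
  expect_equal(build_ispcr_query("", ""), "")
})

test_that("scan_primer recovers planted sites on both strands", {
  set.seed(21)
  primer <- "CAGTGCTGCCAACAWTTYGT"
  site <- "CAGTGCTGCCAACAATTCGT"     # one instantiation of the primer
  g <- paste0(random_dna(500), site, random_dna(500))
  hits <- scan_primer(g, primer, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 501L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$orientation, "forward")

  grc <- reverse_complement(g)
  hits_rc <- scan_primer(grc, primer, max_mismatch = 0)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$orientation, "reverse")
  # mirrored coordinates
  expect_equal(hits_rc$start, nchar(g) - hits$end + 1L)
})

test_that("scan_primer equals the brute-force position scanner", {
  set.seed(22)
  for (i in 1:20) {
    g <- random_dna(1500)
    primer <- random_iupac(12)
    for (mm in c(1, 3)) {
      got <- scan_primer(g, primer, max_mismatch = mm)
      fwd <- oracle_scan_strand(g, primer, mm)
      rev <- oracle_scan_strand(g, oracle_revcomp(primer), mm)
      expect_setequal(got$start[got$orientation == "forward"], fwd)
      expect_setequal(got$start[got$orientation == "reverse"], rev)
    }
  }
  # genome N is non-matching by default
  expect_equal(nrow(scan_primer(strrep("N", 50), "NNNN", 0)), 0L)
  # primer longer than genome
  expect_equal(nrow(scan_primer("ACGT", strrep("A", 10), 3)), 0L)
})

test_that("pair_amplicons enforces span bounds and convergent orientation", {
  mkhit <- function(start, m, ori, primer) data.frame(
    seq_id = "g", start = start, end = start + 19L, primer = primer,
    mismatches = m, orientation = ori, stringsAsFactors = FALSE)
  f <- mkhit(100L, 0L, "forward", "F")
  r <- mkhit(780L, 0L, "reverse", "R")     # span = 799 - 100 + 1 = 700
  amp <- pair_amplicons(f, r, min_len = 400, max_len = 1200)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 700L)
  expect_equal(pair_amplicons(f, mkhit(3081L, 0L, "reverse", "R"),
                              min_len = 400, max_len = 1200) |> nrow(), 0L)
  # divergent-orientation hits never pair
  expect_equal(nrow(pair_amplicons(f, mkhit(781L, 0L, "forward", "R"),
                                   min_len = 400, max_len = 1200)), 0L)
})

test_that("pair_amplicons equals exhaustive enumeration with innermost rule", {
  set.seed(23)
  for (rep in 1:20) {
    f_starts <- sort(sample(1:3000, 3))
    r_starts <- sort(sample(1:3000, 3))
    f <- data.frame(seq_id = "g", start = f_starts, end = f_starts + 19L,
                    primer = "F", mismatches = 0L, orientation = "forward")
    r <- data.frame(seq_id = "g", start = r_starts, end = r_starts + 19L,
                    primer = "R", mismatches = 0L, orientation = "reverse")
    got <- pair_amplicons(f, r, min_len = 200, max_len = 1500)
    # brute force: per forward hit, shortest admissible span
    want <- list()
    for (i in 1:3) {
      spans <- r_starts + 19L - f_starts[i] + 1L
      ok <- which(r_starts >= f_starts[i] & spans >= 200 & spans <= 1500)
      if (length(ok)) {
        j <- ok[which.min(spans[ok])]
        want[[length(want) + 1L]] <- c(f_starts[i], r_starts[j] + 19L)
      }
    }
    want_keys <- sort(vapply(want, function(x) paste(x[1], x[2]), ""))
    expect_equal(sort(paste(got$start, got$end)), want_keys)
  }
})

test_that("detect_tir finds exact and mismatched inverted termini", {
  set.seed(24)
  tir <- "CAGTGCTGCCAA"
  core <- random_dna(300)
  s <- paste0(tir, core, reverse_complement(tir))
  hit <- detect_tir(s, tir_len = 12, max_mismatch = 0)
  expect_equal(hit$mismatches, 0L)
  expect_equal(unname(hit$left), c(1L, 12L))
  expect_equal(unname(hit$right), c(nchar(s) - 11L, nchar(s)))

  # two mutations inside the left TIR (positions 5 and 8, which window
  # shifting cannot realign): found at tolerance 2, absent at 1
  ch <- strsplit(s, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
  s2 <- paste(ch, collapse = "")
  expect_equal(detect_tir(s2, 12, max_mismatch = 2)$mismatches, 2L)
  expect_null(detect_tir(s2, 12, max_mismatch = 1))
  expect_error(detect_tir(s, tir_len = 0), "positive")
  expect_error(detect_tir("ACGTACGT", tir_len = 12), "shorter")
})

test_that("detect_tir recovery at an offset equals the all-window oracle", {
  set.seed(25)
  for (rep in 1:50) {
    tir <- random_dna(12)
    off_l <- sample(0:4, 1); off_r <- sample(0:4, 1)
    s <- paste0(random_dna(off_l), tir, random_dna(200),
                reverse_complement(tir), random_dna(off_r))
    hit <- detect_tir(s, 12, max_mismatch = 0, search_window = 5)
    expect_false(is.null(hit))
    # brute force over all window pairs: no pair can beat 0 mismatches, and
    # the planted pair must be among the zero-mismatch outermost choices
    expect_equal(hit$mismatches, 0L)
    lw <- substr(s, hit$left["start"], hit$left["end"])
    rw <- substr(s, hit$right["start"], hit$right["end"])
    expect_equal(lw, reverse_complement(rw))
  }
})

test_that("detect_tsd compares immediate flanks with a mismatch budget", {
  set.seed(26)
  tsd <- "TACGGATC"
  g <- paste0(random_dna(50), tsd, random_dna(300), tsd, random_dna(50))
  got <- detect_tsd(g, element_start = 59L, element_end = 358L, k = 8)
  expect_equal(got$left, tsd)
  expect_equal(got$right, tsd)
  expect_equal(got$mismatches, 0L)

  g1 <- paste0(random_dna(50), "TACGGATC", random_dna(300), "TACGGATA",
               random_dna(50))
  expect_equal(detect_tsd(g1, 59L, 358L, 8, max_mismatch = 1)$mismatches, 1L)
  expect_null(detect_tsd(g1, 59L, 358L, 8, max_mismatch = 0))
  expect_error(detect_tsd(g, 4L, 358L, 8), "flank")
})

test_that("random flanks almost never look like an exact TSD", {
  # false-positive probability for an exact 8-mer match is 4^-8 ~ 1.5e-5
  set.seed(27)
  n_found <- 0L
  for (i in 1:3000) {
    if (random_dna(8) == random_dna(8)) n_found <- n_found + 1L
  }
  expect_lte(n_found, 1L)
})

test_that("classify_copy applies the MITE criteria", {
  cfg <- sim_config(seed = 28)
  el <- make_element(cfg, seed = 28)
  tir <- detect_tir(el)
  expect_equal(classify_copy(el, tir)$klass, "complete")

  mite <- derive_mite(el)
  expect_equal(classify_copy(mite, detect_tir(mite))$klass, "mite")
  # TIR-less decayed copy
  expect_equal(classify_copy(substr(el, 100, 900), NULL)$klass, "fragment")
  # a long copy with TIRs but no ORF exceeds the MITE length cap
  long_nc <- paste0(substr(el, 1, 30), random_dna(1500),
                    substr(el, nchar(el) - 29, nchar(el)))
  cls <- classify_copy(long_nc, detect_tir(long_nc), mite_max_len = 1000)
  expect_true(cls$klass %in% c("fragment", "complete"))
})
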