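test_that("reverse complement matches the Biostrings oracle", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAATTC"), "GAATTT")
  expect_equal(reverse_complement("N"), "N")
  set.seed(2)
  for (s in replicate(20, random_dna(sample(1:60, 1)))) {
    expect_equal(reverse_complement(s),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
})

test_that("arm mismatch counting treats N as never pairing", {
  expect_equal(arm_mismatches("AAATTCGAATTT", 0, 6, 0), 0L)
  expect_equal(arm_mismatches("AAATTCGACTTT", 0, 6, 0), 1L)
  expect_equal(arm_mismatches("AANTTCGAATTT", 0, 6, 0), 1L)
  expect_error(arm_mismatches("ACGT", 0, 6, 0), "bounds")
})

test_that("simple palindromes are detected with arm, spacer and position", {
  h <- find_irs("AAATTCGAATTT")
  expect_equal(nrow(h), 1L)
  expect_equal(h$left_start, 0L)
  expect_equal(h$arm_len, 6L)
  expect_equal(h$spacer_len, 0L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$left_arm_seq, "AAATTC")

  h <- find_irs(paste0("AAATTC", "GCA", "GAATTT"))
  expect_equal(h$arm_len, 6L)
  expect_equal(h$spacer_len, 3L)
  expect_equal(h$mismatches, 0L)

  expect_equal(nrow(find_irs("")), 0L)
  expect_equal(nrow(brute_force_irs("")), 0L)
})

test_that("printed most-abundant arms are recovered at their full length", {
  arms <- c("AGAGCTCGGATCGAATCGGTAT",
            "AAATTCTTTTATTTTAGATAGAAGAAA",
            "ATAAAAGAAAGAAGA")
  for (arm in arms) {
    hits <- find_irs(palindrome_construct(arm))
    expect_equal(max(hits$arm_len), nchar(arm))
    top <- hits[hits$arm_len == nchar(arm), ]
    expect_equal(top$left_arm_seq, arm)
    expect_equal(top$left_start, 50L)
    expect_equal(top$spacer_len, 0L)
  }
})

test_that("scanner equals the exhaustive oracle on random sequences", {
  for (seed in 1:8) {
    set.seed(seed)
    gc <- c(0.2, 0.37, 0.5)[1 + seed %% 3]
    s <- random_dna(sample(300:800, 1), gc)
    expect_same_hits(find_irs(s), brute_force_irs(s))
  }
  # non-default parameters exercise the same code paths
  p <- ir_params(min_arm = 4, max_arm = 12, max_spacer = 3, max_mismatch = 0)
  set.seed(99)
  s <- random_dna(500, 0.5)
  expect_same_hits(find_irs(s, p), brute_force_irs(s, p))
})

test_that("hits are strand-symmetric", {
  for (seed in c(3, 14, 27)) {
    set.seed(seed)
    s <- random_dna(1000, 0.37)
    n <- nchar(s)
    fwd <- find_irs(s)
    rev <- find_irs(reverse_complement(s))
    mirrored <- data.frame(
      genome_id = rev$genome_id,
      left_start = n - (rev$left_start + 2L * rev$arm_len + rev$spacer_len),
      arm_len = rev$arm_len, spacer_len = rev$spacer_len,
      mismatches = rev$mismatches,
      left_arm_seq = rev$left_arm_seq, stringsAsFactors = FALSE)
    mirrored$left_arm_seq <- vapply(
      substring(s, mirrored$left_start + 1L,
                mirrored$left_start + mirrored$arm_len), identity, "",
      USE.NAMES = FALSE)
    expect_same_hits(fwd, mirrored)
  }
})

test_that("every reported hit is maximal under one-step extension", {
  params <- ir_params()
  for (seed in c(5, 21)) {
    set.seed(seed)
    s <- random_dna(800, 0.37)
    hits <- find_irs(s, params)
    expect_gt(nrow(hits), 0L)
    for (i in seq_len(nrow(hits)))
      expect_false(extension_valid(s, hits[i, ], params))
  }
})

test_that("raising the mismatch budget never shrinks hit coverage", {
  covered <- function(hits) {
    if (!nrow(hits)) return(integer())
    unique(unlist(Map(seq,
                      hits$left_start,
                      hits$left_start + 2L * hits$arm_len +
                        hits$spacer_len - 1L)))
  }
  for (seed in c(8, 12, 30)) {
    set.seed(seed)
    s <- random_dna(1200, 0.37)
    c0 <- covered(find_irs(s, ir_params(max_mismatch = 0)))
    c1 <- covered(find_irs(s, ir_params(max_mismatch = 1)))
    expect_true(all(c0 %in% c1))
  }
})

test_that("planted repeats are recovered at exact arm and spacer", {
  set.seed(17)
  bg <- gen_background(6000, 0.37, id = "p")
  res <- plant_random(bg, 12)
  hits <- find_irs(res$record)
  for (i in seq_len(nrow(res$truth))) {
    tr <- res$truth[i, ]
    match_row <- hits[hits$left_start == tr$left_start, ]
    expect_equal(nrow(match_row[match_row$arm_len == tr$arm_len &
                                  match_row$spacer_len == tr$spacer_len, ]),
                 1L, info = paste("plant", i))
  }
})

test_that("hit writers emit TSV and BED with the outer span", {
  h <- find_irs(genome_record("g1", "AAATTCGCAGAATTT", warn = FALSE))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_tsv(h, tsv)
  back <- read.delim(tsv, colClasses = c(genome_id = "character",
                                         left_arm_seq = "character"))
  expect_equal(back$left_start, h$left_start)
  write_hits_bed(h, bed)
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V3 - b$V2, 2L * h$arm_len + h$spacer_len)
  expect_equal(b$V5, h$arm_len)
})
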