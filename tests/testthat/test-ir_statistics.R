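mk_hits <- function(arms, genome_id = "g1") {
  n <- length(arms)
  data.frame(genome_id = rep_len(genome_id, n),
             left_start = seq(0L, by = 150L, length.out = n),
             arm_len = as.integer(arms),
             spacer_len = rep_len(0L, n),
             mismatches = rep_len(0L, n),
             left_arm_seq = vapply(arms, function(a)
               strrep("A", a), "", USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

mk_record <- function(len, id = "g1") {
  genome_record(id, strrep("C", len), warn = FALSE)
}

test_that("genome profiles count per length and per kbp", {
  p <- profile_genome(mk_hits(6), mk_record(1000))
  expect_equal(p$counts[["6"]], 1L)
  expect_equal(unname(p$freq_per_kbp[["6"]]), 1.0)
  expect_equal(p$total, 1L)

  p <- profile_genome(mk_hits(c(6, 8, 12)), mk_record(2000))
  expect_equal(unname(p$agg_counts),
               c(3L, 2L, 1L, 1L))  # all, 8+, 10+, 12+
  expect_equal(p$total, sum(p$counts))
  expect_equal(unname(p$agg_counts[["all"]]), p$total)
  expect_true(p$agg_counts[["8+"]] >= p$agg_counts[["10+"]])
  expect_true(p$agg_counts[["10+"]] >= p$agg_counts[["12+"]])
  expect_error(profile_genome(mk_hits(6, "other"), mk_record(100)),
               "belong")
})

test_that("profiles of planted genomes equal the planting record", {
  set.seed(3)
  bg <- gen_background(8000, 0.37, id = "s3")
  res <- plant_random(bg, 10, arm_range = c(25L, 40L))
  # arms 25-40 bp are far beyond chance hits: profile counts at those
  # lengths must equal the planted multiset exactly
  hits <- find_irs(res$record)
  p <- profile_genome(hits, res$record)
  planted <- table(factor(res$truth$arm_len, levels = 6:60))
  for (L in 25:40)
    expect_equal(p$counts[[as.character(L)]],
                 unname(planted[[as.character(L)]]))
})

test_that("group aggregation pools counts and summarizes sizes", {
  r1 <- mk_record(1000, "a"); r2 <- mk_record(3000, "b")
  p1 <- profile_genome(mk_hits(c(6, 6, 18), "a"), r1)
  p2 <- profile_genome(mk_hits(c(8, 24), "b"), r2)
  g <- aggregate_group(list(p1, p2), list(r1, r2), "G")
  expect_equal(g$profile$total, 5L)
  expect_equal(g$profile$seq_bp, 4000)
  expect_equal(g$profile$counts[["6"]], 2L)
  s <- g$summary
  expect_equal(s$n_seq, 2L)
  expect_equal(s$median_size, 2000)
  expect_equal(s$min_seq_id, "a")
  expect_equal(s$max_seq_id, "b")
  # unweighted mean of per-genome frequencies: (3/1 + 2/3)/2 per kbp
  expect_equal(s$mean_freq, mean(c(3, 2 / 3)))
  expect_equal(s$pooled_freq, 1000 * 5 / 4000)
  expect_true(s$freq_min <= s$mean_freq && s$mean_freq <= s$freq_max)
  expect_error(aggregate_group(list(), list(), "G"), "empty")
})

test_that("longest-for-half is the largest arm reached by half the group", {
  one <- aggregate_group(list(profile_genome(mk_hits(c(6, 18)), mk_record(1000))),
                         list(mk_record(1000)), "G")
  expect_equal(one$summary$longest_for_half, 18L)

  # with per-genome maxima {18, 24}, arm 24 is reached by exactly half
  expect_equal(sirscan:::longest_for_half(c(18, 24)), 24)
  expect_equal(sirscan:::longest_for_half(c(32, 32, 32, 32, 20, 20, 20, 20)),
               32)
  expect_equal(sirscan:::longest_for_half(c(0, 0, 0, 15)), 0L)
  # non-increasing as genomes with lower maxima join the group
  set.seed(9)
  for (i in 1:20) {
    base <- sample(6:40, 5, replace = TRUE)
    more <- c(base, sample(6:min(base), 2, replace = TRUE))
    expect_lte(sirscan:::longest_for_half(more),
               sirscan:::longest_for_half(base))
  }
})

test_that("dataset length table conserves counts and pools frequencies", {
  p <- profile_genome(mk_hits(6), mk_record(1000))
  t1 <- table1_report(list(p))
  expect_equal(t1$ir_size[1], "6")
  expect_equal(t1$amount[1], 1L)
  expect_equal(t1$freq_per_kbp[1], 1.0)
  expect_equal(nrow(t1), 26L)  # 6..30 plus >30

  p0 <- profile_genome(mk_hits(integer()), mk_record(500))
  expect_true(all(table1_report(list(p0))$amount == 0L))

  set.seed(5)
  recs <- lapply(1:3, function(i) gen_background(3000, 0.37,
                                                 id = paste0("g", i)))
  profs <- lapply(recs, function(r) profile_genome(find_irs(r), r))
  t1 <- table1_report(profs)
  pooled <- Reduce(`+`, lapply(profs, `[[`, "counts"))
  expect_equal(sum(t1$amount), sum(pooled))
  over30 <- t1$amount[t1$ir_size == ">30"]
  expect_equal(over30, sum(pooled[as.integer(names(pooled)) > 30]))
})

test_that("per-kbp frequency is scale invariant", {
  p1 <- profile_genome(mk_hits(rep(6, 4)), mk_record(2000))
  p2 <- profile_genome(mk_hits(rep(6, 8), "g2"), mk_record(4000, "g2"))
  expect_equal(p1$freq_per_kbp, p2$freq_per_kbp)
})
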