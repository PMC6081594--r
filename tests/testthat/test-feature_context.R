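mk_hit <- function(left_start, arm = 6L, spacer = 0L, genome_id = "g1") {
  data.frame(genome_id = genome_id, left_start = as.integer(left_start),
             arm_len = as.integer(arm), spacer_len = as.integer(spacer),
             mismatches = 0L, left_arm_seq = strrep("A", arm),
             stringsAsFactors = FALSE)
}

mk_feat <- function(start, end, ftype = "gene", genome_id = "g1") {
  data.frame(genome_id = genome_id, ftype = ftype,
             start = as.integer(start), end = as.integer(end),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("hits classify by overlap with before/inside/after regions", {
  feat <- mk_feat(200, 300)
  expect_equal(classify_hit(mk_hit(150), feat, 1000), "before")
  expect_equal(classify_hit(mk_hit(195), feat, 1000),
               c("before", "inside"))
  expect_equal(classify_hit(mk_hit(340), feat, 1000), "after")
  expect_equal(classify_hit(mk_hit(440), feat, 1000), character())
  # wholly inside -> inside only
  expect_equal(classify_hit(mk_hit(250), feat, 1000), "inside")
  # spanning the whole feature touches all three regions
  expect_setequal(classify_hit(mk_hit(190, arm = 60, spacer = 10),
                               feat, 1000),
                  c("before", "inside", "after"))
})

test_that("classification is invariant under joint translation", {
  set.seed(4)
  for (i in 1:25) {
    fs <- sample(200:400, 1); fe <- fs + sample(50:200, 1)
    hs <- fs + sample(-150:250, 1)
    shift <- sample(1:500, 1)
    a <- classify_hit(mk_hit(hs, arm = 8, spacer = 2),
                      mk_feat(fs, fe), 5000)
    b <- classify_hit(mk_hit(hs + shift, arm = 8, spacer = 2),
                      mk_feat(fs + shift, fe + shift), 5000)
    expect_equal(a, b)
  }
})

test_that("context counts and frequencies follow the region definition", {
  feats <- mk_feat(200, 300)
  ctx <- context_counts(mk_hit(250), feats, c(g1 = 1000))
  inside_all <- ctx[ctx$region == "inside" & ctx$length_class == "all", ]
  expect_equal(inside_all$ir_count, 1L)
  expect_equal(inside_all$region_bp, 100)
  expect_equal(inside_all$freq_per_kbp, 10.0)
  # interior feature: flanks are exactly `flank` bp each
  expect_equal(ctx$region_bp[ctx$region == "before"], rep(100, 4))
  expect_equal(ctx$region_bp[ctx$region == "after"], rep(100, 4))

  none <- context_counts(mk_hit(250)[0, ], feats, c(g1 = 1000))
  expect_true(all(none$ir_count == 0L))

  # flank clipping at the genome edge
  edge <- context_counts(mk_hit(250)[0, ], mk_feat(30, 80), c(g1 = 120))
  expect_equal(unique(edge$region_bp[edge$region == "before"]), 30)
  expect_equal(unique(edge$region_bp[edge$region == "after"]), 40)
})

test_that("length classes are cumulative and counted per event", {
  feats <- rbind(mk_feat(100, 300), mk_feat(500, 700, "stem_loop"))
  hits <- rbind(mk_hit(150, arm = 6), mk_hit(200, arm = 12),
                mk_hit(550, arm = 10), mk_hit(95, arm = 8))
  ctx <- context_counts(hits, feats, c(g1 = 1000))
  gi <- function(ft, reg, cls)
    ctx$ir_count[ctx$ftype == ft & ctx$region == reg &
                   ctx$length_class == cls]
  expect_equal(gi("gene", "inside", "all"), 3L)  # 150, 200 and 95 (overlap)
  expect_equal(gi("gene", "inside", "8+"), 2L)
  expect_equal(gi("gene", "inside", "10+"), 1L)
  expect_equal(gi("gene", "inside", "12+"), 1L)
  expect_equal(gi("gene", "before", "all"), 1L)  # the boundary hit at 95
  expect_equal(gi("stem_loop", "inside", "10+"), 1L)
  # monotone within every (ftype, region)
  for (ft in unique(ctx$ftype)) for (reg in unique(ctx$region)) {
    v <- vapply(c("all", "8+", "10+", "12+"),
                function(cl) gi(ft, reg, cl), integer(1))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("duplicating features doubles counts and bp, keeping frequencies", {
  set.seed(6)
  feats <- rbind(mk_feat(100, 400), mk_feat(600, 640, "tRNA"))
  hits <- mk_hit(sample(0:900, 40, replace = TRUE))
  a <- context_counts(hits, feats, c(g1 = 1000))
  b <- context_counts(rbind(feats, feats), hits = hits, c(g1 = 1000))
  expect_equal(b$ir_count, 2L * a$ir_count)
  expect_equal(b$region_bp, 2 * a$region_bp)
  expect_equal(b$freq_per_kbp, a$freq_per_kbp)
})

test_that("enrichment is relative to the gene-interior baseline", {
  feats <- rbind(mk_feat(100, 200), mk_feat(400, 500, "stem_loop"))
  hits <- rbind(mk_hit(120), mk_hit(420))
  ctx <- context_counts(hits, feats, c(g1 = 1000))
  # the 8+/10+/12+ baselines are empty here (arm-6 hits only): warned
  enr <- suppressWarnings(enrichment(ctx))
  pick <- function(ft, reg, cls)
    enr$enrichment[enr$ftype == ft & enr$region == reg &
                     enr$length_class == cls]
  expect_equal(pick("stem_loop", "inside", "all"), 1.0)
  expect_equal(pick("gene", "inside", "all"), 1.0)
  expect_equal(pick("stem_loop", "before", "all"), 0.0)
  # zero baseline classes are NA with a warning, never numbers
  expect_warning(enr2 <- enrichment(ctx[ctx$length_class %in%
                                          c("all", "12+"), ]),
                 "undefined")
  expect_true(all(is.na(enr2$enrichment[enr2$length_class == "12+"])))
})

test_that("planted per-region placements are recovered from ground truth", {
  ds <- gen_dataset(synth_config(seed = 9))
  lens <- stats::setNames(
    vapply(ds$records, `[[`, numeric(1), "length"),
    vapply(ds$records, `[[`, "", "id"))
  ctx <- context_counts(ds$truth, ds$features, lens)
  # every planted hit lies wholly inside its recorded planting region, so
  # the contextual count for (ftype, region, all) is at least the number
  # of plants recorded there
  planted <- table(ds$truth$ftype, ds$truth$region)
  for (ft in rownames(planted)) for (reg in colnames(planted)) {
    if (planted[ft, reg] == 0) next
    got <- ctx$ir_count[ctx$ftype == ft & ctx$region == reg &
                          ctx$length_class == "all"]
    expect_gte(got, planted[ft, reg])
  }
})
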