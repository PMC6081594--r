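# Independent oracles and shared fixtures used across the suite.

# Full dynamic-programming Levenshtein matrix, independent of the
# package's implementation.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L,
                               D[i, j] + (x[i] != y[j]))
    }
  }
  D[n + 1L, m + 1L]
}

# Brute-force Lance-Williams agglomeration with the Ward.D2 update:
# squared Euclidean distances inside the criterion, merge heights
# reported on the unsquared scale.  Returns the sorted merge heights.
lw_ward_heights <- function(m) {
  d2 <- as.matrix(dist(m))^2
  n <- nrow(m)
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        v <- d2[active[ii], active[jj]]
        if (v < bestv) { bestv <- v; best <- c(active[ii], active[jj]) }
      }
    }
    i <- best[1L]; j <- best[2L]
    heights <- c(heights, sqrt(bestv))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bestv) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

random_dna <- function(n, gc = 0.37) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# All-C flanked palindrome construct around a printed arm sequence.
palindrome_construct <- function(arm) {
  paste0(strrep("C", 50), arm, reverse_complement(arm), strrep("C", 128))
}

# Hit set comparison ignoring row order/names.
expect_same_hits <- function(a, b) {
  key <- function(h) {
    h <- h[order(h$left_start, h$spacer_len, h$arm_len), ]
    rownames(h) <- NULL
    h
  }
  expect_identical(key(a), key(b))
}

# Is extending a hit outward by one base (same center) still a valid
# inverted repeat under `params`?  Used by the maximality property.
extension_valid <- function(seq, hit, params) {
  n <- nchar(seq)
  a <- hit$arm_len + 1L
  left <- hit$left_start - 1L
  span <- 2L * a + hit$spacer_len
  if (left < 0L || left + span > n || a > params$max_arm) return(FALSE)
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N"))
  comp <- c(4L, 3L, 2L, 1L, NA_integer_)
  pair_ok <- function(p, q) {
    cc <- comp[code[p + 1L]]
    !is.na(cc) && cc == code[q + 1L]
  }
  outer_ok <- pair_ok(left, left + span - 1L)
  inner_ok <- pair_ok(left + a - 1L, left + a + hit$spacer_len)
  total_mm <- arm_mismatches(seq, left, a, hit$spacer_len)
  outer_ok && inner_ok && total_mm <= params$max_mismatch
}

# Study-scale synthetic dataset for enrichment recovery: ten 30-kbp
# genomes, >= 50 features of the contrasted types in total, planted
# inside-density multiplier 10 for stem_loop vs gene.
enrichment_config <- function(seed) {
  synth_config(
    n_genomes = 10L,
    length_bp = 30000L,
    gc = 0.37,
    feature_layout = data.frame(
      ftype = c("gene", "stem_loop", "tRNA", "rRNA", "intron",
                "repeat_region", "exon"),
      count = c(12L, 10L, 5L, 1L, 3L, 1L, 3L),
      length = c(900L, 250L, 70L, 1200L, 250L, 800L, 150L),
      stringsAsFactors = FALSE),
    densities = data.frame(
      ftype = c("gene", "stem_loop", "rRNA", "repeat_region"),
      region = c("inside", "inside", "inside", "before"),
      multiplier = c(1, 10, 0.2, 5),
      stringsAsFactors = FALSE),
    base_rate = 0.8,
    arm_range = c(12L, 20L),
    spacer_range = c(0L, 5L),
    mismatch_prob = 0.2,
    seed = seed)
}
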