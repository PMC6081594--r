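# Synthetic annotated cpDNA-like genomes with planted inverted repeats.
#
# The generator emulates AT-rich plastid-like sequence (default GC 0.37),
# lays out non-overlapping annotated features, and plants inverted repeats
# at Poisson-distributed positions whose per-region rates follow
# configurable density multipliers (e.g. elevated inside stem_loop and
# before repeat_region, depleted inside rRNA).  Every plant is recorded in
# a ground-truth table sufficient to recompute the expected statistics of
# the downstream modules exactly.

#' Generate an i.i.d. random background genome
#'
#' @param length genome length (bp).
#' @param gc GC fraction; G and C (A and T) are equiprobable within their
#'   pair.
#' @param seed optional integer seed (deterministic output for fixed seed).
#' @param id genome identifier.
#' @param group optional group label.
#' @return a [genome_record()].
#' @export
gen_background <- function(length, gc = 0.37, seed = NULL, id = "synth",
                           group = NA_character_) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  genome_record(id, seq, group = group, warn = FALSE)
}

#' Check that a window contains no inverted repeat
#'
#' Runs the exhaustive oracle on the subsequence `[start, end)` (0-based
#' half-open); hits crossing the window boundary are not considered (they
#' cannot compete with a plant inside the window).
#'
#' @param record a [genome_record()].
#' @param start,end window bounds, 0-based half-open.
#' @param params scan parameters.
#' @return TRUE when the window is free of inverted repeats.
#' @export
screen_ir_free <- function(record, start, end, params = ir_params()) {
  win <- substr(record$seq, start + 1L, end)
  nrow(brute_force_irs(genome_record("win", win, warn = FALSE), params)) == 0L
}

replace_at <- function(seq, pos0, replacement) {
  # overwrite starting at 0-based pos0
  paste0(substr(seq, 1L, pos0),
         replacement,
         substr(seq, pos0 + nchar(replacement) + 1L, nchar(seq)))
}

#' Plant one inverted repeat into a genome
#'
#' Writes `arm + spacer + reverse_complement(arm)` at position `at`
#' (0-based); the spacer keeps the pre-existing residues.  Listed
#' mismatches (1-based internal arm indices) are applied to the right arm
#' by replacing the paired base with the left-arm base itself (never a
#' Watson-Crick partner).  The two flanking base pairs just outside the
#' arms are forced to mismatch so the planted arm length is maximal, and
#' the plant is verified with the exhaustive oracle: the expected hit must
#' be recovered exactly at this locus, otherwise an error is raised (the
#' caller can retry elsewhere).
#'
#' @param record a [genome_record()].
#' @param arm_seq left-arm sequence (or NULL to draw one of `arm_len`).
#' @param arm_len arm length used when `arm_seq` is NULL.
#' @param spacer_len spacer length (bp).
#' @param mismatch_positions integer vector of internal arm indices
#'   (1-based; never the first or last index) to mutate on the right arm.
#' @param at 0-based position of the left arm start.
#' @param reserved optional two-column matrix of already-planted reserved
#'   spans (0-based half-open, including the 2 bp extension guard);
#'   overlap raises an error.
#' @param verify verify recoverability with [brute_force_irs()].
#' @param params scan parameters used for verification.
#' @return list with `record` (modified genome), `hit` (one-row
#'   ground-truth data.frame) and `reserved_span` (guarded interval).
#' @export
plant <- function(record, arm_seq = NULL, arm_len = NULL, spacer_len = 0L,
                  mismatch_positions = integer(), at,
                  reserved = NULL, verify = TRUE, params = ir_params()) {
  if (is.null(arm_seq)) {
    stopifnot(!is.null(arm_len))
    arm_seq <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
                     collapse = "")
  }
  a <- nchar(arm_seq)
  stopifnot(a >= params$min_arm, a <= params$max_arm,
            spacer_len >= 0L, spacer_len <= params$max_spacer,
            length(mismatch_positions) <= params$max_mismatch)
  if (length(mismatch_positions) &&
      any(mismatch_positions <= 1L | mismatch_positions >= a))
    stop("mismatch positions must be internal arm indices", call. = FALSE)
  span <- 2L * a + spacer_len
  n <- record$length
  if (at < 0L || at + span > n)
    stop("planted span does not fit in the genome", call. = FALSE)
  guard <- c(max(0L, at - 2L), min(n, at + span + 2L))
  if (!is.null(reserved) && nrow(reserved)) {
    if (any(pmax(reserved[, 1L], guard[1L]) < pmin(reserved[, 2L], guard[2L])))
      stop("planted span overlaps an existing plant", call. = FALSE)
  }

  seq <- record$seq
  seq <- replace_at(seq, at, arm_seq)
  right <- reverse_complement(arm_seq)
  seq <- replace_at(seq, at + a + spacer_len, right)
  # right-arm mutations: left index i pairs absolute 0-based
  # at + span - i; overwrite with the left base (never complementary)
  for (i in mismatch_positions) {
    left_base <- substr(arm_seq, i, i)
    pos0 <- at + span - i
    seq <- replace_at(seq, pos0, left_base)
  }
  # block outward extension: force the two flanking pairs to mismatch by
  # writing the opposing base itself
  for (e in 1:2) {
    pl <- at - e
    pr <- at + span + e - 1L
    if (pl >= 0L && pr < n) {
      b <- substr(seq, pr + 1L, pr + 1L)
      if (b == "N") b <- "A"
      seq <- replace_at(seq, pl, b)
    }
  }
  out <- genome_record(record$id, seq, group = record$group, warn = FALSE)
  hit <- data.frame(genome_id = record$id, left_start = at, arm_len = a,
                    spacer_len = as.integer(spacer_len),
                    mismatches = length(mismatch_positions),
                    left_arm_seq = arm_seq, stringsAsFactors = FALSE)
  if (verify) {
    w0 <- guard[1L]
    win <- substr(out$seq, w0 + 1L, guard[2L])
    bf <- brute_force_irs(genome_record("win", win, warn = FALSE), params)
    ok <- any(bf$left_start == at - w0 & bf$arm_len == a &
                bf$spacer_len == spacer_len)
    if (!ok)
      stop("planted repeat is not cleanly recoverable at this locus",
           call. = FALSE)
  }
  list(record = out, hit = hit, reserved_span = guard)
}

#' Plant many repeats at screened, IR-free loci
#'
#' For each plant a random locus is drawn, the guarded window is rewritten
#' with fresh background residues until it is IR-free
#' ([screen_ir_free()]), and the repeat is planted and verified.  Used by
#' the planted-recovery validation of the detector.
#'
#' @param record background [genome_record()].
#' @param n number of plants.
#' @param arm_range,spacer_range inclusive ranges to draw arm and spacer
#'   lengths from.
#' @param mismatch_prob probability that a plant carries one internal
#'   mismatch.
#' @param gc GC fraction used when rewriting windows.
#' @param params scan parameters.
#' @param max_tries attempts per plant before giving up.
#' @return list with `record` (modified genome) and `truth` (ground-truth
#'   hit data.frame, one row per plant).
#' @export
plant_random <- function(record, n, arm_range = c(6L, 60L),
                         spacer_range = c(0L, 10L), mismatch_prob = 0.3,
                         gc = 0.37, params = ir_params(), max_tries = 200L) {
  reserved <- matrix(numeric(), ncol = 2L)
  truth <- list()
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (k in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      a <- sample(arm_range[1L]:arm_range[2L], 1L)
      sp <- sample(spacer_range[1L]:spacer_range[2L], 1L)
      span <- 2L * a + sp
      at <- sample(2:(record$length - span - 2L), 1L)
      guard <- c(at - 2L, at + span + 2L)
      if (nrow(reserved) &&
          any(pmax(reserved[, 1L], guard[1L]) < pmin(reserved[, 2L], guard[2L])))
        next
      # rewrite the guarded window until it is repeat-free
      clean <- FALSE
      for (r in 1:50) {
        fresh <- paste(sample(names(p), guard[2L] - guard[1L],
                              replace = TRUE, prob = p), collapse = "")
        cand <- genome_record(record$id,
                              replace_at(record$seq, guard[1L], fresh),
                              group = record$group, warn = FALSE)
        if (screen_ir_free(cand, guard[1L], guard[2L], params)) {
          clean <- TRUE
          break
        }
      }
      if (!clean) next
      mm <- if (a > 2L && runif(1) < mismatch_prob)
        sample(2:(a - 1L), 1L) else integer()
      res <- tryCatch(
        plant(cand, arm_len = a, spacer_len = sp, mismatch_positions = mm,
              at = at, reserved = reserved, verify = TRUE, params = params),
        error = function(e) NULL)
      if (is.null(res)) next
      record <- res$record
      reserved <- rbind(reserved, res$reserved_span)
      truth[[length(truth) + 1L]] <- res$hit
      done <- TRUE
      break
    }
    if (!done)
      stop("could not place plant ", k, " after ", max_tries, " tries",
           call. = FALSE)
  }
  list(record = record, truth = do.call(rbind, truth))
}

#' Synthetic dataset configuration
#'
#' @param n_genomes number of genomes.
#' @param length_bp genome length (bp).
#' @param gc background GC fraction (AT-rich plastid-like default 0.37).
#' @param groups group labels recycled across genomes.
#' @param feature_layout data.frame with columns `ftype`, `count`,
#'   `length`: how many features of each type per genome and how long.
#' @param densities data.frame with columns `ftype`, `region`
#'   (inside/before/after) and `multiplier`: planting rate multipliers
#'   relative to `base_rate`.
#' @param base_rate planting rate (plants per kbp) at multiplier 1.
#' @param arm_range,spacer_range inclusive draw ranges for planted arms
#'   and spacers.
#' @param mismatch_prob probability of one internal mismatch per plant.
#' @param flank neighborhood width used for before/after planting regions.
#' @param seed integer seed (mandatory; the whole dataset is deterministic
#'   in it).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genomes = 4L,
                         length_bp = 20000L,
                         gc = 0.37,
                         groups = c("GroupA", "GroupB"),
                         feature_layout = default_feature_layout(),
                         densities = default_densities(),
                         base_rate = 1,
                         arm_range = c(12L, 20L),
                         spacer_range = c(0L, 5L),
                         mismatch_prob = 0.2,
                         flank = 100L,
                         seed) {
  stopifnot(!missing(seed), n_genomes >= 1L, length_bp > 0L,
            all(densities$multiplier >= 0), base_rate >= 0)
  need <- sum(feature_layout$count * (feature_layout$length + 20L))
  if (need > length_bp)
    stop("feature layout does not fit in the genome (needs ~", need,
         " bp of ", length_bp, ")", call. = FALSE)
  structure(list(n_genomes = as.integer(n_genomes),
                 length_bp = as.integer(length_bp), gc = gc,
                 groups = groups, feature_layout = feature_layout,
                 densities = densities, base_rate = base_rate,
                 arm_range = as.integer(arm_range),
                 spacer_range = as.integer(spacer_range),
                 mismatch_prob = mismatch_prob, flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_feature_layout <- function() {
  data.frame(
    ftype = c("gene", "CDS", "tRNA", "rRNA", "exon", "intron",
              "stem_loop", "repeat_region", "regulatory", "misc_feature"),
    count = c(8L, 4L, 6L, 1L, 4L, 4L, 6L, 1L, 2L, 1L),
    length = c(600L, 400L, 70L, 1200L, 150L, 250L, 200L, 800L, 120L, 100L),
    stringsAsFactors = FALSE)
}

#' @rdname synth_config
#' @export
default_densities <- function() {
  data.frame(
    ftype = c("gene", "stem_loop", "rRNA", "tRNA", "intron",
              "repeat_region"),
    region = c("inside", "inside", "inside", "inside", "inside", "before"),
    multiplier = c(1, 10, 0.2, 2, 2, 5),
    stringsAsFactors = FALSE)
}

place_features <- function(cfg, genome_id) {
  # random non-overlapping feature intervals
  occupied <- matrix(numeric(), ncol = 2L)
  rows <- list()
  # place long features first: keeps rejection sampling feasible at
  # moderate occupancy
  layout_order <- order(-cfg$feature_layout$length)
  for (i in layout_order) {
    ft <- cfg$feature_layout$ftype[i]
    w <- cfg$feature_layout$length[i]
    for (k in seq_len(cfg$feature_layout$count[i])) {
      placed <- FALSE
      for (try in 1:500) {
        s <- sample(0:(cfg$length_bp - w), 1L)
        if (!nrow(occupied) ||
            !any(pmax(occupied[, 1L], s) < pmin(occupied[, 2L], s + w))) {
          occupied <- rbind(occupied, c(s, s + w))
          rows[[length(rows) + 1L]] <-
            data.frame(genome_id = genome_id, ftype = ft, start = s,
                       end = s + w,
                       strand = sample(c("+", "-"), 1L),
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("infeasible feature layout for '", genome_id, "'",
             call. = FALSE)
    }
  }
  feats <- do.call(rbind, rows)
  feats[order(feats$start), ]
}

#' Generate a synthetic annotated dataset with planted repeats
#'
#' Generates `n_genomes` background genomes, lays out annotated features,
#' and plants inverted repeats inside (or before/after) features of each
#' configured type at Poisson rates `base_rate * multiplier * region_kbp`,
#' rejecting overlaps.  Deterministic in `cfg$seed`.  When `out_dir` is
#' given, writes `genomes.fasta`, `features.tbl` (NCBI feature table),
#' `manifest.tsv`, `ground_truth.tsv` and `config.yaml` there.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional output directory.
#' @param params scan parameters used for plant verification.
#' @return list with `records` (genome records), `features` (data.frame),
#'   `manifest` (named vector), `truth` (ground-truth hit data.frame with
#'   extra `ftype`/`region` planting columns) and `config`.
#' @export
gen_dataset <- function(cfg, out_dir = NULL, params = ir_params()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  records <- list()
  feats <- list()
  truth <- list()
  groups <- rep_len(cfg$groups, cfg$n_genomes)
  for (gi in seq_len(cfg$n_genomes)) {
    gid <- sprintf("synth%02d", gi)
    rec <- gen_background(cfg$length_bp, cfg$gc, id = gid,
                          group = groups[gi])
    fg <- place_features(cfg, gid)
    reserved <- matrix(numeric(), ncol = 2L)
    for (di in seq_len(nrow(cfg$densities))) {
      ft <- cfg$densities$ftype[di]
      region <- cfg$densities$region[di]
      mult <- cfg$densities$multiplier[di]
      if (mult == 0 || cfg$base_rate == 0) next
      sel <- fg[fg$ftype == ft, ]
      for (fi in seq_len(nrow(sel))) {
        bounds <- switch(region,
          inside = c(sel$start[fi], sel$end[fi]),
          before = c(max(0L, sel$start[fi] - cfg$flank), sel$start[fi]),
          after = c(sel$end[fi], min(cfg$length_bp, sel$end[fi] + cfg$flank)))
        width <- bounds[2L] - bounds[1L]
        if (width <= 0L) next
        n_plant <- rpois(1L, cfg$base_rate * mult * width / 1000)
        for (k in seq_len(n_plant)) {
          for (try in 1:100) {
            a <- sample(cfg$arm_range[1L]:cfg$arm_range[2L], 1L)
            sp <- sample(cfg$spacer_range[1L]:cfg$spacer_range[2L], 1L)
            span <- 2L * a + sp
            if (span > width) next
            at <- bounds[1L] + sample(0:(width - span), 1L)
            if (at < 2L || at + span + 2L > cfg$length_bp) next
            mm <- if (runif(1) < cfg$mismatch_prob)
              sample(2:(a - 1L), 1L) else integer()
            res <- tryCatch(
              plant(rec, arm_len = a, spacer_len = sp,
                    mismatch_positions = mm, at = at, reserved = reserved,
                    verify = TRUE, params = params),
              error = function(e) NULL)
            if (is.null(res)) next
            rec <- res$record
            reserved <- rbind(reserved, res$reserved_span)
            row <- res$hit
            row$ftype <- ft
            row$region <- region
            truth[[length(truth) + 1L]] <- row
            break
          }
        }
      }
    }
    records[[gid]] <- rec
    feats[[gid]] <- fg
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome_id = character(), left_start = integer(),
               arm_len = integer(), spacer_len = integer(),
               mismatches = integer(), left_arm_seq = character(),
               ftype = character(), region = character(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  manifest <- stats::setNames(groups, names(records))
  out <- list(records = records, features = features, manifest = manifest,
              truth = truth, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(records, file.path(out_dir, "genomes.fasta"))
    write_feature_table(features, file.path(out_dir, "features.tbl"))
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    write.table(truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg_list <- unclass(cfg)
    cfg_list$feature_layout <- as.list(cfg$feature_layout)
    cfg_list$densities <- as.list(cfg$densities)
    yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
    out$paths <- file.path(out_dir, c("genomes.fasta", "features.tbl",
                                      "manifest.tsv", "ground_truth.tsv",
                                      "config.yaml"))
  }
  out
}
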