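# S-IR occurrence before / inside / after annotated features.
#
# For a feature [start, end) and flank f, the regions are
#   before = [start - f, start), inside = [start, end), after = [end, end + f),
# clipped to genome bounds.  A hit is counted in every region its outer
# span overlaps by at least 1 bp (boundary-spanning hits are multi-counted;
# this is the only convention that needs no tie-break).  Regions are
# genome-coordinate-based, not strand-aware.  Overlapping features of the
# same type each contribute their own regions.

REGIONS <- c("before", "inside", "after")

feature_regions <- function(start, end, genome_length, flank) {
  data.frame(region = REGIONS,
             start = c(max(0L, start - flank), start, end),
             end = c(start, end, min(genome_length, end + flank)),
             stringsAsFactors = FALSE)
}

#' Classify a hit relative to one feature
#'
#' @param hit one hit (single row of a [find_irs()] data.frame, or a list
#'   with `left_start`, `arm_len`, `spacer_len`).
#' @param feature one feature (single row of a [read_feature_table()]
#'   data.frame, or a list with `start`, `end`).
#' @param genome_length genome length (bp) for clipping flanks.
#' @param flank neighborhood width in bp (default 100).
#' @return character vector: the subset of `c("before","inside","after")`
#'   whose (clipped) region the hit's outer span overlaps by >= 1 bp.
#' @export
classify_hit <- function(hit, feature, genome_length, flank = 100L) {
  h0 <- hit$left_start
  h1 <- h0 + 2L * hit$arm_len + hit$spacer_len
  reg <- feature_regions(feature$start, feature$end, genome_length, flank)
  hitreg <- reg$region[pmax(h0, reg$start) < pmin(h1, reg$end)]
  as.character(hitreg)
}

#' Count S-IRs before/inside/after features, by type and length class
#'
#' For every (feature type, region, length class) the number of
#' (hit, feature) classification events is counted; `region_bp` is the sum
#' of clipped region widths over all features of that type (overlapping
#' features double-count), and `freq_per_kbp = 1000 * ir_count / region_bp`.
#' Length classes are cumulative: all, arm >= 8, >= 10, >= 12.
#'
#' @param hits hit data.frame (possibly multiple genomes).
#' @param features feature data.frame (see [read_feature_table()]).
#' @param genome_lengths named vector: genome id -> length (bp).
#' @param flank neighborhood width in bp (default 100).
#' @return data.frame with columns `ftype`, `region`, `length_class`,
#'   `ir_count`, `region_bp`, `freq_per_kbp`.
#' @export
context_counts <- function(hits, features, genome_lengths, flank = 100L) {
  stopifnot(!is.null(names(genome_lengths)))
  if (!nrow(features)) {
    return(data.frame(ftype = character(), region = character(),
                      length_class = character(), ir_count = integer(),
                      region_bp = numeric(), freq_per_kbp = numeric(),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(features$genome_id, names(genome_lengths))
  if (length(missing))
    stop("no genome length for '", missing[1L], "'", call. = FALSE)

  glen <- genome_lengths[features$genome_id]
  reg <- data.frame(
    genome_id = rep(features$genome_id, times = 3L),
    ftype = rep(features$ftype, times = 3L),
    region = rep(REGIONS, each = nrow(features)),
    start = c(pmax(0L, features$start - flank), features$start, features$end),
    end = c(features$start, features$end, pmin(glen, features$end + flank)),
    stringsAsFactors = FALSE)
  reg <- reg[reg$end > reg$start, ]

  ftypes <- sort(unique(features$ftype))
  grid <- expand.grid(ftype = ftypes, region = REGIONS,
                      length_class = AGG_CLASSES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bp <- tapply(reg$end - reg$start, list(reg$ftype, reg$region), sum)
  grid$region_bp <- vapply(seq_len(nrow(grid)), function(i) {
    v <- bp[grid$ftype[i], grid$region[i]]
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))

  grid$ir_count <- 0L
  if (nrow(hits)) {
    events <- lapply(unique(reg$genome_id), function(gid) {
      rg <- reg[reg$genome_id == gid, ]
      hg <- hits[hits$genome_id == gid, ]
      if (!nrow(hg)) return(NULL)
      hr <- IRanges::IRanges(start = hg$left_start + 1L,
                             width = 2L * hg$arm_len + hg$spacer_len)
      rr <- IRanges::IRanges(start = rg$start + 1L, end = rg$end)
      ov <- IRanges::findOverlaps(hr, rr, minoverlap = 1L)
      if (!length(ov)) return(NULL)
      data.frame(ftype = rg$ftype[S4Vectors::subjectHits(ov)],
                 region = rg$region[S4Vectors::subjectHits(ov)],
                 arm_len = hg$arm_len[S4Vectors::queryHits(ov)],
                 stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, Filter(Negate(is.null), events))
    if (!is.null(events) && nrow(events)) {
      for (i in seq_len(nrow(grid))) {
        sel <- events$ftype == grid$ftype[i] &
          events$region == grid$region[i] &
          events$arm_len >= AGG_MIN_ARM[[grid$length_class[i]]]
        grid$ir_count[i] <- sum(sel)
      }
    }
  }
  grid$freq_per_kbp <- ifelse(grid$region_bp > 0,
                              1000 * grid$ir_count / grid$region_bp, NA_real_)
  grid[order(grid$ftype, match(grid$region, REGIONS),
             match(grid$length_class, AGG_CLASSES)),
       c("ftype", "region", "length_class", "ir_count", "region_bp",
         "freq_per_kbp")] -> out
  rownames(out) <- NULL
  out
}

#' Enrichment of S-IR frequency relative to the gene-interior baseline
#'
#' For every (feature type, region, length class) the ratio of its
#' frequency to the frequency of the same length class inside `gene`
#' features.  Classes whose baseline is zero or absent yield `NA` ratios
#' (flagged with a warning), never a number.
#'
#' @param context data.frame from [context_counts()].
#' @param baseline_ftype,baseline_region baseline cell (default
#'   gene/inside).
#' @return `context` with an additional `enrichment` column.
#' @export
enrichment <- function(context, baseline_ftype = "gene",
                       baseline_region = "inside") {
  base <- context[context$ftype == baseline_ftype &
                    context$region == baseline_region, ]
  ratios <- rep(NA_real_, nrow(context))
  undefined <- character()
  for (cls in unique(context$length_class)) {
    b <- base$freq_per_kbp[base$length_class == cls]
    sel <- context$length_class == cls
    if (length(b) == 1L && !is.na(b) && b > 0) {
      ratios[sel] <- context$freq_per_kbp[sel] / b
    } else {
      undefined <- c(undefined, cls)
    }
  }
  if (length(undefined))
    warning("undefined enrichment baseline (", baseline_ftype, "/",
            baseline_region, ") for length class(es): ",
            paste(undefined, collapse = ", "), call. = FALSE)
  context$enrichment <- ratios
  context
}

#' Write a feature-context report as TSV
#'
#' @param context data.frame from [context_counts()] or [enrichment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_context_tsv <- function(context, path) {
  write.table(context, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
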