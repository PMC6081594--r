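# Per-genome and per-group S-IR frequency statistics: length-resolved
# counts, per-kbp frequencies, 8+/10+/12+ aggregates, and group summaries
# (median genome size, mean frequency, "longest S-IR for 50% of genomes").

AGG_CLASSES <- c("all", "8+", "10+", "12+")
AGG_MIN_ARM <- c(all = 0L, `8+` = 8L, `10+` = 10L, `12+` = 12L)

#' Length-resolved S-IR profile of a genome (or pooled group)
#'
#' @param hits hit data.frame from [find_irs()]; all hits must belong to
#'   `record`.
#' @param record the scanned [genome_record()].
#' @param params the [ir_params()] used for the scan (sets the count bins).
#' @return object of class `length_profile`: list with `owner`, `counts`
#'   (named vector over arm lengths `min_arm..max_arm`), `total`, `seq_bp`,
#'   `freq_per_kbp`, `agg_counts` (all/8+/10+/12+), `agg_freq_per_kbp`,
#'   `over30`, `max_arm_len` (0 when there are no hits) and `n_genomes`.
#' @export
profile_genome <- function(hits, record, params = ir_params()) {
  stopifnot(inherits(record, "genome_record"))
  if (record$length == 0L) stop("genome has zero length", call. = FALSE)
  if (nrow(hits) && !all(hits$genome_id == record$id))
    stop("hits do not all belong to genome '", record$id, "'", call. = FALSE)
  new_length_profile(owner = record$id, arm_lens = hits$arm_len,
                     seq_bp = record$length, params = params, n_genomes = 1L)
}

new_length_profile <- function(owner, arm_lens, seq_bp, params, n_genomes) {
  bins <- params$min_arm:params$max_arm
  counts <- table(factor(arm_lens, levels = bins))
  counts <- stats::setNames(as.integer(counts), as.character(bins))
  total <- sum(counts)
  agg <- vapply(AGG_MIN_ARM, function(m) sum(counts[bins >= m]), integer(1))
  structure(list(owner = owner,
                 counts = counts,
                 total = total,
                 seq_bp = seq_bp,
                 freq_per_kbp = 1000 * counts / seq_bp,
                 agg_counts = agg,
                 agg_freq_per_kbp = 1000 * agg / seq_bp,
                 over30 = sum(counts[bins > 30L]),
                 max_arm_len = if (length(arm_lens)) max(arm_lens) else 0L,
                 n_genomes = n_genomes,
                 bins = bins),
            class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("<length_profile> %s: %d S-IRs over %d bp (%.2f /kbp)\n",
              x$owner, x$total, x$seq_bp, 1000 * x$total / x$seq_bp))
  invisible(x)
}

#' Pool per-genome profiles into a group profile and summary
#'
#' The group profile pools counts and bp over the member genomes.  The
#' summary reports, per group: number of genomes, median genome size,
#' identity and size of the shortest and longest genome, the unweighted
#' mean of per-genome S-IR/kbp frequencies (the pooled-count frequency is
#' emitted separately), the per-genome frequency range, and
#' `longest_for_half`: the largest arm length L such that at least 50% of
#' the group's genomes contain a hit with arm length >= L (0 if fewer than
#' half the genomes have any hit).
#'
#' @param profiles list of per-genome `length_profile` objects.
#' @param records list of the corresponding [genome_record()]s.
#' @param group group label.
#' @return list with elements `profile` (pooled `length_profile`) and
#'   `summary` (a one-row data.frame).
#' @export
aggregate_group <- function(profiles, records, group) {
  if (!length(profiles)) stop("empty group '", group, "'", call. = FALSE)
  stopifnot(length(profiles) == length(records))
  counts <- Reduce(`+`, lapply(profiles, `[[`, "counts"))
  seq_bp <- sum(vapply(profiles, `[[`, numeric(1), "seq_bp"))
  bins <- profiles[[1L]]$bins
  pooled <- new_length_profile(
    owner = group,
    arm_lens = rep(as.integer(names(counts)), counts),
    seq_bp = seq_bp,
    params = ir_params(min_arm = min(bins), max_arm = max(bins)),
    n_genomes = length(profiles))
  per_freq <- vapply(profiles, function(p) 1000 * p$total / p$seq_bp,
                     numeric(1))
  sizes <- vapply(records, `[[`, numeric(1), "length")
  ids <- vapply(records, `[[`, "", "id")
  maxima <- vapply(profiles, `[[`, numeric(1), "max_arm_len")
  summary <- data.frame(
    group = group,
    n_seq = length(profiles),
    median_size = stats::median(sizes),
    min_seq_id = ids[which.min(sizes)],
    min_seq_bp = min(sizes),
    max_seq_id = ids[which.max(sizes)],
    max_seq_bp = max(sizes),
    mean_freq = mean(per_freq),
    pooled_freq = 1000 * pooled$total / seq_bp,
    freq_min = min(per_freq),
    freq_max = max(per_freq),
    longest_for_half = longest_for_half(maxima),
    stringsAsFactors = FALSE)
  list(profile = pooled, summary = summary)
}

# Largest L with #\{genomes whose max arm >= L\} >= n/2; genomes without
# hits have maximum 0, so the statistic is 0 when more than half the group
# is hit-free.
longest_for_half <- function(maxima) {
  n <- length(maxima)
  cand <- sort(unique(maxima), decreasing = TRUE)
  for (L in cand) {
    if (sum(maxima >= L) >= n / 2) return(L)
  }
  0L
}

#' Dataset-wide length table
#'
#' Rows for arm lengths 6..30 individually and a pooled `>30` row, with
#' dataset-wide counts and per-kbp frequencies over the pooled bp of all
#' profiles.
#'
#' @param profiles list of `length_profile` objects (per genome or group).
#' @return data.frame with columns `ir_size`, `amount`, `freq_per_kbp`.
#' @export
table1_report <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  counts <- Reduce(`+`, lapply(profiles, `[[`, "counts"))
  seq_bp <- sum(vapply(profiles, `[[`, numeric(1), "seq_bp"))
  bins <- as.integer(names(counts))
  shown <- 6:30
  amount <- vapply(shown, function(L) {
    if (L %in% bins) counts[[as.character(L)]] else 0L
  }, integer(1))
  over30 <- sum(counts[bins > 30L])
  data.frame(ir_size = c(as.character(shown), ">30"),
             amount = c(amount, over30),
             freq_per_kbp = 1000 * c(amount, over30) / seq_bp,
             stringsAsFactors = FALSE)
}

#' Write per-profile length statistics as TSV
#'
#' One row per (owner, arm length) plus aggregate-class rows.
#'
#' @param profiles list of `length_profile` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    rbind(data.frame(owner = p$owner, bin = names(p$counts),
                     count = as.integer(p$counts),
                     freq_per_kbp = as.numeric(p$freq_per_kbp),
                     stringsAsFactors = FALSE),
          data.frame(owner = p$owner, bin = names(p$agg_counts),
                     count = as.integer(p$agg_counts),
                     freq_per_kbp = as.numeric(p$agg_freq_per_kbp),
                     stringsAsFactors = FALSE))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
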