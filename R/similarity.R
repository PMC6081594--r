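# Ranking of abundant S-IR arm sequences and grouping by Levenshtein
# distance.  "Present N times" tallies hit occurrences pooled over all
# genomes, not the number of genomes containing the arm.  Comparisons are
# restricted to arms of the same length (ranking is within a length
# class); insertions and deletions remain allowed inside the metric.

#' Levenshtein distance between two strings
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`.
#'
#' @param a,b character scalars (or vectors, recycled elementwise).
#' @return integer distance(s).
#' @export
levenshtein <- function(a, b) {
  as.integer(mapply(function(x, y) adist(x, y)[1L, 1L], a, b,
                    USE.NAMES = FALSE))
}

#' Rank arm sequences of a given length by abundance
#'
#' Counts identical left-arm sequences among hits with the given arm
#' length, pooled over genomes; sorted by decreasing count, ties broken
#' lexicographically.
#'
#' @param hits pooled hit data.frame from [find_irs()].
#' @param arm_len arm length class (bp).
#' @param top_k number of top sequences to return.
#' @return data.frame with columns `rank`, `sequence`, `count` (empty when
#'   there are no hits of that length or `top_k` is 0).
#' @export
rank_arms <- function(hits, arm_len, top_k = 10L) {
  sel <- hits$left_arm_seq[hits$arm_len == arm_len]
  empty <- data.frame(rank = integer(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (!length(sel) || top_k <= 0L) return(empty)
  tab <- table(sel)
  o <- order(-as.integer(tab), names(tab))
  n <- min(top_k, length(tab))
  data.frame(rank = seq_len(n),
             sequence = names(tab)[o][seq_len(n)],
             count = as.integer(tab)[o][seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Group arms around a seed sequence by Levenshtein distance
#'
#' Collects all hits of the given arm length whose left-arm sequence lies
#' within `max_dist` of `seed_seq` (identical sequences included).
#'
#' @param hits pooled hit data.frame.
#' @param arm_len arm length class (bp); must equal `nchar(seed_seq)`.
#' @param seed_seq representative arm sequence.
#' @param max_dist inclusion radius (default 2).
#' @return object of class `similarity_group`: list with `representative`,
#'   `exact_count`, `near_count`, `max_dist` and `members` (data.frame of
#'   member sequences with their distances and counts).
#' @export
near_group <- function(hits, arm_len, seed_seq, max_dist = 2L) {
  stopifnot(nchar(seed_seq) == arm_len)
  sel <- hits$left_arm_seq[hits$arm_len == arm_len]
  members <- data.frame(sequence = character(), distance = integer(),
                        count = integer(), stringsAsFactors = FALSE)
  if (length(sel)) {
    tab <- table(sel)
    d <- as.integer(adist(seed_seq, names(tab)))
    keep <- d <= max_dist
    members <- data.frame(sequence = names(tab)[keep],
                          distance = d[keep],
                          count = as.integer(tab)[keep],
                          stringsAsFactors = FALSE)
    members <- members[order(members$distance, -members$count,
                             members$sequence), ]
    rownames(members) <- NULL
  }
  structure(list(representative = seed_seq,
                 exact_count = sum(members$count[members$distance == 0L]),
                 near_count = sum(members$count),
                 max_dist = as.integer(max_dist),
                 members = members),
            class = "similarity_group")
}

#' @export
print.similarity_group <- function(x, ...) {
  cat(sprintf("<similarity_group> %s: %d exact, %d within distance %d (%d distinct sequences)\n",
              x$representative, x$exact_count, x$near_count, x$max_dist,
              nrow(x$members)))
  invisible(x)
}

#' Write an abundance/similarity report as TSV
#'
#' For each requested arm length: the `top_k` most abundant arm sequences
#' with their exact counts and their neighborhood counts at Levenshtein
#' distance `max_dist`.
#'
#' @param hits pooled hit data.frame.
#' @param arm_lens arm lengths to report.
#' @param path output file.
#' @param top_k sequences per length.
#' @param max_dist Levenshtein inclusion radius.
#' @return the report data.frame, invisibly.
#' @export
write_similarity_tsv <- function(hits, arm_lens, path, top_k = 5L,
                                 max_dist = 2L) {
  rows <- lapply(arm_lens, function(L) {
    rk <- rank_arms(hits, L, top_k)
    if (!nrow(rk)) return(NULL)
    near <- vapply(rk$sequence, function(s)
      near_group(hits, L, s, max_dist)$near_count, integer(1))
    data.frame(arm_len = L, rank = rk$rank, sequence = rk$sequence,
               exact_count = rk$count, near_count = near,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(report))
    report <- data.frame(arm_len = integer(), rank = integer(),
                         sequence = character(), exact_count = integer(),
                         near_count = integer(), stringsAsFactors = FALSE)
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
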