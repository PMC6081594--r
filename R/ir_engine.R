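# Detection of short inverted repeats (S-IRs).
#
# An S-IR is a left arm, a spacer of 0-10 bp, and a right arm that is the
# reverse complement of the left arm up to a mismatch budget.  "S-IR
# length" always means ARM length.  The terminal pairs of the arms (the
# outermost pair and the pair adjacent to the spacer) must be exact
# Watson-Crick matches; the allowed mismatch is internal.  Without the
# terminal rule every perfect arm-k repeat would trivially extend to k+1
# under a nonzero budget and reported lengths would be ill-defined.

#' S-IR scan parameters
#'
#' Defaults follow the standard cruciform-competent scan: arms 6-60 bp,
#' spacer 0-10 bp, at most one (internal) mismatch.
#'
#' @param min_arm,max_arm arm length bounds (bp).
#' @param max_spacer maximum spacer (loop) length (bp).
#' @param max_mismatch maximum number of internal arm mismatches.
#' @return list of class `ir_params`.
#' @export
ir_params <- function(min_arm = 6L, max_arm = 60L, max_spacer = 10L,
                      max_mismatch = 1L) {
  min_arm <- as.integer(min_arm); max_arm <- as.integer(max_arm)
  max_spacer <- as.integer(max_spacer); max_mismatch <- as.integer(max_mismatch)
  stopifnot(min_arm > 0L, min_arm <= max_arm, max_spacer >= 0L,
            max_mismatch >= 0L)
  structure(list(min_arm = min_arm, max_arm = max_arm,
                 max_spacer = max_spacer, max_mismatch = max_mismatch),
            class = "ir_params")
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A,C,G,T,N (N maps to N).
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
}

#' Count mismatched arm pairings of a putative inverted repeat
#'
#' Pairs position `left_start + i` (0-based) with position
#' `left_start + 2*arm_len + spacer_len - 1 - i` for `i` in `0..arm_len-1`
#' and counts the non-Watson-Crick pairs.  Any pairing that involves N
#' counts as a mismatch.
#'
#' @param seq DNA string.
#' @param left_start 0-based start of the left arm.
#' @param arm_len arm length (bp).
#' @param spacer_len spacer length (bp).
#' @return integer mismatch count.
#' @export
arm_mismatches <- function(seq, left_start, arm_len, spacer_len) {
  n <- nchar(seq)
  span <- 2L * arm_len + spacer_len
  if (left_start < 0L || left_start + span > n)
    stop("inverted-repeat span out of sequence bounds", call. = FALSE)
  code <- encode_dna(substr(seq, left_start + 1L, left_start + span))
  left <- code[seq_len(arm_len)]
  right <- code[span - seq_len(arm_len) + 1L]  # outer-to-inner, mirrored
  comp <- COMP_CODE[left]
  sum(is.na(comp) | comp != right)
}

# Shared post-processing: keep, among candidate hits sharing an identical
# outer span, only the one with the largest arm (ties: fewer mismatches,
# then smaller spacer); sort by (left_start, spacer_len).
dedup_hits <- function(cand, genome_id, seq) {
  if (!nrow(cand)) {
    return(data.frame(genome_id = character(), left_start = integer(),
                      arm_len = integer(), spacer_len = integer(),
                      mismatches = integer(), left_arm_seq = character(),
                      stringsAsFactors = FALSE))
  }
  span_end <- cand$left_start + 2L * cand$arm_len + cand$spacer_len
  o <- order(cand$left_start, span_end, -cand$arm_len, cand$mismatches,
             cand$spacer_len)
  cand <- cand[o, ]
  span_end <- span_end[o]
  keep <- !duplicated(paste(cand$left_start, span_end))
  cand <- cand[keep, ]
  cand <- cand[order(cand$left_start, cand$spacer_len), ]
  data.frame(genome_id = genome_id,
             left_start = cand$left_start,
             arm_len = cand$arm_len,
             spacer_len = cand$spacer_len,
             mismatches = cand$mismatches,
             left_arm_seq = substring(seq, cand$left_start + 1L,
                                      cand$left_start + cand$arm_len),
             stringsAsFactors = FALSE)
}

#' Detect all maximal short inverted repeats in a genome
#'
#' Candidates are generated per center (gap position and spacer length 0 to
#' `max_spacer`); arms are extended outward as far as the mismatch budget
#' and the terminal-match rule allow, capped at `max_arm`.  Candidate hits
#' sharing an identical outer span are reduced to the one with the largest
#' arm.  Each physical repeat is reported once (the structure is
#' strand-symmetric), sorted by `(left_start, spacer_len)`.
#'
#' @param record a [genome_record()] (or plain DNA string).
#' @param params an [ir_params()] object.
#' @return data.frame of hits with columns `genome_id`, `left_start`
#'   (0-based), `arm_len`, `spacer_len`, `mismatches`, `left_arm_seq`.
#' @export
find_irs <- function(record, params = ir_params()) {
  if (is.character(record)) record <- genome_record("seq", record, warn = FALSE)
  stopifnot(inherits(record, "genome_record"), inherits(params, "ir_params"))
  cand <- cpp_scan_candidates(record$seq, params$min_arm, params$max_arm,
                              params$max_spacer, params$max_mismatch)
  dedup_hits(cand, record$id, record$seq)
}

#' Exhaustive inverted-repeat oracle
#'
#' Enumerates every `(left_start, arm_len, spacer_len)` triple, filters by
#' the terminal-match rule and the interior mismatch budget, reduces each
#' center to its largest valid arm and deduplicates identical outer spans
#' with the same rules as [find_irs()].  Intended for sequences up to a few
#' kbp; used to verify the scanning implementation.
#'
#' @inheritParams find_irs
#' @return data.frame with the same columns as [find_irs()].
#' @export
brute_force_irs <- function(record, params = ir_params()) {
  if (is.character(record)) record <- genome_record("seq", record, warn = FALSE)
  stopifnot(inherits(record, "genome_record"), inherits(params, "ir_params"))
  n <- record$length
  if (n == 0L) return(dedup_hits(data.frame(), record$id, record$seq))
  code <- encode_dna(record$seq)
  pairs_ok <- function(x, y) {
    comp <- COMP_CODE[x]
    !is.na(comp) & comp == y
  }
  rows <- list()
  for (sp in 0:params$max_spacer) {
    for (a in params$min_arm:params$max_arm) {
      span <- 2L * a + sp
      if (span > n) break
      s <- seq_len(n - span + 1L)          # 1-based left-arm starts
      # terminal pairs: outermost (s, s+span-1), innermost (s+a-1, s+a+sp)
      ok <- pairs_ok(code[s], code[s + span - 1L]) &
            pairs_ok(code[s + a - 1L], code[s + a + sp])
      s <- s[ok]
      if (!length(s)) next
      if (a > 2L) {
        j <- seq_len(a - 2L)               # interior pair offsets
        P <- outer(s, j, `+`)
        Q <- outer(s + span - 1L, j, `-`)
        mm <- rowSums(matrix(!pairs_ok(code[P], code[Q]), nrow = length(s)))
      } else mm <- rep(0L, length(s))
      valid <- mm <= params$max_mismatch
      if (!any(valid)) next
      rows[[length(rows) + 1L]] <-
        data.frame(left_start = s[valid] - 1L, arm_len = a, spacer_len = sp,
                   mismatches = as.integer(mm[valid]))
    }
  }
  if (!length(rows)) return(dedup_hits(data.frame(), record$id, record$seq))
  cand <- do.call(rbind, rows)
  # per center (gap position, spacer) keep the largest valid arm
  center <- paste(cand$left_start + cand$arm_len, cand$spacer_len)
  o <- order(center, -cand$arm_len)
  cand <- cand[o, ]
  cand <- cand[!duplicated(center[o]), ]
  dedup_hits(cand, record$id, record$seq)
}

#' Write hits as TSV
#'
#' @param hits hit data.frame from [find_irs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hits as BED6
#'
#' The interval is the outer span (0-based half-open, BED-native); `name`
#' is `arm:spacer:mismatch`, `score` is the arm length, `strand` is `.`
#' (an inverted repeat is strand-symmetric).
#'
#' @inheritParams write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$genome_id,
                    start = hits$left_start,
                    end = hits$left_start + 2L * hits$arm_len + hits$spacer_len,
                    name = paste(hits$arm_len, hits$spacer_len,
                                 hits$mismatches, sep = ":"),
                    score = hits$arm_len,
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
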