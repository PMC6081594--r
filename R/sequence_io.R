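# Reading and writing sequences, annotations, and group manifests.
# Internal coordinates are 0-based half-open everywhere; both annotation
# dialects (NCBI feature table and GFF3, each 1-based inclusive) are
# converted at the boundary.

#' Construct a genome record
#'
#' A genome record holds one normalized DNA sequence together with its
#' identifier and an optional taxonomic group label.  Residues are
#' uppercased and restricted to the alphabet A, C, G, T, N.
#'
#' @param id character identifier.
#' @param seq DNA string; normalized via [normalize_seq()].
#' @param group optional group label (e.g. "Rosids").
#' @param warn warn when residues outside A,C,G,T,N are replaced by N.
#' @return an object of class `genome_record`: a list with elements
#'   `id`, `seq`, `length` (bp) and `group`.
#' @export
genome_record <- function(id, seq, group = NA_character_, warn = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- normalize_seq(seq, warn = warn)
  structure(list(id = id, seq = seq, length = nchar(seq), group = group),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp%s\n", x$id, x$length,
              if (!is.na(x$group)) paste0(" [", x$group, "]") else ""))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased; characters outside A,C,G,T,N are mapped to N
#' with a warning.  Zero-length records and empty files are format errors.
#'
#' @param path FASTA file.
#' @return list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  zero <- which(nchar(seqs) == 0L)
  if (length(zero))
    stop("FASTA record '", ids[zero[1L]], "' has a zero-length sequence",
         call. = FALSE)
  mapply(genome_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write genome records to FASTA
#'
#' @param records list of [genome_record()] objects.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read genome annotations (NCBI 5-column feature table or GFF3)
#'
#' The format is auto-detected from content: a `>Feature` header selects the
#' NCBI feature-table dialect, a `##gff` pragma or 9-column tab layout
#' selects GFF3.  Both dialects use 1-based inclusive coordinates and are
#' converted to the package's 0-based half-open convention.  Feature-table
#' intervals with start > stop (and `complement(a..b)` locations) map to
#' strand "-"; multi-interval joins yield one feature per interval.
#' Unknown feature types are kept verbatim.
#'
#' @param path annotation file.
#' @param genome_id optional filter: return only features of this genome.
#' @param genome_lengths optional named vector of genome lengths (bp) used
#'   to validate that intervals stay within their genome.
#' @return data.frame with columns `genome_id`, `ftype`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), `strand` (`+`, `-` or `*`).
#' @export
read_feature_table <- function(path, genome_id = NULL, genome_lengths = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  content <- lines[nzchar(trimws(lines))]
  if (length(content) == 0L)
    stop("annotation file '", path, "' is empty", call. = FALSE)
  is_tbl <- any(startsWith(content, ">Feature"))
  is_gff <- any(startsWith(content, "##gff")) ||
    all(lengths(strsplit(grep("^[^#]", content, value = TRUE), "\t")) >= 8L)
  feats <- if (is_tbl) parse_ncbi_tbl(lines)
           else if (is_gff) parse_gff3(path)
           else stop("cannot detect annotation format of '", path,
                     "' (expected NCBI feature table or GFF3)", call. = FALSE)
  if (!is.null(genome_id)) feats <- feats[feats$genome_id %in% genome_id, ]
  validate_features(feats, genome_lengths)
  rownames(feats) <- NULL
  feats
}

parse_ncbi_tbl <- function(lines) {
  gid <- NA_character_
  out <- list()
  pend_start <- integer()  # pending 1-based inclusive interval starts
  pend_end <- integer()
  pend_minus <- logical()
  ftype <- NA_character_
  flush <- function() {
    if (!length(pend_start)) return(NULL)
    data.frame(genome_id = gid, ftype = ftype,
               start = pend_start - 1L, end = pend_end,
               strand = ifelse(pend_minus, "-", "+"),
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (startsWith(ln, ">Feature")) {
      out[[length(out) + 1L]] <- flush()
      pend_start <- integer(); pend_end <- integer(); pend_minus <- logical()
      gid <- trimws(sub("^>Feature\\s+", "", ln))
      next
    }
    if (!nzchar(trimws(ln))) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    loc <- parse_tbl_interval(fields)
    if (is.null(loc)) next  # qualifier line
    if (length(fields) >= 3L && nzchar(fields[3L])) {
      # new feature block: flush the previous one
      out[[length(out) + 1L]] <- flush()
      pend_start <- integer(); pend_end <- integer(); pend_minus <- logical()
      ftype <- fields[3L]
    }
    pend_start <- c(pend_start, loc$start)
    pend_end <- c(pend_end, loc$end)
    pend_minus <- c(pend_minus, loc$minus)
  }
  out[[length(out) + 1L]] <- flush()
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    stop("no features found in NCBI feature table", call. = FALSE)
  do.call(rbind, out)
}

# One feature-table line -> list(start, end [1-based inclusive], minus) or
# NULL for qualifier lines.  Accepts reversed coordinates and the
# complement(a..b) location style for minus-strand intervals; strips the
# partial-end markers '<' and '>'.
parse_tbl_interval <- function(fields) {
  if (length(fields) < 1L) return(NULL)
  comp <- regmatches(fields[1L],
                     regexec("^complement\\((\\d+)\\.\\.(\\d+)\\)$",
                             gsub("[<>]", "", fields[1L])))[[1]]
  if (length(comp) == 3L) {
    a <- as.integer(comp[2L]); b <- as.integer(comp[3L])
    return(list(start = min(a, b), end = max(a, b), minus = TRUE))
  }
  if (length(fields) < 2L) return(NULL)
  a <- suppressWarnings(as.integer(gsub("[<>]", "", fields[1L])))
  b <- suppressWarnings(as.integer(gsub("[<>]", "", fields[2L])))
  if (is.na(a) || is.na(b)) return(NULL)
  list(start = min(a, b), end = max(a, b), minus = a > b)
}

parse_gff3 <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  if (nrow(gff) == 0L) stop("no features found in GFF3 file", call. = FALSE)
  strand <- as.character(gff$strand)
  strand[!strand %in% c("+", "-")] <- "*"
  data.frame(genome_id = as.character(gff$seqid),
             ftype = as.character(gff$type),
             start = as.integer(gff$start) - 1L,
             end = as.integer(gff$end),
             strand = strand,
             stringsAsFactors = FALSE)
}

validate_features <- function(feats, genome_lengths = NULL) {
  if (!nrow(feats)) return(invisible(feats))
  if (any(!nzchar(feats$ftype)))
    stop("feature with empty type", call. = FALSE)
  if (any(feats$start < 0L) || any(feats$start >= feats$end))
    stop("invalid feature interval (need 0 <= start < end)", call. = FALSE)
  if (!is.null(genome_lengths)) {
    len <- genome_lengths[feats$genome_id]
    over <- which(!is.na(len) & feats$end > len)
    if (length(over))
      stop("feature interval exceeds genome length for '",
           feats$genome_id[over[1L]], "'", call. = FALSE)
  }
  invisible(feats)
}

#' Write features as an NCBI 5-column feature table
#'
#' Inverse of the feature-table branch of [read_feature_table()]:
#' 0-based half-open intervals become 1-based inclusive, minus-strand
#' intervals are written with reversed coordinates.
#'
#' @param features feature data.frame (see [read_feature_table()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (gid in unique(features$genome_id)) {
    writeLines(paste0(">Feature ", gid), con)
    fg <- features[features$genome_id == gid, ]
    a <- fg$start + 1L
    b <- fg$end
    minus <- fg$strand == "-"
    writeLines(sprintf("%d\t%d\t%s",
                       ifelse(minus, b, a), ifelse(minus, a, b), fg$ftype),
               con)
  }
  invisible(path)
}

#' Read a genome-to-group manifest
#'
#' @param path TSV with columns `genome_id` and `group` (header required
#'   unless the file is empty).
#' @return named character vector mapping genome id to group label.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (!all(c("genome_id", "group") %in% names(tab))) {
    # tolerate a headerless two-column file
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (ncol(tab) < 2L)
      stop("manifest must have columns genome_id and group", call. = FALSE)
    names(tab)[1:2] <- c("genome_id", "group")
  }
  if (nrow(tab) == 0L) return(stats::setNames(character(), character()))
  if (anyDuplicated(tab$genome_id))
    stop("duplicate genome_id in manifest: ",
         tab$genome_id[duplicated(tab$genome_id)][1L], call. = FALSE)
  stats::setNames(tab$group, tab$genome_id)
}

#' Write a genome-to-group manifest
#'
#' @param manifest named character vector (names = genome ids).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(data.frame(genome_id = names(manifest),
                         group = unname(manifest)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert 0-based half-open intervals to 1-based inclusive (and back)
#'
#' Helpers for the package's single internal coordinate convention.
#'
#' @param start,end interval bounds.
#' @return two-column data.frame of converted bounds.
#' @export
to_one_based <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}
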