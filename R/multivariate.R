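# Multivariate analysis of length-frequency profiles: Ward.D2
# hierarchical clustering (Euclidean distances, heights on the distance
# scale) and PCA with a deterministic sign convention.

#' Build a profile matrix from length profiles
#'
#' Rows are profile owners (species or groups); columns are per-kbp
#' frequencies for arm lengths 6..30, a pooled `>30` bin, and the
#' 8+/10+/12+ cumulative classes.
#'
#' @param profiles list of `length_profile` objects.
#' @return numeric matrix with owner rownames and fixed column order
#'   (`L6`..`L30`, `gt30`, `agg8p`, `agg10p`, `agg12p`).
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  rows <- t(vapply(profiles, function(p) {
    bins <- p$bins
    shown <- 6:30
    per <- vapply(shown, function(L) {
      if (L %in% bins) 1000 * p$counts[[as.character(L)]] / p$seq_bp else 0
    }, numeric(1))
    gt30 <- 1000 * sum(p$counts[bins > 30L]) / p$seq_bp
    c(per, gt30, as.numeric(p$agg_freq_per_kbp[c("8+", "10+", "12+")]))
  }, numeric(29)))
  rownames(rows) <- vapply(profiles, `[[`, "", "owner")
  colnames(rows) <- c(paste0("L", 6:30), "gt30", "agg8p", "agg10p", "agg12p")
  rows
}

#' Ward.D2 hierarchical clustering of a profile matrix
#'
#' Agglomerative clustering with Euclidean distances and the Ward.D2
#' criterion (squared distances inside the Lance-Williams update, merge
#' heights reported on the unsquared distance scale).
#'
#' @param m numeric matrix (rows = profiles).
#' @return an [stats::hclust] object.
#' @export
ward_cluster <- function(m) {
  if (is.null(dim(m)) || nrow(m) < 2L)
    stop("need at least 2 rows to cluster", call. = FALSE)
  hclust(dist(m, method = "euclidean"), method = "ward.D2")
}

#' PCA of a profile matrix
#'
#' Columns are centered and unit-scaled by default; zero-variance columns
#' are excluded from scaling with a warning (they carry no signal either
#' way).  Loadings follow a deterministic sign convention: within each
#' component the largest-magnitude loading is positive.
#'
#' @param m numeric matrix (rows = observations).
#' @param center,scale. center / unit-scale columns (default both TRUE).
#' @return list with `scores`, `loadings`, `explained_variance` (per
#'   component), `explained_fraction` and `sdev`.
#' @export
pca <- function(m, center = TRUE, scale. = TRUE) {
  if (is.null(dim(m)) || nrow(m) < 2L || ncol(m) < 2L)
    stop("need a matrix with >= 2 rows and >= 2 columns", call. = FALSE)
  v <- apply(m, 2L, var)
  if (all(v == 0)) stop("all columns are constant", call. = FALSE)
  scale_arg <- scale.
  if (scale. && any(v == 0)) {
    warning("zero-variance column(s) not scaled: ",
            paste(colnames(m)[v == 0], collapse = ", "), call. = FALSE)
    scale_arg <- ifelse(v == 0, FALSE, TRUE)
    scale_arg <- sqrt(ifelse(v == 0, 1, v))  # manual unit scaling
  }
  p <- prcomp(m, center = center, scale. = scale_arg)
  # deterministic signs: largest-|loading| entry positive per component
  flip <- apply(p$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  ev <- p$sdev^2
  list(scores = scores, loadings = loadings,
       explained_variance = ev,
       explained_fraction = ev / sum(ev),
       sdev = p$sdev)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights (each merge height is
#' split evenly across the two child branches, as in the standard
#' hclust-to-phylo conversion).  A single label yields the trivial tree
#' `"label;"`.
#'
#' @param d an [stats::hclust] object, or a single leaf label.
#' @return Newick string.
#' @export
to_newick <- function(d) {
  if (is.character(d) && length(d) == 1L) return(paste0(d, ";"))
  stopifnot(inherits(d, "hclust"))
  ape::write.tree(ape::as.phylo(d))
}

#' Write PCA results as TSV files
#'
#' @param fit list from [pca()].
#' @param prefix output path prefix; writes `<prefix>_scores.tsv`,
#'   `<prefix>_loadings.tsv`, `<prefix>_variance.tsv`.
#' @return character vector of written paths, invisibly.
#' @export
write_pca_tsv <- function(fit, prefix) {
  paths <- paste0(prefix, c("_scores.tsv", "_loadings.tsv", "_variance.tsv"))
  write.table(data.frame(row = rownames(fit$scores), fit$scores,
                         check.names = FALSE),
              paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(variable = rownames(fit$loadings), fit$loadings,
                         check.names = FALSE),
              paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(component = seq_along(fit$explained_variance),
                         variance = fit$explained_variance,
                         fraction = fit$explained_fraction),
              paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
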