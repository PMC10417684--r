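#' Entropy weights for a set of feature sources
#'
#' Each backbone's activations are pooled over all samples into a mean
#' absolute-activation profile, normalized to a probability vector p
#' over its feature dimensions; the source's score is the Shannon
#' entropy H = -sum(p log p) normalized by log(dim) so that a uniform
#' profile scores 1 and a one-hot profile scores 0. Weights are the
#' scores normalized to sum to 1: sources whose activation mass spreads
#' over many dimensions (carrying more distributed information) weigh
#' more. The weights are invariant to any global positive rescaling of a
#' source's features.
#'
#' An all-zero feature matrix has no activation profile; it is assigned
#' the uniform score 1 with a warning.
#'
#' @param per_backbone Named list of numeric matrices (n_samples x
#'   feature_dim_b), equal row counts.
#' @return Named numeric vector of weights, non-negative, summing to 1.
#' @examples
#' entropy_weights(list(a = matrix(1, 2, 4), b = matrix(1, 2, 4)))
#' @export
entropy_weights <- function(per_backbone) {
  if (length(per_backbone) < 1L) abort("Need at least one feature matrix.")
  if (any(vapply(per_backbone, ncol, 0L) < 1L)) {
    abort("Every feature matrix needs at least one column.")
  }
  H <- vapply(per_backbone, function(m) {
    pooled <- colMeans(abs(m))
    if (sum(pooled) == 0) {
      warn("All-zero feature matrix; assigning the uniform entropy score 1.")
      return(1)
    }
    p <- pooled / sum(pooled)
    p <- p[p > 0]
    if (ncol(m) == 1L) return(1)       # a single dimension carries H = 0/0; treat as uniform
    -sum(p * log(p)) / log(ncol(m))
  }, numeric(1))
  if (sum(H) == 0) {
    # every source degenerate: fall back to uniform weights
    H <- rep(1, length(H))
  }
  w <- H / sum(H)
  names(w) <- names(per_backbone)
  w
}

#' Fuse per-backbone feature matrices
#'
#' Column-wise concatenation of each source scaled by its weight; with
#' all weights 1 this is plain concatenation.
#'
#' @param per_backbone Named list of matrices with equal row counts.
#' @param weights Numeric vector, one per source.
#' @return Matrix (n_samples x sum of feature dims).
#' @export
fuse_features <- function(per_backbone, weights) {
  if (length(weights) != length(per_backbone)) {
    abort("`weights` must have one entry per feature matrix.")
  }
  ns <- vapply(per_backbone, nrow, 0L)
  if (length(unique(ns)) != 1L) abort("All feature matrices must have the same number of rows.")
  scaled <- purrr::map2(per_backbone, weights, function(m, w) m * w)
  do.call(cbind, scaled)
}

#' Build a feature bundle: per-source matrices, entropy weights, fusion
#'
#' @param per_backbone Named list of feature matrices (n x dim_b).
#' @return A `feature_bundle` list: `per_backbone`, `weights`, `fused`.
#' @export
feature_bundle <- function(per_backbone) {
  if (is.null(names(per_backbone)) || any(names(per_backbone) == "")) {
    names(per_backbone) <- paste0("backbone", seq_along(per_backbone))
  }
  w <- entropy_weights(per_backbone)
  structure(
    list(per_backbone = per_backbone, weights = w,
         fused = fuse_features(per_backbone, w)),
    class = "feature_bundle"
  )
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("Feature bundle:", nrow(x$fused), "samples,",
      ncol(x$fused), "fused dimensions\n")
  for (nm in names(x$per_backbone)) {
    cat(sprintf("  %-28s dim %4d  entropy weight %.4f\n",
                nm, ncol(x$per_backbone[[nm]]), x$weights[[nm]]))
  }
  invisible(x)
}

#' Round-trip feature matrices through delimited text
#'
#' Writes the named list of per-source matrices as one tab-separated
#' file whose header names each column `<backbone>.<index>`;
#' [read_features()] reconstructs the list by splitting the header.
#'
#' @param per_backbone Named list of feature matrices.
#' @param path File path.
#' @return `path` invisibly; `read_features()` returns the named list.
#' @export
write_features <- function(per_backbone, path) {
  mats <- purrr::imap(per_backbone, function(m, nm) {
    colnames(m) <- paste(nm, seq_len(ncol(m)), sep = ".")
    m
  })
  combined <- do.call(cbind, unname(mats))
  utils::write.table(combined, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab)
  sources <- sub("\\.[0-9]+$", "", colnames(m))
  out <- lapply(unique(sources), function(s) {
    sub <- m[, sources == s, drop = FALSE]
    dimnames(sub) <- NULL
    sub
  })
  names(out) <- unique(sources)
  out
}
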