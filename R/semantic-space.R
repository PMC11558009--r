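# Semantic spaces: the geometry memories live in. Items are unit embedding
# vectors; pre-experimental association strength between two items is the
# cosine of their embeddings, which (after normalization) equals the dot
# product.

#' Construct a semantic space
#'
#' A semantic space holds an ordered set of item labels, their embedding
#' vectors (re-normalized to unit Euclidean length), and the full pairwise
#' cosine similarity matrix. Cosine similarity between items defines the
#' pre-experimental associations used by the retrieval model and the
#' semantic-clustering statistics.
#'
#' @param items Character vector of item labels (unique).
#' @param vectors Numeric matrix, one row per item; rows are re-normalized to
#'   unit length.
#' @return An object of class `semantic_space` with fields `items`, `vectors`
#'   (n x d, unit rows) and `similarity` (n x n cosine matrix, symmetric,
#'   unit diagonal).
#' @export
semantic_space <- function(items, vectors) {
  items <- as.character(items)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(items) != nrow(vectors)) {
    stop_arg("length(items) [%d] must equal nrow(vectors) [%d]",
             length(items), nrow(vectors))
  }
  if (anyDuplicated(items)) stop_arg("item labels must be unique")
  if (nrow(vectors) < 1L || ncol(vectors) < 1L) stop_arg("vectors must be non-empty")
  norms <- sqrt(rowSums(vectors^2))
  if (any(!is.finite(norms)) || any(norms < 1e-12)) {
    stop_arg("all embedding vectors must be finite with nonzero norm")
  }
  vectors <- vectors / norms
  sim <- tcrossprod(vectors)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  diag(sim) <- 1
  rownames(vectors) <- items
  dimnames(sim) <- list(items, items)
  structure(
    list(items = items, vectors = vectors, similarity = sim),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space> %d items, dimension %d\n",
              length(x$items), ncol(x$vectors)))
  invisible(x)
}

#' Number of items in a semantic space
#' @param space A `semantic_space`.
#' @return Integer item count.
#' @export
n_items <- function(space) {
  stopifnot(inherits(space, "semantic_space"))
  length(space$items)
}

#' Generate a synthetic clustered semantic space
#'
#' Draws `n_clusters` centroid directions uniformly on the unit sphere and
#' places each item at `normalize(centroid + cluster_spread * noise)` with
#' standard normal noise, so a single knob controls how semantically
#' clusterable the list is. Items are assigned to clusters round-robin.
#' With `n_clusters = n_items` every item gets its own centroid — an
#' "uncategorized" list with no planned semantic structure, mirroring a
#' 60-word uncategorized study list.
#'
#' @param n_items Number of items (>= 2).
#' @param dim Embedding dimension (>= 2).
#' @param n_clusters Number of cluster centroids, between 1 and `n_items`.
#'   Defaults to `n_items` (uncategorized).
#' @param cluster_spread Nonnegative noise scale around the centroid; small
#'   values give tight clusters.
#' @param seed Integer seed; the space is deterministic given the seed.
#' @param items Optional character labels; defaults to `w001, w002, ...`.
#' @return A `semantic_space` with an extra `clusters` field (integer cluster
#'   id per item).
#' @export
generate_synthetic_space <- function(n_items, dim, n_clusters = n_items,
                                     cluster_spread = 0.25, seed = NULL,
                                     items = NULL) {
  n_items <- check_count(n_items, "n_items", min = 2L)
  dim <- check_count(dim, "dim", min = 2L)
  n_clusters <- check_count(n_clusters, "n_clusters", min = 1L)
  if (n_clusters > n_items) stop_arg("`n_clusters` must be <= `n_items`")
  if (!is.numeric(cluster_spread) || length(cluster_spread) != 1L ||
      is.na(cluster_spread) || cluster_spread < 0) {
    stop_arg("`cluster_spread` must be a single nonnegative number")
  }
  if (is.null(items)) items <- sprintf("w%03d", seq_len(n_items))
  assignment <- rep_len(seq_len(n_clusters), n_items)
  vectors <- with_seed(seed, {
    centroids <- matrix(stats::rnorm(n_clusters * dim), n_clusters, dim)
    centroids <- centroids / sqrt(rowSums(centroids^2))
    v <- centroids[assignment, , drop = FALSE] +
      cluster_spread * matrix(stats::rnorm(n_items * dim), n_items, dim)
    v
  })
  out <- semantic_space(items, vectors)
  out$clusters <- assignment
  out
}

#' Cosine similarity between two items
#'
#' @param space A `semantic_space`.
#' @param i,j Item indices (1-based).
#' @return The cosine of the two item embeddings, in \[-1, 1\].
#' @export
cosine <- function(space, i, j) {
  stopifnot(inherits(space, "semantic_space"))
  n <- n_items(space)
  i <- check_count(i, "i"); j <- check_count(j, "j")
  if (i > n || j > n) stop_arg("item index out of range (n = %d)", n)
  space$similarity[i, j]
}

#' Load embeddings in word2vec text format, restricted to a word list
#'
#' The file must start with a header line `"n d"` followed by `n` lines
#' `"word v1 ... vd"`. The returned space contains exactly the words in
#' `wordlist`, in `wordlist` order, with vectors re-normalized to unit
#' length (so cosine equals dot product).
#'
#' @param path Path to a word2vec text file.
#' @param wordlist Character vector of words to keep, in the desired order.
#' @return A `semantic_space`.
#' @export
load_embeddings <- function(path, wordlist) {
  if (!file.exists(path)) stop_arg("embedding file not found: %s", path)
  wordlist <- as.character(wordlist)
  if (length(wordlist) < 1L) stop_arg("`wordlist` must be non-empty")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop_arg("embedding file is empty: %s", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop_arg("line 1: malformed word2vec header (expected \"n d\")")
  }
  n <- as.integer(header[[1L]]); d <- as.integer(header[[2L]])
  if (length(lines) - 1L < n) {
    stop_arg("embedding file declares %d rows but has %d", n, length(lines) - 1L)
  }
  vecs <- new.env(parent = emptyenv())
  want <- unique(wordlist)
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(lines[[k + 1L]]), "\\s+")[[1L]]
    if (length(fields) != d + 1L) {
      stop_arg("line %d: expected %d fields, found %d", k + 1L, d + 1L, length(fields))
    }
    w <- fields[[1L]]
    if (!(w %in% want)) next
    v <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(v)) stop_arg("line %d: non-numeric vector component", k + 1L)
    assign(w, v, envir = vecs)
  }
  missing <- setdiff(wordlist, ls(vecs))
  if (length(missing) > 0L) {
    stop_arg("word(s) not found in embedding file: %s",
             paste(missing, collapse = ", "))
  }
  vectors <- do.call(rbind, lapply(wordlist, get, envir = vecs))
  semantic_space(wordlist, vectors)
}

#' Write a semantic space in word2vec text format
#'
#' @param space A `semantic_space`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(space, path) {
  stopifnot(inherits(space, "semantic_space"))
  n <- n_items(space); d <- ncol(space$vectors)
  rows <- vapply(seq_len(n), function(i) {
    paste(space$items[i],
          paste(formatC(space$vectors[i, ], format = "g", digits = 17),
                collapse = " "))
  }, character(1L))
  writeLines(c(sprintf("%d %d", n, d), rows), path)
  invisible(path)
}

#' Read a word list (one item per line, UTF-8)
#'
#' @param path Path to a plain-text word list.
#' @return Character vector of words.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) stop_arg("word list not found: %s", path)
  w <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  w[nzchar(w)]
}
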