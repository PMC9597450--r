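#' Dice similarity between two binary profiles
#'
#' 2a / (2a + b + c), with a = shared presences and b, c the presences unique
#' to each profile. Undefined when both profiles are all-zero.
#'
#' @param x,y Equal-length 0/1 vectors.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' dice_similarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
dice_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("profiles must be binary", call. = FALSE)
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1)
  if (2 * a + b + c == 0)
    stop("Dice similarity undefined for two all-zero profiles", call. = FALSE)
  2 * a / (2 * a + b + c)
}

#' Dice similarity matrix over genotypes
#'
#' Pairwise Dice similarities between the genotype (column) band profiles of
#' one or several band matrices.
#'
#' @param x A [band_matrix], a list of band matrices sharing one genotype
#'   roster (profiles are concatenated), or a bands-by-samples 0/1 matrix
#'   with column names.
#' @return Square symmetric matrix of similarities with unit diagonal,
#'   dimnames = genotype labels.
#' @export
dice_matrix <- function(x) {
  m <- .binary_profiles(x)
  labs <- colnames(m)
  n <- ncol(m)
  s <- diag(1, n)
  dimnames(s) <- list(labs, labs)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s[i, j] <- s[j, i] <- dice_similarity(m[, i], m[, j])
    }
  }
  s
}

.binary_profiles <- function(x) {
  if (inherits(x, "band_matrix")) return(x$presence)
  if (is.list(x) && !is.data.frame(x)) {
    rosters <- lapply(x, function(b) b$genotypes)
    if (length(unique(rosters)) != 1L)
      stop("band matrices must share one genotype roster", call. = FALSE)
    return(do.call(rbind, lapply(x, function(b) b$presence)))
  }
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

#' Convert a similarity matrix to a distance matrix
#'
#' @param s Similarity matrix in \[0, 1\].
#' @return Distance matrix 1 - s with zero diagonal.
#' @export
similarity_to_distance <- function(s) {
  d <- 1 - as.matrix(s)
  diag(d) <- 0
  d
}

.check_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Classical unweighted pair-group average agglomeration: the two clusters at
#' the smallest distance are merged, and distances to the merged cluster are
#' the size-weighted means of the members' distances (equivalently, the mean
#' over all cross pairs of the original distances). Node height is half the
#' merge distance, so the tree is ultrametric and leaf-to-leaf path lengths
#' equal the cophenetic distances. Ties are broken deterministically by the
#' lexicographically smallest member label of the candidate pair.
#'
#' @param d Square symmetric distance matrix with zero diagonal (or a
#'   [stats::dist] object).
#' @return An [ape::read.tree] `phylo` tree with branch lengths.
#' @export
upgma <- function(d) {
  d <- .check_distance(d)
  labs <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  # active clusters: newick fragment, height, size, smallest member label
  cl <- lapply(seq_len(n), function(i) {
    list(newick = labs[i], height = 0, size = 1L, min_lab = labs[i])
  })
  dd <- d
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        dij <- dd[i, j]
        key <- sort(c(cl[[i]]$min_lab, cl[[j]]$min_lab))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bi <- h - cl[[i]]$height
    bj <- h - cl[[j]]$height
    merged <- list(
      newick = sprintf("(%s:%.10g,%s:%.10g)", cl[[i]]$newick, bi,
                       cl[[j]]$newick, bj),
      height = h,
      size = cl[[i]]$size + cl[[j]]$size,
      min_lab = min(cl[[i]]$min_lab, cl[[j]]$min_lab)
    )
    # size-weighted average linkage update
    for (k in active) {
      if (k != i && k != j) {
        dd[i, k] <- dd[k, i] <-
          (cl[[i]]$size * dd[i, k] + cl[[j]]$size * dd[j, k]) / merged$size
      }
    }
    cl[[i]] <- merged
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(cl[[active]]$newick, ";"))
}

#' Principal-coordinates analysis of a distance matrix
#'
#' Classical metric multidimensional scaling: the matrix -d^2 / 2 is
#' double-centered and eigendecomposed; axis k is the k-th eigenvector scaled
#' by the square root of its eigenvalue. Negative eigenvalues are clamped to
#' zero and excluded from the explained-variance denominator, so explained
#' percentages are non-negative, non-increasing and sum to at most 100.
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param n_axes Maximum number of axes to keep (default: all with positive
#'   eigenvalue).
#' @return List of class `pcoa_ord` with `labels`, `scores` (samples x axes),
#'   `eig` (positive eigenvalues kept) and `explained` (percent per axis).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- .check_distance(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  # G = (I - 11'/n) A (I - 11'/n) with A = -d^2/2
  a <- -d^2 / 2
  g <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) +
    mean(a)
  e <- eigen(g, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-10 & e$values > 0)
  if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
  ev <- e$values[pos]
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), length(ev))
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PCo", seq_along(pos))
  structure(
    list(labels = rownames(d), scores = scores, eig = ev,
         explained = 100 * ev / sum(e$values[e$values > 0])),
    class = "pcoa_ord"
  )
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("Principal coordinates: %d samples, %d axes\n",
              length(x$labels), ncol(x$scores)))
  cat("explained (%):", paste(sprintf("%.1f", x$explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Combined marker + karyotype feature matrix
#'
#' Concatenates the binary band profiles of one or several marker systems
#' (samples in rows) with z-scored karyotype indices, for joint similarity /
#' heatmap analyses. Zero-variance karyotype columns are dropped with a
#' warning, since they cannot be standardized.
#'
#' @param band_matrices List (possibly named) of [band_matrix] objects
#'   sharing one genotype roster, or a single band matrix.
#' @param karyotype_summaries Optional data frame of per-genotype karyotype
#'   summaries as from [karyotype_summary()] rows; must cover every genotype.
#' @return Numeric matrix, genotypes x features, with attribute `provenance`
#'   (character vector labelling each column's source).
#' @export
combined_feature_matrix <- function(band_matrices, karyotype_summaries = NULL) {
  if (inherits(band_matrices, "band_matrix"))
    band_matrices <- list(band_matrices)
  profiles <- t(.binary_profiles(band_matrices))
  labels <- rownames(profiles)
  colnames(profiles) <- paste0("band", seq_len(ncol(profiles)))
  prov <- rep("marker", ncol(profiles))
  out <- profiles
  if (!is.null(karyotype_summaries)) {
    ks <- as.data.frame(karyotype_summaries)
    missing <- setdiff(labels, ks$genotype)
    if (length(missing))
      stop("karyotype summaries missing genotypes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    ks <- ks[match(labels, ks$genotype), ]
    num <- ks[vapply(ks, is.numeric, logical(1L))]
    num$n_diploid <- NULL
    keep <- vapply(num, function(v) stats::sd(v) > 0, logical(1L))
    if (any(!keep))
      warning("dropping zero-variance karyotype columns: ",
              paste(names(num)[!keep], collapse = ", "), call. = FALSE)
    num <- num[keep]
    if (length(num)) {
      z <- scale(as.matrix(num))
      rownames(z) <- labels
      out <- cbind(out, z)
      prov <- c(prov, rep("karyotype", ncol(z)))
    }
  }
  attr(out, "provenance") <- prov
  out
}
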