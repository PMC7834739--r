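# Within-group sum of squares of a block of rows (squared Euclidean
# dispersion about the block centroid).
block_ss <- function(X, idx) {
  if (length(idx) <= 1L) return(0)
  sub <- X[idx, , drop = FALSE]
  sum(sweep(sub, 2, colMeans(sub))^2)
}

# Total within-group SS of a contiguous partition given its breakpoints
# (last index of each group except the final one).
partition_ss <- function(X, cuts) {
  bounds <- c(0L, sort(cuts), nrow(X))
  total <- 0
  for (g in seq_len(length(bounds) - 1L)) {
    total <- total + block_ss(X, (bounds[g] + 1L):bounds[g + 1L])
  }
  total
}

#' Chronologically constrained incremental sum-of-squares clustering
#'
#' CONISS-style agglomerative clustering of years: only temporally adjacent
#' blocks may merge, and at each step the merge with the smallest increase
#' in within-group (squared Euclidean) sum of squares is chosen. Merge
#' heights are the cumulative within-group dispersion after each merge, so
#' cutting the tree at k groups yields the CONISS k-zonation.
#'
#' @param features numeric matrix or data.frame, rows = years in increasing
#'   order (rownames taken as years), columns = features (e.g. the four
#'   latent trends). No missing values.
#' @param years optional integer vector of years (default: rownames or
#'   1..T).
#' @return object of class `zonation`: `merges` (data.frame with the blocks
#'   merged at each step and the SS increment), `dispersion_by_k` (total
#'   within-group SS for k = 1..T), `years`, and `groups_by_k` (a function
#'   is not stored; use [zonation_groups()]).
#' @export
coniss <- function(features, years = NULL) {
  X <- as.matrix(features)
  assert_that(!anyNA(X), "coniss: missing feature values")
  TT <- nrow(X)
  assert_that(TT >= 2, "coniss: need at least 2 years")
  years <- years %||% (if (!is.null(rownames(X))) as.integer(rownames(X))
                       else seq_len(TT))
  assert_that(!is.unsorted(years, strictly = TRUE),
              "coniss: years must be strictly increasing")

  # blocks as (start, end) index pairs, in chronological order
  starts <- seq_len(TT)
  ends <- seq_len(TT)
  ss <- numeric(TT)              # within-SS of each current block
  merges <- data.frame(step = integer(0), left_start = integer(0),
                       left_end = integer(0), right_start = integer(0),
                       right_end = integer(0), increment = numeric(0),
                       dispersion = numeric(0))
  boundaries <- list()           # breakpoints at each k (T-1 merges)
  disp <- numeric(TT)            # total within-SS indexed by k groups
  disp[TT] <- 0
  total <- 0
  nb <- TT
  while (nb > 1L) {
    inc <- numeric(nb - 1L)
    merged_ss <- numeric(nb - 1L)
    for (j in seq_len(nb - 1L)) {
      idx <- starts[j]:ends[j + 1L]
      merged_ss[j] <- block_ss(X, idx)
      inc[j] <- merged_ss[j] - ss[j] - ss[j + 1L]
    }
    j <- which.min(inc)
    total <- total + inc[j]
    merges <- rbind(merges, data.frame(
      step = TT - nb + 1L,
      left_start = starts[j], left_end = ends[j],
      right_start = starts[j + 1L], right_end = ends[j + 1L],
      increment = inc[j], dispersion = total))
    ss[j] <- merged_ss[j]
    ends[j] <- ends[j + 1L]
    starts <- starts[-(j + 1L)]
    ends <- ends[-(j + 1L)]
    ss <- ss[-(j + 1L)]
    nb <- nb - 1L
    disp[nb] <- total
    boundaries[[nb]] <- ends[-nb]
  }
  structure(list(merges = merges, dispersion_by_k = disp, years = years,
                 boundaries = boundaries, features = X),
            class = "zonation")
}

#' Year groups at a given number of zones
#'
#' @param zonation a [coniss()] result.
#' @param k number of contiguous groups.
#' @return list of integer year vectors, one per group, chronological.
#' @export
zonation_groups <- function(zonation, k) {
  TT <- length(zonation$years)
  assert_that(k >= 1 && k <= TT, "zonation_groups: k out of range")
  cuts <- if (k == 1) integer(0) else if (k == TT) seq_len(TT - 1L) else
    zonation$boundaries[[k]]
  bounds <- c(0L, cuts, TT)
  lapply(seq_len(length(bounds) - 1L), function(g)
    zonation$years[(bounds[g] + 1L):bounds[g + 1L]])
}

#' @export
print.zonation <- function(x, ...) {
  TT <- length(x$years)
  cat(sprintf("Constrained zonation of %d years (%d-%d); total SS %.4g\n",
              TT, min(x$years), max(x$years), x$dispersion_by_k[1]))
  if (!is.null(x$significant_k)) {
    cat(sprintf("  significant zones: %d\n", x$significant_k))
  }
  invisible(x)
}

#' Export the zonation tree as Newick text
#'
#' Nested parenthetical form with the merge increment as branch annotation,
#' for external dendrogram plotting tools.
#'
#' @param zonation a [coniss()] result.
#' @return a single Newick string (terminated by ";").
#' @export
zonation_newick <- function(zonation) {
  labels <- as.character(zonation$years)
  node <- as.list(labels)
  starts <- seq_along(labels)
  for (i in seq_len(nrow(zonation$merges))) {
    m <- zonation$merges[i, ]
    j <- match(m$left_start, starts)
    node[[j]] <- sprintf("(%s,%s):%g", node[[j]], node[[j + 1]],
                         m$increment)
    node[[j + 1]] <- NULL
    starts <- starts[-(j + 1)]
  }
  paste0(node[[1]], ";")
}

#' Broken-stick randomization test for the number of zones
#'
#' The observed proportion of the total dispersion removed by each
#' successive split of the constrained clustering is compared with the
#' proportion predicted for groupings of random length: the sequence of
#' T years admits T-1 splits, and under the null the ordered proportions
#' behave like the ordered pieces of a stick broken at random into T-1
#' segments. The expectation of the (k-1)-th largest segment is estimated
#' by Monte Carlo (`n_random` random sticks). The number of significant
#' zones is the largest k such that every split up to k removes more
#' variance than the corresponding random-segment expectation.
#'
#' @param zonation a [coniss()] result.
#' @param n_random number of random sticks (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed RNG seed for the randomization.
#' @return the input `zonation` with elements `significant_k`,
#'   `observed_reduction` and `random_reduction` (proportions of the total
#'   dispersion, indexed by number of groups k = 2..T).
#' @export
broken_stick <- function(zonation, n_random = 1000, seed = NULL) {
  if (n_random < 100) {
    warning("broken_stick: n_random < 100 gives an unstable null")
  }
  TT <- length(zonation$years)
  total <- zonation$dispersion_by_k[1]
  obs <- (zonation$dispersion_by_k[1:(TT - 1)] -
            zonation$dispersion_by_k[2:TT]) / total
  n_pieces <- TT - 1L
  rnd <- with_seed(seed, {
    acc <- matrix(0, n_random, n_pieces)
    for (r in seq_len(n_random)) {
      pieces <- diff(c(0, sort(stats::runif(n_pieces - 1L)), 1))
      acc[r, ] <- sort(pieces, decreasing = TRUE)
    }
    colMeans(acc)
  })
  sig <- 1L
  for (k in 2:TT) {
    if (obs[k - 1L] > rnd[k - 1L]) sig <- k else break
  }
  zonation$observed_reduction <- stats::setNames(obs, 2:TT)
  zonation$random_reduction <- stats::setNames(rnd, 2:TT)
  zonation$significant_k <- sig
  zonation
}
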