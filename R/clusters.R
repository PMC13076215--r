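#' Uncentered correlation distance
#'
#' The distance used by Cluster 3.0-style k-means:
#' `d = 1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`, i.e. one minus
#' the cosine of the angle between the raw (uncentered) vectors. Ranges
#' over \[0, 2\]; 0 for proportional vectors with positive scale, 1 for
#' orthogonal ones.
#'
#' @param x,y Numeric vectors of equal length, neither all-zero.
#' @return A scalar in \[0, 2\].
#' @export
uncentered_correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("x and y must have equal positive length")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("uncentered correlation is undefined for an all-zero vector")
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)
}

## n x k matrix of distances from rows of x to rows of centers
point_center_distances <- function(x, centers, distance) {
  if (distance == "uncentered_correlation") {
    nx <- sqrt(rowSums(x^2))
    nc <- sqrt(rowSums(centers^2))
    d <- 1 - (x %*% t(centers)) / outer(nx, nc)
    pmin(pmax(d, 0), 2)
  } else {
    d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
      2 * (x %*% t(centers)) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    sqrt(pmax(d2, 0))
  }
}

#' K-means clustering with a choice of distance
#'
#' Lloyd-style k-means under either the uncentered-correlation distance
#' (the metric used for chromatin-signal clustering) or Euclidean distance.
#' Initial centers are picked by a seeded farthest-point heuristic: the
#' first center is a random row, each further center the row farthest (in
#' the chosen distance) from the centers picked so far. Iteration
#' alternates nearest-center assignment (ties to the lowest center index)
#' with per-cluster feature means, and stops when assignments stop
#' changing, when `max_iter` is reached, or when a step would increase the
#' objective (the sum of distances from points to their assigned centers),
#' which keeps the objective trace monotone non-increasing under the
#' non-Euclidean metric. Results are deterministic given `seed`.
#'
#' @param x Numeric matrix, rows = observations (genes), columns =
#'   features. With the uncentered-correlation distance no row may be
#'   all-zero.
#' @param k Number of clusters, between 1 and the number of distinct rows.
#' @param distance `"uncentered_correlation"` or `"euclidean"`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Iteration cap.
#' @return List of class `chromstate_kmeans`: `cluster` (assignments),
#'   `centers`, `objective`, `objective_trace`, `iterations`, `converged`,
#'   `distance`.
#' @export
kmeans_cluster <- function(x, k, distance = c("uncentered_correlation",
                                              "euclidean"),
                           seed = 1, max_iter = 300) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct rows")
  if (distance == "uncentered_correlation" && any(rowSums(x^2) == 0)) {
    stop("uncentered correlation is undefined for an all-zero row")
  }

  centers <- with_seed(seed, function() {
    idx <- sample.int(n, 1)
    for (j in seq_len(k - 1)) {
      d <- point_center_distances(x, x[idx, , drop = FALSE], distance)
      dmin <- apply(d, 1, min)
      dmin[idx] <- -Inf
      cand <- which.max(dmin)
      if (dmin[cand] <= 0) {
        stop("fewer than k distinct rows under the chosen distance")
      }
      idx <- c(idx, cand)
    }
    x[idx, , drop = FALSE]
  })

  assign_step <- function(centers) {
    d <- point_center_distances(x, centers, distance)
    cl <- apply(d, 1, which.min)
    list(cluster = cl, objective = sum(d[cbind(seq_len(n), cl)]))
  }

  st <- assign_step(centers)
  trace <- st$objective
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- st$cluster == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    new_st <- assign_step(new_centers)
    if (new_st$objective > st$objective + 1e-12) break
    centers <- new_centers
    changed <- !identical(new_st$cluster, st$cluster)
    st <- new_st
    trace <- c(trace, st$objective)
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  structure(list(cluster = setNames(st$cluster, rownames(x)),
                 centers = centers, objective = st$objective,
                 objective_trace = trace, iterations = iterations,
                 converged = converged, distance = distance),
            class = "chromstate_kmeans")
}

#' Stratify bivalent promoters into chromatin clusters C1-C4
#'
#' Bivalent promoters fall into four strata by strong/weak combinations of
#' their two histone marks: C1 strong H3K4me3 / weak H3K27me3, C2 strong /
#' strong, C3 weak H3K4me3 / strong H3K27me3, C4 weak / weak. The default
#' `median_split` method calls a mark "strong" when its normalized RPKM
#' lies strictly above that mark's median across the bivalent genes
#' (a value exactly at the median is "weak"). The `kmeans` method instead
#' clusters the 2-feature matrix with k = 4 (Euclidean distance, since the
#' strata are magnitude-defined) and relabels clusters C1-C4 by matching
#' each centroid's strong/weak pattern against the grand medians; if two
#' centroids land on the same pattern the labeling falls back to the
#' permutation agreeing best with the median split.
#'
#' @param h3k4me3,h3k27me3 Normalized promoter signal tables over a common
#'   gene set.
#' @param bivalent Named logical vector from [classify_bivalent()].
#' @param method `"median_split"` or `"kmeans"`.
#' @param seed Seed for the k-means path.
#' @return data.frame with columns `gene_id`, `cluster` (`C1`..`C4`),
#'   `method`, restricted to bivalent genes; attribute `centers` holds the
#'   per-cluster mean (H3K4me3, H3K27me3) signal.
#' @export
stratify_c1c4 <- function(h3k4me3, h3k27me3, bivalent,
                          method = c("median_split", "kmeans"), seed = 1) {
  method <- match.arg(method)
  v <- align_genes(h3k4me3, h3k27me3, "histone-mark")
  biv_genes <- names(bivalent)[bivalent]
  if (length(biv_genes) == 0) stop("no bivalent genes to stratify")
  unknown <- setdiff(biv_genes, names(v$a))
  if (length(unknown) > 0) stop("gene '", unknown[1], "' missing from signal")
  k4 <- v$a[biv_genes]
  k27 <- v$b[biv_genes]
  med4 <- median(k4)
  med27 <- median(k27)
  pattern_label <- function(strong4, strong27) {
    ifelse(strong4 & !strong27, "C1",
           ifelse(strong4 & strong27, "C2",
                  ifelse(!strong4 & strong27, "C3", "C4")))
  }
  median_labels <- pattern_label(k4 > med4, k27 > med27)

  if (method == "median_split") {
    labels <- median_labels
  } else {
    fit <- kmeans_cluster(cbind(h3k4me3 = k4, h3k27me3 = k27), k = 4,
                          distance = "euclidean", seed = seed)
    centroid_pat <- pattern_label(fit$centers[, 1] > med4,
                                  fit$centers[, 2] > med27)
    if (anyDuplicated(centroid_pat) == 0) {
      labels <- centroid_pat[fit$cluster]
    } else {
      perms <- all_permutations(c("C1", "C2", "C3", "C4"))
      scores <- vapply(perms, function(p) {
        as.numeric(sum(p[fit$cluster] == median_labels))
      }, numeric(1))
      labels <- perms[[which.max(scores)]][fit$cluster]
    }
  }
  out <- data.frame(gene_id = biv_genes, cluster = labels, method = method,
                    row.names = NULL)
  centers <- t(vapply(c("C1", "C2", "C3", "C4"), function(cl) {
    sel <- labels == cl
    if (!any(sel)) return(c(h3k4me3 = NA_real_, h3k27me3 = NA_real_))
    c(h3k4me3 = mean(k4[sel]), h3k27me3 = mean(k27[sel]))
  }, numeric(2)))
  attr(out, "centers") <- centers
  out
}

all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Per-gene log2 fold change between two conditions
#'
#' Computed on normalized RPKM with a pseudocount keeping zeros finite:
#' `log2((ko + pseudocount) / (ctrl + pseudocount))`.
#'
#' @param ko,ctrl Normalized signal tables over identical gene sets
#'   (knockout and control).
#' @param pseudocount Positive pseudocount.
#' @return Named numeric vector of log2 fold changes keyed by gene.
#' @export
fold_change <- function(ko, ctrl, pseudocount = 0.1) {
  v <- align_genes(ko, ctrl, "condition")
  if (any(v$a < 0) || any(v$b < 0)) stop("signals must be non-negative")
  stopifnot(pseudocount > 0)
  log2((v$a + pseudocount) / (v$b + pseudocount))
}

#' Fold-change quadrant fractions
#'
#' Fractions of genes in the four quadrants of the (Pol II fold change,
#' H3K27me3 fold change) plane. The upper-left quadrant -- reduced Pol II
#' (fc < 0) with increased H3K27me3 (fc > 0) -- is the one summarizing
#' repressive-mark gain at promoters losing Pol II; fold changes of exactly
#' 0 count as "not reduced" / "not increased". The four fractions sum to 1
#' exactly.
#'
#' @param fc_pol2,fc_k27 Named log2 fold-change vectors from
#'   [fold_change()].
#' @param genes Optional gene subset (character vector); defaults to all
#'   common genes. Must be non-empty.
#' @return Named numeric vector `upper_left`, `upper_right`, `lower_left`,
#'   `lower_right`.
#' @export
quadrant_fractions <- function(fc_pol2, fc_k27, genes = NULL) {
  v <- align_genes(fc_pol2, fc_k27, "fold-change")
  genes <- genes %||% names(v$a)
  if (length(genes) == 0) stop("gene subset is empty")
  missing <- setdiff(genes, names(v$a))
  if (length(missing) > 0) stop("gene '", missing[1], "' missing from fold-change tables")
  p <- v$a[genes]
  k <- v$b[genes]
  n <- length(genes)
  c(upper_left = sum(p < 0 & k > 0),
    upper_right = sum(p >= 0 & k > 0),
    lower_left = sum(p < 0 & k <= 0),
    lower_right = sum(p >= 0 & k <= 0)) / n
}
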