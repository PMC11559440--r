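#' Select the feature matrix for one cluster analysis
#'
#' Four feature sets are supported, mirroring the four cluster analyses:
#' \code{wd} uses \{Lying-WD, Reclined-WD, Upright-WD, Unknown-WD, FPT-WD\},
#' \code{dt} and \code{nt} the analogous daytime/nighttime columns, and
#' \code{combined} concatenates the DT and NT features (10 columns, one row
#' per patient). UserDefined durations are never included: they are
#' essentially zero for all patients and carry no contrast.
#'
#' @param summaries output of [patient_summaries()].
#' @param set \code{"wd"}, \code{"dt"}, \code{"nt"} or \code{"combined"}.
#' @return numeric matrix, rownames = MRN.
#' @export
feature_matrix <- function(summaries, set = c("wd", "dt", "nt", "combined")) {
  set <- match.arg(set)
  s <- data.table::as.data.table(summaries)
  cols_for <- function(w) c(paste0(c("Lying", "Reclined", "Upright", "Unknown"), "-", w),
                            paste0("FPT-", w))
  cols <- switch(set,
                 wd = cols_for("WD"), dt = cols_for("DT"), nt = cols_for("NT"),
                 combined = c(cols_for("DT"), cols_for("NT")))
  m <- as.matrix(s[, cols, with = FALSE])
  rownames(m) <- s$mrn
  m
}

#' Column-wise standardization to mean 0, SD 1
#'
#' Z-scores each column using the sample standard deviation (n-1
#' denominator). The centering/scaling parameters are kept as attributes so
#' centroids can be reported back in original units. A zero-variance column
#' cannot be standardized and raises an error naming the column.
#'
#' @param x numeric matrix (patients x features).
#' @return standardized matrix with attributes \code{"center"} and
#'   \code{"scale"}.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_config("standardize needs >= 2 rows")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  if (any(sdev == 0))
    stop_config("zero-variance column(s): %s",
                paste(colnames(x)[sdev == 0], collapse = ", "))
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdev
  z
}

#' @rdname standardize
#' @param z a matrix produced by [standardize()] (or any matrix plus
#'   explicit \code{center}/\code{scale}).
#' @param center,scale parameters; default from the attributes of \code{z}.
#' @export
de_standardize <- function(z, center = attr(z, "center"), scale = attr(z, "scale")) {
  out <- sweep(sweep(as.matrix(z), 2, scale, "*"), 2, center, "+")
  attr(out, "center") <- NULL; attr(out, "scale") <- NULL
  out
}

#' Silhouette widths
#'
#' Per-point silhouette width s(i) = (b - a) / max(a, b), with a the mean
#' Euclidean distance from point i to the other members of its cluster and b
#' the smallest mean distance to any other cluster. Points in singleton
#' clusters get s = 0 by convention. Distances are Euclidean in whatever
#' space \code{x} is in — for model selection that is the standardized
#' feature space the clustering itself used.
#'
#' @param x numeric matrix of points.
#' @param labels integer/character cluster assignment per row.
#' @return numeric vector of silhouette widths.
#' @export
silhouette_widths <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as.character(labels)
  ulab <- unique(labels)
  if (length(ulab) < 2L) stop_config("silhouette needs >= 2 clusters")
  d <- as.matrix(dist(x))
  # mean distance from each point to each cluster (excluding self for own)
  sums <- vapply(ulab, function(l) rowSums(d[, labels == l, drop = FALSE]),
                 numeric(n))
  sizes <- as.numeric(table(labels)[ulab])
  own <- match(labels, ulab)
  s <- numeric(n)
  for (i in seq_len(n)) {
    size_own <- sizes[own[i]]
    if (size_own == 1L) { s[i] <- 0; next }
    a <- sums[i, own[i]] / (size_own - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(0)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dj <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

run_kmeans_once <- function(z, k, iter_max) {
  init <- kmeanspp_centers(z, k)
  # Lloyd iterations from the seeded centres; k-means++ can seed duplicate
  # centres on degenerate data, so fall back to random rows if kmeans balks
  fit <- tryCatch(
    kmeans(z, centers = init, iter.max = iter_max, algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(suppressWarnings(
      kmeans(z, centers = init, iter.max = iter_max, algorithm = "Lloyd")),
      error = function(e) NULL)
  }
  fit
}

#' k-means subtyping with silhouette model selection
#'
#' Standardizes the feature matrix, runs Lloyd's k-means (k-means++-style
#' seeding, \code{restarts} restarts keeping the lowest within-cluster sum
#' of squares) for each candidate k, computes the average silhouette width
#' in standardized space, and keeps the k that maximizes it (ties broken
#' toward smaller k — parsimony). Cluster labels are canonicalized by
#' descending cluster size (ties by first patient index), so cluster 1 is
#' always the largest. Centroids are reported in original units.
#'
#' @param x numeric matrix (patients x features), original units —
#'   typically [feature_matrix()] output.
#' @param k_range candidate cluster counts (default 2:10). Candidates with
#'   k >= n are skipped with a warning.
#' @param restarts random restarts per k (default 50).
#' @param iter_max Lloyd iteration cap per restart (default 100).
#' @param seed optional integer seed for reproducibility.
#' @return a \code{cluster_result}: \code{k}, \code{assignment} (named by
#'   MRN), \code{centers} (original units), \code{sizes}, \code{pct},
#'   \code{avg_silhouette}, \code{cluster_silhouette} (per-cluster means),
#'   \code{silhouette_by_k} (the model-selection curve), \code{totss_by_k},
#'   and the standardization parameters.
#' @export
fit_kmeans_select <- function(x, k_range = 2:10, restarts = 50,
                              iter_max = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  n <- nrow(x)
  z <- standardize(x)
  k_range <- sort(unique(as.integer(k_range)))
  usable <- k_range[k_range < n & k_range >= 2L]
  if (length(usable) < length(k_range))
    warning(sprintf("skipping k >= n (n = %d): %s", n,
                    paste(setdiff(k_range, usable), collapse = ", ")), call. = FALSE)
  if (length(usable) == 0L) stop_config("no usable k in k_range for n = %d", n)

  sil_by_k <- setNames(rep(NA_real_, length(usable)), usable)
  wss_by_k <- setNames(rep(NA_real_, length(usable)), usable)
  fits <- list()
  for (k in usable) {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- run_kmeans_once(z, k, iter_max)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) next
    fits[[as.character(k)]] <- best
    sil_by_k[as.character(k)] <- mean(silhouette_widths(z, best$cluster))
    wss_by_k[as.character(k)] <- best$tot.withinss
  }
  if (all(is.na(sil_by_k))) stop_config("k-means failed for every k")
  k_star <- usable[which.max(sil_by_k)]  # which.max takes the first (smallest k) on ties
  best <- fits[[as.character(k_star)]]

  # canonical labels: 1 = largest cluster; ties by first patient index
  first_idx <- vapply(seq_len(k_star), function(c) min(which(best$cluster == c)),
                      integer(1))
  ord <- order(-as.integer(best$size), first_idx)
  relabel <- match(seq_len(k_star), ord)
  assignment <- relabel[best$cluster]
  names(assignment) <- rownames(x)
  centers_z <- best$centers[ord, , drop = FALSE]
  rownames(centers_z) <- seq_len(k_star)
  sil <- silhouette_widths(z, assignment)
  structure(list(
    k = k_star,
    assignment = assignment,
    centers = de_standardize(centers_z, attr(z, "center"), attr(z, "scale")),
    sizes = as.integer(table(factor(assignment, levels = seq_len(k_star)))),
    pct = 100 * as.integer(table(factor(assignment, levels = seq_len(k_star)))) / n,
    avg_silhouette = mean(sil),
    cluster_silhouette = vapply(seq_len(k_star),
                                function(c) mean(sil[assignment == c]), numeric(1)),
    silhouette_by_k = sil_by_k,
    totss_by_k = wss_by_k,
    center = attr(z, "center"), scale = attr(z, "scale")
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means subtyping: k = %d (avg silhouette %.3f)\n",
              x$k, x$avg_silhouette))
  tab <- data.frame(size = x$sizes, pct = round(x$pct, 1),
                    silhouette = round(x$cluster_silhouette, 3))
  rownames(tab) <- paste0("cluster ", seq_len(x$k))
  print(tab)
  invisible(x)
}

#' Cluster report table
#'
#' Per-cluster means of every input feature in original units, cluster sizes
#' and percentages, ordered largest cluster first, plus a grand-average row
#' across all patients. The size-weighted mean of the cluster means equals
#' the grand mean by construction.
#'
#' @param result a \code{cluster_result}.
#' @param x the original-unit feature matrix the result was fitted to.
#' @return \code{data.frame}: one row per cluster plus an \code{"Average"}
#'   row; columns = features, \code{n}, \code{pct}.
#' @export
cluster_table <- function(result, x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(result$assignment))
  ks <- seq_len(result$k)
  rows <- lapply(ks, function(c) colMeans(x[result$assignment == c, , drop = FALSE]))
  tab <- as.data.frame(do.call(rbind, rows))
  tab$n <- result$sizes
  tab$pct <- round(result$pct, 1)
  avg <- as.data.frame(t(c(colMeans(x), n = nrow(x), pct = 100)))
  out <- rbind(tab, avg)
  rownames(out) <- c(paste0("C", ks), "Average")
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items; 1 =
#' identical partitions (up to label permutation), ~0 = chance agreement.
#' Used to score recovery of ground-truth archetypes by the clustering.
#'
#' @param a,b two assignment vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(m) sum(m * (m - 1) / 2)
  sum_ij <- choose2(tab)
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
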