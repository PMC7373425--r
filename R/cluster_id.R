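#' Pairwise Euclidean distance matrix between cells
#'
#' @param cells A data frame of cell records with `cell_id`, `x`, `y`, `z`
#'   and `transduced` columns (one acinus, one timepoint).
#' @param subset `"transduced"` (the default, matching the cluster
#'   definition: distances between oncogene-expressing cells only) or
#'   `"all"`.
#' @return An object of class `oncoprox_dist`: list with `ids` (ordered
#'   cell ids) and `d` (symmetric matrix of distances in micrometres).
#' @export
pairwise_distances <- function(cells, subset = c("transduced", "all")) {
  subset <- match.arg(subset)
  keep <- if (subset == "transduced") cells$transduced else rep(TRUE, nrow(cells))
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) {
    stop("no cells in requested subset", call. = FALSE)
  }
  m <- as.matrix(cells[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(cells$cell_id, cells$cell_id)
  structure(list(ids = cells$cell_id, d = d), class = "oncoprox_dist")
}

#' Complete-linkage hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative clustering in which the distance between two groups is the
#' maximum pairwise distance between their members, so every merge height
#' equals the diameter of the merged set. Ties in merge height are broken
#' deterministically: among candidate pairs at the minimal height, the pair
#' whose combined leaf set has the lexicographically smallest
#' (minimum leaf index, maximum leaf index) is merged first. Duplicate
#' coordinates (distance 0) are legal and merge first.
#'
#' @param dm An [oncoprox_dist][pairwise_distances].
#' @return An `oncoprox_dendrogram`: list with `merge` (hclust convention:
#'   negative entries are leaves, positive entries earlier merges),
#'   `height` (non-decreasing, micrometres), `labels` and `order`.
#' @export
complete_linkage <- function(dm) {
  stopifnot(inherits(dm, "oncoprox_dist"))
  n <- length(dm$ids)
  d <- dm$d
  merge <- matrix(0L, nrow = max(n - 1L, 0L), ncol = 2L)
  height <- numeric(max(n - 1L, 0L))
  if (n >= 2) {
    members <- as.list(seq_len(n)) # leaf index sets per active cluster
    codes <- -seq_len(n) # hclust node codes
    active <- rep(TRUE, n)
    for (step in seq_len(n - 1L)) {
      idx <- which(active)
      best <- NULL
      for (a in seq_len(length(idx) - 1L)) {
        for (b in seq(a + 1L, length(idx))) {
          i <- idx[a]
          j <- idx[b]
          h <- max(d[members[[i]], members[[j]]])
          u <- c(members[[i]], members[[j]])
          key <- c(h, min(u), max(u))
          if (is.null(best) ||
            key[1] < best$key[1] ||
            (key[1] == best$key[1] && (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
            best <- list(key = key, i = i, j = j)
          }
        }
      }
      merge[step, ] <- c(codes[[best$i]], codes[[best$j]])
      height[step] <- best$key[1]
      members[[best$i]] <- sort(c(members[[best$i]], members[[best$j]]))
      codes[[best$i]] <- step
      active[best$j] <- FALSE
    }
  }
  dend <- structure(
    list(merge = merge, height = height, labels = dm$ids, n = n),
    class = "oncoprox_dendrogram"
  )
  dend$order <- .dendrogram_leaf_order(dend)
  dend
}

.dendrogram_leaf_order <- function(dend) {
  if (dend$n == 1L) {
    return(1L)
  }
  rec <- function(code) {
    if (code < 0) {
      return(-code)
    }
    c(rec(dend$merge[code, 1]), rec(dend$merge[code, 2]))
  }
  rec(dend$n - 1L)
}

#' Adaptive branch cutting of a dendrogram
#'
#' Cuts the dendrogram into clusters by the shape of its branches rather
#' than at a single fixed height, in the spirit of dynamic branch-cut
#' methods for hierarchical trees. Starting from the root, each join is
#' tested for a genuine gap between its two sub-branches: the join height
#' is compared with the branches' internal cohesion, measured as the
#' median of a branch's internal merge heights (the median, unlike the
#' maximum, is not dominated by deeper between-cluster joins when several
#' clusters merge in a chain; a leaf has cohesion 0). A join at height
#' \eqn{h} whose children have cohesions \eqn{h_L, h_R} is split whenever
#' \eqn{h \ge \code{gap_ratio} \cdot \max(h_L, h_R)}, and always when `h`
#' exceeds `cut_height`, if one is given. A join of two
#' leaves is never split by the adaptive rule. Recursion continues into
#' split branches; a branch that is not split becomes one cluster. Leaves
#' detached by a split, and clusters smaller than `min_cluster_size`,
#' become singleton clusters — a cluster may consist of a single,
#' comparatively isolated cell.
#'
#' A tree of two leaves is a single branch and yields one 2-cell cluster.
#'
#' @param dend An [oncoprox_dendrogram][complete_linkage].
#' @param dm The [oncoprox_dist][pairwise_distances] the dendrogram was
#'   built from (checked for consistency).
#' @param min_cluster_size Minimum size of a multi-cell cluster
#'   (integer >= 1, default 2). Smaller fragments are emitted as singletons.
#' @param gap_ratio Ratio of join height to branch cohesion above which a
#'   join is split (> 1, default 2).
#' @param cut_height Optional static ceiling (micrometres); joins above it
#'   are always split. Default none.
#' @return Tibble with `cell_id` and integer `cluster` (arbitrary labels;
#'   canonicalised by [identify_clusters()]).
#' @export
dynamic_tree_cut <- function(dend, dm, min_cluster_size = 2L, gap_ratio = 2,
                             cut_height = NULL) {
  stopifnot(inherits(dend, "oncoprox_dendrogram"), inherits(dm, "oncoprox_dist"))
  if (!identical(dm$ids, dend$labels)) {
    stop("dm and dend describe different cells", call. = FALSE)
  }
  if (!is.numeric(min_cluster_size) || min_cluster_size < 1) {
    stop("min_cluster_size must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(gap_ratio) || gap_ratio <= 1) {
    stop("gap_ratio must be > 1", call. = FALSE)
  }
  if (!is.null(cut_height) && (!is.numeric(cut_height) || cut_height <= 0)) {
    stop("cut_height must be > 0 when given", call. = FALSE)
  }
  n <- dend$n
  if (n == 1L) {
    return(tibble::tibble(cell_id = dend$labels, cluster = 1L))
  }
  # per-node leaf sets and merge-height vectors (bottom-up)
  sub_heights <- vector("list", n - 1L)
  leaf_sets <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    kids <- dend$merge[m, ]
    inherited <- unlist(lapply(kids[kids > 0], function(c) sub_heights[[c]]))
    sub_heights[[m]] <- c(inherited, dend$height[m])
    leaf_sets[[m]] <- unlist(lapply(kids, function(c) {
      if (c < 0) -c else leaf_sets[[c]]
    }))
  }
  cohesion <- function(code) {
    if (code < 0) 0 else stats::median(sub_heights[[code]])
  }
  leaves <- function(code) if (code < 0) -code else leaf_sets[[code]]
  cut_node <- function(code) {
    if (code < 0) {
      return(list(-code))
    }
    h <- dend$height[code]
    left <- dend$merge[code, 1]
    right <- dend$merge[code, 2]
    core <- max(cohesion(left), cohesion(right))
    force_split <- !is.null(cut_height) && h > cut_height
    adaptive_split <- core > 0 && h >= gap_ratio * core
    if (force_split || adaptive_split) {
      c(cut_node(left), cut_node(right))
    } else {
      list(leaves(code))
    }
  }
  groups <- cut_node(n - 1L)
  # fragments below the minimum size dissolve into singletons
  final <- list()
  for (g in groups) {
    if (length(g) >= min_cluster_size) {
      final[[length(final) + 1L]] <- g
    } else {
      for (leaf in g) final[[length(final) + 1L]] <- leaf
    }
  }
  cluster <- integer(n)
  for (k in seq_along(final)) cluster[final[[k]]] <- k
  tibble::tibble(cell_id = dend$labels, cluster = cluster)
}

#' Identify clusters of transduced cells in every acinus
#'
#' Per acinus: pairwise Euclidean distances between the transduced cells,
#' complete-linkage dendrogram, adaptive branch cut. This realises the
#' cluster definition "a group of oncogene-expressing cells that are closer
#' to each other than to other oncogene-expressing cells of the same
#' acinus"; singleton clusters are permitted. Acini without transduced
#' cells contribute no clusters. Cells are processed in `cell_id` order so
#' the result is invariant to input row permutation, and cluster ids are
#' stable: clusters are labelled `c1`, `c2`, ... ordered by their minimum
#' member `cell_id`.
#'
#' @param cohort A [cohort_table][as_cohort_table]; only rows at
#'   `timepoint == "start"` are used (clusters are defined once, at the
#'   start of imaging) unless the cohort has a single timepoint.
#' @inheritParams dynamic_tree_cut
#' @return Tibble with one row per transduced cell: `acinus_id`,
#'   `cell_id`, `cluster_id`.
#' @export
identify_clusters <- function(cohort, min_cluster_size = 2L, gap_ratio = 2,
                              cut_height = NULL) {
  if ("start" %in% cohort$timepoint) {
    cohort <- cohort[cohort$timepoint == "start", , drop = FALSE]
  }
  out <- list()
  for (aid in sort(unique(cohort$acinus_id))) {
    cells <- cohort[cohort$acinus_id == aid & cohort$transduced, , drop = FALSE]
    if (nrow(cells) == 0) next
    cells <- cells[order(cells$cell_id), , drop = FALSE]
    if (nrow(cells) == 1L) {
      asg <- tibble::tibble(cell_id = cells$cell_id, cluster = 1L)
    } else {
      dm <- pairwise_distances(cells, subset = "transduced")
      dend <- complete_linkage(dm)
      asg <- dynamic_tree_cut(dend, dm,
        min_cluster_size = min_cluster_size,
        gap_ratio = gap_ratio, cut_height = cut_height
      )
    }
    # canonical labels: order clusters by minimum member cell_id
    min_id <- vapply(
      split(asg$cell_id, asg$cluster),
      min, character(1)
    )
    relabel <- stats::setNames(
      seq_along(min_id),
      names(min_id)[order(min_id)]
    )
    ord <- relabel[as.character(asg$cluster)]
    out[[aid]] <- tibble::tibble(
      acinus_id = aid,
      cell_id = asg$cell_id,
      cluster_id = sprintf("c%d", ord)
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      acinus_id = character(0), cell_id = character(0),
      cluster_id = character(0)
    ))
  }
  dplyr::bind_rows(out)
}

#' Per-cluster geometry: centroid and sphere diameter
#'
#' The cluster sphere is centred at the unweighted centroid of the member
#' (transduced) cells with diameter equal to the distance between the two
#' farthest members; a singleton cluster has sphere diameter 0.
#'
#' @param cohort A [cohort_table][as_cohort_table] (start timepoint used).
#' @param assignments Output of [identify_clusters()].
#' @return Tibble: `acinus_id`, `cluster_id`, `n_members`, `com_x`,
#'   `com_y`, `com_z`, `sphere_diameter`.
#' @export
cluster_geometry <- function(cohort, assignments) {
  if ("start" %in% cohort$timepoint) {
    cohort <- cohort[cohort$timepoint == "start", , drop = FALSE]
  }
  joined <- dplyr::inner_join(
    assignments,
    cohort[, c("acinus_id", "cell_id", "x", "y", "z")],
    by = c("acinus_id", "cell_id")
  )
  if (nrow(joined) != nrow(assignments)) {
    stop("assignments reference cells absent from the cohort", call. = FALSE)
  }
  grp <- dplyr::group_by(joined, .data$acinus_id, .data$cluster_id)
  dplyr::summarise(grp,
    n_members = dplyr::n(),
    com_x = mean(.data$x),
    com_y = mean(.data$y),
    com_z = mean(.data$z),
    sphere_diameter = .max_pairwise_distance(cbind(.data$x, .data$y, .data$z)),
    .groups = "drop"
  )
}

.max_pairwise_distance <- function(m) {
  if (nrow(m) < 2) {
    return(0)
  }
  max(stats::dist(m))
}

#' @export
print.oncoprox_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<complete-linkage dendrogram> %d leaves, %d merges, max height %.3g um\n",
    x$n, length(x$height), if (length(x$height)) max(x$height) else 0
  ))
  invisible(x)
}
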