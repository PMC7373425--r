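#' Cell-contact rule from the cell-diameter distribution
#'
#' Two cells are presumed in contact if their centres are strictly less
#' than the average cell diameter plus two standard deviations apart.
#'
#' @param mean_diameter,sd_diameter Mean and standard deviation of the
#'   equivalent-sphere cell diameter, micrometres.
#' @return List with `mean_diameter`, `sd_diameter` and the derived
#'   `threshold = mean_diameter + 2 * sd_diameter`.
#' @export
contact_rule <- function(mean_diameter = 10, sd_diameter = 1) {
  threshold <- mean_diameter + 2 * sd_diameter
  if (!is.finite(threshold) || threshold <= 0) {
    stop("contact threshold must be positive", call. = FALSE)
  }
  list(
    mean_diameter = mean_diameter, sd_diameter = sd_diameter,
    threshold = threshold
  )
}

#' Whole-acinus geometry
#'
#' The acinus is approximated as a sphere whose diameter is the distance
#' between its two most distant cells (Dmax); cell density is the number
#' of cells divided by the surface area of that sphere,
#' `4 * pi * (Dmax/2)^2 = pi * Dmax^2`.
#'
#' @param cells Cell records of one acinus at one timepoint.
#' @return List: `n_cells`, `d_max`, `surface_area` (um^2), `density`
#'   (cells/um^2).
#' @export
acinus_geometry <- function(cells) {
  n <- nrow(cells)
  if (n < 2) {
    stop("degenerate acinus geometry: fewer than 2 cells", call. = FALSE)
  }
  d_max <- .max_pairwise_distance(as.matrix(cells[, c("x", "y", "z")]))
  if (d_max <= 0) {
    stop("degenerate acinus geometry: all cells coincident (Dmax = 0)",
      call. = FALSE
    )
  }
  surface_area <- pi * d_max^2
  list(
    n_cells = n, d_max = d_max, surface_area = surface_area,
    density = n / surface_area
  )
}

#' Cells inside a cluster's sphere volume
#'
#' The cluster volume is the closed ball centred at the centroid of the
#' member (transduced) cells with diameter equal to the distance between
#' the two farthest members. For a singleton the ball has radius 0 and
#' contains the member itself plus any exactly coincident cell. Note that
#' members of a spread-out cluster can lie outside their own cluster
#' volume (e.g. an equilateral triple with side D has its members at
#' D/sqrt(3) > D/2 from the centroid). Membership carries a 1e-9 um
#' numerical slack so that boundary cells — in particular the two
#' farthest members, which sit exactly on the sphere — are counted
#' inside.
#'
#' @param member_ids Character vector of member (transduced) cell ids.
#' @param cells All cell records of the acinus (any transduction state).
#' @return Character vector of `cell_id`s inside the closed ball.
#' @export
cluster_volume_membership <- function(member_ids, cells) {
  stopifnot(length(member_ids) >= 1)
  mem <- cells[cells$cell_id %in% member_ids, , drop = FALSE]
  if (nrow(mem) != length(unique(member_ids))) {
    stop("member cell(s) missing from the acinus table", call. = FALSE)
  }
  m <- as.matrix(mem[, c("x", "y", "z")])
  com <- colMeans(m)
  radius <- .max_pairwise_distance(m) / 2
  all_xyz <- as.matrix(cells[, c("x", "y", "z")])
  dd <- sqrt(colSums((t(all_xyz) - com)^2))
  # 1e-9 um slack: the two farthest members sit exactly on the sphere and
  # must not fall out through floating-point rounding
  cells$cell_id[dd <= radius + 1e-9]
}

#' Count contacts between the transduced members of a cluster
#'
#' @param member_xyz Matrix of member coordinates (rows = cells).
#' @param rule A [contact_rule()].
#' @return Number of unordered member pairs with centre distance strictly
#'   below the contact threshold.
#' @export
contact_count <- function(member_xyz, rule) {
  if (nrow(member_xyz) < 2) {
    return(0L)
  }
  sum(stats::dist(member_xyz) < rule$threshold)
}

#' Names of the nine cluster features
#'
#' In fixed order: cells in the acinus; acinus cell density (cells per
#' um^2 of acinus sphere surface); transduced cells in the acinus; cells
#' in the cluster volume; transduced cells in the cluster; mean pairwise
#' distance between all cells in the cluster volume; mean pairwise
#' distance between transduced member cells; fraction of transduced cells
#' in the cluster volume; contacts between transduced member cells.
#'
#' @return Character vector of length 9.
#' @export
cluster_feature_names <- function() {
  c(
    "n_cells_acinus", "density_acinus", "n_transduced_acinus",
    "n_cells_volume", "n_transduced_cluster", "mean_dist_volume",
    "mean_dist_transduced", "frac_transduced_volume", "n_contacts_transduced"
  )
}

#' Compute the nine per-cluster features
#'
#' One row per cluster. Degenerate conventions: a singleton cluster has
#' `n_transduced_cluster = 1`, `mean_dist_transduced = 0` and
#' `n_contacts_transduced = 0`; a cluster volume containing fewer than two
#' cells has `mean_dist_volume = 0`; an empty cluster volume (possible for
#' spread-out clusters, see [cluster_volume_membership()]) has
#' `frac_transduced_volume = 0`.
#'
#' Acini that fail [acinus_geometry()] (fewer than 2 cells, or all cells
#' coincident) are excluded with a warning.
#'
#' @param cohort A [cohort_table][as_cohort_table] (start timepoint used).
#' @param assignments Output of [identify_clusters()].
#' @param outcomes Optional tibble (`acinus_id`, `cluster_id`, `tumor`),
#'   e.g. from [annotate_outcomes()]; joined in as a `tumor` column.
#' @param diameter_mean,diameter_sd Fallback contact-rule statistics
#'   (micrometres) used for acini without a `diameter` column; when every
#'   cell of an acinus carries a diameter, the rule is computed from that
#'   acinus' own diameter distribution.
#' @return Tibble of cluster features (one row per cluster) with
#'   `acinus_id`, `cluster_id`, `sphere_diameter`, the nine columns of
#'   [cluster_feature_names()], and `tumor` when outcomes are supplied.
#' @export
compute_features <- function(cohort, assignments, outcomes = NULL,
                             diameter_mean = 10, diameter_sd = 1) {
  if ("start" %in% cohort$timepoint) {
    cohort <- cohort[cohort$timepoint == "start", , drop = FALSE]
  }
  rows <- list()
  for (aid in sort(unique(assignments$acinus_id))) {
    cells <- cohort[cohort$acinus_id == aid, , drop = FALSE]
    geom <- tryCatch(acinus_geometry(cells), error = function(e) {
      warning("acinus '", aid, "' excluded: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(geom)) next
    diam <- cells[["diameter"]]
    rule <- if (!is.null(diam) && length(diam) >= 2 && !anyNA(diam)) {
      contact_rule(mean(diam), stats::sd(diam))
    } else {
      contact_rule(diameter_mean, diameter_sd)
    }
    asg <- assignments[assignments$acinus_id == aid, , drop = FALSE]
    n_transduced_acinus <- sum(cells$transduced)
    for (cid in unique(asg$cluster_id)) {
      member_ids <- asg$cell_id[asg$cluster_id == cid]
      mem <- cells[match(member_ids, cells$cell_id), , drop = FALSE]
      mem_xyz <- as.matrix(mem[, c("x", "y", "z")])
      in_volume <- cluster_volume_membership(member_ids, cells)
      vol_cells <- cells[cells$cell_id %in% in_volume, , drop = FALSE]
      vol_xyz <- as.matrix(vol_cells[, c("x", "y", "z")])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        acinus_id = aid,
        cluster_id = cid,
        sphere_diameter = .max_pairwise_distance(mem_xyz),
        n_cells_acinus = geom$n_cells,
        density_acinus = geom$density,
        n_transduced_acinus = n_transduced_acinus,
        n_cells_volume = nrow(vol_cells),
        n_transduced_cluster = nrow(mem),
        mean_dist_volume = if (nrow(vol_cells) >= 2) mean(stats::dist(vol_xyz)) else 0,
        mean_dist_transduced = if (nrow(mem) >= 2) mean(stats::dist(mem_xyz)) else 0,
        frac_transduced_volume = if (nrow(vol_cells) >= 1) {
          sum(vol_cells$transduced) / nrow(vol_cells)
        } else {
          0
        },
        n_contacts_transduced = contact_count(mem_xyz, rule)
      )
    }
  }
  features <- dplyr::bind_rows(rows)
  if (!is.null(outcomes)) {
    features <- dplyr::left_join(features,
      outcomes[, c("acinus_id", "cluster_id", "tumor")],
      by = c("acinus_id", "cluster_id")
    )
  }
  features
}

#' Attach tumour outcomes to clusters
#'
#' A cluster is associated with a tumour outcome if any of its cells leads
#' to tumour formation. Two modes:
#' \describe{
#'   \item{explicit}{`annotations` supplies (`acinus_id`, `cluster_id`,
#'     `tumor`) for every cluster; values are copied verbatim. Missing
#'     clusters raise an error listing their ids.}
#'   \item{derivation}{`lineage` supplies per-cell fold expansion over the
#'     observation window (`acinus_id`, `cell_id`, `fold_expansion`); a
#'     cluster is scored `tumor = TRUE` when any member's fold expansion is
#'     at least `fold_threshold`. The default threshold of 4 is an
#'     implementation heuristic standing in for the phenotypic definition
#'     of tumour formation (multilayering, increased proliferation), which
#'     is not reducible to a single number; tune it to the experiment.}
#' }
#'
#' @param assignments Output of [identify_clusters()].
#' @param annotations Optional explicit outcome table.
#' @param lineage Optional per-cell lineage table (derivation mode).
#' @param fold_threshold Fold-expansion threshold for derivation mode.
#' @return Tibble: `acinus_id`, `cluster_id`, `tumor`.
#' @export
annotate_outcomes <- function(assignments, annotations = NULL, lineage = NULL,
                              fold_threshold = 4) {
  clusters <- dplyr::distinct(assignments[, c("acinus_id", "cluster_id")])
  if (!is.null(annotations)) {
    out <- dplyr::left_join(clusters,
      tibble::as_tibble(annotations)[, c("acinus_id", "cluster_id", "tumor")],
      by = c("acinus_id", "cluster_id")
    )
    if (anyNA(out$tumor)) {
      miss <- out[is.na(out$tumor), ]
      stop(
        "no outcome annotation for cluster(s): ",
        paste(paste(miss$acinus_id, miss$cluster_id, sep = "/"), collapse = ", "),
        call. = FALSE
      )
    }
    return(out)
  }
  if (is.null(lineage)) {
    stop("either annotations or a lineage table must be supplied", call. = FALSE)
  }
  joined <- dplyr::left_join(assignments,
    tibble::as_tibble(lineage)[, c("acinus_id", "cell_id", "fold_expansion")],
    by = c("acinus_id", "cell_id")
  )
  joined$fold_expansion[is.na(joined$fold_expansion)] <- 1
  grp <- dplyr::group_by(joined, .data$acinus_id, .data$cluster_id)
  dplyr::summarise(grp,
    tumor = any(.data$fold_expansion >= fold_threshold),
    .groups = "drop"
  )
}

#' Per-acinus start/end summaries and tumour vs non-tumour comparisons
#'
#' For each acinus present at both timepoints: cell and transduced-cell
#' counts, acinus cell density at start and end, and per-population
#' proliferation rates `(N_end - N_start) / N_start` for transduced and
#' normal cells (undefined — `NA` — when the population starts at 0).
#' Acini are flagged `has_tumor` when any of their clusters has a tumour
#' outcome, and tumour vs non-tumour acini are compared per summary
#' feature with a two-sided Wilcoxon rank-sum test (p-values reported
#' unadjusted plus a Benjamini-Hochberg column).
#'
#' @param cohort_start,cohort_end Cohort tables at the two timepoints.
#' @param outcomes Cluster outcome tibble (`acinus_id`, `cluster_id`,
#'   `tumor`).
#' @return List of class `acinus_summary`: `summary` (one row per acinus)
#'   and `tests` (one row per compared feature).
#' @export
acinus_summaries <- function(cohort_start, cohort_end, outcomes) {
  end_only <- setdiff(unique(cohort_end$acinus_id), unique(cohort_start$acinus_id))
  if (length(end_only) > 0) {
    stop(
      "acini present at end but not start: ", paste(end_only, collapse = ", "),
      call. = FALSE
    )
  }
  acini <- intersect(unique(cohort_start$acinus_id), unique(cohort_end$acinus_id))
  if (length(acini) == 0) {
    stop("no acinus present at both timepoints", call. = FALSE)
  }
  one <- function(aid) {
    s <- cohort_start[cohort_start$acinus_id == aid, , drop = FALSE]
    e <- cohort_end[cohort_end$acinus_id == aid, , drop = FALSE]
    dens <- function(cells) {
      tryCatch(acinus_geometry(cells)$density, error = function(err) NA_real_)
    }
    rate <- function(n0, n1) if (n0 > 0) (n1 - n0) / n0 else NA_real_
    nt0 <- sum(s$transduced)
    nt1 <- sum(e$transduced)
    nn0 <- sum(!s$transduced)
    nn1 <- sum(!e$transduced)
    tibble::tibble(
      acinus_id = aid,
      n_cells_start = nrow(s), n_cells_end = nrow(e),
      n_transduced_start = nt0, n_transduced_end = nt1,
      density_start = dens(s), density_end = dens(e),
      prolif_rate_transduced = rate(nt0, nt1),
      prolif_rate_normal = rate(nn0, nn1),
      has_tumor = aid %in% outcomes$acinus_id[outcomes$tumor]
    )
  }
  summary <- dplyr::bind_rows(lapply(sort(acini), one))
  feats <- setdiff(names(summary), c("acinus_id", "has_tumor"))
  tests <- lapply(feats, function(f) {
    a <- summary[[f]][summary$has_tumor]
    b <- summary[[f]][!summary$has_tumor]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      return(tibble::tibble(feature = f, statistic = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    p <- wt$p.value
    if (is.nan(p)) p <- 1 # zero-variance ties: no evidence of a difference
    tibble::tibble(
      feature = f, statistic = unname(wt$statistic),
      p_value = p
    )
  })
  tests <- dplyr::bind_rows(tests)
  tests$p_adj_bh <- stats::p.adjust(tests$p_value, method = "BH")
  structure(list(summary = summary, tests = tests), class = "acinus_summary")
}

#' @export
print.acinus_summary <- function(x, ...) {
  cat(sprintf(
    "<acinus_summary> %d acini (%d with tumour outcome)\n",
    nrow(x$summary), sum(x$summary$has_tumor)
  ))
  print(x$tests)
  invisible(x)
}
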