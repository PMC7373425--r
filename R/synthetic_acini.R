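#' Configuration for the synthetic acinus generator
#'
#' The generator emulates the statistical structure the proximity analysis
#' assumes: small acini whose cells form a monolayer shell around a lumen,
#' with a minority of transduced cells whose spatial aggregation is
#' controllable, and binary tumour outcomes drawn from a logistic model on
#' the number of transduced cells per cluster.
#'
#' Defaults describe a cohort of 20 acini of 15-60 cells on shells of
#' 20-40 um radius (radius coupled to cell count so surface density stays
#' roughly constant), 4-11 transduced cells per acinus (mean 7.5), strong
#' aggregation (0.9) around 2-4 seed cells (transduction events are
#' independent, so several foci per acinus are the norm; the resulting
#' cluster sizes straddle the transition region of the outcome model,
#' which keeps the logistic coefficient identifiable), and an outcome
#' model with
#' `beta1 = ln 9` (each additional transduced cell in a cluster multiplies
#' the tumour odds by 9) and `beta0 = -3 ln 9` (a 3-cell cluster sits at
#' 50% tumour probability; isolated transduced cells almost never seed a
#' tumour).
#'
#' @param n_acini Number of acini in a cohort.
#' @param cells_per_acinus Integer range `c(lo, hi)` of cells per acinus.
#' @param shell_radius Range `c(lo, hi)` of shell radii, micrometres.
#' @param radial_jitter SD of radial noise around the shell, micrometres.
#' @param min_separation Minimum pairwise centre distance, micrometres.
#' @param n_transduced Integer range of transduced cells per acinus.
#' @param aggregation Real in \[0, 1\]: 0 = transduced cells sampled
#'   uniformly among cells, 1 = maximally co-located around the seed cells.
#' @param n_seeds Integer range of intended transduced clusters per acinus.
#' @param beta0,beta1 Intercept and per-transduced-cell slope (log-odds)
#'   of the cluster-level tumour outcome model.
#' @param cell_diameter_mean,cell_diameter_sd Normal (truncated at > 0)
#'   cell-diameter distribution, micrometres.
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_acini = 20L,
                             cells_per_acinus = c(15L, 60L),
                             shell_radius = c(20, 40),
                             radial_jitter = 1.5,
                             min_separation = 8,
                             n_transduced = c(4L, 11L),
                             aggregation = 0.9,
                             n_seeds = c(2L, 4L),
                             beta0 = -3 * log(9),
                             beta1 = log(9),
                             cell_diameter_mean = 10,
                             cell_diameter_sd = 1,
                             seed = 1L) {
  rng2 <- function(v) if (length(v) == 1L) c(v, v) else sort(v[1:2])
  config <- list(
    n_acini = as.integer(n_acini),
    cells_per_acinus = rng2(as.integer(cells_per_acinus)),
    shell_radius = rng2(shell_radius),
    radial_jitter = radial_jitter,
    min_separation = min_separation,
    n_transduced = rng2(as.integer(n_transduced)),
    aggregation = aggregation,
    n_seeds = rng2(as.integer(n_seeds)),
    beta0 = beta0,
    beta1 = beta1,
    cell_diameter_mean = cell_diameter_mean,
    cell_diameter_sd = cell_diameter_sd,
    seed = as.integer(seed)
  )
  if (config$n_acini < 1) stop("n_acini must be >= 1", call. = FALSE)
  if (config$min_separation <= 0) stop("min_separation must be > 0", call. = FALSE)
  if (config$shell_radius[1] <= config$min_separation) {
    stop("shell_radius must exceed min_separation", call. = FALSE)
  }
  if (config$n_transduced[2] > config$cells_per_acinus[1]) {
    stop("n_transduced cannot exceed cells_per_acinus", call. = FALSE)
  }
  if (config$aggregation < 0 || config$aggregation > 1) {
    stop("aggregation must lie in [0, 1]", call. = FALSE)
  }
  if (config$radial_jitter < 0) stop("radial_jitter must be >= 0", call. = FALSE)
  if (config$cell_diameter_mean <= 0) stop("cell_diameter_mean must be > 0", call. = FALSE)
  if (config$n_seeds[1] < 1) stop("n_seeds must be >= 1", call. = FALSE)
  structure(config, class = "synthetic_config")
}

# Sample an integer uniformly from an inclusive range.
.sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
}

#' Generate one synthetic acinus
#'
#' Cells are placed on a sphere (radius interpolated within
#' `shell_radius` according to the drawn cell count, so larger acini get
#' larger shells) with Gaussian radial jitter, by dart throwing under the
#' minimum-separation constraint. If a placement round fails after a
#' bounded number of attempts the separation is relaxed by 5% with a
#' warning; after 20 relaxations a generation error is raised. Requests
#' that exceed even a hexagonal packing bound at the fully relaxed
#' separation fail immediately with the same error.
#'
#' Transduction: `n_seeds` seed cells are chosen uniformly; each remaining
#' transduced label goes, with probability `aggregation`, to the unlabelled
#' cell nearest any seed, otherwise to a uniformly random unlabelled cell.
#' Each transduced cell's intended cluster is its nearest seed.
#'
#' Uses the current RNG state; seed management is done by
#' [generate_cohort()].
#'
#' @param config A [synthetic_config()].
#' @param acinus_id Identifier for the generated acinus.
#' @return List: `cells` (canonical cell tibble, `timepoint = "start"`)
#'   and `truth` (tibble `cell_id`, `seed_cluster` for transduced cells).
#' @export
generate_acinus <- function(config, acinus_id = "a01") {
  n <- .sample_range(config$cells_per_acinus)
  span <- config$cells_per_acinus
  frac <- if (span[2] > span[1]) (n - span[1]) / (span[2] - span[1]) else 0.5
  radius <- config$shell_radius[1] + frac * diff(config$shell_radius)

  sep <- config$min_separation
  # fast infeasibility check: even hexagonal packing cannot place n points
  # at the fully relaxed separation (20 rounds of 5%) on this shell
  sep_floor <- sep * 0.95^20
  if (4 * pi * radius^2 / (sqrt(3) / 2 * sep_floor^2) < n) {
    stop(
      "infeasible packing: cannot place ", n, " cells on a ", round(radius, 1),
      " um shell at the requested separation",
      call. = FALSE
    )
  }
  xyz <- NULL
  for (round in seq_len(21L)) {
    if (round > 20L) {
      stop(
        "infeasible packing: cannot place ", n, " cells on a ", round(radius, 1),
        " um shell at the requested separation",
        call. = FALSE
      )
    }
    xyz <- .dart_throw_shell(n, radius, config$radial_jitter, sep,
      max_attempts = 200L * n
    )
    if (!is.null(xyz)) {
      if (round > 1L) {
        warning(sprintf(
          "min_separation relaxed to %.3g um for acinus '%s'", sep, acinus_id
        ), call. = FALSE)
      }
      break
    }
    sep <- sep * 0.95
  }

  m <- min(.sample_range(config$n_transduced), n)
  k <- min(.sample_range(config$n_seeds), m)
  # seeds are kept mutually separated (>= 3 x min_separation when possible)
  # so the intended clusters are geometrically distinct and the ground
  # truth well defined; bounded rejection keeps the draw reproducible
  seed_sep <- 3 * config$min_separation
  best_seeds <- NULL
  best_min_d <- -Inf
  for (try in seq_len(200L)) {
    cand <- sample.int(n, k)
    min_d <- if (k <= 1L) Inf else min(stats::dist(xyz[cand, , drop = FALSE]))
    if (min_d > best_min_d) {
      best_min_d <- min_d
      best_seeds <- cand
    }
    if (best_min_d >= seed_sep) break
  }
  seeds <- best_seeds
  labelled <- seeds
  if (m > k) {
    for (i in seq_len(m - k)) {
      pool <- setdiff(seq_len(n), labelled)
      if (stats::runif(1) < config$aggregation) {
        d_to_seed <- vapply(pool, function(p) {
          min(sqrt(colSums((t(xyz[seeds, , drop = FALSE]) - xyz[p, ])^2)))
        }, numeric(1))
        pick <- pool[which.min(d_to_seed)]
      } else {
        pick <- pool[sample.int(length(pool), 1L)]
      }
      labelled <- c(labelled, pick)
    }
  }
  transduced <- seq_len(n) %in% labelled

  diam <- stats::rnorm(n, config$cell_diameter_mean, config$cell_diameter_sd)
  while (any(diam <= 0)) {
    bad <- diam <= 0
    diam[bad] <- stats::rnorm(sum(bad), config$cell_diameter_mean, config$cell_diameter_sd)
  }

  cell_id <- sprintf("c%03d", seq_len(n))
  seed_of <- vapply(labelled, function(p) {
    seeds[which.min(sqrt(colSums((t(xyz[seeds, , drop = FALSE]) - xyz[p, ])^2)))]
  }, integer(1))
  list(
    cells = tibble::tibble(
      acinus_id = acinus_id,
      cell_id = cell_id,
      timepoint = "start",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      transduced = transduced,
      diameter = diam
    ),
    truth = tibble::tibble(
      cell_id = cell_id[labelled],
      seed_cluster = match(seed_of, sort(unique(seed_of)))
    )
  )
}

# Place n points on a jittered sphere shell with pairwise distance >= sep.
# Returns NULL when max_attempts is exhausted.
.dart_throw_shell <- function(n, radius, jitter, sep, max_attempts) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- radius + stats::rnorm(1, 0, jitter)
    p <- u * r
    if (placed == 0L ||
      min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2))) >= sep) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
  }
  if (placed < n) NULL else pts
}

#' Draw cluster-level tumour outcomes from the logistic model
#'
#' `P(tumor) = plogis(beta0 + beta1 * n_transduced_in_cluster)`; outcomes
#' are Bernoulli draws from the current RNG state.
#'
#' @param clusters Tibble with `acinus_id`, `cluster_id` and
#'   `n_transduced_cluster` (one row per cluster).
#' @param beta0,beta1 Outcome-model coefficients (log-odds scale).
#' @return Tibble: `acinus_id`, `cluster_id`, `p_tumor`, `tumor`.
#' @export
assign_outcomes <- function(clusters, beta0, beta1) {
  stopifnot(nrow(clusters) >= 1)
  p <- stats::plogis(beta0 + beta1 * clusters$n_transduced_cluster)
  tibble::tibble(
    acinus_id = clusters$acinus_id,
    cluster_id = clusters$cluster_id,
    p_tumor = p,
    tumor = stats::runif(nrow(clusters)) < p
  )
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws `n_acini` acini with per-acinus RNG streams derived
#' deterministically from `config$seed`, so cohorts are reproducible and
#' acini are independent (shrinking the cohort does not change the acini
#' that remain). Clusters are then identified with the package's own
#' clustering and tumour outcomes are drawn at cluster level from the
#' logistic outcome model, emulating the cluster-level tracking annotation
#' of the real experiment.
#'
#' Optionally an end-timepoint snapshot is synthesised for the
#' start/end summary statistics: transduced cells of tumour clusters
#' expand `tumor_expansion`-fold, other populations grow by
#' `normal_growth`; daughter cells are scattered near their parents. This
#' is a static endpoint emulation, not a growth-dynamics simulation.
#'
#' @param config A [synthetic_config()].
#' @param with_end Also synthesise the end timepoint (default `TRUE`).
#' @param tumor_expansion Fold expansion of transduced cells in tumour
#'   clusters between timepoints.
#' @param normal_growth Fold growth of all other cells.
#' @param clustering Optional list of [identify_clusters()] parameters.
#' @return List of class `synthetic_cohort`: `cohort` (cohort_table,
#'   start + optional end rows), `assignments`, `clusters` (per-cluster
#'   geometry plus `n_transduced_cluster`), `outcomes`, `truth`
#'   (per-acinus intended seed-cluster membership) and `config`.
#' @export
generate_cohort <- function(config, with_end = TRUE, tumor_expansion = 4,
                            normal_growth = 1.3, clustering = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit(
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    )
    set.seed(s)
    expr
  }
  acinus_seeds <- withr_seed(config$seed, sample.int(2147483646L, config$n_acini + 1L))
  ids <- sprintf("a%02d", seq_len(config$n_acini))
  pieces <- vector("list", config$n_acini)
  truths <- vector("list", config$n_acini)
  for (i in seq_len(config$n_acini)) {
    res <- withr_seed(acinus_seeds[i], generate_acinus(config, acinus_id = ids[i]))
    pieces[[i]] <- res$cells
    truths[[i]] <- tibble::tibble(
      acinus_id = ids[i], res$truth
    )
  }
  cohort <- as_cohort_table(
    dplyr::bind_rows(pieces),
    provenance = list(source = "synthetic", seed = config$seed)
  )
  assignments <- do.call(
    identify_clusters,
    c(list(cohort = cohort), clustering)
  )
  geom <- cluster_geometry(cohort, assignments)
  counts <- dplyr::count(assignments, .data$acinus_id, .data$cluster_id,
    name = "n_transduced_cluster"
  )
  clusters <- dplyr::inner_join(geom, counts, by = c("acinus_id", "cluster_id"))
  outcomes <- withr_seed(
    acinus_seeds[config$n_acini + 1L],
    assign_outcomes(clusters, config$beta0, config$beta1)
  )
  if (with_end) {
    end <- withr_seed(
      acinus_seeds[config$n_acini + 1L] + 1L,
      .synthesise_end(cohort, assignments, outcomes, tumor_expansion, normal_growth)
    )
    cohort <- as_cohort_table(
      dplyr::bind_rows(cohort, end),
      provenance = attr(cohort, "provenance")
    )
  }
  structure(
    list(
      cohort = cohort, assignments = assignments, clusters = clusters,
      outcomes = outcomes, truth = dplyr::bind_rows(truths), config = config
    ),
    class = "synthetic_cohort"
  )
}

.synthesise_end <- function(cohort, assignments, outcomes, tumor_expansion,
                            normal_growth) {
  start <- cohort[cohort$timepoint == "start", , drop = FALSE]
  tumor_key <- paste(outcomes$acinus_id, outcomes$cluster_id)[outcomes$tumor]
  cell_key <- paste(assignments$acinus_id, assignments$cell_id)
  cluster_key <- paste(assignments$acinus_id, assignments$cluster_id)
  in_tumor_cluster <- cell_key[cluster_key %in% tumor_key]
  rows <- list()
  for (i in seq_len(nrow(start))) {
    copies <- if (paste(start$acinus_id[i], start$cell_id[i]) %in% in_tumor_cluster) {
      tumor_expansion
    } else {
      normal_growth
    }
    n_copies <- floor(copies) + (stats::runif(1) < copies - floor(copies))
    if (n_copies == 0) next
    jit <- matrix(stats::rnorm(3 * n_copies, 0, 2), ncol = 3)
    jit[1, ] <- 0 # the original cell keeps its position
    rows[[length(rows) + 1L]] <- tibble::tibble(
      acinus_id = start$acinus_id[i],
      cell_id = sprintf("%s_t%d", start$cell_id[i], seq_len(n_copies)),
      timepoint = "end",
      x = start$x[i] + jit[, 1],
      y = start$y[i] + jit[, 2],
      z = start$z[i] + jit[, 3],
      transduced = start$transduced[i],
      diameter = rep(start$diameter[i], n_copies),
      lineage_id = start$cell_id[i]
    )
  }
  dplyr::bind_rows(rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d acini, %d cells at start, %d transduced, %d clusters (%d tumour)\n",
    length(unique(x$cohort$acinus_id)),
    sum(x$cohort$timepoint == "start"),
    sum(x$cohort$transduced[x$cohort$timepoint == "start"]),
    nrow(x$clusters), sum(x$outcomes$tumor)
  ))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " - ")))
  }
  invisible(x)
}
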