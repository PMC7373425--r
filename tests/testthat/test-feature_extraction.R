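test_that("acinus geometry follows the sphere-surface-density formula", {
  cells <- make_cells(
    rbind(c(0, 0, 0), c(10, 0, 0), c(5, 2, 0), c(5, -2, 0)),
    transduced = rep(FALSE, 4)
  )
  geom <- acinus_geometry(cells)
  expect_equal(geom$d_max, 10)
  expect_equal(geom$surface_area, 100 * pi)
  expect_equal(geom$density, 4 / (100 * pi), tolerance = 1e-12)

  coincident <- make_cells(rbind(c(1, 1, 1), c(1, 1, 1)), transduced = c(FALSE, FALSE))
  expect_error(acinus_geometry(coincident), "coincident")
  expect_error(acinus_geometry(coincident[1, ]), "fewer than 2")

  set.seed(21)
  xyz <- matrix(rnorm(60, sd = 25), ncol = 3)
  rnd <- make_cells(xyz, transduced = rep(FALSE, 20))
  expect_equal(acinus_geometry(rnd)$d_max, max(oracle_pairwise(xyz)))
})

test_that("cluster volume membership is the closed ball on the member span", {
  # 2-member cluster spanning (0,0,0)-(10,0,0): centre (5,0,0), radius 5
  cells <- make_cells(
    rbind(c(0, 0, 0), c(10, 0, 0), c(5, 0, 0), c(11, 0, 0)),
    transduced = c(TRUE, TRUE, FALSE, FALSE)
  )
  inside <- cluster_volume_membership(c("c001", "c002"), cells)
  expect_setequal(inside, c("c001", "c002", "c003")) # boundary cells included

  # singleton: radius-0 ball holds the member (and coincident cells only)
  inside <- cluster_volume_membership("c001", cells)
  expect_identical(inside, "c001")

  # equilateral members sit at D/sqrt(3) > D/2 from their own centroid
  D <- 12
  tri <- D * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  cells <- make_cells(tri, transduced = rep(TRUE, 3))
  expect_length(cluster_volume_membership(c("c001", "c002", "c003"), cells), 0)
})

test_that("contact counting is strict at the threshold", {
  rule <- contact_rule(10, 1) # threshold 12
  expect_equal(rule$threshold, 12)
  expect_equal(contact_count(rbind(c(0, 0, 0), c(11.9, 0, 0)), rule), 1)
  expect_equal(contact_count(rbind(c(0, 0, 0), c(12, 0, 0)), rule), 0)
  # 4 mutually-in-contact members -> 4 choose 2
  sq <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0))
  expect_equal(contact_count(sq, rule), 6)
})

test_that("feature rows match hand-computed values and singleton conventions", {
  # acinus: 2-member cluster 10 um apart, one singleton 80 um away,
  # plus a far normal cell fixing the acinus span
  cells <- make_cells(
    rbind(c(0, 0, 0), c(10, 0, 0), c(80, 0, 0), c(0, 60, 0)),
    transduced = c(TRUE, TRUE, TRUE, FALSE)
  )
  asg <- identify_clusters(cells)
  feats <- compute_features(cells, asg)
  feats <- feats[order(feats$cluster_id), ]
  expect_equal(nrow(feats), 2)

  pair <- feats[feats$n_transduced_cluster == 2, ]
  expect_equal(pair$n_cells_acinus, 4)
  expect_equal(pair$n_transduced_acinus, 3)
  expect_equal(pair$n_cells_volume, 2)
  expect_equal(pair$mean_dist_volume, 10)
  expect_equal(pair$mean_dist_transduced, 10)
  expect_equal(pair$frac_transduced_volume, 1)
  expect_equal(pair$n_contacts_transduced, 1) # 10 < default threshold 12

  singleton <- feats[feats$n_transduced_cluster == 1, ]
  expect_equal(singleton$sphere_diameter, 0)
  expect_equal(singleton$n_cells_volume, 1)
  expect_equal(singleton$mean_dist_volume, 0)
  expect_equal(singleton$mean_dist_transduced, 0)
  expect_equal(singleton$frac_transduced_volume, 1)
  expect_equal(singleton$n_contacts_transduced, 0)

  dmax <- max(oracle_pairwise(as.matrix(cells[, c("x", "y", "z")])))
  expect_equal(pair$density_acinus, 4 / (pi * dmax^2))
})

test_that("feature invariants hold across a large synthetic sweep", {
  rows <- list()
  for (s in 1:3) {
    sim <- generate_cohort(synthetic_config(n_acini = 120L, seed = s),
      with_end = FALSE
    )
    rows[[s]] <- compute_features(sim$cohort, sim$assignments,
      outcomes = sim$outcomes
    )
  }
  feats <- dplyr::bind_rows(rows)
  expect_gt(nrow(feats), 1000)
  expect_true(all(feats$n_transduced_cluster <= feats$n_transduced_acinus))
  expect_true(all(feats$n_transduced_acinus <= feats$n_cells_acinus))
  expect_true(all(feats$n_cells_volume >= 0))
  expect_true(all(feats$frac_transduced_volume >= 0 & feats$frac_transduced_volume <= 1))
  expect_true(all(
    feats$n_contacts_transduced <=
      feats$n_transduced_cluster * (feats$n_transduced_cluster - 1) / 2
  ))
  expect_true(all(feats$mean_dist_volume >= 0))
  expect_true(all(feats$mean_dist_transduced >= 0))
  expect_true(all(feats$sphere_diameter == 0 | feats$n_transduced_cluster > 1))
})

test_that("volume features agree exactly with a brute-force ball oracle", {
  set.seed(33)
  for (rep in seq_len(200)) {
    n <- sample(5:20, 1)
    xyz <- matrix(rnorm(3 * n, sd = 25), ncol = 3)
    n_members <- sample(1:min(5, n), 1)
    transduced <- seq_len(n) %in% sample.int(n, n_members)
    cells <- make_cells(xyz, transduced = transduced)
    member_ids <- cells$cell_id[transduced]
    inside <- cluster_volume_membership(member_ids, cells)
    oracle <- oracle_ball_members(xyz[transduced, , drop = FALSE], xyz)
    expect_setequal(inside, cells$cell_id[oracle])
  }
})

test_that("features are invariant under rigid motion", {
  sim <- generate_cohort(synthetic_config(n_acini = 3L, seed = 4L), with_end = FALSE)
  base <- compute_features(sim$cohort, sim$assignments)
  set.seed(9)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(123.4, -56.7, 89.1)
  moved <- sim$cohort
  xyz <- as.matrix(moved[, c("x", "y", "z")]) %*% t(rot)
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]
  after <- compute_features(moved, sim$assignments)
  for (col in cluster_feature_names()) {
    expect_equal(after[[col]], base[[col]], tolerance = 1e-9)
  }
})

test_that("outcome annotation copies explicit labels and derives from lineages", {
  cells <- two_cluster_acinus()
  asg <- identify_clusters(cells)
  ann <- tibble::tibble(
    acinus_id = "a01", cluster_id = c("c1", "c2"), tumor = c(TRUE, FALSE)
  )
  out <- annotate_outcomes(asg, annotations = ann)
  expect_identical(out$tumor[order(out$cluster_id)], c(TRUE, FALSE))
  expect_error(
    annotate_outcomes(asg, annotations = ann[1, ]),
    "c2"
  )

  lineage <- tibble::tibble(
    acinus_id = "a01",
    cell_id = c("c001", "c004"),
    fold_expansion = c(8, 1)
  )
  out <- annotate_outcomes(asg, lineage = lineage, fold_threshold = 4)
  out <- out[order(out$cluster_id), ]
  expect_identical(out$tumor, c(TRUE, FALSE)) # 8 >= 4; all others expand 1x
})

test_that("acinus summaries compute rates and detect shifted groups", {
  # 20 acini: two cells each at start (span 10), tumour acini double their
  # transduced population and carry +100 cells at end
  start <- list()
  end <- list()
  outcomes <- list()
  for (i in 1:20) {
    aid <- sprintf("a%02d", i)
    tumor <- i <= 10
    start[[i]] <- make_cells(
      rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5, 0), c(5, -5, 0)),
      transduced = c(TRUE, TRUE, FALSE, FALSE), acinus_id = aid
    )
    n_extra <- if (tumor) 104 else 0
    base_end <- rbind(
      c(0, 0, 0), c(10, 0, 0), c(5, 5, 0), c(5, -5, 0),
      matrix(runif(3 * n_extra, 0, 10), ncol = 3)
    )
    end[[i]] <- make_cells(base_end,
      transduced = c(TRUE, TRUE, rep(FALSE, 2 + n_extra)),
      acinus_id = aid, timepoint = "end"
    )
    outcomes[[i]] <- tibble::tibble(
      acinus_id = aid, cluster_id = "c1", tumor = tumor
    )
  }
  set.seed(12)
  res <- acinus_summaries(
    dplyr::bind_rows(start), dplyr::bind_rows(end), dplyr::bind_rows(outcomes)
  )
  expect_equal(nrow(res$summary), 20)
  expect_true(all(res$summary$prolif_rate_transduced == 0))
  expect_equal(
    res$summary$n_cells_end[res$summary$has_tumor][1], 108
  )
  cell_test <- res$tests[res$tests$feature == "n_cells_end", ]
  expect_lt(cell_test$p_value, 0.001)
  # identical groups: transduced counts never change
  trans_test <- res$tests[res$tests$feature == "n_transduced_end", ]
  expect_gt(trans_test$p_value, 0.9)
  expect_true(all(res$tests$p_adj_bh >= res$tests$p_value - 1e-12))
})

test_that("start 15 to end 30 normal cells is a proliferation rate of 1", {
  start <- make_cells(
    cbind(seq(0, 70, length.out = 15), 0, 0),
    transduced = rep(FALSE, 15)
  )
  end <- make_cells(
    cbind(seq(0, 70, length.out = 30), 0, 0),
    transduced = rep(FALSE, 30), timepoint = "end"
  )
  res <- acinus_summaries(
    start, end,
    tibble::tibble(acinus_id = "a01", cluster_id = "c1", tumor = FALSE)
  )
  expect_equal(res$summary$prolif_rate_normal, 1)
  expect_true(is.na(res$summary$prolif_rate_transduced)) # 0 at start
})
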