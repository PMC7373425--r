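# Shared fixture builders and independent oracles used across the suite.

# Build a minimal one-timepoint cell table from a coordinate matrix.
make_cells <- function(xyz, transduced, acinus_id = "a01", timepoint = "start",
                       diameter = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  df <- tibble::tibble(
    acinus_id = acinus_id,
    cell_id = sprintf("c%03d", seq_len(nrow(xyz))),
    timepoint = timepoint,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    transduced = transduced
  )
  if (!is.null(diameter)) df$diameter <- diameter
  df
}

# Independent double-loop Euclidean distances.
oracle_pairwise <- function(xyz) {
  n <- nrow(xyz)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  d
}

# Leaf sets under each internal node of an oncoprox dendrogram.
dend_leaf_sets <- function(dend) {
  sets <- vector("list", dend$n - 1L)
  leaf_set <- function(code) if (code < 0) -code else sets[[code]]
  for (m in seq_len(dend$n - 1L)) {
    sets[[m]] <- c(leaf_set(dend$merge[m, 1]), leaf_set(dend$merge[m, 2]))
  }
  sets
}

# Verify the complete-linkage property: every merge height equals the
# maximum pairwise distance between the two merged leaf sets.
check_complete_linkage_property <- function(dend, d) {
  if (dend$n < 2) {
    return(TRUE)
  }
  sets <- vector("list", dend$n - 1L)
  leaf_set <- function(code) if (code < 0) -code else sets[[code]]
  for (m in seq_len(dend$n - 1L)) {
    a <- leaf_set(dend$merge[m, 1])
    b <- leaf_set(dend$merge[m, 2])
    sets[[m]] <- c(a, b)
    expected <- max(d[a, b])
    if (abs(dend$height[m] - expected) > 1e-9) {
      return(FALSE)
    }
  }
  TRUE
}

# Independent closed-ball membership oracle for cluster volumes.
oracle_ball_members <- function(member_xyz, all_xyz) {
  com <- colMeans(matrix(member_xyz, ncol = 3))
  r <- 0
  m <- matrix(member_xyz, ncol = 3)
  if (nrow(m) >= 2) {
    for (i in seq_len(nrow(m) - 1)) {
      for (j in seq(i + 1, nrow(m))) {
        r <- max(r, sqrt(sum((m[i, ] - m[j, ])^2)))
      }
    }
  }
  r <- r / 2
  inside <- logical(nrow(all_xyz))
  for (i in seq_len(nrow(all_xyz))) {
    inside[i] <- sqrt(sum((all_xyz[i, ] - com)^2)) <= r + 1e-9
  }
  inside
}

# Write a small XLSX workbook (one sheet per element of `sheets`, each a
# data frame) through the system Python's openpyxl, for exercising the
# workbook reader on programmatically built fixtures.
write_xlsx_fixture <- function(sheets, path) {
  tmp <- tempfile("xlsx_sheets_")
  dir.create(tmp)
  for (nm in names(sheets)) {
    utils::write.csv(sheets[[nm]], file.path(tmp, paste0(nm, ".csv")),
      row.names = FALSE
    )
  }
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import csv, glob, os, sys",
    "from openpyxl import Workbook",
    sprintf("src, out = %s, %s", deparse(tmp), deparse(path)),
    "wb = Workbook()",
    "wb.remove(wb.active)",
    sprintf(
      "names = %s",
      paste0("[", paste(sprintf("'%s'", names(sheets)), collapse = ","), "]")
    ),
    "for name in names:",
    "    ws = wb.create_sheet(title=name)",
    "    with open(os.path.join(src, name + '.csv')) as fh:",
    "        for row in csv.reader(fh):",
    "            conv = []",
    "            for v in row:",
    "                try:",
    "                    conv.append(float(v))",
    "                except ValueError:",
    "                    conv.append(v)",
    "            ws.append(conv)",
    "wb.save(out)"
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    stop("xlsx fixture generation failed: ", paste(status, collapse = "\n"))
  }
  invisible(path)
}

# Small acinus with two well-separated transduced clusters and a ring of
# normal cells; deterministic coordinates.
two_cluster_acinus <- function() {
  members_a <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  members_b <- rbind(c(80, 0, 0), c(86, 0, 0), c(80, 6, 0))
  normals <- rbind(
    c(40, 20, 0), c(40, -20, 0), c(20, 30, 5), c(60, 30, -5),
    c(40, 0, 30), c(40, 0, -30)
  )
  xyz <- rbind(members_a, members_b, normals)
  make_cells(xyz, transduced = c(rep(TRUE, 6), rep(FALSE, 6)))
}
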