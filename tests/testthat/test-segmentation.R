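disk_mask <- function(n, cy, cx, r) {
  d <- sqrt(outer((1:n - cy)^2, rep(1, n)) + outer(rep(1, n), (1:n - cx)^2))
  d <= r
}

test_that("connected-component labelling is 8-connected with size filter", {
  m <- disk_mask(40, 10, 10, 5) | disk_mask(40, 30, 30, 5)
  lab <- segment_nuclei(m, min_area_px = 10)
  expect_equal(max(lab), 2)
  expect_equal(max(segment_nuclei(matrix(FALSE, 10, 10))), 0)
  # a 10-px object below min_area is removed
  small <- matrix(FALSE, 20, 20); small[5:6, 5:9] <- TRUE
  expect_equal(max(segment_nuclei(small, min_area_px = 30)), 0)
  # diagonal touch merges under 8-connectivity
  diag2 <- matrix(FALSE, 10, 10); diag2[3, 3] <- TRUE; diag2[4, 4] <- TRUE
  expect_equal(max(segment_nuclei(diag2, min_area_px = 1)), 1)
})

test_that("watershed partitions a two-nucleus blob into two covering cells", {
  n <- 60
  blob <- disk_mask(n, 30, 20, 14) | disk_mask(n, 30, 42, 14)
  nuc <- matrix(0L, n, n)
  nuc[disk_mask(n, 30, 20, 4)] <- 1L
  nuc[disk_mask(n, 30, 42, 4)] <- 2L
  cells <- segment_cells(blob, nuc)
  expect_setequal(unique(cells[cells > 0]), c(1, 2))
  expect_true(all(cells[blob] > 0))       # blob fully covered
  expect_true(all(cells[!blob] == 0))     # restricted to foreground
  # each cell contains exactly its seed nucleus
  expect_true(all(cells[nuc == 1L] == 1L))
  expect_true(all(cells[nuc == 2L] == 2L))
  # single nucleus -> cell equals blob
  one <- matrix(0L, n, n); one[disk_mask(n, 30, 30, 4)] <- 1L
  cells1 <- segment_cells(blob, one)
  expect_true(all((cells1 > 0) == blob))
})

test_that("no nuclei yields an empty cell mask with a warning", {
  expect_warning(out <- segment_cells(matrix(TRUE, 10, 10),
                                      matrix(0L, 10, 10)), "no nuclei")
  expect_equal(max(out), 0)
})

test_that("LD-cell assignment follows maximal intersection with tie-breaks", {
  cells <- matrix(0L, 20, 20)
  cells[, 1:10] <- 1L; cells[, 11:20] <- 3L
  lds <- matrix(0L, 20, 20)
  lds[3:5, 12:14] <- 1L            # fully inside cell 3
  lds[8:11, 9:14] <- 2L            # 8 px in cell 1, 16 px in cell 3
  lds[15, 9] <- 3L                 # single pixel in cell 1
  a <- assign_lds_to_cells(lds, cells)
  expect_equal(unname(a[["1"]]), 3L)
  expect_equal(unname(a[["2"]]), 3L)
  expect_equal(unname(a[["3"]]), 1L)
  # LD outside all cells is unassigned
  cells0 <- matrix(0L, 20, 20); cells0[1:5, 1:5] <- 1L
  lds0 <- matrix(0L, 20, 20); lds0[15:16, 15:16] <- 1L
  expect_true(is.na(assign_lds_to_cells(lds0, cells0)[["1"]]))
  # exact tie -> smaller cell label
  ldt <- matrix(0L, 20, 20); ldt[4:5, 9:12] <- 1L  # 4 px in each cell
  expect_equal(unname(assign_lds_to_cells(ldt, cells)[["1"]]), 1L)
  expect_error(assign_lds_to_cells(lds, matrix(0L, 5, 5)), "shapes differ")
})

test_that("assignment is stable under label permutation up to relabelling", {
  set.seed(21)
  cells <- matrix(0L, 30, 30); cells[, 1:15] <- 2L; cells[, 16:30] <- 5L
  lds <- matrix(0L, 30, 30); lds[3:5, 3:5] <- 1L; lds[10:12, 20:22] <- 2L
  a <- assign_lds_to_cells(lds, cells)
  # permute cell labels: 2 -> 9, 5 -> 4
  cells2 <- cells; cells2[cells == 2L] <- 9L; cells2[cells == 5L] <- 4L
  b <- assign_lds_to_cells(lds, cells2)
  expect_equal(unname(b[["1"]]), 9L)
  expect_equal(unname(b[["2"]]), 4L)
})

test_that("end-to-end segmentation recovers counts and shapes on synthetic fields", {
  cls <- test_classifiers()
  cfg <- test_cfg()
  cell_err <- integer(0); ld_err_rel <- numeric(0); ious <- numeric(0)
  for (s in c(31, 32, 33)) {
    fs <- simulate_field(ground_truth_effect(true_ratio = 3), cfg, seed = s)
    out <- analyze_field(fs$image, cls, af_control_mean(cfg),
                         min_nucleus_area = 30)
    cell_err <- c(cell_err, abs(max(out$cells) - max(fs$truth$cells)))
    ld_err_rel <- c(ld_err_rel,
                    abs(max(out$lds) - max(fs$truth$lds)) / max(fs$truth$lds))
    # mean per-cell IoU against matched truth cells
    per_cell <- vapply(seq_len(max(fs$truth$cells)), function(i) {
      tmask <- fs$truth$cells == i
      cand <- out$cells[tmask]
      j <- as.integer(names(which.max(table(cand[cand > 0]))))
      if (length(j) == 0) return(0)
      sum(tmask & out$cells == j) / sum(tmask | out$cells == j)
    }, 1)
    ious <- c(ious, mean(per_cell))
  }
  expect_true(all(cell_err <= 1))
  expect_true(all(ld_err_rel <= 0.15))
  expect_gte(mean(ious), 0.7)
})
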