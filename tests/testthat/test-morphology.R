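test_that("a single-sample soma SWC yields a degenerate one-compartment tree", {
  tree <- load_swc(swc_single_soma())
  expect_equal(nrow(tree$nodes), 1L)
  expect_equal(tree$nodes$path_distance, 0)
  expect_equal(tree$nodes$region, "soma")
  # sphere area conserved by the equivalent cylinder
  expect_equal(tree$nodes$area, 4 * pi * 5^2)
})

test_that("path distances accumulate Euclidean inter-sample distances", {
  tree <- load_swc(swc_collinear_apical())
  apical <- tree$nodes[tree$nodes$region == "apical", ]
  # independent oracle: cumulative point-to-point distances from the soma centre
  expect_equal(sort(apical$path_distance), c(100, 200, 300))
  expect_equal(max(apical$path_distance), 300)
  # child path distance = parent path distance + child length
  for (i in seq_len(nrow(tree$nodes))) {
    row <- tree$nodes[i, ]
    if (is.na(row$parent_id)) next
    parent <- tree$nodes[match(row$parent_id, tree$nodes$id), ]
    expect_equal(row$path_distance, parent$path_distance + row$length)
  }
})

test_that("malformed SWC input is rejected with a useful message", {
  bad_parent <- c(swc_single_soma(), swc_line(2, 4, 0, 50, 0, 1, -5))
  expect_error(load_swc(bad_parent), "parent")
  unknown_type <- c(swc_single_soma(), swc_line(2, 9, 0, 50, 0, 1, 1))
  expect_error(load_swc(unknown_type), "unknown SWC type")
  expect_error(load_swc("1 1 0 0 0 5"), "7 columns")
  self_parent <- c(swc_single_soma(), swc_line(2, 4, 0, 50, 0, 1, 2))
  expect_error(load_swc(self_parent), "structural error")
})

test_that("SWC round-trips through serialization at full precision", {
  txt <- c(swc_line(1, 1, 0.123456789, 0, 0, 5.5, -1),
           swc_line(2, 3, -20.25, 3.5, 1.125, 0.75, 1),
           swc_line(3, 3, -40.5, 7.5, 2.25, 0.6, 2))
  tree <- load_swc(txt)
  back <- load_swc(write_swc(tree))
  expect_equal(back$swc[, c("x", "y", "z", "radius")],
               tree$swc[, c("x", "y", "z", "radius")])
})

test_that("the reference morphology is deterministic and well-formed", {
  t1 <- make_reference_morphology()
  t2 <- make_reference_morphology()
  expect_identical(t1, t2)
  expect_silent(validate_tree(t1))
  n <- t1$nodes
  expect_true(max(n$path_distance[n$region == "apical"]) >= 600)
  expect_true(sum(n$region == "basal") > 0)
  expect_true(sum(n$region == "axon") >= 2)
  # discretization: no electrical segment beyond 20 um (soma excepted)
  expect_true(all(n$length[n$region != "soma"] <= 20 + 1e-9))
})

test_that("passive assignment follows the sigmoidal resistance profile", {
  tree <- assign_passive(make_reference_morphology())
  n <- tree$nodes
  expect_true(all(n$cm == 1.5))
  expect_true(all(n$ra == 68))
  expect_equal(n$rm[n$region == "soma"], 36.0)
  dend <- n[n$region %in% c("apical", "basal"), ]
  dmax <- max(dend$path_distance)
  expect_equal(dend$rm[which.max(dend$path_distance)], 5.4, tolerance = 1e-10)
  # midpoint of the logistic: mean of the extremes by symmetry
  trunk <- dend[dend$region == "apical", ]
  trunk <- trunk[order(trunk$path_distance), ]
  mid <- approx(trunk$path_distance, trunk$rm, xout = dmax / 2, ties = mean)$y
  expect_equal(mid, (36 + 5.4) / 2, tolerance = 0.005)
  # monotone non-increasing with distance along the apical trunk
  ap <- dend[dend$region == "apical", ]
  ap <- ap[order(ap$path_distance), ]
  expect_true(all(diff(ap$rm) <= 1e-9))
  expect_error(assign_passive(tree, rm_soma = 5, rm_tip = 36), "rm_soma > rm_tip")
})

test_that("spine correction applies beyond the onsets, idempotently", {
  tree <- apply_spine_correction(assign_passive(make_reference_morphology()))
  n <- tree$nodes
  basal_near <- n[n$region == "basal" & n$path_distance < 20, ]
  expect_true(all(basal_near$cm == 1.5))
  basal_far <- n[n$region == "basal" & n$path_distance >= 20, ]
  expect_true(all(basal_far$cm == 3.0))
  expect_true(all(basal_far$spine_factor == 2))
  uncorrected <- assign_passive(make_reference_morphology())$nodes
  expect_equal(basal_far$rm,
               uncorrected$rm[match(basal_far$id, uncorrected$id)] / 2)
  apical_near <- n[n$region == "apical" & n$path_distance < 100, ]
  expect_true(all(apical_near$cm == 1.5))
  expect_true(all(n$cm[n$region %in% c("soma", "axon")] == 1.5))
  # idempotent
  twice <- apply_spine_correction(tree)
  expect_identical(twice, tree)
  # geometry (hence total membrane area) untouched
  expect_identical(twice$nodes$area, tree$nodes$area)
})

test_that("subdivision conserves area and the 20-um segment bound", {
  txt <- c(swc_single_soma(), swc_line(2, 4, 0, 150, 0, 1.2, 1))
  tree <- load_swc(txt)
  fine <- subdivide_tree(tree, max_segment = 20)
  expect_true(all(fine$nodes$length[fine$nodes$region != "soma"] <= 20))
  expect_equal(sum(fine$nodes$area), sum(tree$nodes$area), tolerance = 1e-12)
  expect_equal(max(fine$nodes$path_distance), max(tree$nodes$path_distance))
})
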