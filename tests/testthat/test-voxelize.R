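# Winding-number inside tests and labeled voxelization.

test_that("winding number classifies cube and far points correctly", {
  cube <- unit_cube_surface()
  expect_true(winding_inside(cube, rbind(c(0.5, 0.5, 0.5))))
  expect_equal(winding_number(cube, rbind(c(0.5, 0.5, 0.5))), 1,
               tolerance = 1e-9)
  far <- rbind(c(20, 0, 0))  # 10x the bounding radius away
  expect_false(winding_inside(cube, far))
  expect_equal(winding_number(cube, far), 0, tolerance = 1e-9)
})

test_that("winding inside agrees with the analytic sphere on random points", {
  s <- icosphere(3)
  set.seed(17)
  # sample off the polyhedral discretization layer: an inscribed icosphere
  # differs from the exact ball only within ~0.2% of the radius
  pts <- matrix(runif(1500, -1.5, 1.5), ncol = 3)
  r <- sqrt(rowSums(pts^2))
  pts <- pts[abs(r - 1) > 0.01, , drop = FALSE][1:200, ]
  expect_identical(winding_inside(s, pts),
                   sqrt(rowSums(pts^2)) < 1)
})

test_that("open meshes are rejected with a boundary-edge count", {
  tet <- tetra_surface()
  open <- labeled_surface(tet$vertices, tet$faces[-1, , drop = FALSE])
  err <- tryCatch(check_closed_surface(open), error = identity)
  expect_s3_class(err, "fk_topology_error")
  expect_match(conditionMessage(err), "3 boundary")
})

test_that("voxelized icosphere volume is within 5% of analytic", {
  s <- make_folded_phantom(base_radius = 10, fold_amplitude = 0,
                           mesh_subdivisions = 2, n_regions = 2)
  vol <- voxelize_labeled_surface(s, voxel_size = 1)
  count <- sum(vol$array != 0)
  expect_lt(abs(count / (4 / 3 * pi * 1000) - 1), 0.05)
  # every vertex lies in a voxel with a nonzero label
  key <- foliakit:::vertex_voxel_key(s, vol)
  expect_true(all(vol$array[key + 1L] != 0L))
  # no labeled voxel lies strictly outside winding-interior union shell
  expect_true(all(attr(vol, "inside")[vol$array != 0L]))
})

test_that("shell labels equal the per-voxel vertex mode (two hemispheres)", {
  s <- make_folded_phantom(base_radius = 8, fold_amplitude = 0,
                           mesh_subdivisions = 3, n_regions = 2)
  vol <- voxelize_labeled_surface(s, voxel_size = 1.5)
  d <- dim(vol$array)
  ijk <- round(foliakit:::world_to_voxel(vol$affine, s$vertices))
  key <- ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
  for (k in unique(key)) {
    labs <- s$labels[key == k]
    expect_identical(vol$array[k + 1L], oracle_mode(labs, min(labs)),
                     info = sprintf("voxel key %d", k))
  }
})

test_that("halving the voxel size refines the shell but not the volume", {
  s <- make_folded_phantom(base_radius = 15, fold_amplitude = 0.1,
                           mesh_subdivisions = 4, n_regions = 2)
  v1 <- voxelize_labeled_surface(s, voxel_size = 1)
  v2 <- voxelize_labeled_surface(s, voxel_size = 0.5)
  shell1 <- sum(v1$array != 0L & v1$array != attr(v1, "interior_id"))
  shell2 <- sum(v2$array != 0L & v2$array != attr(v2, "interior_id"))
  expect_gt(shell2, shell1)
  # interior volume estimate: count of voxel centers inside the surface
  inside_volume <- function(v, h) {
    interior <- sum(v$array == attr(v, "interior_id"))
    shell_idx <- which(v$array != 0L & v$array != attr(v, "interior_id")) - 1L
    d <- dim(v$array)
    ijk <- cbind(shell_idx %% d[1], (shell_idx %/% d[1]) %% d[2],
                 shell_idx %/% (d[1] * d[2]))
    centers <- voxel_to_world(v$affine, ijk)
    (interior + sum(winding_inside(s, centers))) * h^3
  }
  expect_lt(abs(inside_volume(v2, 0.5) / inside_volume(v1, 1) - 1), 0.05)
})

test_that("component-accelerated interior equals exact per-voxel winding", {
  s <- make_folded_phantom(base_radius = 9, fold_amplitude = 0.15,
                           mesh_subdivisions = 3, n_regions = 2)
  d <- c(26L, 26L, 26L)
  aff <- diag(4); aff[1:3, 4] <- -13
  exact <- foliakit:::winding_inside_grid(s, d, aff, shell_keys = integer(0),
                                          exact = TRUE)
  fast <- foliakit:::winding_inside_grid(s, d, aff, shell_keys = integer(0),
                                         exact = FALSE, exact_budget = 0)
  expect_identical(fast, exact)
})

test_that("too-coarse voxelization warns about collapsed labels", {
  s <- make_folded_phantom(base_radius = 4, fold_amplitude = 0,
                           mesh_subdivisions = 2, n_regions = 6)
  expect_warning(voxelize_labeled_surface(s, voxel_size = 8),
                 class = "fk_resolution_warning")
})
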