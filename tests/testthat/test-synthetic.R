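# Phantom, deformation and subject generators.

test_that("unfolded phantom is a sphere with the right area and topology", {
  s <- make_folded_phantom(base_radius = 25, fold_amplitude = 0,
                           mesh_subdivisions = 4, n_regions = 8)
  area <- sum(foliakit:::face_areas(s))
  expect_lt(abs(area / (4 * pi * 625) - 1), 0.01)
  # Euler characteristic V - E + F = 2 across specs
  for (spec in list(c(0, 3), c(0.2, 3), c(0.35, 2))) {
    p <- make_folded_phantom(fold_amplitude = spec[1],
                             mesh_subdivisions = spec[2])
    e <- nrow(foliakit:::unique_edges(p$faces))
    expect_equal(nrow(p$vertices) - e + nrow(p$faces), 2)
    expect_true(check_closed_surface(p))
  }
})

test_that("surface area grows monotonically with fold amplitude", {
  areas <- sapply(c(0, 0.1, 0.2, 0.3), function(a)
    sum(foliakit:::face_areas(make_folded_phantom(fold_amplitude = a,
                                                  mesh_subdivisions = 3))))
  expect_true(all(diff(areas) > 0))
})

test_that("phantom labels are contiguous bands and spherical coords unit", {
  s <- make_folded_phantom(mesh_subdivisions = 3, n_regions = 5)
  expect_setequal(unique(s$labels), 1:5)
  expect_equal(sqrt(rowSums(s$spherical^2)), rep(1, nrow(s$spherical)),
               tolerance = 1e-9)
  # bands are ordered by polar angle
  theta <- acos(pmin(pmax(s$spherical[, 3], -1), 1))
  expect_true(all(tapply(theta, s$labels, max)[-5] <=
                    tapply(theta, s$labels, min)[-1] + 1e-9))
  # optional midline strip exercises cross-band groups
  sv <- make_folded_phantom(mesh_subdivisions = 3, n_regions = 5,
                            add_vermis = TRUE)
  expect_true(6L %in% sv$labels)
  # the winding-based self-intersection check passes for legal amplitudes
  expect_s3_class(make_folded_phantom(mesh_subdivisions = 3,
                                      check_self_intersection = TRUE),
                  "labeled_surface")
  expect_error(make_folded_phantom(fold_amplitude = 0.6),
               class = "fk_spec_error")
})

test_that("smooth deformations are reproducible diffeomorphisms", {
  zero <- make_smooth_deformation(c(10, 10, 10), diag(4), amplitude_mm = 0,
                                  rng_seed = 1)
  expect_true(all(zero$vectors == 0))
  for (seed in 1:5) {
    f <- make_smooth_deformation(c(12, 12, 12), diag(4), amplitude_mm = 3,
                                 wavelength_mm = 15, rng_seed = seed)
    expect_gt(jacobian_determinant_range(f)["min"], 0)
  }
  f1 <- make_smooth_deformation(c(12, 12, 12), diag(4), 2, 20, rng_seed = 9)
  f2 <- make_smooth_deformation(c(12, 12, 12), diag(4), 2, 20, rng_seed = 9)
  expect_identical(f1$vectors, f2$vectors)
  # numerically inverted field composed with forward is near identity
  # (checked off the grid boundary, where no edge clamping is involved)
  inv <- invert_field(f1)
  resid <- compose_fields(f1, inv)$vectors[4:9, 4:9, 4:9, ]
  expect_lt(max(abs(resid)), 0.1)
})

test_that("synthetic subjects preserve labels and reduce to identity", {
  arr <- array(0L, c(14, 14, 14)); arr[4:10, 4:10, 4:10] <- 2L
  arr[6:8, 6:8, 6:8] <- 5L
  vol <- label_volume(arr)
  vmri <- make_virtual_mri(vol, c("0" = 0, "2" = 110, "5" = 250), 0.5)
  idf <- foliakit:::identity_field(dim(arr))
  subj0 <- make_subject(vol, vmri, idf, noise_sd = 0)
  expect_identical(subj0$subject_segmentation$array, arr)
  expect_equal(subj0$subject_mri$array, vmri$array, tolerance = 1e-12)
  f <- make_smooth_deformation(dim(arr), diag(4), 2, 12, rng_seed = 2)
  subj <- make_subject(vol, vmri, f, noise_sd = 3, rng_seed = 4)
  expect_true(all(unique(as.vector(subj$subject_segmentation$array)) %in%
                    unique(as.vector(arr))))
  # warping the atlas labels with the same field reproduces the subject
  expect_equal(dice(warp_volume(vol, f, "nearest")$array == 2L,
                    subj$subject_segmentation$array == 2L), 1)
  # reproducible bit for bit
  subj2 <- make_subject(vol, vmri, f, noise_sd = 3, rng_seed = 4)
  expect_identical(subj2$subject_mri$array, subj$subject_mri$array)
})

test_that("atlas summaries recompute counts, spacing and fractions", {
  s <- make_folded_phantom(base_radius = 10, fold_amplitude = 0.1,
                           mesh_subdivisions = 3, n_regions = 3)
  td <- withr::local_tempdir()
  write_surface(s, file.path(td, "atlas.srf"))
  write_vertex_labels(s$labels, file.path(td, "atlas.annot"), s$label_table)
  got <- atlas_summaries(file.path(td, "atlas.srf"),
                         file.path(td, "atlas.annot"))
  expect_equal(got$n_vertices, nrow(s$vertices))
  expect_equal(got$n_faces, nrow(s$faces))
  expect_equal(got$mean_edge_length_mm, mean_edge_length(s),
               tolerance = 1e-6)
  expect_equal(got$area_fractions$fraction,
               region_area_fractions(s)$fraction, tolerance = 1e-6)
})
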