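# Virtual MRI synthesis, demons registration, field algebra, surface warping.

test_that("virtual MRI maps labels to intensities and respects the range", {
  arr <- array(0L, c(12, 12, 12)); arr[4:9, 4:9, 4:9] <- 1L
  vol <- label_volume(arr)
  flat <- make_virtual_mri(label_volume(array(2L, c(6, 6, 6))),
                           c("2" = 70), blur_sigma_mm = 0)
  expect_true(all(flat$array == 70))
  sharp <- make_virtual_mri(vol, c("0" = 0, "1" = 100), blur_sigma_mm = 0)
  expect_identical(sort(unique(as.vector(sharp$array))), c(0, 100))
  blurred <- make_virtual_mri(vol, c("0" = 0, "1" = 100), blur_sigma_mm = 1)
  expect_gte(min(blurred$array), 0)
  expect_lte(max(blurred$array), 100)
  expect_error(make_virtual_mri(vol, c("1" = 100)),
               class = "fk_mapping_error")
})

test_that("a blurred two-label slab crosses the midpoint at the interface", {
  arr <- array(0L, c(40, 9, 9))
  arr[1:20, , ] <- 1L; arr[21:40, , ] <- 3L
  vmri <- make_virtual_mri(label_volume(arr), c("1" = 0, "3" = 100),
                           blur_sigma_mm = 2)
  # 1-D Gaussian convolution oracle along x for the center profile
  profile <- vmri$array[, 5, 5]
  x <- 1:40
  step <- ifelse(x <= 20, 0, 100)
  k <- dnorm(seq(-6, 6), sd = 2)
  oracle <- sapply(x, function(i) {
    j <- pmin(pmax(i + seq(-6, 6), 1), 40)
    sum(step[j] * k) / sum(k)
  })
  expect_equal(profile, oracle, tolerance = 0.5)
  interface <- (profile[20] + profile[21]) / 2
  expect_equal(interface, 50, tolerance = 1)
})

test_that("registering an image to itself returns a near-zero field", {
  set.seed(2)
  arr <- array(0, c(24, 24, 24))
  arr[8:16, 8:16, 8:16] <- 100
  arr <- cpp_gaussian_blur3d(arr, dim(arr), c(1.5, 1.5, 1.5))
  img <- intensity_volume(arr, diag(4))
  f <- register(img, img, registration_config(metric = "ssd",
                                              pyramid_levels = 2,
                                              max_iterations = c(20, 10)))
  expect_lt(max(abs(f$vectors)), 0.1)
})

test_that("a 3 mm translation is recovered inside the object", {
  d <- c(32, 32, 32)
  g <- foliakit:::grid_world_coords(d, diag(4))
  blob <- function(cx) array(exp(-rowSums(sweep(g, 2, cx)^2) / 72), d) * 100
  fixed <- intensity_volume(blob(c(15.5, 15.5, 15.5)), diag(4))
  moving <- intensity_volume(blob(c(18.5, 15.5, 15.5)), diag(4))
  f <- register(fixed, moving, registration_config(metric = "ssd"))
  mask <- fixed$array > 20
  mean_d <- c(mean(f$vectors[, , , 1][mask]), mean(f$vectors[, , , 2][mask]),
              mean(f$vectors[, , , 3][mask]))
  expect_lt(sqrt(sum((mean_d - c(3, 0, 0))^2)), 0.5)
  jr <- jacobian_determinant_range(f)
  expect_gt(jr["min"], 0)
})

# mean symmetric label-boundary distance between two masks, voxel units
mean_boundary_distance <- function(a, b) {
  boundary <- function(mask) {
    d <- dim(mask)
    sh <- function(m, ax, s) {
      j <- pmin(pmax(seq_len(d[ax]) + s, 1), d[ax])
      if (ax == 1) m[j, , ] else if (ax == 2) m[, j, ] else m[, , j]
    }
    inner <- mask & sh(mask, 1, 1) & sh(mask, 1, -1) & sh(mask, 2, 1) &
      sh(mask, 2, -1) & sh(mask, 3, 1) & sh(mask, 3, -1)
    which(mask & !inner, arr.ind = TRUE)
  }
  A <- boundary(a); B <- boundary(b)
  mean(c(apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2)))),
         apply(B, 1, function(p) sqrt(min(colSums((t(A) - p)^2))))))
}

test_that("a known sinusoidal warp is substantially undone", {
  d <- c(32, 32, 32)
  g <- foliakit:::grid_world_coords(d, diag(4))
  r <- sqrt(rowSums(sweep(g, 2, c(15.5, 15.5, 15.5))^2))
  arr <- array(0L, d); arr[r < 10] <- 1L; arr[r < 5] <- 2L
  vol <- label_volume(arr)
  vmri <- make_virtual_mri(vol, c("0" = 0, "1" = 110, "2" = 250), 0.5)
  # sinusoidal ground-truth warp, amplitude 2 voxels
  vec <- array(0, c(d, 3))
  vec[, , , 1] <- array(2 * sin(2 * pi * g[, 3] / 32), d)
  truth <- displacement_field(vec, diag(4))
  subj_seg <- warp_volume(vol, truth, "nearest")
  f <- register(warp_volume(vmri, truth, "trilinear"), vmri,
                registration_config(metric = "lncc"))
  warped_labels <- warp_volume(vol, f, "nearest")
  before <- mean_boundary_distance(vol$array == 1L, subj_seg$array == 1L)
  after <- mean_boundary_distance(warped_labels$array == 1L,
                                  subj_seg$array == 1L)
  expect_lt(after, 0.4 * before)  # >= 60% reduction in boundary distance
  expect_gt(jacobian_determinant_range(f)["min"], 0)
})

test_that("lncc on a constant image suggests ssd", {
  flat <- intensity_volume(array(5, c(8, 8, 8)), diag(4))
  expect_error(register(flat, flat, registration_config(metric = "lncc")),
               class = "fk_metric_error")
})

test_that("field composition matches sequential application", {
  d <- c(10, 10, 10)
  idf <- foliakit:::identity_field(d)
  set.seed(14)
  fv <- array(rnorm(prod(d) * 3, sd = 0.5), c(d, 3))
  for (c in 1:3) fv[, , , c] <- cpp_gaussian_blur3d(fv[, , , c], d, c(2, 2, 2))
  f <- displacement_field(fv, diag(4))
  expect_equal(compose_fields(idf, f)$vectors, f$vectors, tolerance = 1e-9)
  # two translations compose to their sum
  t1 <- displacement_field(array(rep(c(1, 0, 0), each = prod(d)), c(d, 3)),
                           diag(4))
  t2 <- displacement_field(array(rep(c(0, 2, 0.5), each = prod(d)), c(d, 3)),
                           diag(4))
  comp <- compose_fields(t1, t2)
  expect_equal(apply(comp$vectors, 4, mean), c(1, 2, 0.5), tolerance = 1e-9)
  # random smooth fields: composed vs sequential on 50 random points
  g <- displacement_field(fv[, , , c(2, 3, 1)], diag(4))
  comp2 <- compose_fields(f, g)
  set.seed(15)
  pts <- matrix(runif(150, 2, 7), ncol = 3)
  seq_warp <- pts + field_at_points(f, pts)
  seq_warp <- seq_warp + field_at_points(g, seq_warp)
  one_warp <- pts + field_at_points(comp2, pts)
  expect_lt(max(abs(one_warp - seq_warp)), 0.25)
})

test_that("field inversion undoes a smooth deformation", {
  f <- make_smooth_deformation(c(20, 20, 20), diag(4), amplitude_mm = 2,
                               wavelength_mm = 16, rng_seed = 6)
  inv <- invert_field(f)
  both <- compose_fields(f, inv)
  # evaluate away from the grid boundary, where x + d(x) stays inside the
  # domain and no edge clamping is involved
  core <- both$vectors[4:17, 4:17, 4:17, ]
  expect_lt(max(abs(core)), 0.1)
})

test_that("surface warping applies fields exactly and checks the domain", {
  s <- tetra_surface(edge = 2)
  s$vertices <- s$vertices + 5
  d <- c(12, 12, 12)
  idf <- foliakit:::identity_field(d)
  expect_equal(warp_surface(s, idf)$vertices, s$vertices)
  tr <- displacement_field(array(rep(c(1, -2, 0.5), each = prod(d)),
                                 c(d, 3)), diag(4))
  w <- warp_surface(s, tr)
  expect_equal(w$vertices, sweep(s$vertices, 2, c(1, -2, 0.5), "+"))
  expect_identical(w$faces, s$faces)
  # analytic warp: interpolation error shrinks like h^2 on a refined grid
  warp_fun <- function(p) cbind(0.5 * sin(p[, 1] / 3), 0 * p[, 2],
                                0.2 * cos(p[, 3] / 3))
  make_f <- function(h) {
    dd <- as.integer(c(12, 12, 12) / h) + 1L
    aff <- diag(c(h, h, h, 1))
    gw <- foliakit:::grid_world_coords(dd, aff)
    displacement_field(array(warp_fun(gw), c(dd, 3)), aff)
  }
  err <- sapply(c(1, 0.5), function(h) {
    w <- warp_surface(s, make_f(h))
    max(abs(w$vertices - (s$vertices + warp_fun(s$vertices))))
  })
  # second derivative of the warp is <= 0.5/9; h^2 * max|f''| bounds the error
  expect_lt(err[1], 1^2 * 0.5 / 9 + 1e-9)
  expect_lt(err[2], 0.5^2 * 0.5 / 9 + 1e-9)
  # out-of-domain vertices raise a domain error
  far <- s; far$vertices <- far$vertices + 100
  expect_error(warp_surface(far, idf), class = "fk_domain_error")
})

test_that("the external backend adapter round-trips a field", {
  img <- intensity_volume(array(rnorm(8^3), c(8, 8, 8)), diag(4))
  mock <- function(fixed_path, moving_path, mask_path, out_path) {
    fx <- read_volume(fixed_path)   # adapter contract: two NIfTI inputs
    f <- displacement_field(array(1, c(dim(fx$array), 3)), fx$affine)
    write_field(f, out_path)
  }
  f <- register(img, img, registration_config(backend = "external-adapter",
                                              external_fn = mock))
  expect_equal(unique(as.vector(f$vectors)), 1)
})
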