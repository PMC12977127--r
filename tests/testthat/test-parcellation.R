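# Equal-area patch parcellation: apportionment, seeding, growth, balancing.

test_that("patch apportionment is exact, minimal-one and largest-remainder", {
  expect_identical(patches_per_region(c("1" = 1), 800), c("1" = 800L))
  expect_identical(patches_per_region(c("1" = 0.5, "2" = 0.5), 800),
                   c("1" = 400L, "2" = 400L))
  expect_identical(patches_per_region(c(a = 0.5, b = 0.3, c = 0.2), 800),
                   c(a = 400L, b = 240L, c = 160L))
  # largest remainder: 0.4/0.35/0.25 of 10 -> 4/4/2 (remainders 0, .5, .5)
  got <- patches_per_region(c(a = 0.4, b = 0.35, c = 0.25), 10)
  expect_equal(sum(got), 10)
  expect_identical(got, c(a = 4L, b = 4L, c = 2L))
  # tiny region still gets one patch
  got2 <- patches_per_region(c(a = 0.999, b = 0.001), 10)
  expect_identical(got2, c(a = 9L, b = 1L))
  expect_error(patches_per_region(c(a = 1, b = 0), 10),
               class = "fk_apportionment_error")
})

test_that("a lone pointer never moves; repelled pointers spread apart", {
  s <- make_folded_phantom(base_radius = 10, fold_amplitude = 0,
                           mesh_subdivisions = 3, n_regions = 2)
  seeds1 <- spread_seeds(s, counts = c("1" = 1L, "2" = 1L), iterations = 50,
                         rng_seed = 4)
  seeds0 <- spread_seeds(s, counts = c("1" = 1L, "2" = 1L), iterations = 0,
                         rng_seed = 4)
  expect_identical(seeds1$vertex, seeds0$vertex)
  # min pairwise distance within a region is non-decreasing sweep by sweep
  region <- rep(1L, nrow(s$vertices))
  mins <- numeric(0)
  for (it in 0:15) {
    sd <- spread_seeds(s, region, c("1" = 10L), iterations = it, rng_seed = 9)
    pos <- s$spherical[sd$vertex, ]
    mins <- c(mins, min(dist(pos)))
  }
  expect_true(all(diff(mins) >= -1e-12))
})

test_that("two pointers on a discretized ring converge to antipodes", {
  # triangulated band: region 1 is the bottom ring (a 24-cycle)
  n <- 24
  ang <- 2 * pi * (0:(n - 1)) / n
  bottom <- cbind(cos(ang), sin(ang), 0)
  top <- cbind(cos(ang + pi / n) * 0.98, sin(ang + pi / n) * 0.98,
               rep(0.199, n))
  v <- rbind(bottom, top)
  v <- v / sqrt(rowSums(v^2))
  idx <- function(i) (i - 1) %% n + 1
  f <- do.call(rbind, lapply(1:n, function(i)
    rbind(c(i, idx(i + 1), n + i), c(idx(i + 1), n + idx(i + 1), n + i))))
  s <- labeled_surface(v, f, spherical = v)
  region <- rep(c(1L, 2L), each = n)
  sd <- spread_seeds(s, region, c("1" = 2L), iterations = 100, rng_seed = 2)
  got <- sort(sd$vertex)
  # brute force over all ring position pairs: the max-min chord distance
  best <- max(dist(v[1:n, ]))
  expect_equal(sqrt(sum((v[got[1], ] - v[got[2], ])^2)), best,
               tolerance = 0.02)
})

test_that("patch growth equals the FIFO multi-source BFS oracle", {
  s <- make_folded_phantom(base_radius = 5, fold_amplitude = 0.1,
                           mesh_subdivisions = 2, n_regions = 2)  # 162 verts
  set.seed(12)
  seeds <- do.call(rbind, lapply(1:2, function(r) {
    verts <- sample(which(s$labels == r), 3)
    data.frame(region = r, vertex = verts)
  }))
  seeds$patch_id <- seq_len(nrow(seeds))
  got <- grow_patches(s, s$labels, seeds)
  want <- oracle_grow(adj_list(s), s$labels, seeds$vertex, seeds$patch_id)
  expect_identical(got, as.integer(want))
  expect_true(all(got >= 1L))
  # one seed per region makes each region one patch
  one <- data.frame(patch_id = 1:2, region = 1:2,
                    vertex = c(which(s$labels == 1)[1],
                               which(s$labels == 2)[1]))
  grown <- grow_patches(s, s$labels, one)
  expect_identical(grown, s$labels)
})

test_that("balancing splits oversized patches and never raises the area CV", {
  s <- make_folded_phantom(base_radius = 10, fold_amplitude = 0,
                           mesh_subdivisions = 3, n_regions = 1)
  region <- rep(1L, nrow(s$vertices))
  # equal-area fixed point: latitude bands of equal vertex count are close to
  # balanced; build an exactly balanced 2-patch split by hemisphere
  patch <- ifelse(s$vertices[, 3] > 0, 1L, 2L)
  bal <- balance_patches(s, patch, region)
  expect_equal(bal$stats$n_patches, 2)
  # one oversized patch among equals: exactly one split occurs
  theta <- acos(pmin(pmax(s$spherical[, 3], -1), 1))
  patch3 <- as.integer(cut(theta, quantile(theta, c(0, .7, .85, 1),
                                           type = 8),
                           include.lowest = TRUE))
  a <- foliakit:::patch_areas(patch3, vertex_areas(s))
  expect_gt(max(a) / mean(a), 2)  # the first band is ~2.1x the mean
  bal3 <- balance_patches(s, patch3, region)
  expect_equal(bal3$stats$n_patches, 4)
  # CV does not increase on a random parcellation
  set.seed(33)
  seeds <- spread_seeds(s, region, c("1" = 12L), iterations = 20, rng_seed = 5)
  patch_r <- grow_patches(s, region, seeds)
  cv0 <- stats::sd(foliakit:::patch_areas(patch_r, vertex_areas(s))) /
    mean(foliakit:::patch_areas(patch_r, vertex_areas(s)))
  bal_r <- balance_patches(s, patch_r, region)
  expect_lte(bal_r$stats$cv, cv0 + 1e-12)
  # after the forced pass no patch except its own products exceeds 2x mean
  a2 <- bal_r$stats$areas_mm2
  expect_lt(max(a2) / mean(a2), 4)  # loose sanity bound
})

test_that("full parcellation is connected, region-nested and reproducible", {
  ph <- make_folded_phantom(base_radius = 12, fold_amplitude = 0.1,
                            mesh_subdivisions = 3, n_regions = 4)
  p <- parcellate(ph, total_patches = 60, rng_seed = 7)
  adj <- build_adjacency(ph)
  comp <- foliakit:::cpp_mesh_components(adj$offsets, adj$neighbors,
                                         p$patch_ids)
  crosstab <- table(p$patch_ids, comp)
  expect_true(all(rowSums(crosstab > 0) == 1))          # connected
  expect_true(all(tapply(ph$labels, p$patch_ids,
                         function(x) length(unique(x))) == 1))  # nested
  expect_identical(sort(unique(p$patch_ids)),
                   seq_len(p$stats$n_patches))           # contiguous ids
  p2 <- parcellate(ph, total_patches = 60, rng_seed = 7)
  expect_identical(p$patch_ids, p2$patch_ids)
  p3 <- parcellate(ph, total_patches = 60, rng_seed = 8)
  expect_false(identical(p$patch_ids, p3$patch_ids))
  expect_lt(abs(p3$stats$n_patches - p$stats$n_patches) /
              p$stats$n_patches, 0.15)
})
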