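# DICE, hierarchy grouping, two-stage summaries, Hausdorff distances.

test_that("dice handles identity, disjoint, partial overlap and empties", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(dice(a, b), 0)
  # 8-voxel cube shifted by one voxel: overlap 4 -> 2*4/16
  cube <- array(FALSE, c(6, 6, 6)); cube[2:3, 2:3, 2:3] <- TRUE
  shifted <- array(FALSE, c(6, 6, 6)); shifted[3:4, 2:3, 2:3] <- TRUE
  expect_equal(dice(cube, shifted), 0.5)
  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(empty, empty), 1)   # agreement on absence
  expect_equal(dice(a, empty), 0)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), class = "fk_grid_error")
  expect_equal(dice(a, b), dice(b, a))
  # random masks match the counting oracle
  set.seed(19)
  for (i in 1:5) {
    m1 <- array(runif(64) < 0.4, c(4, 4, 4))
    m2 <- array(runif(64) < 0.4, c(4, 4, 4))
    expect_equal(dice(m1, m2), oracle_dice(m1, m2))
  }
})

test_that("hierarchy groups must be disjoint and dice aggregates unions", {
  expect_error(hierarchy("h", list(a = 1:2, b = 2:3)),
               class = "fk_label_error")
  h <- hierarchy("lobe", list(upper = c(1L, 2L), lower = 3L, absent = 9L))
  set.seed(23)
  arr <- array(sample(0:3, 216, TRUE), c(6, 6, 6))
  arr2 <- array(sample(0:3, 216, TRUE), c(6, 6, 6))
  sa <- label_volume(arr); sb <- label_volume(arr2)
  res <- dice_hierarchy(sa, sb, h)
  # brute-force union masks per group
  expect_equal(res$dice[res$group == "upper"],
               oracle_dice(arr %in% 1:2, arr2 %in% 1:2))
  expect_equal(res$dice[res$group == "lower"],
               oracle_dice(arr == 3, arr2 == 3))
  expect_true(res$missing[res$group == "absent"])
  expect_true(is.na(res$dice[res$group == "absent"]))
  # identical segmentations: every present group scores 1
  res_same <- dice_hierarchy(sa, sa, h)
  expect_true(all(res_same$dice[!res_same$missing] == 1))
  # whole-object dice equals the dice of the nonzero masks
  hall <- hierarchy("coarse", list(whole = 1:3))
  expect_equal(dice_hierarchy(sa, sb, hall)$dice,
               oracle_dice(arr != 0, arr2 != 0))
})

test_that("hierarchies round-trip through editable JSON", {
  h <- hierarchy("coarse", list(whole = 1:3, wm = 4L))
  p <- withr::local_tempfile(fileext = ".json")
  write_hierarchy_json(h, p)
  back <- read_hierarchy_json(p)
  expect_identical(back$groups, h$groups)
  expect_identical(back$name, h$name)
})

test_that("two-stage summaries match a hand-rolled median-of-medians oracle", {
  one <- data.frame(subject = "s1", group = "g1", value = 0.7)
  s <- summarize_scores(one)
  expect_equal(s$median_of_medians, 0.7)
  expect_equal(s$mean_of_medians, 0.7)
  expect_equal(unname(s$pooled["median"]), 0.7)
  two <- data.frame(subject = "s1", group = c("g1", "g2"),
                    value = c(0.6, 0.8))
  s2 <- summarize_scores(two)
  expect_equal(s2$mean_of_medians, 0.7)
  expect_equal(s2$median_of_medians, 0.7)
  expect_equal(s2$min_group, "g1")
  expect_equal(s2$max_group, "g2")
  set.seed(29)
  tab <- expand.grid(subject = paste0("s", 1:3), group = paste0("g", 1:4))
  tab$value <- runif(nrow(tab))
  s3 <- summarize_scores(tab)
  med_or <- sapply(split(tab$value, tab$group), median)
  expect_equal(s3$median_of_medians, median(med_or))
  expect_equal(s3$mean_of_medians, mean(med_or))
  expect_equal(unname(s3$pooled["iqr_low"]),
               as.numeric(quantile(tab$value, 0.25, type = 8)))
})

test_that("surface-volume Hausdorff matches geometry and a brute-force oracle", {
  # A == B -> 0
  arr <- array(0L, c(8, 8, 8)); arr[4, 4, 4] <- 1L  # 0-based voxel (3,3,3)
  vol <- label_volume(arr)
  s <- labeled_surface(rbind(c(3, 3, 3)), matrix(integer(0), 0, 3),
                       labels = 1L)
  expect_equal(hausdorff_surface_volume(s, vol, 1L), 0)
  # 3-4-5 triangle at 1 mm voxels
  arr2 <- array(0L, c(8, 8, 8)); arr2[1, 1, 1] <- 1L
  s2 <- labeled_surface(rbind(c(3, 4, 0)), matrix(integer(0), 0, 3),
                        labels = 1L)
  expect_equal(hausdorff_surface_volume(s2, label_volume(arr2), 1L), 5)
  # empty group raises an undefined-distance error naming the side
  expect_error(hausdorff_surface_volume(s2, label_volume(arr2), 7L),
               class = "fk_undefined_distance_error")
  # random voxel sets against the O(|A||B|) oracle, plus symmetry
  set.seed(37)
  for (i in 1:5) {
    A <- matrix(sample(0:9, 90, TRUE), ncol = 3)
    B <- matrix(sample(0:9, 90, TRUE), ncol = 3)
    got <- foliakit:::cpp_hausdorff(A, B)
    expect_equal(got, oracle_hausdorff(A, B))
    expect_equal(got, foliakit:::cpp_hausdorff(B, A))
    # joint translation invariance
    expect_equal(foliakit:::cpp_hausdorff(A + 11.5, B + 11.5), got)
  }
})
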