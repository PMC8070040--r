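test_that("foreground stage thresholds two flat plateaus at the centroid mean", {
  g <- matrix(10L, 20, 20)
  g[6:15, 6:15] <- 200L
  fg <- foreground_stage(g)
  expect_equal(fg$tau_fg, 105)
  # the bright plateau (minus the cross-element corner chamfer) is kept
  expect_true(all(fg$fg[8:13, 8:13] == 1L))
  expect_true(all(fg$fg[g == 10L] == 0L))
  expect_true(all(fg$fg_hull >= fg$fg))
  expect_error(foreground_stage(matrix(50L, 10, 10)), "distinct")
})

test_that("foreground hull covers the phantom body almost entirely", {
  ph <- small_phantom(seed = 11, n_slices = 1L, shape = 128L, liver_onset = 2L)
  g <- heartseg:::gray_slice(to_grayscale(ph$hu), 1)
  fg <- foreground_stage(g)
  body <- ph$gt$body[, , 1]
  recall <- sum(fg$fg_hull * body) / sum(body)
  expect_gte(recall, 0.99)
})

test_that("lung stage only admits dark pixels inside the foreground hull", {
  g <- matrix(200L, 12, 12)
  hull <- matrix(0L, 12, 12)
  hull[3:10, 3:10] <- 1L
  g[5:8, 5:8] <- 20L      # dark region inside the hull
  g[1, 1] <- 20L          # dark pixel outside the hull: E becomes 255
  lg <- lung_stage(g, hull, tau_fg = 115)
  expect_equal(lg$lung[1, 1], 0L)
  expect_true(all(lg$lung[5:8, 5:8] == 1L))
  expect_true(all(lg$lung[g == 200L] == 0L))
  expect_true(all(lg$lung_hull >= lg$lung))
})

test_that("lung mask recovers the phantom lungs", {
  ph <- small_phantom(seed = 11, n_slices = 1L, shape = 128L, liver_onset = 2L)
  g <- heartseg:::gray_slice(to_grayscale(ph$hu), 1)
  fg <- foreground_stage(g)
  lg <- lung_stage(g, fg$fg_hull, fg$tau_fg)
  expect_gte(pixel_iou(lg$lung, ph$gt$lungs[, , 1]), 0.9)
})

test_that("lung-hull refinement follows the top-row rule", {
  mk <- function(r0, r1, c0, c1, n = 40) {
    m <- matrix(0L, n, n); m[r0:r1, c0:c1] <- 1L; m
  }
  l_ref <- mk(10, 30, 5, 35)
  u_ref <- convex_hull(l_ref)
  st0 <- NULL
  r1 <- refine_lung_hull(l_ref, u_ref, st0, 1)
  expect_identical(r1$hull, u_ref)
  expect_equal(r1$state$ref_top_row, 10)

  # lungs receding (top row moved down): union with the reference hull
  l_low <- mk(30, 36, 15, 25)
  u_low <- convex_hull(l_low)
  r2 <- refine_lung_hull(l_low, u_low, r1$state, 2)
  expect_identical(r2$hull, heartseg:::as_mask(u_low | u_ref))
  expect_equal(r2$state$ref_top_row, 10)  # reference unchanged

  # lungs higher than the reference: current hull kept, reference updated
  l_high <- mk(8, 28, 5, 35)
  u_high <- convex_hull(l_high)
  r3 <- refine_lung_hull(l_high, u_high, r1$state, 3)
  expect_identical(r3$hull, u_high)
  expect_equal(r3$state$ref_top_row, 8)

  # empty lung mask: fall back to the reference hull
  empty <- matrix(0L, 40, 40)
  r4 <- refine_lung_hull(empty, NULL, r1$state, 4)
  expect_identical(r4$hull, u_ref)
  expect_error(refine_lung_hull(empty, NULL, NULL, 1), "reference")
})

test_that("intermediate and heart stages implement their mask algebra", {
  u <- matrix(0L, 6, 6); u[2:5, 2:5] <- 1L
  l <- matrix(0L, 6, 6); l[2:5, 2] <- 1L; l[2:5, 5] <- 1L
  i <- intermediate_stage(u, l)
  expect_true(all(i[2:5, 3:4] == 1L))
  expect_true(all(i[l == 1L] == 0L))
  expect_true(all(i[u == 0L] == 0L))

  p <- matrix(0L, 6, 6); p[4:6, ] <- 1L
  h <- heart_stage(i, p)
  expect_true(all(h[p == 1L] == 0L))
  expect_identical(heart_stage(i, matrix(0L, 6, 6)), i)  # empty fill: identity
})

test_that("spine fill suppresses everything below the spine anchors", {
  s <- matrix(0L, 8, 8)
  s[5:6, 4:5] <- 1L  # spine block, top at (x = 4, y = 5)
  p <- spine_fill(s)
  expect_true(all(p[6:8, ] == 1L))          # all rows below the top row
  expect_identical(p[1:4, ], matrix(0L, 4, 8))
  expect_true(all(p[5, 4:5] == 1L))         # the mask itself stays

  # one-sided literal variant keeps the right side above the centroid row
  pl <- spine_fill(s, side = "left")
  a <- region_anchors(s)
  yc <- a$centroid[["y"]]
  below_top_above_yc <- setdiff(seq(a$top[["y"]] + 1, yc), 0)
  for (r in below_top_above_yc) {
    expect_true(all(pl[r, seq_len(a$top[["x"]] - 1)] == 1L))
  }
  expect_true(all(pl[(yc + 1):8, ] == 1L))  # full rows below the centroid
})

test_that("heart extraction keeps HU under the mask and air elsewhere", {
  hu <- matrix(sample(-500:500, 36), 6, 6)
  h <- matrix(0L, 6, 6); h[2:4, 2:4] <- 1L
  z <- extract_heart(hu, h)
  expect_identical(z[h == 1L], hu[h == 1L])
  expect_true(all(z[h == 0L] == -1000L))
  expect_identical(extract_heart(hu, matrix(0L, 6, 6)),
                   matrix(-1000L, 6, 6))
  expect_identical(extract_heart(hu, matrix(1L, 6, 6)), hu)
})

test_that("running a volume is deterministic and preserves the mask chain", {
  ph <- small_phantom(seed = 12, n_slices = 2L, liver_onset = 3L)
  cfg <- seg_config(n_slices = 2)
  r1 <- run_volume(ph$hu, cfg)
  r2 <- run_volume(ph$hu, cfg)
  expect_identical(heart_mask_stack(r1), heart_mask_stack(r2))
  expect_identical(r1$report, r2$report)
  expect_equal(r1$report$status, c("ok", "ok"))
  for (i in 1:2) {
    m <- r1$slices[[i]]$masks
    expect_true(all(m$heart <= m$intermediate))
    expect_true(all(m$intermediate <= m$lung_hull))
    expect_equal(sum(m$lung * m$intermediate), 0)
    expect_equal(sum(m$heart * m$spine_hull), 0)
    # thresholds sit between their centroids
    expect_gt(r1$report$tau_fg[i], 0)
    expect_lt(r1$report$tau_fg[i], 255)
    # segmented HU is air outside the heart mask
    expect_true(all(r1$slices[[i]]$segmented_hu[m$heart == 0L] == -1000L))
  }
  # single-slice volume initializes the refinement state trivially
  one <- trim_volume(ph$hu, 1)
  rr <- run_volume(one, seg_config(n_slices = 1))
  expect_equal(nrow(rr$report), 1)
  expect_equal(rr$report$status, "ok")
})

test_that("silhouette aggregation reports range summaries and pooled scores", {
  rep_tbl <- tibble::tibble(
    subject = "s", slice = 1:4,
    tau_fg = 100, tau_spine = 200,
    sil_fg = c(0.4, 0.6, 0.5, 0.5),
    sil_spine = c(0.8, 0.6, 0.7, 0.7),
    area_foreground = 1L, area_lung = 1L, area_lung_hull = 1L,
    area_intermediate = 1L, area_spine = 1L, area_heart = 1L,
    status = "ok"
  )
  agg <- aggregate_silhouette(rep_tbl, ranges = list(c(1L, 2L), c(1L, 4L)))
  r12_fg <- agg[agg$range == "1-2" & agg$filter == "foreground", ]
  expect_equal(r12_fg$min, 0.4)
  expect_equal(r12_fg$max, 0.6)
  expect_equal(r12_fg$mean, 0.5)
  expect_equal(r12_fg$sd, sd(c(0.4, 0.6)))
  # overall pools the foreground and spine score lists
  r14_all <- agg[agg$range == "1-4" & agg$filter == "overall", ]
  pooled <- c(0.4, 0.6, 0.5, 0.5, 0.8, 0.6, 0.7, 0.7)
  expect_equal(r14_all$n, 8L)
  expect_equal(r14_all$mean, mean(pooled))
  expect_equal(r14_all$sd, sd(pooled))
  # constant scores: zero SD
  rep_c <- rep_tbl; rep_c$sil_fg <- 0.5; rep_c$sil_spine <- 0.5
  agg_c <- aggregate_silhouette(rep_c, ranges = list(c(1L, 4L)))
  expect_true(all(agg_c$mean == 0.5))
  expect_true(all(agg_c$sd == 0))
  expect_warning(aggregate_silhouette(rep_tbl, ranges = list(c(9L, 10L))),
                 "no slices")
})

test_that("tidy, glance and autoplot work on a run", {
  ph <- small_phantom(seed = 13, n_slices = 2L, liver_onset = 3L)
  run <- run_volume(ph$hu, seg_config(n_slices = 2))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(run)
  expect_equal(gl$n_ok, 2L)
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_mask(run$slices[[1]]$masks$heart), "ggplot")
})
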