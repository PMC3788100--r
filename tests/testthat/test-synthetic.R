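test_that("templates are exactly flip-invariant", {
  sp <- tiny_spec()
  tpl <- make_symmetric_template(sp, "GM")
  expect_identical(tpl$data, flip_x(tpl)$data)

  # off-midline blob is auto-paired with its mirror
  sp2 <- phantom_spec(grid_shape = c(21, 21, 21), voxel_size_mm = 4,
                      template_blobs = list(
                        list(center_mm = c(16, 0, 0), radius_mm = 12,
                             amplitude = 0.5, tissue = "GM")),
                      effect_blobs = list(), behavior_link = NULL,
                      n_per_group = 4, n_female = 2)
  tpl2 <- make_symmetric_template(sp2, "GM")
  expect_identical(tpl2$data, flip_x(tpl2)$data)
  expect_gt(max(tpl2$data), 0)

  # empty blob list for a tissue gives an all-zero volume
  expect_true(all(make_symmetric_template(sp2, "WM")$data == 0))
})

test_that("blob containment and link references are validated", {
  expect_error(
    phantom_spec(grid_shape = c(11, 11, 11), voxel_size_mm = 2,
                 template_blobs = list(
                   list(center_mm = c(8, 0, 0), radius_mm = 6,
                        amplitude = 0.5, tissue = "GM")),
                 effect_blobs = list(), behavior_link = NULL),
    "outside the grid")
  expect_error(tiny_spec(behavior_link = list(blob = "nope", slope = 1,
                                              base = 0.5, noise_sd = 0,
                                              group = "patient",
                                              score = "score_monaural")),
               "unknown effect blob")
})

test_that("noiseless subjects reproduce the template plus a closed-form AI", {
  sp <- tiny_spec(amp_control = 0.1, noise_sd = 0)
  tg <- make_symmetric_template(sp, "GM")
  tw <- make_symmetric_template(sp, "WM")
  set.seed(1)
  s_pat <- simulate_subject(sp, tg, tw, "patient")  # amplitude 0
  expect_identical(s_pat$gm$data, tg$data)

  set.seed(1)
  s_ctl <- simulate_subject(sp, tg, tw, "control")
  # template value at effect centre is 0.5; additive amplitude 0.1 there:
  # AI = (0.6 - 0.5) / (0.5 * (0.6 + 0.5)) = 0.1818...
  m <- compute_ai(s_ctl$gm, eps = 0.05)
  centre <- world_to_voxel(s_ctl$gm, c(20, 0, 0)) + 1L
  expect_equal(m$ai$data[centre[1], centre[2], centre[3]], 0.1 / 0.55,
               tolerance = 1e-12)
  expect_error(simulate_subject(sp, tg, tw, "martian"), "unknown group")
})

test_that("cohorts are reproducible from the seed and sized correctly", {
  sp <- tiny_spec(noise_sd = 0.02, n_per_group = 3, seed = 77)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$gm_maps[[1]]$data, c2$gm_maps[[1]]$data)
  expect_identical(c1$wm_maps[[6]]$data, c2$wm_maps[[6]]$data)

  sp2 <- tiny_spec(noise_sd = 0.02, n_per_group = 3, seed = 78)
  c3 <- simulate_cohort(sp2)
  expect_false(identical(c1$gm_maps[[1]]$data, c3$gm_maps[[1]]$data))

  expect_equal(nrow(c1$subjects), 6)
  expect_equal(sum(c1$subjects$group == "control"), 3)
  expect_true(all(vapply(c1$gm_maps, function(v) min(v$data) >= 0,
                         logical(1))))
  score_cols <- grep("^score_", names(c1$subjects), value = TRUE)
  expect_length(score_cols, 3)
  for (sc in score_cols)
    expect_true(all(c1$subjects[[sc]] >= 0 & c1$subjects[[sc]] <= 1))
})

test_that("the default cohort emulates the two-group study design", {
  sp <- phantom_spec(seed = 42)
  co <- simulate_cohort(sp, tissues = "GM")
  expect_equal(nrow(co$subjects), 28)          # 14 per group
  expect_equal(as.integer(table(co$subjects$group)), c(14L, 14L))
  expect_equal(as.integer(table(co$subjects$gender, co$subjects$group)[2, ]),
               c(6L, 6L))                      # 6 females per group
})

test_that("behavioral link controls the score-asymmetry correlation", {
  # strong link, near-zero score noise: correlation near 1 in the linked
  # group; zero slope: correlation near 0
  link <- list(blob = "gm_right", slope = 0.5, base = 0.5, noise_sd = 1e-4,
               group = "patient", score = "score_monaural")
  sp <- tiny_spec(amp_control = 0.1, amp_patient = 0.1, subject_sd = 0.06,
                  noise_sd = 0.01, n_per_group = 12, seed = 5,
                  behavior_link = link)
  co <- simulate_cohort(sp, tissues = "GM")
  pat <- co$subjects$group == "patient"
  r <- cor(co$subjects$score_monaural[pat], co$truth$link_ai[pat])
  expect_gt(r, 0.99)

  link0 <- link; link0$slope <- 0; link0$noise_sd <- 0.05
  sp0 <- tiny_spec(amp_control = 0.1, amp_patient = 0.1, subject_sd = 0.06,
                   noise_sd = 0.01, n_per_group = 100, seed = 6,
                   behavior_link = link0)
  co0 <- simulate_cohort(sp0, tissues = "GM")
  pat0 <- co0$subjects$group == "patient"
  r0 <- cor(co0$subjects$score_monaural[pat0], co0$truth$link_ai[pat0])
  expect_lt(abs(r0), 0.2)
})

test_that("null cohorts have zero expected asymmetry", {
  sp <- tiny_spec(amp_control = 0, amp_patient = 0, noise_sd = 0.03,
                  n_per_group = 50, seed = 12)
  co <- simulate_cohort(sp, tissues = "GM")
  ais <- lapply(co$gm_maps, function(v) compute_ai(v, eps = 0.05))
  mask <- Reduce(`&`, lapply(ais, function(m) m$mask$data > 0))
  vals <- vapply(ais, function(m) mean(m$ai$data[mask]), numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("a cohort round-trips to disk as NIfTI + CSV + YAML", {
  sp <- tiny_spec(noise_sd = 0.02, n_per_group = 2, seed = 9)
  co <- simulate_cohort(sp)
  d <- tempfile("cohort")
  write_cohort(co, d)
  tab <- read.csv(file.path(d, "subjects.csv"))
  expect_equal(nrow(tab), 4)
  v <- read_volume(file.path(d, paste0(co$subjects$id[1], "_gm.nii.gz")))
  expect_equal(v$data, co$gm_maps[[1]]$data, tolerance = 1e-6)
  truth <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_equal(truth$effect_blobs$gm_right$amplitude$control, 0.15)
})
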