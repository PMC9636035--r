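test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(n_patients = 0), "counts")
  expect_error(synth_config(signal_strength = 1.5), "signal_strength")
  expect_error(synth_config(confound_strength = -0.1), "confound_strength")
  expect_error(synth_config(confound_label_corr = 2), "confound_label_corr")
  expect_error(synth_config(tmb_prevalence = 0), "tmb_prevalence")
})

test_that("patch generator renders deterministic images with the confound applied", {
  cfg <- synth_config(patch_px = 64)
  set.seed(7)
  img1 <- generate_patch_image("high", c(0, 0, 0), cfg)
  set.seed(7)
  img2 <- generate_patch_image("high", c(0, 0, 0), cfg)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(64L, 64L, 3L))
  expect_true(all(img1 >= 0 & img1 <= 255))

  # additive shift then clipping
  set.seed(7)
  img3 <- generate_patch_image("high", c(30, -300, 10), cfg)
  expect_true(all(img3 >= 0 & img3 <= 255))
  expect_equal(mean(img3[, , 2]), 0, tolerance = 1e-8)  # fully clipped down
  expect_equal(img3[, , 1], pmin(img1[, , 1] + 30, 255))

  expect_error(generate_patch_image("high", config = synth_config(patch_px = 8)),
               "unrenderable")
})

test_that("nucleus counts are class-indistinguishable at zero signal and separated at full signal", {
  cfg0 <- synth_config(signal_strength = 0)
  set.seed(11)
  n0_high <- replicate(200, count_blobs(generate_patch_image("high", c(0, 0, 0), cfg0)))
  n0_low <- replicate(200, count_blobs(generate_patch_image("low", c(0, 0, 0), cfg0)))
  expect_gt(t.test(n0_high, n0_low)$p.value, 0.01)

  cfg1 <- synth_config(signal_strength = 1)
  set.seed(12)
  n1_high <- replicate(200, count_blobs(generate_patch_image("high", c(0, 0, 0), cfg1)))
  n1_low <- replicate(200, count_blobs(generate_patch_image("low", c(0, 0, 0), cfg1)))
  expect_gt(mean(n1_high), mean(n1_low))
  expect_lt(t.test(n1_high, n1_low)$p.value, 0.01)
})

test_that("cohort generation obeys the manifest arithmetic and confound construction", {
  cfg <- synth_config(n_patients = 10, slides_per_patient = 2,
                      patches_per_slide = 5, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$manifest), 20L)
  expect_equal(length(co$patches), 100L)
  expect_setequal(names(co$manifest),
                  c("patient_id", "slide_id", "cohort", "split", "tmb_value",
                    "tmb_class", "surv_time_days", "surv_event"))
  expect_true(all(co$manifest$tmb_class == ifelse(co$manifest$tmb_value >= 206,
                                                  "high", "low")))

  # perfect confound-label correlation forces the sign
  co1 <- generate_cohort(synth_config(n_patients = 10, confound_label_corr = 1,
                                      seed = 4))
  high_slides <- co1$manifest$slide_id[co1$manifest$tmb_class == "high"]
  signs <- co1$truth$slides$shift_sign[match(high_slides,
                                             co1$truth$slides$slide_id)]
  expect_true(all(signs == 1))

  expect_error(generate_cohort(synth_config(n_patients = 1)), ">= 2")
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- synth_config(n_patients = 4, patches_per_slide = 3, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$patches, b$patches)
})

test_that("cohort round-trips through disk byte-identically", {
  cfg <- synth_config(n_patients = 3, patches_per_slide = 2, seed = 5)
  co <- generate_cohort(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_cohort(co, d1)
  write_cohort(co, d2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(file.path(d2, "manifest.csv"), "raw",
                           file.size(file.path(d2, "manifest.csv"))))
  expect_error(write_cohort(co, d1), "overwrite")

  back <- read_cohort(d1)
  expect_equal(back$manifest, co$manifest)
  expect_identical(back$patches[[1]], co$patches[[1]])

  files <- list.files(file.path(d1, "patches"))
  expect_true(all(grepl("^train_P[0-9]+_S[0-9]+_[0-9]+_[0-9]+\\.png$", files)))

  empty <- co; empty$patches <- list()
  expect_error(write_cohort(empty, tempfile()), "no patches")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("bags pool all of a patient's patches with the patient label", {
  co <- generate_cohort(synth_config(n_patients = 3, slides_per_patient = 2,
                                     patches_per_slide = 4, seed = 8))
  bags <- cohort_bags(co)
  expect_length(bags, 3L)
  b <- bags[[1]]
  expect_length(b$slides, 2L)
  expect_equal(sum(vapply(b$slides, length, 1L)), 8L)
  expect_true(b$class %in% c("high", "low"))
})

test_that("slide identity is linearly decodable from mean color when confounded", {
  co <- generate_cohort(synth_config(n_patients = 10, patches_per_slide = 20,
                                     confound_strength = 1, seed = 21))
  keys <- sub("\\.png$", "", co$patch_index$file)
  mean_rgb <- t(vapply(co$patches[keys],
                       function(p) c(mean(p[, , 1]), mean(p[, , 2]),
                                     mean(p[, , 3])), numeric(3)))
  pr <- probe_confounder(mean_rgb, co$patch_index$slide_id)
  expect_gt(pr$accuracy, 5 * pr$chance)

  # and not decodable beyond chance structure when the confound is off
  co0 <- generate_cohort(synth_config(n_patients = 10, patches_per_slide = 20,
                                      confound_strength = 0, seed = 21))
  mean_rgb0 <- t(vapply(co0$patches[keys],
                        function(p) c(mean(p[, , 1]), mean(p[, , 2]),
                                      mean(p[, , 3])), numeric(3)))
  pr0 <- probe_confounder(mean_rgb0, co0$patch_index$slide_id)
  expect_lt(pr0$accuracy, pr$accuracy / 2)
})
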