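test_that("sim_config validates probabilities, effect size and slide size", {
  expect_error(sim_config(p_impaired = 1.2), "probability")
  expect_error(sim_config(effect_size = 1), "effect_size")
  expect_error(sim_config(slide_px = 256), "slide_px")
  expect_s3_class(sim_config(n_donors = 5, slide_px = 512), "sim_config")
})

test_that("cohort generation is deterministic and respects the seed", {
  cfg <- sim_config(n_donors = 25, slide_px = 512, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- sim_config(n_donors = 25, slide_px = 512, seed = 10)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("without corruption every donor's measures agree with the true state", {
  cfg <- sim_config(n_donors = 60, slide_px = 512, label_noise = 0,
                    missingness = 0, seed = 4)
  co <- label_cohort(generate_cohort(cfg))
  expect_false(anyNA(co$cdr))
  expect_equal(co$label, co$true_state)
})

test_that("true impairment is positively rank-correlated with age", {
  cfg <- sim_config(n_donors = 2000, slide_px = 512, seed = 7, age_ci_slope = 0.08)
  co <- generate_cohort(cfg)
  rho <- cor(co$age, as.integer(co$true_state == "CI"), method = "spearman")
  expect_gt(rho, 0)
})

test_that("label noise produces the expected disagreement rate", {
  noise <- 0.1
  cfg <- sim_config(n_donors = 1000, slide_px = 512, seed = 12,
                    label_noise = noise, missingness = 0)
  co <- label_cohort(generate_cohort(cfg))
  dis <- mean(co$label != co$true_state)
  se <- sqrt(noise * (1 - noise) / 1000)
  expect_lt(abs(dis - noise), 4 * se)
})

test_that("slides are deterministic under the seed and masks use only declared codes", {
  run <- small_cohort_run(n = 2, seed = 31)
  sl <- run$slides[[1]]
  cfg <- run$cfg
  sl2 <- generate_slide(run$cohort[1, ], cfg)
  ps2 <- lfbmil:::process_slide(run$cohort[1, ], pipeline_config(sim = cfg),
                                default_extractor(64))
  expect_identical(ps2$bag$features, sl$bag$features)
  expect_true(all(sl2$region_mask %in% 0:2))
  expect_true(all(c(1L, 2L) %in% sl2$region_mask))
  expect_equal(dim(sl2$image)[1:2], dim(sl2$region_mask))
  expect_true(all(sl2$true_tile_density >= 0 & sl2$true_tile_density <= 1))
  # pixel-identical regeneration
  sl3 <- generate_slide(run$cohort[1, ], cfg)
  expect_identical(sl2$image, sl3$image)
})

test_that("planted effect scales WM dark-blue density and is monotone", {
  wm_density <- function(effect, n = 50, seed = 77) {
    cfg <- sim_config(n_donors = n, slide_px = 512, seed = seed,
                      effect_size = effect, patchiness = 1,
                      label_noise = 0, missingness = 0, stain_gain_sd = 0)
    co <- generate_cohort(cfg)
    dens <- vapply(seq_len(n), function(i) {
      sl <- generate_slide(co[i, ], cfg)
      # dark pixels live only in WM; normalise their total by the WM area
      sum(sl$true_tile_density) * 256^2 / sum(sl$region_mask == 2L)
    }, numeric(1))
    list(ci = mean(dens[co$true_state == "CI"]),
         nci = mean(dens[co$true_state == "NCI"]))
  }
  d0 <- wm_density(0)
  # no planted effect: group means equal within Monte Carlo error
  expect_lt(abs(d0$ci - d0$nci) / d0$nci, 0.1)
  d15 <- wm_density(0.15)
  d30 <- wm_density(0.3)
  # ratio of planted densities ~ 1 - effect
  expect_lt(abs(d30$ci / d30$nci - 0.7), 0.05)
  # monotone decrease of the CI-group density with effect size
  expect_gt(d0$ci, d15$ci)
  expect_gt(d15$ci, d30$ci)
})

test_that("cohort and density CSV round-trips preserve the contracted columns", {
  cfg <- sim_config(n_donors = 5, slide_px = 512, seed = 2)
  co <- label_cohort(generate_cohort(cfg))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(names(back)[1:12],
               c("donor_id", "age", "sex", "cdr", "mmse", "clinical_dx",
                 "braak", "cerad", "artag", "cvd", "region", "slide_path"))
  expect_equal(back$donor_id, co$donor_id)
  sl <- generate_slide(co[1, ], cfg)
  fd <- tempfile(fileext = ".csv")
  write_true_density_csv(list(sl), fd)
  dd <- read.csv(fd)
  expect_equal(nrow(dd), length(sl$true_tile_density))
  expect_equal(dd$true_density[dd$tile_row == 0 & dd$tile_col == 0],
               sl$true_tile_density[1, 1])
  unlink(c(f, fd))
})

test_that("slide PNG and mask round-trips are value-faithful", {
  cfg <- sim_config(n_donors = 2, slide_px = 512, seed = 3)
  co <- generate_cohort(cfg)
  sl <- generate_slide(co[1, ], cfg)
  fi <- tempfile(fileext = ".png"); fm <- tempfile(fileext = ".png")
  write_slide_png(sl, fi)
  write_mask_png(sl, fm)
  img <- read_slide_png(fi)
  expect_equal(dim(img), dim(sl$image))
  expect_lt(max(abs(img - round(sl$image))), 0.51)
  expect_identical(read_mask_png(fm), sl$region_mask)
  unlink(c(fi, fm))
})

test_that("two-piece slides carry both pieces in mask and segmentation", {
  cfg <- sim_config(n_donors = 1, slide_px = 1024, seed = 5, n_pieces = 2)
  co <- generate_cohort(cfg)
  sl <- generate_slide(co[1, ], cfg)
  # two disconnected tissue blobs: left and right halves both contain tissue
  half <- ncol(sl$region_mask) %/% 2
  expect_true(any(sl$region_mask[, 1:half] > 0))
  expect_true(any(sl$region_mask[, (half + 1):(2 * half)] > 0))
  mask <- segment_tissue(sl$image)
  expect_true(any(mask[, 1:half]) && any(mask[, (half + 1):(2 * half)]))
})
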