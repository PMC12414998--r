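test_that("subject parameters respect the group distribution and the seed", {
  cfg <- synthetic_config(n_subjects = 1000)
  sp <- gen_subject_params(cfg, seed = 9)
  expect_identical(sp, gen_subject_params(cfg, seed = 9))
  # law-of-large-numbers check on the raw-scale parameters
  se <- cfg$group_sd["v0"] / sqrt(1000)
  expect_lt(abs(mean(sp$v0) - cfg$group_mean["v0"]), 3 * se)
  expect_lt(abs(mean(sp$delta) - cfg$group_mean["delta"]),
            3 * cfg$group_sd["delta"] / sqrt(1000))
  expect_true(all(sp$A > 0 & sp$B > 0 & sp$t0 > 0))
  # zero group SDs collapse everyone onto the group mean
  cfg0 <- synthetic_config(n_subjects = 5,
                           group_sd = c(A = 0, B = 0, t0 = 0,
                                        v0 = 0, delta = 0))
  sp0 <- gen_subject_params(cfg0, seed = 1)
  expect_equal(unname(diff(range(sp0$v0))), 0)
})

test_that("behaviour tables follow the block design and the drift link", {
  cfg <- synthetic_config(n_subjects = 2)
  sp <- gen_subject_params(cfg, seed = 3)
  beh <- gen_behavior(sp, cfg, seed = 3)
  one <- beh[beh$subject == "S01", ]
  expect_equal(nrow(one), 800)
  expect_equal(unname(table(one$block)), rep(100L, 8), ignore_attr = TRUE)
  # 50/50 directions within block, alternating cue blocks
  expect_true(all(tapply(one$direction == "flattened", one$block,
                         sum) == 50))
  expect_equal(unique(one$cue[one$block == 1]), "native")
  expect_equal(unique(one$cue[one$block == 2]), "novel")
  expect_true(all(beh$rt > 0))
  # determinism
  expect_identical(beh, gen_behavior(sp, cfg, seed = 3))
  # dominant drift forces the choice
  cfgbig <- synthetic_config(n_subjects = 1, n_blocks = 2,
                             trials_per_block = 20,
                             group_mean = c(A = 0.2, B = 1, t0 = 0.2,
                                            v0 = 6, delta = 40),
                             group_sd = c(A = 0, B = 0, t0 = 0, v0 = 0,
                                          delta = 0),
                             beta_eeg = 0)
  bb <- gen_behavior(gen_subject_params(cfgbig, seed = 1), cfgbig, seed = 1)
  expect_true(all(bb$choice[bb$direction == "flattened"] == "looming"))
  expect_true(all(bb$choice[bb$direction == "shaped"] == "receding"))
})

test_that("eeg amplitudes carry the condition pattern and link to behaviour", {
  cfg <- synthetic_config(n_subjects = 1, n_blocks = 250, amp_sd = 1)
  frame <- loomingbias:::design_cells(cfg)
  amp <- gen_eeg_amplitudes(frame, cfg, seed = 4)
  expect_identical(amp, gen_eeg_amplitudes(frame, cfg, seed = 4))
  means <- tapply(amp, paste(frame$cue, frame$direction, sep = "_"), mean)
  expect_lt(means["native_flattened"], means["native_shaped"])
  expect_lt(means["novel_shaped"], means["novel_flattened"])
  expect_equal(unname(means["native_flattened"]), -2, tolerance = 0.1)
  # beta = 0 decouples amplitude from behaviour
  cfg0 <- synthetic_config(n_subjects = 1, n_blocks = 24, beta_eeg = 0)
  beh0 <- gen_behavior(gen_subject_params(cfg0, seed = 5), cfg0, seed = 5)
  expect_lt(abs(stats::cor(beh0$eeg_amp, beh0$rt)), 0.05)
  # negative beta: more negative amplitudes speed up responses
  cfgn <- synthetic_config(n_subjects = 1, n_blocks = 24,
                           beta_eeg = -0.05)
  behn <- gen_behavior(gen_subject_params(cfgn, seed = 5), cfgn, seed = 5)
  expect_gt(stats::cor(behn$eeg_amp, behn$rt), 0)
})

test_that("erp epochs carry the injected contrast with baseline near zero", {
  cfg <- small_config()
  ep <- gen_erp_epochs(cfg, seed = 11)
  expect_identical(ep$data, gen_erp_epochs(cfg, seed = 11)$data)
  expect_equal(length(ep$data), 4)
  expect_equal(names(ep$data[[1]]),
               c("native_flattened", "native_shaped",
                 "novel_flattened", "novel_shaped"))
  # grand-mean baseline near zero
  sel <- ep$times < 0
  g <- mean(vapply(ep$data, function(s)
    mean(vapply(s, function(a) mean(a[, sel, ]), 0)), 0))
  expect_lt(abs(g), 0.1)
  # effect present in the window for native_flattened, absent for shaped
  lay <- ep$layout
  D <- as.matrix(dist(lay$positions))
  effch <- order(D[1, ])[1:5]
  win <- ep$times >= 0.08 & ep$times <= 0.17
  m_fl <- mean(vapply(ep$data, function(s)
    mean(s$native_flattened[effch, win, ]), 0))
  m_sh <- mean(vapply(ep$data, function(s)
    mean(s$native_shaped[effch, win, ]), 0))
  expect_lt(m_fl, m_sh)
  expect_equal(m_sh, 0, tolerance = 0.2)
})

test_that("the full bundle regenerates bit-identically", {
  cfg <- small_config()
  b1 <- simulate_bundle(cfg, seed = 12)
  b2 <- simulate_bundle(cfg, seed = 12)
  expect_identical(b1$behavior, b2$behavior)
  expect_identical(b1$epochs$data, b2$epochs$data)
  expect_identical(b1$localization, b2$localization)
  expect_identical(b1$subject_params, b2$subject_params)
  b3 <- simulate_bundle(cfg, seed = 13)
  expect_false(identical(b1$behavior$rt, b3$behavior$rt))
})

test_that("localization generator spans oracle to fully biased responders", {
  tg <- data.frame(target_lat = seq(-60, 60, by = 20),
                   target_pol = seq(-60, 200, length.out = 7))
  oracle <- gen_localization_responses(
    tg, list(gain = 1, bias_lat = 0, bias_pol = 0, scatter_lat = 0,
             scatter_pol = 0, confusion_rate = 0, confusion_center = 180),
    seed = 1)
  s <- score_trials(data.frame(target_lat = tg$target_lat,
                               target_pol = tg$target_pol,
                               resp_lat = oracle$resp_lat,
                               resp_pol = oracle$resp_pol))
  expect_equal(s$lateral_error, 0)
  expect_equal(s$quadrant_error_rate, 0)
  # gain 0 with polar bias 180: all responses at the rear
  rear <- gen_localization_responses(
    tg, list(gain = 0, bias_lat = 0, bias_pol = 180, scatter_lat = 0,
             scatter_pol = 0, confusion_rate = 0, confusion_center = 180),
    seed = 1)
  expect_true(all(abs(rear$resp_pol - 180) < 1e-9))
  sq <- score_trials(data.frame(target_lat = tg$target_lat,
                                target_pol = tg$target_pol,
                                resp_lat = rear$resp_lat,
                                resp_pol = rear$resp_pol))
  expect_equal(sq$quadrant_error_rate,
               100 * mean(polar_error(tg$target_pol, 180) > 90))
  # confusion-rate binomial check on frontal targets
  tgf <- data.frame(target_lat = rep(0, 10000), target_pol = rep(0, 10000))
  rc <- gen_localization_responses(
    tgf, list(gain = 1, bias_lat = 0, bias_pol = 0, scatter_lat = 0,
              scatter_pol = 0, confusion_rate = 0.3,
              confusion_center = 180), seed = 2)
  sc <- score_trials(data.frame(target_lat = 0, target_pol = 0,
                                resp_lat = rc$resp_lat,
                                resp_pol = rc$resp_pol))
  se <- 100 * sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(sc$quadrant_error_rate - 30), 3 * se + 0.5)
})
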