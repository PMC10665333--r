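test_that("dual-rate sampling: uniform indices, nesting, degenerate ratios", {
  s <- sample_dual_rate(32, t_x3d = 4, alpha = 4)
  expect_length(s$fast_idx, 16)
  expect_length(s$x3d_idx, 4)
  expect_true(all(diff(s$fast_idx) > 0))
  expect_true(all(s$x3d_idx %in% s$fast_idx))

  s1 <- sample_dual_rate(10, t_x3d = 5, alpha = 1)
  expect_identical(s1$fast_idx, s1$x3d_idx)

  # 25 fps, 2 s clip
  s2 <- sample_dual_rate(50, t_x3d = 8, alpha = 4)
  expect_length(s2$fast_idx, 32)
  expect_true(all(diff(s2$fast_idx) > 0))
  expect_lte(max(s2$fast_idx), 50)

  # short clips loop (wrap padding)
  s3 <- sample_dual_rate(5, t_x3d = 4, alpha = 2)
  expect_length(s3$fast_idx, 8)
  expect_true(all(s3$fast_idx <= 5))

  expect_error(sample_dual_rate(0, 4, 2), "empty")
})

test_that("profile invariants: full group counts, beta-scaled fast widths", {
  cfg <- x3dfast_profile("full")
  expect_identical(cfg$x3d_profile$stage_groups, c(3L, 5L, 11L, 7L))
  expect_identical(sum(cfg$x3d_profile$stage_groups), 26L)
  expect_identical(fast_channels(c(24, 48, 96, 192), 1 / 8), c(3L, 6L, 12L, 24L))
  expect_identical(cfg$fast_profile$stage_channels, c(3L, 6L, 12L, 24L))
  expect_identical(cfg$fast_profile$t_frames, 4L * cfg$x3d_profile$t_frames)
})

test_that("pathway forward: stage outputs shrink spatially, keep T, honor widths", {
  set.seed(30)
  prof <- pathway_profile(stage_groups = c(1, 1, 2, 1),
                          stage_channels = c(8, 12, 16, 24), t_frames = 4,
                          attention = TRUE)
  out <- x3d_pathway_forward(rand5(1, 4, 3, 32, 32), prof)
  expect_length(out, 4)
  hw <- vapply(out, function(o) dim(o$value)[4], numeric(1))
  expect_true(all(diff(hw) < 0))
  expect_identical(vapply(out, function(o) dim(o$value)[2], numeric(1)),
                   rep(4, 4))  # temporal invariance
  expect_identical(vapply(out, function(o) dim(o$value)[3], numeric(1)),
                   c(8, 12, 16, 24))
})

test_that("fast pathway keeps the input frame count at every stage", {
  set.seed(31)
  prof <- pathway_profile(stage_groups = c(1, 1, 1, 1),
                          stage_channels = c(4, 6, 8, 12), t_frames = 8,
                          conv_style = "r2plus1d")
  out <- fast_pathway_forward(rand5(1, 8, 3, 32, 32), prof)
  expect_identical(vapply(out, function(o) dim(o$value)[2], numeric(1)),
                   rep(8, 4))
})

test_that("group-count conservation and parameter ordering for the full profile", {
  set.seed(32)
  cfg <- x3dfast_profile("full")
  x3dp <- build_pathway(cfg$x3d_profile)
  fastp <- build_pathway(cfg$fast_profile)
  for (s in 1:4) {
    st <- x3dp$modules[[paste0("stage", s)]]
    expect_identical(sum(grepl("^group", names(st$modules))),
                     cfg$x3d_profile$stage_groups[s])
    expect_identical(sum(grepl("^action", names(st$modules))),
                     cfg$x3d_profile$stage_groups[s])  # attention after each group
  }
  expect_lt(n_params(fastp), n_params(x3dp))
})

test_that("disabling attention reproduces the plain pathway (ablation arm)", {
  prof_on <- pathway_profile(c(1, 1, 1, 1), c(4, 4, 4, 4), 4, attention = TRUE)
  prof_off <- prof_on; prof_off$attention <- FALSE
  set.seed(33); p_on <- build_pathway(prof_on)
  set.seed(33); p_off <- build_pathway(prof_off)
  act <- 0
  for (s in 1:4) {
    st <- p_on$modules[[paste0("stage", s)]]
    expect_identical(sum(grepl("^action", names(p_off$modules[[paste0("stage", s)]]$modules))), 0L)
    act <- act + sum(vapply(st$modules[grepl("^action", names(st$modules))],
                            n_params, numeric(1)))
  }
  expect_identical(n_params(p_on) - n_params(p_off), act)
  # frame-count contract is enforced
  expect_error(p_on$forward(ag_tensor(rand5(1, 3, 3, 16, 16))), "T = 4")
})
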