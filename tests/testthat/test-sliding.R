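test_that("bending energy vanishes on affine maps and is positive semidefinite", {
  set.seed(8)
  ref <- matrix(rnorm(24), 8, 3)
  be <- bending_energy(ref)
  # translation, uniform scaling, and a general affine map all cost nothing
  expect_equal(tps_energy(be, sweep(ref, 2, c(1, -2, 0.5), `+`)), 0,
               tolerance = 1e-8)
  expect_equal(tps_energy(be, ref * 3.7), 0, tolerance = 1e-8)
  A <- matrix(rnorm(9), 3, 3)
  expect_equal(tps_energy(be, ref %*% A), 0, tolerance = 1e-8)
  ev <- eigen(be$energy_matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # non-affine deformation costs energy
  bent <- ref; bent[1, ] <- bent[1, ] + c(0.5, 0, 0)
  expect_gt(tps_energy(be, bent), 1e-6)
  dup <- ref; dup[2, ] <- dup[1, ]
  expect_error(bending_energy(dup), "duplicate")
})

test_that("bending energy agrees with the independent interpolation-route evaluation", {
  set.seed(12)
  for (rep in 1:3) {
    ref <- matrix(rnorm(24), 8, 3)
    target <- ref + matrix(rnorm(24, sd = 0.3), 8, 3)
    be <- bending_energy(ref)
    expect_equal(tps_energy(be, target), tps_energy_interpolation(ref, target),
                 tolerance = 1e-8)
  }
})

test_that("a single semilandmark on a line converges to the closed-form quadratic minimum", {
  sch <- line_scheme()
  ref <- line_reference()
  target <- ref
  target[6, ] <- c(0.15, 0.2, 0)   # displaced along and off the curve tangent
  # tangent is the fixed segment direction (1, 0, 0); energy is an exact
  # quadratic in the slide coordinate t, minimised in closed form from
  # three evaluations
  be <- bending_energy(ref)
  energy_at <- function(t) {
    y <- target; y[6, 1] <- y[6, 1] + t
    tps_energy(be, y)
  }
  e0 <- energy_at(0); e1 <- energy_at(1); em <- energy_at(-1)
  a <- (e1 + em - 2 * e0) / 2
  t_star <- -(e1 - em) / (4 * a)
  slid <- slide_semilandmarks(target, sch, ref, damping = 0.1, tol = 1e-12,
                              max_iter = 2000)
  expect_equal(slid[6, 1], target[6, 1] + t_star, tolerance = 1e-6)
  expect_equal(slid[6, 2:3], target[6, 2:3])        # moved only along tangent
  expect_equal(slid[1:5, ], target[1:5, ])          # anchors never move
})

test_that("sliding applies the damping contract and descends monotonically", {
  sch <- labyrinth_scheme()
  tpl <- landmarks_to_array(make_template_labyrinth())[1, , ]
  set.seed(42)
  pert <- tpl + matrix(rnorm(length(tpl), sd = 0.02), nrow(tpl), 3)

  # reference identical to target: no sliding at all
  still <- slide_semilandmarks(tpl, sch, tpl, max_iter = 5)
  expect_equal(max(abs(still - tpl)), 0, tolerance = 1e-12)

  # first-iteration step with damping d equals d x the undamped step
  s_full <- slide_semilandmarks(pert, sch, tpl, damping = 1, max_iter = 1,
                                tol = 0) - pert
  s_damp <- slide_semilandmarks(pert, sch, tpl, damping = 0.1, max_iter = 1,
                                tol = 0) - pert
  expect_equal(s_damp, 0.1 * s_full, tolerance = 1e-12)

  # bending energy to the reference never increases between iterations
  be <- bending_energy(tpl)
  Y <- pert
  energies <- tps_energy(be, Y)
  for (i in 1:12) {
    Y <- slide_semilandmarks(Y, sch, tpl, damping = 0.1, max_iter = 1, tol = 0)
    energies <- c(energies, tps_energy(be, Y))
  }
  expect_true(all(diff(energies) <= 1e-12))

  # damping changes the path, not the optimum, on a convex case with a
  # fixed tangent (one semilandmark on a straight segment)
  lsch <- line_scheme()
  lref <- line_reference()
  ltar <- lref; ltar[6, ] <- c(0.2, 0.1, 0)
  lfull <- slide_semilandmarks(ltar, lsch, lref, damping = 1, tol = 1e-12,
                               max_iter = 1000)
  ldamp <- slide_semilandmarks(ltar, lsch, lref, damping = 0.1, tol = 1e-12,
                               max_iter = 5000)
  expect_equal(ldamp, lfull, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("joint sliding and alignment reduces consensus bending energy", {
  st <- small_study(seed = 6, n_species = 8, n_focal = 4)
  fit0 <- gpa(st$landmarks)
  be <- bending_energy(fit0$consensus)
  before <- sum(vapply(seq_len(8), function(i)
    tps_energy(be, fit0$aligned[i, , ]), numeric(1)))
  res <- slide_and_align(st$landmarks, max_outer = 3, slide_max_iter = 20)
  fit1 <- res$alignment
  be1 <- bending_energy(fit1$consensus)
  after <- sum(vapply(seq_len(8), function(i)
    tps_energy(be1, fit1$aligned[i, , ]), numeric(1)))
  expect_lt(after, before)
  expect_true(fit1$converged)
})
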