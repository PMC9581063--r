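# Voxel- and residue-level F1 evaluation with NA semantics.

test_that("f1_class reproduces hand-computed values and NA semantics", {
  # perfect prediction
  expect_equal(f1_class(c(1, 1, 0, 2), c(1, 1, 0, 2), 1L), 1)
  # TP = 8, FP = 2, FN = 4 -> F1 = 2*0.8*(2/3) / (0.8 + 2/3) = 0.7273
  pred <- c(rep(1, 8), rep(1, 2), rep(0, 4), rep(0, 6))
  true <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  expect_equal(f1_class(pred, true, 1L), 0.7273, tolerance = 1e-4)
  # class absent from truth and predictions: NA
  expect_true(is.na(f1_class(c(0, 1, 1), c(0, 1, 1), 2L)))
  # class predicted but absent from truth (or vice versa): 0, not NA
  expect_equal(f1_class(c(2, 0), c(0, 0), 2L), 0)
  expect_equal(f1_class(c(0, 0), c(2, 0), 2L), 0)
  # character labels and class names work the same way
  expect_equal(f1_class(c("helix", "other"), c("helix", "helix"), "helix"),
               2 / 3)
  expect_error(f1_class(c(0, 1), c(0, 1, 2), 1L), "length")
})

test_that("f1_class agrees with a confusion-matrix oracle on random labelings", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pred <- sample(0:2, n, replace = TRUE, prob = c(.6, .2, .2))
    true <- sample(0:2, n, replace = TRUE, prob = c(.6, .2, .2))
    for (cls in 0:2)
      expect_equal(f1_class(pred, true, cls), oracle_f1(pred, true, cls))
  }
})

test_that("vote_residue counts a 3 A sphere and applies helix > sheet > other ties", {
  # unanimous helix neighborhood
  g <- label_grid(array(1L, c(9, 9, 9)))
  expect_equal(vote_residue(g, c(4, 4, 4)), "helix")

  # constructed split vote: fill the 123-voxel sphere with 50 helix, 50
  # sheet, 23 background -> helix by tie priority
  dims <- c(9L, 9L, 9L)
  labs <- array(0L, dims)
  ctr <- c(4, 4, 4)
  in_sphere <- which(oracle_label_voxels(dims, c(0, 0, 0), c(1, 1, 1),
    data.frame(chain_id = "A", residue_number = 1, residue_name = "A",
               ss_class = "helix", x = 4, y = 4, z = 4)) == 1L)
  expect_length(in_sphere, 123L)
  labs[in_sphere[1:50]] <- 1L
  labs[in_sphere[51:100]] <- 2L
  expect_equal(vote_residue(label_grid(labs), ctr), "helix")

  # three-way 41/41/41 tie -> helix
  labs3 <- array(0L, dims)
  labs3[in_sphere[1:41]] <- 1L
  labs3[in_sphere[42:82]] <- 2L
  expect_equal(vote_residue(label_grid(labs3), ctr), "helix")

  # sheet/other tie without helix -> sheet (off-center sphere holds an even
  # 110 voxels: 55 sheet vs 55 background)
  gidx <- expand.grid(i = 0:8, j = 0:8, k = 0:8)
  d_off <- sqrt((gidx$i - 4.5)^2 + (gidx$j - 4)^2 + (gidx$k - 4)^2)
  in_off <- which(d_off <= 3)
  expect_length(in_off, 110L)
  labs4 <- array(0L, dims)
  labs4[in_off[1:55]] <- 2L
  expect_equal(vote_residue(label_grid(labs4), c(4.5, 4, 4)), "sheet")

  # Calpha outside the grid: "other" with a warning
  expect_warning(v <- vote_residue(g, c(50, 50, 50)), "voting 'other'")
  expect_equal(v, "other")
})

test_that("vote_residue matches the brute-force sphere-count oracle", {
  set.seed(17)
  for (rep in 1:12) {
    dims <- sample(7:12, 3, replace = TRUE)
    g <- random_label_grid(dims, origin = runif(3, -2, 2))
    ca <- g$origin + runif(3, 0, dims - 1)
    expect_equal(vote_residue(g, ca), oracle_vote(g, ca))
  }
})

test_that("evaluate_case combines voxel and residue scores with NA semantics", {
  ann <- rbind(make_helix(8, origin = c(0, 0, 0)),
               make_helix(6, origin = c(14, 0, 0), first_resno = 20L))
  map <- simulate_density(as.matrix(ann[, c("x", "y", "z")]),
                          resolution = 5, noise_sd = 0, seed = 2)
  truth <- label_voxels(map, ann)

  # perfect prediction: all defined F1s are 1, sheet F1s are NA (no sheet)
  r <- evaluate_case(truth, truth, ann, case_id = "perfect")
  expect_equal(r$f1_voxel_helix, 1)
  expect_equal(r$f1_residue_helix, 1)
  expect_true(is.na(r$f1_voxel_sheet))
  expect_true(is.na(r$f1_residue_sheet))
  expect_equal(r$n_helix, 14L)
  expect_equal(r$n_sheet, 0L)
  expect_equal(r$n_total, 14L)

  # all-background prediction on a case with helices: helix F1 = 0 (not NA)
  empty <- label_grid(array(0L, dim(truth$labels)), truth$origin,
                      truth$voxel_size)
  r0 <- evaluate_case(empty, truth, ann)
  expect_equal(r0$f1_voxel_helix, 0)
  expect_equal(r0$f1_residue_helix, 0)

  expect_error(
    evaluate_case(label_grid(array(0L, c(2, 2, 2))), truth, ann), "lattice")
})

test_that("residue-level F1 ignores voxels outside all Calpha neighborhoods", {
  ann <- make_helix(6)
  map <- simulate_density(as.matrix(ann[, c("x", "y", "z")]),
                          resolution = 5, noise_sd = 0, seed = 3)
  truth <- label_voxels(map, ann)
  pred <- truth
  # relabel voxels further than 3 A from every Calpha
  near <- asNamespace("cryosse")$sphere_mask(
    dim(truth$labels), truth$origin, truth$voxel_size,
    as.matrix(ann[, c("x", "y", "z")]), 3)
  scramble <- pred$labels
  scramble[!near] <- 2L
  pred$labels <- scramble
  r_base <- evaluate_case(truth, truth, ann)
  r_scrambled <- evaluate_case(pred, truth, ann)
  expect_equal(r_scrambled$f1_residue_helix, r_base$f1_residue_helix)
})

test_that("weighted_average weights per-case F1 by class residue counts", {
  cases <- data.frame(
    case_id = c("a", "b"),
    n_helix = c(10L, 30L), n_sheet = c(0L, 5L), n_total = c(10L, 35L),
    f1_voxel_helix = c(0.5, 0.5), f1_voxel_sheet = c(NA, 0.4),
    f1_residue_helix = c(0.8, 0.6), f1_residue_sheet = c(NA, 0.9))
  expect_equal(weighted_average(cases, "f1_residue_helix", "helix"), 0.65)
  # single contributing case (NA excluded): its own F1
  expect_equal(weighted_average(cases, "f1_residue_sheet", "sheet"), 0.9)
  # constant F1: the constant, regardless of weights
  expect_equal(weighted_average(cases, "f1_voxel_helix", "helix"), 0.5)
  # weighted average lies within the contributing range
  wa <- weighted_average(cases, "f1_residue_helix", "helix")
  expect_gte(wa, 0.6); expect_lte(wa, 0.8)
  cases$f1_residue_sheet <- NA_real_
  expect_error(weighted_average(cases, "f1_residue_sheet", "sheet"), "no case")
})

test_that("evaluate_cases summarizes per-case rows and weighted averages", {
  ann <- make_helix(8)
  map <- simulate_density(as.matrix(ann[, c("x", "y", "z")]),
                          resolution = 5, noise_sd = 0, seed = 9)
  truth <- label_voxels(map, ann)
  rep <- evaluate_cases(list(
    list(pred = truth, truth = truth, annotations = ann, case_id = "x"),
    list(pred = truth, truth = truth, annotations = ann, case_id = "y")))
  expect_equal(nrow(rep$cases), 2L)
  expect_equal(rep$summary$weighted_f1[rep$summary$metric == "f1_residue_helix"], 1)
  expect_true(is.na(
    rep$summary$weighted_f1[rep$summary$metric == "f1_residue_sheet"]))
})
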