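# Brute-force PCA oracle: eigen-decomposition of the feature covariance.
eigen_pca <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors,
       scores = Xc %*% e$vectors)
}

toy_library <- function(R = 50, M = 5, seed = 99) {
  set.seed(seed)
  feats <- t(vapply(seq_len(R), function(i) {
    g <- matrix(rexp(M * M), M, M)
    as.vector(g / sum(g))
  }, numeric(M * M)))
  structure(list(models = tibble::tibble(motif_id = rep(misa_motif_id(), R),
                                         motif_class = "mutual-repression"),
                 features = feats, representation = "probability",
                 M = M, floor = NA_real_),
            class = "landscape_library")
}

test_that("the fitted shape-space matches a brute-force covariance eigendecomposition", {
  lib <- toy_library()
  space <- fit_shape_space(lib, n_components = 3)
  oracle <- eigen_pca(lib$features)
  vf_oracle <- oracle$values / sum(oracle$values)
  expect_equal(space$var_fraction[1:5], vf_oracle[1:5], tolerance = 1e-8)
  # scores agree up to the frozen sign convention
  for (j in 1:3) {
    s_pkg <- sweep(lib$features, 2, space$mean) %*% space$rotation[, j]
    agree <- max(abs(s_pkg - oracle$scores[, j]))
    flipped <- max(abs(s_pkg + oracle$scores[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
  # variance fractions nonincreasing, in [0, 1], summing to <= 1
  expect_true(all(diff(space$var_fraction) <= 1e-12))
  expect_true(all(space$var_fraction >= 0 & space$var_fraction <= 1))
  expect_lte(sum(space$var_fraction), 1 + 1e-12)
})

test_that("projection is centered, complete, and representation-checked", {
  lib <- toy_library()
  space <- fit_shape_space(lib, 3)
  # the training mean projects to the origin
  mean_land <- coexpression_landscape(matrix(space$mean, lib$M) / sum(space$mean),
                                      "probability", "model")
  # scale back: construct exactly the mean vector
  mean_land$grid <- matrix(space$mean, lib$M)
  sc <- project_landscape(mean_land, space)
  expect_equal(unlist(sc), c(c1 = 0, c2 = 0, c3 = 0), tolerance = 1e-10)
  # reconstructing a training row from all components recovers it
  r <- 7
  all_scores <- project_landscape(library_landscape(lib, r), space, n_components = Inf)
  rec <- reconstruct_landscape(unlist(all_scores), space)
  expect_equal(rec, lib$features[r, ], tolerance = 1e-8)
  # identical landscapes get identical coordinates
  expect_equal(project_landscape(library_landscape(lib, 2), space),
               project_landscape(library_landscape(lib, 2), space))
  # representation mismatch is an error
  q <- quasipotential(library_landscape(lib, 1))
  expect_error(project_landscape(q, space), class = "coexland_error_representation")
})

test_that("a zero-variance library cannot define a shape-space", {
  lib <- toy_library(R = 10)
  lib$features <- matrix(rep(lib$features[1, ], 10), nrow = 10, byrow = TRUE)
  expect_error(fit_shape_space(lib, 2), class = "coexland_error_degenerate")
})

test_that("MISA quasipotential components order the archetype landscapes as expected", {
  space <- small_misa_space()
  expect_equal(space$representation, "quasipotential")
  ar <- archetype_landscapes(space$M, "quasipotential", floor = space$floor)
  sc <- purrr::map(ar, ~ unlist(project_landscape(.x, space)))
  # component 1 tracks overall expression: lo/lo < antagonistic < hi/hi
  expect_lt(sc$lo_lo["c1"], sc$antagonistic["c1"])
  expect_lt(sc$antagonistic["c1"], sc$hi_hi["c1"])
  # component 2 separates coexpression (positive, by sign convention)
  # from antagonistic expression (negative side)
  expect_gt(sc$hi_hi["c2"], 0)
  expect_lt(sc$antagonistic["c2"], sc$lo_lo["c2"])
  expect_lt(sc$antagonistic["c2"], 0)
  # component 3 captures asymmetry between the genes
  expect_gt(abs(sc$asymmetric["c3"]), abs(sc$hi_hi["c3"]) + 1)
  expect_gt(abs(sc$asymmetric["c3"]), abs(sc$antagonistic["c3"]) + 1)
})

test_that("motif occupancy groups cover the library and separate motif classes", {
  lib <- fixture("small_flex_lib", {
    grid <- flex_grid(g_hi = 1.1, h_a = c(0.01, 100), f_a = c(0.1, 100),
                      h_r = c(0.01, 100), f_r = c(0.1, 100), M = 12)
    compute_landscape_library(grid, "probability")
  })
  space <- fit_shape_space(lib, 3)
  occ <- motif_occupancy(space, lib)
  expect_equal(sort(unique(occ$motif_class)),
               c("incoherent", "mutual-activation", "mutual-repression",
                 "no-interaction"))
  expect_equal(nrow(occ), nrow(lib$features))
  # mutual activation cannot reach the extreme antagonistic (bistable
  # hi/lo-lo/hi) region: its maximal score along the direction of the
  # antagonistic archetype stays below mutual repression's
  ar <- archetype_landscapes(lib$M, "probability")
  a_sc <- unlist(project_landscape(ar$antagonistic, space))[1:2]
  u <- a_sc / sqrt(sum(a_sc^2))
  along <- as.matrix(occ[, c("c1", "c2")]) %*% u
  expect_lt(max(along[occ$motif_class == "mutual-activation"]),
            max(along[occ$motif_class == "mutual-repression"]))
  # unlabeled rows are rejected
  lib2 <- lib
  lib2$models$motif_class <- NULL
  expect_error(motif_occupancy(space, lib2), class = "coexland_error_args")
})

test_that("tidy and glance summarize a fitted shape-space", {
  space <- fit_shape_space(toy_library(), 3)
  td <- tidy(space)
  expect_true(all(c("component", "sdev", "var_fraction", "cum_fraction") %in% names(td)))
  expect_equal(td$cum_fraction, cumsum(td$var_fraction))
  gl <- glance(space)
  expect_equal(gl$n_components, 3L)
  expect_equal(gl$var_fraction_1, space$var_fraction[1])
})
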