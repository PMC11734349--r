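test_that("grid sizing reproduces the near-square rule", {
  d <- grid_dimensions(26795L)
  expect_equal(c(d$rows, d$cols, d$n_dummy), c(165L, 163L, 100L))
  expect_equal(unlist(grid_dimensions(9L)), c(rows = 3L, cols = 3L, n_dummy = 0L))
  expect_equal(unlist(grid_dimensions(11L)), c(rows = 4L, cols = 3L, n_dummy = 1L))
  expect_equal(unlist(grid_dimensions(1L)), c(rows = 1L, cols = 1L, n_dummy = 0L))
})

test_that("grid sizing is exact and row-major for every count up to 10000", {
  for (n in 1:10000) {
    d <- grid_dimensions(n)
    expect_true(d$rows * d$cols - d$n_dummy == n && d$rows >= d$cols,
                info = paste("n =", n))
  }
})

test_that("points at cell centres assign with zero cost", {
  centres <- cbind(rep(1:2, each = 2) - 0.5, rep(1:2, times = 2) - 0.5)
  # scale to arbitrary units; min-max normalisation restores the lattice
  gm <- assign_to_grid(centres * 3.7 + 11, 2L, 2L)
  expect_equal(gm$total_cost, 0, tolerance = 1e-12)
  expect_equal(nrow(gm$dummy_cells), 0L)
  expect_equal(anyDuplicated(gm$assignment), 0L)
})

test_that("assignments are injective with the right number of dummy cells", {
  set.seed(4)
  pts <- matrix(runif(14L), 7L, 2L)
  gm <- assign_to_grid(pts, 3L, 3L)
  cells <- paste(gm$assignment$row, gm$assignment$col)
  expect_equal(anyDuplicated(cells), 0L)
  expect_equal(nrow(gm$dummy_cells), 2L)
  expect_length(intersect(cells, paste(gm$dummy_cells$row,
                                       gm$dummy_cells$col)), 0L)
  expect_error(assign_to_grid(pts, 2L, 3L), "too small")
})

test_that("assignment cost equals factorial brute force for small instances", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:6, 1L)
    dims <- grid_dimensions(n)
    rows <- dims$rows; cols <- dims$cols
    pts <- matrix(runif(2L * n), n, 2L)
    gm <- assign_to_grid(pts, rows, cols)
    norm01 <- function(v, hi) {
      r <- range(v); if (diff(r) == 0 || hi == 1) rep(hi / 2, length(v))
      else 0.5 + (v - r[1L]) / diff(r) * (hi - 1)
    }
    x <- norm01(pts[, 1L], rows); y <- norm01(pts[, 2L], cols)
    cr <- rep(seq_len(rows), each = cols); cc <- rep(seq_len(cols), rows)
    cost <- outer(x, cr - 0.5, "-")^2 + outer(y, cc - 0.5, "-")^2
    ncell <- rows * cols
    best <- min(vapply(all_perms(seq_len(ncell)), function(p) {
      sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    }, numeric(1)))
    expect_equal(gm$total_cost, best, tolerance = 1e-10)
  }
})

test_that("2D embedding is deterministic and separates planted clusters", {
  set.seed(10)
  V <- rbind(matrix(rnorm(25L * 12L, 0), 25L, 12L),
             matrix(rnorm(25L * 12L, 9), 25L, 12L),
             matrix(rnorm(25L * 12L, -9), 25L, 12L))
  c1 <- embed_2d(V, seed = 3L, max_iter = 250L)
  c2 <- embed_2d(V, seed = 3L, max_iter = 250L)
  expect_equal(dim(c1), c(75L, 2L))
  expect_identical(c1, c2)
  lab <- rep(1:3, each = 25L)
  centroids <- t(vapply(1:3, function(k) colMeans(c1[lab == k, ]),
                        numeric(2)))
  intra <- mean(vapply(1:3, function(k)
    mean(dist(c1[lab == k, ])), numeric(1)))
  inter <- mean(dist(centroids))
  expect_gt(inter, intra)
})

test_that("small embeddings reduce perplexity and tiny inputs error", {
  set.seed(11)
  V <- matrix(rnorm(5L * 4L), 5L, 4L)
  expect_warning(coords <- embed_2d(V, seed = 1L, max_iter = 50L),
                 "perplexity")
  expect_equal(dim(coords), c(5L, 2L))
  expect_error(embed_2d(V[1:2, ], seed = 1L), "at least 3")
})

test_that("property layers report the documented structural facts", {
  pl <- property_layers(c("*c1ccccc1", "*C1CCCCC1", "*C", "*C(=O)O",
                          "*c1ccc2ccccc2c1"))
  expect_named(pl, c("fragment_smiles", "MW", "LogP", "TPSA", "heavy_atoms",
                     "aromatic_rings", "Fsp3"))
  expect_equal(pl$aromatic_rings, c(1L, 0L, 0L, 0L, 2L))
  expect_equal(pl$Fsp3, c(0, 1, 1, 0, 0))
  expect_equal(pl$heavy_atoms, c(6L, 6L, 1L, 3L, 10L))
  expect_true(all(is.finite(pl$MW)))
  expect_gt(pl$TPSA[4L], 0)
  expect_warning(bad <- property_layers(c("*C", "C1CC")), "unparsable")
  expect_true(is.na(bad$MW[2L]))
})

test_that("a grid map built from a model carries fragments and layers", {
  set.seed(12)
  frags <- c("*C", "*CC", "*CCC", "*O", "*OC", "*N", "*F", "*Cl", "*Br",
             "*C#N", "*c1ccccc1", "*C(=O)O")
  vecs <- matrix(rnorm(length(frags) * 16L), length(frags), 16L,
                 dimnames = list(frags, NULL))
  gm <- suppressWarnings(build_grid_map(vecs, seed = 2L, max_iter = 120L))
  expect_s3_class(gm, "grid_map")
  expect_equal(nrow(gm$assignment), length(frags))
  expect_equal(gm$assignment$fragment_smiles, frags)
  expect_equal(nrow(gm$layers), length(frags))
  expect_true(all(!is.na(gm$layers$MW)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_map(gm, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(frags))
  expect_true(all(c("fragment_smiles", "row", "col", "MW", "Fsp3") %in%
                    names(tab)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(gm, layer = "MW"))
  expect_error(plot(gm, layer = "nope"), "no such layer")
})
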